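# Score tables are delimited text (comma or tab, sniffed from the header
# line) with a header row: sample_id, then one column per class label.
# Floats are written with 10 significant digits, so write/read round-trips
# are stable.

#' Read a classifier's score table
#'
#' @param path delimited text file (comma- or tab-separated, sniffed), UTF-8,
#'   with header `sample_id` followed by one column per class label.
#' @return a validated [prob_matrix()]; row order is preserved and rows with
#'   sums off one by at most `1e-6` are renormalised with a warning.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(first) == 0L)
    stop("empty score table: ", path, call. = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          encoding = "UTF-8", comment.char = "",
                          quote = "\"")
  if (ncol(df) < 3L)
    stop(sprintf("%s: need a sample_id column and >= 2 class columns", path),
         call. = FALSE)
  if (names(df)[1L] != "sample_id")
    stop(sprintf("%s: first header field must be 'sample_id', got '%s'",
                 path, names(df)[1L]), call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[1L]
    stop(sprintf("%s: duplicate sample_id '%s' at data line %d", path,
                 ids[dup], dup), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, names(df)[-1L]))
  if (any(is.na(vals))) {
    i <- which(is.na(vals))[1L]
    r <- (i - 1L) %% nrow(vals) + 1L
    stop(sprintf("%s: non-numeric value at data line %d", path, r),
         call. = FALSE)
  }
  pm <- tryCatch(
    prob_matrix(vals, sample_ids = ids, class_labels = names(df)[-1L]),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  pm
}

#' Write a score table
#'
#' @param pm a [prob_matrix()] (or coercible).
#' @param path output file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_score_table <- function(pm, path, sep = ",") {
  pm <- .as_prob_matrix(pm)
  txt <- apply(unclass(pm), 1:2, function(v) formatC(v, digits = 10,
                                                     format = "g"))
  lines <- c(paste(c("sample_id", colnames(pm)), collapse = sep),
             paste(rownames(pm), apply(txt, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a labels file
#'
#' Two-column delimited text: `sample_id`, `label`.
#'
#' @param path file path.
#' @return named character vector of labels (names are sample ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "sample_id")
    stop(sprintf("%s: expected header 'sample_id%slabel'", path, sep),
         call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname read_labels
#' @param labels named vector (names = sample ids) of class labels.
#' @param sep field separator.
#' @export
write_labels <- function(labels, path, sep = ",") {
  lines <- c(paste(c("sample_id", "label"), collapse = sep),
             paste(names(labels), as.character(labels), sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ensemble manifest
#'
#' The manifest names the classifiers to fuse. JSON and YAML dialects are
#' both accepted (chosen by file extension, falling back to content
#' sniffing). Required structure: a `classifiers` list whose entries have
#' `id` (unique), `path` (score table, relative paths resolved against the
#' manifest's directory) and `accuracy` in `(0, 1]`; optional `labels`
#' (path), `positive_class`, and `options` (e.g. `accuracy_policy`,
#' `"manifest"` or `"out-of-fold"`).
#'
#' @param path manifest file (`.json`, `.yaml`/`.yml`).
#' @return list with normalised fields; score-table paths are made absolute.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
    if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt, simplifyVector = FALSE)
    else yaml::yaml.load(txt)
  }
  if (is.null(m$classifiers) || length(m$classifiers) < 1L)
    stop(sprintf("%s: manifest needs a non-empty 'classifiers' list", path),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  ids <- character(0)
  for (i in seq_along(m$classifiers)) {
    e <- m$classifiers[[i]]
    if (is.null(e$id) || is.null(e$path) || is.null(e$accuracy))
      stop(sprintf("%s: classifier entry %d needs id, path, accuracy",
                   path, i), call. = FALSE)
    a <- as.numeric(e$accuracy)
    if (!is.finite(a) || a <= 0 || a > 1)
      stop(sprintf("%s: classifier '%s': accuracy %s outside (0, 1]",
                   path, e$id, format(e$accuracy)), call. = FALSE)
    m$classifiers[[i]]$accuracy <- a
    m$classifiers[[i]]$path <- resolve(as.character(e$path))
    ids <- c(ids, as.character(e$id))
  }
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate classifier ids: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  if (!is.null(m$labels)) m$labels <- resolve(as.character(m$labels))
  if (is.null(m$options)) m$options <- list()
  if (is.null(m$options$accuracy_policy))
    m$options$accuracy_policy <- "manifest"
  m
}

#' @rdname read_manifest
#' @param manifest manifest list as documented above (paths may be relative).
#' @export
write_manifest <- function(manifest, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(manifest, path)
  } else {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Serialise a metrics report (or fold table) as JSON
#'
#' @param x a `"metrics_report"`, a `"dsfuse_cv"` result, or a plain list.
#' @param path output file.
#' @export
write_metrics_json <- function(x, path) {
  if (inherits(x, "metrics_report")) {
    x <- unclass(x)
  } else if (inherits(x, "dsfuse_cv")) {
    x <- list(per_fold = x$per_fold, mean = as.list(x$mean),
              agreement_rate = x$agreement_rate,
              accuracy_policy = x$accuracy_policy)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Load the score tables and accuracies referenced by a manifest.
.load_manifest_inputs <- function(manifest) {
  tables <- lapply(manifest$classifiers, function(e) read_score_table(e$path))
  names(tables) <- vapply(manifest$classifiers, `[[`, character(1), "id")
  acc <- vapply(manifest$classifiers, `[[`, numeric(1), "accuracy")
  list(tables = .check_aligned(tables), accuracies = acc)
}
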