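# Independent oracles, written directly from the defining formulas and kept
# free of the package's code paths.

# Closed-form Sugeno subset measure: g(A) = (prod_{i in A}(1 + lambda g_i) - 1)
# / lambda for lambda != 0, sum of densities for lambda = 0.
oracle_subset_measure <- function(g, lambda, subset) {
  if (length(subset) == 0L) return(0)
  if (lambda == 0) return(sum(g[subset]))
  (prod(1 + lambda * g[subset]) - 1) / lambda
}

# Brute-force Choquet integral from the sorted-difference definition, using
# the closed-form subset measures above.
oracle_choquet <- function(values, g, lambda) {
  C <- length(values)
  ord <- order(-values, seq_len(C))
  v <- c(values[ord], 0)
  total <- 0
  for (k in seq_len(C)) {
    total <- total + (v[k] - v[k + 1]) * oracle_subset_measure(g, lambda,
                                                               ord[seq_len(k)])
  }
  total
}

# Direct elementwise transforms, for cross-checking the vectorised paths.
oracle_deviation <- function(p) 1 - exp(-(p - 1)^2 / 2)
oracle_support <- function(p) 1 - tanh((p - 1)^2 / 2)

# Small aligned binary probability tables for C classifiers.
make_tables <- function(probs_class1, class_labels = c("0", "1"),
                        ids = NULL) {
  lapply(probs_class1, function(p1) {
    n <- length(p1)
    if (is.null(ids)) ids <- paste0("s", seq_len(n))
    prob_matrix(cbind(p1, 1 - p1), sample_ids = ids,
                class_labels = class_labels)
  })
}

# Random aligned tables: C classifiers, n samples, N classes.
random_tables <- function(C, n, N, seed) {
  set.seed(seed)
  lapply(seq_len(C), function(c) {
    m <- matrix(stats::rgamma(n * N, shape = 1), n, N)
    prob_matrix(m / rowSums(m),
                sample_ids = paste0("s", seq_len(n)),
                class_labels = as.character(seq_len(N) - 1L))
  })
}
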