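# Independent brute-force oracle: plug-in mutual information computed by
# dense enumeration of ALL 2^m joint bit patterns (feasible for m <= 10).
# Deliberately shares no code with the package's sparse pattern counting.
brute_force_mi <- function(values, labels) {
  m <- ncol(values)
  stopifnot(m <= 10L)
  n <- nrow(values)
  all_patterns <- as.matrix(expand.grid(rep(list(0:1), m)))
  row_key <- apply(values, 1L, paste, collapse = "")
  pat_key <- apply(all_patterns, 1L, paste, collapse = "")
  mi <- 0
  for (p in pat_key) {
    in_p <- row_key == p
    px <- sum(in_p) / n
    if (px == 0) next
    for (y in 0:1) {
      pxy <- sum(in_p & labels == y) / n
      py <- sum(labels == y) / n
      if (pxy > 0) mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# Random activity set / collection with non-degenerate labels.
random_activity_set <- function(n_compounds, n_features, target_id = "t1",
                                prevalence = NULL) {
  if (is.null(prevalence)) prevalence <- runif(1, 0.2, 0.8)
  values <- matrix(rbinom(n_compounds * n_features, 1L, prevalence),
                   n_compounds, n_features,
                   dimnames = list(sprintf("c%d", seq_len(n_compounds)),
                                   sprintf("fp:%d", seq_len(n_features))))
  labels <- rbinom(n_compounds, 1L, runif(1, 0.2, 0.8))
  while (length(unique(labels)) < 2L) {
    labels <- rbinom(n_compounds, 1L, 0.5)
  }
  activity_set(bit_matrix(values), labels, target_id)
}

random_collection <- function(n_compounds, n_features, k = 1L) {
  universe_names <- sprintf("fp:%d", seq_len(n_features))
  sets <- lapply(seq_len(k), function(i) {
    a <- random_activity_set(n_compounds, n_features, sprintf("t%d", i))
    a
  })
  target_collection(sets)
}

# Small deterministic collection where the label equals one planted bit and
# the remaining bits are noise; used by the CV tests.
perfect_bit_collection <- function(n = 200, n_noise = 4, active_frac = 0.1,
                                   seed = 42) {
  withr::with_seed(seed, {
    labels <- as.integer(seq_len(n) <= round(n * active_frac))
    labels <- sample(labels)
    noise <- matrix(rbinom(n * n_noise, 1L, 0.5), n, n_noise)
    values <- cbind(labels, noise)
    dimnames(values) <- list(sprintf("c%d", seq_len(n)),
                             c("perfect:1", sprintf("noise:%d",
                                                    seq_len(n_noise))))
    target_collection(list(activity_set(bit_matrix(values), labels, "tgt")))
  })
}
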