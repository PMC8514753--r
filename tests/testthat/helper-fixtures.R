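# Shared fixture builders. Everything is generated in code; no files.

dlabs <- function(n) sprintf("D%03d", seq_len(n))
mlabs <- function(n) sprintf("M%03d", seq_len(n))

# random symmetric nonnegative kernel with unit diagonal
random_kernel <- function(n, side = "disease", labels = NULL) {
  if (is.null(labels)) {
    labels <- if (side == "disease") dlabs(n) else mlabs(n)
  }
  M <- matrix(runif(n * n), n, n)
  K <- (M + t(M)) / 2
  diag(K) <- 1
  sim_kernel(K, labels = labels, side = side)
}

# random binary association matrix guaranteed nonzero
random_assoc <- function(nd, nm, p = 0.3) {
  repeat {
    vals <- matrix(rbinom(nd * nm, 1, p), nd, nm)
    if (sum(vals) > 0) break
  }
  assoc_matrix(vals, dlabs(nd), mlabs(nm))
}

# the 3x3 kernel used in several worked examples
toy_kernel3 <- function(side = "disease") {
  sim_kernel(matrix(c(1, .9, .1,
                      .9, 1, .2,
                      .1, .2, 1), 3, 3, byrow = TRUE),
             labels = if (side == "disease") dlabs(3) else mlabs(3),
             side = side)
}

# identity 2x2 association toy (diseases x miRNAs)
toy_assoc2 <- function() assoc_matrix(diag(2), dlabs(2), mlabs(2))

# constant-off-diagonal 2x2 similarity kernel
toy_kernel2 <- function(offdiag, side = "disease") {
  K <- matrix(offdiag, 2, 2)
  diag(K) <- 1
  sim_kernel(K, labels = if (side == "disease") dlabs(2) else mlabs(2),
             side = side)
}

# small synthetic benchmark for end-to-end tests that need speed
small_benchmark <- function(seed = 42L) {
  generate_benchmark(synthetic_spec(nd = 20L, nm = 25L, rank = 3L,
                                    density = 0.12, kernel_noise_sd = 0.05,
                                    seed = seed))
}

# fast pipeline configuration for protocol-level tests
fast_config <- function(...) {
  pipeline_config(fusion = fusion_params(k_neighbors = 5),
                  wknkn = wknkn_params(K = 3),
                  lp = lp_params(k_neighbors = 5, ...))
}
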