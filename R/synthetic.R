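#' Synthetic benchmark specification
#'
#' Parameters of the planted-structure generator: entity counts, latent
#' rank, association density, per-side kernel count and the noise level of
#' the similarity kernels. Defaults define the package's reference
#' benchmark conditions.
#'
#' @param nd,nm numbers of diseases and miRNAs (each `>= rank`).
#' @param rank latent dimension of the planted low-rank structure.
#' @param density fraction of pairs set to 1, in `(0, 1)`.
#' @param kernel_noise_sd standard deviation of the symmetric Gaussian
#'   noise added to each similarity kernel.
#' @param kernels_per_side number of noisy kernels generated per side.
#' @param seed integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nd = 60L, nm = 80L, rank = 4L, density = 0.08,
                           kernel_noise_sd = 0.1, kernels_per_side = 3L,
                           seed = 42L) {
  stopifnot(rank >= 1, nd >= rank, nm >= rank,
            density > 0, density < 1,
            kernel_noise_sd >= 0, kernels_per_side >= 1)
  structure(list(nd = as.integer(nd), nm = as.integer(nm),
                 rank = as.integer(rank), density = density,
                 kernel_noise_sd = kernel_noise_sd,
                 kernels_per_side = as.integer(kernels_per_side),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-structure benchmark
#'
#' Draws nonnegative latent factors `U` (`nd x rank`) and `V`
#' (`nm x rank`) from a Gamma(2, 1) distribution, plants the score matrix
#' `P = U %*% t(V)`, and sets the top `density` fraction of pairs to 1 to
#' form the binary association matrix. Each similarity kernel is the
#' cosine similarity of the corresponding side's latent rows plus
#' symmetric zero-mean Gaussian noise, clipped to `[0, 1]` with the
#' diagonal forced to 1 — so the kernels are informative about the planted
#' structure, mimicking the assumption that similar entities share
#' association partners. Because a purely global top-fraction cut
#' routinely leaves low-magnitude entities with no association at the
#' default density, the selection is repaired deterministically: every
#' isolated entity receives its highest-scoring pair, and the
#' lowest-scoring planted pairs whose removal isolates nobody are trimmed
#' so the total count stays at the target density. Fully reproducible
#' from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `assoc` (an [assoc_matrix()]), `disease_kernels`,
#'   `mirna_kernels` (lists of [sim_kernel()]), `planted` (the real-valued
#'   planted score matrix).
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dlab <- sprintf("D%03d", seq_len(spec$nd))
  mlab <- sprintf("M%03d", seq_len(spec$nm))
  withr::with_seed(spec$seed, {
    U <- matrix(stats::rgamma(spec$nd * spec$rank, shape = 2, rate = 1),
                spec$nd, spec$rank)
    V <- matrix(stats::rgamma(spec$nm * spec$rank, shape = 2, rate = 1),
                spec$nm, spec$rank)
    P <- U %*% t(V)
    npos <- max(1L, round(spec$density * spec$nd * spec$nm))
    A <- plant_top_fraction(P, npos)
    if (any(rowSums(A) == 0) || any(colSums(A) == 0)) {
      stop("generated association matrix has an isolated entity", call. = FALSE)
    }
    dimnames(A) <- list(dlab, mlab)
    dimnames(P) <- list(dlab, mlab)
    make_kernels <- function(latent, labels, side) {
      unit <- latent / sqrt(rowSums(latent^2))
      base <- tcrossprod(unit)
      lapply(seq_len(spec$kernels_per_side), function(i) {
        n <- nrow(base)
        E <- matrix(stats::rnorm(n * n, sd = spec$kernel_noise_sd), n, n)
        E <- (E + t(E)) / 2
        K <- pmin(pmax(base + E, 0), 1)
        diag(K) <- 1
        sim_kernel(K, labels = labels, side = side)
      })
    }
    list(assoc = assoc_matrix(A),
         disease_kernels = make_kernels(U, dlab, "disease"),
         mirna_kernels = make_kernels(V, mlab, "mirna"),
         planted = P)
  })
}

# Plant the top `npos` pairs of a score matrix as associations, with a
# deterministic coverage repair so no row or column ends up all-zero.
plant_top_fraction <- function(P, npos) {
  vals <- matrix(0, nrow(P), ncol(P))
  vals[order(P, decreasing = TRUE)[seq_len(npos)]] <- 1
  repeat {
    zr <- which(rowSums(vals) == 0)
    zc <- which(colSums(vals) == 0)
    if (length(zr) == 0 && length(zc) == 0) break
    for (i in zr) vals[i, which.max(P[i, ])] <- 1
    zc <- which(colSums(vals) == 0)
    for (j in zc) vals[which.max(P[, j]), j] <- 1
    # trim lowest-scoring planted pairs whose removal isolates nobody
    excess <- sum(vals) - npos
    if (excess > 0) {
      ones <- which(vals == 1)
      for (idx in ones[order(P[ones])]) {
        if (excess == 0) break
        rc <- arrayInd(idx, dim(vals))
        if (sum(vals[rc[1], ]) > 1 && sum(vals[, rc[2]]) > 1) {
          vals[idx] <- 0
          excess <- excess - 1
        }
      }
    }
  }
  vals
}

#' Mask a random subset of known associations
#'
#' Zeroes a uniformly random fraction of the known pairs, returning the
#' masked training matrix and the held-out pair list for recovery tests.
#'
#' @param A a binary [assoc_matrix()].
#' @param fraction fraction of known pairs to mask, in `(0, 1)` (at least
#'   one pair is always masked).
#' @param seed integer seed.
#' @return A list: `train` (an [assoc_matrix()]) and `held_out` (data
#'   frame with columns `disease`, `mirna`, `row`, `col`).
#' @export
mask_positives <- function(A, fraction, seed = 1L) {
  stopifnot(inherits(A, "assoc_matrix"), fraction > 0, fraction < 1)
  if (!all(A$values %in% c(0, 1))) {
    stop("mask_positives requires a binary association matrix", call. = FALSE)
  }
  pos <- which(A$values == 1)
  nmask <- max(1L, round(fraction * length(pos)))
  masked <- withr::with_seed(as.integer(seed), sample(pos, nmask))
  train_vals <- A$values
  train_vals[masked] <- 0
  if (all(train_vals == 0)) {
    stop("masking removed every known association", call. = FALSE)
  }
  rc <- arrayInd(masked, dim(A$values))
  list(train = assoc_matrix(train_vals,
                            disease_labels = A$disease_labels,
                            mirna_labels = A$mirna_labels),
       held_out = data.frame(disease = A$disease_labels[rc[, 1]],
                             mirna = A$mirna_labels[rc[, 2]],
                             row = rc[, 1], col = rc[, 2],
                             stringsAsFactors = FALSE))
}
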