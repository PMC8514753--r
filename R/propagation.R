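#' Local affinity (KNN-sparsified, row-stochastic kernel)
#'
#' For each entity, keeps only its `k` most similar entities excluding
#' itself (`Q_i`) and row-normalizes over them:
#' `aff(i, j) = K(i, j) / sum_{l in Q_i} K(i, l)` for `j` in `Q_i`, zero
#' elsewhere. The diagonal is always zero; self-retention is handled by
#' the `(1 - gamma)` term of the propagation, not by the affinity. Rows
#' whose neighbor mass is zero stay entirely zero.
#'
#' @param K a [sim_kernel()].
#' @param k neighborhood size (clipped to `n - 1`).
#' @return A row-oriented [stoch_kernel()].
#' @export
local_affinity <- function(K, k) {
  stopifnot(inherits(K, "sim_kernel"), k >= 1)
  n <- nrow(K$values)
  nbrs <- neighbor_sets(K, min(as.integer(k), n - 1L), include_self = FALSE)
  aff <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Qi <- nbrs$neighbors[[i]]
    mass <- sum(K$values[i, Qi])
    if (mass == 0) next
    aff[i, Qi] <- K$values[i, Qi] / mass
  }
  stoch_kernel(aff, labels = K$labels, orientation = "row")
}

#' One-sided label propagation
#'
#' Spreads association labels over one side's local affinity graph. With
#' source matrix `Y` (the association matrix for the disease side, its
#' transpose for the miRNA side) and `X_0 = Y`, the default `"as_printed"`
#' iteration is
#'
#' `X_t = gamma * aff %*% Y + (1 - gamma) * X_{t-1}`
#'
#' a linear recursion with constant source whose iterates admit the closed
#' form `X_t = (1 - gamma)^t * Y + (1 - (1 - gamma)^t) * aff %*% Y` and
#' contract with factor `(1 - gamma)`. `"recurrent"` mode instead
#' propagates the previous iterate
#' (`X_t = gamma * aff %*% X_{t-1} + (1 - gamma) * Y`), the conventional
#' label-propagation update. Iteration stops when the maximum absolute
#' change between successive label matrices falls below `tolerance` (or at
#' `max_iterations`, with a warning). The side's score matrix is the sum
#' of all iterates `X_0 + X_1 + ... + X_k`, final iterate included.
#'
#' @param aff a row-oriented [stoch_kernel()] over the chosen side.
#' @param A an [assoc_matrix()].
#' @param side `"disease"` or `"mirna"`.
#' @param params [lp_params()].
#' @return A list: `score` (numeric matrix, `nd x nm` for the disease
#'   side, `nm x nd` for the miRNA side) and `state` (fields `iteration`,
#'   `converged`).
#' @export
propagate_side <- function(aff, A, side = c("disease", "mirna"),
                           params = lp_params()) {
  side <- match.arg(side)
  stopifnot(inherits(aff, "stoch_kernel"), inherits(A, "assoc_matrix"),
            inherits(params, "lp_params"))
  target <- if (side == "disease") A$disease_labels else A$mirna_labels
  if (!identical(aff$labels, target)) {
    stop(sprintf("affinity labels are not aligned with the association matrix on the %s side",
                 side), call. = FALSE)
  }
  Y <- if (side == "disease") A$values else t(A$values)
  gamma <- params$gamma
  X <- Y
  score <- Y                       # X_0
  affY <- aff$values %*% Y         # constant source term of as_printed mode
  iteration <- 0L
  converged <- FALSE
  for (t in seq_len(params$max_iterations)) {
    Xnew <- if (params$mode == "as_printed") {
      gamma * affY + (1 - gamma) * X
    } else {
      gamma * (aff$values %*% X) + (1 - gamma) * Y
    }
    delta <- max(abs(Xnew - X))
    score <- score + Xnew
    X <- Xnew
    iteration <- t
    if (delta < params$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("label propagation (%s side) did not converge in %d iterations",
                    side, params$max_iterations))
  }
  list(score = score,
       state = list(iteration = iteration, converged = converged))
}

#' Ensemble of the two directional score matrices
#'
#' `F = alpha * F_d + (1 - alpha) * t(F_m)`: the disease-side scores are
#' combined with the transposed miRNA-side scores.
#'
#' @param Fd numeric `nd x nm` score matrix from the disease side.
#' @param Fm numeric `nm x nd` score matrix from the miRNA side.
#' @param params [lp_params()] (uses `alpha`).
#' @return A numeric `nd x nm` matrix.
#' @export
ensemble_scores <- function(Fd, Fm, params = lp_params()) {
  stopifnot(inherits(params, "lp_params"))
  if (!identical(dim(Fd), rev(dim(Fm)))) {
    stop("score matrices have incompatible shapes", call. = FALSE)
  }
  params$alpha * Fd + (1 - params$alpha) * t(Fm)
}

#' Full prediction pipeline
#'
#' Runs the complete method on an association matrix and optional
#' precomputed similarity kernels:
#' \enumerate{
#'   \item compute the Gaussian interaction profile kernel on each side
#'     from `A`;
#'   \item fuse (provided kernels + GIP kernel) per side with
#'     [skf_fuse()];
#'   \item densify `A` with [wknkn_update()] using the fused kernels;
#'   \item build KNN local affinities from the fused kernels and run
#'     [propagate_side()] in both directions on the densified matrix;
#'   \item combine the two score matrices with [ensemble_scores()].
#' }
#'
#' All internal computation happens in a canonical (sorted-label) entity
#' order and the result is mapped back to the caller's order, so the
#' output is exactly equivariant under joint relabeling permutations of
#' the inputs.
#'
#' @param A an [assoc_matrix()] with at least one known association.
#' @param disease_kernels,mirna_kernels lists of precomputed
#'   [sim_kernel()]s (possibly empty; labels must cover `A`'s).
#' @param config a [pipeline_config()].
#' @return A numeric `nd x nm` score matrix with `A`'s dimnames and
#'   attributes `fd_state`, `fm_state`, `fusion_iterations`.
#' @export
fuselp_predict <- function(A, disease_kernels = list(), mirna_kernels = list(),
                           config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- align_inputs(A, disease_kernels, mirna_kernels)
  # canonical entity order: makes every internal reduction independent of
  # the caller's label ordering (bitwise permutation equivariance)
  od <- order(bundle$assoc$disease_labels, method = "radix")
  om <- order(bundle$assoc$mirna_labels, method = "radix")
  Ac <- assoc_matrix(bundle$assoc$values[od, om, drop = FALSE])
  dk <- lapply(bundle$disease_kernels, function(k) {
    sim_kernel(k$values[od, od, drop = FALSE], side = "disease")
  })
  mk <- lapply(bundle$mirna_kernels, function(k) {
    sim_kernel(k$values[om, om, drop = FALSE], side = "mirna")
  })

  gd <- gip_kernel(Ac, "disease", config$gip)
  gm <- gip_kernel(Ac, "mirna", config$gip)
  SD <- skf_fuse(c(dk, list(gd)), config$fusion)
  SM <- skf_fuse(c(mk, list(gm)), config$fusion)
  A2 <- wknkn_update(Ac, SD, SM, config$wknkn)
  aff_d <- local_affinity(SD, config$lp$k_neighbors)
  aff_m <- local_affinity(SM, config$lp$k_neighbors)
  fd <- propagate_side(aff_d, A2, "disease", config$lp)
  fm <- propagate_side(aff_m, A2, "mirna", config$lp)
  Fc <- ensemble_scores(fd$score, fm$score, config$lp)

  # back to the caller's order
  id <- match(bundle$assoc$disease_labels, bundle$assoc$disease_labels[od])
  im <- match(bundle$assoc$mirna_labels, bundle$assoc$mirna_labels[om])
  out <- Fc[id, im, drop = FALSE]
  dimnames(out) <- dimnames(bundle$assoc$values)
  attr(out, "fd_state") <- fd$state
  attr(out, "fm_state") <- fm$state
  attr(out, "fusion_iterations") <- c(disease = attr(SD, "iterations"),
                                      mirna = attr(SM, "iterations"))
  out
}
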