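#' Column-normalize a similarity kernel
#'
#' `P(i, j) = K(i, j) / sum_k K(k, j)`: each column sums to one. This is
#' the initial state of the fusion diffusion.
#'
#' @param K a [sim_kernel()] with no all-zero column.
#' @return A column-oriented [stoch_kernel()].
#' @export
normalize_kernel <- function(K) {
  stopifnot(inherits(K, "sim_kernel"))
  cs <- colSums(K$values)
  zero <- which(cs == 0)
  if (length(zero) > 0) {
    stop(sprintf("cannot normalize kernel: all-zero column for entity '%s'",
                 K$labels[zero[1]]), call. = FALSE)
  }
  stoch_kernel(sweep(K$values, 2L, cs, "/"), labels = K$labels,
               orientation = "column")
}

#' K-nearest-neighbor sets of a similarity kernel
#'
#' For each entity, the `k` highest-similarity entities in descending
#' similarity order, ties broken by ascending index. When `include_self` is
#' `TRUE` the entity itself is always a member (counting toward `k`); when
#' `FALSE` it is always excluded.
#'
#' @param K a [sim_kernel()].
#' @param k neighborhood size (clipped, with a warning, when it exceeds
#'   the number of available candidates).
#' @param include_self logical.
#' @return An object of class `neighbor_index`: fields `neighbors` (list
#'   of integer vectors), `k`, `include_self`.
#' @export
neighbor_sets <- function(K, k, include_self = TRUE) {
  stopifnot(inherits(K, "sim_kernel"), k >= 1)
  n <- nrow(K$values)
  k <- as.integer(k)
  avail <- if (include_self) n else n - 1L
  if (k > avail) {
    warning(sprintf("k = %d exceeds the %d available candidates; clipping",
                    k, avail))
    k <- avail
  }
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    sims <- K$values[i, ]
    cand <- seq_len(n)
    if (include_self) {
      others <- cand[cand != i]
      # stable radix order: ties fall back to ascending index
      ord <- others[order(sims[others], decreasing = TRUE, method = "radix")]
      neighbors[[i]] <- c(i, ord[seq_len(k - 1L)])
    } else {
      others <- cand[cand != i]
      ord <- others[order(sims[others], decreasing = TRUE, method = "radix")]
      neighbors[[i]] <- ord[seq_len(min(k, length(ord)))]
    }
  }
  structure(list(neighbors = neighbors, k = k, include_self = include_self),
            class = "neighbor_index")
}

#' Neighbor-constraint kernel
#'
#' Row-normalizes a kernel over each entity's neighbor set (built with the
#' entity itself included): `C(i, j) = K(i, j) / sum_{l in N_i} K(i, l)`
#' for `j` in `N_i`, zero elsewhere. Rows with zero neighbor mass are left
#' entirely zero with a warning.
#'
#' @param K a [sim_kernel()].
#' @param nbrs a `neighbor_index` built from `K` with `include_self = TRUE`.
#' @return A row-oriented [stoch_kernel()].
#' @export
neighbor_constraint_kernel <- function(K, nbrs) {
  stopifnot(inherits(K, "sim_kernel"), inherits(nbrs, "neighbor_index"))
  if (!nbrs$include_self) {
    stop("neighbor-constraint kernel requires neighbor sets that include self",
         call. = FALSE)
  }
  n <- nrow(K$values)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Ni <- nbrs$neighbors[[i]]
    mass <- sum(K$values[i, Ni])
    if (mass == 0) {
      warning(sprintf("entity '%s' has zero neighbor mass; row left zero",
                      K$labels[i]))
      next
    }
    C[i, Ni] <- K$values[i, Ni] / mass
  }
  stoch_kernel(C, labels = K$labels, orientation = "row")
}

#' Similarity kernel fusion
#'
#' Cross-diffuses 2-3 similarity kernels of one side into a single fused
#' kernel. Each kernel is column-normalized (`P_n`) and row-normalized
#' over its k-nearest neighborhood including self (`C_n`); the iteration
#'
#' `P_n <- beta * C_n %*% mean(P_t, t != n) %*% t(C_n) +
#'         (1 - beta) * mean(P_t^0, t != n)`
#'
#' runs synchronously over all kernels until the largest elementwise
#' change drops below `tolerance` (or `max_iterations`). The iterates are
#' averaged into an overall kernel, which is then masked elementwise by
#' the mutual-neighborhood weight matrix `W` (1 for mutual neighbors, 0.5
#' for one-way, 0 otherwise; built from the overall kernel's
#' neighborhoods) and symmetrized.
#'
#' @param kernels list of 2-3 [sim_kernel()] objects, same side and
#'   labels. A single kernel is returned column-normalized and symmetrized
#'   (fusion is degenerate).
#' @param params [fusion_params()].
#' @return A [sim_kernel()] with attributes `iterations` and `converged`.
#' @export
skf_fuse <- function(kernels, params = fusion_params()) {
  stopifnot(inherits(params, "fusion_params"), length(kernels) >= 1)
  lapply(kernels, function(k) stopifnot(inherits(k, "sim_kernel")))
  side <- kernels[[1]]$side
  labels <- kernels[[1]]$labels
  for (k in kernels[-1]) {
    if (k$side != side || !identical(k$labels, labels)) {
      stop("all kernels must share side and label order; align them first",
           call. = FALSE)
    }
  }
  n <- length(labels)
  k_use <- min(params$k_neighbors, n - 1L)
  if (length(kernels) == 1L) {
    P <- normalize_kernel(kernels[[1]])$values
    out <- sim_kernel((P + t(P)) / 2, labels = labels, side = side)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }
  count <- length(kernels)
  P0 <- lapply(kernels, function(k) normalize_kernel(k)$values)
  C <- lapply(kernels, function(k) {
    neighbor_constraint_kernel(k, neighbor_sets(k, k_use, include_self = TRUE))$values
  })
  # mean of the initial normalized kernels excluding kernel n (constant term)
  others0 <- lapply(seq_len(count), function(nn) {
    Reduce(`+`, P0[-nn]) / (count - 1L)
  })
  P <- P0
  iterations <- 0L
  converged <- FALSE
  for (l in seq_len(params$max_iterations)) {
    Pnew <- vector("list", count)
    for (nn in seq_len(count)) {
      othersl <- Reduce(`+`, P[-nn]) / (count - 1L)
      Pnew[[nn]] <- params$beta * (C[[nn]] %*% othersl %*% t(C[[nn]])) +
        (1 - params$beta) * others0[[nn]]
    }
    delta <- max(vapply(seq_len(count),
                        function(nn) max(abs(Pnew[[nn]] - P[[nn]])), 0))
    P <- Pnew
    iterations <- l
    if (delta < params$tolerance) {
      converged <- TRUE
      break
    }
  }
  overall <- Reduce(`+`, P) / count
  overall_sym <- (overall + t(overall)) / 2
  overall_kernel <- sim_kernel(overall_sym, labels = labels, side = side)
  W <- mutual_neighbor_weights(neighbor_sets(overall_kernel, k_use,
                                             include_self = TRUE))
  fused <- W * overall_sym
  fused <- (fused + t(fused)) / 2
  out <- sim_kernel(fused, labels = labels, side = side)
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' Mutual-neighborhood weight matrix
#'
#' `W(i, j)` is 1 when `i` and `j` are in each other's neighbor sets, 0.5
#' when the membership is one-way, and 0 otherwise. With self-inclusive
#' neighborhoods the diagonal is 1.
#'
#' @param nbrs a `neighbor_index`.
#' @return A numeric matrix with entries in `{0, 0.5, 1}`.
#' @export
mutual_neighbor_weights <- function(nbrs) {
  stopifnot(inherits(nbrs, "neighbor_index"))
  n <- length(nbrs$neighbors)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) M[i, nbrs$neighbors[[i]]] <- 1
  (M + t(M)) / 2
}

#' Average fusion baseline
#'
#' Elementwise mean of the input kernels; the simple integration baseline
#' against which cross-diffusion fusion is compared.
#'
#' @param kernels nonempty list of [sim_kernel()] objects sharing side and
#'   labels.
#' @return A [sim_kernel()].
#' @export
average_fuse <- function(kernels) {
  if (length(kernels) == 0) stop("average_fuse requires at least one kernel", call. = FALSE)
  lapply(kernels, function(k) stopifnot(inherits(k, "sim_kernel")))
  labels <- kernels[[1]]$labels
  side <- kernels[[1]]$side
  for (k in kernels[-1]) {
    if (k$side != side || !identical(k$labels, labels)) {
      stop("all kernels must share side and label order", call. = FALSE)
    }
  }
  vals <- Reduce(`+`, lapply(kernels, `[[`, "values")) / length(kernels)
  sim_kernel(vals, labels = labels, side = side)
}
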