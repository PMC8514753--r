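#' Entities with at least one known association
#'
#' "Verified" entities in the k-nearest-known-neighbor sense: rows (or
#' columns) of the association matrix with at least one nonzero entry.
#'
#' @param A an [assoc_matrix()].
#' @param side `"disease"` or `"mirna"`.
#' @return Integer vector of indices.
#' @export
known_entities <- function(A, side = c("disease", "mirna")) {
  side <- match.arg(side)
  stopifnot(inherits(A, "assoc_matrix"))
  idx <- if (side == "disease") which(rowSums(A$values) > 0)
         else which(colSums(A$values) > 0)
  unname(idx)
}

#' Neighborhood-reconstructed interaction profiles for one side
#'
#' For each entity `r`, takes its `K` most similar entities among those
#' with at least one known association (the query itself excluded;
#' descending similarity, index tie-break), weights the `i`-th neighbor's
#' profile by `t^(i-1) * S(i, r)` and divides by the sum of the selected
#' neighbors' similarities (undecayed, as the procedure is printed — so
#' with `decay < 1` the reconstruction is deliberately shrunk). Entities
#' with no verified neighbor, or zero similarity to all of them, get a
#' zero profile.
#'
#' @param A an [assoc_matrix()].
#' @param S a [sim_kernel()] aligned with `A` on that side.
#' @param side `"disease"` (reconstruct rows) or `"mirna"` (columns).
#' @param params [wknkn_params()].
#' @return A numeric `nd x nm` matrix.
#' @export
side_profiles <- function(A, S, side = c("disease", "mirna"),
                          params = wknkn_params()) {
  side <- match.arg(side)
  stopifnot(inherits(A, "assoc_matrix"), inherits(S, "sim_kernel"),
            inherits(params, "wknkn_params"))
  target <- if (side == "disease") A$disease_labels else A$mirna_labels
  if (!identical(S$labels, target)) {
    stop(sprintf("similarity kernel is not aligned with the association matrix on the %s side",
                 side), call. = FALSE)
  }
  known <- known_entities(A, side)
  out <- matrix(0, nrow(A$values), ncol(A$values),
                dimnames = dimnames(A$values))
  n <- length(target)
  for (r in seq_len(n)) {
    cand <- setdiff(known, r)
    if (length(cand) == 0) next
    sims <- S$values[r, cand]
    ord <- cand[order(sims, decreasing = TRUE, method = "radix")]
    sel <- ord[seq_len(min(params$K, length(ord)))]
    s_sel <- S$values[r, sel]
    normalizer <- sum(s_sel)
    if (normalizer == 0) next
    w <- params$decay^(seq_along(sel) - 1L) * s_sel
    if (side == "disease") {
      prof <- crossprod(w, A$values[sel, , drop = FALSE])[1, ] / normalizer
      out[r, ] <- prof
    } else {
      prof <- (A$values[, sel, drop = FALSE] %*% w)[, 1] / normalizer
      out[, r] <- prof
    }
  }
  out
}

#' Combine disease- and miRNA-derived profiles
#'
#' Weighted convex combination
#' `A_md = (delta_disease * AD + delta_mirna * AM) / (delta_disease + delta_mirna)`.
#'
#' @param AD,AM numeric matrices of identical shape.
#' @param params [wknkn_params()].
#' @return A numeric matrix.
#' @export
combine_profiles <- function(AD, AM, params = wknkn_params()) {
  stopifnot(inherits(params, "wknkn_params"))
  if (!identical(dim(AD), dim(AM))) {
    stop("profile matrices have mismatched shapes", call. = FALSE)
  }
  (params$delta_disease * AD + params$delta_mirna * AM) /
    (params$delta_disease + params$delta_mirna)
}

#' Weighted k-nearest known neighbor update
#'
#' Densifies a sparse binary association matrix: reconstructs every
#' entity's interaction profile from its nearest verified neighbors on
#' both sides ([side_profiles()]), combines the two reconstructions
#' ([combine_profiles()]), and takes the elementwise maximum with the
#' original matrix so that known associations are always preserved.
#'
#' @param A an [assoc_matrix()].
#' @param SD,SM disease and miRNA [sim_kernel()]s aligned with `A`.
#' @param params [wknkn_params()].
#' @return An [assoc_matrix()] with entries in `[0, 1]`, elementwise
#'   `>= A`.
#' @export
wknkn_update <- function(A, SD, SM, params = wknkn_params()) {
  AD <- side_profiles(A, SD, "disease", params)
  AM <- side_profiles(A, SM, "mirna", params)
  A_md <- combine_profiles(AD, AM, params)
  assoc_matrix(pmax(A$values, A_md),
               disease_labels = A$disease_labels,
               mirna_labels = A$mirna_labels)
}
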