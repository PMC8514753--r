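#' Gaussian interaction profile kernel
#'
#' Similarity between two entities computed from their interaction
#' profiles (rows of the association matrix for diseases, columns for
#' miRNAs):
#' `K(i, j) = exp(-rho * ||profile_i - profile_j||^2)`, with the effective
#' bandwidth `rho` obtained by dividing the base bandwidth by the mean
#' squared profile norm over all entities on that side. Entities sharing an
#' identical profile get similarity 1; the diagonal is exactly 1.
#'
#' @param A an [assoc_matrix()] with at least one known association
#'   (otherwise the bandwidth normalizer is zero).
#' @param side `"disease"` (profiles are rows of `A`) or `"mirna"`
#'   (columns).
#' @param params [gip_params()].
#' @return A [sim_kernel()] with attribute `bandwidth` holding the
#'   effective `rho`.
#' @export
gip_kernel <- function(A, side = c("disease", "mirna"), params = gip_params()) {
  side <- match.arg(side)
  stopifnot(inherits(A, "assoc_matrix"), inherits(params, "gip_params"))
  profiles <- if (side == "disease") A$values else t(A$values)
  labels <- if (side == "disease") A$disease_labels else A$mirna_labels
  base <- if (side == "disease") params$bandwidth_disease else params$bandwidth_mirna
  mean_sq_norm <- mean(rowSums(profiles^2))
  if (mean_sq_norm == 0) {
    stop("association matrix has no known associations: GIP bandwidth is degenerate (division by zero)",
         call. = FALSE)
  }
  rho <- base / mean_sq_norm
  d2 <- as.matrix(stats::dist(profiles, method = "euclidean"))^2
  values <- exp(-rho * d2)
  diag(values) <- 1
  out <- sim_kernel(values, labels = labels, side = side)
  attr(out, "bandwidth") <- rho
  out
}
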