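#' Labeled disease-by-miRNA association matrix
#'
#' Container for the bipartite adjacency matrix `A` (diseases in rows,
#' miRNAs in columns). On ingest from a database export every entry is 0/1;
#' after neighborhood-based densification ([wknkn_update()]) entries lie in
#' `[0, 1]`. Row `i` is the interaction profile of disease `i`; column `j`
#' the interaction profile of miRNA `j`.
#'
#' @param values numeric matrix, `nd x nm`, entries in `[0, 1]`.
#' @param disease_labels character vector of unique row identifiers
#'   (defaults to `rownames(values)`).
#' @param mirna_labels character vector of unique column identifiers
#'   (defaults to `colnames(values)`).
#'
#' @return An object of class `assoc_matrix` with fields `values`,
#'   `disease_labels`, `mirna_labels`.
#' @export
assoc_matrix <- function(values,
                         disease_labels = rownames(values),
                         mirna_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(disease_labels) || is.null(mirna_labels)) {
    stop("assoc_matrix requires disease and miRNA labels", call. = FALSE)
  }
  disease_labels <- as.character(disease_labels)
  mirna_labels <- as.character(mirna_labels)
  check_labels(disease_labels, nrow(values), "disease")
  check_labels(mirna_labels, ncol(values), "miRNA")
  if (any(!is.finite(values))) {
    stop("association matrix contains non-finite values", call. = FALSE)
  }
  if (any(values < 0) || any(values > 1)) {
    stop("association values must lie in [0, 1]", call. = FALSE)
  }
  dimnames(values) <- list(disease_labels, mirna_labels)
  structure(
    list(values = values,
         disease_labels = disease_labels,
         mirna_labels = mirna_labels),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d diseases x %d miRNAs, %d known associations\n",
              nrow(x$values), ncol(x$values), sum(x$values == 1)))
  invisible(x)
}

#' Labeled square similarity kernel
#'
#' A symmetric nonnegative similarity matrix over one side of the bipartite
#' network (all diseases, or all miRNAs). Semantic, functional, sequence and
#' Gaussian interaction profile kernels, as well as fused kernels, are all
#' carried in this container.
#'
#' @param values square numeric matrix, symmetric within `1e-10`,
#'   nonnegative and finite.
#' @param labels character vector of unique entity identifiers.
#' @param side `"disease"` or `"mirna"`.
#'
#' @return An object of class `sim_kernel`.
#' @export
sim_kernel <- function(values, labels = rownames(values),
                       side = c("disease", "mirna")) {
  side <- match.arg(side)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop("similarity kernel must be square", call. = FALSE)
  }
  if (is.null(labels)) stop("similarity kernel requires labels", call. = FALSE)
  labels <- as.character(labels)
  check_labels(labels, nrow(values), side)
  if (any(!is.finite(values))) {
    stop("similarity kernel contains non-finite values", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("similarity kernel contains negative values", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-10) {
    stop(sprintf("similarity kernel is not symmetric (max |K - t(K)| = %g)",
                 asym), call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, side = side),
            class = "sim_kernel")
}

#' @export
print.sim_kernel <- function(x, ...) {
  cat(sprintf("<sim_kernel> %s side, %d x %d\n",
              x$side, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Row- or column-stochastic kernel
#'
#' A normalized kernel where every vector along the stochastic orientation
#' sums to one (or is entirely zero, for an isolated entity). Column
#' orientation holds the normalized kernels `P_n`; row orientation holds
#' neighbor-constraint kernels `C_n` and local affinities.
#'
#' @param values square numeric nonnegative matrix.
#' @param labels entity identifiers.
#' @param orientation `"row"` or `"column"`.
#' @return An object of class `stoch_kernel`.
#' @export
stoch_kernel <- function(values, labels = rownames(values),
                         orientation = c("row", "column")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop("stochastic kernel must be square", call. = FALSE)
  }
  labels <- as.character(labels)
  check_labels(labels, nrow(values), "entity")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("stochastic kernel entries must be finite and nonnegative",
         call. = FALSE)
  }
  sums <- if (orientation == "row") rowSums(values) else colSums(values)
  bad <- abs(sums - 1) > 1e-10 & sums != 0
  if (any(bad)) {
    stop(sprintf("stochastic kernel %ss do not sum to 1 (e.g. %s: %g)",
                 orientation, labels[which(bad)[1]], sums[which(bad)[1]]),
         call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, orientation = orientation),
            class = "stoch_kernel")
}

#' @export
print.stoch_kernel <- function(x, ...) {
  cat(sprintf("<stoch_kernel> %s-stochastic, %d x %d\n",
              x$orientation, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# shared label validation: uniqueness + length
check_labels <- function(labels, n, what) {
  if (length(labels) != n) {
    stop(sprintf("%s labels (%d) do not match matrix dimension (%d)",
                 what, length(labels), n), call. = FALSE)
  }
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s labels: %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
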