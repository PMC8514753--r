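#' Read a labeled numeric matrix from TSV
#'
#' Expects one header row of column labels and a first column of row
#' labels; the body must be fully numeric and finite. Square matrices read
#' with `expect_square = TRUE` must carry identical row and column labels
#' in identical order.
#'
#' @param path TSV file path (tab-separated, UTF-8, `.` decimal).
#' @param expect_square require a square matrix with matching row/column
#'   labels.
#' @return A numeric matrix with `dimnames`.
#' @seealso [read_association_matrix()], [read_similarity_kernel()],
#'   [write_labeled_matrix()]
#' @export
read_labeled_matrix <- function(path, expect_square = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("labeled matrix needs at least one data column", call. = FALSE)
  row_labels <- raw[[1]]
  col_labels <- colnames(raw)[-1]
  check_labels(row_labels, nrow(raw), "row")
  check_labels(col_labels, ncol(raw) - 1L, "column")
  values <- matrix(NA_real_, nrow(raw), length(col_labels))
  for (j in seq_along(col_labels)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.finite(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or non-finite value '%s' at row '%s', column '%s'",
                   cell[bad[1]], row_labels[bad[1]], col_labels[j]),
           call. = FALSE)
    }
    values[, j] <- num
  }
  dimnames(values) <- list(row_labels, col_labels)
  if (expect_square) {
    if (nrow(values) != ncol(values)) {
      stop("expected a square matrix", call. = FALSE)
    }
    if (!identical(row_labels, col_labels)) {
      stop("square matrix row labels do not match column labels", call. = FALSE)
    }
  }
  values
}

#' Write a labeled numeric matrix to TSV
#'
#' Values are written with 12 significant digits, tab-separated, `.`
#' decimal, UTF-8.
#'
#' @param x numeric matrix with `dimnames`, or an [assoc_matrix()] /
#'   [sim_kernel()] / [stoch_kernel()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path) {
  if (inherits(x, c("assoc_matrix", "sim_kernel", "stoch_kernel"))) {
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must carry row and column labels", call. = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v) paste(sprintf("%.12g", v), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a binary association matrix
#'
#' @param path TSV path (diseases in rows, miRNAs in columns).
#' @return An [assoc_matrix()]; every entry must be 0 or 1.
#' @export
read_association_matrix <- function(path) {
  values <- read_labeled_matrix(path, expect_square = FALSE)
  if (!all(values %in% c(0, 1))) {
    stop("association matrix must be binary (0/1) on ingest", call. = FALSE)
  }
  assoc_matrix(values)
}

#' Read a similarity kernel
#'
#' @param path TSV path of a square labeled similarity matrix.
#' @param side `"disease"` or `"mirna"`.
#' @return A [sim_kernel()].
#' @export
read_similarity_kernel <- function(path, side = c("disease", "mirna")) {
  side <- match.arg(side)
  values <- read_labeled_matrix(path, expect_square = TRUE)
  sim_kernel(values, side = side)
}

#' Align similarity kernels to an association matrix
#'
#' Reorders (and subsets) each kernel so that entry `[i, j]` refers to the
#' same entity pair as the association matrix's label order. Every kernel
#' must cover all entities present in the association matrix; surplus
#' entities are dropped and reported.
#'
#' @param A an [assoc_matrix()].
#' @param disease_kernels,mirna_kernels lists of [sim_kernel()] objects.
#' @return A list with fields `assoc`, `disease_kernels`, `mirna_kernels`
#'   and `dropped` (per-side list of labels removed from the kernels).
#' @export
align_inputs <- function(A, disease_kernels = list(), mirna_kernels = list()) {
  stopifnot(inherits(A, "assoc_matrix"))
  align_side <- function(kernels, target, side) {
    dropped <- character(0)
    aligned <- lapply(kernels, function(k) {
      stopifnot(inherits(k, "sim_kernel"))
      if (k$side != side) {
        stop(sprintf("kernel side '%s' does not match expected '%s'",
                     k$side, side), call. = FALSE)
      }
      missing <- setdiff(target, k$labels)
      if (length(missing) > 0) {
        stop(sprintf("%s kernel is missing labels present in the association matrix: %s",
                     side, paste(missing, collapse = ", ")), call. = FALSE)
      }
      dropped <<- union(dropped, setdiff(k$labels, target))
      idx <- match(target, k$labels)
      sim_kernel(k$values[idx, idx, drop = FALSE], labels = target, side = side)
    })
    list(kernels = aligned, dropped = dropped)
  }
  d <- align_side(disease_kernels, A$disease_labels, "disease")
  m <- align_side(mirna_kernels, A$mirna_labels, "mirna")
  list(assoc = A,
       disease_kernels = d$kernels,
       mirna_kernels = m$kernels,
       dropped = list(disease = d$dropped, mirna = m$dropped))
}
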