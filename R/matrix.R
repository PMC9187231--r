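#' Construct a contact matrix object
#'
#' @param counts symmetric non-negative numeric matrix of binned cis
#'   contacts (diagonal counted once).
#' @param chrom chromosome name.
#' @param bin_size_bp bin size in bp.
#' @param normalized `FALSE` for raw counts, or the name of the applied
#'   normalization (e.g. `"VC_SQRT"`).
#' @param total_read_pairs total read pairs behind the matrix, used for
#'   depth scaling in the loop caller; defaults to the matrix mass.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(counts, chrom = "chrS", bin_size_bp,
                           normalized = FALSE, total_read_pairs = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stopf("counts must be a square matrix")
  }
  if (any(counts < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8) {
    stopf("counts must be symmetric")
  }
  if (is.null(total_read_pairs)) {
    ut <- counts[upper.tri(counts)]
    total_read_pairs <- round(sum(ut, na.rm = TRUE) +
                                sum(diag(counts), na.rm = TRUE))
  }
  structure(list(
    chrom = chrom,
    bin_size_bp = as.integer(bin_size_bp),
    counts = counts,
    normalized = normalized,
    total_read_pairs = as.numeric(total_read_pairs)
  ), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %d bp, %s, %.0f read pairs\n",
              x$chrom, nrow(x$counts), x$bin_size_bp,
              if (identical(x$normalized, FALSE)) "raw"
              else paste0("normalized (", x$normalized, ")"),
              x$total_read_pairs))
  invisible(x)
}

#' Coverage (sqrt) normalization of a contact matrix
#'
#' Vanilla-coverage square-root balancing: each entry is divided by the
#' square root of the product of its row and column sums,
#' `N[i,j] = M[i,j] / sqrt(r_i * r_j)`. Bins with zero coverage produce
#' missing values rather than division errors.
#'
#' A single pass (the reference normalization) halves the exponent of a
#' multiplicative per-bin bias `b_i * b_j`; iterating the update is
#' Sinkhorn balancing and converges to a matrix from which any planted
#' rank-1 bias is removed entirely. `iterations = 1` is the default used
#' throughout the analyses.
#'
#' @param M a raw `contact_matrix`.
#' @param iterations number of balancing passes (default 1).
#' @return a `contact_matrix` with `normalized = "VC_SQRT"`.
#' @export
vc_sqrt_normalize <- function(M, iterations = 1L) {
  stopifnot(inherits(M, "contact_matrix"))
  C <- M$counts
  if (all(rowSums(C, na.rm = TRUE) == 0)) {
    warning("all-zero contact matrix: normalization yields all-missing output")
  }
  for (it in seq_len(iterations)) {
    r <- rowSums(C, na.rm = TRUE)
    C <- C / sqrt(outer(r, r))
    C[!is.finite(C)] <- NA_real_
  }
  out <- M
  out$counts <- C
  out$normalized <- "VC_SQRT"
  out
}

#' Log2 ratio map between two matched contact matrices
#'
#' `R[i,j] = log2((A[i,j] + pc) / (B[i,j] + pc))`. The two matrices must
#' share shape and bin size and should be normalized and depth-matched.
#'
#' @param A,B `contact_matrix` objects of identical shape.
#' @param pseudocount stabilising pseudocount; default is the mean pixel
#'   value of the two matrices (the normalized mass spread over all bins).
#' @return numeric matrix of log2 ratios.
#' @export
ratio_map <- function(A, B, pseudocount = NULL) {
  stopifnot(inherits(A, "contact_matrix"), inherits(B, "contact_matrix"))
  if (!all(dim(A$counts) == dim(B$counts)) ||
      A$bin_size_bp != B$bin_size_bp) {
    stopf("ratio_map: matrices must have identical shape and bin size")
  }
  if (is.null(pseudocount)) {
    pseudocount <- mean(c(A$counts, B$counts), na.rm = TRUE)
  }
  log2((A$counts + pseudocount) / (B$counts + pseudocount))
}

#' Mean contact intensity per diagonal
#'
#' Average pixel value at each bin separation, i.e. the matrix-level
#' distance-decay profile (per-pixel, so unaffected by the shrinking
#' number of pixels at long range).
#'
#' @param M a `contact_matrix`.
#' @param max_sep_bins largest separation to report.
#' @return data.frame with `sep_bins` and `mean_count`.
#' @export
mean_diagonal_profile <- function(M, max_sep_bins = nrow(M$counts) - 1L) {
  n <- nrow(M$counts)
  sep <- seq_len(min(max_sep_bins, n - 1L))
  mc <- vapply(sep, function(d) {
    i <- seq_len(n - d)
    mean(M$counts[cbind(i, i + d)], na.rm = TRUE)
  }, numeric(1))
  data.frame(sep_bins = sep, mean_count = mc)
}
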