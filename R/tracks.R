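#' Construct a fold-enrichment track
#'
#' Per-bin ChIP/input fold-enrichment values for one chromosome, with an
#' optional between-sample scaling factor (see [chip_scaling_factors()]).
#'
#' @param values non-negative finite per-bin fold enrichment.
#' @param chrom chromosome name.
#' @param bin_size_bp bin size in bp.
#' @param sample_name sample label.
#' @param scaling_factor multiplicative between-sample scaling factor.
#' @return an `fe_track` object.
#' @export
fe_track <- function(values, chrom = "chrS", bin_size_bp,
                     sample_name = "sample", scaling_factor = 1.0) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("fold-enrichment values must be finite and >= 0")
  }
  structure(list(
    chrom = chrom,
    bin_size_bp = as.integer(bin_size_bp),
    values = as.numeric(values),
    sample_name = sample_name,
    scaling_factor = scaling_factor
  ), class = "fe_track")
}

#' Apply a track's scaling factor to its values
#' @param track an `fe_track`.
#' @return an `fe_track` with scaled values and factor reset to 1.
#' @export
scale_track <- function(track) {
  track$values <- track$values * track$scaling_factor
  track$scaling_factor <- 1.0
  track
}

#' @export
print.fe_track <- function(x, ...) {
  cat(sprintf("fe_track '%s': %s, %d bins @ %d bp, mean FE %.3f, scaling %.3f\n",
              x$sample_name, x$chrom, length(x$values), x$bin_size_bp,
              mean(x$values), x$scaling_factor))
  invisible(x)
}
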