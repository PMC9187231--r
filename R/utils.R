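# Internal helpers shared across modules.
#
# Conventions used throughout the package:
#  * base-pair coordinates are 0-based, half-open [start, end), BED-style;
#  * bin indices are 1-based (R matrix convention); the bin holding base-pair
#    position p at bin size b is floor(p / b) + 1.

#' @keywords internal
bin_of <- function(pos_bp, bin_size_bp) {
  as.integer(floor(pos_bp / bin_size_bp)) + 1L
}

# sample() misbehaves on length-1 numeric input; this never does.
resample <- function(x, ...) x[sample.int(length(x), ...)]

# Vectorised "does point p fall in any [start, end) interval" test.
point_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  s <- IRanges::IRanges(start = starts + 1L, end = ends)
  IRanges::overlapsAny(q, s)
}

# Vectorised interval-vs-interval overlap (>= 1 bp) on half-open coordinates.
intervals_overlap_any <- function(q_start, q_end, s_start, s_end) {
  if (length(s_start) == 0L) return(rep(FALSE, length(q_start)))
  q <- IRanges::IRanges(start = q_start + 1L, end = q_end)
  s <- IRanges::IRanges(start = s_start + 1L, end = s_end)
  IRanges::overlapsAny(q, s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
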