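#' Call chromatin loops by local-background enrichment
#'
#' HICCUPS-style punctate-peak detection on a coverage-normalized contact
#' matrix. For every upper-triangle pixel far enough from the diagonal and
#' the matrix edge, the expected value is the mean over a local background
#' neighbourhood: the donut (Chebyshev ring between `peak_radius` and
#' `donut_radius`) pooled with the lower-left quadrant region, both
#' excluding the peak disc. Observed and expected values are rescaled to
#' read-count units via the matrix depth, a one-sided Poisson upper-tail
#' p-value `P(X >= obs | expected)` is computed per pixel, and
#' Benjamini-Hochberg correction is applied across all tested pixels.
#' Significant enriched pixels are clustered by 8-connectivity; each
#' cluster yields one call at its maximally enriched pixel. Calls are then
#' filtered to loop lengths (anchor midpoint separation) strictly greater
#' than `min_length_bp`.
#'
#' @param M a normalized `contact_matrix`.
#' @param peak_radius_bins radius of the peak disc (bins).
#' @param donut_radius_bins outer radius of the background ring; must be
#'   greater than `peak_radius_bins`.
#' @param fdr Benjamini-Hochberg threshold (default 0.001).
#' @param min_length_bp minimum loop length, strict (default 10 kb).
#' @param min_enrichment minimum observed/expected ratio for a significant
#'   pixel (default 1.5, the usual punctate-peak requirement; guards
#'   against barely-enriched pixels reaching significance at high depth).
#' @param details if `TRUE`, also return the per-pixel table.
#' @return a data.frame of loop calls with columns `anchor_up_start`,
#'   `anchor_up_end`, `anchor_down_start`, `anchor_down_end` (bp,
#'   half-open), `length_bp`, `enrichment` (observed/expected),
#'   `q_value` and `anchor_filter_passed` (NA until
#'   [filter_by_anchors()] is applied). With `details = TRUE`, a list
#'   `list(calls, pixels)`.
#' @export
call_loops <- function(M, peak_radius_bins = 2L, donut_radius_bins = 5L,
                       fdr = 0.001, min_length_bp = 10000,
                       min_enrichment = 1.5, details = FALSE) {
  stopifnot(inherits(M, "contact_matrix"))
  p <- as.integer(peak_radius_bins); d <- as.integer(donut_radius_bins)
  if (d <= p) stopf("donut_radius must exceed peak_radius")
  n <- nrow(M$counts)
  if (n < 2L * d + 2L) stopf("matrix too small for the donut background")
  C <- M$counts
  C[is.na(C)] <- 0
  bs <- M$bin_size_bp

  # background offsets: donut ring + lower-left region, minus peak disc
  offs <- expand.grid(da = -d:d, db = -d:d)
  cheb <- pmax(abs(offs$da), abs(offs$db))
  in_donut <- cheb > p & cheb <= d
  in_ll <- offs$da >= 1L & offs$da <= d & offs$db <= -1L & offs$db >= -d & cheb > p
  offs <- offs[in_donut | in_ll, , drop = FALSE]
  n_off <- nrow(offs)

  # tested pixels: full background support inside the matrix, and far
  # enough above the diagonal that the background never crosses it
  iu <- which(upper.tri(C), arr.ind = TRUE)
  sep <- iu[, 2L] - iu[, 1L]
  ok <- iu[, 1L] > d & iu[, 2L] > d & iu[, 1L] <= n - d & iu[, 2L] <= n - d &
    sep > 2L * d
  iu <- iu[ok, , drop = FALSE]
  if (nrow(iu) == 0L) stopf("no testable pixels")

  bg <- numeric(nrow(iu))
  for (k in seq_len(n_off)) {
    bg <- bg + C[cbind(iu[, 1L] + offs$da[k], iu[, 2L] + offs$db[k])]
  }
  expected <- bg / n_off
  obs <- C[iu]

  # depth scaling: convert normalized units back to count scale
  mass <- sum(C[upper.tri(C, diag = TRUE)])
  scale <- if (mass > 0) M$total_read_pairs / mass else 1
  pval <- stats::ppois(ceiling(obs * scale) - 1L, expected * scale,
                       lower.tail = FALSE)
  qval <- stats::p.adjust(pval, method = "BH")

  pixels <- data.frame(i = iu[, 1L], j = iu[, 2L], observed = obs,
                       expected = expected, p_value = pval, q_value = qval)
  sig <- pixels[pixels$q_value <= fdr &
                  pixels$observed >= min_enrichment * pixels$expected, ,
                drop = FALSE]
  calls <- cluster_pixels_to_calls(sig, bs)
  calls <- calls[calls$length_bp > min_length_bp, , drop = FALSE]
  rownames(calls) <- NULL
  if (details) list(calls = calls, pixels = pixels) else calls
}

# group significant pixels by 8-connectivity; one call per cluster at the
# maximally enriched pixel
cluster_pixels_to_calls <- function(sig, bin_size_bp) {
  empty <- data.frame(
    anchor_up_start = integer(0), anchor_up_end = integer(0),
    anchor_down_start = integer(0), anchor_down_end = integer(0),
    length_bp = numeric(0), enrichment = numeric(0), q_value = numeric(0),
    n_pixels = integer(0), anchor_filter_passed = logical(0)
  )
  if (nrow(sig) == 0L) return(empty)
  m <- nrow(sig)
  cluster <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (cluster[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    cluster[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(cluster == 0L &
                    abs(sig$i - sig$i[v]) <= 1L & abs(sig$j - sig$j[v]) <= 1L)
      cluster[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  rows <- lapply(split(seq_len(m), cluster), function(idx) {
    sub <- sig[idx, , drop = FALSE]
    enr <- sub$observed / pmax(sub$expected, .Machine$double.eps)
    top <- which.max(enr)
    data.frame(
      anchor_up_start = (sub$i[top] - 1L) * bin_size_bp,
      anchor_up_end = sub$i[top] * bin_size_bp,
      anchor_down_start = (sub$j[top] - 1L) * bin_size_bp,
      anchor_down_end = sub$j[top] * bin_size_bp,
      length_bp = (sub$j[top] - sub$i[top]) * bin_size_bp,
      enrichment = enr[top],
      q_value = min(sub$q_value),
      n_pixels = nrow(sub),
      anchor_filter_passed = NA
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter loop calls by anchor overlap with binding sites
#'
#' A call passes only if **both** anchors, extended by `slack_bp` on each
#' side, overlap at least one site interval (AND semantics).
#'
#' @param calls loop-call data.frame from [call_loops()].
#' @param sites data.frame with `start`, `end` (0-based half-open),
#'   sorted.
#' @param slack_bp anchor extension (default one bin is a sensible
#'   choice; the reference analysis does not state a tolerance).
#' @return `calls` with `anchor_filter_passed` set.
#' @export
filter_by_anchors <- function(calls, sites, slack_bp = 0L) {
  if (nrow(calls) == 0L) return(calls)
  up <- intervals_overlap_any(pmax(calls$anchor_up_start - slack_bp, 0),
                              calls$anchor_up_end + slack_bp,
                              sites$start, sites$end)
  dn <- intervals_overlap_any(pmax(calls$anchor_down_start - slack_bp, 0),
                              calls$anchor_down_end + slack_bp,
                              sites$start, sites$end)
  calls$anchor_filter_passed <- up & dn
  calls
}

#' Binomial comparison of call counts between two conditions
#'
#' Delegates to [binomial_compare()] on the two call counts; the two call
#' sets must come from depth-matched maps.
#'
#' @param calls_a,calls_b loop/domain call data.frames (or integers).
#' @return two-sided binomial p-value, `NA` if both counts are zero.
#' @export
compare_call_counts <- function(calls_a, calls_b) {
  na <- if (is.data.frame(calls_a)) nrow(calls_a) else as.integer(calls_a)
  nb <- if (is.data.frame(calls_b)) nrow(calls_b) else as.integer(calls_b)
  if (na + nb == 0L) return(NA_real_)
  binomial_compare(na, nb)
}
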