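#' Insulation score of a contact matrix
#'
#' For every bin `i`, the raw insulation score is the total contact signal
#' formed across the bin by pairs of loci on either side within the
#' window: `sum of M[a, b]` over `a` in `[i - w, i - 1]`, `b` in
#' `[i + 1, i + w]` with `b - a <= w` bins, where `w = window_bp /
#' bin_size`. Scores are normalized by the mean over valid bins, so the
#' normalized track has mean exactly 1 and boundaries appear as local
#' minima. Bins closer than `w` to a chromosome end are masked invalid.
#'
#' @param M a normalized `contact_matrix` (1-kb bins in the reference
#'   analysis; any bin size dividing `window_bp` is accepted).
#' @param window_bp window size in bp on each side (default 40 kb).
#' @return an `insulation_track`: list with `bin_size_bp`, `window_bp`,
#'   `raw_scores`, `normalized_scores`, `valid_mask`.
#' @export
insulation_score <- function(M, window_bp = 40000) {
  stopifnot(inherits(M, "contact_matrix"))
  bs <- M$bin_size_bp
  w <- as.integer(round(window_bp / bs))
  n <- nrow(M$counts)
  raw <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  if (n < 2L * w + 1L) {
    warning("chromosome shorter than twice the insulation window; all bins invalid")
  } else {
    C <- M$counts
    C[is.na(C)] <- 0
    raw <- numeric(n)
    # accumulate over relative offsets (da upstream, db downstream), capped
    # at a total pair separation of w bins
    for (da in 1:w) {
      for (db in 1:(w - da + 1L)) {
        if (da + db > w) next
        i <- seq.int(da + 1L, n - db)
        raw[i] <- raw[i] + C[cbind(i - da, i + db)]
      }
    }
    valid <- seq_len(n) > w & seq_len(n) <= n - w
    raw[!valid] <- NA_real_
  }
  m <- mean(raw[valid])
  normalized <- if (isTRUE(m > 0)) raw / m else rep(NA_real_, n)
  structure(list(
    bin_size_bp = bs, window_bp = as.integer(window_bp),
    raw_scores = raw, normalized_scores = normalized, valid_mask = valid
  ), class = "insulation_track")
}

#' Local minima of an insulation track
#'
#' @param track an `insulation_track`.
#' @param deep_quantile if not `NULL`, keep only minima whose normalized
#'   score lies below this quantile of valid scores (e.g. 0.1 keeps the
#'   deepest decile).
#' @return integer vector of bin indices of (deep) local minima.
#' @export
insulation_minima <- function(track, deep_quantile = NULL) {
  x <- track$normalized_scores
  n <- length(x)
  idx <- which(track$valid_mask)
  idx <- idx[idx > 1L & idx < n]
  is_min <- vapply(idx, function(i) {
    isTRUE(x[i] <= x[i - 1L]) && isTRUE(x[i] <= x[i + 1L]) &&
      (isTRUE(x[i] < x[i - 1L]) || isTRUE(x[i] < x[i + 1L]))
  }, logical(1))
  mins <- idx[is_min]
  if (!is.null(deep_quantile)) {
    thr <- stats::quantile(x[track$valid_mask], deep_quantile, na.rm = TRUE)
    mins <- mins[x[mins] < thr]
  }
  mins
}

#' Average insulation profile around anchor sites
#'
#' Per-offset mean of normalized insulation scores over windows centred
#' at the anchors, together with a size-matched random-site control drawn
#' from the valid bins.
#'
#' @param track an `insulation_track`.
#' @param anchor_bp anchor positions in bp (>= 1 required).
#' @param flank_bp half-width of the averaged window (default 20 kb, i.e.
#'   40-kb spans).
#' @param seed seed for the random-site control.
#' @return list with `offset_bp`, `mean_score`, `n_anchors_used`,
#'   `n_dropped`, and `random_mean_score` (the control profile).
#' @export
average_insulation <- function(track, anchor_bp, flank_bp = 20000, seed = 1L) {
  if (length(anchor_bp) < 1L) stopf("need at least one anchor")
  bs <- track$bin_size_bp
  fw <- as.integer(round(flank_bp / bs))
  x <- track$normalized_scores
  n <- length(x)
  centers <- bin_of(anchor_bp, bs)
  usable <- centers - fw >= 1L & centers + fw <= n &
    vapply(centers, function(cc) {
      cc - fw >= 1L && cc + fw <= n &&
        all(track$valid_mask[(cc - fw):(cc + fw)])
    }, logical(1))
  dropped <- sum(!usable)
  if (dropped) message(sprintf("average_insulation: dropped %d anchor(s) outside the valid region", dropped))
  centers <- centers[usable]
  if (!length(centers)) stopf("no usable anchors")
  prof_at <- function(cs) {
    wins <- vapply(cs, function(cc) x[(cc - fw):(cc + fw)],
                   numeric(2L * fw + 1L))
    rowMeans(wins)
  }
  valid_bins <- which(track$valid_mask)
  valid_bins <- valid_bins[vapply(valid_bins, function(cc) {
    cc - fw >= 1L && cc + fw <= n && all(track$valid_mask[(cc - fw):(cc + fw)])
  }, logical(1))]
  rand_centers <- withr::with_seed(seed,
                                   resample(valid_bins, length(centers),
                                            replace = length(valid_bins) < length(centers)))
  list(
    offset_bp = (seq.int(-fw, fw)) * bs,
    mean_score = prof_at(centers),
    n_anchors_used = length(centers),
    n_dropped = dropped,
    random_mean_score = prof_at(rand_centers)
  )
}
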