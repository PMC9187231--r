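#' Construct a canonical pairs table
#'
#' Unbinned contact records (cis and trans). Each record is canonicalized
#' so that `chrom1 <= chrom2` (lexicographic) and, within a chromosome,
#' `pos1 <= pos2`. Positions are 0-based base pairs.
#'
#' @param df data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @return a `pairs_table` (data.frame subclass).
#' @export
pairs_table <- function(df) {
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(df))) {
    stopf("pairs table needs columns: %s", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$chrom1 <- as.character(df$chrom1); df$chrom2 <- as.character(df$chrom2)
  df$pos1 <- as.integer(df$pos1); df$pos2 <- as.integer(df$pos2)
  if (nrow(df) && (any(df$pos1 < 0) || any(df$pos2 < 0))) {
    stopf("positions must be >= 0")
  }
  swap <- df$chrom1 > df$chrom2 |
    (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
  if (any(swap)) {
    tmp_c <- df$chrom1[swap]; tmp_p <- df$pos1[swap]
    df$chrom1[swap] <- df$chrom2[swap]; df$pos1[swap] <- df$pos2[swap]
    df$chrom2[swap] <- tmp_c; df$pos2[swap] <- tmp_p
  }
  rownames(df) <- NULL
  class(df) <- c("pairs_table", "data.frame")
  df
}

#' Downsample a pairs table to a fixed depth
#'
#' Uniform sampling without replacement, used to depth-match libraries to
#' the smallest sample before comparative analyses.
#'
#' @param pairs a `pairs_table`.
#' @param n_target number of records to keep; must be `<= nrow(pairs)`.
#' @param seed integer seed; sampling is deterministic per seed.
#' @return a `pairs_table` with exactly `n_target` records.
#' @export
downsample_pairs <- function(pairs, n_target, seed = 1L) {
  if (n_target > nrow(pairs)) {
    stopf("n_target (%d) exceeds available pairs (%d)", n_target, nrow(pairs))
  }
  if (n_target == nrow(pairs)) return(pairs)
  idx <- withr::with_seed(seed, sample.int(nrow(pairs), n_target))
  out <- pairs[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pairs_table", "data.frame")
  out
}

#' Bin cis pairs of one chromosome into a contact matrix
#'
#' Bin index is `floor(pos / bin_size_bp)` (0-based half-open bins); both
#' triangles are filled symmetrically and same-bin pairs contribute once
#' to the diagonal, so the matrix sum equals
#' `2 * off-diagonal cis pairs + diagonal pairs`.
#'
#' @param pairs a `pairs_table`.
#' @param chrom chromosome to bin.
#' @param bin_size_bp bin size in bp.
#' @param chrom_length_bp optional chromosome length fixing the bin count;
#'   defaults to covering the largest observed position.
#' @return a raw `contact_matrix`. `total_read_pairs` is the number of cis
#'   pairs binned.
#' @export
bin_pairs <- function(pairs, chrom, bin_size_bp, chrom_length_bp = NULL) {
  if (bin_size_bp <= 0) stopf("bin_size_bp must be > 0")
  cis <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
  p1 <- pairs$pos1[cis]; p2 <- pairs$pos2[cis]
  nb <- if (is.null(chrom_length_bp)) {
    if (length(p1)) max(bin_of(c(p1, p2), bin_size_bp)) else 1L
  } else {
    as.integer(ceiling(chrom_length_bp / bin_size_bp))
  }
  M <- matrix(0, nb, nb)
  if (length(p1)) {
    i <- bin_of(p1, bin_size_bp); j <- bin_of(p2, bin_size_bp)
    k <- (pmax(i, j) - 1L) * nb + pmin(i, j)
    tab <- table(k)
    M[as.integer(names(tab))] <- as.integer(tab)
    M <- M + t(M)
    diag(M) <- diag(M) / 2
  }
  contact_matrix(M, chrom = chrom, bin_size_bp = bin_size_bp,
                 normalized = FALSE, total_read_pairs = length(p1))
}

#' Contact probability as a function of genomic distance, P(s)
#'
#' Cis pair separations are tallied in 1-kb distance bins; the probability
#' in each bin is the pair count divided by the number of pairs used and
#' by the bin width in kb, so the curve integrates to 1 over the covered
#' range. Same-bin separations (< one distance step) are excluded:
#' distance 0 is undefined at 1-kb steps.
#'
#' @param pairs a `pairs_table`.
#' @param chrom chromosome to analyse.
#' @param step_bp distance bin width (default 1000).
#' @return data.frame with `distance_bp` (bin lower edge), `count` and
#'   `probability` (per kb); zero rows if there are no usable cis pairs.
#' @export
contact_probability <- function(pairs, chrom, step_bp = 1000L) {
  cis <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
  s <- pairs$pos2[cis] - pairs$pos1[cis]
  s <- s[s >= step_bp]
  if (!length(s)) {
    return(data.frame(distance_bp = integer(0), count = integer(0),
                      probability = numeric(0)))
  }
  d <- floor(s / step_bp)
  tab <- table(d)
  dist_bin <- as.integer(names(tab))
  cnt <- as.integer(tab)
  width_kb <- step_bp / 1000
  data.frame(
    distance_bp = dist_bin * step_bp,
    count = cnt,
    probability = cnt / sum(cnt) / width_kb
  )
}

#' Fit the power-law exponent of a contact probability curve
#'
#' Ordinary least squares on `log(probability) ~ log(distance)` over a
#' distance window.
#'
#' @param ps output of [contact_probability()].
#' @param min_bp,max_bp fitting window.
#' @return the fitted slope (the exponent; negative for decaying curves).
#' @export
fit_ps_exponent <- function(ps, min_bp = 2000, max_bp = 100000) {
  use <- ps$distance_bp >= min_bp & ps$distance_bp <= max_bp &
    ps$probability > 0
  if (sum(use) < 3L) stopf("too few P(s) points in fitting window")
  stats::coef(stats::lm(log(ps$probability[use]) ~
                          log(ps$distance_bp[use])))[[2L]]
}

#' Cis and trans contact counts per million pairs
#'
#' @param pairs a `pairs_table`.
#' @return list with `cis`, `trans` (raw counts), `cis_per_million`,
#'   `trans_per_million` and `total`. The per-million values sum to 1e6.
#' @export
cis_trans_counts <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    warning("empty pairs table")
    return(list(cis = 0L, trans = 0L, cis_per_million = 0,
                trans_per_million = 0, total = 0L))
  }
  cis <- sum(pairs$chrom1 == pairs$chrom2)
  list(cis = cis, trans = n - cis,
       cis_per_million = cis / n * 1e6,
       trans_per_million = (n - cis) / n * 1e6,
       total = n)
}

#' Fraction of cis pairs at long range
#'
#' @param pairs a `pairs_table`.
#' @param chrom chromosome to analyse.
#' @param min_separation_bp separation threshold (default 100 kb).
#' @return fraction of cis pairs with separation > `min_separation_bp`.
#' @export
long_range_cis_fraction <- function(pairs, chrom, min_separation_bp = 100000) {
  cis <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
  s <- pairs$pos2[cis] - pairs$pos1[cis]
  if (!length(s)) return(NA_real_)
  mean(s > min_separation_bp)
}

#' Cis interactions anchored at a feature set
#'
#' Counts cis pairs separated by more than `min_separation_bp` with either
#' (or both) ends falling inside a feature interval; each pair is counted
#' once. Reported both raw and per million total pairs.
#'
#' @param pairs a `pairs_table`.
#' @param features data.frame with `start`, `end` (0-based half-open),
#'   sorted, non-empty.
#' @param min_separation_bp strict separation threshold (default 10 kb).
#' @param feature_set_name label stored in the result.
#' @return an `anchored_count`: list with `feature_set_name`, `count`,
#'   `count_per_million`, `min_separation_bp`, `total_pairs`.
#' @export
anchored_cis_counts <- function(pairs, features, min_separation_bp = 10000,
                                feature_set_name = "features") {
  if (is.null(features) || nrow(features) == 0L) {
    stopf("feature list must be non-empty")
  }
  cis <- pairs$chrom1 == pairs$chrom2
  sep <- pairs$pos2 - pairs$pos1
  use <- cis & sep > min_separation_bp
  hit1 <- point_in_intervals(pairs$pos1[use], features$start, features$end)
  hit2 <- point_in_intervals(pairs$pos2[use], features$start, features$end)
  cnt <- sum(hit1 | hit2)
  total <- nrow(pairs)
  structure(list(
    feature_set_name = feature_set_name,
    count = cnt,
    count_per_million = if (total > 0) cnt / total * 1e6 else 0,
    min_separation_bp = min_separation_bp,
    total_pairs = total
  ), class = "anchored_count")
}

#' Two-sided exact binomial comparison of two depth-matched counts
#'
#' Tests whether `count_a` successes out of `count_a + count_b` trials are
#' consistent with `expected_fraction` -- the comparison used for loop
#' counts, cis/trans counts and anchored interactions between
#' depth-matched libraries.
#'
#' @param count_a,count_b non-negative integer counts.
#' @param expected_fraction null success probability (default 0.5).
#' @return two-sided exact binomial p-value.
#' @export
binomial_compare <- function(count_a, count_b, expected_fraction = 0.5) {
  if (count_a < 0 || count_b < 0) stopf("counts must be non-negative")
  if (count_a + count_b == 0) stopf("both counts are zero")
  stats::binom.test(count_a, count_a + count_b,
                    p = expected_fraction)$p.value
}
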