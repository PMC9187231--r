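#' Call self-interacting domains by corner detection
#'
#' Arrowhead-style domain detection. The arrowhead transform
#' `A[i, d] = (M[i, i-d] - M[i, i+d]) / (M[i, i-d] + M[i, i+d])`
#' compares, for each bin `i`, contacts reaching a distance `d` upstream
#' versus downstream. A domain `[a, b]` makes `A` negative where the
#' downstream contact is inside the domain and the upstream one outside
#' (near the left boundary) and positive in the mirrored configuration
#' (near the right boundary). The corner score of a candidate interval is
#' the fraction of such informative cells with the expected sign;
#' candidates must exceed `score_threshold` *and* reject the
#' coin-flip null by an exact sign test (Bonferroni-corrected over all
#' scanned candidates at `alpha`) -- sign-consistency alone is reached
#' by chance on small windows. Survivors pass greedy non-maximum
#' suppression (higher score first, ties to the tighter interval,
#' overlaps with Jaccard > 0.5 suppressed). Degenerate cells (zero
#' denominator) are treated as missing.
#'
#' @param M a normalized `contact_matrix` (one resolution; use
#'   [merge_domain_calls()] to combine resolutions).
#' @param min_size_bp,max_size_bp candidate domain size range.
#' @param score_threshold minimum corner score (default 0.6).
#' @param alpha familywise significance level of the sign test.
#' @param min_cells minimum number of informative cells for a candidate.
#' @return data.frame of domain calls: `start_bp`, `end_bp`,
#'   `resolution_called_bp`, `corner_score`, `boundary_filter_passed`
#'   (NA until [filter_domains_by_boundaries()]).
#' @export
call_domains <- function(M, min_size_bp = 6000, max_size_bp = 50000,
                         score_threshold = 0.6, alpha = 0.01,
                         min_cells = 8L) {
  stopifnot(inherits(M, "contact_matrix"))
  bs <- M$bin_size_bp
  n <- nrow(M$counts)
  smin <- max(3L, as.integer(floor(min_size_bp / bs)))
  smax <- min(n - 2L, (n - 1L) %/% 2L,
              as.integer(ceiling(max_size_bp / bs)))
  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      resolution_called_bp = integer(0),
                      corner_score = numeric(0),
                      boundary_filter_passed = logical(0))
  if (smax < smin) return(empty)
  C <- M$counts

  # arrowhead transform, rows = i, cols = d
  A <- matrix(NA_real_, n, smax)
  for (d in seq_len(smax)) {
    i <- seq.int(d + 1L, n - d)
    up <- C[cbind(i, i - d)]; dn <- C[cbind(i, i + d)]
    den <- up + dn
    v <- (up - dn) / den
    v[!is.finite(v) | den == 0] <- NA_real_
    A[i, d] <- v
  }

  cand <- list(); ci <- 0L
  n_scanned <- 0L
  for (a in seq_len(n)) {
    for (size in smin:smax) {
      b <- a + size
      if (b > n) break
      n_scanned <- n_scanned + 1L
      sc <- corner_score(A, a, b)
      if (!is.na(sc$score) && sc$n >= min_cells && sc$score >= score_threshold) {
        ci <- ci + 1L
        cand[[ci]] <- c(a = a, b = b, score = sc$score, ncell = sc$n)
      }
    }
  }
  if (ci == 0L) return(empty)
  cand <- as.data.frame(do.call(rbind, cand))
  # exact sign test against the coin-flip null, Bonferroni over the scan
  good <- round(cand$score * cand$ncell)
  pval <- stats::pbinom(good - 1L, cand$ncell, 0.5, lower.tail = FALSE)
  cand <- cand[pval * n_scanned <= alpha, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$b - cand$a), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ov <- FALSE
    if (any(keep)) {
      kept <- cand[keep, , drop = FALSE]
      inter <- pmax(0, pmin(kept$b, cand$b[k]) - pmax(kept$a, cand$a[k]))
      uni <- (kept$b - kept$a) + (cand$b[k] - cand$a[k]) - inter
      ov <- any(inter / uni > 0.5)
    }
    keep[k] <- !ov
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    start_bp = (cand$a - 1L) * bs,
    end_bp = cand$b * bs,
    resolution_called_bp = bs,
    corner_score = cand$score,
    boundary_filter_passed = NA
  )
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sign-consistency corner score of candidate [a, b] (bins, inclusive)
corner_score <- function(A, a, b) {
  good <- 0L; tot <- 0L
  size <- b - a
  for (i in a:b) {
    dmax <- min(ncol(A), size)
    for (d in seq_len(dmax)) {
      inside_dn <- (i + d) <= b
      inside_up <- (i - d) >= a
      if (inside_dn == inside_up) next    # both in or both out: uninformative
      v <- if (i - d >= 1L && d <= ncol(A)) A[i, d] else NA_real_
      if (is.na(v)) next
      tot <- tot + 1L
      if (inside_dn && v < 0) good <- good + 1L
      if (inside_up && v > 0) good <- good + 1L
    }
  }
  list(score = if (tot > 0L) good / tot else NA_real_, n = tot)
}

#' Merge domain calls made at different resolutions
#'
#' Unions the call sets; calls whose two boundaries each agree within one
#' coarse bin are collapsed, keeping the higher-scoring call. Merged calls
#' record the contributing resolutions.
#'
#' @param ... domain-call data.frames from [call_domains()].
#' @return merged data.frame with a `merged_from` provenance column.
#' @export
merge_domain_calls <- function(...) {
  sets <- list(...)
  all <- do.call(rbind, sets)
  if (is.null(all) || nrow(all) == 0L) {
    out <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      resolution_called_bp = integer(0),
                      corner_score = numeric(0),
                      boundary_filter_passed = logical(0))
    out$merged_from <- character(0)
    return(out)
  }
  coarse <- max(all$resolution_called_bp)
  all <- all[order(-all$corner_score), , drop = FALSE]
  kept <- all[0, , drop = FALSE]
  merged_from <- character(0)
  for (k in seq_len(nrow(all))) {
    dup <- FALSE
    if (nrow(kept)) {
      dup_idx <- which(abs(kept$start_bp - all$start_bp[k]) <= coarse &
                         abs(kept$end_bp - all$end_bp[k]) <= coarse)
      if (length(dup_idx)) {
        dup <- TRUE
        merged_from[dup_idx[1L]] <- paste(unique(c(
          strsplit(merged_from[dup_idx[1L]], ",")[[1L]],
          as.character(all$resolution_called_bp[k])
        )), collapse = ",")
      }
    }
    if (!dup) {
      kept <- rbind(kept, all[k, , drop = FALSE])
      merged_from <- c(merged_from, as.character(all$resolution_called_bp[k]))
    }
  }
  kept$merged_from <- merged_from
  kept <- kept[order(kept$start_bp), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Filter domain calls by boundary overlap with binding sites
#'
#' A domain passes only if **both** boundaries (extended by `slack_bp`)
#' overlap at least one site interval.
#'
#' @param domains domain-call data.frame.
#' @param sites data.frame with `start`, `end`.
#' @param slack_bp boundary extension in bp.
#' @return `domains` with `boundary_filter_passed` set.
#' @export
filter_domains_by_boundaries <- function(domains, sites, slack_bp = 0L) {
  if (nrow(domains) == 0L) return(domains)
  up <- intervals_overlap_any(pmax(domains$start_bp - slack_bp, 0),
                              domains$start_bp + slack_bp + 1L,
                              sites$start, sites$end)
  dn <- intervals_overlap_any(pmax(domains$end_bp - slack_bp - 1L, 0),
                              domains$end_bp + slack_bp,
                              sites$start, sites$end)
  domains$boundary_filter_passed <- up & dn
  domains
}
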