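#' Call peaks on a fold-enrichment track
#'
#' Peaks are maximal runs of consecutive bins whose fold enrichment
#' (ChIP/input) exceeds the threshold. Any peak overlapping an exclusion
#' interval (by >= 1 bp) is dropped -- used to remove peaks over long
#' terminal repeats. Note the threshold applies to the stored values: any
#' between-sample scaling factor must be applied (see [scale_track()])
#' before thresholding.
#'
#' @param track an `fe_track`.
#' @param threshold strict fold-enrichment threshold (default 2.0).
#' @param exclusions data.frame with `start`, `end` (0-based half-open)
#'   intervals to exclude, or `NULL`.
#' @return data.frame of peak intervals `start`, `end` (bp, half-open).
#' @export
call_peaks <- function(track, threshold = 2.0, exclusions = NULL) {
  hot <- track$values > threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  bs <- track$bin_size_bp
  peaks <- data.frame(start = (starts[sel] - 1L) * bs, end = ends[sel] * bs)
  if (!is.null(exclusions) && nrow(exclusions) > 0L && nrow(peaks) > 0L) {
    drop <- intervals_overlap_any(peaks$start, peaks$end,
                                  exclusions$start, exclusions$end)
    peaks <- peaks[!drop, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks
}

#' Restrict peaks to chromosome arms
#'
#' Removes peaks overlapping the pericentromeric region, the 25-kb span
#' centred on the centromere (`centromere +/- halfwidth_bp`).
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param centromere_bp centromere position in bp.
#' @param halfwidth_bp pericentromere half-width (default 12.5 kb).
#' @return filtered peak data.frame.
#' @export
arm_sites <- function(peaks, centromere_bp, halfwidth_bp = 12500) {
  if (nrow(peaks) == 0L) return(peaks)
  drop <- intervals_overlap_any(peaks$start, peaks$end,
                                max(centromere_bp - halfwidth_bp, 0),
                                centromere_bp + halfwidth_bp)
  out <- peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify stress-response genes
#'
#' A gene is a stress-response gene if all three conditions hold: mean
#' RNA pol II fold enrichment over its ORF is greater than
#' `fe_high` under the transcription inhibitor, lower than `fe_low` in the
#' vehicle control, and the gene is flagged as up-regulated in the
#' expression analysis (differential-expression FDR below 1e-5, consumed
#' here as a precomputed flag). ORF means are overlap-weighted over the
#' bins the gene touches; a gene shorter than one bin uses its single
#' overlapping bin.
#'
#' @param rpo21_treated,rpo21_control `fe_track`s on the same binning.
#' @param genes gene data.frame with `start`, `end`.
#' @param deg_up_flags logical vector per gene (up-regulated calls).
#' @param fe_high,fe_low the classification thresholds (defaults 4.0 and
#'   2.0).
#' @return logical vector: `TRUE` for classified stress-response genes.
#' @export
classify_stress_genes <- function(rpo21_treated, rpo21_control, genes,
                                  deg_up_flags, fe_high = 4.0, fe_low = 2.0) {
  if (rpo21_treated$bin_size_bp != rpo21_control$bin_size_bp) {
    stopf("tracks must share a binning")
  }
  if (length(deg_up_flags) != nrow(genes)) {
    stopf("deg_up_flags must have one entry per gene")
  }
  mt <- gene_mean_fe(rpo21_treated, genes)
  mc <- gene_mean_fe(rpo21_control, genes)
  mt > fe_high & mc < fe_low & deg_up_flags
}

# overlap-weighted mean fold enrichment over each gene's ORF bins
gene_mean_fe <- function(track, genes) {
  bs <- track$bin_size_bp
  n <- length(track$values)
  vapply(seq_len(nrow(genes)), function(k) {
    b1 <- bin_of(genes$start[k], bs)
    b2 <- bin_of(genes$end[k] - 1L, bs)
    b2 <- min(b2, n); b1 <- min(b1, n)
    bins <- b1:b2
    bin_start <- (bins - 1L) * bs
    w <- pmin(genes$end[k], bin_start + bs) - pmax(genes$start[k], bin_start)
    sum(track$values[bins] * w) / sum(w)
  }, numeric(1))
}

#' Identify early-firing replication origins from BrdU incorporation
#'
#' Origins overlapping a BrdU-IP peak (fold enrichment above `threshold`,
#' called with [call_peaks()]) are classed as having fired early under HU
#' arrest. For the chromosome-arm variant, origins in the pericentromeric
#' 25-kb span are removed.
#'
#' @param origins data.frame with `position` (bp).
#' @param brdu_track an `fe_track` of BrdU incorporation.
#' @param threshold BrdU fold-enrichment threshold (default 1.5).
#' @param centromere_bp if not `NULL`, apply the pericentromere exclusion.
#' @param halfwidth_bp pericentromere half-width (default 12.5 kb).
#' @return logical vector per origin: early (and on-arm, if requested).
#' @export
call_early_origins <- function(origins, brdu_track, threshold = 1.5,
                               centromere_bp = NULL, halfwidth_bp = 12500) {
  peaks <- call_peaks(brdu_track, threshold, exclusions = NULL)
  early <- point_in_intervals(origins$position, peaks$start, peaks$end)
  if (!is.null(centromere_bp)) {
    peri <- origins$position >= centromere_bp - halfwidth_bp &
      origins$position < centromere_bp + halfwidth_bp
    early <- early & !peri
  }
  early
}

#' qPCR-anchored between-sample ChIP scaling factors
#'
#' Computes, per sample, the factor that makes scaled ChIP-seq tracks
#' reproduce the relative levels measured by ChIP-qPCR at a small panel of
#' shared anchor sites: the mean over sites of
#' `(qpcr_sample / qpcr_reference) / (chip_sample / chip_reference)`.
#' The reference sample gets factor 1. Four to seven anchor sites are
#' expected; fewer triggers a warning but the computation proceeds. Sites
#' with a zero denominator are dropped.
#'
#' @param qpcr_table data.frame with `sample`, `site`, `value` (qPCR
#'   enrichment).
#' @param chip_table data.frame with `sample`, `site`, `value` (ChIP-seq
#'   track enrichment at the same sites).
#' @param reference_sample name of the reference sample.
#' @return named numeric vector of scaling factors, one per sample.
#' @export
chip_scaling_factors <- function(qpcr_table, chip_table, reference_sample) {
  samples <- unique(qpcr_table$sample)
  if (!reference_sample %in% samples) {
    stopf("reference sample '%s' absent from qPCR table", reference_sample)
  }
  get <- function(tab, smp) {
    sub <- tab[tab$sample == smp, ]
    stats::setNames(sub$value, sub$site)
  }
  q_ref <- get(qpcr_table, reference_sample)
  c_ref <- get(chip_table, reference_sample)
  out <- stats::setNames(numeric(length(samples)), samples)
  for (smp in samples) {
    if (smp == reference_sample) { out[smp] <- 1; next }
    q_s <- get(qpcr_table, smp); c_s <- get(chip_table, smp)
    sites <- Reduce(intersect, list(names(q_s), names(q_ref),
                                    names(c_s), names(c_ref)))
    ratios <- (q_s[sites] / q_ref[sites]) / (c_s[sites] / c_ref[sites])
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) < 4L) {
      warning(sprintf("only %d usable common site(s) for sample '%s'",
                      length(ratios), smp))
    }
    if (!length(ratios)) stopf("no usable common sites for sample '%s'", smp)
    out[smp] <- mean(ratios)
  }
  out
}

#' Spike-in scaling factor for RNA expression values
#'
#' Equal spike-in input across samples is assumed, so expression values
#' are rescaled inversely to the number of reads mapped to the spike-in
#' genome: `factor = reference_spike_reads / sample_spike_reads`.
#'
#' @param sample_spike_reads,reference_spike_reads spike-in read counts
#'   (> 0).
#' @return multiplicative scaling factor.
#' @export
rna_spikein_scale <- function(sample_spike_reads, reference_spike_reads) {
  if (sample_spike_reads <= 0 || reference_spike_reads <= 0) {
    stopf("spike-in read counts must be > 0")
  }
  reference_spike_reads / sample_spike_reads
}

#' Cohesin peaks on a qPCR-rescaled track
#'
#' Fold-enrichment tracks are relative (per-sample mean-normalized), so a
#' fixed threshold is not comparable between samples whose total bound
#' protein differs (loader/unloader depletion). This reproduces the
#' qPCR-anchored workflow: enrichment at a panel of shared anchor sites
#' (taken from the reference sample's strongest peaks) is measured by an
#' emulated ChIP-qPCR (the simulator's absolute occupancy), a per-sample
#' scaling factor is derived with [chip_scaling_factors()], the sample
#' track is rescaled into the reference's fold-enrichment units, and
#' peaks are called at the usual threshold.
#'
#' @param sample_track cohesin `fe_track` of the sample (from
#'   [render_tracks()], carrying the `occupancy` attribute).
#' @param reference_track cohesin `fe_track` of the reference sample.
#' @param annotation the shared `genome_annotation` (for LTR exclusions).
#' @param n_sites number of shared qPCR anchor sites (default 6).
#' @param threshold fold-enrichment threshold in reference units.
#' @return peak data.frame as from [call_peaks()].
#' @export
scaled_cohesin_peaks <- function(sample_track, reference_track, annotation,
                                 n_sites = 6L, threshold = 2.0) {
  occ_s <- attr(sample_track, "occupancy")
  occ_r <- attr(reference_track, "occupancy")
  if (is.null(occ_s) || is.null(occ_r)) {
    stopf("tracks must carry the occupancy attribute from render_tracks()")
  }
  sites <- order(reference_track$values, decreasing = TRUE)[seq_len(n_sites)]
  qpcr <- data.frame(
    sample = rep(c("ref", "smp"), each = n_sites),
    site = rep(paste0("s", sites), 2L),
    value = c(occ_r[sites], occ_s[sites])
  )
  chip <- data.frame(
    sample = rep(c("ref", "smp"), each = n_sites),
    site = rep(paste0("s", sites), 2L),
    value = c(reference_track$values[sites], sample_track$values[sites])
  )
  f <- chip_scaling_factors(qpcr, chip, "ref")[["smp"]]
  tr <- sample_track
  tr$scaling_factor <- f
  tr <- scale_track(tr)
  call_peaks(tr, threshold = threshold, exclusions = annotation$ltrs)
}
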