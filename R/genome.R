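#' Generate a yeast-like single-chromosome genome annotation
#'
#' Builds a compact, gene-dense chromosome in the style of *S. cerevisiae*:
#' non-overlapping genes with alternating orientation (so that convergent
#' gene pairs -- adjacent `+`/`-` genes whose 3' ends face each other --
#' recur roughly every other gene junction), one centromere, replication
#' origins spaced 30--60 kb with an early/late flag, and a handful of LTR
#' intervals. Convergent sites (midpoints between the facing 3' ends) are
#' derived and stored, and serve as the ground-truth cohesin accumulation
#' sites of the simulator.
#'
#' All coordinates are 0-based half-open base pairs.
#'
#' @param n_genes number of genes (>= 2).
#' @param chrom_length_bp chromosome length; must be at least
#'   `n_genes * 2000` so the genes can be packed.
#' @param seed integer seed; the annotation is deterministic given the seed.
#' @param bin_size_bp bin size carried as metadata for downstream binning.
#' @param stress_frac fraction of genes flagged as stress-response genes
#'   (inducible under transcription-inhibitor stress).
#' @param chrom chromosome name.
#'
#' @return an object of class `genome_annotation`: a list with elements
#'   `chrom`, `chrom_length_bp`, `bin_size_bp`, `genes` (data.frame with
#'   `start`, `end`, `strand`, `expression_level`, `is_stress_gene`),
#'   `origins` (data.frame with `position`, `is_early`), `centromere_bp`,
#'   `ltrs` (data.frame with `start`, `end`) and `convergent_sites`
#'   (numeric vector of bp midpoints).
#' @export
make_genome <- function(n_genes, chrom_length_bp, seed = 1L,
                        bin_size_bp = 2000L, stress_frac = 0.08,
                        chrom = "chrS") {
  if (n_genes < 2L) stopf("n_genes must be >= 2, got %d", n_genes)
  if (chrom_length_bp < n_genes * 2000) {
    stopf("chromosome too short to pack %d genes: need >= %d bp, got %d",
          n_genes, n_genes * 2000, chrom_length_bp)
  }
  withr::with_seed(seed, {
    margin <- round(0.02 * chrom_length_bp)
    avail <- chrom_length_bp - 2 * margin
    # relative gene/gap widths, rescaled to fill the available span
    raw_gene <- stats::runif(n_genes, 1.0, 2.0)
    raw_gap <- stats::runif(n_genes + 1L, 0.10, 0.40)
    scale <- avail / (sum(raw_gene) + sum(raw_gap))
    gene_len <- pmax(500L, as.integer(round(raw_gene * scale)))
    gap_len <- pmax(100L, as.integer(round(raw_gap * scale)))
    starts <- integer(n_genes)
    pos <- margin
    ends <- integer(n_genes)
    for (g in seq_len(n_genes)) {
      pos <- pos + gap_len[g]
      starts[g] <- pos
      pos <- pos + gene_len[g]
      ends[g] <- pos
    }
    if (pos + gap_len[n_genes + 1L] > chrom_length_bp) {
      stopf("gene packing overflowed the chromosome; increase chrom_length_bp")
    }
    strand <- rep(c("+", "-"), length.out = n_genes)
    expression_level <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    is_stress <- rep(FALSE, n_genes)
    n_stress <- max(1L, round(stress_frac * n_genes))
    is_stress[resample(seq_len(n_genes), n_stress)] <- TRUE
    genes <- data.frame(
      start = starts, end = ends, strand = strand,
      expression_level = expression_level, is_stress_gene = is_stress,
      stringsAsFactors = FALSE
    )

    centromere_bp <- as.integer(round(chrom_length_bp *
                                        stats::runif(1, 0.45, 0.55)))

    # origins: random walk with 30-60 kb spacing; half fire early under HU
    ori_pos <- integer(0)
    p <- round(stats::runif(1, 10000, 20000))
    while (p < chrom_length_bp - 10000) {
      ori_pos <- c(ori_pos, as.integer(p))
      p <- p + stats::runif(1, 30000, 60000)
    }
    if (length(ori_pos) == 0L) ori_pos <- as.integer(chrom_length_bp %/% 2L)
    is_early <- rep(FALSE, length(ori_pos))
    is_early[resample(seq_along(ori_pos),
                      ceiling(length(ori_pos) / 2))] <- TRUE
    origins <- data.frame(position = ori_pos, is_early = is_early)

    # LTRs live in intergenic gaps away from convergent junctions (as for
    # tRNA-adjacent Ty elements); convergent intergenic regions are the
    # cohesin accumulation sites and are kept clear
    n_ltr <- max(2L, round(n_genes / 12))
    gap_mid <- floor((ends[-n_genes] + starts[-1L]) / 2)
    non_conv <- !(strand[-n_genes] == "+" & strand[-1L] == "-")
    cand <- gap_mid[non_conv]
    ltr_start <- sort(resample(cand, min(n_ltr, length(cand)))) - 150L
    ltrs <- data.frame(start = ltr_start, end = ltr_start + 300L)

    ann <- structure(list(
      chrom = chrom,
      chrom_length_bp = as.integer(chrom_length_bp),
      bin_size_bp = as.integer(bin_size_bp),
      genes = genes,
      origins = origins,
      centromere_bp = centromere_bp,
      ltrs = ltrs,
      convergent_sites = find_convergent_sites(genes)
    ), class = "genome_annotation")
    validate_genome(ann)
    ann
  })
}

#' Locate convergent sites between adjacent gene pairs
#'
#' A convergent site is the midpoint between the 3' ends of an adjacent
#' `+`/`-` gene pair (the two genes transcribe toward each other, so their
#' 3' ends flank the intergenic region where extruding cohesin accumulates).
#' For a `+` gene the 3' end is its `end` coordinate; for a `-` gene it is
#' its `start`.
#'
#' @param genes data.frame with `start`, `end`, `strand`, sorted by `start`.
#' @return numeric vector of midpoints (bp), possibly empty.
#' @export
find_convergent_sites <- function(genes) {
  n <- nrow(genes)
  if (n < 2L) return(numeric(0))
  i <- seq_len(n - 1L)
  conv <- genes$strand[i] == "+" & genes$strand[i + 1L] == "-"
  floor((genes$end[i][conv] + genes$start[i + 1L][conv]) / 2)
}

#' 3' end coordinate of each gene
#' @param genes gene data.frame (see [make_genome()]).
#' @return integer vector of 3'-end positions (bp, 0-based).
#' @export
gene_three_prime_ends <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

validate_genome <- function(ann) {
  g <- ann$genes
  if (is.unsorted(g$start)) stopf("genes must be sorted by start")
  if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])) {
    stopf("genes overlap")
  }
  if (any(g$start < 0) || any(g$end > ann$chrom_length_bp)) {
    stopf("gene coordinates outside chromosome")
  }
  if (ann$centromere_bp < 0 || ann$centromere_bp >= ann$chrom_length_bp) {
    stopf("centromere outside chromosome")
  }
  invisible(ann)
}

#' Number of bins spanned by an annotation at its bin size
#' @param ann a `genome_annotation`.
#' @return integer bin count.
#' @export
n_bins <- function(ann) {
  as.integer(ceiling(ann$chrom_length_bp / ann$bin_size_bp))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %s, %d bp, %d genes (%d stress), %d origins (%d early),\n  centromere %d bp, %d LTRs, %d convergent sites, bin size %d bp\n",
    x$chrom, x$chrom_length_bp, nrow(x$genes), sum(x$genes$is_stress_gene),
    nrow(x$origins), sum(x$origins$is_early), x$centromere_bp, nrow(x$ltrs),
    length(x$convergent_sites), x$bin_size_bp
  ))
  invisible(x)
}
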