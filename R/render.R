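#' Render a binned contact map from an extrusion trajectory
#'
#' Converts snapshots of extruder leg positions into a sampled cis contact
#' matrix. The expected (pre-sampling) intensity of pixel `(i, j)` is a
#' mixture of a polymer distance-decay background and extruder-mediated
#' contacts:
#'
#' `E[i,j] = w * B[i,j] + (1 - w) * L[i,j] / (rho_ref * n_bins)`
#'
#' where `B[i,j] ~ (1 + |i-j|)^-alpha` (normalized to unit mass), `L[i,j]`
#' is the mean per-snapshot count of extruders with legs at `(i, j)` (plus
#' a 0.25-weight short-range within-loop bonus at the two pixels adjacent
#' to the loop base), `w` is `background_weight` and `rho_ref = 0.1`
#' extruders per bin is the reference density at which loop contacts carry
#' exactly `1 - w` of the map mass. Extruder-mediated signal therefore
#' scales with extruder abundance: loader depletion drains the loop signal
#' rather than renormalising it. The mixture is rescaled to unit mass and
#' `read_depth` counts are drawn multinomially.
#'
#' @param snapshots output of [simulate_extrusion()] (may contain empty
#'   snapshots; must be non-empty as a list).
#' @param annotation the `genome_annotation` simulated on.
#' @param config the `sim_config`; uses `contact_background_exponent`,
#'   `background_weight`, `read_depth` and `seed` (offset by 1 so the
#'   renderer consumes an RNG stream distinct from the simulator's).
#' @return a raw `contact_matrix`.
#' @export
render_contact_map <- function(snapshots, annotation, config) {
  if (length(snapshots) == 0L) stopf("no snapshots to render")
  nb <- n_bins(annotation)
  alpha <- config$contact_background_exponent
  w <- config$background_weight

  # background: upper triangle incl. diagonal
  B <- matrix(0, nb, nb)
  iu <- which(upper.tri(B, diag = TRUE), arr.ind = TRUE)
  B[iu] <- (1 + (iu[, 2L] - iu[, 1L]))^(-alpha)
  B <- B / sum(B)

  L <- loop_signal_matrix(snapshots, nb)
  P <- w * B + (1 - w) * L / (0.1 * nb)
  P <- P / sum(P)

  pvec <- P[iu]
  cnt <- withr::with_seed(config$seed + 1L, {
    as.vector(stats::rmultinom(1L, size = config$read_depth, prob = pvec))
  })
  M <- matrix(0, nb, nb)
  M[iu] <- cnt
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  contact_matrix(M, chrom = annotation$chrom,
                 bin_size_bp = annotation$bin_size_bp,
                 normalized = FALSE, total_read_pairs = config$read_depth)
}

# mean per-snapshot extruder contact weight per pixel (upper triangle)
loop_signal_matrix <- function(snapshots, nb) {
  L <- matrix(0, nb, nb)
  legs <- do.call(rbind, snapshots[vapply(snapshots, nrow, integer(1)) > 0L])
  if (!is.null(legs) && nrow(legs)) {
    l <- legs[, "left"]; r <- legs[, "right"]
    acc <- function(i, j, wgt) {
      k <- (j - 1L) * nb + i
      s <- rowsum(wgt, k)
      L[as.integer(rownames(s))] <<- L[as.integer(rownames(s))] + s[, 1L]
    }
    acc(l, r, rep(1, length(l)))
    sm <- r - l >= 2L   # within-loop bonus just inside the loop base
    if (any(sm)) {
      acc(l[sm], r[sm] - 1L, rep(0.25, sum(sm)))
      acc(l[sm] + 1L, r[sm], rep(0.25, sum(sm)))
    }
  }
  L / length(snapshots)
}

#' Render cohesin, RNA polymerase II and BrdU fold-enrichment tracks
#'
#' * cohesin: time-averaged extruder leg occupancy per bin plus a
#'   nonspecific-binding floor (the ChIP background captured in any
#'   immunoprecipitation), scaled so the genome mean is 1.0
#'   (fold-enrichment units); when the factor is depleted the specific
#'   signal sinks into the floor and the track flattens toward 1, as a
#'   ChIP of a depleted protein does;
#' * RNA pol II: baseline 1.0 plus expression level painted over gene
#'   bodies (overlap-weighted); under transcription inhibition only
#'   stress-response genes are painted, amplified by `stress_amp`;
#' * BrdU: under HU arrest, a fold-enrichment plateau of 2.0 over
#'   `origin +/- fork_distance_bp` around early origins, 1.0 elsewhere;
#'   flat 1.0 in all other conditions (no replication).
#'
#' @param snapshots output of [simulate_extrusion()].
#' @param annotation the `genome_annotation`.
#' @param condition one of [conditions()].
#' @param fork_distance_bp replicated half-width around early origins.
#' @param stress_amp amplification of stress-gene expression under
#'   transcription-inhibitor stress.
#' @param nonspecific cohesin ChIP background, in occupancy units
#'   (legs per bin per snapshot).
#' @return named list of `fe_track` objects: `cohesin`, `rnapii`, `brdu`.
#' @export
render_tracks <- function(snapshots, annotation, condition,
                          fork_distance_bp = 7500, stress_amp = 5,
                          nonspecific = 0.08) {
  check_condition(condition)
  if (length(snapshots) == 0L) stopf("no snapshots to render")
  nb <- n_bins(annotation)
  bs <- annotation$bin_size_bp

  occ <- numeric(nb)
  legs <- do.call(rbind, snapshots[vapply(snapshots, nrow, integer(1)) > 0L])
  if (!is.null(legs) && nrow(legs)) {
    t1 <- tabulate(legs[, "left"], nb) + tabulate(legs[, "right"], nb)
    occ <- t1 / length(snapshots)
  }
  if (mean(occ) + nonspecific > 0) {
    cohesin <- (occ + nonspecific) / (mean(occ) + nonspecific)
  } else {
    warning("no extruder occupancy recorded; cohesin track is all zero")
    cohesin <- occ
  }

  rnapii <- rep(1, nb)
  g <- annotation$genes
  paint <- if (condition_is_thiolutin(condition)) {
    ifelse(g$is_stress_gene, g$expression_level * stress_amp, 0)
  } else {
    g$expression_level
  }
  bin_start <- (seq_len(nb) - 1L) * bs
  for (k in seq_len(nrow(g))) {
    if (paint[k] == 0) next
    ov <- pmin(g$end[k], bin_start + bs) - pmax(g$start[k], bin_start)
    ov <- pmax(ov, 0) / bs
    rnapii <- rnapii + paint[k] * ov
  }

  brdu <- rep(1, nb)
  if (condition_is_hu(condition)) {
    early <- annotation$origins$position[annotation$origins$is_early]
    for (p in early) {
      b1 <- max(1L, bin_of(p - fork_distance_bp, bs))
      b2 <- min(nb, bin_of(p + fork_distance_bp, bs))
      brdu[b1:b2] <- 2.0
    }
  }

  coh <- fe_track(cohesin, annotation$chrom, bs, "cohesin")
  # absolute IP-able material per bin (occupancy + nonspecific background):
  # the ground truth a ChIP-qPCR assay would measure, used to emulate
  # qPCR-anchored between-sample scaling
  attr(coh, "occupancy") <- occ + nonspecific
  list(
    cohesin = coh,
    rnapii = fe_track(rnapii, annotation$chrom, bs, "rnapii"),
    brdu = fe_track(brdu, annotation$chrom, bs, "brdu")
  )
}

#' Expand a binned contact matrix into an unbinned pairs table
#'
#' Each binned count becomes one pairs record with base-pair positions
#' drawn uniformly within the two bins -- the inverse of [bin_pairs()] up
#' to intra-bin position. Used to feed pair-level quantifications
#' (contact probability, anchored counts) from simulated maps.
#'
#' @param M a raw `contact_matrix`.
#' @param seed integer seed.
#' @return a `pairs_table`.
#' @export
sample_pairs_from_matrix <- function(M, seed = 1L) {
  stopifnot(inherits(M, "contact_matrix"))
  n <- nrow(M$counts)
  bs <- M$bin_size_bp
  iu <- which(upper.tri(M$counts, diag = TRUE), arr.ind = TRUE)
  cnt <- round(M$counts[iu])
  keep <- cnt > 0
  iu <- iu[keep, , drop = FALSE]; cnt <- cnt[keep]
  i <- rep(iu[, 1L], cnt); j <- rep(iu[, 2L], cnt)
  withr::with_seed(seed, {
    pos1 <- (i - 1L) * bs + floor(stats::runif(length(i)) * bs)
    pos2 <- (j - 1L) * bs + floor(stats::runif(length(j)) * bs)
  })
  pairs_table(data.frame(
    chrom1 = M$chrom, pos1 = as.integer(pos1),
    chrom2 = M$chrom, pos2 = as.integer(pos2),
    stringsAsFactors = FALSE
  ))
}
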