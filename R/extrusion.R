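#' Construct a simulation configuration
#'
#' Parameters of the fixed-timestep kinetic Monte Carlo loop-extrusion
#' model and of the downstream map renderer. One time step corresponds to
#' one attempted single-bin move per extruder leg (per unit of
#' `extrusion_step`); rates are therefore dimensionless per-step
#' probabilities.
#'
#' @param condition one of [conditions()].
#' @param loading_rate probability per vacant adjacent bin pair per step of
#'   loading a new extruder (before condition multipliers and pool
#'   depletion).
#' @param unloading_prob probability per extruder per step of unloading
#'   (before condition multipliers).
#' @param extrusion_step attempted single-bin moves per leg per step.
#' @param n_steps total simulated steps per cell.
#' @param burn_in_steps steps discarded before snapshots are recorded;
#'   must be < `n_steps`.
#' @param n_cells number of independent trajectories pooled by
#'   [simulate_population()]; a Hi-C library averages over a cell
#'   population, not a single nucleus, and slow-turnover conditions
#'   (unloader depletion) are badly represented by any single trajectory.
#' @param contact_background_exponent exponent `alpha` of the
#'   `(1 + s)^-alpha` distance-decay background of the rendered map.
#' @param background_weight weight in \[0, 1\] of the distance-decay
#'   background relative to extruder-mediated contacts at the reference
#'   extruder density of 0.1 extruders per bin (see
#'   [render_contact_map()]).
#' @param cohesin_pool total number of extruders available to the
#'   chromosome (nuclear cohesin is limiting); the effective loading rate
#'   is scaled by the free-pool fraction `1 - n_bound / cohesin_pool`.
#' @param read_depth total read pairs sampled into the rendered map.
#' @param seed integer seed governing both simulation and rendering.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(condition = "WT_G2M",
                              loading_rate = 0.002,
                              unloading_prob = 0.02,
                              extrusion_step = 1L,
                              n_steps = 560L,
                              burn_in_steps = 500L,
                              n_cells = 25L,
                              contact_background_exponent = 1.5,
                              background_weight = 0.7,
                              cohesin_pool = 18L,
                              read_depth = 400000L,
                              seed = 1L) {
  check_condition(condition)
  if (loading_rate < 0 || unloading_prob < 0 || unloading_prob > 1) {
    stopf("rates must be >= 0 and probabilities in [0,1]")
  }
  if (background_weight < 0 || background_weight > 1) {
    stopf("background_weight must lie in [0,1]")
  }
  if (contact_background_exponent <= 0) stopf("background exponent must be > 0")
  if (burn_in_steps >= n_steps) stopf("burn_in_steps must be < n_steps")
  structure(list(
    condition = condition,
    loading_rate = loading_rate,
    unloading_prob = unloading_prob,
    extrusion_step = as.integer(extrusion_step),
    n_steps = as.integer(n_steps),
    burn_in_steps = as.integer(burn_in_steps),
    n_cells = as.integer(n_cells),
    contact_background_exponent = contact_background_exponent,
    background_weight = background_weight,
    cohesin_pool = as.integer(cohesin_pool),
    read_depth = as.integer(read_depth),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate stochastic loop extrusion against directional barriers
#'
#' Fixed-timestep kinetic Monte Carlo on a one-dimensional lattice of bins.
#' Each step: (1) every vacant adjacent bin pair may load a new two-legged
#' extruder with probability `loading_rate`; (2) every leg attempts
#' `extrusion_step` outward single-bin moves, each succeeding unless the
#' target bin is occupied by another leg (no bypass, no stacking) or a
#' barrier blocking that direction of movement sits on the target bin, in
#' which case the move is rejected with probability `1 - permeability`;
#' (3) every extruder unloads with probability `unloading_prob`, freeing
#' its bins. Loading never places a leg on an absolute (permeability-0)
#' barrier bin -- those loci are occupied by the blocking machinery --
#' so absolute barriers are never crossed, not even by loading astride
#' them. Legs are updated in random order within a step. Condition
#' presets scale the rates via [condition_rate_multipliers()], and the
#' effective loading rate is further scaled by the free fraction of a
#' finite cohesin pool (`config$cohesin_pool`). Barrier
#' semantics are entry-blocking: a blocked leg never enters the barrier
#' bin, so it parks on the near side.
#'
#' @param annotation a `genome_annotation`.
#' @param barriers a `barrier_set` from [derive_barriers()].
#' @param config a `sim_config`; `config$seed` makes the trajectory
#'   deterministic.
#' @param initial optional integer matrix with columns `left`, `right`:
#'   extruders already bound at step 0 (used to study single-extruder
#'   trajectories and barrier encounters under controlled conditions).
#' @return list of snapshots (one per step after `burn_in_steps`); each is
#'   an integer matrix with columns `left`, `right` (1-based bin index of
#'   the two legs, `left <= right`) and attribute `time_step`.
#' @export
simulate_extrusion <- function(annotation, barriers, config, initial = NULL) {
  nb <- n_bins(annotation)
  mult <- condition_rate_multipliers(config$condition)
  load_p <- config$loading_rate * mult$loading
  unload_p <- config$unloading_prob * mult$unloading

  block_left <- numeric(nb)   # rejection prob entering bin moving leftward
  block_right <- numeric(nb)  # ... moving rightward
  loadable <- rep(TRUE, nb)   # absolute barrier bins cannot take a new leg
  loadable[barriers$bin[barriers$permeability <= 0]] <- FALSE
  for (k in seq_len(nrow(barriers))) {
    b <- barriers$bin[k]; p <- 1 - barriers$permeability[k]
    d <- barriers$direction[k]
    if (d %in% c("left", "both")) block_left[b] <- max(block_left[b], p)
    if (d %in% c("right", "both")) block_right[b] <- max(block_right[b], p)
  }

  withr::with_seed(config$seed, {
    occ <- integer(nb)              # 0 = free, otherwise extruder id
    left <- integer(0); right <- integer(0); alive <- logical(0)
    if (!is.null(initial) && nrow(initial) > 0L) {
      left <- as.integer(initial[, 1L]); right <- as.integer(initial[, 2L])
      if (any(left > right) || any(left < 1L) || any(right > nb)) {
        stopf("invalid initial extruder positions")
      }
      alive <- rep(TRUE, length(left))
      for (id in seq_along(left)) {
        occ[left[id]] <- id; occ[right[id]] <- id
      }
    }
    snapshots <- vector("list", config$n_steps - config$burn_in_steps)
    si <- 0L

    for (step in seq_len(config$n_steps)) {
      # -- loading --------------------------------------------------------
      if (load_p > 0) {
        n_bound <- sum(alive)
        free_frac <- max(0, 1 - n_bound / config$cohesin_pool)
        vac <- which(occ[-nb] == 0L & occ[-1L] == 0L &
                       loadable[-nb] & loadable[-1L])
        if (length(vac) && free_frac > 0) {
          cand <- vac[stats::runif(length(vac)) < load_p * free_frac]
          for (i in resample(cand)) {
            if (occ[i] == 0L && occ[i + 1L] == 0L) {
              left <- c(left, i); right <- c(right, i + 1L)
              alive <- c(alive, TRUE)
              id <- length(left)
              occ[i] <- id; occ[i + 1L] <- id
            }
          }
        }
      }
      # -- extrusion ------------------------------------------------------
      ids <- which(alive)
      for (id in resample(ids)) {
        for (rep_ in seq_len(config$extrusion_step)) {
          l <- left[id]
          if (l > 1L && occ[l - 1L] == 0L &&
              (block_left[l - 1L] == 0 || stats::runif(1) >= block_left[l - 1L])) {
            occ[l - 1L] <- id
            if (right[id] != l) occ[l] <- 0L
            left[id] <- l - 1L
          }
          r <- right[id]
          if (r < nb && occ[r + 1L] == 0L &&
              (block_right[r + 1L] == 0 || stats::runif(1) >= block_right[r + 1L])) {
            occ[r + 1L] <- id
            if (left[id] != r) occ[r] <- 0L
            right[id] <- r + 1L
          }
        }
      }
      # -- unloading ------------------------------------------------------
      if (length(ids) && unload_p > 0) {
        gone <- ids[stats::runif(length(ids)) < unload_p]
        for (id in gone) {
          occ[occ == id] <- 0L
          alive[id] <- FALSE
        }
      }
      # -- snapshot -------------------------------------------------------
      if (step > config$burn_in_steps) {
        si <- si + 1L
        live <- which(alive)
        snap <- cbind(left = left[live], right = right[live])
        attr(snap, "time_step") <- step
        snapshots[[si]] <- snap
      }
    }
    snapshots
  })
}

#' Per-snapshot extruder counts
#' @param snapshots output of [simulate_extrusion()].
#' @return integer vector, one count per snapshot.
#' @export
extruder_counts <- function(snapshots) {
  vapply(snapshots, nrow, integer(1))
}

#' Mean extruded loop length across a trajectory
#' @param snapshots output of [simulate_extrusion()].
#' @param bin_size_bp bin size used to convert leg separation to bp.
#' @return mean loop length in bp over all extruder-snapshots (NA if none).
#' @export
mean_loop_length <- function(snapshots, bin_size_bp) {
  spans <- unlist(lapply(snapshots, function(s) {
    if (nrow(s) == 0L) numeric(0) else (s[, "right"] - s[, "left"])
  }))
  if (!length(spans)) return(NA_real_)
  mean(spans) * bin_size_bp
}


#' Simulate a population of cells
#'
#' Runs [simulate_extrusion()] for `config$n_cells` independent
#' trajectories (seeds `config$seed + cell - 1`) and pools their
#' post-burn-in snapshots. Downstream renderers treat the pooled
#' ensemble as the cell population sampled by a sequencing library.
#'
#' @param annotation a `genome_annotation`.
#' @param barriers a `barrier_set`.
#' @param config a `sim_config`.
#' @return pooled list of snapshots.
#' @export
simulate_population <- function(annotation, barriers, config) {
  n_cells <- config$n_cells %||% 1L
  out <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    cfg <- config
    cfg$seed <- config$seed + cell - 1L
    out[[cell]] <- simulate_extrusion(annotation, barriers, cfg)
  }
  do.call(c, out)
}
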