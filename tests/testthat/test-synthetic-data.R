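test_that("convergent sites are defined by facing 3' ends", {
  genes_conv <- data.frame(start = c(1000L, 4000L), end = c(3000L, 6000L),
                           strand = c("+", "-"))
  expect_equal(find_convergent_sites(genes_conv), floor((3000 + 4000) / 2))

  genes_div <- data.frame(start = c(1000L, 4000L), end = c(3000L, 6000L),
                          strand = c("-", "+"))
  expect_length(find_convergent_sites(genes_div), 0L)
})

test_that("generated genomes satisfy their invariants and match a brute-force scan", {
  ann <- make_genome(40, 300000, seed = 1)
  g <- ann$genes
  expect_false(is.unsorted(g$start))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  expect_true(all(g$start >= 0) && all(g$end <= ann$chrom_length_bp))
  expect_true(ann$centromere_bp > 0 &&
                ann$centromere_bp < ann$chrom_length_bp)
  expect_true(all(diff(ann$origins$position) >= 30000 - 1))

  # independent re-scan of adjacent strand pairs
  brute <- 0L
  for (k in seq_len(nrow(g) - 1L)) {
    if (g$strand[k] == "+" && g$strand[k + 1L] == "-") brute <- brute + 1L
  }
  expect_equal(length(ann$convergent_sites), brute)
  # every convergent site lies strictly between the facing 3' ends
  for (cs in ann$convergent_sites) {
    k <- max(which(g$end <= cs))
    expect_true(g$strand[k] == "+" && g$strand[k + 1L] == "-")
    expect_true(cs > g$end[k] - 1 && cs < g$start[k + 1L])
  }

  expect_identical(make_genome(12, 60000, seed = 7),
                   make_genome(12, 60000, seed = 7))
  expect_error(make_genome(40, 50000, seed = 1), "too short")
})

test_that("barrier derivation follows the condition presets", {
  ann <- make_genome(6, 40000, seed = 3, bin_size_bp = 1000L)
  ann$genes$is_stress_gene <- FALSE
  ann$genes$expression_level <- rep(1, 6)
  ann$convergent_sites <- find_convergent_sites(ann$genes)

  # transcription inhibition with no stress genes: centromere only
  b_thio <- derive_barriers(ann, "thiolutin")
  expect_equal(nrow(b_thio), 1L)
  expect_equal(b_thio$bin, floor(ann$centromere_bp / 1000) + 1L)
  expect_equal(b_thio$direction, "both")
  expect_equal(b_thio$permeability, 0)

  # a convergent pair gives two barriers facing each other at the 3' ends
  b_wt <- derive_barriers(ann, "WT_G2M")
  g <- ann$genes
  conv_left <- bin_of_bp(g$end[g$strand == "+"] - 1L, 1000L)
  conv_right <- bin_of_bp(g$start[g$strand == "-"], 1000L)
  expect_true(all(conv_left %in% b_wt$bin[b_wt$direction %in% c("left", "both")]))
  expect_true(all(conv_right %in% b_wt$bin[b_wt$direction %in% c("right", "both")]))
  # permeability decreases with expression
  ann2 <- ann
  ann2$genes$expression_level <- c(0.1, 0.5, 1, 1.5, 2.5, 3)
  b2 <- derive_barriers(ann2, "WT_G2M")
  tp <- bin_of_bp(gene_three_prime_ends(ann2$genes), 1000L)
  perms <- b2$permeability[match(tp, b2$bin)]
  expect_true(all(diff(perms) <= 1e-12))
  expect_true(all(perms[5:6] == 0))

  # HU adds 2 fork barriers per early origin; count by enumeration
  b_hu <- derive_barriers(ann, "HU")
  n_early <- sum(ann$origins$is_early)
  fork_bins <- bin_of_bp(c(
    ann$origins$position[ann$origins$is_early] - 7500,
    ann$origins$position[ann$origins$is_early] + 7500
  ), 1000L)
  fork_bins <- fork_bins[fork_bins >= 1 & fork_bins <= n_bins(ann)]
  expected_bins <- sort(unique(c(b_wt$bin, fork_bins)))
  expect_equal(sort(b_hu$bin), expected_bins)
  expect_true(all(b_hu$permeability[b_hu$bin %in% fork_bins] == 0))

  # loader/unloader depletion alters rates, not barriers
  expect_equal(derive_barriers(ann, "scc2_depleted"), b_wt)
  expect_equal(derive_barriers(ann, "wpl1_depleted"), b_wt)
  m <- condition_rate_multipliers("scc2_depleted")
  expect_equal(m$loading, 0.05); expect_equal(m$unloading, 1)
  m <- condition_rate_multipliers("wpl1_depleted")
  expect_equal(m$loading, 1); expect_equal(m$unloading, 0.1)

  expect_error(derive_barriers(ann, "nonsense"), "unknown condition")
})

test_that("extrusion dynamics: loading, free growth, absolute blocking", {
  ann <- make_genome(4, 60000, seed = 2, bin_size_bp = 1000L)
  no_barriers <- structure(
    data.frame(bin = integer(0), direction = character(0),
               permeability = numeric(0)),
    class = c("barrier_set", "data.frame")
  )

  # nothing loads at rate zero
  cfg0 <- simulation_config(loading_rate = 0, n_steps = 50L,
                            burn_in_steps = 0L, seed = 1)
  sn <- simulate_extrusion(ann, no_barriers, cfg0)
  expect_true(all(vapply(sn, nrow, integer(1)) == 0L))

  # deterministic free extrusion of one pre-loaded extruder
  cfg1 <- simulation_config(loading_rate = 0, unloading_prob = 0,
                            n_steps = 10L, burn_in_steps = 0L, seed = 1)
  sn <- simulate_extrusion(ann, no_barriers, cfg1,
                           initial = cbind(30L, 31L))
  for (k in seq_along(sn)) {
    expect_equal(unname(sn[[k]][1, ]), c(max(1L, 30L - k), min(60L, 31L + k)))
  }

  # a permeability-0 barrier is never passed over a long trajectory
  bar <- structure(
    data.frame(bin = 40L, direction = "right", permeability = 0),
    class = c("barrier_set", "data.frame")
  )
  cfgb <- simulation_config(loading_rate = 0, unloading_prob = 0,
                            n_steps = 2000L, burn_in_steps = 0L, seed = 5)
  sn <- simulate_extrusion(ann, bar, cfgb, initial = cbind(38L, 39L))
  right_legs <- vapply(sn, function(s) s[1, "right"], integer(1))
  expect_true(all(right_legs <= 39L))
  expect_equal(max(right_legs), 39L)
})

test_that("leg ordering and no-bypass invariants hold along full trajectories", {
  run <- condition_run("WT_G2M", seed = 101)
  for (snap in run$snapshots) {
    if (nrow(snap) == 0L) next
    expect_true(all(snap[, "left"] <= snap[, "right"]))
    legs <- c(snap[, "left"], snap[, "right"])
    # no two legs of different extruders share a bin (an extruder's own
    # two legs share one only at loading width zero, which cannot happen)
    expect_true(all(table(legs) <= 1L) ||
                  all(snap[, "left"] != snap[, "right"]))
    expect_equal(anyDuplicated(legs), 0L)
  }
  # zero crossings of absolute barriers in the whole trajectory
  ab <- absolute_barrier_bins(run$barriers)
  both_abs <- run$barriers$bin[run$barriers$permeability <= 0 &
                                 run$barriers$direction == "both"]
  for (snap in run$snapshots) {
    if (nrow(snap) == 0L) next
    for (b in both_abs) {
      expect_true(all(snap[, "left"] > b | snap[, "right"] < b |
                        snap[, "left"] == b | snap[, "right"] == b))
    }
  }
})

test_that("condition presets shift extruder counts and loop lengths as expected", {
  seeds <- 201:210
  wt_len <- thio_len <- wpl1_len <- wt_n <- scc2_n <- numeric(length(seeds))
  ann <- ref_genome()
  for (k in seq_along(seeds)) {
    mk <- function(cond) {
      cfg <- simulation_config(condition = cond, seed = seeds[k],
                               n_cells = 3L)
      simulate_population(ann, derive_barriers(ann, cond), cfg)
    }
    wt <- mk("WT_G2M"); th <- mk("thiolutin"); wp <- mk("wpl1_depleted")
    sc <- mk("scc2_depleted")
    wt_len[k] <- mean_loop_length(wt, 2000)
    thio_len[k] <- mean_loop_length(th, 2000)
    wpl1_len[k] <- mean_loop_length(wp, 2000)
    wt_n[k] <- mean(extruder_counts(wt))
    scc2_n[k] <- mean(extruder_counts(sc))
  }
  expect_true(all(thio_len > wt_len))
  expect_true(all(wpl1_len > wt_len))
  # steady-state extruder abundance under loader depletion
  expect_lt(mean(scc2_n) / mean(wt_n), 0.10)
})

test_that("rendered maps honour the background/loop mixture and the seed", {
  ann <- ref_genome()

  # pure background: per-diagonal mean decays with the configured exponent
  cfg <- simulation_config(background_weight = 1, read_depth = 2000000L,
                           seed = 3)
  Mb <- render_contact_map(empty_snapshots(10), ann, cfg)
  dp <- mean_diagonal_profile(Mb, 80)
  fit <- stats::lm(log(mean_count) ~ log(1 + sep_bins),
                   data = dp[dp$mean_count > 0, ])
  expect_lt(abs(stats::coef(fit)[[2]] - (-1.5)), 0.1)

  # one permanent extruder, no background: contacts concentrate at (a, b)
  cfg0 <- simulation_config(background_weight = 0, read_depth = 10000L,
                            seed = 4)
  snaps <- lapply(1:100, function(i) cbind(left = 40L, right = 70L))
  M0 <- render_contact_map(snaps, ann, cfg0)
  expect_gt(M0$counts[40, 70] / sum(M0$counts[upper.tri(M0$counts, TRUE)]),
            0.6)
  expect_equal(unname(M0$counts[40, 70]), max(M0$counts))

  # seeding contract
  cfgA <- simulation_config(seed = 11); cfgB <- simulation_config(seed = 12)
  sn <- planted_snapshots(cbind(c(20L, 50L), c(35L, 70L)), seed = 1)
  M1 <- render_contact_map(sn, ann, cfgA)
  M2 <- render_contact_map(sn, ann, cfgA)
  M3 <- render_contact_map(sn, ann, cfgB)
  expect_identical(M1$counts, M2$counts)
  expect_false(identical(M1$counts, M3$counts))
})

test_that("rendered tracks reflect occupancy, transcription and replication", {
  run <- condition_run("WT_G2M", seed = 101)
  ann <- run$ann
  tr <- run$tracks

  # cohesin maxima co-locate with convergent sites
  conv <- bin_of_bp(ann$convergent_sites, ann$bin_size_bp)
  top <- order(tr$cohesin$values, decreasing = TRUE)[1:15]
  near <- vapply(top, function(b) min(abs(b - conv)) <= 1, logical(1))
  expect_gte(mean(near), 0.7)
  expect_equal(mean(tr$cohesin$values), 1.0, tolerance = 1e-9)

  # transcription inhibition flattens RNA pol II over non-stress ORFs
  thio <- condition_run("thiolutin", seed = 101)
  g <- ann$genes
  ns <- which(!g$is_stress_gene)
  mid_bins <- bin_of_bp(floor((g$start[ns] + g$end[ns]) / 2),
                        ann$bin_size_bp)
  expect_true(all(thio$tracks$rnapii$values[mid_bins] <= 1 + 1e-9))
  s <- which(g$is_stress_gene)[1]
  sb <- bin_of_bp(floor((g$start[s] + g$end[s]) / 2), ann$bin_size_bp)
  expect_gt(thio$tracks$rnapii$values[sb],
            run$tracks$rnapii$values[sb])

  # BrdU flat outside HU arrest, plateau > 1.5 at early origins under HU
  expect_true(all(run$tracks$brdu$values == 1))
  hu <- condition_run("HU", seed = 101)
  early_bins <- bin_of_bp(ann$origins$position[ann$origins$is_early],
                          ann$bin_size_bp)
  expect_true(all(hu$tracks$brdu$values[early_bins] > 1.5))
  late_bins <- bin_of_bp(ann$origins$position[!ann$origins$is_early],
                         ann$bin_size_bp)
  expect_true(all(hu$tracks$brdu$values[late_bins] == 1))
})
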