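# brute-force oracles, kept deliberately naive
oracle_insulation_raw <- function(C, w) {
  n <- nrow(C)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= w || i > n - w) next
    s <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) {
      if (b - a <= w) s <- s + C[a, b]
    }
    raw[i] <- s
  }
  raw
}

oracle_pileup <- function(C, centers, w) {
  agg <- matrix(0, 2 * w + 1, 2 * w + 1)
  for (k in seq_len(nrow(centers))) {
    i <- centers[k, 1]; j <- centers[k, 2]
    agg <- agg + C[(i - w):(i + w), (j - w):(j + w)]
  }
  agg
}

test_that("insulation scores equal brute-force window sums and are scale-free", {
  # uniform matrix: every valid bin scores exactly 1
  U <- contact_matrix(matrix(3, 60, 60), bin_size_bp = 1000L,
                      normalized = "VC_SQRT")
  tr <- insulation_score(U, window_bp = 10000)
  expect_true(all(abs(tr$normalized_scores[tr$valid_mask] - 1) < 1e-12))
  expect_equal(mean(tr$normalized_scores[tr$valid_mask]), 1, tolerance = 1e-9)

  # block-diagonal: global minimum at the junction
  B <- matrix(0.1, 80, 80)
  B[1:40, 1:40] <- 5; B[41:80, 41:80] <- 5
  Mb <- contact_matrix(B, bin_size_bp = 1000L, normalized = "VC_SQRT")
  trb <- insulation_score(Mb, window_bp = 10000)
  gm <- which.min(trb$normalized_scores)
  expect_true(gm %in% 40:41)

  # oracle equivalence on random instances
  for (seed in 1:10) {
    M <- random_matrix(50, seed = seed)
    tr <- insulation_score(M, window_bp = 8000)
    raw_oracle <- oracle_insulation_raw(M$counts, 8L)
    expect_equal(tr$raw_scores, raw_oracle, tolerance = 1e-9)
  }

  # doubling the matrix leaves normalized scores unchanged
  M <- random_matrix(50, seed = 21)
  M2 <- M; M2$counts <- 2 * M$counts
  expect_equal(insulation_score(M, 8000)$normalized_scores,
               insulation_score(M2, 8000)$normalized_scores,
               tolerance = 1e-12)

  expect_warning(insulation_score(random_matrix(10, 1), window_bp = 40000),
                 "shorter")
})

test_that("averaged insulation distinguishes barriers from random sites", {
  run <- condition_run("WT_G2M", seed = 101)
  ins <- insulation_score(run$map_norm, window_bp = 40000)
  ab <- absolute_barrier_bins(run$barriers)
  anchors_bp <- (ab - 0.5) * run$ann$bin_size_bp
  prof <- average_insulation(ins, anchors_bp, flank_bp = 20000, seed = 2)
  c0 <- which(prof$offset_bp == 0)
  center <- min(prof$mean_score[(c0 - 1):(c0 + 1)])
  flank <- mean(prof$mean_score[c(1:3, length(prof$mean_score) - 2:0)])
  expect_lt(center, flank)
  expect_lt(center, min(prof$random_mean_score[(c0 - 1):(c0 + 1)]) + 0.2)

  # single anchor reproduces its own window; anchor order irrelevant
  single <- average_insulation(ins, anchors_bp[1], flank_bp = 10000, seed = 1)
  cb <- bin_of_bp(anchors_bp[1], run$ann$bin_size_bp)
  expect_equal(single$mean_score,
               ins$normalized_scores[(cb - 5):(cb + 5)])
  p1 <- average_insulation(ins, anchors_bp, seed = 5)
  p2 <- average_insulation(ins, rev(anchors_bp), seed = 5)
  expect_equal(p1$mean_score, p2$mean_score)
})

test_that("APA equals its pile-up oracle and scores planted peaks", {
  # uniform matrix: strength exactly 1
  U <- contact_matrix(matrix(2, 120, 120), bin_size_bp = 1000L,
                      normalized = "VC_SQRT")
  ap <- apa(U, cbind(30500, 80500), w = 20)
  expect_equal(ap$strength, 1.0)

  # planted bright pixel at the pair centre: strength equals the hand ratio
  C <- matrix(1, 120, 120)
  C[30, 85] <- C[85, 30] <- 41
  Mp <- contact_matrix(C, bin_size_bp = 1000L, normalized = "VC_SQRT")
  app <- apa(Mp, cbind(29500, 84500), w = 20)
  expect_equal(app$strength, (121 + 40) / 121, tolerance = 1e-12)
  expect_gt(app$strength, 1.3)

  # oracle equivalence on random instances, including margin skipping
  for (seed in 1:25) {
    M <- random_matrix(60, seed = 30 + seed)
    withr::with_seed(seed, {
      i <- sample(10:18, 4); j <- i + sample(24:30, 4, replace = TRUE)
    })
    ap <- apa(M, cbind((i - 0.5) * 1000, (j - 0.5) * 1000), w = 8)
    orc <- oracle_pileup(M$counts, cbind(i, j), 8L)
    expect_equal(ap$aggregate, orc, tolerance = 1e-9)
  }

  # pairs violating the margin are skipped and counted
  M <- random_matrix(60, seed = 77)
  res <- apa(M, rbind(c(10500, 50500), c(500, 30500)), w = 8)
  expect_equal(res$n_pairs_used, 1L)
  expect_equal(res$n_pairs_skipped, 1L)
  expect_error(apa(M, cbind(500, 2500), w = 8), "no usable pairs")
})

test_that("distance-stratified APA partitions all cross pairs exactly once", {
  M <- random_matrix(200, seed = 41)
  a <- c(20500, 60500, 110500); b <- c(45500, 90500, 160500)
  classes <- list(c(0, 50000), c(50000, 100000), c(100000, 250000))
  res <- apa_by_distance(M, a, b, classes, w = 8)
  n_in_classes <- sum(vapply(res, function(r) r$n_pairs_used +
                               r$n_pairs_skipped, numeric(1)))
  cross <- expand.grid(a = a, b = b)
  cross <- cross[cross$a != cross$b, ]
  key <- paste(pmin(cross$a, cross$b), pmax(cross$a, cross$b))
  expect_equal(n_in_classes, length(unique(key)))

  # two sites 55 kb apart land only in [50,100)
  r2 <- apa_by_distance(M, 60500, 115500, classes, w = 8)
  expect_equal(r2[[1]]$n_pairs_used, 0L)
  expect_equal(r2[[2]]$n_pairs_used + r2[[2]]$n_pairs_skipped, 1L)

  # symmetric site lists match plain APA on the deduplicated union pairs
  r3 <- apa_by_distance(M, a, a, list(c(0, 250000)), w = 8)[[1]]
  pairs_u <- t(utils::combn(a, 2))
  r4 <- apa(M, pairs_u, w = 8)
  expect_equal(r3$aggregate, r4$aggregate, tolerance = 1e-9)
})

test_that("centromere pile-ups show insulation in WT but not without loading", {
  # oracle equivalence
  for (seed in 1:10) {
    M <- random_matrix(60, seed = 50 + seed)
    cen <- c(25, 33)
    pu <- pileup_centromeres(M, (cen - 0.5) * 1000, w = 6)
    orc <- oracle_pileup(M$counts, cbind(cen, cen), 6L)
    expect_equal(pu$aggregate, orc, tolerance = 1e-9)
    expect_equal(pu$n_used, 2L)
  }

  wt <- condition_run("WT_G2M", seed = 101)
  sc <- condition_run("scc2_depleted", seed = 101)
  w <- 10L
  pu_wt <- pileup_centromeres(wt$map_norm, wt$ann$centromere_bp, w = w)
  pu_sc <- pileup_centromeres(sc$map_norm, sc$ann$centromere_bp, w = w)
  expect_gt(pu_wt$arm_contrast, pu_sc$arm_contrast)
})

test_that("meta-profiles report per-offset means with a shrinking CI", {
  tr <- fe_track(rep(c(1, 2, 5, 2, 1), 20), bin_size_bp = 1000L)
  sites <- (seq(3, 98, by = 5) - 0.5) * 1000   # identical windows
  mp <- meta_profile(tr, sites, flank_bp = 2000)
  expect_equal(mp$ci_hi - mp$ci_lo, rep(0, 5))
  expect_equal(mp$mean, c(1, 2, 5, 2, 1))

  withr::with_seed(6, {
    vals <- stats::runif(200, 0.5, 3)
    tr2 <- fe_track(vals, bin_size_bp = 1000L)
    sites2 <- (sample(20:180, 12) - 0.5) * 1000
  })
  mp2 <- meta_profile(tr2, sites2, flank_bp = 5000)
  cb <- bin_of_bp(sites2, 1000L)
  for (off in -5:5) {
    v <- vals[cb + off]
    expect_equal(mp2$mean[off + 6], mean(v), tolerance = 1e-12)
    se <- stats::sd(v) / sqrt(length(v))
    expect_equal(mp2$ci_hi[off + 6], mean(v) + 1.96 * se, tolerance = 1e-9)
  }
})
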