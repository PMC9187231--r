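test_that("pairs tables canonicalize and downsample reproducibly", {
  pt <- pairs_table(data.frame(
    chrom1 = c("chrB", "chrA", "chrA"), pos1 = c(100L, 900L, 5L),
    chrom2 = c("chrA", "chrA", "chrB"), pos2 = c(50L, 200L, 10L)
  ))
  expect_true(all(pt$chrom1 <= pt$chrom2))
  expect_true(all(pt$pos1 <= pt$pos2 | pt$chrom1 != pt$chrom2))

  pr <- random_pairs(5000, seed = 3)
  expect_equal(nrow(downsample_pairs(pr, nrow(pr), seed = 1)), nrow(pr))
  expect_equal(nrow(downsample_pairs(pr, 0L, seed = 1)), 0L)
  expect_error(downsample_pairs(pr, nrow(pr) + 1L, seed = 1), "exceeds")

  expect_identical(downsample_pairs(pr, 1000L, seed = 9),
                   downsample_pairs(pr, 1000L, seed = 9))
  expect_false(identical(downsample_pairs(pr, 1000L, seed = 9),
                         downsample_pairs(pr, 1000L, seed = 10)))

  # a 30% cis table stays near 30% cis after sampling (binomial 99% CI)
  n_cis <- 6000L; n_trans <- 14000L
  big <- pairs_table(data.frame(
    chrom1 = c(rep("chrA", n_cis), rep("chrA", n_trans)),
    pos1 = 0:(n_cis + n_trans - 1L),
    chrom2 = c(rep("chrA", n_cis), rep("chrB", n_trans)),
    pos2 = seq_len(n_cis + n_trans) * 2L
  ))
  sub <- downsample_pairs(big, 10000L, seed = 4)
  frac <- mean(sub$chrom1 == sub$chrom2)
  ci <- 2.58 * sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), ci + 0.01)
})

test_that("binning is half-open, symmetric and count-conserving", {
  p1 <- pairs_table(data.frame(chrom1 = "c", pos1 = 1500L,
                               chrom2 = "c", pos2 = 3500L))
  M <- bin_pairs(p1, "c", 2000L)
  expect_equal(M$counts[1, 2], 1)
  expect_equal(M$counts[2, 1], 1)

  p2 <- pairs_table(data.frame(chrom1 = "c", pos1 = 1999L,
                               chrom2 = "c", pos2 = 2000L))
  M2 <- bin_pairs(p2, "c", 2000L)
  expect_equal(M2$counts[1, 2], 1)
  expect_equal(M2$counts[1, 1], 0)

  pr <- random_pairs(1000, seed = 5, chroms = c("chrA", "chrB"))
  M3 <- bin_pairs(pr, "chrA", 5000L)
  cis <- pr[pr$chrom1 == "chrA" & pr$chrom2 == "chrA", ]
  same_bin <- floor(cis$pos1 / 5000) == floor(cis$pos2 / 5000)
  expect_equal(sum(M3$counts), 2 * sum(!same_bin) + sum(same_bin))
  # brute-force recount of five random pixels
  withr::with_seed(1, {
    for (rep in 1:5) {
      i <- sample.int(nrow(M3$counts), 1); j <- sample.int(nrow(M3$counts), 1)
      brute <- sum((floor(cis$pos1 / 5000) + 1 == min(i, j) &
                      floor(cis$pos2 / 5000) + 1 == max(i, j)) |
                     (floor(cis$pos1 / 5000) + 1 == max(i, j) &
                        floor(cis$pos2 / 5000) + 1 == min(i, j)))
      expect_equal(unname(M3$counts[i, j]), unname(brute))
    }
  })
})

test_that("coverage-sqrt normalization matches the formula and removes rank-1 bias", {
  M <- contact_matrix(matrix(c(4, 2, 2, 1), 2), bin_size_bp = 1000L)
  N <- vc_sqrt_normalize(M)
  expect_equal(N$counts, matrix(c(4 / 6, 2 / sqrt(18), 2 / sqrt(18), 1 / 3), 2),
               tolerance = 1e-12)
  expect_equal(N$normalized, "VC_SQRT")

  Mc <- contact_matrix(matrix(5, 4, 4), bin_size_bp = 1000L)
  Nc <- vc_sqrt_normalize(Mc)
  expect_equal(max(Nc$counts) - min(Nc$counts), 0)

  # planted multiplicative per-bin bias is removed
  withr::with_seed(7, {
    n <- 40
    C <- matrix(stats::runif(n * n, 1, 5), n, n); C <- (C + t(C)) / 2
    b <- stats::runif(n, 0.2, 3)
    Mb <- contact_matrix(outer(b, b) * C, bin_size_bp = 1000L)
    Mt <- contact_matrix(C, bin_size_bp = 1000L)
    # one pass halves the bias exponent; the balanced fixed point
    # removes it entirely
    r1 <- stats::cor(as.vector(vc_sqrt_normalize(Mb)$counts),
                     as.vector(vc_sqrt_normalize(Mt)$counts))
    r50 <- stats::cor(as.vector(vc_sqrt_normalize(Mb, iterations = 50)$counts),
                      as.vector(vc_sqrt_normalize(Mt, iterations = 50)$counts))
    expect_gt(r50, 0.999)
    expect_gt(r50, r1)
  })

  expect_warning(vc_sqrt_normalize(contact_matrix(matrix(0, 3, 3),
                                                  bin_size_bp = 1000L)),
                 "all-zero")
})

test_that("ratio maps obey identity, scaling and the pointwise formula", {
  A <- random_matrix(20, seed = 8)
  expect_true(all(ratio_map(A, A) == 0))

  B <- A; B$counts <- 2 * A$counts
  r <- ratio_map(B, A, pseudocount = 1e-12)
  expect_equal(stats::median(r[A$counts > 0]), 1, tolerance = 1e-6)

  pc <- 0.7
  r2 <- ratio_map(A, B, pseudocount = pc)
  withr::with_seed(2, for (rep in 1:5) {
    i <- sample.int(20, 1); j <- sample.int(20, 1)
    expect_equal(r2[i, j],
                 log2((A$counts[i, j] + pc) / (B$counts[i, j] + pc)))
  })

  small <- random_matrix(10, seed = 9)
  expect_error(ratio_map(A, small), "identical shape")
})

test_that("contact probability is a normalized density recovering its exponent", {
  p50 <- pairs_table(data.frame(chrom1 = "c", pos1 = seq(0, 9000, 1000),
                                chrom2 = "c",
                                pos2 = seq(0, 9000, 1000) + 50000L))
  ps <- contact_probability(p50, "c")
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$distance_bp, 50000L)
  expect_equal(sum(ps$probability) * 1, 1, tolerance = 1e-9)

  # separations drawn from (1+s)^-1.5 recover the exponent
  withr::with_seed(11, {
    u <- stats::runif(200000)
    s <- round(u^(1 / (1 - 1.5)) - 1)
    s <- s[s >= 1000 & s < 200000]
    p1 <- round(stats::runif(length(s), 0, 20000))
    pt <- pairs_table(data.frame(chrom1 = "c", pos1 = p1,
                                 chrom2 = "c", pos2 = p1 + s))
  })
  psl <- contact_probability(pt, "c")
  expect_equal(sum(psl$probability), 1, tolerance = 1e-9)
  expect_lt(abs(fit_ps_exponent(psl, 2000, 80000) - (-1.5)), 0.1)

  expect_equal(nrow(contact_probability(random_pairs(10, 1), "chrZ")), 0L)
})

test_that("cis/trans and anchored quantifications match brute force", {
  all_cis <- pairs_table(data.frame(chrom1 = "c", pos1 = 1:10,
                                    chrom2 = "c", pos2 = 11:20))
  ct <- cis_trans_counts(all_cis)
  expect_equal(ct$cis_per_million, 1e6)
  expect_equal(ct$trans_per_million, 0)

  mix <- pairs_table(data.frame(chrom1 = c("a", "a", "a", "a"),
                                pos1 = 1:4,
                                chrom2 = c("a", "a", "a", "b"),
                                pos2 = 5:8))
  ct2 <- cis_trans_counts(mix)
  expect_equal(ct2$cis_per_million, 750000)
  expect_equal(ct2$trans_per_million, 250000)

  pr <- random_pairs(2000, seed = 13)
  ct3 <- cis_trans_counts(pr)
  expect_equal(ct3$cis, sum(pr$chrom1 == pr$chrom2))
  expect_warning(cis_trans_counts(pr[0, ]), "empty")

  # anchored counts: "either or both ends" semantics, strict separation
  f1 <- data.frame(start = 0L, end = 100000L)
  one <- pairs_table(data.frame(chrom1 = "a", pos1 = 10L,
                                chrom2 = "a", pos2 = 50000L))
  expect_equal(anchored_cis_counts(one, f1)$count, 1L)

  exact <- pairs_table(data.frame(chrom1 = "a", pos1 = 0L,
                                  chrom2 = "a", pos2 = 10000L))
  expect_equal(anchored_cis_counts(exact, f1)$count, 0L)

  feats <- data.frame(start = c(5000L, 30000L, 52000L, 70000L, 90000L),
                      end = c(9000L, 34000L, 56000L, 74000L, 94000L))
  pr2 <- random_pairs(500, seed = 14, chroms = "a")
  got <- anchored_cis_counts(pr2, feats)$count
  brute <- 0L
  for (k in seq_len(nrow(pr2))) {
    if (pr2$pos2[k] - pr2$pos1[k] <= 10000) next
    hit <- FALSE
    for (m in seq_len(nrow(feats))) {
      if ((pr2$pos1[k] >= feats$start[m] && pr2$pos1[k] < feats$end[m]) ||
          (pr2$pos2[k] >= feats$start[m] && pr2$pos2[k] < feats$end[m])) {
        hit <- TRUE
      }
    }
    if (hit) brute <- brute + 1L
  }
  expect_equal(got, brute)

  # monotone in the feature set
  got_fewer <- anchored_cis_counts(pr2, feats[1:2, ])$count
  expect_lte(got_fewer, got)
  expect_error(anchored_cis_counts(pr2, feats[0, ]), "non-empty")
})

test_that("binomial comparison is exact, symmetric and two-sided", {
  expect_equal(binomial_compare(5, 5), 1.0)
  expect_equal(binomial_compare(0, 10), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(binomial_compare(13, 37), binomial_compare(37, 13))
  expect_error(binomial_compare(-1, 5), "non-negative")
  expect_error(binomial_compare(0, 0), "zero")
})
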