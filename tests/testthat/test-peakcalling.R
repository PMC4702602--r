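test_that("smoothing reproduces closed-form Gaussian kernel values", {
  tr <- make_track(plus = rep(100, 10), len = 1000L)
  sm <- smooth_track(tr, "chr1", sigma = 5)
  expect_equal(sm$plus[101], 10 * stats::dnorm(0, sd = 5), tolerance = 1e-3)

  tr2 <- make_track(plus = c(rep(100, 10), rep(101, 10)), len = 1000L)
  sm2 <- smooth_track(tr2, "chr1", sigma = 5)
  expected <- 10 * (stats::dnorm(0, sd = 5) + stats::dnorm(1, sd = 5))
  expect_equal(sm2$plus[101], expected, tolerance = 1e-3)
  expect_equal(sm2$plus[102], expected, tolerance = 1e-3)

  empty <- make_track(len = 500L)
  expect_true(all(smooth_track(empty, "chr1")$plus == 0))
  expect_error(smooth_track(tr, "chr1", sigma = 0), "sigma")
})

test_that("smoothing preserves total tag mass away from edges", {
  set.seed(71)
  tr <- make_track(plus = sample(100:9900, 300, replace = TRUE),
                   len = 10000L)
  sm <- smooth_track(tr, "chr1", sigma = 5)
  expect_equal(sum(sm$plus), 300, tolerance = 1e-4)
})

test_that("exclusion zone keeps the higher peak and respects >= distance", {
  v <- numeric(300)
  v[101] <- 5; v[107] <- 4       # 0-based 100 and 106: 6 bp apart
  raw <- numeric(300); raw[c(101, 107)] <- 10
  pk <- call_peaks(v, raw, exclusion = 10, min_raw = 1)
  expect_equal(pk$position, 100)

  v2 <- numeric(300)
  v2[101] <- 5; v2[111] <- 4     # exactly 10 apart: both survive
  raw2 <- numeric(300); raw2[c(101, 111)] <- 10
  pk2 <- call_peaks(v2, raw2, exclusion = 10, min_raw = 1)
  expect_equal(pk2$position, c(100, 110))

  expect_equal(nrow(call_peaks(numeric(100), numeric(100))), 0)
})

test_that("peak calling matches a brute-force greedy oracle", {
  oracle <- function(x, exclusion) {
    n <- length(x)
    cand <- Filter(function(i) {
      x[i] > 0 && x[i] > x[i - 1] && x[i] >= x[i + 1]
    }, 2:(n - 1))
    cand <- cand[order(-x[cand], cand)]
    acc <- integer()
    for (p in cand)
      if (!length(acc) || min(abs(acc - p)) >= exclusion)
        acc <- c(acc, p)
    sort(acc) - 1L
  }
  set.seed(37)
  for (rep in 1:10) {
    tr <- make_track(plus = sample(0:9999, 400, replace = TRUE),
                     len = 10000L)
    sm <- smooth_track(tr, "chr1", sigma = 5)
    pk <- call_peaks(sm$plus, sm$plus_raw, exclusion = 10, min_raw = 0)
    expect_equal(pk$position, oracle(sm$plus, 10))
  }
})

test_that("pairing applies the separation window and tie-break rules", {
  mk <- function(pos, rc = 10) data.frame(position = pos,
                                          smoothed_height = 1,
                                          raw_count = rc)
  pr <- pair_peaks(mk(100), mk(112))
  expect_equal(pr$midpoint, 106)
  expect_equal(pr$separation, 12)

  expect_equal(nrow(pair_peaks(mk(100), mk(90))), 0)   # d = -10

  pr3 <- pair_peaks(mk(100), mk(c(104, 112)))
  expect_equal(pr3$minus_pos, 112)                     # |12-12| < |4-12|
})

test_that("pair separations always lie in the window; matching is stable", {
  set.seed(91)
  for (rep in 1:5) {
    pp <- data.frame(position = sort(sample(0:5000, 40)),
                     smoothed_height = runif(40), raw_count = 5)
    mp <- data.frame(position = sort(sample(0:5000, 40)),
                     smoothed_height = runif(40), raw_count = 5)
    pr <- pair_peaks(pp, mp)
    expect_true(all(pr$separation >= -5 & pr$separation <= 25))
    shuf <- sample(40)
    pr2 <- pair_peaks(pp[shuf, ], mp[rev(shuf), ])
    expect_equal(pr[order(pr$plus_pos), ], pr2[order(pr2$plus_pos), ])
  }
})

test_that("blacklist filtering is half-open on midpoints", {
  pairs <- data.frame(chrom = "chr1", midpoint = c(500L, 600L, 399L))
  bl <- data.frame(chrom = "chr1", start = 400L, end = 600L)
  kept <- filter_blacklist(pairs, bl)
  expect_equal(kept$midpoint, c(600L, 399L))
  expect_equal(filter_blacklist(pairs, bl[0, ]), pairs)
})

test_that("enrichment fold and binomial p match the exact computation", {
  # equal library totals: 20 chip vs 5 input tags at the pair midpoint
  chip <- make_track(plus = c(rep(500, 20), rep(5000, 80)), len = 10000L)
  input <- make_track(plus = c(rep(500, 5), rep(6000, 95)), len = 10000L)
  pairs <- data.frame(chrom = "chr1", midpoint = 500L)
  res <- test_enrichment(pairs, chip, input, count_halfwidth = 40,
                         keep_all = TRUE)
  expect_equal(res$chip_count, 20)
  expect_equal(res$input_count, 5)
  expect_equal(res$fold, 20 / 6)
  expect_equal(res$p_value, 68406 / 2^25, tolerance = 1e-9)
  expect_true(res$selected)

  # fold ~1 is rejected regardless of p
  chip2 <- make_track(plus = c(rep(500, 4), rep(5000, 96)), len = 10000L)
  input2 <- make_track(plus = c(rep(500, 4), rep(6000, 96)), len = 10000L)
  res2 <- test_enrichment(pairs, chip2, input2, keep_all = TRUE)
  expect_lt(res2$fold, 2)
  expect_false(res2$selected)

  empty_input <- make_track(len = 10000L)
  expect_error(test_enrichment(pairs, chip, empty_input), "pseudo-control")
})

test_that("identical chip and input tracks are never called enriched", {
  n_called <- 0L
  for (seed in 1:20) {
    sl <- c(chr1 = 100000L)
    tk <- simulate_input_track(sl, 0.02, seed = seed)
    pairs <- call_peak_pairs(tk, min_raw = 1)
    if (!nrow(pairs)) next
    sel <- test_enrichment(pairs, tk, tk)
    n_called <- n_called + (nrow(sel) > 0)
  }
  expect_lte(n_called, 1)   # >= 95% of simulations retain nothing
})

test_that("cross-condition merging unions within 40 bp", {
  l0 <- data.frame(chrom = "chr1", midpoint = c(100L, 5000L),
                   occupancy = c(10, 10))
  l3 <- data.frame(chrom = "chr1", midpoint = 130L, occupancy = 10)
  un <- merge_conditions(list(t0 = l0, t3 = l3), merge_dist = 40)
  first <- un[un$midpoint < 1000, ]
  expect_equal(first$midpoint, 115L)
  expect_true(first$bound_t0 && first$bound_t3)
  expect_equal(nrow(un), 2)

  far <- merge_conditions(list(
    t0 = data.frame(chrom = "chr1", midpoint = 100L, occupancy = 1),
    t3 = data.frame(chrom = "chr1", midpoint = 145L, occupancy = 1)))
  expect_equal(nrow(far), 2)                       # 45 > 40

  solo <- merge_conditions(list(t0 = l0))
  expect_equal(solo$midpoint, l0$midpoint)
})

test_that("external intersection keeps external coordinates within 100 bp", {
  un <- data.frame(chrom = "chr1", midpoint = 1000L)
  ext <- data.frame(chrom = "chr1", midpoint = c(1040L, 1200L))
  res <- intersect_locations(un, ext, window = 100)
  expect_equal(res$final$midpoint, 1040L)
  expect_equal(res$external_only$midpoint, 1200L)

  res2 <- intersect_locations(un, ext[0, ])
  expect_equal(nrow(res2$final), 0)
  expect_equal(res2$union_only$midpoint, 1000L)
})

test_that("full chain recovers simulated sites with high sensitivity", {
  sim <- sim_sites(n = 250, classes = "gata_only", seed = 55)
  m <- crosslink_model("GATA1", 0, exo_stop_offset = 6, jitter_sd = 1,
                       background_rate = 1e-4)
  chip <- simulate_exo_tags(sim$truth, m, sim$seqlengths, 100, seed = 56)
  input <- simulate_input_track(
    sim$seqlengths, total_tags(chip) / (2 * sim$seqlengths[[1]]), seed = 57)
  locs <- call_locations(chip, input)
  # sensitivity over sites carrying at least ~50 tags, the stated regime
  tags_per_site <- window_counts(chip, "chr1", sim$truth$reference_point,
                                 -40, 40)
  strong <- sim$truth$reference_point[tags_per_site >= 50]
  recovered <- vapply(strong, function(x) {
    any(abs(locs$midpoint - x) <= 20)
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  dist_to_truth <- vapply(locs$midpoint, function(x) {
    min(abs(sim$truth$reference_point - x))
  }, numeric(1))
  expect_lte(mean(dist_to_truth > 40), 0.05)
})
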