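test_that("haplotype diversity matches the unbiased formula and Nei's SD", {
  # degenerate: everyone identical
  d0 <- make_haps("A", L1 = rep(12L, 5), L2 = rep(9L, 5))
  expect_equal(haplotype_diversity(d0)$hd, 0)

  # all 13 haplotypes distinct: HD = 1.0000 +/- 0.0302
  d1 <- make_haps("A", L1 = 10L + seq_len(13), L2 = rep(9L, 13))
  hd <- haplotype_diversity(d1)
  expect_equal(hd$h, 13)
  expect_equal(hd$hd, 1)
  expect_equal(round(hd$hd_sd, 4), 0.0302)

  # n = 4 with counts {2,1,1}: HD = (4/3)(1 - 0.375)
  d2 <- make_haps("A", L1 = c(10L, 10L, 11L, 12L), L2 = rep(9L, 4))
  expect_equal(haplotype_diversity(d2)$hd, (4 / 3) * (1 - 0.375))

  expect_error(
    haplotype_diversity(make_haps("A", L1 = 10L)),
    "n >= 2"
  )
})

test_that("HD ignores labels and rises when a duplicate becomes novel", {
  withr::local_seed(42)
  for (i in 1:10) {
    d <- random_dataset(n_pops = 1, n_range = c(4, 8))
    base <- haplotype_diversity(d)$hd
    shifted <- d
    shifted[paste0("L", 1:3)] <- shifted[paste0("L", 1:3)] + 5L
    expect_equal(haplotype_diversity(shifted)$hd, base)
  }
  # replace one copy of a duplicated haplotype by a brand-new one
  d <- make_haps("A",
    L1 = c(10L, 10L, 10L, 12L), L2 = c(9L, 9L, 9L, 9L)
  )
  d_new <- d
  d_new$L1[2] <- 20L
  expect_gt(haplotype_diversity(d_new)$hd, haplotype_diversity(d)$hd)
})

test_that("mean pairwise difference averages the chosen metric over pairs", {
  d0 <- make_haps("A", L1 = rep(12L, 4), L2 = rep(9L, 4))
  expect_equal(mean_pairwise_difference(d0)$mpd, 0)

  # three singletons with step distances 1, 3, 2 -> MPD 2
  d1 <- make_haps("A", L1 = c(0L, 0L, 2L), L2 = c(0L, 1L, 1L))
  expect_equal(mean_pairwise_difference(d1, metric = "step")$mpd, 2)
  expect_equal(
    mean_pairwise_difference(d1, metric = "step")$mpd_sd,
    sd(c(1, 3, 2))
  )

  # Tajima-style total variance of the mean depends only on n and MPD
  n <- 21
  dd <- make_haps("A", L1 = c(rep(10L, 20), 13L), L2 = rep(9L, n))
  got <- mean_pairwise_difference(dd, metric = "step", sd_method = "tajima")
  pi_ <- got$mpd
  v <- (3 * n * (n + 1) * pi_ + 2 * (n^2 + n + 3) * pi_^2) /
    (11 * (n^2 - 7 * n + 6))
  expect_equal(got$mpd_sd, sqrt(v))

  expect_error(mean_pairwise_difference(make_haps("A", L1 = 1L)), "n >= 2")
})

test_that("pairwise-loop MPD equals the haplotype-frequency computation", {
  withr::local_seed(7)
  for (i in 1:20) {
    d <- random_dataset(n_pops = 1, n_range = c(3, 8))
    for (metric in c("allele", "step", "squared")) {
      expect_equal(
        mean_pairwise_difference(d, metric = metric)$mpd,
        oracle_mpd_freq(d, metric, paste0("L", 1:3))
      )
    }
  }
})

test_that("repeat variance is the mean per-locus sample variance", {
  d0 <- make_haps("A", L1 = rep(12L, 3), L2 = rep(9L, 3))
  expect_equal(repeat_variance(d0)$variance, 0)

  # two haplotypes differing by one repeat at one locus of 15
  d1 <- tibble::as_tibble(
    matrix(10L, 2, 15, dimnames = list(NULL, sprintf("X%02d", 1:15)))
  )
  d1$population <- "A"
  d1$X01 <- c(10L, 11L)
  expect_equal(repeat_variance(d1)$variance, 0.5 / 15)
})

test_that("modal haplotype is the majority type with lexicographic tie-break", {
  d <- make_haps("A", L1 = c(10L, 10L, 10L, 11L), L2 = c(9L, 9L, 9L, 9L))
  expect_equal(unlist(modal_haplotype(d)[, -1]), c(L1 = 10L, L2 = 9L))

  # single haplotype is its own mode
  d1 <- make_haps("A", L1 = 14L, L2 = 23L)
  expect_equal(unlist(modal_haplotype(d1)[, -1]), c(L1 = 14L, L2 = 23L))

  # tie {2, 2}: lexicographically smaller vector wins
  d2 <- make_haps("A", L1 = c(11L, 11L, 10L, 10L), L2 = c(1L, 1L, 9L, 9L))
  expect_equal(unlist(modal_haplotype(d2)[, -1]), c(L1 = 10L, L2 = 9L))

  # per-locus mode need not be observed
  d3 <- make_haps("A", L1 = c(10L, 10L, 11L), L2 = c(5L, 6L, 6L))
  expect_equal(
    unlist(modal_haplotype(d3, per_locus = TRUE)[, -1]),
    c(L1 = 10L, L2 = 6L)
  )
})

test_that("average mutational distance behaves as a mean distance to a reference", {
  d <- make_haps("A", L1 = c(10L, 10L), L2 = c(9L, 9L))
  expect_equal(avg_mutational_distance(d, c(L1 = 10, L2 = 9))$amd, 0)

  # two individuals at step distances 1 and 3
  d1 <- make_haps("A", L1 = c(11L, 13L), L2 = c(9L, 9L))
  expect_equal(avg_mutational_distance(d1, c(L1 = 10, L2 = 9))$amd, 2)

  # AMD >= 0, and 0 iff everyone equals the reference
  withr::local_seed(11)
  for (i in 1:10) {
    d <- random_dataset(n_pops = 1, n_range = c(2, 6))
    ref <- stats::setNames(as.numeric(d[1, paste0("L", 1:3)]), paste0("L", 1:3))
    amd <- avg_mutational_distance(d, ref)$amd
    expect_gte(amd, 0)
    all_eq <- all(apply(
      d[paste0("L", 1:3)], 1, function(r) all(r == ref)
    ))
    expect_identical(amd == 0, all_eq)
  }
})

test_that("star-genealogy MPD approaches twice the per-branch mutation load", {
  # two branches separate each pair, so E[MPD_step] ~ 2 L mu t; compared to
  # the exact Skellam mean absolute displacement to account for back-steps
  mu <- 6.9e-4
  t <- 100
  L <- 15
  founder <- stats::setNames(rep(14L, L), sprintf("X%02d", 1:L))
  pop <- simulate_star_population(400, t, founder, mu = mu, seed = 99)
  got <- mean_pairwise_difference(pop, metric = "step")$mpd
  expected <- L * skellam_mean_abs(2 * mu * t)
  naive <- 2 * L * mu * t
  # back-steps shrink the distance below the count by about lambda/2 = 7%
  expect_lt(abs(expected - naive) / naive, 0.10)
  expect_lt(abs(got - expected) / expected, 0.15) # Monte-Carlo agreement
})
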