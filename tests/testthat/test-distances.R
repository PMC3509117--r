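test_that("pi_between averages the metric over all cross pairs", {
  # two single-haplotype populations at step distance 3
  d <- dplyr::bind_rows(
    make_haps("A", L1 = 10L, L2 = 9L),
    make_haps("B", L1 = 12L, L2 = 10L)
  )
  expect_equal(pi_between(d, "A", "B", metric = "step"), 3)
  expect_equal(
    pi_between(d, "A", "B", metric = "step"),
    pi_between(d, "B", "A", metric = "step")
  )

  # identical content: cross-pair mean includes the zero self-pairs
  d2 <- dplyr::bind_rows(
    make_haps("A", L1 = c(10L, 11L), L2 = c(9L, 9L)),
    make_haps("B", L1 = c(10L, 11L), L2 = c(9L, 9L))
  )
  # pairs: (10,10)=0 (10,11)=1 (11,10)=1 (11,11)=0 -> mean 0.5
  expect_equal(pi_between(d2, "A", "B", metric = "step"), 0.5)

  # bounded by the extreme cross-pair values
  withr::local_seed(3)
  for (i in 1:10) {
    d <- random_dataset(n_pops = 2)
    ma <- as.matrix(d[d$population == "P1", paste0("L", 1:3)])
    mb <- as.matrix(d[d$population == "P2", paste0("L", 1:3)])
    vals <- c(outer(
      seq_len(nrow(ma)), seq_len(nrow(mb)),
      Vectorize(function(i, j) oracle_metric(ma[i, ], mb[j, ], "allele"))
    ))
    pb <- pi_between(d, "P1", "P2")
    expect_gte(pb, min(vals))
    expect_lte(pb, max(vals))
  }
})

test_that("(delta-mu)^2 is the mean squared difference of locus means", {
  d <- dplyr::bind_rows(
    make_haps("A", L1 = c(10L, 10L), L2 = c(9L, 9L)),
    make_haps("B", L1 = c(10L, 10L), L2 = c(9L, 9L))
  )
  expect_equal(delta_mu_squared(d, "A", "B"), 0)

  # single haplotypes differing by 2 repeats at one locus of 15
  m <- matrix(10L, 2, 15, dimnames = list(NULL, sprintf("X%02d", 1:15)))
  d1 <- tibble::as_tibble(m)
  d1$population <- c("A", "B")
  d1$X05[2] <- 12L
  expect_equal(delta_mu_squared(d1, "A", "B"), 4 / 15)

  # symmetric and invariant to row order
  withr::local_seed(5)
  for (i in 1:10) {
    d <- random_dataset(n_pops = 2)
    v1 <- delta_mu_squared(d, "P1", "P2")
    expect_equal(v1, delta_mu_squared(d, "P2", "P1"))
    expect_equal(v1, delta_mu_squared(d[sample(nrow(d)), ], "P1", "P2"))
  }
})

test_that("AMOVA recovers the limit cases and matches brute force", {
  # two populations fixed for different haplotypes: Phi_ST = 1
  d <- dplyr::bind_rows(
    make_haps("A", L1 = rep(10L, 3), L2 = rep(9L, 3)),
    make_haps("B", L1 = rep(12L, 3), L2 = rep(9L, 3))
  )
  expect_equal(amova(d)$phi[["phi_st"]], 1)

  # brute-force sums-of-squares oracle, one- and two-level designs
  withr::local_seed(13)
  for (i in 1:25) {
    d1 <- random_dataset(n_pops = sample(2:4, 1))
    fit <- amova(d1, metric = "allele")
    orc <- oracle_amova(d1, "allele", paste0("L", 1:3))
    expect_equal(fit$phi[["phi_st"]], orc$phi_st, tolerance = 1e-10)
    expect_equal(fit$components$sigma2, orc$sigma2, tolerance = 1e-10)
  }
  for (i in 1:15) {
    d2 <- random_dataset(n_pops = 4, groups = c("G1", "G1", "G2", "G2"))
    gmap <- stats::setNames(c("G1", "G1", "G2", "G2"), paste0("P", 1:4))
    fit <- amova(d2, group = gmap, metric = "squared")
    orc <- oracle_amova(d2, "squared", paste0("L", 1:3), group = gmap)
    expect_equal(fit$phi[["phi_st"]], orc$phi_st, tolerance = 1e-10)
    expect_equal(fit$phi[["phi_ct"]], orc$phi_ct, tolerance = 1e-10)
    expect_equal(fit$phi[["phi_sc"]], orc$phi_sc, tolerance = 1e-10)
  }

  # degenerate design: every population a single individual
  d3 <- dplyr::bind_rows(
    make_haps("A", L1 = 10L, L2 = 9L),
    make_haps("B", L1 = 12L, L2 = 9L)
  )
  expect_error(amova(d3), "undefined")
})

test_that("AMOVA permutation p-value is seeded and sensible", {
  withr::local_seed(21)
  d <- dplyr::bind_rows(
    make_haps("A", L1 = 10L + sample(0:1, 8, TRUE), L2 = rep(9L, 8)),
    make_haps("B", L1 = 20L + sample(0:1, 8, TRUE), L2 = rep(9L, 8))
  )
  fit1 <- amova(d, nperm = 99, seed = 5)
  fit2 <- amova(d, nperm = 99, seed = 5)
  expect_equal(fit1$p_value, fit2$p_value)
  expect_lte(fit1$p_value, 0.05) # strong separation
})

test_that("pairwise Rst equals the two-population AMOVA on squared steps", {
  withr::local_seed(17)
  d <- random_dataset(n_pops = 3, n_range = c(3, 6))
  rst <- rst_matrix(d)
  raw <- attr(rst, "raw")
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    pops <- paste0("P", pair)
    sub <- d[d$population %in% pops, ]
    expect_equal(
      raw[pops[1], pops[2]],
      amova(sub, metric = "squared")$phi[["phi_st"]]
    )
  }
  # identical populations give (clamped) zero
  d0 <- dplyr::bind_rows(
    make_haps("A", L1 = c(10L, 11L, 10L), L2 = c(9L, 9L, 10L)),
    make_haps("B", L1 = c(10L, 11L, 10L), L2 = c(9L, 9L, 10L))
  )
  m0 <- as.matrix(rst_matrix(d0))
  expect_gte(min(m0), 0)
  expect_lte(m0["A", "B"], 1e-9)
})

test_that("Rst rises with simulated divergence time", {
  mu <- 6.9e-4
  L <- 10
  founder <- stats::setNames(rep(14L, L), sprintf("X%02d", 1:L))
  times <- c(50, 200, 600, 1500, 4000)
  rsts <- vapply(seq_along(times), function(i) {
    # two populations whose founders split times[i] generations ago
    fa <- simulate_star_population(1, times[i], founder,
      mu = mu,
      seed = 1000 + i, population = "FA"
    )
    fb <- simulate_star_population(1, times[i], founder,
      mu = mu,
      seed = 2000 + i, population = "FB"
    )
    a <- simulate_star_population(
      25, 50, unlist(fa[1, sprintf("X%02d", 1:L)]),
      mu = mu, seed = 3000 + i, population = "A"
    )
    b <- simulate_star_population(
      25, 50, unlist(fb[1, sprintf("X%02d", 1:L)]),
      mu = mu, seed = 4000 + i, population = "B"
    )
    as.matrix(rst_matrix(dplyr::bind_rows(a, b)))["A", "B"]
  }, numeric(1))
  expect_gt(cor(times, rsts, method = "spearman"), 0)
})

test_that("(delta-mu)^2 grows linearly in divergence time with slope 2 mu", {
  mu <- 2e-3
  L <- 200 # many loci to tame the variance of the slope
  founder <- stats::setNames(rep(30L, L), sprintf("X%03d", 1:L))
  times <- c(100, 300, 600, 1000)
  reps <- 8
  means <- vapply(seq_along(times), function(i) {
    mean(vapply(seq_len(reps), function(r) {
      seeds <- 10000 + 100 * i + r
      fa <- simulate_star_population(1, times[i], founder,
        mu = mu, seed = seeds, population = "FA"
      )
      fb <- simulate_star_population(1, times[i], founder,
        mu = mu, seed = seeds + 50000, population = "FB"
      )
      d <- dplyr::bind_rows(
        dplyr::mutate(fa, population = "A"),
        dplyr::mutate(fb, population = "B")
      )
      delta_mu_squared(d, "A", "B")
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(means ~ times))[["times"]]
  expect_lt(abs(slope - 2 * mu) / (2 * mu), 0.25)
})

test_that("classical MDS recovers planar configurations and reports spectra", {
  pts <- matrix(c(0, 0, 4, 0, 4, 3, 0, 3), 4, 2, byrow = TRUE)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("P", 1:4)
  emb <- mds_embed(D, dims = 2)
  expect_lt(procrustes_rms(pts, as.matrix(emb[, c("dim1", "dim2")])), 1e-8)

  # all-zero matrix: everything at the origin
  z <- matrix(0, 3, 3)
  embz <- mds_embed(z, dims = 2)
  expect_true(all(abs(as.matrix(embz[, c("dim1", "dim2")])) < 1e-12))

  # triangle-inequality violation shows up as a negative eigenvalue
  bad <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3, 3)
  embb <- mds_embed(bad, dims = 2)
  expect_lt(min(attr(embb, "eig")), -1e-9)
  expect_gt(glance(embb)$negative_eig_mass, 0)

  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
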