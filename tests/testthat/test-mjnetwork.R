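# Small haplotype sets are written as (L1, L2) integer pairs; weights default
# to 10 per locus so a one-step link has length 10 and steps 1.

two_locus <- function(pop, a, b) make_haps(pop, L1 = a, L2 = b)

test_that("minimum spanning network is the union of all MSTs", {
  # two haplotypes: one edge at their step distance
  d2 <- two_locus("A", c(0L, 1L), c(0L, 2L))
  net <- build_minimum_spanning_network(d2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 3)
  expect_equal(net$edges$length, 30)

  # three pairwise equidistant haplotypes: full triangle retained
  d3 <- two_locus("A", c(0L, 1L, 2L), c(0L, 1L, 0L))
  net3 <- build_minimum_spanning_network(d3)
  expect_equal(nrow(net3$edges), 3)

  # collinear haplotypes: chain without the long chord
  dc <- two_locus("A", c(0L, 1L, 2L), c(0L, 0L, 0L))
  netc <- build_minimum_spanning_network(dc)
  expect_equal(nrow(netc$edges), 2)
  expect_false(any(netc$edges$steps > 1))
})

test_that("median joining adds cost-reducing quasi-medians and only those", {
  # quasi-median already observed: star through it, no inferred nodes
  d1 <- two_locus("A", c(0L, 1L, 0L), c(0L, 0L, 1L))
  net1 <- build_median_joining_network(d1)
  expect_equal(sum(!net1$observed), 0)
  expect_equal(nrow(net1$edges), 2)

  # (0,0), (1,1) with (1,0) observed: chain, nothing new
  d2 <- two_locus("A", c(0L, 1L, 1L), c(0L, 1L, 0L))
  net2 <- build_median_joining_network(d2)
  expect_equal(sum(!net2$observed), 0)
  expect_equal(sort(net2$edges$steps), c(1, 1))

  # equidistant triple (0,0), (1,1), (2,0): unobserved median (1,0) saves
  # one step and turns the triangle into a star
  d3 <- two_locus("A", c(0L, 1L, 2L), c(0L, 1L, 0L))
  net3 <- build_median_joining_network(d3)
  expect_equal(sum(!net3$observed), 1)
  mv <- net3$haps[!net3$observed, , drop = FALSE]
  expect_equal(unname(mv[1, ]), c(1L, 0L))
  expect_equal(nrow(net3$edges), 3)
  expect_true(all(net3$edges$steps == 1))

  # when every quasi-median is observed, MJ output equals the MSN
  dc <- two_locus("A", c(0L, 1L, 2L), c(0L, 0L, 0L))
  expect_equal(
    edge_keys(build_median_joining_network(dc)),
    edge_keys(build_minimum_spanning_network(dc))
  )
})

test_that("maximum-parsimony pruning removes links outside all shortest trees", {
  # a tree is untouched
  dc <- two_locus("A", c(0L, 1L, 2L), c(0L, 0L, 0L))
  netc <- build_median_joining_network(dc)
  expect_equal(edge_keys(mp_prune(netc)), edge_keys(netc))

  # triangle over equidistant observed haplotypes: every edge is in some MST
  d3 <- two_locus("A", c(0L, 1L, 2L), c(0L, 1L, 0L))
  net3 <- build_minimum_spanning_network(d3)
  expect_equal(edge_keys(mp_prune(net3)), edge_keys(net3))

  # epsilon-relaxed chain gains the long chord; pruning removes it again
  nete <- build_minimum_spanning_network(dc, epsilon = 10)
  expect_equal(nrow(nete$edges), 3)
  pruned <- mp_prune(nete)
  expect_equal(nrow(pruned$edges), 2)
  expect_false(any(pruned$edges$steps > 1))
})

test_that("pruned links equal the exhaustive spanning-structure search", {
  withr::local_seed(29)
  done <- 0
  while (done < 12) {
    nh <- sample(3:5, 1)
    d <- tibble::tibble(
      population = "A",
      L1 = sample(0:3, nh, replace = TRUE),
      L2 = sample(0:3, nh, replace = TRUE),
      L3 = sample(0:2, nh, replace = TRUE)
    )
    if (nrow(dplyr::distinct(d[paste0("L", 1:3)])) < 2) next
    net <- build_median_joining_network(d, epsilon = sample(c(0, 10), 1))
    if (nrow(net$haps) > 6) next
    pruned <- mp_prune(net)
    expect_equal(edge_keys(pruned), oracle_mp_links(net))
    done <- done + 1
  }
})

test_that("networks keep every observed haplotype connected and metric-sane", {
  withr::local_seed(31)
  for (i in 1:8) {
    d <- random_dataset(n_pops = 2, n_range = c(3, 6), repeat_range = c(10, 14))
    net <- build_median_joining_network(d)
    nodes <- network_nodes(net)
    # all observed haplotypes present
    obs <- dplyr::distinct(d[paste0("L", 1:3)])
    keys_obs <- apply(as.matrix(obs), 1, paste, collapse = "|")
    keys_net <- apply(
      net$haps[net$observed, , drop = FALSE], 1, paste,
      collapse = "|"
    )
    expect_setequal(keys_obs, keys_net)
    # connected, no zero-length edges, medians distinct from observed
    expect_gt(min(net$edges$steps), 0)
    expect_equal(igraph::components(as_igraph(net))$no, 1)
    # shortest network path is never shorter than the direct step distance
    g <- as_igraph(net)
    D <- hap_distance_matrix(net$haps, metric = "step")
    P <- igraph::distances(g, weights = igraph::E(g)$steps)
    P <- P[rownames(net$haps), rownames(net$haps)]
    expect_true(all(P - D > -1e-9))
  }
})

test_that("founder clusters anchor focal haplotypes at source-shared roots", {
  # all focal identical to one source haplotype: one cluster, rho zero
  d <- dplyr::bind_rows(
    two_locus("SRC", c(10L, 12L), c(9L, 9L)),
    two_locus("ROMA", c(10L, 10L, 10L), c(9L, 9L, 9L))
  )
  net <- build_median_joining_network(d)
  cl <- extract_founder_clusters(net, focal = "ROMA", source = "SRC")
  expect_equal(nrow(cl$summary), 1)
  expect_equal(cl$summary$n, 3)
  expect_equal(rho_statistic(cl)$rho, 0)

  # two focal clumps, each adjacent to its own source node, far apart
  d2 <- dplyr::bind_rows(
    two_locus("SRC", c(10L, 20L), c(9L, 9L)),
    two_locus("ROMA", c(10L, 11L, 20L, 21L), c(9L, 9L, 9L, 9L))
  )
  net2 <- build_median_joining_network(d2)
  cl2 <- extract_founder_clusters(net2, focal = "ROMA", source = "SRC")
  expect_equal(nrow(cl2$summary), 2)
  expect_equal(sort(cl2$summary$n), c(2, 2))
  roots <- sort(cl2$summary$root)
  root_haps <- net2$haps[roots, , drop = FALSE]
  expect_setequal(root_haps[, "L1"], c(10L, 20L))

  # a manual assignment overrides the automatic rule
  nodes <- network_nodes(net2)
  focal_nodes <- cl2$clusters[[1]]$members$node
  manual <- tibble::tibble(
    node = unique(tidy(cl2)$node),
    cluster = "ALL"
  )
  clm <- extract_founder_clusters(
    net2,
    focal = "ROMA", source = "SRC", assignment = manual
  )
  expect_equal(nrow(clm$summary), 1)
  expect_equal(clm$summary$n, 4)

  # unknown focal label errors
  expect_error(
    extract_founder_clusters(net2, focal = "NOPE", source = "SRC"),
    "focal"
  )
})

test_that("network export formats are written and reloadable", {
  d <- two_locus("A", c(0L, 1L, 2L), c(0L, 1L, 0L))
  net <- build_median_joining_network(d)
  gml <- withr::local_tempfile(fileext = ".gml")
  write_network(net, gml, format = "gml")
  g <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::gorder(g), nrow(net$haps))
  expect_equal(igraph::gsize(g), nrow(net$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, format = "tsv")
  expect_true(file.exists(sub("\\.tsv$", "_nodes.tsv", tsv)))
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
})
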