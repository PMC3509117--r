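# Shared fixtures and independent oracles for the test suite. Everything here
# deliberately re-derives quantities from definitions (explicit loops,
# exhaustive enumeration) rather than calling package internals.

make_haps <- function(pop, ...) {
  tibble::tibble(population = pop, ...)
}

# Random multi-population haplotype tibble for property tests.
random_dataset <- function(n_pops = 3, n_range = c(2, 6), n_loci = 3,
                           repeat_range = c(10, 13), groups = NULL) {
  pops <- paste0("P", seq_len(n_pops))
  rows <- lapply(seq_along(pops), function(i) {
    n <- sample(seq(n_range[1], n_range[2]), 1)
    m <- matrix(
      sample(seq(repeat_range[1], repeat_range[2]), n * n_loci, replace = TRUE),
      n, n_loci
    )
    colnames(m) <- paste0("L", seq_len(n_loci))
    out <- tibble::as_tibble(m)
    out$population <- pops[i]
    if (!is.null(groups)) out$group <- groups[i]
    out
  })
  dplyr::bind_rows(rows)[, c(
    intersect(c("population", "group"), names(rows[[1]])),
    paste0("L", seq_len(n_loci))
  )]
}

# Pairwise metric by definition (scalar loops).
oracle_metric <- function(a, b, metric) {
  switch(metric,
    allele = sum(a != b),
    step = sum(abs(a - b)),
    squared = sum((a - b)^2)
  )
}

# AMOVA variance components from first principles: explicit double loops for
# every sum of squared deviations, textbook expected-mean-square
# coefficients for the unbalanced nested design.
oracle_amova <- function(data, metric, loci, group = NULL) {
  m <- as.matrix(data[loci])
  pop <- as.character(data$population)
  N <- nrow(m)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      d2[i, j] <- oracle_metric(m[i, ], m[j, ], metric)
    }
  }
  ssd <- function(idx) {
    if (length(idx) < 2) {
      return(0)
    }
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  pops <- unique(pop)
  P <- length(pops)
  n_p <- sapply(pops, function(p) sum(pop == p))
  ss_tot <- ssd(1:N)
  ss_wp <- sum(sapply(pops, function(p) ssd(which(pop == p))))
  if (is.null(group)) {
    ms_ap <- (ss_tot - ss_wp) / (P - 1)
    ms_wp <- ss_wp / (N - P)
    nprime <- (N - sum(n_p^2) / N) / (P - 1)
    sig_w <- ms_wp
    sig_a <- (ms_ap - ms_wp) / nprime
    list(
      sigma2 = c(sig_a, sig_w),
      phi_st = sig_a / (sig_a + sig_w)
    )
  } else {
    grp <- as.character(group[pop])
    groups <- unique(grp)
    G <- length(groups)
    n_g <- sapply(groups, function(g) sum(grp == g))
    ss_wg <- sum(sapply(groups, function(g) ssd(which(grp == g))))
    ms_ag <- (ss_tot - ss_wg) / (G - 1)
    ms_ap <- (ss_wg - ss_wp) / (P - G)
    ms_wp <- ss_wp / (N - P)
    grp_of_pop <- sapply(pops, function(p) unique(grp[pop == p]))
    s1 <- sum(n_p^2 / n_g[grp_of_pop])
    n1 <- (N - s1) / (P - G)
    n2 <- (s1 - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(
      sigma2 = c(sig_a, sig_b, sig_c),
      phi_st = (sig_a + sig_b) / tot,
      phi_ct = sig_a / tot,
      phi_sc = sig_b / (sig_b + sig_c)
    )
  }
}

# MPD from haplotype frequencies and the distinct-haplotype distance matrix.
oracle_mpd_freq <- function(data, metric, loci) {
  m <- as.matrix(data[loci])
  key <- apply(m, 1, paste, collapse = "|")
  tab <- table(key)
  uh <- m[match(names(tab), key), , drop = FALSE]
  cnt <- as.numeric(tab)
  n <- sum(cnt)
  s <- 0
  for (i in seq_along(cnt)) {
    for (j in seq_along(cnt)) {
      if (i < j) {
        s <- s + cnt[i] * cnt[j] * oracle_metric(uh[i, ], uh[j, ], metric)
      }
    }
  }
  s / choose(n, 2)
}

# Exhaustive minimum-length spanning-structure search over a network:
# enumerate all subsets of median vectors and, for each induced node set,
# every spanning tree (edge subsets of size |V|-1 checked for connectivity);
# return the union of edges over all globally minimal trees, as sorted
# "from|to" keys.
oracle_mp_links <- function(net) {
  ids <- rownames(net$haps)
  obs <- ids[net$observed]
  med <- ids[!net$observed]
  edges <- net$edges
  best <- Inf
  kept <- character(0)
  subsets <- list(character(0))
  if (length(med) > 0) {
    for (k in seq_along(med)) {
      subsets <- c(subsets, combn(med, k, simplify = FALSE))
    }
  }
  for (S in subsets) {
    V <- c(obs, S)
    e_in <- which(edges$from %in% V & edges$to %in% V)
    nv <- length(V)
    if (length(e_in) < nv - 1) next
    for (tr in combn(e_in, nv - 1, simplify = FALSE)) {
      sub <- edges[tr, ]
      # connectivity check by label propagation
      comp <- stats::setNames(seq_along(V), V)
      for (r in seq_len(nrow(sub))) {
        a <- comp[sub$from[r]]
        b <- comp[sub$to[r]]
        comp[comp == b] <- a
      }
      if (length(unique(comp)) != 1) next
      cost <- sum(sub$length)
      key <- paste(pmin(sub$from, sub$to), pmax(sub$from, sub$to), sep = "|")
      if (cost < best - 1e-9) {
        best <- cost
        kept <- key
      } else if (cost < best + 1e-9) {
        kept <- union(kept, key)
      }
    }
  }
  sort(kept)
}

edge_keys <- function(net) {
  e <- net$edges
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "|"))
}

# Procrustes RMS between two configurations after centering, optimal
# rotation/reflection and scaling.
procrustes_rms <- function(X, Y) {
  fit <- vegan::procrustes(X, Y, symmetric = FALSE)
  sqrt(mean((fit$Yrot - fit$X)^2))
}

# Exact mean absolute value of a symmetric Skellam displacement with total
# mutation rate lambda: E|D| = lambda * exp(-lambda) * (I0(lambda) + I1(lambda)).
skellam_mean_abs <- function(lambda) {
  if (lambda == 0) {
    return(0)
  }
  lambda * exp(-lambda) * (besselI(lambda, 0) + besselI(lambda, 1))
}
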