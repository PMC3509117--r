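#' Mean pairwise difference between two populations
#'
#' Mean of a pairwise haplotype metric over all `nA x nB` cross-population
#' pairs of individuals (the between-population "PiXY"; the within-population
#' counterpart "PiX" is [mean_pairwise_difference()]).
#'
#' @param data Haplotype data frame with a `population` column.
#' @param pop_a,pop_b Population labels.
#' @param metric Pairwise metric, see [hap_distance()].
#' @param loci Optional locus columns.
#' @return A single non-negative number.
#' @export
pi_between <- function(data, pop_a, pop_b,
                       metric = c("allele", "step", "squared"), loci = NULL) {
  metric <- match.arg(metric)
  loci <- str_loci(data, loci)
  ma <- pop_matrix(data, pop_a, loci)
  mb <- pop_matrix(data, pop_b, loci)
  mean(cross_distances(ma, mb, metric))
}

#' Goldstein's (delta-mu)^2 distance between two populations
#'
#' Mean over loci of the squared difference in mean repeat count,
#' `mean_l((mu_A,l - mu_B,l)^2)`. Under the stepwise mutation model its
#' expectation grows linearly with divergence time (slope `2 * mu` per locus
#' per generation), which makes it the classic microsatellite distance for
#' dating population splits.
#'
#' @inheritParams pi_between
#' @return A single non-negative number; 0 when the populations have equal
#'   per-locus means.
#' @export
delta_mu_squared <- function(data, pop_a, pop_b, loci = NULL) {
  loci <- str_loci(data, loci)
  ma <- pop_matrix(data, pop_a, loci)
  mb <- pop_matrix(data, pop_b, loci)
  mean((colMeans(ma) - colMeans(mb))^2)
}

#' Combined within/between distance table
#'
#' The classic square presentation of STR population comparisons: within-
#' population mean pairwise differences (PiX) on the diagonal, between-
#' population mean pairwise differences (PiXY) above it, and (delta-mu)^2
#' distances below it.
#'
#' @inheritParams pi_between
#' @return A `ystr_dist` object (measure `"combined"`); `as.matrix()` gives
#'   the square matrix, [tidy()] a long tibble.
#' @export
combined_distance_table <- function(data, metric = c("allele", "step", "squared"),
                                    loci = NULL) {
  metric <- match.arg(metric)
  loci <- str_loci(data, loci)
  pops <- unique(data$population)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) {
    mi <- pop_matrix(data, pops[i], loci)
    Di <- hap_distance_matrix(mi, metric = metric)
    m[i, i] <- mean(Di[upper.tri(Di)])
    if (i < k) {
      for (j in seq(i + 1, k)) {
        m[i, j] <- pi_between(data, pops[i], pops[j], metric, loci)
        m[j, i] <- delta_mu_squared(data, pops[i], pops[j], loci)
      }
    }
  }
  new_ystr_dist(m, "combined")
}

#' Pairwise distance matrices between populations
#'
#' `delta_mu_matrix()` returns the symmetric matrix of [delta_mu_squared()]
#' values; `rst_matrix()` returns pairwise Rst: for each population pair a
#' two-population AMOVA on squared repeat differences, whose among-
#' population fixation index is Slatkin's Rst. Negative Rst estimates
#' (possible by sampling noise when true differentiation is near zero) are
#' clamped to 0 in the matrix; raw values are kept in the `"raw"` attribute.
#'
#' @inheritParams pi_between
#' @return A `ystr_dist` object.
#' @export
delta_mu_matrix <- function(data, loci = NULL) {
  loci <- str_loci(data, loci)
  pops <- unique(data$population)
  m <- outer_pop(pops, function(a, b) delta_mu_squared(data, a, b, loci))
  new_ystr_dist(m, "delta_mu_sq")
}

#' @rdname delta_mu_matrix
#' @export
rst_matrix <- function(data, loci = NULL) {
  loci <- str_loci(data, loci)
  pops <- unique(data$population)
  if (length(pops) < 2) abort("Rst needs at least two populations.")
  raw <- outer_pop(pops, function(a, b) {
    sub <- data[data$population %in% c(a, b), , drop = FALSE]
    sub$group <- NULL # pairwise Rst is always a one-level design
    fit <- amova(sub, metric = "squared", loci = loci)
    fit$phi[["phi_st"]]
  })
  m <- pmax(raw, 0)
  out <- new_ystr_dist(m, "rst")
  attr(out, "raw") <- raw
  out
}

#' Analysis of molecular variance (AMOVA) for STR haplotypes
#'
#' Distance-based AMOVA in the Excoffier-Smouse-Quattro framework: the
#' pairwise metric values are treated as squared distances, sums of squared
#' deviations are computed from them for the nested design, and variance
#' components and Phi fixation indices are obtained from the mean squares.
#' With only populations (no `group`), a one-level design partitions
#' variance among/within populations and reports `phi_st`. With a grouping
#' (populations nested in groups) a two-level design adds the among-group
#' component and reports `phi_ct` (among groups), `phi_sc` (among
#' populations within groups) and `phi_st` (among populations overall).
#'
#' The `"squared"` metric makes `phi_st` Slatkin's Rst; the `"allele"`
#' metric gives the haplotype-level Fst analogue.
#'
#' @param data Haplotype data frame with a `population` column.
#' @param group Optional population-to-group assignment: a named character
#'   vector (`names` = populations) or a two-column data frame
#'   (`population`, `group`). If omitted and `data` has a `group` column,
#'   that is used; otherwise the design is one-level.
#' @param metric Pairwise metric used as the squared distance.
#' @param nperm Number of label permutations for a p-value on `phi_st`
#'   (0 = none). Individuals are permuted across populations.
#' @param seed Optional seed for the permutations.
#' @param loci Optional locus columns.
#' @return A `ystr_amova` object with elements `components` (tibble:
#'   source, df, SS, MS, sigma2, pct), `phi` (named numeric), `design`,
#'   and optionally `p_value`. [tidy()] returns the component table,
#'   [glance()] a one-row tibble of Phi statistics.
#' @export
amova <- function(data, group = NULL, metric = c("allele", "step", "squared"),
                  nperm = 0, seed = NULL, loci = NULL) {
  metric <- match.arg(metric)
  loci <- str_loci(data, loci)
  data <- validate_haplotypes(data, loci, missing = "error")
  pop <- as.character(data$population)
  grp <- resolve_groups(data, group)
  D <- hap_distance_matrix(hap_matrix(data, loci), metric = metric)
  res <- amova_components(D, pop, grp)
  res$metric <- metric
  if (nperm > 0) {
    obs <- res$phi[["phi_st"]]
    pop2grp <- if (is.null(grp)) NULL else {
      setNames(
        vapply(unique(pop), function(p) unique(grp[pop == p])[1], character(1)),
        unique(pop)
      )
    }
    hits <- with_seed(seed, {
      sum(vapply(seq_len(nperm), function(i) {
        pp <- sample(pop)
        gg <- if (is.null(pop2grp)) NULL else unname(pop2grp[pp])
        amova_components(D, pp, gg)$phi[["phi_st"]]
      }, numeric(1)) >= obs - 1e-12)
    })
    res$p_value <- (hits + 1) / (nperm + 1)
    res$nperm <- nperm
  }
  structure(res, class = "ystr_amova")
}

# Core AMOVA computation from a squared-distance matrix and labels.
# grp: per-individual group labels (NULL for one-level design).
amova_components <- function(D, pop, grp = NULL) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  if (P < 2) abort("AMOVA needs at least two populations.")
  n_p <- as.numeric(table(factor(pop, levels = pops)))
  ss_of <- function(idx) {
    if (length(idx) < 2) {
      return(0)
    }
    sum(D[idx, idx]) / (2 * length(idx))
  }
  ss_total <- ss_of(seq_len(N))
  ss_wp <- sum(vapply(pops, function(p) ss_of(which(pop == p)), numeric(1)))
  if (N - P <= 0) {
    abort("Within-population component undefined: every population has n = 1.")
  }
  if (is.null(grp)) {
    df <- c(among_populations = P - 1, within_populations = N - P)
    ss <- c(ss_total - ss_wp, ss_wp)
    ms <- ss / df
    nprime <- (N - sum(n_p^2) / N) / (P - 1)
    sig_w <- ms[2]
    sig_a <- (ms[1] - sig_w) / nprime
    sigma2 <- c(sig_a, sig_w)
    phi <- c(phi_st = unname(sig_a / (sig_a + sig_w)))
    design <- "one-level"
  } else {
    if (length(grp) != N) abort("One group label per individual required.")
    pg <- tapply(grp, pop, function(g) unique(g))
    if (any(lengths(pg) != 1)) {
      abort("Each population must belong to exactly one group.")
    }
    groups <- unique(grp)
    G <- length(groups)
    if (G < 2) abort("Two-level AMOVA needs at least two groups.")
    if (P - G <= 0) {
      abort("Two-level AMOVA needs more populations than groups.")
    }
    n_g <- as.numeric(table(factor(grp, levels = groups)))
    ss_wg <- sum(vapply(groups, function(g) ss_of(which(grp == g)), numeric(1)))
    df <- c(
      among_groups = G - 1, among_populations_within_groups = P - G,
      within_populations = N - P
    )
    ss <- c(ss_total - ss_wg, ss_wg - ss_wp, ss_wp)
    ms <- ss / df
    # Coefficients of the expected mean squares for the unbalanced nested
    # design (Excoffier-Smouse-Quattro).
    grp_of_pop <- vapply(pops, function(p) as.character(pg[[p]]), character(1))
    n_g_of_pop <- n_g[match(grp_of_pop, groups)]
    s1 <- sum(n_p^2 / n_g_of_pop)
    n1 <- (N - s1) / (P - G)
    n2 <- (s1 - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sig_c <- ms[3]
    sig_b <- (ms[2] - sig_c) / n1
    sig_a <- (ms[1] - sig_c - n2 * sig_b) / n3
    sigma2 <- c(sig_a, sig_b, sig_c)
    tot <- sig_a + sig_b + sig_c
    phi <- c(
      phi_ct = unname(sig_a / tot),
      phi_sc = unname(sig_b / (sig_b + sig_c)),
      phi_st = unname((sig_a + sig_b) / tot)
    )
    design <- "two-level"
  }
  components <- tibble::tibble(
    source = names(df),
    df = as.numeric(df),
    SS = unname(ss),
    MS = unname(ms),
    sigma2 = unname(sigma2),
    pct = 100 * unname(sigma2) / sum(sigma2)
  )
  list(components = components, phi = phi, design = design)
}

#' @export
print.ystr_amova <- function(x, ...) {
  cat("AMOVA (", x$design, " design, metric = ", x$metric, ")\n\n", sep = "")
  print(as.data.frame(x$components), row.names = FALSE, digits = 5)
  cat("\nPhi statistics:\n")
  print(round(x$phi, 5))
  if (!is.null(x$p_value)) {
    cat("\nP(phi_st >= observed), ", x$nperm, " permutations: ",
      format(x$p_value, digits = 4), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.ystr_amova <- function(x, ...) x$components

#' @export
glance.ystr_amova <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$phi))
  out$design <- x$design
  out$metric <- x$metric
  if (!is.null(x$p_value)) out$p_value <- x$p_value
  out
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson's metric MDS (principal coordinates) via double-centering and
#' eigendecomposition. Eigenvalues are returned so the mass on negative
#' eigenvalues -- the part of the distance structure a Euclidean embedding
#' cannot represent -- is visible.
#'
#' @param x A `ystr_dist` object or symmetric numeric matrix of distances.
#' @param dims Number of embedding dimensions.
#' @return A `ystr_mds` object: tibble of coordinates (`label`, `dim1`,
#'   `dim2`, ...) with an `eig` attribute; [glance()] summarises the
#'   eigenvalue spectrum; [autoplot()] draws the configuration.
#' @export
mds_embed <- function(x, dims = 2) {
  m <- as.matrix(x)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8)) {
    abort("MDS needs a symmetric square distance matrix.")
  }
  if (dims < 1 || dims > nrow(m) - 1) {
    abort("dims must be between 1 and n - 1.")
  }
  fit <- suppressWarnings(cmdscale(m, k = dims, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < dims) {
    # degenerate spectra (e.g. an all-zero matrix) yield fewer coordinates
    pts <- cbind(pts, matrix(0, nrow(m), dims - ncol(pts)))
  }
  pts[is.na(pts)] <- 0
  labels <- rownames(m) %||% paste0("P", seq_len(nrow(m)))
  out <- tibble::as_tibble(pts, .name_repair = ~ paste0("dim", seq_len(dims)))
  out <- dplyr::bind_cols(tibble::tibble(label = labels), out)
  structure(out,
    eig = fit$eig,
    class = c("ystr_mds", class(out))
  )
}

#' @export
glance.ystr_mds <- function(x, ...) {
  eig <- attr(x, "eig")
  tibble::tibble(
    n = nrow(x),
    dims = sum(startsWith(names(x), "dim")),
    positive_eig_mass = sum(eig[eig > 0]),
    negative_eig_mass = sum(abs(eig[eig < 0])),
    gof = if (sum(abs(eig)) > 0) {
      sum(head(sort(eig, decreasing = TRUE), sum(startsWith(names(x), "dim")))) /
        sum(abs(eig))
    } else {
      NA_real_
    }
  )
}

# ---- ystr_dist -------------------------------------------------------------

new_ystr_dist <- function(m, measure) {
  stopifnot(is.matrix(m))
  structure(list(matrix = m, measure = measure), class = "ystr_dist")
}

#' @export
as.matrix.ystr_dist <- function(x, ...) x$matrix

#' @export
print.ystr_dist <- function(x, ...) {
  cat("Population distance matrix (", x$measure, ")\n", sep = "")
  print(round(x$matrix, 5))
  invisible(x)
}

#' @export
tidy.ystr_dist <- function(x, ...) {
  m <- x$matrix
  tibble::as_tibble(m, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "value") |>
    dplyr::mutate(measure = x$measure)
}

# ---- helpers ---------------------------------------------------------------

pop_matrix <- function(data, pop, loci) {
  rows <- data$population == pop
  if (!any(rows)) abort(paste0("Population not found: ", pop))
  sub <- validate_haplotypes(
    data[rows, , drop = FALSE], loci,
    missing = "error", context = paste0("population ", pop)
  )
  hap_matrix(sub, loci)
}

cross_distances <- function(ma, mb, metric) {
  out <- matrix(0, nrow(ma), nrow(mb))
  for (l in seq_len(ncol(ma))) {
    d <- abs(outer(ma[, l], mb[, l], "-"))
    out <- out + switch(metric,
      allele = (d > 0),
      step = d,
      squared = d^2
    )
  }
  out
}

outer_pop <- function(pops, f) {
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        v <- f(pops[i], pops[j])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

resolve_groups <- function(data, group) {
  if (is.null(group)) {
    if ("group" %in% names(data)) {
      return(as.character(data$group))
    }
    return(NULL)
  }
  if (is.data.frame(group)) {
    group <- setNames(as.character(group$group), as.character(group$population))
  }
  missing <- setdiff(unique(data$population), names(group))
  if (length(missing) > 0) {
    abort(paste0(
      "No group assignment for population(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  as.character(group[as.character(data$population)])
}
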