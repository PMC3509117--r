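#' Dating parameters
#'
#' Parameters converting mutational statistics to calendar years. The
#' default mutation rate, 6.9e-4 per locus per generation, is the
#' evolutionary effective Y-STR rate commonly used with a 25-year
#' generation for haplogroup founder dating; `L` is the number of analysis
#' loci (15 for the reduced Yfiler panel).
#'
#' @param mu Mutation rate per locus per generation (> 0).
#' @param generation_years Years per generation (> 0).
#' @param L Number of loci (>= 1).
#' @return A list of class `dating_params`.
#' @export
dating_params <- function(mu = 6.9e-4, generation_years = 25, L = 15) {
  if (!is.numeric(mu) || mu <= 0) abort("mu must be > 0.")
  if (!is.numeric(generation_years) || generation_years <= 0) {
    abort("generation_years must be > 0.")
  }
  if (!is.numeric(L) || L < 1) abort("L must be >= 1.")
  structure(
    list(mu = mu, generation_years = generation_years, L = as.integer(L)),
    class = "dating_params"
  )
}

#' The rho statistic
#'
#' `rho` is the mean number of single-step mutations separating each sampled
#' individual from an assumed root haplotype. For a star genealogy its
#' standard deviation is `sqrt(sum(d_i)) / n` (each mutation an independent
#' Poisson event on its own branch). When a haplotype network is supplied,
#' the branch-sharing-aware estimator is used instead: mutational distances
#' are measured along the shortest-path tree from the root, and
#' `var(rho) = sum_e (m_e^2 * l_e) / n^2` over tree edges, where `m_e`
#' individuals descend through an edge of `l_e` steps.
#'
#' @param x Member haplotypes: a haplotype data frame or integer matrix
#'   (one row per individual, multiplicities expanded), or a
#'   `ystr_clusters` object (then `root` is taken per cluster and a tibble
#'   with one row per cluster is returned).
#' @param root Root haplotype (named vector or one-row data frame).
#' @param network Optional `ystr_network` for the branch-aware SD (only
#'   used when `x` is a cluster object, whose network is carried along).
#' @param loci Optional locus columns.
#' @return A tibble with `rho`, `rho_sd`, `n` (one row, or one per cluster).
#' @export
rho_statistic <- function(x, root = NULL, network = NULL, loci = NULL) {
  if (inherits(x, "ystr_clusters")) {
    net <- network %||% x$network
    g <- as_igraph(net)
    return(purrr::map_dfr(x$clusters, function(cl) {
      counts <- cl$members |>
        dplyr::group_by(.data$node) |>
        dplyr::summarise(n = sum(.data$n), .groups = "drop")
      # shortest-path tree from the root: per-edge descendant counts give
      # the branch-sharing-aware Saillard variance
      edge_m <- new.env(parent = emptyenv())
      edge_l <- new.env(parent = emptyenv())
      d_node <- numeric(nrow(counts))
      for (i in seq_len(nrow(counts))) {
        if (counts$node[i] == cl$root) next
        sp <- igraph::shortest_paths(
          g,
          from = cl$root, to = counts$node[i],
          weights = igraph::E(g)$steps, output = "epath"
        )$epath[[1]]
        steps <- igraph::edge_attr(g, "steps", sp)
        d_node[i] <- sum(steps)
        eids <- as.integer(sp)
        for (k in seq_along(eids)) {
          key <- as.character(eids[k])
          edge_m[[key]] <- (edge_m[[key]] %||% 0L) + counts$n[i]
          edge_l[[key]] <- steps[k]
        }
      }
      n <- sum(counts$n)
      rho <- sum(d_node * counts$n) / n
      keys <- ls(edge_m)
      v <- if (length(keys) == 0) 0 else {
        sum(vapply(keys, function(k) edge_m[[k]]^2 * edge_l[[k]], numeric(1))) / n^2
      }
      tibble::tibble(
        cluster = cl$cluster, root = cl$root,
        rho = rho, rho_sd = sqrt(v), n = n
      )
    }))
  }
  if (is.null(root)) abort("A root haplotype is required.")
  m <- if (is.matrix(x)) x else hap_matrix(x, str_loci(x, loci))
  refv <- ref_haplotype(root, colnames(m) %||% seq_len(ncol(m)))
  if (length(refv) != ncol(m)) abort("Root haplotype panel mismatch.")
  d <- dist_to_ref(m, refv, "step")
  rho_from_distances(d)
}

# Star-genealogy rho and SD from per-individual distances to the root:
# every mutation is an independent Poisson event on a private branch, so
# var(rho) = sum(d_i) / n^2.
rho_from_distances <- function(d) {
  n <- length(d)
  if (n < 1) abort("rho needs at least one individual.")
  tibble::tibble(rho = mean(d), rho_sd = sqrt(sum(d)) / n, n = n)
}

#' Convert a rho statistic to calendar years
#'
#' `age_years = rho / (L * mu) * generation_years`; the standard deviation
#' scales identically.
#'
#' @param rho,rho_sd The statistic and its SD (e.g. from
#'   [rho_statistic()]); `rho` may also be the tibble returned by
#'   [rho_statistic()], in which case `rho_sd` is ignored.
#' @param params A [dating_params()] object.
#' @return A tibble with `method`, `statistic`, `age_years`, `sd_years`.
#' @examples
#' rho_to_age(1.0, 0.5, dating_params())
#' @export
rho_to_age <- function(rho, rho_sd = 0, params = dating_params()) {
  stopifnot(inherits(params, "dating_params"))
  if (is.data.frame(rho)) {
    tbl <- rho
    scale <- params$generation_years / (params$L * params$mu)
    out <- tibble::tibble(
      method = "rho",
      statistic = tbl$rho,
      age_years = tbl$rho * scale,
      sd_years = tbl$rho_sd * scale
    )
    extra <- setdiff(names(tbl), c("rho", "rho_sd"))
    return(dplyr::bind_cols(tbl[extra], out))
  }
  scale <- params$generation_years / (params$L * params$mu)
  tibble::tibble(
    method = "rho",
    statistic = rho,
    age_years = rho * scale,
    sd_years = rho_sd * scale
  )
}

#' TD (average squared distance) dating
#'
#' The ASD statistic is the mean over individuals and loci of the squared
#' repeat difference from a founder haplotype. Under the stepwise mutation
#' model `E[ASD] = mu * t` per locus, so `age_years = ASD / mu *
#' generation_years`. The SD is taken across loci: `sd(per-locus ASD) /
#' sqrt(L)`, scaled to years.
#'
#' @param x Haplotype data frame or integer matrix of member individuals.
#' @param founder Founder haplotype (named vector or one-row data frame).
#' @param params A [dating_params()] object.
#' @param loci Optional locus columns.
#' @return A tibble with `method`, `statistic` (ASD), `age_years`,
#'   `sd_years`, `n`.
#' @export
td_statistic <- function(x, founder, params = dating_params(), loci = NULL) {
  stopifnot(inherits(params, "dating_params"))
  m <- if (is.matrix(x)) x else hap_matrix(x, str_loci(x, loci))
  refv <- ref_haplotype(founder, colnames(m) %||% seq_len(ncol(m)))
  if (length(refv) != ncol(m)) abort("Founder haplotype panel mismatch.")
  sq <- sweep(m, 2, refv)^2
  per_locus <- colMeans(sq)
  asd <- mean(per_locus)
  sd_asd <- if (ncol(m) > 1) sd(per_locus) / sqrt(ncol(m)) else 0
  scale <- params$generation_years / params$mu
  tibble::tibble(
    method = "td",
    statistic = asd,
    age_years = asd * scale,
    sd_years = sd_asd * scale,
    n = nrow(m)
  )
}

#' Summarise founder-cluster ages
#'
#' Combines per-cluster age estimates into a single founding-age summary:
#' the point estimate is the unweighted mean of the cluster ages and the
#' dispersion the unweighted mean of the cluster SDs (the convention of
#' founder-analysis tables); `weighting = "invvar"` gives the
#' inverse-variance weighted mean and its standard error instead.
#'
#' @param estimates A data frame with columns `age_years` and `sd_years`
#'   (one row per cluster), or a numeric vector of ages with `sd_years`
#'   supplied separately.
#' @param sd_years SDs when `estimates` is a numeric vector.
#' @param weighting `"mean"` (default) or `"invvar"`.
#' @return A one-row tibble with `age_years`, `sd_years`, `k` (number of
#'   clusters).
#' @examples
#' founder_age_summary(
#'   data.frame(age_years = c(1110, 1024, 2081), sd_years = c(785, 407, 873))
#' )
#' @export
founder_age_summary <- function(estimates, sd_years = NULL,
                                weighting = c("mean", "invvar")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(estimates)) {
    ages <- estimates$age_years
    sds <- estimates$sd_years
  } else {
    ages <- as.numeric(estimates)
    sds <- as.numeric(sd_years)
  }
  if (length(ages) < 1) abort("At least one cluster estimate is required.")
  if (length(sds) != length(ages)) {
    abort("One SD per age estimate is required.")
  }
  if (weighting == "mean") {
    tibble::tibble(
      age_years = mean(ages), sd_years = mean(sds), k = length(ages)
    )
  } else {
    w <- 1 / sds^2
    tibble::tibble(
      age_years = sum(w * ages) / sum(w),
      sd_years = sqrt(1 / sum(w)),
      k = length(ages)
    )
  }
}

#' Population expansion age by rho dating from a central haplotype
#'
#' Dates each population's expansion by treating a central haplotype as the
#' root and applying rho dating with the single-step metric. The default
#' root is each population's per-locus modal haplotype (the componentwise
#' mode of repeat counts), the usual construction for STR expansion dating:
#' in a diverse population most whole haplotypes are singletons, so the
#' most frequent whole haplotype is an arbitrary tie-break, while the
#' per-locus mode sits at the centre of the radiation. Ages are reported in
#' years and KYA.
#'
#' @param data Haplotype data frame with a `population` column.
#' @param params A [dating_params()] object.
#' @param center Optional reference haplotype used for every population;
#'   default is each population's own per-locus modal haplotype.
#' @param loci Optional locus columns.
#' @return A tibble with one row per population: `population`, `n`, `rho`,
#'   `rho_sd`, `age_years`, `sd_years`, `age_kya`, `age_sd_kya`.
#' @export
group_expansion_age <- function(data, params = dating_params(), center = NULL,
                                loci = NULL) {
  stopifnot(inherits(params, "dating_params"))
  loci <- str_loci(data, loci)
  modal <- if (is.null(center)) {
    modal_haplotype(data, per_locus = TRUE, loci = loci)
  } else {
    NULL
  }
  per_population(data, loci, function(m, pop) {
    refv <- if (is.null(center)) {
      ref_haplotype(modal[modal$population == pop, , drop = FALSE][, -1], loci)
    } else {
      ref_haplotype(center, loci)
    }
    if (nrow(m) < 2) {
      abort(paste0("Expansion age needs n >= 2 (population ", pop, ")."))
    }
    r <- rho_from_distances(dist_to_ref(m, refv, "step"))
    a <- rho_to_age(r$rho, r$rho_sd, params)
    tibble::tibble(
      n = nrow(m), rho = r$rho, rho_sd = r$rho_sd,
      age_years = a$age_years, sd_years = a$sd_years,
      age_kya = a$age_years / 1000, age_sd_kya = a$sd_years / 1000
    )
  })
}

#' Date founder clusters with rho and TD
#'
#' Produces a founder-analysis table: one row per cluster with its size,
#' rho-based TMRCA and TD-based TMRCA (both in years before present), plus
#' a summary row combining clusters via [founder_age_summary()].
#'
#' @param clusters A `ystr_clusters` object.
#' @param params A [dating_params()] object.
#' @param summary_method Default age used in the summary: `"rho"` or
#'   `"td"`.
#' @return A list with `table` (per-cluster tibble) and `summary` (one-row
#'   tibble from [founder_age_summary()]).
#' @export
date_founder_clusters <- function(clusters, params = dating_params(),
                                  summary_method = c("rho", "td")) {
  stopifnot(inherits(clusters, "ystr_clusters"))
  summary_method <- match.arg(summary_method)
  rho_tbl <- rho_to_age(rho_statistic(clusters), params = params)
  td_tbl <- purrr::map_dfr(clusters$clusters, function(cl) {
    counts <- cl$members |>
      dplyr::group_by(.data$node) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    m <- clusters$network$haps[counts$node, , drop = FALSE]
    m <- m[rep(seq_len(nrow(m)), counts$n), , drop = FALSE]
    dplyr::mutate(
      td_statistic(m, cl$root_haplotype, params),
      cluster = cl$cluster
    )
  })
  table <- rho_tbl |>
    dplyr::transmute(
      cluster = .data$cluster, root = .data$root, n = .data$n,
      rho = .data$statistic,
      age_rho = .data$age_years, sd_rho = .data$sd_years
    ) |>
    dplyr::left_join(
      dplyr::transmute(td_tbl,
        cluster = .data$cluster, asd = .data$statistic,
        age_td = .data$age_years, sd_td = .data$sd_years
      ),
      by = "cluster"
    )
  est <- if (summary_method == "rho") {
    data.frame(age_years = table$age_rho, sd_years = table$sd_rho)
  } else {
    data.frame(age_years = table$age_td, sd_years = table$sd_td)
  }
  list(table = table, summary = founder_age_summary(est))
}
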