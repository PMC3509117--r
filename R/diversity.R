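#' Haplotype diversity per population
#'
#' Unbiased gene (haplotype) diversity `HD = n/(n-1) * (1 - sum(p_i^2))`
#' over the whole-haplotype frequencies `p_i`, with Nei's sampling-variance
#' estimator for the standard deviation:
#' `V(HD) = 2/(n(n-1)) * (2(n-2) * (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2)`.
#'
#' @param data Haplotype data frame with a `population` column.
#' @param loci Optional locus columns.
#' @return A tibble with one row per population: `population`, `n`, `h`
#'   (number of distinct haplotypes), `hd`, `hd_sd`.
#' @examples
#' d <- tibble::tibble(
#'   population = "A",
#'   DYS19 = c(14, 14, 15, 16), DYS390 = c(23, 23, 23, 23)
#' )
#' haplotype_diversity(d)
#' @export
haplotype_diversity <- function(data, loci = NULL) {
  loci <- str_loci(data, loci)
  per_population(data, loci, function(m, pop) {
    n <- nrow(m)
    if (n < 2) {
      abort(paste0(
        "Haplotype diversity needs n >= 2 (population ", pop, " has n = ",
        n, ")."
      ))
    }
    key <- apply(m, 1, paste, collapse = "\r")
    p <- as.numeric(table(key)) / n
    s2 <- sum(p^2)
    s3 <- sum(p^3)
    hd <- n / (n - 1) * (1 - s2)
    v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
    tibble::tibble(
      n = n, h = length(p), hd = hd, hd_sd = sqrt(max(v, 0))
    )
  })
}

#' Mean pairwise difference within populations
#'
#' Mean of a pairwise haplotype metric over all unordered pairs of
#' individuals in each population (pairs within a repeated haplotype
#' contribute zero). The default metric counts differing loci, the usual
#' "number of pairwise differences" for STR haplotypes.
#'
#' Two dispersion estimators are available. `"empirical"` (default) is the
#' sample standard deviation of the metric over the unordered pairs --- a
#' description of the pairwise-difference distribution. `"tajima"` is the
#' total (sampling + stochastic) variance of the mean,
#' `V = (3n(n+1)MPD + 2(n^2+n+3)MPD^2) / (11(n^2-7n+6))`, as reported by
#' standard population-genetics software.
#'
#' @inheritParams haplotype_diversity
#' @param metric Pairwise metric, see [hap_distance()].
#' @param sd_method `"empirical"` or `"tajima"`.
#' @return A tibble with `population`, `n`, `mpd`, `mpd_sd`.
#' @export
mean_pairwise_difference <- function(data, metric = c("allele", "step", "squared"),
                                     sd_method = c("empirical", "tajima"),
                                     loci = NULL) {
  metric <- match.arg(metric)
  sd_method <- match.arg(sd_method)
  loci <- str_loci(data, loci)
  per_population(data, loci, function(m, pop) {
    n <- nrow(m)
    if (n < 2) {
      abort(paste0(
        "Mean pairwise difference needs n >= 2 (population ", pop, ")."
      ))
    }
    D <- hap_distance_matrix(m, metric = metric)
    pairs <- D[upper.tri(D)]
    mpd <- mean(pairs)
    s <- if (sd_method == "empirical") {
      if (length(pairs) > 1) sd(pairs) else 0
    } else {
      v <- (3 * n * (n + 1) * mpd + 2 * (n^2 + n + 3) * mpd^2) /
        (11 * (n^2 - 7 * n + 6))
      sqrt(max(v, 0))
    }
    tibble::tibble(n = n, mpd = mpd, mpd_sd = s)
  })
}

#' Mean per-locus repeat-number variance
#'
#' Arithmetic mean over loci of the sample variance (denominator `n - 1`) of
#' repeat counts at each locus; the "Variance" column of STR diversity
#' tables and the quantity that grows linearly with expansion time under the
#' stepwise mutation model.
#'
#' @inheritParams haplotype_diversity
#' @return A tibble with `population`, `n`, `variance`.
#' @export
repeat_variance <- function(data, loci = NULL) {
  loci <- str_loci(data, loci)
  per_population(data, loci, function(m, pop) {
    n <- nrow(m)
    if (n < 2) {
      abort(paste0("Repeat variance needs n >= 2 (population ", pop, ")."))
    }
    tibble::tibble(n = n, variance = mean(apply(m, 2, var)))
  })
}

#' Modal haplotype per population
#'
#' The most frequent whole haplotype in each population; ties are broken by
#' taking the lexicographically smallest repeat vector among the
#' maximal-count haplotypes, so the result is deterministic. With
#' `per_locus = TRUE` the per-locus mode is returned instead (the smallest
#' modal value at each locus on ties); note a per-locus mode need not be an
#' observed haplotype.
#'
#' @inheritParams haplotype_diversity
#' @param per_locus Return per-locus modes instead of the modal whole
#'   haplotype.
#' @return A tibble with `population` and one column per locus.
#' @export
modal_haplotype <- function(data, per_locus = FALSE, loci = NULL) {
  loci <- str_loci(data, loci)
  per_population(data, loci, function(m, pop) {
    if (per_locus) {
      mode1 <- function(v) {
        tb <- table(v)
        as.integer(names(tb)[tb == max(tb)][1])
      }
      vals <- vapply(seq_len(ncol(m)), function(j) mode1(m[, j]), integer(1))
    } else {
      key <- apply(m, 1, paste, collapse = "\r")
      tb <- table(key)
      top <- names(tb)[tb == max(tb)]
      rows <- m[match(top, key), , drop = FALSE]
      ord <- do.call(order, as.data.frame(rows))
      vals <- rows[ord[1], ]
    }
    tibble::as_tibble(as.list(setNames(as.integer(vals), colnames(m))))
  })
}

#' Average mutational distance from a reference haplotype
#'
#' Mean over individuals of the pairwise metric between each haplotype and a
#' fixed reference (typically a modal haplotype); the "AMD" column of STR
#' diversity tables. The default metric is the single-step mutational
#' distance `sum(|a - b|)`.
#'
#' @inheritParams haplotype_diversity
#' @param ref Reference haplotype: a named numeric vector or a one-row data
#'   frame covering the panel (e.g. one row of [modal_haplotype()] output).
#' @param metric Pairwise metric, see [hap_distance()].
#' @return A tibble with `population`, `n`, `amd`.
#' @export
avg_mutational_distance <- function(data, ref,
                                    metric = c("step", "allele", "squared"),
                                    loci = NULL) {
  metric <- match.arg(metric)
  loci <- str_loci(data, loci)
  refv <- ref_haplotype(ref, loci)
  per_population(data, loci, function(m, pop) {
    tibble::tibble(n = nrow(m), amd = mean(dist_to_ref(m, refv, metric)))
  })
}

#' Combined per-population diversity report
#'
#' One row per population with sample size, haplotype count, haplotype
#' diversity, mean pairwise difference, mean repeat variance, optionally the
#' average mutational distance from a reference haplotype, and optionally a
#' rho-statistic expansion age (see [group_expansion_age()]).
#'
#' @inheritParams mean_pairwise_difference
#' @param amd_ref Optional reference haplotype for the AMD column.
#' @param amd_metric Metric for AMD (default `"step"`).
#' @param params Optional [dating_params()]; when supplied, `age_kya` and
#'   `age_sd_kya` columns are added by rho dating from each population's
#'   modal haplotype.
#' @return A tibble, one row per population.
#' @export
diversity_summary <- function(data, metric = c("allele", "step", "squared"),
                              sd_method = c("empirical", "tajima"),
                              amd_ref = NULL, amd_metric = "step",
                              params = NULL, loci = NULL) {
  metric <- match.arg(metric)
  sd_method <- match.arg(sd_method)
  loci <- str_loci(data, loci)
  out <- haplotype_diversity(data, loci) |>
    dplyr::left_join(
      mean_pairwise_difference(data, metric, sd_method, loci) |>
        dplyr::select(-"n"),
      by = "population"
    ) |>
    dplyr::left_join(
      repeat_variance(data, loci) |> dplyr::select(-"n"),
      by = "population"
    )
  if (!is.null(amd_ref)) {
    out <- dplyr::left_join(
      out,
      avg_mutational_distance(data, amd_ref, amd_metric, loci) |>
        dplyr::select(-"n"),
      by = "population"
    )
  }
  if (!is.null(params)) {
    ages <- group_expansion_age(data, params, loci = loci)
    out <- dplyr::left_join(
      out,
      dplyr::select(ages, "population", "age_kya", "age_sd_kya"),
      by = "population"
    )
  }
  out
}

# Apply f(matrix, population_name) per population, bind with population col.
per_population <- function(data, loci, f) {
  if (!("population" %in% names(data))) {
    abort("Haplotype data needs a 'population' column.")
  }
  data <- validate_haplotypes(data, loci, missing = "error")
  pops <- unique(data$population)
  purrr::map_dfr(pops, function(p) {
    m <- hap_matrix(data[data$population == p, , drop = FALSE], loci)
    dplyr::bind_cols(tibble::tibble(population = p), f(m, p))
  })
}
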