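#' Simulate a star-genealogy STR population
#'
#' Every sampled individual descends independently from the founder along a
#' private branch of `t_gens` generations. At each locus the number of
#' mutations is Poisson(`mu * t_gens`) and each mutation moves the repeat
#' count by +1 or -1 with equal probability (single-step symmetric
#' stepwise mutation model, no range constraints). Repeat counts below 1
#' are floored to 1 at output with a warning, since real repeat counts are
#' small positive integers.
#'
#' @param n Number of individuals.
#' @param t_gens Branch length in generations (>= 0).
#' @param founder Founder haplotype: named integer vector (names become the
#'   locus columns) or unnamed vector (loci named `L01`, `L02`, ...).
#' @param mu Mutation rate per locus per generation.
#' @param seed Optional seed; the output is fully determined by it.
#' @param population Population label.
#' @return A haplotype tibble (`id`, `population`, locus columns) with the
#'   true `t_gens` and founder in attributes `"t_gens"` and `"founder"`.
#' @examples
#' simulate_star_population(3, 100, c(DYS19 = 14, DYS390 = 23), seed = 1)
#' @export
simulate_star_population <- function(n, t_gens, founder, mu = 6.9e-4,
                                     seed = NULL, population = "pop1") {
  if (n < 1) abort("n must be >= 1.")
  if (t_gens < 0) abort("t_gens must be >= 0.")
  if (mu < 0) abort("mu must be >= 0.")
  founder <- prepare_founder(founder)
  L <- length(founder)
  m <- with_seed(seed, {
    steps <- smm_displacement(n * L, mu * t_gens)
    matrix(rep(founder, each = n) + steps, n, L)
  })
  finish_simulated(m, names(founder), population,
    t_gens = t_gens, founder = founder
  )
}

#' Simulate a Kingman-coalescent STR population
#'
#' Draws a neutral Kingman coalescent genealogy for `n` lineages in a
#' population of effective size `Ne` (pairwise coalescence rate
#' `k(k-1)/(2*Ne)` per generation with `k` active lineages), places
#' stepwise mutations on every branch (Poisson(`mu * branch length`) per
#' locus, steps of +/-1), and returns the tip haplotypes. Unlike the star
#' genealogy, lineages share internal branches, which is what inflates the
#' variance of rho-type estimators on real genealogies.
#'
#' @inheritParams simulate_star_population
#' @param Ne Effective population size in individuals (> 0).
#' @return A haplotype tibble; the realised TMRCA in generations is in
#'   attribute `"tmrca_gens"`.
#' @export
simulate_coalescent_population <- function(n, Ne, founder, mu = 6.9e-4,
                                           seed = NULL, population = "pop1") {
  if (n < 2) abort("n must be >= 2.")
  if (Ne <= 0) abort("Ne must be > 0.")
  if (mu < 0) abort("mu must be >= 0.")
  founder <- prepare_founder(founder)
  L <- length(founder)
  res <- with_seed(seed, {
    total <- 2L * n - 1L
    parent <- integer(total)
    time <- numeric(total) # node times, 0 at tips, increasing into the past
    active <- seq_len(n)
    nxt <- n + 1L
    t_now <- 0
    while (length(active) > 1) {
      k <- length(active)
      t_now <- t_now + rexp(1, rate = k * (k - 1) / (2 * Ne))
      pair <- sample(active, 2)
      parent[pair] <- nxt
      time[nxt] <- t_now
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1L
    }
    root <- active
    haps <- matrix(0L, total, L)
    haps[root, ] <- founder
    # assign children after parents, walking down from the root
    for (node in order(time, decreasing = TRUE)) {
      if (node == root) next
      br <- time[parent[node]] - time[node]
      haps[node, ] <- haps[parent[node], ] + smm_displacement(L, mu * br)
    }
    list(m = haps[seq_len(n), , drop = FALSE], tmrca = time[root])
  })
  finish_simulated(res$m, names(founder), population,
    tmrca_gens = res$tmrca, founder = founder
  )
}

#' Simulate a founder-effect out-of-source scenario
#'
#' Generates the data structure the package's analyses assume: deep,
#' diverse source populations and shallow focal (diaspora) populations
#' founded recently by a handful of haplotypes drawn from the first source
#' population. Defaults emulate a Romani-like history: two source
#' populations of n = 64 and 43 expanding in star fashion for 642 and 998
#' generations (about 16 and 25 thousand years at 25 years/generation), and
#' three focal populations of n = 21, 41 and 76 founded 56 generations
#' (about 1400 years) before present from 1, 2 and 2 founder haplotypes
#' respectively. All lineages evolve under the single-step symmetric SMM at
#' `mu` per locus per generation.
#'
#' @param config Optional list overriding any of: `L`, `mu`,
#'   `generation_years`, `base_repeat`, `source_n`, `source_t_gens`,
#'   `focal_n`, `founding_t_gens`, `founders_per_focal`,
#'   `source_divergence_gens` (star-branch generations separating the
#'   source founder haplotypes from a common base).
#' @param seed Optional seed; output is fully determined by it.
#' @return A list with `data` (haplotype tibble over all populations, with
#'   a `group` column `"Source"`/`"Focal"`) and `truth` (list: the config
#'   in force, founder haplotypes per focal population, founder population
#'   of origin, founding time and source expansion times in generations).
#' @export
simulate_roma_scenario <- function(config = list(), seed = NULL) {
  cfg <- utils::modifyList(
    list(
      L = 15L,
      mu = 6.9e-4,
      generation_years = 25,
      base_repeat = 14L,
      source_n = c(64L, 43L),
      source_t_gens = c(642, 998),
      focal_n = c(21L, 41L, 76L),
      founding_t_gens = 56,
      founders_per_focal = c(1L, 2L, 2L),
      source_divergence_gens = 400
    ),
    config
  )
  if (cfg$mu <= 0 || cfg$founding_t_gens <= 0 || any(cfg$source_t_gens <= 0)) {
    abort("Rates and times must be positive.")
  }
  if (length(cfg$founders_per_focal) != length(cfg$focal_n)) {
    abort("founders_per_focal must match focal_n in length.")
  }
  loci <- sprintf("L%02d", seq_len(cfg$L))
  base <- setNames(rep(cfg$base_repeat, cfg$L), loci)
  with_seed(seed, {
    src_founders <- lapply(seq_along(cfg$source_n), function(i) {
      setNames(
        base + smm_displacement(cfg$L, cfg$mu * cfg$source_divergence_gens),
        loci
      )
    })
    sources <- purrr::map_dfr(seq_along(cfg$source_n), function(i) {
      d <- simulate_star_population(
        cfg$source_n[i], cfg$source_t_gens[i], src_founders[[i]],
        mu = cfg$mu, population = paste0("Source", i)
      )
      d$group <- "Source"
      d
    })
    focal_founders <- list()
    focals <- purrr::map_dfr(seq_along(cfg$focal_n), function(i) {
      k <- cfg$founders_per_focal[i]
      pool <- sources[sources$population == "Source1", loci, drop = FALSE]
      picks <- pool[sample(nrow(pool), k, replace = FALSE), , drop = FALSE]
      focal_founders[[i]] <<- as.matrix(picks)
      sizes <- diff(round(seq(0, cfg$focal_n[i], length.out = k + 1)))
      purrr::map_dfr(seq_len(k), function(j) {
        d <- simulate_star_population(
          sizes[j], cfg$founding_t_gens, unlist(picks[j, ]),
          mu = cfg$mu, population = paste0("Focal", i)
        )
        d$founder_index <- j
        d
      }) |> dplyr::mutate(group = "Focal")
    })
    focals$id <- sprintf("ind%04d", seq_len(nrow(focals)))
    sources$id <- sprintf("src%04d", seq_len(nrow(sources)))
    truth_assignment <- focals[c("id", "population", "founder_index")]
    focals$founder_index <- NULL
    data <- dplyr::bind_rows(sources, focals)[
      , c("id", "population", "group", loci)
    ]
    attr(data, "loci") <- loci
    list(
      data = data,
      truth = list(
        config = cfg,
        source_founders = src_founders,
        focal_founders = focal_founders,
        founder_source = "Source1",
        founding_t_gens = cfg$founding_t_gens,
        founding_t_years = cfg$founding_t_gens * cfg$generation_years,
        source_t_gens = cfg$source_t_gens,
        founder_assignment = truth_assignment
      )
    )
  })
}

#' Write a simulated scenario to files
#'
#' Runs [simulate_roma_scenario()] and writes the haplotype table (TSV, the
#' [read_haplotype_table()] layout) and the ground truth (JSON) into a
#' directory.
#'
#' @inheritParams simulate_roma_scenario
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the two file paths.
#' @export
simulate_to_files <- function(config = list(), dir, seed = NULL) {
  sim <- simulate_roma_scenario(config, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "haplotypes.tsv")
  truth_path <- file.path(dir, "ground_truth.json")
  write_haplotype_table(sim$data, data_path)
  truth <- sim$truth
  truth$source_founders <- lapply(truth$source_founders, as.list)
  truth$focal_founders <- lapply(truth$focal_founders, function(m) {
    apply(m, 1, as.list, simplify = FALSE)
  })
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, truth = truth_path))
}

# Net displacement of a symmetric single-step random walk with a
# Poisson(lambda) number of steps, vectorised.
smm_displacement <- function(n, lambda) {
  k <- rpois(n, lambda)
  as.integer(2L * rbinom(n, k, 0.5) - k)
}

prepare_founder <- function(founder) {
  founder <- unlist(founder)
  if (!is.numeric(founder) || length(founder) < 1) {
    abort("Founder haplotype must be a numeric vector.")
  }
  if (is.null(names(founder))) {
    names(founder) <- sprintf("L%02d", seq_along(founder))
  }
  setNames(as.integer(founder), names(founder))
}

finish_simulated <- function(m, loci, population, ...) {
  if (any(m < 1)) {
    warn(paste0(
      sum(m < 1), " simulated repeat count(s) below 1 floored to 1."
    ))
    m[m < 1] <- 1L
  }
  colnames(m) <- loci
  out <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("ind%04d", seq_len(nrow(m))),
      population = population
    ),
    tibble::as_tibble(m)
  )
  attr(out, "loci") <- loci
  extras <- list(...)
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  out
}
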