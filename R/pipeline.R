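#' Run the full Y-STR phylogeography analysis
#'
#' Orchestrates every stage of the package on one haplotype table and
#' writes plain TSV reports into an output directory: per-population
#' diversity (with expansion ages), the combined within/between distance
#' table, (delta-mu)^2 and Rst matrices, MDS coordinates of the Rst matrix,
#' AMOVA group comparisons, the median-joining network (node/edge tables
#' and GML), and -- when focal and source populations are named -- founder
#' clusters with rho/TD dating. Every report carries header comment lines
#' with the package version and a hash of the configuration, so reruns with
#' the same inputs are byte-identical.
#'
#' @param data Haplotype data frame, or a path passed to
#'   [read_haplotype_table()].
#' @param outdir Output directory (created if needed).
#' @param focal,source Optional character vectors of focal (e.g. diaspora)
#'   and source population labels; enable the network/founder/dating and
#'   AMOVA comparison stages.
#' @param group Optional population-to-group assignment for a two-level
#'   AMOVA (see [amova()]).
#' @param metric Pairwise metric for diversity/distance stages.
#' @param params A [dating_params()] object.
#' @param epsilon Median-joining tolerance.
#' @param stages Character subset of
#'   `c("diversity", "distances", "amova", "network", "dating", "mds")`.
#' @param assignment Optional manual founder assignment (see
#'   [extract_founder_clusters()]).
#' @param prune Apply [mp_prune()] to the network when its median-vector
#'   count is within the exact-enumeration cap.
#' @param loci Optional locus columns.
#' @return Invisibly, a list of the computed objects and written paths.
#' @export
run_full_analysis <- function(data, outdir,
                              focal = NULL, source = NULL, group = NULL,
                              metric = "allele",
                              params = dating_params(),
                              epsilon = 0,
                              stages = c(
                                "diversity", "distances", "amova",
                                "network", "dating", "mds"
                              ),
                              assignment = NULL, prune = FALSE,
                              loci = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(data) && length(data) == 1) {
    data <- read_haplotype_table(data)
  }
  loci <- str_loci(data, loci)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(
    loci = loci, focal = focal, source = source, metric = metric,
    mu = params$mu, generation_years = params$generation_years,
    L = params$L, epsilon = epsilon, stages = stages, prune = prune
  )
  hdr <- report_header(cfg)
  out <- list(config = cfg, paths = character(0))
  emit <- function(tbl, name) {
    path <- file.path(outdir, name)
    writeLines(hdr, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
    out$paths[[name]] <<- path
    path
  }

  if ("diversity" %in% stages) {
    amd_ref <- NULL
    if (!is.null(focal)) {
      pooled <- data[data$population %in% focal, , drop = FALSE]
      pooled$population <- "pooled_focal"
      amd_ref <- modal_haplotype(pooled, loci = loci)[, -1]
    }
    out$diversity <- diversity_summary(
      data,
      metric = metric, amd_ref = amd_ref, params = params, loci = loci
    )
    emit(out$diversity, "diversity.tsv")
  }

  if ("distances" %in% stages) {
    out$combined <- combined_distance_table(data, metric = metric, loci = loci)
    emit(
      tibble::as_tibble(as.matrix(out$combined), rownames = "population"),
      "distance_combined.tsv"
    )
    out$delta_mu <- delta_mu_matrix(data, loci = loci)
    emit(
      tibble::as_tibble(as.matrix(out$delta_mu), rownames = "population"),
      "delta_mu.tsv"
    )
    out$rst <- rst_matrix(data, loci = loci)
    emit(
      tibble::as_tibble(as.matrix(out$rst), rownames = "population"),
      "rst.tsv"
    )
  }

  if ("amova" %in% stages) {
    if (!is.null(focal) && !is.null(source)) {
      # focal group vs each source population's group: two-level design
      pops <- unique(data$population)
      others <- setdiff(pops, focal)
      comp <- purrr::map_dfr(intersect(source, others), function(s) {
        sub <- data[data$population %in% c(focal, s), , drop = FALSE]
        gmap <- setNames(
          ifelse(unique(sub$population) %in% focal, "focal", "source"),
          unique(sub$population)
        )
        fit <- tryCatch(
          amova(sub, group = gmap, metric = metric, loci = loci),
          error = function(e) amova(sub, metric = metric, loci = loci)
        )
        tibble::tibble(
          comparison = paste0("focal_vs_", s),
          phi_st = fit$phi[["phi_st"]],
          phi_ct = if ("phi_ct" %in% names(fit$phi)) fit$phi[["phi_ct"]] else NA_real_
        )
      })
      out$amova_comparisons <- comp
      emit(comp, "amova_comparisons.tsv")
    }
    grp <- resolve_groups(data, group)
    if (!is.null(grp) && length(unique(grp)) >= 2) {
      out$amova <- amova(data, group = group, metric = metric, loci = loci)
      emit(tidy(out$amova), "amova_components.tsv")
      emit(glance(out$amova), "amova_phi.tsv")
    }
  }

  if ("network" %in% stages) {
    net_data <- if (!is.null(focal) && !is.null(source)) {
      data[data$population %in% c(focal, source), , drop = FALSE]
    } else {
      data
    }
    net <- build_median_joining_network(net_data, epsilon = epsilon, loci = loci)
    if (prune && sum(!net$observed) <= 16) net <- mp_prune(net)
    out$network <- net
    emit(network_nodes(net), "network_nodes.tsv")
    emit(network_edges(net), "network_edges.tsv")
    gml <- file.path(outdir, "network.gml")
    write_network(net, gml, format = "gml")
    out$paths[["network.gml"]] <- gml
  }

  if ("dating" %in% stages && !is.null(focal) && !is.null(source) &&
    "network" %in% stages) {
    out$clusters <- extract_founder_clusters(
      out$network,
      focal = focal, source = source, assignment = assignment
    )
    dated <- date_founder_clusters(out$clusters, params = params)
    out$founder_table <- dated$table
    out$founder_summary <- dated$summary
    emit(dated$table, "founder_clusters.tsv")
    emit(dated$summary, "founder_summary.tsv")
  }

  if ("mds" %in% stages && "distances" %in% stages &&
    length(unique(data$population)) >= 3) {
    out$mds <- mds_embed(out$rst, dims = 2)
    emit(tibble::as_tibble(out$mds), "mds_coordinates.tsv")
  }

  invisible(out)
}

# Stable polynomial hash of the serialised configuration for report
# provenance (mod 2^31 - 1 so it stays in integer-exact double range).
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

report_header <- function(cfg) {
  c(
    paste0(
      "# ystrhap ",
      as.character(utils::packageVersion("ystrhap")),
      " config=", config_hash(cfg)
    )
  )
}
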