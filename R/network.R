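#' Haplotype networks for multistate STR data
#'
#' Networks over distinct STR haplotypes with edges weighted by single-step
#' mutational differences. [build_minimum_spanning_network()] returns the
#' union of all minimum spanning trees (every link that occurs in at least
#' one MST under the weighted step metric), optionally relaxed by a
#' tolerance `epsilon`: a link of length `d` is kept whenever
#' `d <= minimax(u, v) + epsilon`, where `minimax` is the smallest possible
#' maximum link along any path between the two haplotypes.
#' [build_median_joining_network()] iterates: build the spanning network,
#' and for every connected triplet of nodes add its quasi-median (the
#' per-locus median of the three repeat counts) as an inferred node whenever
#' connecting the triplet through it is strictly cheaper than the best
#' pairwise connection; repeat until no new median vectors arise. Inferred
#' leaf nodes are discarded. [mp_prune()] applies maximum-parsimony
#' cleaning: it deletes every median vector and link that is not part of
#' some minimum-total-length tree (within the network) connecting all
#' observed haplotypes.
#'
#' STR characters are treated as ordered multistate: the contribution of a
#' locus to a link is `weight * |repeat difference|`. The default weight is
#' 10 per locus and `epsilon = 0`, the conventional defaults for this class
#' of network software; both are configurable. Haplotypes are processed in
#' lexicographic order and candidate medians in sorted order, so networks
#' are reproducible.
#'
#' @param data Haplotype data frame with a `population` column.
#' @param epsilon Non-negative tolerance on the spanning criterion.
#' @param weights Per-locus character weights (default 10 each).
#' @param loci Optional locus columns.
#' @param max_iter Iteration cap for the median-joining loop.
#' @return A `ystr_network` object: node matrix (observed haplotypes and
#'   median vectors), per-population node multiplicities, and an edge table
#'   with weighted `length` and unweighted mutational `steps`. See
#'   [network_nodes()], [network_edges()], [as_igraph()],
#'   [write_network()], [autoplot.ystr_network()].
#' @examples
#' d <- tibble::tibble(
#'   population = "A",
#'   DYS19 = c(14L, 15L, 16L), DYS390 = c(23L, 23L, 23L)
#' )
#' network_edges(build_minimum_spanning_network(d))
#' @export
build_minimum_spanning_network <- function(data, epsilon = 0, weights = NULL,
                                           loci = NULL) {
  st <- network_state(data, epsilon, weights, loci)
  finalize_network(st)
}

#' @rdname build_minimum_spanning_network
#' @export
build_median_joining_network <- function(data, epsilon = 0, weights = NULL,
                                         loci = NULL, max_iter = 50L) {
  st <- network_state(data, epsilon, weights, loci)
  for (iter in seq_len(max_iter)) {
    edges <- msn_edge_matrix(st)
    new_medians <- candidate_medians(st, edges)
    if (nrow(new_medians) == 0) {
      return(finalize_network(st, prune_leaf_medians = TRUE))
    }
    st$haps <- rbind(st$haps, new_medians)
    st$observed <- c(st$observed, rep(FALSE, nrow(new_medians)))
  }
  abort(paste0(
    "Median-joining did not converge in ", max_iter, " iterations (",
    nrow(st$haps), " nodes); raise max_iter or check the input."
  ))
}

#' Maximum-parsimony pruning of a haplotype network
#'
#' Removes median vectors and links that lie in no minimum-total-length
#' tree, within the network, connecting all observed haplotypes. Exact by
#' enumeration over subsets of median vectors (all minimum spanning trees of
#' each candidate node set are unioned); observed nodes are never deleted.
#'
#' @param network A `ystr_network`.
#' @param max_medians Enumeration cap; more median vectors than this is an
#'   error (2^m subsets are examined).
#' @return The pruned `ystr_network`.
#' @export
mp_prune <- function(network, max_medians = 16L) {
  stopifnot(inherits(network, "ystr_network"))
  obs <- which(network$observed)
  med <- which(!network$observed)
  if (length(med) > max_medians) {
    abort(paste0(
      length(med), " median vectors exceed the exact-pruning cap (",
      max_medians, ")."
    ))
  }
  ids <- rownames(network$haps)
  n <- length(ids)
  W <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(W) <- 0
  for (k in seq_len(nrow(network$edges))) {
    i <- match(network$edges$from[k], ids)
    j <- match(network$edges$to[k], ids)
    W[i, j] <- W[j, i] <- network$edges$length[k]
  }
  subsets <- if (length(med) == 0) list(integer(0)) else {
    unlist(lapply(0:length(med), function(k) {
      if (k == 0) list(integer(0)) else {
        asplit(utils::combn(med, k), 2)
      }
    }), recursive = FALSE)
  }
  best <- Inf
  optima <- list()
  for (S in subsets) {
    V <- sort(c(obs, as.integer(S)))
    w <- W[V, V, drop = FALSE]
    cost <- mst_cost(w)
    if (is.finite(cost)) {
      if (cost < best - 1e-9) {
        best <- cost
        optima <- list(V)
      } else if (cost < best + 1e-9) {
        optima <- c(optima, list(V))
      }
    }
  }
  if (!is.finite(best)) {
    abort("Network does not connect the observed haplotypes.")
  }
  keep_edge <- matrix(FALSE, n, n)
  for (V in optima) {
    w <- W[V, V, drop = FALSE]
    mm <- minimax_matrix(w)
    inmst <- is.finite(w) & abs(w - mm) < 1e-9 & upper.tri(w)
    idx <- which(inmst, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      keep_edge[cbind(V[idx[, 1]], V[idx[, 2]])] <- TRUE
    }
  }
  kept <- which(keep_edge, arr.ind = TRUE)
  keep_nodes <- sort(union(obs, unique(c(kept[, 1], kept[, 2]))))
  pair_id <- paste(ids[kept[, 1]], ids[kept[, 2]])
  edges <- network$edges
  edges <- edges[paste(edges$from, edges$to) %in% pair_id |
    paste(edges$to, edges$from) %in% pair_id, , drop = FALSE]
  out <- network
  out$haps <- network$haps[keep_nodes, , drop = FALSE]
  out$observed <- network$observed[keep_nodes]
  out$edges <- edges
  out$node_pops <- network$node_pops[
    network$node_pops$node %in% rownames(out$haps), ,
    drop = FALSE
  ]
  check_connected(out)
  out
}

#' Founder-cluster extraction from a haplotype network
#'
#' Partitions the individuals of focal populations (e.g. diaspora groups)
#' into founder clusters anchored at root nodes shared with, or nearest to,
#' source populations. Roots are, in order of preference: nodes carrying
#' both focal and source individuals; focal nodes directly linked to a
#' source node; failing both, the focal node(s) at minimal network distance
#' from any source node. Each focal node is then assigned to the root it can
#' reach by the shortest network path that passes through no other root
#' (ties: smaller distance, then root id). A user-supplied `assignment`
#' (tibble with columns `node`, `cluster`, optional `root`) overrides the
#' automatic rule, e.g. to reproduce a published manual clustering.
#'
#' @param network A `ystr_network` built from focal + source populations.
#' @param focal,source Character vectors of population labels.
#' @param assignment Optional manual node-to-cluster table.
#' @return A `ystr_clusters` object; its `summary` element is a tibble with
#'   one row per cluster (`cluster`, `root`, `n`), and `clusters` holds per-
#'   cluster membership. [tidy()] returns the member table.
#' @export
extract_founder_clusters <- function(network, focal, source, assignment = NULL) {
  stopifnot(inherits(network, "ystr_network"))
  np <- network$node_pops
  have <- unique(np$population)
  if (!any(focal %in% have)) {
    abort(paste0(
      "No focal population present in the network: ",
      paste(focal, collapse = ", ")
    ))
  }
  if (!any(source %in% have)) {
    abort(paste0(
      "No source population present in the network: ",
      paste(source, collapse = ", ")
    ))
  }
  focal_nodes <- sort(unique(np$node[np$population %in% focal & np$n > 0]))
  source_nodes <- sort(unique(np$node[np$population %in% source & np$n > 0]))
  g <- as_igraph(network)
  if (is.null(assignment)) {
    roots <- intersect(focal_nodes, source_nodes)
    if (length(roots) == 0) {
      adj <- igraph::as_edgelist(g)
      touching <- unique(c(
        adj[adj[, 1] %in% source_nodes, 2],
        adj[adj[, 2] %in% source_nodes, 1]
      ))
      roots <- sort(intersect(focal_nodes, touching))
    }
    if (length(roots) == 0) {
      dmat <- igraph::distances(g,
        v = focal_nodes, to = source_nodes,
        weights = igraph::E(g)$length
      )
      dmin <- apply(dmat, 1, min)
      roots <- sort(focal_nodes[dmin <= min(dmin) + 1e-9])
    }
    assign_tbl <- assign_to_roots(g, focal_nodes, roots)
  } else {
    assignment <- tibble::as_tibble(assignment)
    if (!all(c("node", "cluster") %in% names(assignment))) {
      abort("Manual assignment needs 'node' and 'cluster' columns.")
    }
    missing <- setdiff(focal_nodes, assignment$node)
    if (length(missing) > 0) {
      abort(paste0(
        "Manual assignment misses focal node(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    assign_tbl <- assignment[assignment$node %in% focal_nodes, c("node", "cluster")]
    if ("root" %in% names(assignment)) {
      root_map <- unique(assignment[c("cluster", "root")])
      assign_tbl <- dplyr::left_join(assign_tbl, root_map, by = "cluster")
    } else {
      # default manual root: the cluster node nearest to any source node
      dmat <- igraph::distances(g,
        v = unique(assign_tbl$node), to = source_nodes,
        weights = igraph::E(g)$length
      )
      nearest <- setNames(apply(dmat, 1, min), unique(assign_tbl$node))
      assign_tbl <- assign_tbl |>
        dplyr::group_by(.data$cluster) |>
        dplyr::mutate(root = .data$node[which.min(nearest[.data$node])]) |>
        dplyr::ungroup()
    }
  }
  members <- np |>
    dplyr::filter(.data$population %in% focal, .data$n > 0) |>
    dplyr::inner_join(assign_tbl, by = "node")
  clusters <- members |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(df, key) {
      root_id <- unique(df$root)[1]
      list(
        cluster = key$cluster,
        root = root_id,
        root_haplotype = network$haps[root_id, ],
        members = tibble::as_tibble(df[c("node", "population", "n")]),
        n = sum(df$n)
      )
    })
  summary <- purrr::map_dfr(clusters, function(cl) {
    tibble::tibble(cluster = cl$cluster, root = cl$root, n = cl$n)
  }) |> dplyr::arrange(dplyr::desc(.data$n))
  structure(
    list(
      clusters = clusters, summary = summary,
      loci = network$loci, network = network,
      focal = focal, source = source
    ),
    class = "ystr_clusters"
  )
}

#' @export
print.ystr_clusters <- function(x, ...) {
  cat(
    "Founder clusters (", length(x$clusters), " cluster(s), focal: ",
    paste(x$focal, collapse = ", "), ")\n",
    sep = ""
  )
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.ystr_clusters <- function(x, ...) {
  purrr::map_dfr(x$clusters, function(cl) {
    dplyr::mutate(cl$members, cluster = cl$cluster, root = cl$root)
  })
}

# Assign each focal node to the root with the shortest path avoiding other
# roots; falls back to the plain shortest path when every route is blocked.
assign_to_roots <- function(g, focal_nodes, roots) {
  if (length(roots) == 0) abort("No founder root could be identified.")
  dist_free <- igraph::distances(g,
    v = focal_nodes, to = roots,
    weights = igraph::E(g)$length
  )
  davoid <- matrix(Inf, length(focal_nodes), length(roots),
    dimnames = list(focal_nodes, roots)
  )
  for (r in seq_along(roots)) {
    others <- setdiff(roots, roots[r])
    gsub <- igraph::delete_vertices(g, others)
    keep <- intersect(focal_nodes, igraph::V(gsub)$name)
    if (length(keep) > 0) {
      dd <- igraph::distances(gsub,
        v = keep, to = roots[r],
        weights = igraph::E(gsub)$length
      )
      davoid[keep, r] <- dd[, 1]
    }
  }
  # nodes that are themselves roots stay home
  for (r in seq_along(roots)) {
    if (roots[r] %in% focal_nodes) davoid[roots[r], r] <- 0
  }
  blocked <- !is.finite(apply(davoid, 1, min))
  davoid[blocked, ] <- dist_free[blocked, , drop = FALSE]
  pick <- apply(davoid, 1, which.min) # ties: first (sorted root id)
  tibble::tibble(
    node = focal_nodes,
    cluster = paste0("C", pick),
    root = roots[pick]
  )
}

# ---- construction internals ------------------------------------------------

network_state <- function(data, epsilon, weights, loci) {
  if (epsilon < 0) abort("epsilon must be non-negative.")
  loci <- str_loci(data, loci)
  data <- validate_haplotypes(data, loci, missing = "error")
  if (!("population" %in% names(data))) {
    abort("Haplotype data needs a 'population' column.")
  }
  m <- hap_matrix(data, loci)
  key <- apply(m, 1, paste, collapse = "\r")
  uk <- sort(unique(key)) # placeholder order; re-sorted lexicographically below
  um <- m[match(uk, key), , drop = FALSE]
  ord <- do.call(order, as.data.frame(um))
  um <- um[ord, , drop = FALSE]
  uk <- uk[ord]
  ids <- sprintf("H%03d", seq_len(nrow(um)))
  rownames(um) <- ids
  node_pops <- tibble::tibble(
    node = ids[match(key, uk)],
    population = as.character(data$population)
  ) |>
    dplyr::count(.data$node, .data$population, name = "n")
  w <- weights %||% rep(10, length(loci))
  if (length(w) != length(loci) || any(w <= 0)) {
    abort("One positive weight per locus required.")
  }
  list(
    haps = um, observed = rep(TRUE, nrow(um)), node_pops = node_pops,
    epsilon = epsilon, weights = w, loci = loci
  )
}

# Upper-triangular logical matrix of links satisfying the relaxed MST
# criterion over the current node set.
msn_edge_matrix <- function(st) {
  D <- hap_distance_matrix(st$haps, metric = "step", weights = st$weights)
  mm <- minimax_matrix(D)
  (D <= mm + st$epsilon + 1e-9) & upper.tri(D)
}

# All-pairs minimax path weight (smallest possible maximum edge) by a
# Floyd-Warshall style sweep; rows vectorised per pivot.
minimax_matrix <- function(D) {
  n <- nrow(D)
  mm <- D
  diag(mm) <- 0
  for (k in seq_len(n)) {
    via <- outer(mm[, k], mm[k, ], pmax)
    mm <- pmin(mm, via)
  }
  mm
}

# Quasi-medians of connected triplets that strictly reduce connection cost
# and are not already nodes; returned deduplicated in lexicographic order.
# Vectorised: triples are enumerated per MSN edge (u, v) against every node
# adjacent to either endpoint, and the per-locus median / range arithmetic
# runs on whole matrices.
candidate_medians <- function(st, edges) {
  n <- nrow(st$haps)
  if (n < 3) {
    return(st$haps[0, , drop = FALSE])
  }
  adj <- edges | t(edges)
  D <- hap_distance_matrix(st$haps, metric = "step", weights = st$weights)
  key_of <- function(m) apply(m, 1, paste, collapse = "\r")
  existing <- key_of(st$haps)
  eidx <- which(edges, arr.ind = TRUE)
  if (nrow(eidx) == 0) {
    return(st$haps[0, , drop = FALSE])
  }
  # unique unordered triples with >= 2 links among them
  trip <- NULL
  for (e in seq_len(nrow(eidx))) {
    u <- eidx[e, 1]
    v <- eidx[e, 2]
    ws <- which(adj[u, ] | adj[v, ])
    ws <- ws[ws != u & ws != v]
    if (length(ws) > 0) {
      trip <- rbind(trip, cbind(pmin(u, v), pmax(u, v), ws))
    }
  }
  trip <- t(apply(trip, 1, sort))
  trip <- trip[!duplicated(trip), , drop = FALSE]
  A <- st$haps[trip[, 1], , drop = FALSE]
  B <- st$haps[trip[, 2], , drop = FALSE]
  C <- st$haps[trip[, 3], , drop = FALSE]
  mx <- pmax(A, B, C)
  mn <- pmin(A, B, C)
  star <- as.numeric((mx - mn) %*% st$weights)
  pd12 <- D[trip[, c(1, 2), drop = FALSE]]
  pd13 <- D[trip[, c(1, 3), drop = FALSE]]
  pd23 <- D[trip[, c(2, 3), drop = FALSE]]
  mst <- pd12 + pd13 + pd23 - pmax(pd12, pd13, pd23)
  hit <- star < mst - 1e-9
  if (!any(hit)) {
    return(st$haps[0, , drop = FALSE])
  }
  found <- (A + B + C - mx - mn)[hit, , drop = FALSE]
  found <- found[!duplicated(key_of(found)), , drop = FALSE]
  found <- found[!(key_of(found) %in% existing), , drop = FALSE]
  if (nrow(found) == 0) {
    return(st$haps[0, , drop = FALSE])
  }
  ord <- do.call(order, as.data.frame(found))
  found <- found[ord, , drop = FALSE]
  storage.mode(found) <- "integer"
  nmed <- sum(!st$observed)
  rownames(found) <- sprintf("mv%03d", nmed + seq_len(nrow(found)))
  colnames(found) <- colnames(st$haps)
  found
}

finalize_network <- function(st, prune_leaf_medians = FALSE) {
  repeat {
    edges <- msn_edge_matrix(st)
    if (!prune_leaf_medians) break
    deg <- colSums(edges | t(edges))
    drop <- which(!st$observed & deg <= 1)
    if (length(drop) == 0) break
    st$haps <- st$haps[-drop, , drop = FALSE]
    st$observed <- st$observed[-drop]
  }
  D <- hap_distance_matrix(st$haps, metric = "step", weights = st$weights)
  S <- hap_distance_matrix(st$haps, metric = "step")
  idx <- which(edges, arr.ind = TRUE)
  ids <- rownames(st$haps)
  edge_tbl <- tibble::tibble(
    from = ids[idx[, 1]],
    to = ids[idx[, 2]],
    length = D[idx],
    steps = S[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
  out <- structure(
    list(
      haps = st$haps, observed = st$observed, node_pops = st$node_pops,
      edges = edge_tbl, loci = st$loci, weights = st$weights,
      epsilon = st$epsilon
    ),
    class = "ystr_network"
  )
  check_connected(out)
  out
}

check_connected <- function(net) {
  if (nrow(net$haps) > 1) {
    g <- as_igraph(net)
    if (igraph::components(g)$no != 1) {
      abort("Internal error: haplotype network is disconnected.")
    }
  }
  invisible(net)
}

# ---- accessors & export ----------------------------------------------------

#' Network accessors
#'
#' `network_nodes()` returns one row per node with total multiplicity and a
#' median-vector flag plus the repeat counts; `network_edges()` the link
#' table; `as_igraph()` an igraph graph with `length`/`steps` edge
#' attributes.
#'
#' @param network A `ystr_network`.
#' @return A tibble (or an igraph object for `as_igraph()`).
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "ystr_network"))
  totals <- network$node_pops |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  tibble::tibble(
    node = rownames(network$haps),
    median_vector = !network$observed
  ) |>
    dplyr::left_join(totals, by = "node") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::bind_cols(tibble::as_tibble(network$haps))
}

#' @rdname network_nodes
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "ystr_network"))
  network$edges
}

#' @rdname network_nodes
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ystr_network"))
  v <- network_nodes(network)[c("node", "median_vector", "n")]
  v$median_vector <- as.integer(v$median_vector) # GML has no booleans
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = v)
}

#' @export
print.ystr_network <- function(x, ...) {
  cat(
    "Haplotype network: ", sum(x$observed), " observed node(s), ",
    sum(!x$observed), " median vector(s), ", nrow(x$edges),
    " link(s); epsilon = ", x$epsilon, "\n",
    sep = ""
  )
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes the network as GML or DOT (via igraph) for external layout tools,
#' or as a pair of plain TSV tables (`<path>` for edges, with node rows in
#' `<path>` prefixed sections) for archiving.
#'
#' @param network A `ystr_network`.
#' @param path Output file path.
#' @param format `"gml"`, `"dot"` or `"tsv"` (edge list + node table,
#'   written to `path` and `sub("\\.tsv$", "_nodes.tsv", path)`).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("gml", "dot", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(network_edges(network), path)
    readr::write_tsv(
      network_nodes(network),
      sub("\\.tsv$", "_nodes.tsv", path)
    )
  } else {
    igraph::write_graph(as_igraph(network), path, format = format)
  }
  invisible(path)
}

# Prim's algorithm on a dense weight matrix (Inf = no link); returns the
# total MST weight, or Inf when the graph is disconnected.
mst_cost <- function(W) {
  n <- nrow(W)
  if (n <= 1) {
    return(0)
  }
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- W[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(mind[cand])]
    if (!is.finite(mind[j])) {
      return(Inf)
    }
    total <- total + mind[j]
    intree[j] <- TRUE
    mind <- pmin(mind, W[j, ])
  }
  total
}

# Step distance between two member nodes along shortest network paths,
# summed in mutational steps; used by branch-aware rho.
network_path_steps <- function(network, from, to) {
  g <- as_igraph(network)
  d <- igraph::distances(g, v = from, to = to, weights = igraph::E(g)$steps)
  d
}
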