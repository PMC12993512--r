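#' Louvain community detection with small-community pruning
#'
#' Greedy modularity optimisation (igraph's Louvain implementation,
#' node order randomised by the seed); communities smaller than
#' `min_size` are recorded as pruned and excluded from cluster counts,
#' but modularity Q is reported for the full, unpruned partition.
#'
#' @param net A `cooccurrence_network` or igraph graph.
#' @param resolution Louvain resolution parameter; default 1.
#' @param min_size Minimum community size retained; default 5.
#' @param seed Integer seed.
#' @param n_restarts Seeded restarts with randomised node order; the
#'   partition with the highest Q is kept. Default 100.
#' @return A list of class `community_partition`: `membership` tibble
#'   (`taxon_id`, `community`, `pruned`), `modularity`, `n_clusters`
#'   (unpruned communities), `pruned_communities`, `resolution`.
#' @export
louvain_communities <- function(net, resolution = 1, min_size = 5, seed = 1L,
                                n_restarts = 100) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) {
    return(structure(list(membership = tibble::tibble(taxon_id = character(),
                                                      community = integer(),
                                                      pruned = logical()),
                          modularity = NA_real_, n_clusters = 0L,
                          pruned_communities = integer(),
                          resolution = resolution),
                     class = "community_partition"))
  }
  if (igraph::ecount(g) == 0) {
    # Q is undefined without edges; every node is its own community
    n <- igraph::vcount(g)
    membership <- tibble::tibble(
      taxon_id = igraph::V(g)$name %||% as.character(seq_len(n)),
      community = seq_len(n),
      pruned = rep(min_size > 1, n)
    )
    return(structure(list(membership = membership, modularity = NA_real_,
                          n_clusters = if (min_size <= 1) n else 0L,
                          pruned_communities = if (min_size > 1) seq_len(n)
                                               else integer(),
                          resolution = resolution),
                     class = "community_partition"))
  }
  # greedy optimisation is order-sensitive; keep the best of several
  # seeded restarts over random vertex permutations
  set.seed(seed)
  nv <- igraph::vcount(g)
  best_q <- -Inf
  memb <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    perm <- sample.int(nv)
    pg <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(pg, resolution = resolution)
    mq <- igraph::modularity(pg, igraph::membership(cl),
                             resolution = resolution)
    if (mq > best_q) {
      best_q <- mq
      memb <- igraph::membership(cl)[perm]   # back to original order
    }
  }
  q <- best_q
  sizes <- table(memb)
  pruned_ids <- as.integer(names(sizes)[sizes < min_size])
  membership <- tibble::tibble(
    taxon_id = igraph::V(g)$name %||% as.character(seq_along(memb)),
    community = as.integer(memb),
    pruned = as.integer(memb) %in% pruned_ids
  )
  structure(list(membership = membership, modularity = q,
                 n_clusters = sum(sizes >= min_size),
                 pruned_communities = pruned_ids,
                 resolution = resolution),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d clusters (>= min size), Q = %.4f, %d pruned\n",
              x$n_clusters, x$modularity, length(x$pruned_communities)))
  invisible(x)
}

#' Network topology metrics
#'
#' Node/edge counts, unpruned cluster count, diameter (unweighted hops on
#' the largest connected component), edge density 2E/(N(N-1)),
#' modularity of the supplied partition, degree assortativity and global
#' transitivity.
#'
#' @param net A `cooccurrence_network` or igraph graph.
#' @param partition Optional [louvain_communities()] result; computed with
#'   defaults when missing.
#' @return A one-row tibble.
#' @export
topology <- function(net, partition = NULL) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (is.null(partition)) partition <- louvain_communities(g)
  diam <- if (n < 2) NA_integer_ else {
    comp <- igraph::components(g)
    big <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
    as.integer(igraph::diameter(big, weights = NA))
  }
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    n_clusters = partition$n_clusters,
    diameter = diam,
    edge_density = if (n < 2) NA_real_ else 2 * e / (n * (n - 1)),
    modularity = partition$modularity,
    assortativity = if (e < 2) NA_real_ else
      suppressWarnings(igraph::assortativity_degree(g)),
    transitivity = igraph::transitivity(g, type = "global")
  )
}

#' Degree and betweenness centrality with dense ranks
#'
#' Degree is the incident-edge count; betweenness is unnormalised
#' shortest-path betweenness (unweighted, endpoints excluded). Ranks are
#' dense (ties share the better rank, 1 = highest value).
#'
#' @param net A `cooccurrence_network` or igraph graph.
#' @return A tibble: `taxon_id`, `degree`, `betweenness`, `degree_rank`,
#'   `betweenness_rank`.
#' @export
centrality <- function(net) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))
  tibble::tibble(
    taxon_id = igraph::V(g)$name %||% as.character(seq_along(deg)),
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    degree_rank = dense_rank_desc(deg),
    betweenness_rank = dense_rank_desc(btw)
  )
}

#' Select keystone taxa by joint degree/betweenness rank
#'
#' The top-`k` nodes by ascending rank-sum (degree rank + betweenness
#' rank), i.e. nodes with both a high degree and a high betweenness. Ties
#' are broken by higher betweenness, then lexical taxon id. Keystones
#' need not be abundant; mean relative abundance is attached when a
#' source table is supplied.
#'
#' @param scores A [centrality()] tibble (or a network, in which case
#'   centrality is computed).
#' @param k Number of keystones; default 10. If `k` exceeds the node
#'   count, all nodes are returned with a warning.
#' @param tables Optional list of `abundance_table`s used to attach mean
#'   relative abundance per keystone.
#' @return A tibble sorted by ascending `rank_sum` with columns
#'   `taxon_id`, `degree`, `betweenness`, `rank_sum`,
#'   `relative_abundance`.
#' @export
select_keystones <- function(scores, k = 10, tables = NULL) {
  if (!is.data.frame(scores)) scores <- centrality(scores)
  if (nrow(scores) == 0) stop("no nodes to rank", call. = FALSE)
  if (k > nrow(scores)) {
    warning("k exceeds node count; returning all ", nrow(scores), " nodes",
            call. = FALSE)
    k <- nrow(scores)
  }
  out <- scores |>
    dplyr::mutate(rank_sum = .data$degree_rank + .data$betweenness_rank) |>
    dplyr::arrange(.data$rank_sum, dplyr::desc(.data$betweenness),
                   .data$taxon_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::select("taxon_id", "degree", "betweenness", "rank_sum")
  out$relative_abundance <- NA_real_
  if (!is.null(tables)) {
    for (tab in tables) {
      rel <- relative_abundance(tab)
      hit <- out$taxon_id %in% rownames(rel)
      out$relative_abundance[hit] <- rowMeans(rel)[out$taxon_id[hit]]
    }
  }
  out
}

#' Network fragmentation
#'
#' The number of disconnected subgraphs (connected components) divided by
#' the number of nodes: 1/N for a connected graph, 1 for an edgeless one.
#'
#' @param net A `cooccurrence_network` or igraph graph.
#' @return A single fraction in (0, 1].
#' @export
fragmentation <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) stop("fragmentation is undefined for an empty graph", call. = FALSE)
  igraph::components(g)$no / n
}

#' Fragmentation trajectory under iterative keystone removal
#'
#' Removes the keystone taxa one at a time in rank order, recomputing the
#' connected components, the fragmentation f and (optionally) the Louvain
#' cluster count after each removal. With `recompute = TRUE` the keystone
#' list is re-ranked on the reduced graph after every removal instead of
#' using the static list. With `original_n = TRUE` f uses the
#' pre-removal node count as denominator instead of the current one.
#'
#' @param net A `cooccurrence_network` or igraph graph.
#' @param keystones A [select_keystones()] tibble (or character vector of
#'   taxon ids). Must all be present in the graph.
#' @param recompute Re-rank keystones after each removal; default FALSE.
#' @param original_n Use the original node count as the f denominator.
#' @param clusters Also report the Louvain cluster count (min size 5)
#'   after each removal; default TRUE.
#' @param seed Seed for the per-step Louvain runs.
#' @return A list of class `fragmentation_trajectory`: `steps` tibble
#'   (`step`, `removed_node`, `n_nodes_remaining`, `n_components`, `f`,
#'   `n_clusters`), `baseline_f`, `f_mean`.
#' @export
removal_trajectory <- function(net, keystones, recompute = FALSE,
                               original_n = FALSE, clusters = TRUE,
                               seed = 1L) {
  g <- as_igraph(net)
  ids <- if (is.data.frame(keystones)) keystones$taxon_id else as.character(keystones)
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing)) {
    stop("keystones absent from graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n0 <- igraph::vcount(g)
  baseline <- igraph::components(g)$no / n0
  k <- length(ids)
  steps <- vector("list", k)
  cur <- g
  for (t in seq_len(k)) {
    victim <- if (recompute) {
      # re-rank among the declared keystones still in the graph
      remaining <- intersect(ids, igraph::V(cur)$name)
      if (!length(remaining)) break
      scs <- centrality(cur)
      select_keystones(scs[scs$taxon_id %in% remaining, ], k = 1)$taxon_id
    } else ids[t]
    cur <- igraph::delete_vertices(cur, victim)
    nrem <- igraph::vcount(cur)
    ncomp <- igraph::components(cur)$no
    steps[[t]] <- tibble::tibble(
      step = t,
      removed_node = victim,
      n_nodes_remaining = nrem,
      n_components = ncomp,
      f = ncomp / if (original_n) n0 else nrem,
      n_clusters = if (clusters)
        louvain_communities(cur, seed = seed)$n_clusters else NA_integer_
    )
  }
  steps <- dplyr::bind_rows(steps)
  structure(list(steps = steps, baseline_f = baseline,
                 f_mean = mean(steps$f)),
            class = "fragmentation_trajectory")
}

#' @export
print.fragmentation_trajectory <- function(x, ...) {
  cat(sprintf("<fragmentation_trajectory> %d removals, baseline f = %.4f, f_mean = %.4f\n",
              nrow(x$steps), x$baseline_f, x$f_mean))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
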