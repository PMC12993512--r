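test_that("Louvain finds two disjoint triangles with Q = 0.5", {
  part <- louvain_communities(triangle_pair(), seed = 1)
  expect_equal(part$modularity, 0.5)
  expect_equal(length(unique(part$membership$community)), 2)
  # with min_size 5 both 3-node communities are pruned
  expect_equal(part$n_clusters, 0)
  expect_equal(length(part$pruned_communities), 2)
  part3 <- louvain_communities(triangle_pair(), min_size = 3, seed = 1)
  expect_equal(part3$n_clusters, 2)
})

test_that("communities below the size floor are pruned but keep Q", {
  el <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"),  # 4-cycle
              c("p", "q"), c("q", "r"), c("r", "s"), c("s", "t"), c("t", "p"),
              c("p", "r"), c("q", "s"))                            # 5-clique-ish
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  part <- louvain_communities(g, min_size = 5, seed = 2)
  sizes <- table(part$membership$community)
  expect_true(any(sizes < 5))
  expect_equal(part$n_clusters, sum(sizes >= 5))
  expect_true(all(part$membership$pruned[part$membership$community %in%
                                           part$pruned_communities]))
  # modularity of the reported assignment matches an independent evaluation
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  expect_equal(part$modularity,
               oracle_modularity(adj, part$membership$community),
               tolerance = 1e-10)
})

test_that("topology metrics match closed forms on canonical graphs", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  t_k5 <- topology(k5)
  expect_equal(t_k5$edge_density, 1)
  expect_equal(t_k5$diameter, 1L)
  expect_equal(t_k5$transitivity, 1)

  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  t_p4 <- topology(p4)
  expect_equal(t_p4$diameter, 3L)
  expect_equal(t_p4$edge_density, 0.5)
})

test_that("assortativity equals the Pearson correlation over edge endpoints", {
  set.seed(77)
  adj <- random_adjacency(6, 0.5)
  while (sum(adj) / 2 < 3) adj <- random_adjacency(6, 0.5)
  g <- adj_to_igraph(adj)
  deg <- rowSums(adj)
  ep <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  # each undirected edge contributes both orientations
  x <- c(deg[ep[, 1]], deg[ep[, 2]])
  y <- c(deg[ep[, 2]], deg[ep[, 1]])
  expect_equal(topology(g)$assortativity, stats::cor(x, y), tolerance = 1e-10)
})

test_that("centrality matches closed forms and the exhaustive oracle", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:6)
  sc <- centrality(star)
  expect_equal(sc$degree[1], 5L)
  expect_equal(sc$betweenness[1], choose(5, 2))
  expect_true(all(sc$betweenness[-1] == 0))

  set.seed(15)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, runif(1, 0.3, 0.7))
    g <- adj_to_igraph(adj)
    expect_equal(centrality(g)$betweenness, oracle_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("keystones are the lowest rank-sums with documented tie-breaks", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:7)
  keys <- select_keystones(centrality(star), k = 3)
  expect_equal(keys$taxon_id[1], "v1")
  expect_equal(keys$rank_sum[1], 2)

  # sort oracle on a random score table
  set.seed(5)
  sc <- tibble::tibble(
    taxon_id = paste0("t", 1:12),
    degree = sample(1:6, 12, replace = TRUE),
    betweenness = round(runif(12, 0, 20), 1)
  )
  sc$degree_rank <- match(sc$degree, sort(unique(sc$degree), decreasing = TRUE))
  sc$betweenness_rank <- match(sc$betweenness,
                               sort(unique(sc$betweenness), decreasing = TRUE))
  keys <- select_keystones(sc, k = 5)
  oracle <- sc[order(sc$degree_rank + sc$betweenness_rank, -sc$betweenness,
                     sc$taxon_id), ][1:5, ]
  expect_identical(keys$taxon_id, oracle$taxon_id)

  expect_warning(all6 <- select_keystones(centrality(star), k = 10), "exceeds")
  expect_equal(nrow(all6), 7)
})

test_that("fragmentation is components over nodes", {
  edgeless <- igraph::make_empty_graph(7, directed = FALSE)
  igraph::V(edgeless)$name <- paste0("v", 1:7)
  expect_equal(fragmentation(edgeless), 1)
  ring <- igraph::make_ring(20)
  igraph::V(ring)$name <- paste0("v", 1:20)
  expect_equal(fragmentation(ring), 0.05)
  expect_error(fragmentation(igraph::make_empty_graph(0)), "empty")

  # articulation example: two 5-cliques joined through one bridge vertex
  g <- igraph::graph_from_edgelist(rbind(
    t(combn(c(paste0("a", 1:4), "bridge"), 2)),
    t(combn(paste0("b", 1:5), 2)),
    c("bridge", "b1")),
    directed = FALSE)
  expect_equal(igraph::vcount(g), 10)
  expect_equal(fragmentation(g), 1 / 10)
  g2 <- igraph::delete_vertices(g, "b1")   # cut vertex
  expect_equal(fragmentation(g2), 2 / 9)
})

test_that("fragmentation matches the union-find oracle on random graphs", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.05, 0.5))
    g <- adj_to_igraph(adj)
    expect_equal(fragmentation(g), oracle_n_components(adj) / n)
  }
})

test_that("removal trajectories keep exact bookkeeping", {
  # connected 9-node graph plus an isolated node
  set.seed(3)
  adj <- matrix(0L, 10, 10)
  for (i in 1:8) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj[1, 5] <- adj[5, 1] <- 1L
  g <- adj_to_igraph(adj)   # v10 isolated
  expect_equal(fragmentation(g), 2 / 10)
  traj <- removal_trajectory(g, "v10", clusters = FALSE)
  expect_equal(traj$steps$n_components, 1)
  expect_equal(traj$steps$f, 1 / 9)

  keys <- c("v5", "v2", "v8")
  traj2 <- removal_trajectory(g, keys, clusters = FALSE)
  expect_equal(nrow(traj2$steps), 3)
  expect_equal(traj2$steps$n_nodes_remaining, 10 - seq_len(3))
  expect_equal(traj2$steps$f,
               traj2$steps$n_components / traj2$steps$n_nodes_remaining)
  # alternative denominator: the original node count
  traj3 <- removal_trajectory(g, keys, original_n = TRUE, clusters = FALSE)
  expect_equal(traj3$steps$f, traj3$steps$n_components / 10)
  expect_error(removal_trajectory(g, "ghost"), "absent")
})

test_that("removing a planted hub fragments the true network", {
  cfg <- sim_config(p_bacteria = 20, p_phototroph = 10, p_fungus = 5,
                    n_samples = 30, seed = 7)
  net <- plant_network(cfg)
  g <- adj_to_igraph(net$adjacency)
  igraph::V(g)$name <- net$taxon_ids
  base <- fragmentation(g)
  traj <- removal_trajectory(g, net$hub_ids, clusters = FALSE)
  expect_gt(traj$steps$f[nrow(traj$steps)], base)
  # oracle recount after all removals
  keep <- setdiff(net$taxon_ids, net$hub_ids)
  sub <- net$adjacency[keep, keep]
  expect_equal(traj$steps$n_components[nrow(traj$steps)],
               oracle_n_components(sub))
})

test_that("planted hubs surface among the top-10 keystones of the true graph", {
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = s)
    net <- plant_network(cfg)
    g <- adj_to_igraph(net$adjacency)
    igraph::V(g)$name <- net$taxon_ids
    keys <- select_keystones(centrality(g), k = 10)
    if (all(net$hub_ids %in% keys$taxon_id)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("degree sums equal twice the edge count on constructed networks", {
  set.seed(55)
  for (i in 1:20) {
    adj <- random_adjacency(sample(5:15, 1), runif(1, 0.2, 0.6))
    g <- adj_to_igraph(adj)
    expect_equal(sum(centrality(g)$degree), 2 * igraph::ecount(g))
  }
})
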