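# Independent brute-force oracles and small fixture builders.
# Everything here avoids the code paths under test: betweenness by
# matrix-power path counting, components by union-find, modularity by
# exhaustive partition enumeration.

# shortest-path betweenness by counting walks with adjacency powers:
# the number of shortest s-t paths through v is the product of shortest
# walk counts s->v and v->t when the hop counts add up
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  pow <- vector("list", n)
  pow[[1]] <- adj
  for (k in 2:max(2, n)) pow[[k]] <- pow[[k - 1]] %*% adj
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in 1:n) for (t in 1:n) {
    if (s == t) next
    for (k in 1:n) {
      if (pow[[k]][s, t] > 0) { dist[s, t] <- k; sigma[s, t] <- pow[[k]][s, t]; break }
    }
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t])) next
    for (v in 1:n) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw
}

# connected components by union-find on the adjacency matrix
oracle_n_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j] > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# all set partitions of n elements as restricted growth strings
enumerate_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) { res[[length(res) + 1]] <<- prefix; return(invisible()) }
    for (g in seq_len(mx + 1)) rec(c(prefix, g), max(mx, g))
  }
  rec(integer(0), 0L)
  do.call(rbind, res)
}

# modularity of a partition from first principles
oracle_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    ec <- sum(adj[idx, idx]) / 2
    dc <- sum(deg[idx])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

oracle_best_modularity <- function(adj, partitions) {
  max(apply(partitions, 1, function(memb) oracle_modularity(adj, memb)))
}

random_adjacency <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  adj[ut] <- as.integer(stats::runif(length(ut)) < p_edge)
  adj + t(adj)
}

adj_to_igraph <- function(adj) {
  dimnames(adj) <- list(paste0("v", seq_len(nrow(adj))),
                        paste0("v", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# tiny abundance tables for IO / preprocessing tests
toy_table <- function(counts, marker = "16S", domains = NULL,
                      families = NULL) {
  taxa <- tibble::tibble(
    taxon_id = rownames(counts),
    domain_label = domains %||% if (marker == "16S") "bacteria" else "phototroph",
    lineage = NA_character_,
    family = families %||% "unclassified"
  )
  abundance_table(counts, taxa, marker = marker)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_counts_tsv <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

triangle_pair <- function() {
  el <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
              c("d", "e"), c("e", "f"), c("d", "f"))
  igraph::graph_from_edgelist(el, directed = FALSE)
}
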