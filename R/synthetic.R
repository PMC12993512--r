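#' Simulation configuration for paired 16S/18S synthetic data
#'
#' Defaults emulate a single proglacial-stream stratum at desk scale:
#' 60 bacterial ASVs, 30 eukaryotic phototroph OTUs and 10 fungal OTUs,
#' 150 paired samples, sequencing depths between 5,000 and 20,000 reads,
#' a sparse planted interaction network (5% of pairs) with 3 hub
#' ("keystone") taxa, and an environmental gradient that shifts a fifth
#' of the taxa.
#'
#' @param p_bacteria,p_phototroph,p_fungus Taxon counts per domain.
#' @param n_samples Number of paired samples.
#' @param depth_range Length-2 integer vector, min/max library size.
#' @param n_hubs Number of planted hub taxa.
#' @param edge_density Fraction of taxon pairs carrying a planted edge.
#' @param gradient_strength Per-unit-gradient shift of latent log
#'   abundance for gradient-responsive taxa (0 disables the gradient).
#' @param gradient_fraction Fraction of taxa responding to the gradient.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(p_bacteria = 60, p_phototroph = 30, p_fungus = 10,
                       n_samples = 150, depth_range = c(5000L, 20000L),
                       n_hubs = 3, edge_density = 0.05,
                       gradient_strength = 0.8, gradient_fraction = 0.2,
                       seed = 1L) {
  cfg <- list(p_bacteria = as.integer(p_bacteria),
              p_phototroph = as.integer(p_phototroph),
              p_fungus = as.integer(p_fungus),
              n_samples = as.integer(n_samples),
              depth_range = as.integer(depth_range),
              n_hubs = as.integer(n_hubs),
              edge_density = edge_density,
              gradient_strength = gradient_strength,
              gradient_fraction = gradient_fraction,
              seed = as.integer(seed))
  p <- cfg$p_bacteria + cfg$p_phototroph + cfg$p_fungus
  if (any(c(cfg$p_bacteria, cfg$p_phototroph, cfg$p_fungus, cfg$n_samples) <= 0)) {
    stop("taxon and sample counts must be positive", call. = FALSE)
  }
  if (cfg$edge_density <= 0 || cfg$edge_density >= 1) {
    stop("edge_density must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$depth_range[1] > cfg$depth_range[2] || cfg$depth_range[1] < 1) {
    stop("depth_range must satisfy 1 <= min <= max", call. = FALSE)
  }
  if (cfg$n_hubs < 0 || cfg$n_hubs > p) {
    stop("n_hubs must lie between 0 and the number of taxa", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Plant a sparse cross-domain interaction network
#'
#' Builds a three-block graph — a bacteria-rich block, a phototroph-rich
#' block and a mixed fungal/bacterial block, mirroring the cluster
#' structure typical of cross-domain biofilm networks — with designated
#' hub nodes whose degree is at least three times the median degree, and
#' converts it to a diagonally-dominant precision matrix whose nonzero
#' off-diagonal entries sit exactly on the planted edges. Off-diagonal
#' precision entries are negative so every planted edge is a positive
#' association.
#'
#' @param config A [sim_config()].
#' @return A list of class `planted_network`: `adjacency` (binary symmetric
#'   matrix), `precision`, `hub_ids`, `domain_labels`, `taxon_ids`, `signs`.
#' @export
plant_network <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pick_from <- function(x, k) x[sample.int(length(x), k)]  # safe for length 1
  p <- config$p_bacteria + config$p_phototroph + config$p_fungus
  if (config$n_hubs > p / 2) {
    stop("infeasible hub count for ", p, " taxa", call. = FALSE)
  }
  max_edges <- p * (p - 1) / 2
  if (config$edge_density * max_edges < config$n_hubs * 3) {
    stop("edge_density too low to support the requested hubs", call. = FALSE)
  }
  set.seed(config$seed)

  ids <- c(sprintf("bac%03d", seq_len(config$p_bacteria)),
           sprintf("pho%03d", seq_len(config$p_phototroph)),
           sprintf("fun%03d", seq_len(config$p_fungus)))
  domains <- rep(c("bacteria", "phototroph", "fungus"),
                 c(config$p_bacteria, config$p_phototroph, config$p_fungus))

  # three blocks: bacteria-rich, phototroph-rich, mixed fungi + bacteria
  n_bac_mixed <- max(1L, round(config$p_bacteria * 0.15))
  block <- integer(p)
  block[domains == "bacteria"] <- 1L
  block[domains == "phototroph"] <- 2L
  block[domains == "fungus"] <- 3L
  block[pick_from(which(domains == "bacteria"), n_bac_mixed)] <- 3L

  adj <- matrix(0L, p, p, dimnames = list(ids, ids))
  target_edges <- round(config$edge_density * max_edges)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  same_block <- block[pairs[, 1]] == block[pairs[, 2]]
  # within-block pairs are ~8x likelier, giving the dense-cluster look
  w <- ifelse(same_block, 8, 1)
  sel <- sample(nrow(pairs), min(target_edges, nrow(pairs)), prob = w)
  adj[pairs[sel, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  adj[adj > 1L] <- 1L

  # hubs: raise designated nodes (one per block where possible) to
  # >= 3x median degree, wiring half of the extra edges across blocks
  hubs <- integer(0)
  if (config$n_hubs > 0) {
    hubs <- vapply(seq_len(config$n_hubs), function(k) {
      b <- ((k - 1) %% 3) + 1
      cand <- setdiff(which(block == b), hubs)
      if (!length(cand)) cand <- setdiff(seq_len(p), hubs)
      cand[which.max(rowSums(adj)[cand])]
    }, integer(1))
    # top up until every hub holds degree >= 3x the non-hub median
    # (hub edges raise neighbours' degrees, so iterate to a fixed point)
    for (pass in 1:10) {
      med <- stats::median(rowSums(adj)[-hubs])
      done <- TRUE
      for (h in hubs) {
        need <- max(0, ceiling(3 * med) - sum(adj[h, ]))
        if (need == 0) next
        done <- FALSE
        cand <- setdiff(which(adj[h, ] == 0L), c(h, hubs))
        other <- cand[block[cand] != block[h]]
        own <- cand[block[cand] == block[h]]
        pick <- c(pick_from(other, min(ceiling(need / 2), length(other))),
                  pick_from(own, min(floor(need / 2), length(own))))
        if (length(pick) < need) {
          rest <- setdiff(cand, pick)
          pick <- c(pick, pick_from(rest, min(need - length(pick), length(rest))))
        }
        adj[h, pick] <- adj[pick, h] <- 1L
      }
      if (done) break
    }
  }

  # guarantee the cross-domain edges the analysis is about
  ensure_edge <- function(adj, da, db) {
    ia <- which(domains == da); ib <- which(domains == db)
    if (!any(adj[ia, ib] == 1L)) {
      i <- pick_from(ia, 1); j <- pick_from(ib, 1)
      adj[i, j] <- adj[j, i] <- 1L
    }
    adj
  }
  adj <- ensure_edge(adj, "bacteria", "phototroph")
  adj <- ensure_edge(adj, "phototroph", "fungus")
  diag(adj) <- 0L

  # precision: negative off-diagonal weights on edges, diagonally dominant
  wmat <- matrix(0, p, p)
  ut <- which(upper.tri(adj) & adj == 1L)
  wmat[ut] <- stats::runif(length(ut), 0.2, 0.4)
  wmat <- wmat + t(wmat)
  prec <- -wmat
  diag(prec) <- rowSums(wmat) + 0.5
  dimnames(prec) <- dimnames(adj)

  structure(list(adjacency = adj, precision = prec,
                 hub_ids = ids[hubs], taxon_ids = ids,
                 domain_labels = domains,
                 signs = ifelse(adj == 1L, 1L, 0L),
                 block = block, config = config),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted_network> %d taxa, %d edges, hubs: %s\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              paste(x$hub_ids, collapse = ", ")))
  invisible(x)
}

#' Correlation matrix implied by a planted network
#'
#' The ground-truth latent correlation: invert the precision matrix and
#' scale to unit diagonal. Used as the oracle in recovery tests.
#'
#' @param net A `planted_network`.
#' @return A p x p correlation matrix.
#' @export
planted_correlation <- function(net) {
  stopifnot(inherits(net, "planted_network"))
  stats::cov2cor(solve(net$precision))
}

#' Simulate paired 16S/18S count tables from a planted network
#'
#' Logistic-normal-multinomial sampling: latent log-abundances are drawn
#' from a multivariate normal with covariance equal to the inverse planted
#' precision matrix; gradient-responsive taxa are shifted along a
#' standard-normal environmental gradient; per sample, latent values are
#' soft-maxed to compositions within each marker and counts drawn
#' multinomially at a depth uniform in `depth_range`. Stream-type and
#' deglaciation labels are tied to the gradient sign (with 15% label
#' noise) so constrained ordination has structure to find.
#'
#' @param net A [plant_network()] result.
#' @param config The same [sim_config()]; defaults to the one in `net`.
#' @return A list: `t16`, `t18` ([abundance_table()]s), `metadata` tibble,
#'   `latent` matrix (taxa x samples, exposed for oracle checks),
#'   `gradient_taxa`, `truth` (the planted network).
#' @export
simulate_counts <- function(net, config = net$config) {
  stopifnot(inherits(net, "planted_network"), inherits(config, "sim_config"))
  p <- nrow(net$precision)
  n <- config$n_samples
  set.seed(config$seed + 1L)

  sigma <- solve(net$precision)
  ch <- chol(sigma)
  mu <- stats::rnorm(p, mean = 0, sd = 1)  # taxon baseline log-abundance
  z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  z <- sweep(z, 2, mu, `+`)

  gradient <- stats::rnorm(n)
  n_grad <- round(p * config$gradient_fraction)
  grad_taxa <- if (n_grad > 0) sample(p, n_grad) else integer(0)
  if (length(grad_taxa) && config$gradient_strength != 0) {
    dir <- sample(c(-1, 1), length(grad_taxa), replace = TRUE)
    z[, grad_taxa] <- z[, grad_taxa] +
      outer(gradient, dir * config$gradient_strength)
  }
  latent <- t(z)  # taxa x samples
  sids <- sprintf("S%03d", seq_len(n))
  colnames(latent) <- sids
  rownames(latent) <- net$taxon_ids

  draw_marker <- function(rows) {
    depth <- sample(seq(config$depth_range[1], config$depth_range[2]), n,
                    replace = TRUE)
    counts <- vapply(seq_len(n), function(s) {
      lp <- latent[rows, s]
      pr <- exp(lp - max(lp))
      stats::rmultinom(1, depth[s], pr / sum(pr))[, 1]
    }, integer(length(rows)))
    dimnames(counts) <- list(net$taxon_ids[rows], sids)
    counts
  }
  is_bac <- net$domain_labels == "bacteria"
  c16 <- draw_marker(which(is_bac))
  c18 <- draw_marker(which(!is_bac))

  taxa16 <- tibble::tibble(taxon_id = rownames(c16),
                           domain_label = "bacteria",
                           lineage = NA_character_,
                           family = paste0("Family_", substr(rownames(c16), 1, 4)))
  taxa18 <- tibble::tibble(taxon_id = rownames(c18),
                           domain_label = net$domain_labels[!is_bac],
                           lineage = NA_character_,
                           family = paste0("Family_", substr(rownames(c18), 1, 4)))

  flip <- stats::runif(n) < 0.15
  gfs <- xor(gradient > 0, flip)
  metadata <- tibble::tibble(
    sample_id = sids,
    floodplain = rep(c("Otemma", "ValRoseg"), length.out = n),
    stream_type = ifelse(gfs, "GFS", "TRIB"),
    deglaciation = ifelse(xor(gradient > stats::median(gradient),
                              stats::runif(n) < 0.15), "pre2000", "post2000"),
    consistent = TRUE,
    gradient = gradient,
    temperature = 4 + 2 * gradient + stats::rnorm(n, 0, 0.5),
    conductivity = exp(4 + 0.3 * gradient + stats::rnorm(n, 0, 0.2)),
    doc = exp(0.5 - 0.2 * gradient + stats::rnorm(n, 0, 0.3))
  )

  list(t16 = abundance_table(c16, taxa16, marker = "16S"),
       t18 = abundance_table(c18, taxa18, marker = "18S"),
       metadata = metadata,
       latent = latent,
       gradient_taxa = net$taxon_ids[grad_taxa],
       truth = net)
}

#' Write a simulated dataset to a directory of standard files
#'
#' Emits the two count TSVs, a taxonomy TSV, the metadata TSV and a
#' ground-truth JSON (adjacency edge list, hubs, seed).
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts <- function(tab, path) {
    df <- data.frame(taxon_id = rownames(tab$counts), tab$counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_counts(sim$t16, file.path(dir, "counts_16S.tsv"))
  write_counts(sim$t18, file.path(dir, "counts_18S.tsv"))
  utils::write.table(as.data.frame(sim$metadata), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  adj <- sim$truth$adjacency
  ut <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  truth <- list(
    edges = data.frame(source = rownames(adj)[ut[, 1]],
                       target = colnames(adj)[ut[, 2]]),
    hubs = sim$truth$hub_ids,
    seed = sim$truth$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
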