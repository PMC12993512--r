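#' Ensemble configuration for co-occurrence network inference
#'
#' Defaults: SparCC edges need \eqn{|\rho| \ge 0.3} and permutation
#' pseudo-p < 0.05 (100 resamples); Spearman edges need
#' \eqn{|\rho| \ge 0.5} and BH q < 0.01; the Meinshausen-Buhlmann graph
#' uses a 20-point log-spaced penalty grid with StARS selection
#' (instability target 0.05, 50 subsamples of 80% of samples). Consensus
#' keeps edges supported by at least `min_support` methods whose
#' supporting signs are all positive.
#'
#' @param sparcc List of SparCC options (see [sparcc()]), plus `rho_cut`
#'   and `pseudo_p_cut`.
#' @param spearman List with `rho_cut`, `q_cut`.
#' @param mb List with `nlambda`, `lambda_min_ratio`, `stars_subsamples`,
#'   `stars_beta`, `subsample_fraction`.
#' @param min_support Methods required to support an edge (1-3).
#' @param positive_only Keep only sign-consistent positive edges.
#' @param combine `"vote"` (threshold per method, then count support) or
#'   `"average"` (mean of the SparCC and Spearman correlations thresholded
#'   at the SparCC cut, MB membership still counted).
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(sparcc = list(), spearman = list(), mb = list(),
                            min_support = 2, positive_only = TRUE,
                            combine = c("vote", "average"), seed = 1L) {
  combine <- match.arg(combine)
  sp <- utils::modifyList(list(iterations = 10, exclusion_threshold = 0.8,
                               exclusion_rounds = 10, n_bootstrap = 100,
                               pseudocount = 1, rho_cut = 0.3,
                               pseudo_p_cut = 0.05), sparcc)
  se <- utils::modifyList(list(rho_cut = 0.5, q_cut = 0.01), spearman)
  nb <- utils::modifyList(list(nlambda = 20, lambda_min_ratio = 0.01,
                               stars_subsamples = 50, stars_beta = 0.05,
                               subsample_fraction = 0.8, pseudocount = 1),
                          mb)
  if (!min_support %in% 1:3) stop("min_support must be 1, 2 or 3", call. = FALSE)
  if (nb$stars_beta <= 0 || nb$stars_beta >= 0.5) {
    stop("stars_beta must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(sparcc = sp, spearman = se, mb = nb,
                 min_support = as.integer(min_support),
                 positive_only = isTRUE(positive_only),
                 combine = combine, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Spearman correlation network with BH-adjusted p-values
#'
#' Pairwise Spearman rank correlations on per-sample relative abundances,
#' two-sided p-values from the t approximation, Benjamini-Hochberg
#' adjustment across the upper triangle. Constant taxa get correlation 0
#' and p = 1.
#'
#' @param table An [abundance_table()], `stacked_table` or count matrix.
#' @return A list of class `correlation_matrix`: `rho`, `pvals`, `qvals`.
#' @export
spearman_network <- function(table) {
  counts <- if (is.list(table)) table$counts else as.matrix(table)
  n <- ncol(counts)
  if (n < 3) stop("Spearman network needs at least 3 samples", call. = FALSE)
  rel <- relative_abundance(counts)
  rho <- suppressWarnings(stats::cor(t(rel), method = "spearman"))
  constant <- apply(rel, 1, function(x) length(unique(x)) == 1)
  rho[is.na(rho)] <- 0
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1

  r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pv[abs(rho) >= 1] <- 0
  pv[constant, ] <- 1
  pv[, constant] <- 1
  diag(pv) <- 0

  qv <- pv
  ut <- upper.tri(pv)
  qv[ut] <- stats::p.adjust(pv[ut], method = "BH")
  qv[lower.tri(qv)] <- t(qv)[lower.tri(qv)]
  structure(list(rho = rho, pvals = pv, qvals = qv),
            class = "correlation_matrix")
}

#' Meinshausen-Buhlmann neighborhood selection with StARS
#'
#' For each taxon, an L1-penalised regression of its CLR profile on all
#' other taxa over a shared penalty grid; the penalty is chosen by StARS
#' (edge-selection instability over subsamples, the densest graph whose
#' monotonised instability stays at or below `stars_beta`); the final
#' graph OR-symmetrises the selected neighborhoods. Edge sign is the sign
#' of the larger-magnitude coefficient of the pair.
#'
#' @param table An [abundance_table()], `stacked_table` or count matrix
#'   (counts; CLR applied internally), or an already-CLR matrix if
#'   `clr = FALSE`.
#' @param config An [ensemble_config()]; the `mb` entry is used.
#' @param clr Apply [clr_transform()] to `table` first (default TRUE).
#' @return A list of class `mb_graph`: `adjacency`, `sign`,
#'   `lambda_selected`, `lambda_grid`, `instability`, `stability_path`.
#' @export
mb_neighborhood <- function(table, config = ensemble_config(), clr = TRUE) {
  cfg <- config$mb
  x <- if (clr) clr_transform(table, cfg$pseudocount)
       else if (is.list(table)) table$counts else as.matrix(table)
  X <- t(x)                      # samples x taxa
  n <- nrow(X)
  p <- ncol(X)
  if (n < 10) stop("neighborhood selection needs at least 10 samples", call. = FALSE)
  keep <- apply(X, 2, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant taxa excluded from neighborhood selection",
            call. = FALSE)
  }
  Xk <- scale(X[, keep, drop = FALSE])
  pk <- ncol(Xk)
  nodes <- rownames(x)
  ids <- nodes[keep]

  lambda_max <- max(abs(crossprod(Xk)) [upper.tri(diag(pk))]) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * cfg$lambda_min_ratio),
                  length.out = cfg$nlambda))

  fit_adj <- function(Z) {
    # OR-symmetrised adjacency per lambda from per-node lasso paths
    nz <- nrow(Z)
    adj <- array(FALSE, c(pk, pk, length(grid)))
    for (j in seq_len(pk)) {
      fit <- glmnet::glmnet(Z[, -j, drop = FALSE], Z[, j], lambda = grid,
                            standardize = FALSE, intercept = TRUE)
      B <- as.matrix(fit$beta)
      # glmnet may drop trailing lambdas; align by position
      for (l in seq_len(ncol(B))) {
        sel <- which(B[, l] != 0)
        others <- seq_len(pk)[-j]
        adj[j, others[sel], l] <- TRUE
      }
      if (ncol(B) < length(grid)) {
        for (l in seq(ncol(B) + 1, length(grid))) adj[j, , l] <- adj[j, , ncol(B)]
      }
    }
    adj | aperm(adj, c(2, 1, 3))
  }

  set.seed(config$seed)
  # canonical StARS subsample size floor(10*sqrt(n)), capped by the
  # configured fraction of n
  b <- min(floor(10 * sqrt(n)), floor(cfg$subsample_fraction * n))
  b <- max(10L, b)
  freq <- array(0, c(pk, pk, length(grid)))
  for (s in seq_len(cfg$stars_subsamples)) {
    idx <- sample.int(n, b)
    freq <- freq + fit_adj(Xk[idx, , drop = FALSE])
  }
  theta <- freq / cfg$stars_subsamples
  npairs <- pk * (pk - 1) / 2
  instab <- apply(theta, 3, function(th) {
    sum((2 * th * (1 - th))[upper.tri(th)]) / npairs
  })
  # StARS selection with two small-p guards: the sparsest lambdas can
  # flicker on single borderline edges, and near-saturated graphs are
  # spuriously stable. Search only where mean subsample density <= 0.5,
  # anchor at the instability minimum there, and monotonise (cummax)
  # toward denser graphs; pick the densest lambda still at or below beta.
  dens <- apply(theta, 3, function(th) mean(th[upper.tri(th)]))
  kmax <- if (any(dens <= 0.5)) max(which(dens <= 0.5)) else 1L
  m <- which.min(instab[1:kmax])
  if (instab[m] > cfg$stars_beta) {
    sel_idx <- m
  } else {
    mono <- cummax(instab[m:kmax])
    sel_idx <- m - 1L + max(which(mono <= cfg$stars_beta))
  }
  lambda_selected <- grid[sel_idx]

  full <- fit_adj(Xk)[, , sel_idx]
  # signs from full-data coefficients at the selected lambda
  signs <- matrix(0, pk, pk)
  coefm <- matrix(0, pk, pk)
  for (j in seq_len(pk)) {
    fit <- glmnet::glmnet(Xk[, -j, drop = FALSE], Xk[, j],
                          lambda = lambda_selected,
                          standardize = FALSE, intercept = TRUE)
    coefm[j, seq_len(pk)[-j]] <- as.numeric(fit$beta)
  }
  for (i in seq_len(pk - 1)) for (j in seq(i + 1, pk)) {
    if (full[i, j]) {
      cij <- coefm[i, j]; cji <- coefm[j, i]
      s <- if (abs(cij) >= abs(cji)) sign(cij) else sign(cji)
      if (s == 0) s <- sign(cij + cji)
      signs[i, j] <- signs[j, i] <- s
    }
  }
  adj_out <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  sgn_out <- matrix(0, p, p, dimnames = list(nodes, nodes))
  adj_out[ids, ids] <- full * 1L
  sgn_out[ids, ids] <- signs
  structure(list(adjacency = adj_out, sign = sgn_out,
                 lambda_selected = lambda_selected, lambda_grid = grid,
                 instability = instab,
                 stability_path = theta),
            class = "mb_graph")
}

#' Build the consensus co-occurrence network from the three methods
#'
#' Per-method edge calls: SparCC — \eqn{|\rho| \ge} `rho_cut` and pseudo-p
#' < `pseudo_p_cut`; Spearman — \eqn{|\rho| \ge} `rho_cut` and q <
#' `q_cut`; MB — membership in the selected adjacency. An edge enters the
#' consensus network iff at least `min_support` methods call it and (with
#' `positive_only`) every supporting method reports a positive sign.
#' Nodes left without edges are dropped from the graph and listed in the
#' `isolated` attribute.
#'
#' @param sparcc_est A [sparcc()] result.
#' @param spearman_est A [spearman_network()] result.
#' @param mb_est A [mb_neighborhood()] result.
#' @param taxa Optional tibble of node annotations (`taxon_id`,
#'   `domain_label`, `family`).
#' @param config An [ensemble_config()].
#' @return A [cooccurrence_network()] whose edges carry `support_count`,
#'   `sparcc_rho`, `spearman_rho`, `mb_selected` and `consensus_sign`.
#' @export
build_ensemble <- function(sparcc_est, spearman_est, mb_est, taxa = NULL,
                           config = ensemble_config()) {
  ids <- rownames(sparcc_est$rho)
  if (!identical(ids, rownames(spearman_est$rho)) ||
      !identical(ids, rownames(mb_est$adjacency))) {
    stop("method results cover different taxon sets", call. = FALSE)
  }
  p <- length(ids)
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)

  s_rho <- sparcc_est$rho[ut]
  s_p <- if (!is.null(sparcc_est$pvals)) sparcc_est$pvals[ut] else rep(0, nrow(ut))
  sp_rho <- spearman_est$rho[ut]
  sp_q <- spearman_est$qvals[ut]
  mb_sel <- mb_est$adjacency[ut] == 1
  mb_sign <- mb_est$sign[ut]

  if (config$combine == "vote") {
    call_sparcc <- abs(s_rho) >= config$sparcc$rho_cut & s_p < config$sparcc$pseudo_p_cut
    call_spear <- abs(sp_rho) >= config$spearman$rho_cut & sp_q < config$spearman$q_cut
  } else {
    avg <- (s_rho + sp_rho) / 2
    call_sparcc <- abs(avg) >= config$sparcc$rho_cut & s_p < config$sparcc$pseudo_p_cut
    call_spear <- abs(avg) >= config$sparcc$rho_cut & sp_q < config$spearman$q_cut
  }
  support <- call_sparcc + call_spear + mb_sel

  sign_ok <- rep(TRUE, nrow(ut))
  if (config$positive_only) {
    sign_ok <- (!call_sparcc | s_rho > 0) &
               (!call_spear | sp_rho > 0) &
               (!mb_sel | mb_sign > 0)
  }
  keep <- support >= config$min_support & sign_ok

  edges <- tibble::tibble(
    source = ids[ut[keep, 1]],
    target = ids[ut[keep, 2]],
    support_count = as.integer(support[keep]),
    sparcc_rho = s_rho[keep],
    spearman_rho = sp_rho[keep],
    mb_selected = mb_sel[keep],
    consensus_sign = 1L
  )
  connected <- unique(c(edges$source, edges$target))
  nodes <- tibble::tibble(taxon_id = connected)
  if (!is.null(taxa)) {
    nodes <- dplyr::left_join(nodes, tibble::as_tibble(taxa), by = "taxon_id")
  }
  net <- cooccurrence_network(edges, nodes)
  attr(net, "isolated") <- setdiff(ids, connected)
  attr(net, "config") <- config
  net
}

#' Infer the consensus network from a stacked table in one call
#'
#' Convenience wrapper running [sparcc()], [spearman_network()] and
#' [mb_neighborhood()] with a shared seed and combining them with
#' [build_ensemble()]. SparCC sees counts, Spearman relative abundances,
#' MB the CLR transform — each method's native convention.
#'
#' @param stacked A `stacked_table` from [stack_tables()] (or an
#'   [abundance_table()]).
#' @param config An [ensemble_config()].
#' @return A [cooccurrence_network()].
#' @export
infer_network <- function(stacked, config = ensemble_config()) {
  sp <- config$sparcc
  s_est <- sparcc(stacked, iterations = sp$iterations,
                  exclusion_threshold = sp$exclusion_threshold,
                  exclusion_rounds = sp$exclusion_rounds,
                  n_bootstrap = sp$n_bootstrap, pseudocount = sp$pseudocount,
                  seed = config$seed)
  se_est <- spearman_network(stacked)
  mb_est <- mb_neighborhood(stacked, config)
  taxa <- if (is.list(stacked) && !is.null(stacked$taxa)) stacked$taxa else NULL
  build_ensemble(s_est, se_est, mb_est, taxa = taxa, config = config)
}
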