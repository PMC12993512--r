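test_that("Spearman networks honour rank-correlation identities", {
  x <- c(10L, 20L, 30L, 40L, 50L, 60L)
  y <- c(11L, 22L, 35L, 47L, 52L, 80L)   # increasing in x
  z <- c(60L, 50L, 40L, 30L, 20L, 10L)   # reversal of x
  w <- rep(5L, 6)                        # constant
  # equal column totals so compositional closure preserves every rank
  counts <- rbind(x = x, y = y, z = z, w = w, filler = 400L - (x + y + z + w))
  colnames(counts) <- paste0("s", 1:6)
  est <- spearman_network(counts)
  expect_equal(est$rho["x", "y"], 1)
  expect_equal(est$rho["x", "z"], -1)
  expect_equal(est$rho["x", "w"], 0)
  expect_equal(est$pvals["x", "w"], 1)
  expect_true(all(est$qvals[upper.tri(est$qvals)] >=
                  est$pvals[upper.tri(est$pvals)] - 1e-15))
})

test_that("Spearman matches the direct rank formula on untied vectors", {
  # relative abundance is a per-sample rescaling; ranks across samples are
  # driven by the raw profiles here because each column is closed over the
  # same two taxa plus a large constant filler
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  d <- rank(x) - rank(y)
  brute <- 1 - 6 * sum(d^2) / (6 * (6^2 - 1))
  expect_equal(brute, 0.8285714, tolerance = 1e-6)
  expect_equal(unname(stats::cor(x, y, method = "spearman")), brute)
  counts <- rbind(a = as.integer(x * 10), b = as.integer(y * 10),
                  filler = rep(1000L, 6), filler2 = rep(500L, 6))
  colnames(counts) <- paste0("s", 1:6)
  est <- spearman_network(counts)
  expect_equal(est$rho["a", "b"], brute, tolerance = 1e-12)
})

test_that("Spearman is invariant to per-taxon monotone transforms", {
  set.seed(4)
  counts <- matrix(rpois(5 * 40, 30) + 1L, 5, 40,
                   dimnames = list(paste0("t", 1:5), paste0("s", 1:40)))
  e1 <- spearman_network(counts)
  # cubing one taxon's relative profile is monotone; rank structure of the
  # raw matrix feeds through relative abundance identically when totals
  # are matched, so compare on the closed data directly
  rel <- relative_abundance(counts)
  r1 <- stats::cor(t(rel), method = "spearman")
  r2 <- stats::cor(t(rbind(rel[1, ]^3, rel[-1, ])), method = "spearman")
  expect_equal(abs(unname(r1[1, 2])), abs(unname(r2[1, 2])), tolerance = 1e-12)
  expect_error(spearman_network(counts[, 1:2]), "3 samples")
})

test_that("neighborhood selection recovers a chain and stays sparse on noise", {
  want <- matrix(0, 5, 5)
  for (i in 1:4) want[i, i + 1] <- want[i + 1, i] <- 1
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    prec <- diag(1.1, 5)
    for (i in 1:4) prec[i, i + 1] <- prec[i + 1, i] <- -0.4
    Z <- matrix(rnorm(500 * 5), 500, 5) %*% chol(solve(prec))
    dimnames(Z) <- list(paste0("s", 1:500), paste0("t", 1:5))
    g <- mb_neighborhood(t(Z), ensemble_config(seed = s), clr = FALSE)
    if (all(g$adjacency == want)) hits <- hits + 1
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
    expect_true(g$lambda_selected %in% g$lambda_grid)
  }
  expect_gte(hits, 9)

  set.seed(101)
  Z <- matrix(rnorm(300 * 15), 300, 15,
              dimnames = list(paste0("s", 1:300), paste0("t", 1:15)))
  g0 <- mb_neighborhood(t(Z), ensemble_config(seed = 1), clr = FALSE)
  expect_lt(sum(g0$adjacency) / (15 * 14), 0.02)
})

test_that("constant taxa are excluded from neighborhood selection with a warning", {
  set.seed(2)
  Z <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("s", 1:50), paste0("t", 1:6)))
  Z[, 6] <- 3
  expect_warning(g <- mb_neighborhood(t(Z), ensemble_config(seed = 1),
                                      clr = FALSE), "constant")
  expect_true(all(g$adjacency[6, ] == 0))
})

test_that("the ensemble vote applies support and positive-sign rules", {
  ids <- paste0("t", 1:4)
  mk <- function(v) matrix(v, 4, 4, dimnames = list(ids, ids))
  rho_s <- mk(0); diag(rho_s) <- 1
  rho_s["t1", "t2"] <- rho_s["t2", "t1"] <- 0.6   # all three call this
  rho_s["t1", "t3"] <- rho_s["t3", "t1"] <- 0.5   # sparcc only
  rho_s["t2", "t3"] <- rho_s["t3", "t2"] <- 0.4   # sign conflict with spearman
  pv <- mk(0.001)
  sp_est <- structure(list(rho = rho_s, pvals = pv), class = "sparcc_estimate")

  rho_p <- mk(0); diag(rho_p) <- 1
  rho_p["t1", "t2"] <- rho_p["t2", "t1"] <- 0.7
  rho_p["t2", "t3"] <- rho_p["t3", "t2"] <- -0.6
  qv <- mk(0.0001)
  se_est <- structure(list(rho = rho_p, pvals = qv, qvals = qv),
                      class = "correlation_matrix")

  adj <- mk(0)
  adj["t1", "t2"] <- adj["t2", "t1"] <- 1
  adj["t2", "t3"] <- adj["t3", "t2"] <- 1
  sgn <- adj
  mb_est <- structure(list(adjacency = adj, sign = sgn), class = "mb_graph")

  net <- build_ensemble(sp_est, se_est, mb_est, config = ensemble_config())
  key <- paste(pmin(net$edges$source, net$edges$target),
               pmax(net$edges$source, net$edges$target))
  expect_identical(key, "t1 t2")                       # support 3, all positive
  expect_equal(net$edges$support_count, 3L)
  expect_setequal(attr(net, "isolated"), c("t3", "t4"))

  # t1-t3: sparcc only -> below min_support 2; with min_support 1 it enters
  net1 <- build_ensemble(sp_est, se_est, mb_est,
                         config = ensemble_config(min_support = 1))
  key1 <- paste(pmin(net1$edges$source, net1$edges$target),
                pmax(net1$edges$source, net1$edges$target))
  expect_true("t1 t3" %in% key1)
  # t2-t3 carries a sign conflict (spearman negative) -> never included
  expect_false("t2 t3" %in% key1)

  bad <- sp_est; rownames(bad$rho) <- rev(rownames(bad$rho))
  expect_error(build_ensemble(bad, se_est, mb_est), "different taxon sets")
})

test_that("end-to-end inference is deterministic under seed", {
  cfg <- sim_config(p_bacteria = 12, p_phototroph = 6, p_fungus = 4,
                    n_samples = 40, seed = 6)
  sim <- simulate_counts(plant_network(cfg), cfg)
  st <- stack_tables(sim$t16, sim$t18)
  ec <- ensemble_config(sparcc = list(iterations = 2, n_bootstrap = 20),
                        mb = list(stars_subsamples = 10), seed = 9)
  n1 <- infer_network(st, ec)
  n2 <- infer_network(st, ec)
  expect_identical(n1$edges, n2$edges)
  expect_true(all(n1$edges$consensus_sign == 1L))
})
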