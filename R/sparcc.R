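#' SparCC basis correlations from compositional counts
#'
#' Estimates correlations between the unobserved "basis" abundances
#' underlying compositional count data. For each pair the log-ratio
#' variance \eqn{t_{ij} = Var[\log(x_i/x_j)]} is computed from estimated
#' fractions; basis variances \eqn{\omega_i^2} are obtained by solving the
#' linear system that results from assuming correlations are sparse, and
#' \deqn{\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2 \omega_i \omega_j),}
#' clipped to \eqn{[-1, 1]}. Strongly correlated pairs
#' (\eqn{|\rho| >} `exclusion_threshold`) violate the sparsity assumption
#' and are iteratively excluded from the system and the estimate re-solved,
#' up to `exclusion_rounds` times. Fractions are posterior-mean
#' (count + pseudocount over shifted total); with `iterations > 1` the
#' estimate is the element-wise median over Dirichlet resamples of the
#' fractions. A permutation null (each taxon's counts shuffled across
#' samples independently, `n_bootstrap` times) yields two-sided pseudo
#' p-values.
#'
#' @param table An [abundance_table()], `stacked_table`, or taxa x samples
#'   count matrix with at least 4 taxa.
#' @param iterations Dirichlet resampling iterations (1 = posterior-mean
#'   fractions only).
#' @param exclusion_threshold \eqn{|\rho|} above which a pair is excluded.
#' @param exclusion_rounds Maximum exclusion/re-solve rounds.
#' @param n_bootstrap Permutation resamples for pseudo p-values (0 skips).
#' @param pseudocount Added to counts when forming fractions.
#' @param seed Integer seed for Dirichlet and permutation draws.
#' @return A list of class `sparcc_estimate`: `rho` (correlations),
#'   `omega2` (basis variances), `t_matrix` (log-ratio variances),
#'   `pvals` (or NULL), `excluded_pairs`, `n_iterations`.
#' @export
sparcc <- function(table, iterations = 20, exclusion_threshold = 0.8,
                   exclusion_rounds = 10, n_bootstrap = 100,
                   pseudocount = 1, seed = 1L) {
  counts <- if (is.list(table)) table$counts else as.matrix(table)
  p <- nrow(counts)
  n <- ncol(counts)
  if (p < 4) stop("SparCC needs at least 4 taxa", call. = FALSE)
  set.seed(seed)

  est <- sparcc_once(counts, iterations, exclusion_threshold,
                     exclusion_rounds, pseudocount)

  pvals <- NULL
  if (n_bootstrap > 0) {
    exceed <- matrix(0, p, p)
    for (b in seq_len(n_bootstrap)) {
      perm <- counts
      for (i in seq_len(p)) perm[i, ] <- perm[i, sample.int(n)]
      rb <- sparcc_once(perm, 1, exclusion_threshold, exclusion_rounds,
                        pseudocount)$rho
      exceed <- exceed + (abs(rb) >= abs(est$rho))
    }
    pvals <- (exceed + 1) / (n_bootstrap + 1)
    diag(pvals) <- 0
    dimnames(pvals) <- dimnames(est$rho)
  }
  structure(c(est, list(pvals = pvals, n_iterations = iterations)),
            class = "sparcc_estimate")
}

# single SparCC estimate (median over Dirichlet iterations)
sparcc_once <- function(counts, iterations, exclusion_threshold,
                        exclusion_rounds, pseudocount) {
  p <- nrow(counts)
  rhos <- vector("list", iterations)
  last <- NULL
  for (it in seq_len(iterations)) {
    if (iterations == 1) {
      fr <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), `/`)
    } else {
      g <- matrix(stats::rgamma(length(counts), shape = counts + pseudocount),
                  nrow(counts))
      fr <- sweep(g, 2, colSums(g), `/`)
    }
    last <- sparcc_basis(log(fr), exclusion_threshold, exclusion_rounds)
    rhos[[it]] <- last$rho
  }
  rho <- if (iterations == 1) rhos[[1]] else {
    apply(simplify2array(rhos), c(1, 2), stats::median)
  }
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  list(rho = rho, omega2 = last$omega2, t_matrix = last$t_matrix,
       excluded_pairs = last$excluded_pairs)
}

# solve the basis system from log-fraction data with iterative exclusion
sparcc_basis <- function(logf, exclusion_threshold, exclusion_rounds) {
  p <- nrow(logf)
  V <- stats::cov(t(logf))
  v <- diag(V)
  tmat <- outer(v, v, `+`) - 2 * V    # t_ij = Var(log x_i - log x_j)
  tmat[tmat < 0] <- 0
  diag(tmat) <- 0

  inc <- matrix(TRUE, p, p)
  diag(inc) <- FALSE
  excluded <- matrix(integer(0), ncol = 2)

  solve_basis <- function(inc) {
    d <- rowSums(inc)
    M <- inc * 1
    diag(M) <- d
    tvec <- rowSums(tmat * inc)
    w <- tryCatch(solve(M, tvec), error = function(e) NULL)
    if (is.null(w)) return(NULL)
    w[w < 1e-10] <- 1e-10
    sw <- sqrt(w)
    rho <- (outer(w, w, `+`) - tmat) / (2 * outer(sw, sw))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    list(rho = rho, omega2 = w)
  }

  sol <- solve_basis(inc)
  if (is.null(sol)) stop("singular SparCC basis system", call. = FALSE)
  for (round in seq_len(exclusion_rounds)) {
    cand <- abs(sol$rho)
    cand[!inc | lower.tri(cand)] <- 0
    m <- which.max(cand)
    if (cand[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(cand))
    inc2 <- inc
    inc2[ij[1], ij[2]] <- inc2[ij[2], ij[1]] <- FALSE
    if (min(rowSums(inc2)) < 2) break   # keep the system well posed
    new_sol <- solve_basis(inc2)
    if (is.null(new_sol)) break         # fall back to previous round
    inc <- inc2
    sol <- new_sol
    excluded <- rbind(excluded, ij)
  }
  list(rho = sol$rho, omega2 = sol$omega2, t_matrix = tmat,
       excluded_pairs = excluded)
}

#' @export
print.sparcc_estimate <- function(x, ...) {
  cat(sprintf("<sparcc_estimate> %d taxa, %d excluded pair(s)\n",
              nrow(x$rho), nrow(x$excluded_pairs)))
  invisible(x)
}
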