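#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all
#' pairs of sample rows.
#'
#' @param m Samples x taxa non-negative matrix with positive row sums.
#' @return A symmetric n x n matrix with zero diagonal, entries in
#'   \eqn{[0, 1]}, sample ids as dimnames.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("zero-sum sample(s): ",
         paste((rownames(m) %||% seq_len(nrow(m)))[rs == 0], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(abs(xi - m[j, ])) / (rs[i] + rs[j])
    }
  }
  d
}

# principal-coordinate workspace shared by dbrda and forward selection
pcoa_space <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  thr <- tol * max(abs(e$values))
  pos <- e$values > thr
  neg <- e$values < -thr
  Y <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                               nrow = sum(pos))
  rownames(Y) <- rownames(d)
  list(Y = Y, total_inertia = sum(e$values[pos]),
       negative_inertia = sum(abs(e$values[neg])), n = n)
}

#' Distance-based redundancy analysis (db-RDA)
#'
#' Double-centers the squared dissimilarities into a Gower matrix,
#' extracts the real (positive-eigenvalue) principal-coordinate space and
#' regresses it on the constraint matrix. Constrained inertia is the sum
#' of the canonical eigenvalues; the inertia carried by negative
#' eigenvalues of the non-Euclidean dissimilarity is excluded from the
#' decomposition and reported separately. Collinear constraint columns
#' are dropped with a warning.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param constraints Samples x q numeric matrix or data frame; rows must
#'   align with `d`.
#' @param n_perm Permutations for the overall-model pseudo-F test
#'   (0 skips the test).
#' @param seed Integer seed for the permutations.
#' @return A list of class `dbrda_fit`: `total_inertia`,
#'   `constrained_inertia`, `unconstrained_inertia`, `negative_inertia`,
#'   `explained_fraction`, `adj_explained_fraction`, `eigenvalues`
#'   (canonical, descending), `rank` (constraint df), `pseudo_f`,
#'   `p_value`, `n`, `constraint_names`.
#' @export
dbrda <- function(d, constraints, n_perm = 0, seed = 1L) {
  sp <- pcoa_space(d)
  X <- as.matrix(constraints)
  if (nrow(X) != sp$n) stop("constraints do not align with the distance matrix",
                            call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0)) stop("zero-variance constraint", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("dropping ", ncol(Xc) - qr_x$rank, " collinear constraint column(s)",
            call. = FALSE)
    Xc <- Xc[, keep, drop = FALSE]
    qr_x <- qr(Xc)
  }
  Q <- qr.Q(qr_x)
  fit <- crossprod(Q, sp$Y)              # q x axes
  M <- tcrossprod(fit)                   # q x q, same nonzero spectrum as Y'HY
  ev <- sort(eigen((M + t(M)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev <- ev[ev > 1e-12 * max(1, abs(ev[1]))]
  ci <- sum(diag(M))
  q <- qr_x$rank
  n <- sp$n
  r2 <- ci / sp$total_inertia
  out <- list(
    total_inertia = sp$total_inertia,
    constrained_inertia = ci,
    unconstrained_inertia = sp$total_inertia - ci,
    negative_inertia = sp$negative_inertia,
    explained_fraction = r2,
    adj_explained_fraction = 1 - (1 - r2) * (n - 1) / (n - 1 - q),
    eigenvalues = ev,
    rank = q,
    pseudo_f = (ci / q) / ((sp$total_inertia - ci) / (n - 1 - q)),
    p_value = NA_real_,
    n = n,
    constraint_names = colnames(X) %||% paste0("X", seq_len(ncol(X)))
  )
  if (n_perm > 0) {
    set.seed(seed)
    f_obs <- out$pseudo_f
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Xp <- Xc[sample.int(n), , drop = FALSE]
      Qp <- qr.Q(qr(Xp))
      cip <- sum(crossprod(Qp, sp$Y)^2)
      fp <- (cip / q) / ((sp$total_inertia - cip) / (n - 1 - q))
      if (fp >= f_obs) hits <- hits + 1L
    }
    out$p_value <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat(sprintf(
    "<dbrda_fit> n = %d, constraints (df) = %d\n  inertia: total %.4f = constrained %.4f + unconstrained %.4f (negative %.4f apart)\n  explained: %.1f%% (adjusted %.1f%%)\n",
    x$n, x$rank, x$total_inertia, x$constrained_inertia,
    x$unconstrained_inertia, x$negative_inertia,
    100 * x$explained_fraction, 100 * x$adj_explained_fraction))
  if (!is.na(x$p_value)) cat(sprintf("  pseudo-F = %.3f, p = %.4f\n",
                                     x$pseudo_f, x$p_value))
  invisible(x)
}

#' Permutation-based forward selection of db-RDA constraints
#'
#' Starting from the null model, iteratively adds the candidate with the
#' largest marginal pseudo-F whose permutation p-value (free permutation
#' of that candidate's rows, conditioned on the terms already selected)
#' is strictly below `alpha`. Stops when no candidate qualifies.
#' Candidates nearly collinear with the selected set (|r| > 0.999 after
#' projection) are skipped.
#'
#' @param d Dissimilarity matrix.
#' @param candidates Samples x q data frame or matrix of named candidate
#'   constraints.
#' @param alpha Per-step significance level; default 0.01.
#' @param n_perm Permutations per test; default 999.
#' @param seed Integer seed.
#' @return A list of class `forward_selection`: `selected` tibble
#'   (`term`, `pseudo_f`, `p_value`, `cum_explained`), `model` (the
#'   [dbrda()] fit on the selected terms, or NULL when empty),
#'   `candidates` (names).
#' @export
forward_select <- function(d, candidates, alpha = 0.01, n_perm = 999,
                           seed = 1L) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)", call. = FALSE)
  sp <- pcoa_space(d)
  X <- as.matrix(candidates)
  nm <- colnames(X) %||% paste0("X", seq_len(ncol(X)))
  colnames(X) <- nm
  n <- sp$n
  set.seed(seed)

  keep_rows <- stats::complete.cases(X)
  if (!all(keep_rows)) stop("candidates contain missing values; subset samples first",
                            call. = FALSE)
  selected <- character()
  records <- list()
  Qz <- matrix(0, n, 0)
  ci_z <- 0

  repeat {
    remaining <- setdiff(nm, selected)
    if (!length(remaining) || length(selected) >= n - 2) break
    q_next <- length(selected) + 1
    df_res <- n - 1 - q_next
    if (df_res < 1) break

    stat <- vapply(remaining, function(v) {
      x <- X[, v]
      xt <- x - mean(x)
      if (ncol(Qz)) xt <- xt - Qz %*% crossprod(Qz, xt)
      ss <- sum(xt^2)
      if (ss < 1e-12 * sum((x - mean(x))^2) || ss == 0) return(c(NA, NA))
      added <- sum(crossprod(sp$Y, xt)^2) / ss
      f <- (added / 1) / ((sp$total_inertia - ci_z - added) / df_res)
      c(added, f)
    }, numeric(2))
    fs <- stat[2, ]
    if (all(is.na(fs))) break
    best <- remaining[which.max(fs)]
    f_obs <- fs[which.max(fs)]

    # permutation null: shuffle the best candidate, condition on selected
    x <- X[, best]
    P <- vapply(seq_len(n_perm), function(b) x[sample.int(n)], numeric(n))
    P <- sweep(P, 2, colMeans(P))
    if (ncol(Qz)) P <- P - Qz %*% crossprod(Qz, P)
    ss <- colSums(P^2)
    added_p <- colSums((crossprod(sp$Y, P))^2) / ss
    f_p <- added_p / ((sp$total_inertia - ci_z - added_p) / df_res)
    p_val <- (sum(f_p >= f_obs) + 1) / (n_perm + 1)
    if (!(p_val < alpha)) break

    selected <- c(selected, best)
    xt <- x - mean(x)
    if (ncol(Qz)) xt <- xt - Qz %*% crossprod(Qz, xt)
    Qz <- cbind(Qz, xt / sqrt(sum(xt^2)))
    ci_z <- sum(crossprod(Qz, sp$Y)^2)
    records[[best]] <- tibble::tibble(
      term = best, pseudo_f = f_obs, p_value = p_val,
      cum_explained = ci_z / sp$total_inertia
    )
  }

  model <- if (length(selected)) {
    suppressWarnings(dbrda(d, X[, selected, drop = FALSE]))
  } else NULL
  structure(list(selected = dplyr::bind_rows(records), model = model,
                 candidates = nm, alpha = alpha, n_perm = n_perm),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("<forward_selection> %d of %d candidates selected (alpha = %g)\n",
              nrow(x$selected), length(x$candidates), x$alpha))
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Log-standardise environmental variables
#'
#' Natural log; columns containing zeros (or negative values, which are
#' first shifted to zero) get an offset of half their smallest positive
#' value.
#'
#' @param env Data frame or matrix of numeric environmental columns.
#' @return A numeric matrix of the same shape.
#' @export
log_standardize <- function(env) {
  env <- as.matrix(env)
  apply(env, 2, function(x) {
    if (all(is.na(x))) return(x)
    mn <- min(x, na.rm = TRUE)
    if (mn > 0) return(log(x))
    y <- x - mn
    pos <- y[y > 0 & !is.na(y)]
    log(y + min(pos) / 2)
  })
}

#' Explained variance: keystone taxa versus environment
#'
#' Runs forward selection + db-RDA three times against the same
#' Wisconsin-standardised Bray-Curtis matrix of the bacterial community:
#' constrained by (1) bacterial keystone relative abundances, (2)
#' eukaryotic keystone relative abundances, (3) log-standardised
#' environmental variables; and reports the three explained-variance
#' fractions side by side (raw and adjusted).
#'
#' @param bacteria A 16S [abundance_table()].
#' @param keystones16,keystones18 Character vectors of keystone taxon ids
#'   present in the respective tables.
#' @param t18 The paired 18S [abundance_table()].
#' @param env Samples x variables data frame of environmental columns
#'   (aligned with the sample order of `bacteria`).
#' @param alpha,n_perm,seed Forward-selection settings; defaults 0.01 /
#'   999 / 1.
#' @return A list of class `keystone_variance`: `summary` tibble (one row
#'   per constraint set: `constraint_set`, `n_candidates`, `n_selected`,
#'   `explained`, `adj_explained`) and `fits` (the three
#'   `forward_selection` objects).
#' @export
keystone_vs_environment <- function(bacteria, keystones16, keystones18, t18,
                                    env, alpha = 0.01, n_perm = 999,
                                    seed = 1L) {
  stopifnot(inherits(bacteria, "abundance_table"), inherits(t18, "abundance_table"))
  miss16 <- setdiff(keystones16, taxon_ids(bacteria))
  miss18 <- setdiff(keystones18, taxon_ids(t18))
  if (length(miss16) || length(miss18)) {
    stop("keystones absent from tables: ",
         paste(c(miss16, miss18), collapse = ", "), call. = FALSE)
  }
  comm <- wisconsin_double_standardize(t(bacteria$counts))
  d <- bray_curtis(comm)
  rel16 <- t(relative_abundance(bacteria))[, keystones16, drop = FALSE]
  rel18 <- t(relative_abundance(t18))[, keystones18, drop = FALSE]
  envm <- log_standardize(env)

  run <- function(cand, label, s) {
    cand <- as.matrix(cand)
    ok <- stats::complete.cases(cand)
    fsel <- forward_select(d[ok, ok, drop = FALSE], cand[ok, , drop = FALSE],
                           alpha = alpha, n_perm = n_perm, seed = s)
    tibble::tibble(
      constraint_set = label,
      n_candidates = ncol(cand),
      n_selected = nrow(fsel$selected),
      explained = if (is.null(fsel$model)) 0 else fsel$model$explained_fraction,
      adj_explained = if (is.null(fsel$model)) 0 else
        fsel$model$adj_explained_fraction,
      fit = list(fsel)
    )
  }
  rows <- dplyr::bind_rows(
    run(rel16, "bacterial_keystones", seed),
    run(rel18, "eukaryotic_keystones", seed + 1L),
    run(envm, "environment", seed + 2L)
  )
  structure(list(summary = dplyr::select(rows, -"fit"), fits = rows$fit),
            class = "keystone_variance")
}

#' @export
print.keystone_variance <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
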