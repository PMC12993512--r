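#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a db-RDA fit: one row per canonical axis
#'
#' @param x A [dbrda()] fit.
#' @param ... Unused.
#' @return A tibble with `axis`, `eigenvalue`, `proportion` (of
#'   constrained inertia).
#' @export
tidy.dbrda_fit <- function(x, ...) {
  k <- length(x$eigenvalues)
  tibble::tibble(
    axis = paste0("CAP", seq_len(k)),
    eigenvalue = x$eigenvalues,
    proportion = x$eigenvalues / x$constrained_inertia
  )
}

#' One-row summary of a db-RDA fit
#'
#' @param x A [dbrda()] fit.
#' @param ... Unused.
#' @return A one-row tibble with the inertia decomposition, explained
#'   fractions, pseudo-F and p-value.
#' @export
glance.dbrda_fit <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    constrained_inertia = x$constrained_inertia,
    unconstrained_inertia = x$unconstrained_inertia,
    negative_inertia = x$negative_inertia,
    explained_fraction = x$explained_fraction,
    adj_explained_fraction = x$adj_explained_fraction,
    df = x$rank, n = x$n,
    pseudo_f = x$pseudo_f, p_value = x$p_value
  )
}

#' Tidy a forward selection: one row per selected term
#' @param x A [forward_select()] result.
#' @param ... Unused.
#' @return The `selected` tibble.
#' @export
tidy.forward_selection <- function(x, ...) x$selected

#' One-row summary of a forward selection
#' @param x A [forward_select()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.forward_selection <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates),
    n_selected = nrow(x$selected),
    explained_fraction = if (is.null(x$model)) 0 else x$model$explained_fraction,
    adj_explained_fraction = if (is.null(x$model)) 0 else
      x$model$adj_explained_fraction,
    alpha = x$alpha, n_perm = x$n_perm
  )
}

#' Tidy a fragmentation trajectory
#' @param x A [removal_trajectory()] result.
#' @param ... Unused.
#' @return The per-step tibble.
#' @export
tidy.fragmentation_trajectory <- function(x, ...) x$steps

#' One-row summary of a fragmentation trajectory
#' @param x A [removal_trajectory()] result.
#' @param ... Unused.
#' @return A one-row tibble with `baseline_f`, `f_mean`, `n_removals`.
#' @export
glance.fragmentation_trajectory <- function(x, ...) {
  tibble::tibble(baseline_f = x$baseline_f, f_mean = x$f_mean,
                 n_removals = nrow(x$steps))
}

#' Tidy a community partition
#' @param x A [louvain_communities()] result.
#' @param ... Unused.
#' @return The membership tibble.
#' @export
tidy.community_partition <- function(x, ...) x$membership

#' Tidy a co-occurrence network: its edge table
#' @param x A `cooccurrence_network`.
#' @param ... Unused.
#' @return The edges tibble.
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' One-row summary of a co-occurrence network
#' @param x A `cooccurrence_network`.
#' @param ... Unused.
#' @return The [topology()] tibble.
#' @export
glance.cooccurrence_network <- function(x, ...) topology(x)

#' Plot a fragmentation trajectory
#'
#' Fragmentation f against the number of keystones removed, with the
#' baseline as a dashed reference line.
#'
#' @param object A [removal_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fragmentation_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$steps, ggplot2::aes(x = .data$step, y = .data$f)) +
    ggplot2::geom_hline(yintercept = object$baseline_f, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "keystones removed", y = "fragmentation f") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network coloured by domain
#'
#' @param object A `cooccurrence_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object (Fruchterman-Reingold layout).
#' @export
autoplot.cooccurrence_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = xy[match(el[, 1], object$nodes$taxon_id), 1],
    y = xy[match(el[, 1], object$nodes$taxon_id), 2],
    xend = xy[match(el[, 2], object$nodes$taxon_id), 1],
    yend = xy[match(el[, 2], object$nodes$taxon_id), 2]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$domain_label), size = 2) +
    ggplot2::labs(colour = "domain") +
    ggplot2::theme_void()
}

#' Plot explained variance per constraint set
#'
#' @param object A [keystone_vs_environment()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of explained-variance fractions.
#' @export
autoplot.keystone_variance <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$constraint_set,
                               y = 100 * .data$explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "explained variance (%)") +
    ggplot2::theme_minimal()
}
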