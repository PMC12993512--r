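#' Family-level two-way ANOVA enrichment tests
#'
#' For each family, a two-way fixed-effects ANOVA of its relative
#' abundance on stream type and deglaciation class with their
#' interaction; p-values are Benjamini-Hochberg adjusted across families
#' within each effect. Families are skipped (with a warning) when any
#' factor cell has fewer than 2 samples.
#'
#' @param family_matrix Family x sample matrix of relative abundances
#'   (e.g. from [aggregate_family()]).
#' @param metadata Tibble with `sample_id`, `stream_type`, `deglaciation`
#'   covering the matrix columns.
#' @param factors Character vector of the two factor columns; default
#'   `c("stream_type", "deglaciation")`.
#' @return A tibble: `family`, `effect`, `f_statistic`, `p_value`,
#'   `adjusted_p`, sorted by `adjusted_p` within effect.
#' @export
family_enrichment <- function(family_matrix, metadata,
                              factors = c("stream_type", "deglaciation")) {
  if (length(factors) != 2) stop("exactly two factors required", call. = FALSE)
  md <- metadata[match(colnames(family_matrix), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples", call. = FALSE)
  f1 <- factor(md[[factors[1]]])
  f2 <- factor(md[[factors[2]]])
  cells <- table(f1, f2)
  if (any(cells < 2)) {
    warning("factor cell(s) with < 2 samples; results may be unstable",
            call. = FALSE)
    if (any(cells == 0)) {
      warning("empty factor cell; enrichment tests skipped", call. = FALSE)
      return(tibble::tibble(family = character(), effect = character(),
                            f_statistic = numeric(), p_value = numeric(),
                            adjusted_p = numeric()))
    }
  }
  effects <- c(factors, paste0(factors[1], ":", factors[2]))
  res <- purrr::map_dfr(rownames(family_matrix), function(fam) {
    y <- family_matrix[fam, ]
    if (stats::sd(y) == 0) return(NULL)
    fit <- stats::aov(y ~ f1 * f2)
    tab <- summary(fit)[[1]]
    tibble::tibble(
      family = fam,
      effect = effects,
      f_statistic = tab[1:3, "F value"],
      p_value = tab[1:3, "Pr(>F)"]
    )
  })
  if (!nrow(res)) return(tibble::tibble(family = character(), effect = character(),
                                        f_statistic = numeric(), p_value = numeric(),
                                        adjusted_p = numeric()))
  res |>
    dplyr::group_by(.data$effect) |>
    dplyr::mutate(adjusted_p = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(.data$effect, .data$adjusted_p) |>
    dplyr::ungroup()
}
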