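#' Prevalence filter: discard taxa seen in fewer than a fraction of samples
#'
#' Retains taxa whose nonzero-count sample fraction is at least
#' `threshold`; strictly-below is discarded, so a taxon present in exactly
#' `threshold` of the samples is kept. The boundary matters: retained-ASV
#' counts are sensitive to it, and "found in less than 5% of the samples
#' were discarded" pins equality to the retained side.
#'
#' @param table An [abundance_table()].
#' @param threshold Fraction of samples in (0, 1); default 0.05.
#' @return A list: `table` (filtered) and `report` tibble with
#'   `threshold`, `taxa_before`, `taxa_after` and `discarded_ids`
#'   (list-column).
#' @export
prevalence_filter <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  prev <- rowMeans(table$counts > 0)
  keep <- prev >= threshold
  report <- tibble::tibble(
    threshold = threshold,
    taxa_before = nrow(table$counts),
    taxa_after = sum(keep),
    discarded_ids = list(rownames(table$counts)[!keep])
  )
  list(table = subset_table(table, taxa = rownames(table$counts)[keep]),
       report = report)
}

#' Drop singleton taxa
#'
#' Removes taxa whose total count is 1 or that are nonzero in exactly one
#' sample.
#'
#' @param table An [abundance_table()].
#' @return A filtered [abundance_table()].
#' @export
singleton_filter <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- rowSums(table$counts) > 1 & rowSums(table$counts > 0) > 1
  subset_table(table, taxa = rownames(table$counts)[keep])
}

#' Per-sample relative abundances
#'
#' @param table An [abundance_table()] or a taxa x samples matrix.
#' @return A taxa x samples matrix with unit column sums.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "abundance_table") || inherits(table, "stacked_table"))
    table$counts else as.matrix(table)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("zero-sum sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(m, 2, tot, `/`)
}

#' Wisconsin double standardisation
#'
#' Species-maximum then sample-total standardisation of a samples x taxa
#' matrix (each taxon column divided by its maximum, then each sample row
#' by its total), the conventional pre-treatment before Bray-Curtis
#' ordination. Delegates to [vegan::wisconsin()].
#'
#' @param m Non-negative samples x taxa matrix with no all-zero column.
#' @return Matrix of the same shape; rows sum to 1.
#' @export
wisconsin_double_standardize <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("matrix must be non-negative", call. = FALSE)
  if (any(colSums(m) == 0)) stop("all-zero taxon column", call. = FALSE)
  out <- as.matrix(vegan::wisconsin(m))
  matrix(as.numeric(out), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Centered log-ratio transform
#'
#' Per sample: log of (count + pseudocount) over the sample's geometric
#' mean of the same shifted values, so every sample's transformed values
#' sum to zero. Standard input transform for neighborhood-selection
#' network inference on compositions.
#'
#' @param table An [abundance_table()], `stacked_table`, or matrix
#'   (taxa x samples).
#' @param pseudocount Positive value added to counts; default 1.
#' @return A taxa x samples matrix of CLR values.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  m <- if (inherits(table, "abundance_table") || inherits(table, "stacked_table"))
    table$counts else as.matrix(table)
  lg <- log(m + pseudocount)
  sweep(lg, 2, colMeans(lg), `-`)
}

#' Aggregate a taxon subset to family-level relative abundances
#'
#' Restricts the table to `node_subset` (e.g. the taxa retained in a
#' network), sums counts within family labels and renormalises per
#' sample. Missing family labels are grouped under `"unclassified"`.
#'
#' @param table An [abundance_table()] or `stacked_table`.
#' @param node_subset Character vector of taxon ids; must be nonempty.
#' @return A family x sample matrix of relative abundances.
#' @export
aggregate_family <- function(table, node_subset = taxon_ids_of(table)) {
  m <- table$counts
  fam <- table$taxa$family
  fam[is.na(fam)] <- "unclassified"
  if (!length(node_subset)) stop("node_subset must be nonempty", call. = FALSE)
  missing <- setdiff(node_subset, rownames(m))
  if (length(missing)) stop("taxa not in table: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  idx <- match(node_subset, rownames(m))
  agg <- rowsum(m[idx, , drop = FALSE], group = fam[idx])
  tot <- colSums(agg)
  if (any(tot == 0)) {
    stop("zero-sum sample(s) after restriction: ",
         paste(colnames(agg)[tot == 0], collapse = ", "), call. = FALSE)
  }
  sweep(agg, 2, tot, `/`)
}

taxon_ids_of <- function(table) rownames(table$counts)
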