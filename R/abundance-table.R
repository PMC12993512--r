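#' Construct an abundance table
#'
#' An abundance table bundles a non-negative integer count matrix
#' (taxa in rows, samples in columns) with per-taxon annotations and the
#' amplicon marker it came from. It is the substrate every other function
#' in the package consumes.
#'
#' @param counts Non-negative numeric matrix, taxa x samples, with unique
#'   rownames (taxon ids) and colnames (sample ids). Values are coerced to
#'   integer counts.
#' @param taxa Data frame with one row per taxon: columns `taxon_id`,
#'   `domain_label` (one of `"bacteria"`, `"phototroph"`, `"fungus"`,
#'   or `"unknown"`), `lineage` (semicolon-delimited rank string, may be
#'   `NA`) and `family`. Missing columns other than `taxon_id` are filled.
#' @param marker `"16S"` or `"18S"`.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix), `taxa` (tibble) and `marker`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("asv1", "asv2"), c("s1", "s2")))
#' abundance_table(m, marker = "16S")
abundance_table <- function(counts, taxa = NULL, marker = c("16S", "18S")) {
  marker <- match.arg(marker)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry taxon rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("taxon and sample ids must be unique", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  storage.mode(counts) <- "integer"

  if (is.null(taxa)) {
    taxa <- tibble::tibble(taxon_id = rownames(counts))
  }
  taxa <- tibble::as_tibble(taxa)
  if (!"taxon_id" %in% names(taxa)) stop("`taxa` needs a taxon_id column", call. = FALSE)
  for (col in c("domain_label", "lineage", "family")) {
    if (!col %in% names(taxa)) taxa[[col]] <- NA_character_
  }
  taxa$domain_label[is.na(taxa$domain_label)] <-
    if (marker == "16S") "bacteria" else "unknown"
  taxa$family[is.na(taxa$family)] <- "unclassified"
  if (!setequal(taxa$taxon_id, rownames(counts)) ||
      nrow(taxa) != nrow(counts)) {
    stop("`taxa` must annotate exactly the rows of `counts`", call. = FALSE)
  }
  taxa <- taxa[match(rownames(counts), taxa$taxon_id), ]

  bad <- !taxa$domain_label %in% c("bacteria", "phototroph", "fungus", "unknown")
  if (any(bad)) {
    stop("unknown domain_label: ", paste(unique(taxa$domain_label[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (marker == "16S" && any(taxa$domain_label != "bacteria")) {
    stop("16S tables must carry only bacterial taxa", call. = FALSE)
  }
  if (marker == "18S" && any(taxa$domain_label == "bacteria")) {
    stop("18S tables must not carry bacterial taxa", call. = FALSE)
  }

  structure(list(counts = counts, taxa = taxa, marker = marker),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %s: %d taxa x %d samples\n",
              x$marker, nrow(x$counts), ncol(x$counts)))
  tab <- table(x$taxa$domain_label)
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Sample ids of an abundance table
#' @param x An `abundance_table`.
#' @return Character vector of sample ids (column names).
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Taxon ids of an abundance table
#' @param x An `abundance_table`.
#' @return Character vector of taxon ids (row names).
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' Subset an abundance table by taxa and/or samples
#'
#' @param x An `abundance_table`.
#' @param taxa,samples Character vectors of ids to keep (order respected);
#'   `NULL` keeps everything.
#' @return An `abundance_table`.
#' @export
subset_table <- function(x, taxa = NULL, samples = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  if (is.null(taxa)) taxa <- rownames(x$counts)
  if (is.null(samples)) samples <- colnames(x$counts)
  missing_t <- setdiff(taxa, rownames(x$counts))
  missing_s <- setdiff(samples, colnames(x$counts))
  if (length(missing_t)) stop("unknown taxa: ", paste(missing_t, collapse = ", "), call. = FALSE)
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "), call. = FALSE)
  abundance_table(x$counts[taxa, samples, drop = FALSE],
                  x$taxa[match(taxa, x$taxa$taxon_id), ],
                  marker = x$marker)
}

#' Stack a 16S and an 18S table over shared samples
#'
#' Row-binds the two count matrices over the sample columns both tables
#' share (error if the sample sets differ), keeping domain labels. The
#' stacked table is the input to cross-domain network inference.
#'
#' @param t16,t18 `abundance_table`s with marker 16S and 18S.
#' @return A list with class `stacked_table`: `counts`, `taxa`, markers per row.
#' @export
stack_tables <- function(t16, t18) {
  stopifnot(inherits(t16, "abundance_table"), inherits(t18, "abundance_table"))
  if (t16$marker != "16S" || t18$marker != "18S") {
    stop("arguments must be a 16S and an 18S table, in that order", call. = FALSE)
  }
  if (!setequal(sample_ids(t16), sample_ids(t18))) {
    stop("tables must share an identical sample set; run pair_samples() first",
         call. = FALSE)
  }
  shared <- sample_ids(t16)
  dup <- intersect(taxon_ids(t16), taxon_ids(t18))
  if (length(dup)) stop("taxon ids duplicated across markers: ",
                        paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  counts <- rbind(t16$counts[, shared, drop = FALSE],
                  t18$counts[, shared, drop = FALSE])
  taxa <- dplyr::bind_rows(
    dplyr::mutate(t16$taxa, marker = "16S"),
    dplyr::mutate(t18$taxa, marker = "18S")
  )
  structure(list(counts = counts, taxa = taxa), class = "stacked_table")
}

#' @export
print.stacked_table <- function(x, ...) {
  cat(sprintf("<stacked_table> %d taxa (16S+18S) x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
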