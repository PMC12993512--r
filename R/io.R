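#' Read a taxon-by-sample count table with taxonomy annotations
#'
#' Expects a tab-separated matrix whose header row holds sample ids and
#' whose first column holds taxon ids, plus a two-column taxonomy TSV
#' (taxon id, semicolon-delimited lineage). 18S taxa are labeled
#' phototroph/fungus by lineage keywords; 16S taxa matching the archaeal /
#' organellar exclusion list are dropped; taxa missing from the taxonomy
#' are labeled `"unknown"` and reported via a warning, not an error.
#'
#' @param path Path to the count TSV (taxa x samples).
#' @param marker `"16S"` or `"18S"`.
#' @param taxonomy_path Path to the taxonomy TSV.
#' @param keywords Domain keyword list, see [domain_keywords()].
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, marker = c("16S", "18S"),
                                 taxonomy_path = NULL,
                                 keywords = domain_keywords()) {
  marker <- match.arg(marker)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("malformed count table (need a header and at least one taxon row): ", path,
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  body_w <- unique(widths[-1])
  if (length(body_w) != 1) {
    stop("malformed count table (ragged rows): ", path, call. = FALSE)
  }
  header <- fields[[1]]
  samples <- if (widths[1] == body_w) header[-1] else header
  if (length(samples) != body_w - 1) {
    stop("malformed count table (header/body width mismatch): ", path, call. = FALSE)
  }
  taxa_ids <- vapply(fields[-1], `[[`, character(1), 1)
  vals <- t(vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric count in table: ", path, call. = FALSE)
    v
  }, numeric(body_w - 1)))
  if (body_w == 2) vals <- matrix(vals, ncol = 1)
  dimnames(vals) <- list(taxa_ids, samples)

  lineage <- rep(NA_character_, length(taxa_ids))
  if (!is.null(taxonomy_path)) {
    tax <- utils::read.delim(taxonomy_path, header = FALSE, sep = "\t",
                             colClasses = "character")[, 1:2]
    lineage <- tax[[2]][match(taxa_ids, tax[[1]])]
  }
  label <- assign_domain(lineage, marker, keywords)
  n_unknown <- sum(is.na(lineage))
  if (n_unknown > 0 && !is.null(taxonomy_path)) {
    warning(n_unknown, " taxa absent from taxonomy; labeled 'unknown'/'bacteria'",
            call. = FALSE)
  }
  keep <- label != "drop"
  if (marker == "16S" && any(!keep)) {
    message("dropped ", sum(!keep), " non-bacterial 16S taxa (archaea/organellar)")
  }
  taxa <- tibble::tibble(
    taxon_id = taxa_ids[keep],
    domain_label = label[keep],
    lineage = lineage[keep],
    family = lineage_family(lineage[keep])
  )
  abundance_table(round(vals[keep, , drop = FALSE]), taxa, marker = marker)
}

#' Read per-sample metadata
#'
#' A TSV keyed by `sample_id`, with optional categorical columns
#' `floodplain`, `stream_type` (GFS/TRIB), `deglaciation` (pre2000/post2000),
#' a logical `consistent` flag (stream-type categorisation agrees across
#' sampling campaigns) and any number of numeric environmental columns.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
  if (!"sample_id" %in% names(md)) stop("metadata needs a sample_id column", call. = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  checks <- list(stream_type = c("GFS", "TRIB"),
                 deglaciation = c("pre2000", "post2000"))
  for (col in names(checks)) {
    if (col %in% names(md)) {
      bad <- setdiff(unique(stats::na.omit(md[[col]])), checks[[col]])
      if (length(bad)) stop(col, " has levels outside ",
                            paste(checks[[col]], collapse = "/"), ": ",
                            paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(md)
}

#' Restrict paired 16S/18S tables to shared, consistently categorised samples
#'
#' Cross-domain networks need the same samples in both marker tables, and
#' samples whose stream-type categorisation changed between sampling
#' campaigns are excluded as potential confounders. Metadata rows with a
#' logical `consistent` column set to `FALSE` are dropped; absent flag
#' means consistent.
#'
#' @param t16,t18 `abundance_table`s (16S and 18S).
#' @param metadata Optional tibble with `sample_id` and optional `consistent`.
#' @return A list with elements `t16` and `t18`, identical column order.
#' @export
pair_samples <- function(t16, t18, metadata = NULL) {
  stopifnot(inherits(t16, "abundance_table"), inherits(t18, "abundance_table"))
  shared <- intersect(sample_ids(t16), sample_ids(t18))
  if (!is.null(metadata) && "consistent" %in% names(metadata)) {
    inconsistent <- metadata$sample_id[!is.na(metadata$consistent) & !metadata$consistent]
    shared <- setdiff(shared, inconsistent)
  }
  if (length(shared) == 0) {
    stop("no samples shared by both markers after pairing; unmatched 16S: ",
         paste(utils::head(setdiff(sample_ids(t16), sample_ids(t18)), 5), collapse = ", "),
         "; unmatched 18S: ",
         paste(utils::head(setdiff(sample_ids(t18), sample_ids(t16)), 5), collapse = ", "),
         call. = FALSE)
  }
  shared <- sort(shared)
  list(t16 = subset_table(t16, samples = shared),
       t18 = subset_table(t18, samples = shared))
}

## ---- networks ----------------------------------------------------------

#' Construct a co-occurrence network object
#'
#' @param edges Tibble with columns `source`, `target` and optionally
#'   `support_count`, `sparcc_rho`, `spearman_rho`, `mb_selected`,
#'   `consensus_sign`.
#' @param nodes Tibble with `taxon_id` and optional `domain_label`,
#'   `family`, `community` columns; defaults to the taxa present in edges.
#' @return A `cooccurrence_network`: list of `graph` (igraph), `nodes`,
#'   `edges` tibbles.
#' @export
cooccurrence_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    stop("edges need source and target columns", call. = FALSE)
  }
  if (nrow(edges) && any(edges$source == edges$target)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- tibble::tibble(taxon_id = unique(c(edges$source, edges$target)))
  }
  nodes <- tibble::as_tibble(nodes)
  if (!"taxon_id" %in% names(nodes)) stop("nodes need a taxon_id column", call. = FALSE)
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate node ids", call. = FALSE)
  dangling <- setdiff(unique(c(edges$source, edges$target)), nodes$taxon_id)
  if (length(dangling)) {
    stop("edges reference missing nodes: ", paste(dangling, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("domain_label", "family")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (nrow(edges) && anyDuplicated(key(edges$source, edges$target))) {
    stop("multi-edges are not allowed", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges), directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  if (inherits(net, "cooccurrence_network")) return(net$graph)
  stop("expected a cooccurrence_network or igraph object", call. = FALSE)
}

#' Write a network to GraphML or a TSV edge list
#'
#' GraphML carries all node and edge attributes; the edge TSV has one
#' row per edge with the per-method statistics. Both round-trip through
#' [read_network()].
#'
#' @param net A `cooccurrence_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    utils::write.table(as.data.frame(net$edges), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return A `cooccurrence_network`.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
    names(nodes)[names(nodes) == "name"] <- "taxon_id"
    edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
    names(edges)[1:2] <- c("source", "target")
    cooccurrence_network(edges, nodes)
  } else {
    edges <- tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    cooccurrence_network(edges)
  }
}
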