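#' Keyword maps used to assign domain labels from taxonomic lineages
#'
#' 18S lineages are mapped to `fungus` or `phototroph` by matching rank
#' names against editable keyword lists; 16S lineages matching the
#' exclusion list (archaea, organellar reads) are dropped at read time.
#' The lists reflect the taxa named in proglacial-stream biofilm work
#' (chytrids and other parasitic fungi; green algae, diatoms, chrysophytes
#' and allied algal lineages) and can be extended by the user.
#'
#' @return A named list of character vectors: `fungus`, `phototroph`,
#'   `exclude_16S`.
#' @export
domain_keywords <- function() {
  list(
    fungus = c("Fungi", "Chytridiomycota", "Cryptomycota", "Rozellomycota",
               "Zoopagomycota", "Dikarya", "Ascomycota", "Basidiomycota",
               "Mucoromycota", "Aphelidea"),
    phototroph = c("Chlorophyta", "Chlorophyceae", "Charophyta",
                   "Phragmoplastophyta", "Klebsormidiophyceae",
                   "Cryptomonadales", "Cryptophyceae",
                   "Ochrophyta", "Diatomea", "Bacillariophyta",
                   "Chrysophyceae", "Xanthophyceae", "Eustigmatophyceae",
                   "Euglenida", "Dinoflagellata"),
    exclude_16S = c("Archaea", "Chloroplast", "Mitochondria", "Eukaryota")
  )
}

#' Assign a domain label to one lineage string
#'
#' Deterministic keyword lookup: fungal keywords win over phototroph
#' keywords (parasitic fungi are often annotated inside algal host
#' lineages the other way around never happens in SILVA-style strings),
#' anything unmatched is `"unknown"`.
#'
#' @param lineage Character vector of semicolon-delimited lineages.
#' @param marker `"16S"` or `"18S"`.
#' @param keywords Keyword list as from [domain_keywords()].
#' @return Character vector of labels: `bacteria`, `phototroph`, `fungus`,
#'   `unknown`, or `drop` (16S lineages matching the exclusion list).
#' @export
assign_domain <- function(lineage, marker = c("16S", "18S"),
                          keywords = domain_keywords()) {
  marker <- match.arg(marker)
  lineage <- as.character(lineage)
  hit <- function(keys) {
    pat <- paste0("(", paste(keys, collapse = "|"), ")")
    !is.na(lineage) & grepl(pat, lineage, ignore.case = FALSE)
  }
  if (marker == "16S") {
    out <- rep("bacteria", length(lineage))
    out[hit(keywords$exclude_16S)] <- "drop"
    out[is.na(lineage)] <- "bacteria"  # unannotated 16S reads stay bacterial
    return(out)
  }
  out <- rep("unknown", length(lineage))
  out[hit(keywords$phototroph)] <- "phototroph"
  out[hit(keywords$fungus)] <- "fungus"  # fungal match takes precedence
  out
}

#' Extract the family rank from a lineage string
#'
#' Uses the 5th semicolon-delimited rank (Kingdom;Phylum;Class;Order;Family;
#' Genus;Species convention); strips common rank prefixes; anything absent
#' or unparseable becomes `"unclassified"`.
#'
#' @param lineage Character vector of lineages.
#' @return Character vector of family names.
#' @export
lineage_family <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  fam <- vapply(parts, function(p) {
    if (length(p) < 5) return(NA_character_)
    f <- trimws(p[[5]])
    f <- sub("^[a-z]__", "", f)
    if (!nzchar(f)) NA_character_ else f
  }, character(1))
  fam[is.na(fam)] <- "unclassified"
  fam
}
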