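test_that("count tables round-trip through TSV with taxonomy-based labels", {
  counts <- matrix(c(5L, 0L, 2L, 1L, 3L, 8L), 3, 2,
                   dimnames = list(c("asv1", "asv2", "asv3"), c("s1", "s2")))
  tsv <- write_counts_tsv(counts, tempfile(fileext = ".tsv"))
  taxpath <- tempfile(fileext = ".tsv")
  writeLines(c("asv1\tBacteria;Proteobacteria;Gamma;Burkholderiales;Comamonadaceae;Genus1",
               "asv2\tBacteria;Bacteroidota;Bacteroidia;Ord;Fam2;G",
               "asv3\tBacteria;Cyanobacteria;Cyano;Ord;Fam3;G"), taxpath)
  tab <- read_abundance_table(tsv, "16S", taxpath)
  expect_equal(dim(tab), c(3L, 2L))
  expect_identical(unname(tab$counts), unname(counts))
  expect_true(all(tab$taxa$domain_label == "bacteria"))
  expect_equal(tab$taxa$family[1], "Comamonadaceae")
})

test_that("18S lineages map to fungus/phototroph and 16S exclusions are dropped", {
  counts <- matrix(c(4L, 2L, 9L, 1L, 7L, 3L), 3, 2,
                   dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  tsv <- write_counts_tsv(counts, tempfile(fileext = ".tsv"))
  taxpath <- tempfile(fileext = ".tsv")
  writeLines(c("otu1\tEukaryota;Fungi;Chytridiomycota;Ord;Fam;G",
               "otu2\tEukaryota;Archaeplastida;Chlorophyta;Chlorophyceae;Fam;G",
               "otu3\tEukaryota;Amorphea;SomeClade;Ord;Fam;G"), taxpath)
  tab <- read_abundance_table(tsv, "18S", taxpath)
  expect_equal(tab$taxa$domain_label, c("fungus", "phototroph", "unknown"))

  tax16 <- tempfile(fileext = ".tsv")
  writeLines(c("otu1\tBacteria;Proteobacteria;G;O;F;G",
               "otu2\tArchaea;Crenarchaeota;G;O;F;G",
               "otu3\tBacteria;Cyanobacteria;Chloroplast;O;F;G"), tax16)
  expect_message(t16 <- read_abundance_table(tsv, "16S", tax16), "dropped 2")
  expect_equal(taxon_ids(t16), "otu1")
})

test_that("malformed and degenerate count files are rejected", {
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(read_abundance_table(empty, "16S"), "malformed")
  ragged <- tempfile()
  writeLines(c("s1\ts2", "t1\t1\t2", "t2\t3"), ragged)
  expect_error(read_abundance_table(ragged, "16S"), "ragged")
})

test_that("taxa missing from the taxonomy are labeled, not fatal", {
  counts <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  tsv <- write_counts_tsv(counts, tempfile(fileext = ".tsv"))
  taxpath <- tempfile()
  writeLines("a\tEukaryota;Fungi;Ascomycota;O;F;G", taxpath)
  expect_warning(tab <- read_abundance_table(tsv, "18S", taxpath), "absent")
  expect_equal(tab$taxa$domain_label, c("fungus", "unknown"))
})

test_that("domain labeling is a deterministic function of the lineage string", {
  lin <- c("Eukaryota;Fungi;Chytridiomycota;O;F;G",
           "Eukaryota;Ochrophyta;Diatomea;O;F;G")
  expect_identical(assign_domain(lin, "18S"), assign_domain(lin, "18S"))
  expect_identical(assign_domain(rep(lin[1], 5), "18S"), rep("fungus", 5))
})

test_that("sample pairing intersects markers and honours the consistency flag", {
  c16 <- matrix(1L, 2, 3, dimnames = list(c("b1", "b2"), c("A", "B", "C")))
  c18 <- matrix(1L, 2, 3, dimnames = list(c("p1", "p2"), c("B", "C", "D")))
  t16 <- toy_table(c16, "16S")
  t18 <- toy_table(c18, "18S")
  paired <- pair_samples(t16, t18)
  expect_equal(sample_ids(paired$t16), c("B", "C"))
  expect_identical(sample_ids(paired$t16), sample_ids(paired$t18))

  md <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                       consistent = c(TRUE, FALSE, TRUE, TRUE))
  paired2 <- pair_samples(t16, t18, md)
  expect_equal(sample_ids(paired2$t16), "C")

  c18d <- matrix(1L, 2, 2, dimnames = list(c("p1", "p2"), c("X", "Y")))
  expect_error(pair_samples(t16, toy_table(c18d, "18S")), "no samples shared")
})

test_that("networks round-trip through GraphML and edge TSV", {
  edges <- tibble::tibble(source = c("a", "b", "c"),
                          target = c("b", "c", "a"),
                          support_count = c(3L, 2L, 2L),
                          sparcc_rho = c(0.5, 0.4, 0.31),
                          spearman_rho = c(0.6, 0.55, 0.52),
                          mb_selected = c(TRUE, FALSE, TRUE),
                          consensus_sign = 1L)
  nodes <- tibble::tibble(taxon_id = c("a", "b", "c"),
                          domain_label = c("bacteria", "phototroph", "fungus"),
                          family = c("F1", "F2", "F3"))
  net <- cooccurrence_network(edges, nodes)
  for (fmt in c("graphml", "edge_tsv")) {
    path <- tempfile()
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    key <- function(e) sort(paste(pmin(e$source, e$target), pmax(e$source, e$target)))
    expect_identical(key(back$edges), key(net$edges))
    expect_equal(sort(back$nodes$taxon_id)[1:3], c("a", "b", "c"))
    # per-edge attributes survive, keyed by the unordered endpoint pair
    bk <- paste(pmin(back$edges$source, back$edges$target),
                pmax(back$edges$source, back$edges$target))
    ok <- paste(pmin(edges$source, edges$target),
                pmax(edges$source, edges$target))
    expect_equal(back$edges$sparcc_rho[match(ok, bk)], edges$sparcc_rho)
  }
  # GraphML keeps node attributes
  p <- tempfile(); write_network(net, p, "graphml")
  back <- read_network(p, "graphml")
  expect_equal(back$nodes$domain_label[match("c", back$nodes$taxon_id)], "fungus")
})

test_that("degenerate networks are validated before write", {
  empty <- cooccurrence_network(tibble::tibble(source = character(),
                                               target = character()),
                                tibble::tibble(taxon_id = c("a", "b")))
  p <- tempfile()
  write_network(empty, p, "graphml")
  expect_equal(nrow(read_network(p, "graphml")$edges), 0)

  expect_error(cooccurrence_network(
    tibble::tibble(source = "a", target = "ghost"),
    tibble::tibble(taxon_id = "a")), "missing nodes")
  expect_error(cooccurrence_network(tibble::tibble(source = "a", target = "a")),
               "self-loops")
  expect_error(cooccurrence_network(
    tibble::tibble(source = c("a", "b"), target = c("b", "a"))), "multi-edges")
})

test_that("abundance table invariants are enforced", {
  m <- matrix(1L, 2, 2, dimnames = list(c("x", "y"), c("s1", "s2")))
  expect_error(abundance_table(m - 2L), "non-negative")
  bad <- m; rownames(bad) <- c("x", "x")
  expect_error(abundance_table(bad), "unique")
  t18 <- toy_table(m, "18S", domains = c("phototroph", "fungus"))
  expect_error(stack_tables(t18, t18), "16S and an 18S")
  t16 <- toy_table(m, "16S")
  m2 <- m; colnames(m2) <- c("s1", "s3")
  expect_error(stack_tables(t16, toy_table(m2, "18S", domains = "fungus")),
               "identical sample set")
})
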