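#' Pipeline configuration
#'
#' Bundles every stage option: the synthetic-data configuration (or input
#' file paths), the prevalence threshold, the ensemble configuration,
#' graph-analysis options, ordination options and the root seed. All
#' randomness in a run flows from `seed`, split deterministically per
#' stage and stratum.
#'
#' @param sim A [sim_config()] (used when no input paths are given).
#' @param paths Optional named list with `counts_16S`, `counts_18S`,
#'   `taxonomy_16S`, `taxonomy_18S`, `metadata` to run on files instead.
#' @param prevalence Prevalence-filter threshold; default 0.05.
#' @param drop_singletons Apply the singleton filter; default TRUE.
#' @param ensemble An [ensemble_config()].
#' @param min_cluster_size Louvain pruning size; default 5.
#' @param k_keystones Keystones per network; default 10.
#' @param recompute_keystones Re-rank during removal; default FALSE.
#' @param original_n_fragmentation Use the original node count as the f
#'   denominator; default FALSE.
#' @param alpha,n_perm Forward-selection settings; defaults 0.01, 199.
#' @param min_samples_per_stratum Strata below this sample floor are
#'   skipped with a logged reason; default 10.
#' @param seed Root integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            prevalence = 0.05, drop_singletons = TRUE,
                            ensemble = ensemble_config(),
                            min_cluster_size = 5, k_keystones = 10,
                            recompute_keystones = FALSE,
                            original_n_fragmentation = FALSE,
                            alpha = 0.01, n_perm = 199,
                            min_samples_per_stratum = 10, seed = 1L) {
  structure(list(sim = sim, paths = paths, prevalence = prevalence,
                 drop_singletons = drop_singletons, ensemble = ensemble,
                 min_cluster_size = min_cluster_size,
                 k_keystones = k_keystones,
                 recompute_keystones = recompute_keystones,
                 original_n_fragmentation = original_n_fragmentation,
                 alpha = alpha, n_perm = n_perm,
                 min_samples_per_stratum = min_samples_per_stratum,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) paired 16S/18S tables, then per stratum
#' (floodplain x stream type x deglaciation class): filter, infer the
#' consensus network, detect communities, compute topology, select
#' keystones and trace fragmentation under their removal; finally run the
#' keystone-versus-environment variance partitioning per floodplain.
#' Writes one GraphML plus keystone/trajectory/topology tables per
#' stratum into `out_dir` and returns a manifest. Identical config and
#' seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed.
#' @return A list of class `pipeline_manifest`: `config_hash`, `seed`,
#'   `strata` tibble (per-stratum status and metrics), `ordination`
#'   tibble, `outputs` (file paths), `versions`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (is.null(config$paths)) {
    cfg <- config$sim
    cfg$seed <- config$seed
    net <- plant_network(cfg)
    sim <- simulate_counts(net, cfg)
    t16 <- sim$t16; t18 <- sim$t18; metadata <- sim$metadata
  } else {
    p <- config$paths
    t16 <- read_abundance_table(p$counts_16S, "16S", p$taxonomy_16S)
    t18 <- read_abundance_table(p$counts_18S, "18S", p$taxonomy_18S)
    metadata <- read_sample_metadata(p$metadata)
  }
  for (col in c("floodplain", "stream_type", "deglaciation")) {
    if (!col %in% names(metadata)) {
      stop("metadata lacks required column: ", col, call. = FALSE)
    }
  }
  paired <- pair_samples(t16, t18, metadata)
  metadata <- metadata[metadata$sample_id %in% sample_ids(paired$t16), ]

  strata <- metadata |>
    dplyr::distinct(.data$floodplain, .data$stream_type, .data$deglaciation) |>
    dplyr::arrange(.data$floodplain, .data$stream_type, .data$deglaciation)

  outputs <- character()
  rows <- vector("list", nrow(strata))
  networks <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    label <- paste(st$floodplain, st$stream_type, st$deglaciation, sep = "_")
    sids <- metadata$sample_id[
      metadata$floodplain == st$floodplain &
      metadata$stream_type == st$stream_type &
      metadata$deglaciation == st$deglaciation]
    row <- tibble::tibble(stratum = label, n_samples = length(sids),
                          status = "ok", n_nodes = NA_integer_,
                          n_edges = NA_integer_, f_baseline = NA_real_,
                          f_mean = NA_real_, modularity = NA_real_,
                          n_clusters = NA_integer_, reason = NA_character_)
    if (length(sids) < config$min_samples_per_stratum) {
      row$status <- "skipped"
      row$reason <- sprintf("only %d samples (< %d)", length(sids),
                            config$min_samples_per_stratum)
      rows[[i]] <- row
      next
    }
    res <- tryCatch({
      s16 <- subset_table(paired$t16, samples = sids)
      s18 <- subset_table(paired$t18, samples = sids)
      if (config$drop_singletons) {
        s16 <- singleton_filter(s16); s18 <- singleton_filter(s18)
      }
      s16 <- prevalence_filter(s16, config$prevalence)$table
      s18 <- prevalence_filter(s18, config$prevalence)$table
      stacked <- stack_tables(s16, s18)
      ecfg <- config$ensemble
      ecfg$seed <- (config$seed + 101L * i) %% .Machine$integer.max
      network <- infer_network(stacked, ecfg)
      if (nrow(network$nodes) == 0) {
        row$status <- "empty"
        row$reason <- "no consensus edges survived"
        row$n_nodes <- 0L; row$n_edges <- 0L
        rows[[i]] <- row
        next
      }
      part <- louvain_communities(network, min_size = config$min_cluster_size,
                                  seed = ecfg$seed)
      topo <- topology(network, part)
      keys <- select_keystones(centrality(network),
                               k = min(config$k_keystones, nrow(network$nodes)),
                               tables = list(s16, s18))
      traj <- removal_trajectory(network, keys,
                                 recompute = config$recompute_keystones,
                                 original_n = config$original_n_fragmentation,
                                 seed = ecfg$seed)
      gml <- file.path(out_dir, paste0(label, "_network.graphml"))
      write_network(network, gml, "graphml")
      ktsv <- file.path(out_dir, paste0(label, "_keystones.tsv"))
      utils::write.table(as.data.frame(keys), ktsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ttsv <- file.path(out_dir, paste0(label, "_trajectory.tsv"))
      utils::write.table(as.data.frame(traj$steps), ttsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tjson <- file.path(out_dir, paste0(label, "_topology.json"))
      jsonlite::write_json(c(as.list(topo), seed = ecfg$seed), tjson,
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, gml, ktsv, ttsv, tjson)
      row$n_nodes <- topo$n_nodes; row$n_edges <- topo$n_edges
      row$f_baseline <- traj$baseline_f; row$f_mean <- traj$f_mean
      row$modularity <- topo$modularity; row$n_clusters <- topo$n_clusters
      networks[[i]] <- list(network = network, keystones = keys,
                            t16 = s16, t18 = s18, samples = sids)
      row
    }, error = function(e) {
      row$status <- "failed"; row$reason <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  strata_tbl <- dplyr::bind_rows(rows)

  # keystone-vs-environment variance partitioning, per floodplain
  ord_rows <- list()
  env_cols <- intersect(c("temperature", "conductivity", "doc", "gradient",
                          "pH", "turbidity", "dissolved_oxygen"),
                        names(metadata))
  for (fp in unique(strata$floodplain)) {
    idx <- which(strata$floodplain == fp & strata_tbl$status == "ok")
    if (!length(idx)) next
    nets <- networks[idx]
    k16 <- unique(unlist(lapply(nets, function(x)
      intersect(x$keystones$taxon_id, taxon_ids(x$t16)))))
    k18 <- unique(unlist(lapply(nets, function(x)
      intersect(x$keystones$taxon_id, taxon_ids(x$t18)))))
    sids <- unique(unlist(lapply(nets, `[[`, "samples")))
    if (!length(k16) || !length(k18) || length(sids) < 10) next
    b <- subset_table(paired$t16, samples = sort(sids))
    e <- subset_table(paired$t18, samples = sort(sids))
    b <- subset_table(b, taxa = taxon_ids(b)[rowSums(b$counts) > 0])
    e <- subset_table(e, taxa = taxon_ids(e)[rowSums(e$counts) > 0])
    k16 <- intersect(k16, taxon_ids(b)); k18 <- intersect(k18, taxon_ids(e))
    if (!length(k16) || !length(k18)) next
    env <- as.data.frame(metadata[match(sort(sids), metadata$sample_id),
                                  env_cols, drop = FALSE])
    kv <- tryCatch(
      keystone_vs_environment(b, k16, k18, e, env, alpha = config$alpha,
                              n_perm = config$n_perm,
                              seed = (config$seed + 7L) %% .Machine$integer.max),
      error = function(e) NULL)
    if (!is.null(kv)) {
      ord_rows[[fp]] <- dplyr::mutate(kv$summary, floodplain = fp,
                                      .before = 1)
    }
  }
  ordination <- dplyr::bind_rows(ord_rows)
  if (nrow(ordination)) {
    otsv <- file.path(out_dir, "ordination.tsv")
    utils::write.table(as.data.frame(ordination), otsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, otsv)
  }

  manifest <- structure(list(
    config_hash = config_hash(config),
    seed = config$seed,
    strata = strata_tbl,
    ordination = ordination,
    outputs = outputs,
    versions = list(package = as.character(utils::packageVersion("biofilmnet")),
                    r = as.character(getRversion()))
  ), class = "pipeline_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         strata = strata_tbl, outputs = basename(outputs),
         versions = manifest$versions),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> seed %d, %d strata (%d ok)\n",
              x$seed, nrow(x$strata), sum(x$strata$status == "ok")))
  print(x$strata[, c("stratum", "n_samples", "status", "n_nodes", "n_edges",
                     "f_baseline", "f_mean")])
  invisible(x)
}
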