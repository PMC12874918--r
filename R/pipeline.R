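# deterministic per-stage seed derived from the root seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + h * 1009L) %% 2147483647L
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the whole synthetic-study pipeline
#'
#' Executes every stage on the default synthetic scenario: tree simulation
#' and phylotyping; community simulation, soil reclassification, filtering
#' and rarefaction; core-phylotype and consensus niche-specificity
#' identification; cross-niche comparison; fruitbody co-occurrence network
#' with Markov clustering; and Phenotype MicroArray scoring. All outputs
#' are written as TSV under `out_dir` together with a machine-readable
#' manifest (parameters, seeds, per-file MD5 checksums). Identical seeds
#' give identical manifests.
#'
#' @param out_dir output directory (created if missing).
#' @param seed root seed; every stage derives its own seed from it.
#' @param config community scenario configuration (see [community_config()]).
#' @param n_perm,n_boot permutation/bootstrap counts (default 1000).
#' @return (invisibly) the manifest list.
#' @export
run_all <- function(out_dir, seed = 42,
                    config = community_config(unknown_frac = 0.25),
                    n_perm = 1000, n_boot = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  manifest <- list(seed = seed, config = config,
                   n_perm = n_perm, n_boot = n_boot, stages = list())

  # --- phylotyping on the synthetic tree scenario
  ts <- make_tree_scenario(seed = derive_seed(seed, "trees"))
  ps <- phylotype_tree(ts$trees, ts$records)
  merged <- merge(ps$membership, ts$truth, by = "tip_id")
  q <- merged[merged$kind == "query" & !merged$is_outlier, ]
  recovery <- mean(q$phylotype_id == q$species)
  files <- c(files,
             .write_tsv(ps$phylotypes[, setdiff(names(ps$phylotypes), "tips")],
                        file.path(out_dir, "phylotypes.tsv")),
             .write_tsv(ps$membership, file.path(out_dir, "membership.tsv")))
  manifest$stages$phylotyping <- list(
    n_phylotypes = nrow(ps$phylotypes), query_species_recovery = recovery)

  # --- community simulation + reclassification
  cs <- make_community_scenario(config, seed = derive_seed(seed, "community"),
                                kingdoms = c("fungi", "bacteria"))
  fungi <- reclassify_soil(cs$fungi)
  bact <- inherit_soil_type(cs$bacteria, fungi)
  truth_niche <- cs$truth$true_niche
  recl <- attr(fungi, "reclassified")
  recl_acc <- if (length(recl)) mean(recl == truth_niche[names(recl)]) else NA_real_
  files <- c(files, .write_tsv(fungi$metadata, file.path(out_dir, "metadata_fungi.tsv")),
             .write_tsv(bact$metadata, file.path(out_dir, "metadata_bacteria.tsv")))
  manifest$stages$reclassification <- list(
    n_reclassified = length(recl), accuracy_vs_truth = recl_acc)

  # --- core phylotypes (non-rarefied table)
  core <- find_core(fungi)
  files <- c(files, .write_tsv(core, file.path(out_dir, "core_report.tsv")))
  truth_core <- cs$truth$expected_core
  called <- core$phylotype_id[core$is_core]
  manifest$stages$core <- list(
    n_core = length(called),
    recall = mean(truth_core %in% called),
    precision = if (length(called)) mean(called %in% truth_core) else NA_real_)

  # --- niche specificity (rarefied, prefiltered)
  rar <- filter_and_rarefy(fungi, min_reads = 100,
                           seed = derive_seed(seed, "rarefy"))
  pre <- suppressMessages(prefilter(rar))
  spec <- niche_specificity(pre, n_boot = n_boot, n_perm = n_perm,
                            seed = derive_seed(seed, "niche"))
  cons <- consensus_calls(spec)
  files <- c(files, .write_tsv(spec, file.path(out_dir, "specificity.tsv")),
             .write_tsv(cons, file.path(out_dir, "consensus.tsv")))
  planted <- cs$truth$specific$phylotype_id[cs$truth$specific$target_niche == "S-soil"]
  called_s <- cons$phylotype_id[cons$s_soil_specific]
  nulls <- intersect(cs$truth$null_ids, cons$phylotype_id)
  manifest$stages$consensus <- list(
    sensitivity = mean(planted %in% called_s),
    false_positive_rate = if (length(nulls)) mean(nulls %in% called_s) else NA_real_)

  # --- cross-niche comparison (fungi: LDA >= 3.5)
  cn <- cross_niche_lefse(pre, lda_min = 3.5, n_boot = n_boot,
                          seed = derive_seed(seed, "crossniche"))
  files <- c(files, .write_tsv(cn, file.path(out_dir, "cross_niche.tsv")))
  manifest$stages$cross_niche <- list(n_significant = sum(cn$significant))

  # --- fruitbody co-occurrence network + MCL
  fb <- pre$metadata$sample_id[pre$metadata$niche == "S-fruitbody"]
  rel_fb <- relative_abundance(pre)[fb, , drop = FALSE]
  net <- build_network(rel_fb, tm_id = pre$tm_id)
  cl <- mcl(net)
  grp <- group_by_tm(net, cl)
  files <- c(files, .write_tsv(net$edges, file.path(out_dir, "network_edges.tsv")),
             .write_tsv(grp$nodes, file.path(out_dir, "network_nodes.tsv")))
  manifest$stages$network <- list(
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    n_clusters = cl$n_clusters)

  # --- Phenotype MicroArray scoring
  pmsc <- make_pm_scenario(seed = derive_seed(seed, "pm"), noise_sd = 0.01)
  av <- pm_pipeline(pmsc$pm)
  files <- c(files, .write_tsv(av, file.path(out_dir, "pm_activity.tsv")))
  truth_lvl <- pmsc$truth[av$well]
  ok <- truth_lvl > 0
  manifest$stages$pm <- list(
    av_level_agreement = mean(av$av[ok] == truth_lvl[ok]))

  manifest$checksums <- as.list(tools::md5sum(sort(files)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
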