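# Beta shape parameters from a mean and standard deviation
.beta_shapes <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) stop("infeasible Beta mean/sd")
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Synthetic reference-anchored subtrees with planted species
#'
#' Builds pure-birth-shaped subtrees in which each species is a small clade
#' of database tips (carrying a consistent 7-rank taxonomy) and query tips,
#' rescaled so same-species tip pairs sit below the clustering threshold and
#' different-species pairs far above it. Designated outlier query tips get
#' pendant edges an order of magnitude above the median branch length.
#'
#' @param seed RNG seed.
#' @param n_subtrees number of subtrees (default 3).
#' @param n_species species per subtree (default 8).
#' @param db_per_species,q_per_species database / query tips per species.
#' @param within_species_distance maximum same-species tip distance
#'   (default 0.01, below the 0.02 clustering threshold).
#' @param between_species_distance minimum different-species distance
#'   (default 0.2).
#' @param n_outliers long-branch query tips per subtree (default 2).
#' @param outlier_length pendant edge length for outliers (default 2.0).
#' @return list with `trees` (list of `phylo`), `records` (tip records),
#'   `truth` (data.frame: `tip_id`, `subtree`, `species` intended binomial,
#'   `kind`, `is_outlier`).
#' @export
make_tree_scenario <- function(seed = 42, n_subtrees = 3, n_species = 8,
                               db_per_species = 2, q_per_species = 2,
                               within_species_distance = 0.01,
                               between_species_distance = 0.2,
                               n_outliers = 2, outlier_length = 2.0) {
  if (within_species_distance >= 0.02)
    warning("within-species distance at or above the default clustering threshold")
  if (between_species_distance <= within_species_distance)
    stop("infeasible distance constraints")
  set.seed(seed)
  w <- within_species_distance / 2
  trees <- list()
  recs <- list()
  truth <- list()
  for (x in seq_len(n_subtrees)) {
    n_bb <- n_species + n_outliers
    bb <- ape::rtree(n_bb, rooted = TRUE,
                     tip.label = sprintf("BB%03d", seq_len(n_bb)))
    bb$edge.length <- rep(between_species_distance / 2, nrow(bb$edge))
    txt <- write_newick(bb)
    for (k in seq_len(n_species)) {
      genus <- sprintf("Genus%d_%d", x, k)
      species <- sprintf("%s sym%d", genus, k)
      lineage <- sprintf(
        "d__Fungi;p__Phylum%d;c__Class%d;o__Order%d;f__Family%d_%d;g__%s;s__%s",
        x, x, x, x, ceiling(k / 2), genus, species)
      db <- sprintf("db_%d_%d_%d", x, k, seq_len(db_per_species))
      qs <- sprintf("q_%d_%d_%d", x, k, seq_len(q_per_species))
      clade <- paste0("(", paste(sprintf("%s:%.10g", c(db, qs), w), collapse = ","), ")")
      txt <- sub(sprintf("BB%03d:", k), paste0(clade, ":"), txt, fixed = TRUE)
      recs[[length(recs) + 1L]] <- data.frame(
        tip_id = c(db, qs), kind = rep(c("database", "query"),
                                       c(db_per_species, q_per_species)),
        lineage = rep(c(lineage, ""), c(db_per_species, q_per_species)),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        tip_id = c(db, qs), subtree = x, species = species,
        kind = rep(c("database", "query"), c(db_per_species, q_per_species)),
        is_outlier = FALSE, stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_outliers)) {
      out_id <- sprintf("qout_%d_%d", x, j)
      txt <- sub(sprintf("BB%03d:%.10g", n_species + j, between_species_distance / 2),
                 sprintf("%s:%.10g", out_id, outlier_length), txt, fixed = TRUE)
      recs[[length(recs) + 1L]] <- data.frame(
        tip_id = out_id, kind = "query", lineage = "", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        tip_id = out_id, subtree = x, species = NA_character_, kind = "query",
        is_outlier = TRUE, stringsAsFactors = FALSE)
    }
    trees[[x]] <- read_newick(txt)
  }
  recs <- do.call(rbind, recs)
  list(trees = trees,
       records = tip_records(recs$tip_id, recs$kind, recs$lineage),
       truth = do.call(rbind, truth))
}

#' Default multi-study community scenario configuration
#'
#' The defaults emulate the structure of the real cross-study survey: four
#' studies over three geographic regions, ten samples per niche per study,
#' 300 phylotypes at 20,000 reads per sample with Dirichlet-multinomial
#' noise (concentration 50). The TM phylotype's relative abundance is drawn
#' per niche from Beta distributions matching the observed S-soil
#' (62.1% +/- 19.7%) and NS-soil (2.0% +/- 4.7%) moments. Planted core
#' phylotypes hold a flat expected proportion in every niche/region;
#' planted niche-specific phylotypes carry a multiplicative fold-change
#' (default log2FC = 2) of their expected relative abundance in the target
#' niche. Remaining ("background") phylotypes are endemic to a single study,
#' reflecting cross-study taxonomic turnover.
#'
#' @param ... overrides for any default field.
#' @return named list of scenario parameters.
#' @export
community_config <- function(...) {
  cfg <- list(
    n_studies = 4,
    regions = c("Finland", "Southwest China", "South Korea"),
    niches = c("S-soil", "NS-soil", "S-root", "S-fruitbody"),
    n_per_niche = 10,
    n_phylotypes = 300,
    reads_per_sample = 20000,
    dirichlet_conc = 50,
    tm_id = "Tricholoma matsutake",
    tm_mean = c("S-soil" = 0.62, "NS-soil" = 0.02,
                "S-root" = 0.45, "S-fruitbody" = 0.85),
    tm_sd = c("S-soil" = 0.197, "NS-soil" = 0.047,
              "S-root" = 0.15, "S-fruitbody" = 0.08),
    n_core = 6, core_abund = 0.008,
    n_specific = 3, specific_base = 0.015, specific_log2fc = 2,
    n_root_specific = 2, n_fruit_specific = 2,
    other_specific_base = 0.004, other_specific_log2fc = 3,
    unknown_frac = 0,
    min_background = 0.01
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Synthetic multi-study community tables with ground truth
#'
#' Generates per-sample expected proportions (TM Beta draw, planted core
#' and niche-specific effects, study-endemic background), then adds
#' Dirichlet noise at the configured concentration and draws multinomial
#' counts. Optionally withholds the soil labels of a fraction of soil
#' samples (`unknown-soil`) and emits a paired bacterial table without TM.
#'
#' @param config list from [community_config()].
#' @param seed RNG seed.
#' @param kingdoms `"fungi"` (default) or `c("fungi", "bacteria")`.
#' @return list with `fungi` (a `community_table`), optional `bacteria`,
#'   and `truth` (ground-truth ledger: planted ids, expected core set,
#'   true niches of withheld samples).
#' @export
make_community_scenario <- function(config = community_config(), seed = 42,
                                    kingdoms = "fungi") {
  set.seed(seed)
  cfg <- config
  studies <- sprintf("ST%02d", seq_len(cfg$n_studies))
  region_of <- stats::setNames(
    rep(cfg$regions, length.out = cfg$n_studies), studies)

  ids_core <- sprintf("core_pt_%d", seq_len(cfg$n_core))
  ids_spec <- sprintf("ssoil_pt_%d", seq_len(cfg$n_specific))
  ids_root <- if (cfg$n_root_specific > 0)
    sprintf("root_pt_%d", seq_len(cfg$n_root_specific)) else character(0)
  ids_fruit <- if (cfg$n_fruit_specific > 0)
    sprintf("fruit_pt_%d", seq_len(cfg$n_fruit_specific)) else character(0)
  n_bg <- cfg$n_phylotypes - 1 - length(ids_core) - length(ids_spec) -
    length(ids_root) - length(ids_fruit)
  if (n_bg < cfg$n_studies) stop("too few phylotypes for the planted design")
  ids_bg <- sprintf("bg_pt_%d", seq_len(n_bg))
  all_ids <- c(cfg$tm_id, ids_core, ids_spec, ids_root, ids_fruit, ids_bg)

  bg_study <- stats::setNames(rep(studies, length.out = n_bg), ids_bg)
  bg_weight <- stats::setNames(stats::runif(n_bg, 0.7, 1.3), ids_bg)

  specific_tab <- data.frame(
    phylotype_id = c(ids_spec, ids_root, ids_fruit),
    target_niche = c(rep("S-soil", length(ids_spec)),
                     rep("S-root", length(ids_root)),
                     rep("S-fruitbody", length(ids_fruit))),
    base = c(rep(cfg$specific_base, length(ids_spec)),
             rep(cfg$other_specific_base, length(ids_root) + length(ids_fruit))),
    log2fc = c(rep(cfg$specific_log2fc, length(ids_spec)),
               rep(cfg$other_specific_log2fc,
                   length(ids_root) + length(ids_fruit))),
    stringsAsFactors = FALSE)

  shapes <- lapply(cfg$niches, function(nc)
    .beta_shapes(cfg$tm_mean[[nc]], cfg$tm_sd[[nc]]))
  names(shapes) <- cfg$niches

  gen_kingdom <- function(kingdom) {
    has_tm <- kingdom == "fungi"
    rows <- list()
    meta <- list()
    for (s in studies) {
      bg_ids_s <- ids_bg[bg_study == s]
      w_s <- bg_weight[bg_ids_s] / sum(bg_weight[bg_ids_s])
      for (nc in cfg$niches) {
        for (i in seq_len(cfg$n_per_niche)) {
          sid <- sprintf("%s_%s_%s_%02d", substr(kingdom, 1, 1), s, nc, i)
          tm <- if (has_tm) stats::rbeta(1, shapes[[nc]][1], shapes[[nc]][2]) else 0
          # fruitbody-specific phylotypes track the TM mycelium they grow on:
          # their share of the non-TM remainder scales with the TM odds, so
          # after closure their relative abundance still rises with TM
          tm_track <- if (has_tm && nc == "S-fruitbody") {
            m <- cfg$tm_mean[[nc]]
            fac <- min(10, (tm / (1 - tm + 1e-9)) / (m / (1 - m)))
            ifelse(specific_tab$target_niche == "S-fruitbody", fac, 1)
          } else 1
          planted <- c(
            stats::setNames(rep(cfg$core_abund, length(ids_core)), ids_core),
            stats::setNames(
              specific_tab$base *
                ifelse(specific_tab$target_niche == nc,
                       2^specific_tab$log2fc, 1) * tm_track,
              specific_tab$phylotype_id))
          avail <- 1 - tm
          if (sum(planted) > avail - cfg$min_background) {
            planted <- planted * (avail - cfg$min_background) / sum(planted)
          }
          leftover <- avail - sum(planted)
          p <- stats::setNames(numeric(length(all_ids)), all_ids)
          p[cfg$tm_id] <- tm
          p[names(planted)] <- planted
          p[bg_ids_s] <- leftover * w_s
          pos <- p > 0
          g <- stats::rgamma(sum(pos), shape = cfg$dirichlet_conc * p[pos])
          props <- numeric(length(p))
          props[pos] <- g / sum(g)
          if (sum(g) == 0) stop("internal error: degenerate Dirichlet draw")
          cnt <- stats::rmultinom(1, cfg$reads_per_sample, props)[, 1]
          rows[[sid]] <- cnt
          meta[[sid]] <- data.frame(
            sample_id = sid, study_id = s, region = region_of[[s]],
            niche = nc, host = NA_character_, kingdom = kingdom,
            stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- all_ids
    list(counts = counts, metadata = do.call(rbind, meta))
  }

  fungi <- gen_kingdom("fungi")
  meta_f <- fungi$metadata
  meta_f$paired_sample_id <- NA_character_

  true_niche <- stats::setNames(meta_f$niche, meta_f$sample_id)
  if (cfg$unknown_frac > 0) {
    soil <- meta_f$sample_id[meta_f$niche %in% c("S-soil", "NS-soil")]
    hide <- sample(soil, size = round(cfg$unknown_frac * length(soil)))
    meta_f$niche[meta_f$sample_id %in% hide] <- "unknown-soil"
  }
  fungi_tab <- community_table(fungi$counts, meta_f, cfg$tm_id)

  out <- list(fungi = fungi_tab)
  if ("bacteria" %in% kingdoms) {
    bact <- gen_kingdom("bacteria")
    meta_b <- bact$metadata
    meta_b$paired_sample_id <- sub("^b_", "f_", meta_b$sample_id)
    meta_b$niche <- meta_f$niche[match(meta_b$paired_sample_id, meta_f$sample_id)]
    counts_b <- bact$counts[, setdiff(all_ids, cfg$tm_id)]
    colnames(counts_b) <- paste0("b_", colnames(counts_b))
    rownames(counts_b) <- meta_b$sample_id
    out$bacteria <- community_table(counts_b, meta_b, NULL)
  }

  expected_ssoil_mean <- c(
    stats::setNames(rep(cfg$core_abund, length(ids_core)), ids_core),
    stats::setNames(specific_tab$base *
                      ifelse(specific_tab$target_niche == "S-soil",
                             2^specific_tab$log2fc, 1),
                    specific_tab$phylotype_id))
  out$truth <- list(
    tm_id = cfg$tm_id,
    core_ids = ids_core,
    specific = specific_tab,
    background_study = bg_study,
    expected_core = c(cfg$tm_id,
                      names(expected_ssoil_mean)[expected_ssoil_mean >= 0.001]),
    null_ids = ids_core,   # shared, niche-neutral features: honest nulls
    true_niche = true_niche,
    config = cfg, seed = seed)
  out
}

#' Synthetic Phenotype MicroArray plates with planted utilization levels
#'
#' Logistic growth curves `OD(t) = baseline + A / (1 + exp(-r (t - t0)))`
#' plus optional Gaussian noise, read every 24 h over 8 days at two
#' wavelengths. The A1 negative control stays flat at the baseline; the
#' other wells cycle through `n_levels` planted utilization amplitudes.
#'
#' @param seed RNG seed.
#' @param n_strains number of strains (default 4).
#' @param n_levels planted activity levels (default 9).
#' @param noise_sd Gaussian OD noise (default 0).
#' @param baseline,rate,t_mid logistic parameters.
#' @param hours measurement times (default `seq(0, 192, 24)`).
#' @param wavelengths default `c(590, 750)`.
#' @return list with `pm` (long data.frame: strain, plate, well, wavelength,
#'   hour, od) and `truth` (well -> planted level, 0 for A1).
#' @export
make_pm_scenario <- function(seed = 42, n_strains = 4, n_levels = 9,
                             noise_sd = 0, baseline = 0.05, rate = 0.06,
                             t_mid = 72, hours = seq(0, 192, by = 24),
                             wavelengths = c(590, 750)) {
  set.seed(seed)
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  level <- stats::setNames(rep(seq_len(n_levels), length.out = length(wells)),
                           wells)
  level["A1"] <- 0L
  strains <- sprintf("strain_%02d", seq_len(n_strains))
  grid <- expand.grid(strain = strains, wavelength = wavelengths,
                      well = wells, hour = hours,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  amp <- 0.12 * level[grid$well]
  logis <- 1 / (1 + exp(-rate * (grid$hour - t_mid)))
  od <- baseline + amp * logis
  if (noise_sd > 0) od <- pmax(0, od + stats::rnorm(length(od), 0, noise_sd))
  pm <- data.frame(strain = grid$strain, plate = "PM1", well = grid$well,
                   wavelength = grid$wavelength, hour = grid$hour, od = od,
                   stringsAsFactors = FALSE)
  list(pm = pm, truth = level)
}
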