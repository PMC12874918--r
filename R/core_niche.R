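#' Abundance prefilter
#'
#' Drops phylotypes whose mean relative abundance across all samples is
#' strictly below `min_mean` (default 0.1%); a phylotype at exactly the
#' threshold is kept.
#'
#' @param table a `community_table`.
#' @param min_mean threshold on the unweighted mean of per-sample relative
#'   abundances (default 0.001).
#' @return filtered `community_table`; dropped count in the `n_dropped`
#'   attribute.
#' @export
prefilter <- function(table, min_mean = 0.001) {
  rel <- relative_abundance(table)
  keep <- colMeans(rel) >= min_mean
  out <- community_table(table$counts[, keep, drop = FALSE], table$metadata,
                         if (!is.null(table$tm_id) && keep[table$tm_id])
                           table$tm_id else NULL)
  attr(out, "n_dropped") <- sum(!keep)
  message(sum(!keep), " phylotype(s) below ", min_mean * 100,
          "% mean relative abundance dropped")
  out
}

#' Identify shiro core phylotypes
#'
#' A phylotype is core when it is (1) detected (count > 0 in at least one
#' S-soil sample) in every geographic region present in the data, (2)
#' present in at least `min_study_prev` of the studies (by default studies
#' that contribute S-soil samples), and (3) at `min_mean_abund` or more mean
#' relative abundance across S-soil samples (unweighted mean of per-sample
#' proportions, non-rarefied table).
#'
#' @param table a `community_table` with S-soil samples from >= 2 regions
#'   and >= 2 studies.
#' @param min_study_prev study-prevalence threshold (default 0.5).
#' @param min_mean_abund S-soil mean relative-abundance threshold (default
#'   0.001).
#' @param study_universe `"with_s_soil"` (default) counts prevalence over
#'   studies contributing S-soil samples; `"all"` over every study.
#' @return data.frame (`core_report`): `phylotype_id`, `n_regions_detected`,
#'   `study_prevalence`, `mean_rel_abundance_ssoil`, `is_core`.
#' @export
find_core <- function(table, min_study_prev = 0.5, min_mean_abund = 0.001,
                      study_universe = c("with_s_soil", "all")) {
  study_universe <- match.arg(study_universe)
  meta <- table$metadata
  ss <- meta$niche == "S-soil"
  if (!any(ss)) stop("no S-soil samples")
  regions <- unique(meta$region)
  rel <- relative_abundance(table)

  detected_region <- vapply(regions, function(rg) {
    rows <- ss & meta$region == rg
    if (!any(rows)) return(rep(TRUE, ncol(table$counts)))  # region has no S-soil
    colSums(table$counts[rows, , drop = FALSE] > 0) > 0
  }, logical(ncol(table$counts)))
  n_regions <- rowSums(detected_region)
  all_regions <- n_regions == ncol(detected_region)

  studies <- if (study_universe == "with_s_soil")
    unique(meta$study_id[ss]) else unique(meta$study_id)
  in_study <- vapply(studies, function(s) {
    rows <- ss & meta$study_id == s
    if (!any(rows)) return(rep(FALSE, ncol(table$counts)))
    colSums(table$counts[rows, , drop = FALSE] > 0) > 0
  }, logical(ncol(table$counts)))
  study_prev <- rowMeans(in_study)

  mean_ab <- colMeans(rel[ss, , drop = FALSE])

  data.frame(
    phylotype_id = colnames(table$counts),
    n_regions_detected = n_regions,
    study_prevalence = study_prev,
    mean_rel_abundance_ssoil = mean_ab,
    is_core = all_regions & study_prev >= min_study_prev & mean_ab >= min_mean_abund,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' TM co-occurrence screen
#'
#' Within one (rarefied) study table, phylotypes present in fewer than
#' `prevalence_min` of samples are excluded; the remainder are correlated
#' with the TM phylotype's relative abundance, and a positive correlation
#' `r >= r_min` is called significantly S-soil-related.
#'
#' @param rel samples x phylotypes relative-abundance matrix including TM.
#' @param tm_id TM column name.
#' @param prevalence_min sample-prevalence filter (default 0.20).
#' @param r_min correlation threshold (default 0.35).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `phylotype_id`, `r`, `significant` (TM itself and
#'   excluded phylotypes are absent).
#' @export
tm_cooccurrence <- function(rel, tm_id, prevalence_min = 0.20, r_min = 0.35,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!(tm_id %in% colnames(rel))) stop("TM phylotype absent from table")
  prev <- colMeans(rel > 0)
  keep <- setdiff(colnames(rel)[prev >= prevalence_min], tm_id)
  tm <- rel[, tm_id]
  r <- vapply(keep, function(j) {
    x <- rel[, j]
    if (stats::sd(x) == 0 || stats::sd(tm) == 0) return(NA_real_)
    stats::cor(x, tm, method = method)
  }, numeric(1))
  data.frame(phylotype_id = keep, r = unname(r),
             significant = !is.na(r) & r >= r_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-study S-soil specificity by multiple methods
#'
#' For every study with both S-soil and NS-soil samples, runs the requested
#' methods on that study's (rarefied) sub-table and collects one row per
#' phylotype x study x method with the statistic, p-value, significance
#' call, and direction.
#'
#' @param table a rarefied, prefiltered `community_table`.
#' @param methods subset of `c("lefse", "isa", "cooccurrence")`.
#' @param lda_min LEfSe score threshold (default 3).
#' @param alpha p-value threshold for LEfSe/ISA (default 0.05).
#' @param n_boot,n_perm bootstrap/permutation counts (default 1000).
#' @param r_min,prevalence_min co-occurrence thresholds.
#' @param seed RNG seed.
#' @return data.frame of specificity results.
#' @export
niche_specificity <- function(table,
                              methods = c("lefse", "isa", "cooccurrence"),
                              lda_min = 3, alpha = 0.05,
                              n_boot = 1000, n_perm = 1000,
                              r_min = 0.35, prevalence_min = 0.20,
                              seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  meta <- table$metadata
  out <- list()
  for (s in unique(meta$study_id)) {
    rows <- meta$study_id == s & meta$niche %in% c("S-soil", "NS-soil")
    niche <- meta$niche[rows]
    if (sum(niche == "S-soil") < 3 || sum(niche == "NS-soil") < 3) next
    rel <- relative_abundance(
      community_table(table$counts[meta$sample_id[rows], , drop = FALSE],
                      meta[rows, ], table$tm_id))
    if ("lefse" %in% methods) {
      lf <- lefse_effect_size(rel, niche, n_boot = n_boot, alpha = alpha,
                              seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        phylotype_id = lf$phylotype_id, study_id = s, method = "lefse",
        statistic = lf$lda_score, p_value = lf$p_value,
        significant = lf$p_value <= alpha & lf$lda_score >= lda_min,
        direction = lf$direction, stringsAsFactors = FALSE)
    }
    if ("isa" %in% methods) {
      ia <- isa_rg(rel, niche, "S-soil", n_perm = n_perm, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        phylotype_id = ia$phylotype_id, study_id = s, method = "isa",
        statistic = ia$r_g, p_value = ia$p_value,
        significant = !is.na(ia$r_g) & ia$p_value <= alpha,
        direction = ifelse(!is.na(ia$r_g) & ia$r_g < 0, "NS-soil", "S-soil"),
        stringsAsFactors = FALSE)
    }
    if ("cooccurrence" %in% methods && !is.null(table$tm_id) &&
        table$tm_id %in% colnames(rel)) {
      cc <- tm_cooccurrence(rel, table$tm_id, prevalence_min = prevalence_min,
                            r_min = r_min)
      out[[length(out) + 1L]] <- data.frame(
        phylotype_id = cc$phylotype_id, study_id = s, method = "cooccurrence",
        statistic = cc$r, p_value = NA_real_, significant = cc$significant,
        direction = "S-soil", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no study with >= 3 S-soil and >= 3 NS-soil samples")
  do.call(rbind, out)
}

#' Cross-study consensus of S-soil specificity
#'
#' A phylotype is called S-soil-specific when it is significant (toward
#' S-soil) by at least one method in each of at least `min_studies`
#' independent studies.
#'
#' @param results data.frame from [niche_specificity()].
#' @param min_studies study-replication threshold (default 2).
#' @return data.frame: `phylotype_id`, `n_supporting_studies`,
#'   `supporting_methods` (comma-joined), `s_soil_specific`.
#' @export
consensus_calls <- function(results, min_studies = 2) {
  sig <- results[results$significant & results$direction == "S-soil", ]
  ids <- unique(results$phylotype_id)
  n_stud <- vapply(ids, function(p)
    length(unique(sig$study_id[sig$phylotype_id == p])), integer(1))
  meths <- vapply(ids, function(p)
    paste(sort(unique(sig$method[sig$phylotype_id == p])), collapse = ","),
    character(1))
  data.frame(phylotype_id = ids, n_supporting_studies = n_stud,
             supporting_methods = meths,
             s_soil_specific = n_stud >= min_studies,
             stringsAsFactors = FALSE, row.names = NULL)
}
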