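#' Construct a community table
#'
#' Bundles a sample-by-phylotype count matrix with per-sample metadata and
#' the identity of the *Tricholoma matsutake* (TM) phylotype column.
#'
#' @param counts non-negative integer matrix, samples in rows (rownames =
#'   sample IDs), phylotypes in columns.
#' @param metadata data.frame with columns `sample_id`, `study_id`, `region`,
#'   `niche` (one of S-soil, NS-soil, S-root, S-fruitbody, unknown-soil),
#'   optional `host`, `kingdom`, `paired_sample_id`.
#' @param tm_id column name of the TM phylotype (NULL if absent, e.g. a
#'   bacterial table).
#' @return object of class `community_table`.
#' @export
community_table <- function(counts, metadata, tm_id = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id")
  if (!setequal(rownames(counts), metadata$sample_id))
    stop("counts rownames must match metadata sample_id")
  niches <- c("S-soil", "NS-soil", "S-root", "S-fruitbody", "unknown-soil")
  if (!all(metadata$niche %in% niches))
    stop("niche outside closed vocabulary: ",
         paste(setdiff(metadata$niche, niches), collapse = ", "))
  if (!is.null(tm_id) && !(tm_id %in% colnames(counts)))
    stop("tm_id not among phylotype columns")
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  structure(list(counts = counts, metadata = metadata, tm_id = tm_id),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "phylotypes;", length(unique(x$metadata$study_id)), "studies\n")
  print(table(x$metadata$niche))
  invisible(x)
}

#' Aggregate sequence-level counts to phylotypes
#'
#' Sums sample x sequence (ASV/barcode) counts over a tip-to-phylotype
#' membership map. Total mapped reads are conserved per sample. Unmapped
#' sequence IDs raise a warning and are reported in the `unmapped`
#' attribute; more than 50% of reads unmapped is an error.
#'
#' @param asv_counts samples x sequence matrix (rownames = sample IDs).
#' @param membership data.frame with `tip_id`, `phylotype_id`.
#' @param metadata,tm_id passed to [community_table()].
#' @return a `community_table` of phylotype counts.
#' @export
aggregate_counts <- function(asv_counts, membership, metadata, tm_id = NULL) {
  asv_counts <- as.matrix(asv_counts)
  map <- stats::setNames(membership$phylotype_id, membership$tip_id)
  unmapped <- setdiff(colnames(asv_counts), names(map))
  if (length(unmapped) > 0) {
    frac <- sum(asv_counts[, unmapped, drop = FALSE]) / max(1, sum(asv_counts))
    if (frac > 0.5)
      stop(sprintf("%.1f%% of reads belong to unmapped sequence ids", 100 * frac))
    warning(length(unmapped), " sequence id(s) not in membership map; dropped")
  }
  keep <- intersect(colnames(asv_counts), names(map))
  grp <- map[keep]
  agg <- t(rowsum(t(asv_counts[, keep, drop = FALSE]), group = grp))
  out <- community_table(agg, metadata, tm_id)
  attr(out, "unmapped") <- unmapped
  out
}

#' Relative-abundance view of a community table
#'
#' @param table a `community_table` or a counts matrix.
#' @return matrix of row-normalized proportions; all-zero rows stay zero and
#'   are listed in the `empty_samples` attribute.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  totals <- rowSums(counts)
  rel <- counts / ifelse(totals == 0, 1, totals)
  attr(rel, "empty_samples") <- rownames(counts)[totals == 0]
  rel
}

#' Phylotype prevalence
#'
#' Fraction of samples (or of studies, via any sample within the study) with
#' a positive count.
#'
#' @param table a `community_table`.
#' @param by `"sample"` or `"study"`.
#' @return named numeric vector, one fraction per phylotype.
#' @export
prevalence <- function(table, by = c("sample", "study")) {
  by <- match.arg(by)
  pres <- table$counts > 0
  if (by == "sample") return(colMeans(pres))
  studies <- unique(table$metadata$study_id)
  per_study <- vapply(studies, function(s) {
    colSums(pres[table$metadata$study_id == s, , drop = FALSE]) > 0
  }, logical(ncol(table$counts)))
  rowMeans(per_study)
}

#' Reclassify unlabeled soil samples by TM abundance
#'
#' Computes the TM relative abundance of every `unknown-soil` sample and
#' splits the values with exact univariate 2-means; the high-center cluster
#' becomes S-soil, the low-center cluster NS-soil. A single unknown sample
#' is pooled with the labeled soil samples' TM abundances for the split.
#' Bacterial samples paired to a reclassified fungal sample (via
#' `paired_sample_id`) inherit the fungal call through
#' [inherit_soil_type()].
#'
#' @param table a fungal `community_table` with `tm_id` set.
#' @param use_relative cluster TM relative abundance (default) or raw reads.
#' @return the table with `unknown-soil` niches replaced; the calls are in
#'   the `reclassified` attribute.
#' @export
reclassify_soil <- function(table, use_relative = TRUE) {
  if (is.null(table$tm_id)) stop("tm_id must be set for reclassification")
  unknown <- table$metadata$sample_id[table$metadata$niche == "unknown-soil"]
  if (length(unknown) == 0) return(table)
  vals_all <- if (use_relative)
    relative_abundance(table)[, table$tm_id] else table$counts[, table$tm_id]
  vals <- vals_all[unknown]

  pool_ids <- unknown
  if (length(unknown) == 1) {
    labeled <- table$metadata$sample_id[table$metadata$niche %in% c("S-soil", "NS-soil")]
    pool_ids <- c(unknown, labeled)
  }
  pool <- vals_all[pool_ids]
  if (length(unique(pool)) < 2) {
    warning("all TM abundances identical; assigning NS-soil")
    calls <- stats::setNames(rep("NS-soil", length(unknown)), unknown)
  } else {
    km <- kmeans_1d(pool, 2)
    hi <- which.max(km$centers)
    calls <- ifelse(km$cluster[seq_along(unknown)] == hi, "S-soil", "NS-soil")
    names(calls) <- unknown
  }
  idx <- match(unknown, table$metadata$sample_id)
  table$metadata$niche[idx] <- unname(calls)
  attr(table, "reclassified") <- calls
  table
}

#' Propagate fungal soil-type calls to paired bacterial samples
#'
#' @param bacterial_table `community_table` whose metadata has
#'   `paired_sample_id` pointing at fungal sample IDs.
#' @param fungal_table reclassified fungal `community_table`.
#' @return the bacterial table with inherited niches.
#' @export
inherit_soil_type <- function(bacterial_table, fungal_table) {
  meta_b <- bacterial_table$metadata
  if (is.null(meta_b$paired_sample_id)) stop("bacterial metadata lacks paired_sample_id")
  fun_niche <- stats::setNames(fungal_table$metadata$niche,
                               fungal_table$metadata$sample_id)
  idx <- which(meta_b$niche == "unknown-soil" & !is.na(meta_b$paired_sample_id))
  inh <- fun_niche[meta_b$paired_sample_id[idx]]
  ok <- !is.na(inh) & inh %in% c("S-soil", "NS-soil")
  bacterial_table$metadata$niche[idx[ok]] <- unname(inh[ok])
  bacterial_table
}

#' Minimum-read filtering and per-study rarefaction
#'
#' Within each study, samples with fewer than `min_reads` total reads are
#' dropped and the remaining samples are subsampled without replacement to
#' the study's minimum total. Studies left with fewer than 2 samples are
#' dropped with a warning.
#'
#' @param table a `community_table`.
#' @param min_reads minimum total reads per sample (default 100).
#' @param seed RNG seed for reproducible subsampling.
#' @return rarefied `community_table`; within each study all row totals are
#'   equal.
#' @export
filter_and_rarefy <- function(table, min_reads = 100, seed = 1) {
  set.seed(seed)
  keep_rows <- character(0)
  out_counts <- NULL
  for (s in unique(table$metadata$study_id)) {
    ids <- table$metadata$sample_id[table$metadata$study_id == s]
    m <- table$counts[ids, , drop = FALSE]
    totals <- rowSums(m)
    m <- m[totals >= min_reads, , drop = FALSE]
    if (nrow(m) < 2) {
      warning("study ", s, " left with <2 samples; dropped")
      next
    }
    depth <- min(rowSums(m))
    # vegan warns whenever the smallest nonzero count exceeds 1; that
    # heuristic misfires on aggregated phylotype tables
    rar <- withCallingHandlers(
      vegan::rrarefy(m, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    keep_rows <- c(keep_rows, rownames(m))
    out_counts <- rbind(out_counts, rar)
  }
  if (is.null(out_counts)) stop("no study retained after filtering")
  community_table(out_counts,
                  table$metadata[match(keep_rows, table$metadata$sample_id), ],
                  table$tm_id)
}
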