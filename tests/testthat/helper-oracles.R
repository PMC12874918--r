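# Independent brute-force oracles used across the suite.

# random tree with continuous branch lengths (no ties at thresholds)
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE, br = stats::runif)
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

# single-linkage oracle: agglomerative clustering on the distance matrix,
# dendrogram cut at the threshold
bf_single_linkage <- function(tree, threshold) {
  d <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  ct <- stats::cutree(hc, h = threshold)
  unname(lapply(split(names(ct), ct), sort))
}

# canonical form of a partition for set comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, function(p) sort(unname(p)))
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# exhaustive optimal 1-D k-means: enumerate all contiguous partitions of the
# sorted values, return the minimum total WCSS
bf_kmeans_wcss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  wcss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  if (k == 1) return(wcss(x))
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- sum(vapply(seq_len(k), function(m)
      wcss(x[(cuts[m] + 1):cuts[m + 1]]), numeric(1)))
    best <- min(best, tot)
  }
  best
}

# clade enumeration oracle for monophyly (via ape::prop.part, a code path
# independent of the package's phangorn-based tipsets)
bf_is_monophyletic <- function(tree, tips) {
  if (length(tips) == 1) return("monotypic")
  pp <- ape::prop.part(tree)
  clades <- lapply(pp, function(i) tree$tip.label[i])
  # pendant singleton clades can't hold >= 2 tips; internal clades suffice
  for (cl in clades) if (setequal(cl, tips)) return("monophyletic")
  "non_monophyletic"
}

# planted two-module adjacency for MCL checks
two_module_adj <- function(n_per = 5, intra = 0.9, inter = 0.36) {
  n <- 2 * n_per
  A <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  A[1:n_per, 1:n_per] <- intra
  A[(n_per + 1):n, (n_per + 1):n] <- intra
  diag(A) <- 0
  A[n_per, n_per + 1] <- A[n_per + 1, n_per] <- inter
  A
}

# weighted Pearson correlation oracle via stats::cov.wt
bf_weighted_cor <- function(x, p, w) {
  cw <- stats::cov.wt(cbind(x, p), wt = w / sum(w), cor = TRUE, method = "ML")
  cw$cor[1, 2]
}

# reclassification replicate under the planted TM Beta mixture: returns the
# fraction of correct S/NS calls for 10 + 10 unknown soil samples
sim_reclassification <- function(seed, n_per_group = 10, reads = 20000) {
  set.seed(seed)
  sh_s <- c(3.145084, 1.919463)    # Beta(mean .62, sd .197)
  sh_ns <- c(0.1574559, 7.715337)  # Beta(mean .02, sd .047)
  tm <- c(stats::rbeta(n_per_group, sh_s[1], sh_s[2]),
          stats::rbeta(n_per_group, sh_ns[1], sh_ns[2]))
  truth <- rep(c("S-soil", "NS-soil"), each = n_per_group)
  counts <- cbind(TM = round(tm * reads), other = reads - round(tm * reads))
  colnames(counts) <- c("Tricholoma matsutake", "other_pt")
  rownames(counts) <- sprintf("s%02d", seq_along(tm))
  meta <- data.frame(sample_id = rownames(counts), study_id = "ST01",
                     region = "synthetic", niche = "unknown-soil",
                     kingdom = "fungi", stringsAsFactors = FALSE)
  tab <- community_table(counts, meta, "Tricholoma matsutake")
  calls <- attr(reclassify_soil(tab), "reclassified")
  mean(calls[rownames(counts)] == truth)
}
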