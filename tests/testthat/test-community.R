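make_toy_table <- function(counts, niche, study = "ST01", kingdom = "fungi",
                           tm_id = NULL) {
  meta <- data.frame(sample_id = rownames(counts), study_id = study,
                     region = "synthetic", niche = niche, kingdom = kingdom,
                     stringsAsFactors = FALSE)
  community_table(counts, meta, tm_id)
}

test_that("aggregation conserves reads and reports unmapped sequences", {
  counts <- matrix(c(3, 4, 2, 0, 5, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("asv1", "asv2", "asv3")))
  memb <- data.frame(tip_id = c("asv1", "asv2", "asv3"),
                     phylotype_id = c("ptA", "ptA", "ptB"))
  meta <- data.frame(sample_id = c("s1", "s2"), study_id = "ST01",
                     region = "r", niche = "S-soil", kingdom = "fungi")
  tab <- aggregate_counts(counts, memb, meta)
  expect_equal(unname(tab$counts["s1", "ptA"]), 7)
  expect_equal(rowSums(tab$counts), rowSums(counts), ignore_attr = TRUE)

  # empty sample retained as an all-zero row
  counts0 <- rbind(counts, s3 = c(0, 0, 0))
  meta0 <- rbind(meta, data.frame(sample_id = "s3", study_id = "ST01",
                                  region = "r", niche = "S-soil",
                                  kingdom = "fungi"))
  tab0 <- aggregate_counts(counts0, memb, meta0)
  expect_equal(unname(rowSums(tab0$counts)["s3"]), 0)

  # unmapped minority warns; unmapped majority errors
  memb_part <- memb[1:2, ]
  expect_warning(tabp <- aggregate_counts(counts, memb_part, meta), "not in membership")
  expect_equal(attr(tabp, "unmapped"), "asv3")
  big <- matrix(c(1, 1, 100, 100), 2,
                dimnames = list(c("s1", "s2"), c("asv1", "huge")))
  expect_error(suppressWarnings(
    aggregate_counts(big, memb[1, , drop = FALSE], meta)), "unmapped")
})

test_that("relative abundance and prevalence behave on edge cases", {
  counts <- matrix(c(5, 5, 0, 0), 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("p1", "p2")))
  tab <- make_toy_table(counts, "S-soil")
  rel <- relative_abundance(tab)
  expect_equal(unname(rel["s1", ]), c(0.5, 0.5))
  expect_equal(unname(rel["s2", ]), c(0, 0))
  expect_equal(attr(rel, "empty_samples"), "s2")
  expect_equal(unname(prevalence(tab)["p1"]), 0.5)
})

test_that("soil reclassification splits TM abundance and assigns by center", {
  tm_rel <- c(0.62, 0.55, 0.70, 0.01, 0.03)
  reads <- 10000
  counts <- cbind(tm = round(tm_rel * reads), other = reads - round(tm_rel * reads))
  colnames(counts) <- c("TM", "other")
  rownames(counts) <- sprintf("s%d", 1:5)
  tab <- make_toy_table(counts, "unknown-soil", tm_id = "TM")
  out <- reclassify_soil(tab)
  calls <- attr(out, "reclassified")
  expect_equal(unname(calls), c("S-soil", "S-soil", "S-soil", "NS-soil", "NS-soil"))
  expect_false(any(out$metadata$niche == "unknown-soil"))

  # all-identical TM abundances fall back to NS-soil with a warning
  flat <- cbind(TM = rep(50, 3), other = rep(950, 3))
  rownames(flat) <- c("a", "b", "c")
  expect_warning(out2 <- reclassify_soil(make_toy_table(flat, "unknown-soil",
                                                        tm_id = "TM")),
                 "identical")
  expect_true(all(out2$metadata$niche == "NS-soil"))

  # a single unknown sample is pooled with labeled samples for the split
  one <- cbind(TM = c(6500, 6000, 200, 100), other = c(3500, 4000, 9800, 9900))
  rownames(one) <- c("u1", "l1", "l2", "l3")
  tab1 <- make_toy_table(one, c("unknown-soil", "S-soil", "NS-soil", "NS-soil"),
                         tm_id = "TM")
  out3 <- reclassify_soil(tab1)
  expect_equal(unname(attr(out3, "reclassified")["u1"]), "S-soil")
})

test_that("paired bacterial samples inherit the fungal soil call", {
  fcounts <- cbind(TM = c(6000, 100), other = c(4000, 9900))
  rownames(fcounts) <- c("f1", "f2")
  ftab <- make_toy_table(fcounts, "unknown-soil", tm_id = "TM")
  ftab <- reclassify_soil(ftab)
  bcounts <- cbind(b1 = c(10, 20), b2 = c(5, 5))
  rownames(bcounts) <- c("bs1", "bs2")
  bmeta <- data.frame(sample_id = c("bs1", "bs2"), study_id = "ST01",
                      region = "synthetic", niche = "unknown-soil",
                      kingdom = "bacteria", paired_sample_id = c("f1", "f2"))
  btab <- community_table(bcounts, bmeta, NULL)
  btab <- inherit_soil_type(btab, ftab)
  expect_equal(btab$metadata$niche, c("S-soil", "NS-soil"))
})

test_that("filtering drops low-read samples and rarefaction equalizes totals", {
  set.seed(1)
  counts <- rbind(s1 = c(60, 40), s2 = c(200, 50), s3 = c(50, 30))
  colnames(counts) <- c("p1", "p2")
  tab <- make_toy_table(counts, "S-soil")
  out <- filter_and_rarefy(tab, min_reads = 100, seed = 5)
  expect_setequal(rownames(out$counts), c("s1", "s2"))
  expect_true(all(rowSums(out$counts) == 100))
  expect_true(all(out$counts <= counts[rownames(out$counts), ]))

  # rarefying a sample to its own total leaves counts unchanged
  eq <- rbind(a = c(70, 30), b = c(60, 40))
  colnames(eq) <- c("p1", "p2")
  out_eq <- filter_and_rarefy(make_toy_table(eq, "S-soil"), min_reads = 100,
                              seed = 2)
  expect_equal(out_eq$counts, eq, ignore_attr = TRUE)

  # a study reduced below 2 samples is dropped
  two_st <- rbind(a = c(500, 0), b = c(80, 10), c = c(300, 300), d = c(250, 250))
  colnames(two_st) <- c("p1", "p2")
  meta <- data.frame(sample_id = rownames(two_st),
                     study_id = c("ST01", "ST01", "ST02", "ST02"),
                     region = "r", niche = "S-soil", kingdom = "fungi")
  expect_warning(out2 <- filter_and_rarefy(community_table(two_st, meta), 100, 3),
                 "dropped")
  expect_setequal(unique(out2$metadata$study_id), "ST02")

  # same seed, same subsample
  r1 <- filter_and_rarefy(tab, 100, seed = 11)
  r2 <- filter_and_rarefy(tab, 100, seed = 11)
  expect_identical(r1$counts, r2$counts)
})

test_that("rarefaction preserves expected proportions", {
  set.seed(42)
  base <- c(5000, 3000, 1500, 500)
  counts <- matrix(rep(base, each = 2), nrow = 2,
                   dimnames = list(c("x", "y"),
                                   paste0("p", 1:4)))
  counts["y", ] <- c(200, 100, 50, 50)  # depth 400 defines the study minimum
  tab <- make_toy_table(counts, "S-soil")
  props <- replicate(300, {
    out <- filter_and_rarefy(tab, min_reads = 100,
                             seed = sample.int(1e6, 1))
    out$counts["x", "p1"] / sum(out$counts["x", ])
  })
  p0 <- 0.5
  se <- sqrt(p0 * (1 - p0) / 400)
  expect_lt(abs(mean(props) - p0), 4 * se / sqrt(300))
})
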