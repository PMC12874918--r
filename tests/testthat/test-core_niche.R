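core_table <- function(counts, region, study, niche) {
  meta <- data.frame(sample_id = rownames(counts), study_id = study,
                     region = region, niche = niche, kingdom = "fungi",
                     stringsAsFactors = FALSE)
  community_table(counts, meta)
}

test_that("the abundance prefilter is strict below 0.1%", {
  # p2 at exactly 0.1% mean is kept; p3 just below is dropped
  counts <- rbind(s1 = c(9979, 10, 11), s2 = c(9983, 10, 7))
  colnames(counts) <- c("p1", "p2", "p3")
  tab <- core_table(counts, "r", "ST01", "S-soil")
  rel <- relative_abundance(tab)
  expect_equal(unname(colMeans(rel)["p2"]), 0.001)
  expect_lt(colMeans(rel)["p3"], 0.001)
  out <- suppressMessages(prefilter(tab))
  expect_setequal(colnames(out$counts), c("p1", "p2"))

  # surviving set equals a brute-force recomputation on a random table
  set.seed(3)
  rc <- matrix(rpois(20 * 30, 3), 20, 30,
               dimnames = list(sprintf("s%d", 1:20), sprintf("p%d", 1:30)))
  rtab <- core_table(rc, "r", "ST01", "S-soil")
  surv <- colnames(suppressMessages(prefilter(rtab))$counts)
  rel <- rc / rowSums(rc)
  expect_setequal(surv, colnames(rc)[colMeans(rel) >= 0.001])
})

test_that("core calling enforces region, prevalence, and abundance rules", {
  # 2 regions x 2 studies, 2 S-soil samples each
  ids <- sprintf("s%d", 1:8)
  niche <- rep(c("S-soil", "NS-soil"), 4)
  region <- rep(c("A", "B"), each = 4)
  study <- rep(c("ST01", "ST02", "ST03", "ST04"), each = 2)
  # p_core: everywhere at 1%; p_rare: qualifying but at 0.09%;
  # p_oneregion: only region A; p_halfstudy: in 2 of 4 studies (exactly 50%)
  counts <- matrix(0, 8, 5, dimnames = list(ids,
    c("p_core", "p_rare", "p_oneregion", "p_halfstudy", "filler")))
  ssoil <- niche == "S-soil"
  counts[, "filler"] <- 10000
  counts[ssoil, "p_core"] <- 100
  counts[ssoil, "p_rare"] <- 9   # 9 / 10109 = 0.089%
  counts[ssoil & region == "A", "p_oneregion"] <- 100
  counts[ssoil & study %in% c("ST01", "ST03"), "p_halfstudy"] <- 100
  meta <- data.frame(sample_id = ids, study_id = study, region = region,
                     niche = niche, kingdom = "fungi")
  tab <- community_table(counts, meta)
  rep_ <- find_core(tab)
  core <- stats::setNames(rep_$is_core, rep_$phylotype_id)
  expect_true(core[["p_core"]])
  expect_false(core[["p_rare"]])       # 0.09% < 0.1%, boundary is >=
  expect_false(core[["p_oneregion"]])  # missing a region
  expect_true(core[["p_halfstudy"]])   # exactly 50% passes (>=)
  expect_error(find_core(core_table(counts, region, study,
                                    rep("NS-soil", 8))), "no S-soil")
})

test_that("LEfSe screen and effect size behave on trivial and strong features", {
  set.seed(1)
  n <- 12
  classes <- rep(c("S-soil", "NS-soil"), each = n / 2)
  # identical feature -> p = 1, score 0; strong feature -> p <= .05, LDA >= 4
  rel <- cbind(flat = rep(0.1, n),
               strong = c(stats::runif(n / 2, 0.4, 0.5),
                          stats::runif(n / 2, 0.001, 0.002)),
               noise = stats::runif(n, 0.05, 0.06))
  rel <- rel / rowSums(rel)
  rel[, "flat"] <- 0.2  # constant after renormalization drift: force exact
  res <- lefse_effect_size(rel, classes, n_boot = 200, seed = 1)
  expect_equal(res$p_value[res$phylotype_id == "flat"], 1)
  expect_equal(res$lda_score[res$phylotype_id == "flat"], 0)
  strong <- res[res$phylotype_id == "strong", ]
  expect_lte(strong$p_value, 0.05)
  expect_gte(strong$lda_score, 4)
  expect_equal(strong$direction, "S-soil")

  # small classes are excluded with a warning; remaining classes still run
  expect_warning(
    lefse_effect_size(rel, c(rep("A", 5), rep("B", 5), "C", "C"),
                      n_boot = 10, seed = 1),
    "< 3 samples")
})

test_that("KW screen holds its level under a permuted null", {
  set.seed(7)
  n <- 20
  classes <- rep(c("a", "b"), each = n / 2)
  n_feat <- 400
  rel <- matrix(stats::rlnorm(n * n_feat), n, n_feat,
                dimnames = list(NULL, sprintf("f%d", seq_len(n_feat))))
  rel <- rel / rowSums(rel)
  res <- lefse_effect_size(rel, classes, n_boot = 1, seed = 1)
  rate <- mean(res$p_value <= 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n_feat)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("isa_rg matches its definition, oracle, and exact enumeration", {
  # perfect indicator with equal group sizes -> r.g = 1
  groups <- rep(c("S-soil", "NS-soil"), each = 4)
  x <- ifelse(groups == "S-soil", 3, 0)
  rel <- cbind(ind = x, flat = rep(1, 8))
  res <- isa_rg(rel, groups, "S-soil", n_perm = 99, seed = 1)
  expect_equal(res$r_g[res$phylotype_id == "ind"], 1, tolerance = 1e-12)
  expect_true(is.na(res$r_g[res$phylotype_id == "flat"]))
  expect_equal(res$p_value[res$phylotype_id == "flat"], 1)

  # r.g equals the weighted-correlation oracle under unequal group sizes
  set.seed(2)
  g2 <- c(rep("S-soil", 3), rep("NS-soil", 6))
  y <- stats::rlnorm(9)
  w <- ifelse(g2 == "S-soil", 1 / (2 * 3), 1 / (2 * 6))
  expect_equal(isa_rg(cbind(f = y), g2, "S-soil", n_perm = 9, seed = 1)$r_g,
               bf_weighted_cor(y, as.numeric(g2 == "S-soil"), w),
               tolerance = 1e-12)

  # exact enumeration equals an independent brute-force loop (n = 8)
  set.seed(3)
  rel8 <- cbind(a = stats::rpois(8, 5), b = stats::rpois(8, 5))
  g8 <- rep(c("S-soil", "NS-soil"), each = 4)
  ex <- isa_rg(rel8, g8, "S-soil", exact = TRUE)
  pos <- utils::combn(8, 4)
  for (feat in c("a", "b")) {
    robs <- bf_weighted_cor(rel8[, feat], as.numeric(g8 == "S-soil"),
                            rep(1 / 8, 8))
    rperm <- apply(pos, 2, function(ii) {
      ind <- as.numeric(seq_len(8) %in% ii)
      bf_weighted_cor(rel8[, feat], ind, rep(1 / 8, 8))
    })
    expect_equal(ex$p_value[ex$phylotype_id == feat],
                 mean(rperm >= robs - 1e-12), tolerance = 1e-12)
  }
})

test_that("isa_rg permutation p-values are valid under the null", {
  set.seed(11)
  n <- 16
  groups <- rep(c("S-soil", "NS-soil"), each = n / 2)
  n_feat <- 500
  rel <- matrix(stats::rlnorm(n * n_feat), n, n_feat,
                dimnames = list(NULL, sprintf("f%d", seq_len(n_feat))))
  res <- isa_rg(rel, groups, "S-soil", n_perm = 400, seed = 2)
  rate <- mean(res$p_value <= 0.05)
  bound <- 0.05 + 1 / 401 + 2 * sqrt(0.05 * 0.95 / n_feat)
  expect_lte(rate, bound)
})

test_that("TM co-occurrence screens by prevalence and correlation", {
  set.seed(5)
  n <- 10
  tm <- stats::runif(n, 0.3, 0.9)
  rel <- cbind(TM = tm, prop = tm * 0.1, rare = c(0.5, rep(0, n - 1)),
               anti = max(tm) + 0.05 - tm)
  res <- tm_cooccurrence(rel, "TM")
  expect_equal(res$r[res$phylotype_id == "prop"], 1, tolerance = 1e-9)
  expect_true(res$significant[res$phylotype_id == "prop"])
  expect_false("rare" %in% res$phylotype_id)     # 10% prevalence < 20%
  expect_false(res$significant[res$phylotype_id == "anti"])  # r = -1
  expect_error(tm_cooccurrence(rel[, -1], "TM"), "absent")
})

test_that("consensus needs two studies and is monotone in added support", {
  base <- data.frame(
    phylotype_id = c("p1", "p1", "p2", "p2", "p2"),
    study_id = c("A", "B", "A", "A", "A"),
    method = c("isa", "lefse", "isa", "lefse", "cooccurrence"),
    statistic = 1, p_value = 0.01, significant = TRUE,
    direction = "S-soil", stringsAsFactors = FALSE)
  calls <- consensus_calls(base)
  expect_true(calls$s_soil_specific[calls$phylotype_id == "p1"])
  expect_false(calls$s_soil_specific[calls$phylotype_id == "p2"])  # one study

  # NS-soil-direction significance does not count toward the S-soil call
  ns <- base
  ns$direction[ns$phylotype_id == "p1"] <- "NS-soil"
  expect_false(consensus_calls(ns)$s_soil_specific[1])

  # monotone: adding a significant study never flips true -> false
  extra <- rbind(base, data.frame(phylotype_id = "p1", study_id = "C",
                                  method = "isa", statistic = 1,
                                  p_value = 0.01, significant = TRUE,
                                  direction = "S-soil"))
  expect_true(consensus_calls(extra)$s_soil_specific[
    consensus_calls(extra)$phylotype_id == "p1"])
})

test_that("cross-niche comparison finds planted niche-exclusive phylotypes", {
  cs <- make_community_scenario(community_config(), seed = 11)
  rar <- filter_and_rarefy(cs$fungi, seed = 12)
  pre <- suppressMessages(prefilter(rar))
  cn <- cross_niche_lefse(pre, lda_min = 3.5, n_boot = 200, seed = 13)
  planted <- cs$truth$specific
  for (i in seq_len(nrow(planted))) {
    row <- cn[cn$phylotype_id == planted$phylotype_id[i], ]
    expect_true(row$significant)
    expect_equal(row$niche, planted$target_niche[i])
  }
  # a feature uniform across niches is never called on constructed data
  ids <- sprintf("s%d", 1:12)
  niche3 <- rep(c("S-soil", "S-root", "S-fruitbody"), each = 4)
  cmat <- matrix(c(rep(100, 12), rep(900, 12)), 12, 2,
                 dimnames = list(ids, c("uniform", "bulk")))
  cmat[niche3 == "S-root", "bulk"] <- 900  # keep compositions identical
  meta3 <- data.frame(sample_id = ids, study_id = "ST01", region = "A",
                      niche = niche3, kingdom = "fungi")
  cn2 <- cross_niche_lefse(community_table(cmat, meta3), lda_min = 3.5,
                           n_boot = 50, seed = 2)
  expect_false(any(cn2$significant))
})
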