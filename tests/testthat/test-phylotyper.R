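test_that("single-linkage clustering matches the dendrogram-cut oracle", {
  tr <- read_newick("((A:0.005,B:0.005):0.1,(C:0.005,D:0.005):0.1);")
  cl <- single_linkage_cluster(tr, 0.02)
  expect_equal(canon_partition(cl), canon_partition(list(c("A", "B"), c("C", "D"))))

  # threshold 0 with positive pendant edges: all singletons
  expect_length(single_linkage_cluster(tr, 0), 4)
  # threshold above the diameter: one cluster
  expect_length(single_linkage_cluster(tr, 1), 1)
  expect_error(single_linkage_cluster(tr, -0.1), "non-negative")

  for (seed in 1:20) {
    tr <- random_tree(sample(5:32, 1), seed + 100)
    thr <- stats::runif(1, 0.1, 2)
    expect_equal(canon_partition(single_linkage_cluster(tr, thr)),
                 canon_partition(bf_single_linkage(tr, thr)))
  }
})

test_that("monophyly refinement splits non-monophyletic clusters correctly", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  pre <- refine_monophyly(tr, list(c("A", "B", "C"), "D"))
  expect_equal(canon_partition(lapply(pre, `[[`, "tips")),
               canon_partition(list(c("A", "B"), "C", "D")))
  # the split-off outlier records its parent and z
  child <- pre[[which(vapply(pre, function(p) identical(unname(p$tips), "C"),
                             logical(1)))]]
  expect_equal(child$parent_y, 1L)
  expect_equal(child$z, 1L)

  # already-monophyletic clusters come back unchanged
  ok <- refine_monophyly(tr, list(c("A", "B"), c("C", "D")))
  expect_equal(canon_partition(lapply(ok, `[[`, "tips")),
               canon_partition(list(c("A", "B"), c("C", "D"))))
  expect_true(all(is.na(vapply(ok, `[[`, integer(1), "z"))))

  # caterpillar: no multi-tip clade inside {A, C, D} -> three singletons
  cat_tr <- read_newick("(((A:1,B:1):1,C:1):1,D:1);")
  pre3 <- refine_monophyly(cat_tr, list(c("A", "C", "D"), "B"))
  expect_equal(canon_partition(lapply(pre3, `[[`, "tips")),
               canon_partition(list("A", "B", "C", "D")))

  expect_error(refine_monophyly(tr, list(c("A", "B"))), "partition")

  # singleton outlier mode
  pre_s <- refine_monophyly(tr, list(c("A", "C", "D"), "B"),
                            outlier_mode = "singletons")
  expect_true(all(vapply(pre_s, function(p) length(p$tips), integer(1)) <= 2))
})

test_that("every multi-tip cluster is monophyletic after refinement", {
  for (seed in 1:10) {
    tr <- random_tree(16, seed + 200)
    # random partition into 4 groups, usually non-monophyletic
    set.seed(seed)
    grp <- sample(1:4, 16, replace = TRUE)
    clusters <- split(tr$tip.label, grp)
    pre <- refine_monophyly(tr, clusters)
    tips_out <- sort(unlist(lapply(pre, `[[`, "tips")))
    expect_equal(tips_out, sort(tr$tip.label))
    for (p in pre)
      expect_true(is_monophyletic(tr, p$tips) %in% c("monophyletic", "monotypic"))
  }
})

test_that("taxonomy assignment: direct consensus and LCA walk", {
  # query + database tip -> species-level direct consensus
  tr <- read_newick("((q1:0.004,db1:0.004):0.1,db2:0.2);")
  rec <- tip_records(c("q1", "db1", "db2"), c("query", "database", "database"),
                     c("",
                       "d__Fungi;p__Mucoromycota;c__Mucoromycetes;o__Mucorales;f__Mucoraceae;g__Mucor;s__Mucor zonatus",
                       "d__Fungi;p__Mucoromycota;c__Mucoromycetes;o__Mucorales;f__Mucoraceae;g__Mucor;s__Mucor hiemalis"))
  ta <- assign_taxonomy(tr, c("q1", "db1"), rec)
  expect_equal(ta$source, "direct_consensus")
  expect_equal(unname(ta$taxonomy["species"]), "Mucor zonatus")

  # query-only phylotype: walk up, consensus above species level
  tr2 <- read_newick("(((q1:0.004,q2:0.004):0.05,(db1:0.01,db2:0.01):0.05):0.1,db3:0.3);")
  lin1 <- "d__Bacteria;p__Pseudomonadota;c__Beta;o__Burkholderiales;f__Burkholderiaceae;g__Caballeronia;s__Caballeronia udeis"
  lin2 <- "d__Bacteria;p__Pseudomonadota;c__Beta;o__Burkholderiales;f__Burkholderiaceae;g__Caballeronia;s__Caballeronia sp"
  lin3 <- "d__Bacteria;p__Pseudomonadota;c__Beta;o__Burkholderiales;f__Oxalobacteraceae;g__Massilia;s__Massilia sp"
  rec2 <- tip_records(c("q1", "q2", "db1", "db2", "db3"),
                      c("query", "query", "database", "database", "database"),
                      c("", "", lin1, lin2, lin3))
  ta2 <- assign_taxonomy(tr2, c("q1", "q2"), rec2)
  expect_equal(ta2$source, "lca_walk")
  expect_equal(unname(ta2$taxonomy["genus"]), "Caballeronia")
  expect_false("species" %in% names(ta2$taxonomy))

  # nearby database tips long-branch-flagged: the walk continues to an
  # ancestor holding two families of the same order -> order-level consensus
  tr3 <- read_newick(paste0("(((q1:0.004,q2:0.004):0.05,",
                            "(db1:0.01,db2:0.01):0.05):0.1,",
                            "(db3:0.02,db4:0.02):0.3);"))
  lin4 <- "d__Bacteria;p__Pseudomonadota;c__Beta;o__Burkholderiales;f__Oxalobacteraceae;g__Janthinobacterium;s__Janthinobacterium sp"
  lin5 <- "d__Bacteria;p__Pseudomonadota;c__Beta;o__Burkholderiales;f__Burkholderiaceae;g__Ralstonia;s__Ralstonia insidiosa"
  rec3 <- tip_records(c("q1", "q2", "db1", "db2", "db3", "db4"),
                      c("query", "query", rep("database", 4)),
                      c("", "", lin1, lin2, lin4, lin5))
  rec3$long_branch[rec3$tip_id %in% c("db1", "db2")] <- TRUE
  ta3 <- assign_taxonomy(tr3, c("q1", "q2"), rec3)
  expect_equal(ta3$source, "lca_walk")
  expect_equal(names(ta3$taxonomy)[length(ta3$taxonomy)], "order")
  expect_equal(unname(ta3$taxonomy["order"]), "Burkholderiales")

  # all database tips invalid -> empty lineage
  rec3$long_branch <- TRUE
  ta4 <- assign_taxonomy(tr3, c("q1", "q2"), rec3)
  expect_length(ta4$taxonomy, 0)
})

test_that("phylotype naming follows the pt x.y(.z) / species / M rules", {
  mk <- function(tips, parent_y, z, tax, src)
    list(tips = tips, parent_y = parent_y, z = z, taxonomy = tax,
         taxonomy_source = src)
  rank <- stats::setNames(1:6, c("a", "b", "c", "d", "e", "f"))
  sp_tax <- parse_lineage("d__Fungi;p__P;c__C;o__O;f__F;g__Mucor;s__Mucor zonatus")
  gen_tax <- parse_lineage("d__Bacteria;p__P;c__C;o__O;f__F;g__Paraburkholderia")
  pre <- list(
    mk(c("a", "b"), 1L, NA_integer_, sp_tax, "direct_consensus"),
    mk(c("c", "d"), 2L, NA_integer_, gen_tax, "direct_consensus"),
    mk(c("e"), 2L, 1L, gen_tax, "lca_walk"),
    mk(c("f"), 3L, NA_integer_, character(0), "lca_walk"))
  tab <- name_phylotypes(pre, 108, rank)
  expect_equal(tab$phylotype_id[1], "Mucor zonatus")
  expect_equal(tab$phylotype_id[2], "Paraburkholderia pt 108.2")
  expect_equal(tab$phylotype_id[3], "Paraburkholderia pt 108.M.1")
  expect_equal(tab$phylotype_id[4], "pt 108.M.2")
  expect_true(all(!duplicated(tab$phylotype_id)))

  parsed <- parse_phylotype_id(tab$phylotype_id[-1])
  expect_equal(parsed$x, rep(108L, 3))
  expect_equal(parsed$y, c("2", "M", "M"))
  expect_equal(parsed$z, c(NA_integer_, 1L, 2L))

  # species-name collision falls back to the unique pt form
  pre2 <- list(mk("a", 1L, NA_integer_, sp_tax, "direct_consensus"),
               mk(c("b", "c"), 2L, NA_integer_, sp_tax, "direct_consensus"))
  tab2 <- name_phylotypes(pre2, 5, rank)
  expect_true(all(!duplicated(tab2$phylotype_id)))
  expect_true(all(grepl("^Mucor zonatus", tab2$phylotype_id)))
})

test_that("the phylotyping orchestrator is deterministic and complete", {
  ts <- make_tree_scenario(seed = 7, n_subtrees = 2, n_species = 5)
  ps1 <- phylotype_tree(ts$trees, ts$records)
  ps2 <- phylotype_tree(ts$trees, ts$records)
  expect_identical(ps1$membership, ps2$membership)
  # the membership covers every tip exactly once
  expect_setequal(ps1$membership$tip_id, ts$records$tip_id)
  expect_false(anyDuplicated(ps1$membership$tip_id) > 0)
  expect_false(anyDuplicated(ps1$phylotypes$phylotype_id) > 0)
  # no lca_walk phylotype carries a species rank
  walk <- ps1$phylotypes[ps1$phylotypes$taxonomy_source == "lca_walk", ]
  expect_false(any(grepl("s__", walk$lineage)))
})
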