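#!/usr/bin/env Rscript
# Stage 2 -- phylotype the subtrees.
#
# Midpoint-roots each subtree, flags long branches, clusters tips by single
# linkage at a 0.02 branch-length threshold, refines every cluster to
# monophyly, and assigns consensus / tree-walking taxonomy and pt-style
# names. Reports how many query tips recover their planted species.

suppressPackageStartupMessages(library(shirocore))

dat <- "results/data"
out <- "results"
trees <- lapply(sort(list.files(dat, pattern = "^subtree_.*\\.nwk$",
                                full.names = TRUE)), read_newick)
records <- read_tip_records(file.path(dat, "tips.tsv"))

ps <- phylotype_tree(trees, records, threshold = 0.02)
print(ps)

write.table(ps$phylotypes[, setdiff(names(ps$phylotypes), "tips")],
            file.path(out, "phylotypes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ps$membership, file.path(out, "membership.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(dat, "tree_truth.tsv"))
mg <- merge(ps$membership, truth, by = "tip_id")
q <- mg[mg$kind == "query" & !mg$is_outlier, ]
cat(sprintf("planted species recovered by %.1f%% of %d non-outlier query tips\n",
            100 * mean(q$phylotype_id == q$species), nrow(q)))
cat(sprintf("%d of %d planted outliers ended as monotypic phylotypes\n",
            sum(table(mg$phylotype_id[mg$is_outlier]) == 1),
            sum(mg$is_outlier)))
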