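#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study inputs.
#
# Emulates the structure of the real cross-study surveys: reference-anchored
# subtrees with planted species and long-branch outliers, four studies of
# fungal (and paired bacterial) communities over three regions and four
# shiro niches with a quarter of the soil labels withheld, and Phenotype
# MicroArray plates with nine planted utilization levels.

suppressPackageStartupMessages(library(shirocore))

seed <- 42
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ts <- make_tree_scenario(seed = seed)
for (x in seq_along(ts$trees))
  write_newick(ts$trees[[x]], file.path(out, sprintf("subtree_%02d.nwk", x)))
write.table(ts$records[, c("tip_id", "kind", "lineage")],
            file.path(out, "tips.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ts$truth, file.path(out, "tree_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cfg <- community_config(unknown_frac = 0.25)
cs <- make_community_scenario(cfg, seed = seed,
                              kingdoms = c("fungi", "bacteria"))
for (k in c("fungi", "bacteria")) {
  tab <- cs[[k]]
  write.table(data.frame(sample_id = rownames(tab$counts), tab$counts,
                         check.names = FALSE),
              file.path(out, sprintf("counts_%s.tsv", k)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tab$metadata, file.path(out, sprintf("metadata_%s.tsv", k)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
truth_out <- cs$truth
# named vectors as JSON objects so names survive the round trip
truth_out$true_niche <- as.list(truth_out$true_niche)
truth_out$background_study <- as.list(truth_out$background_study)
jsonlite::write_json(truth_out, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

pm <- make_pm_scenario(seed = seed, noise_sd = 0.01)
write.table(pm$pm, file.path(out, "pm.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(well = names(pm$truth), level = pm$truth),
            file.path(out, "pm_truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("wrote %d subtrees (%d tips), %d fungal + %d bacterial samples, %d PM rows to %s\n",
            length(ts$trees), nrow(ts$records), nrow(cs$fungi$counts),
            nrow(cs$bacteria$counts), nrow(pm$pm), out))
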