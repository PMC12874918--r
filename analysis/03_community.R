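#!/usr/bin/env Rscript
# Stage 3 -- community tables: soil reclassification, filtering, rarefaction.
#
# Unlabeled soil samples are assigned to S-soil or NS-soil by an exact
# univariate 2-means split of their TM relative abundance; paired bacterial
# samples inherit the fungal call. Samples under 100 reads are removed per
# study and the rest rarefied to the study minimum.

suppressPackageStartupMessages(library(shirocore))

dat <- "results/data"
read_tab <- function(k) {
  cnt <- read.delim(file.path(dat, sprintf("counts_%s.tsv", k)),
                    check.names = FALSE)
  counts <- as.matrix(cnt[, -1])
  rownames(counts) <- cnt$sample_id
  meta <- read.delim(file.path(dat, sprintf("metadata_%s.tsv", k)))
  community_table(counts, meta,
                  if (k == "fungi") "Tricholoma matsutake" else NULL)
}

fungi <- read_tab("fungi")
bact <- read_tab("bacteria")

fungi <- reclassify_soil(fungi)
bact <- inherit_soil_type(bact, fungi)
recl <- attr(fungi, "reclassified")
truth <- jsonlite::read_json(file.path(dat, "truth.json"), simplifyVector = TRUE)
acc <- mean(recl == truth$true_niche[names(recl)])
cat(sprintf("reclassified %d unlabeled soil samples (%.0f%% agree with the generating labels): %d S-soil, %d NS-soil\n",
            length(recl), 100 * acc, sum(recl == "S-soil"),
            sum(recl == "NS-soil")))

rar <- filter_and_rarefy(fungi, min_reads = 100, seed = 43)
cat(sprintf("rarefied %d fungal samples; per-study depths: %s\n",
            nrow(rar$counts),
            paste(tapply(rowSums(rar$counts), rar$metadata$study_id, unique),
                  collapse = ", ")))

for (obj in list(list(fungi, "community_fungi"), list(bact, "community_bacteria"),
                 list(rar, "community_fungi_rarefied"))) {
  tab <- obj[[1]]
  write.table(data.frame(sample_id = rownames(tab$counts), tab$counts,
                         check.names = FALSE),
              file.path("results", paste0(obj[[2]], ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tab$metadata,
              file.path("results", paste0(obj[[2]], "_metadata.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
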