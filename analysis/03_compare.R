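#!/usr/bin/env Rscript

# Stage 3: union catalogue and coverage fold reduction (CFR).
#
# Tetramer (A) and dimer (B) consensus peaks are joined into one
# catalogue: peaks overlapping by at least 80% of the smaller peak
# with under 50% non-overlap collapse into a common entry; the rest
# are complex-specific candidates. Each entry's mean normalized
# coverage is recomputed per experiment over a summit +/- 200 bp
# window, entries are labelled common / tetramer- / dimer-specific at
# 2-fold, and ranked into deciles by CFR = cov_tetramer / cov_dimer.

library(dapcompare)

data_dir <- "results/data"
genome <- read_fasta(file.path(data_dir, "genome.fa"))
chrom_lengths <- nchar(genome)
libs <- utils::read.table(file.path(data_dir, "library_sizes.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
tracks <- lapply(c(tetramer = "tetramer", dimer = "dimer"), function(kind)
  lapply(1:2, function(r) {
    f <- sprintf("%s_rep%d.bedGraph", kind, r)
    read_bedgraph(file.path(data_dir, f), chrom_lengths,
                  library_size = libs$library_size[libs$file == f])
  }))
cons <- lapply(c(tetramer = "tetramer", dimer = "dimer"), function(kind)
  utils::read.table(sprintf("results/consensus_%s.tsv", kind),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE))

uni <- build_union_catalogue(cons$tetramer, cons$dimer,
                             tracks$tetramer, tracks$dimer)
uni <- cfr_rank_and_deciles(uni)
cat("union catalogue:", nrow(uni), "entries -",
    sum(uni$label == "common"), "common,",
    sum(uni$label == "A_specific"), "tetramer-specific,",
    sum(uni$label == "B_specific"), "dimer-specific\n")
cat(sprintf("CFR range: %.2f (strongest) to %.2f (weakest)\n",
            max(uni$cfr), min(uni$cfr)))

pm <- profile_matrices(uni, tracks$tetramer, tracks$dimer)
utils::write.table(uni, "results/union.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
write_union_bed(uni, "results/union.bed")
utils::write.table(round(pm$A, 4), "results/heatmap_tetramer.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
utils::write.table(round(pm$B, 4), "results/heatmap_dimer.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
utils::write.table(data.frame(position = pm$positions,
                              tetramer = pm$mean_A, dimer = pm$mean_B),
                   "results/mean_profiles.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
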