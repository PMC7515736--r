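#!/usr/bin/env Rscript

# Stage 5: model evaluation by AUROC.
#
# Held-out bound regions (consensus peaks excluding the 600 training
# peaks) are scored against an unbound set matched for length, origin
# class (promoter / exon / intron / intergenic) and GC content; the
# AUROC of the best-score-per-region classifier is computed for the
# PWM and the TFFM by the rank statistic.

library(dapcompare)

seed <- as.integer(Sys.getenv("DAPC_SEED", "1"))
genome <- read_fasta("results/data/genome.fa")
genes <- read_gene_models("results/data/genes.tsv")
cons <- utils::read.table("results/consensus_tetramer.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
cons_d <- utils::read.table("results/consensus_dimer.tsv", header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
train <- utils::read.table("results/training_peaks.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
pwm <- model_from_json("results/pwm.json")
tffm <- model_from_json("results/tffm.json")

held <- cons[!paste(cons$chrom, cons$start) %in%
               paste(train$chrom, train$start), ]
if (nrow(held) < 20L) held <- cons
all_peaks <- rbind(cons[, c("chrom", "start", "end")],
                   cons_d[, c("chrom", "start", "end")])
neg <- sample_matched_negatives(held, genome, genes, all_peaks,
                                seed = seed)
pos_seqs <- get_sequences(genome, held)
neg_seqs <- get_sequences(genome, neg)

a_pwm <- compute_auroc(pwm, pos_seqs, neg_seqs)
a_tffm <- compute_auroc(tffm, pos_seqs, neg_seqs)
cat(sprintf("AUROC on %d held-out regions: PWM %.3f, TFFM %.3f\n",
            length(pos_seqs), a_pwm$auroc, a_tffm$auroc))

cmp <- compare_best_scores(tffm, pos_seqs, neg_seqs)
cat(sprintf("bound vs unbound best TFFM scores: t = %.1f, p = %.3g\n",
            cmp$t, cmp$p))

utils::write.table(a_pwm$roc, "results/roc_pwm.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(a_tffm$roc, "results/roc_tffm.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cbind(neg, gc = round(neg$gc, 4)),
                   "results/negatives.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
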