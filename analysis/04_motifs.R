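#!/usr/bin/env Rscript

# Stage 4: binding-site models.
#
# The 600 best tetramer consensus peaks (by mean normalized coverage)
# train a 16-bp quasi-palindromic PWM by seeded ZOOPS-EM, and a
# first-order TFFM (dinucleotide dependencies) by Baum-Welch
# initialised from that PWM.

library(dapcompare)

seed <- as.integer(Sys.getenv("DAPC_SEED", "1"))
genome <- read_fasta("results/data/genome.fa")
cons <- utils::read.table("results/consensus_tetramer.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)

train <- select_training_peaks(cons, genome, n = 600L)
cat("training on", length(train$seqs), "peak sequences\n")

pwm <- train_pwm(train$seqs, W = 16L, palindromic = TRUE, seed = seed)
cat("PWM trained in", length(attr(pwm, "logL")), "EM iterations;",
    sprintf("fitted site probability %.2f\n", attr(pwm, "site_prob")))
cat("PWM consensus:",
    paste(c("A", "C", "G", "T")[apply(pwm$probs, 2, which.max)],
          collapse = ""), "\n")

tffm <- train_tffm(train$seqs, pwm, seed = seed)
cat("TFFM trained in", length(attr(tffm, "logL")),
    "Baum-Welch iterations\n")

model_to_json(pwm, "results/pwm.json")
model_to_json(tffm, "results/tffm.json")
write_meme(pwm, "results/pwm.meme")
utils::write.table(data.frame(chrom = train$peaks$chrom,
                              start = train$peaks$start,
                              end = train$peaks$end),
                   "results/training_peaks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
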