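#!/usr/bin/env Rscript

# Stage 2: consensus peak determination per experiment.
#
# Replicate narrowPeak calls are merged where they overlap; a region
# is kept when at least two replicates support it and the Fisher
# combination of the callers' -log10 p-values passes the 1e-4
# reproducibility cutoff. Regions are split at subpeak summits and
# width-normalized to summit +/- 200 bp, with a mean normalized
# (reads-per-million) coverage over the replicates.

library(dapcompare)

data_dir <- "results/data"
genome <- read_fasta(file.path(data_dir, "genome.fa"))
chrom_lengths <- nchar(genome)
libs <- utils::read.table(file.path(data_dir, "library_sizes.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)

for (kind in c("dimer", "tetramer")) {
  reps <- lapply(1:2, function(r)
    read_narrowpeak(file.path(data_dir,
                              sprintf("%s_rep%d.narrowPeak", kind, r))))
  tracks <- lapply(1:2, function(r) {
    f <- sprintf("%s_rep%d.bedGraph", kind, r)
    read_bedgraph(file.path(data_dir, f), chrom_lengths,
                  library_size = libs$library_size[libs$file == f])
  })
  cons <- consensus_peaks(reps, tracks)
  cat(kind, ":", sum(vapply(reps, nrow, integer(1L))),
      "replicate calls ->", nrow(cons), "consensus peaks; widths all",
      unique(cons$end - cons$start), "bp\n")
  utils::write.table(cons, sprintf("results/consensus_%s.tsv", kind),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_consensus_bed(cons, sprintf("results/consensus_%s.bed", kind))
}
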