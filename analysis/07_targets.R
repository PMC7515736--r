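#!/usr/bin/env Rscript

# Stage 7: bound and regulated target genes.
#
# Each gene's regulatory region spans 3 kb upstream of the TSS to
# 1 kb past the TTS; a gene is bound when any tetramer consensus peak
# overlaps that region by at least 1 bp. The DE table is filtered at
# |logFC| > 1 and FDR < 0.05; bound-and-regulated genes are the
# intersection, with a hypergeometric test for the overlap.

library(dapcompare)

genome <- read_fasta("results/data/genome.fa")
genes <- read_gene_models("results/data/genes.tsv")
cons <- utils::read.table("results/consensus_tetramer.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
de_tab <- utils::read.table("results/data/de_table.tsv", header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)

regions <- regulatory_regions(genes, chrom_lengths = nchar(genome))
bound <- bound_genes(cons, regions)
de <- de_gene_sets(list(de_tab))
targets <- bound_and_regulated(bound, de)
sig <- overlap_significance(bound, de$gene_id, nrow(genes))

cat(length(bound), "of", nrow(genes), "genes bound;",
    nrow(de), "DE genes;", nrow(targets), "bound and regulated\n")
cat(sprintf("hypergeometric overlap: %d genes, -log10(p) = %.1f\n",
            sig$overlap, sig$neg_log10_p))

writeLines(bound, "results/bound_genes.txt")
writeLines(de$gene_id, "results/de_genes.txt")
writeLines(targets$gene_id, "results/target_genes.txt")
venn <- data.frame(set = c("bound_only", "de_only", "bound_and_de"),
                   count = c(length(setdiff(bound, de$gene_id)),
                             length(setdiff(de$gene_id, bound)),
                             sig$overlap))
utils::write.table(venn, "results/venn_counts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
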