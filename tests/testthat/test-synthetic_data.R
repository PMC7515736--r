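test_that("planted pairs have the configured center-to-center spacing", {
  cfg <- synth_config(genome_length = 1e5, n_chrom = 1L,
                      n_single_sites = 0L, n_pair_sites = 10L,
                      n_decoy_sites = 0L,
                      spacings = 46L, spacing_weights = 1,
                      n_genes = 0L, seed = 2L)
  gen <- generate_genome(cfg)
  s <- gen$truth$sites
  expect_equal(nrow(s), 20L)
  for (pid in unique(s$pair_id[!is.na(s$pair_id)])) {
    pp <- s[!is.na(s$pair_id) & s$pair_id == pid, ]
    expect_equal(abs(diff(pp$center)), 46)
  }
  # the planted 16-mers really sit in the genome: they score like sites
  expect_true(all(s$loglr > 0))
})

test_that("generation and simulation are deterministic under the seed", {
  cfg <- synth_config(genome_length = 5e4, n_chrom = 1L,
                      n_single_sites = 10L, n_pair_sites = 5L,
                      n_genes = 20L, seed = 4L)
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$sites, g2$truth$sites)

  e1 <- simulate_experiment(g1$genome, g1$truth, cfg, "tetramer")
  e2 <- simulate_experiment(g2$genome, g2$truth, cfg, "tetramer")
  expect_identical(e1$peaks, e2$peaks)
  expect_identical(e1$tracks, e2$tracks)

  t1 <- assign_regulatory_truth(g1$truth, generate_gene_models(g1$truth))
  t2 <- assign_regulatory_truth(g2$truth, generate_gene_models(g2$truth))
  expect_identical(generate_de_table(t1, cfg), generate_de_table(t2, cfg))
})

test_that("an empty site configuration plants nothing", {
  cfg <- synth_config(genome_length = 5e4, n_chrom = 1L,
                      n_single_sites = 0L, n_pair_sites = 0L,
                      n_decoy_sites = 0L, n_genes = 0L, seed = 6L)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$truth$sites), 0L)
})

test_that("cooperativity raises tetramer over dimer signal only at pairs", {
  cfg <- synth_config(genome_length = 2e5, n_chrom = 1L,
                      n_single_sites = 20L, n_pair_sites = 10L,
                      spacings = 46L, spacing_weights = 1,
                      n_genes = 0L, seed = 9L)
  gen <- generate_genome(cfg)
  di <- simulate_experiment(gen$genome, gen$truth, cfg, "dimer")
  te <- simulate_experiment(gen$genome, gen$truth, cfg, "tetramer")
  # loci tables align (same order); pairs are the rows after singles
  is_pair <- seq_len(nrow(te$loci)) > 20L
  expect_true(all(te$loci$amplitude[is_pair] > di$loci$amplitude[is_pair]))
  expect_equal(te$loci$amplitude[!is_pair], di$loci$amplitude[!is_pair])

  # omega == 1 and no pairs: expected signals identical everywhere
  cfg0 <- synth_config(genome_length = 1e5, n_chrom = 1L,
                       n_single_sites = 15L, n_pair_sites = 0L,
                       omega_amplitude = 0, n_genes = 0L, seed = 9L)
  gen0 <- generate_genome(cfg0)
  d0 <- simulate_experiment(gen0$genome, gen0$truth, cfg0, "dimer")
  t0 <- simulate_experiment(gen0$genome, gen0$truth, cfg0, "tetramer")
  expect_equal(t0$loci$amplitude, d0$loci$amplitude)
})

test_that("replicates share loci but differ in summit under jitter", {
  cfg <- synth_config(genome_length = 1e5, n_chrom = 1L,
                      n_single_sites = 25L, n_pair_sites = 0L,
                      n_noise_peaks = 0L, summit_jitter_sd = 10,
                      n_genes = 0L, seed = 12L)
  gen <- generate_genome(cfg)
  ex <- simulate_experiment(gen$genome, gen$truth, cfg, "dimer")
  p1 <- ex$peaks[[1]]; p2 <- ex$peaks[[2]]
  expect_equal(nrow(p1), nrow(p2))
  s1 <- sort(p1$start + p1$summit_offset)
  s2 <- sort(p2$start + p2$summit_offset)
  expect_true(all(abs(s1 - s2) <= 100))  # same loci
  expect_true(any(s1 != s2))             # jittered summits
})

test_that("DE tables couple to regulatory truth at the configured rates", {
  cfg <- synth_config(genome_length = 4e5, n_chrom = 1L,
                      n_single_sites = 60L, n_pair_sites = 0L,
                      n_genes = 150L, reg_prob = 0.6, seed = 14L)
  gen <- generate_genome(cfg)
  truth <- assign_regulatory_truth(gen$truth, generate_gene_models(gen$truth))
  g <- truth$genes

  de1 <- generate_de_table(truth, cfg, sensitivity = 1, fp_rate = 0)
  pass1 <- abs(de1$logFC) > 1 & de1$FDR < 0.05
  expect_true(all(pass1[g$regulated]))
  expect_false(any(pass1[!g$regulated]))

  # sensitivity 0: only false positives pass, binomially at fp_rate
  fp <- 0.1
  de0 <- generate_de_table(truth, cfg, sensitivity = 0, fp_rate = fp)
  pass0 <- abs(de0$logFC) > 1 & de0$FDR < 0.05
  expect_equal(sum(pass0[g$regulated]), 0L + sum(pass0[g$regulated]))
  n_null <- sum(!g$regulated)
  k <- sum(pass0[!g$regulated])
  # 99.9% binomial band around the expectation
  band <- qbinom(c(5e-4, 1 - 5e-4), n_null, fp)
  expect_gte(k, band[1]); expect_lte(k, band[2])
  expect_equal(sum(pass0[g$regulated]), 0L)
})

test_that("a written dataset round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(genome_length = 5e4, n_chrom = 1L,
                      n_single_sites = 8L, n_pair_sites = 4L,
                      n_decoy_sites = 20L,
                      n_genes = 10L, n_noise_peaks = 2L, seed = 16L)
  obj <- write_synthetic_dataset(dir, cfg)
  expect_true(all(c("single", "pair", "decoy") %in% obj$truth$sites$kind))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, obj$genome)
  pk <- read_narrowpeak(file.path(dir, "tetramer_rep1.narrowPeak"))
  expect_equal(pk$start, obj$tetramer$peaks[[1]]$start)
  tr <- read_bedgraph(file.path(dir, "dimer_rep2.bedGraph"),
                      c(chr1 = nchar(genome[[1]])))
  expect_equal(tr$cov$chr1, obj$dimer$tracks[[2]]$cov$chr1)
  gm <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(gm$gene_id, obj$truth$genes$gene_id)
})
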