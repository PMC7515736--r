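test_that("AUROC degenerate cases and rank/trapezoid agreement", {
  r1 <- compute_auroc(pos_scores = rep(1, 20), neg_scores = rep(0, 20))
  expect_equal(r1$auroc, 1)

  set.seed(71)
  r2 <- compute_auroc(pos_scores = runif(500), neg_scores = runif(500))
  expect_lt(abs(r2$auroc - 0.5), 0.05)

  # rank formula equals trapezoidal integration of the ROC curve
  trapz <- function(roc) {
    sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                           utils::tail(roc$tpr, -1)) / 2)
  }
  for (i in 1:20) {
    ps <- rnorm(40, mean = runif(1, 0, 2))
    ns <- rnorm(60)
    if (runif(1) < 0.5) {  # exercise ties
      ps <- round(ps, 1); ns <- round(ns, 1)
    }
    r <- compute_auroc(pos_scores = ps, neg_scores = ns)
    expect_equal(r$auroc, trapz(r$roc), tolerance = 1e-9)
  }

  # invariance under strictly monotone transforms of the scores
  ps <- runif(100); ns <- runif(80)
  a0 <- compute_auroc(pos_scores = ps, neg_scores = ns)$auroc
  expect_equal(compute_auroc(pos_scores = exp(3 * ps),
                             neg_scores = exp(3 * ns))$auroc, a0)

  expect_error(compute_auroc(pos_scores = numeric(), neg_scores = 1),
               "non-empty")
})

test_that("matched negatives preserve length, origin and GC strata", {
  set.seed(73)
  cfg <- synth_config(genome_length = 3e5, n_chrom = 1L,
                      n_single_sites = 25L, n_pair_sites = 0L,
                      n_genes = 40L, seed = 73L)
  gen <- generate_genome(cfg)
  truth <- assign_regulatory_truth(gen$truth, generate_gene_models(gen$truth))
  ex <- simulate_experiment(gen$genome, truth, cfg, "dimer")
  cons <- consensus_peaks(ex$peaks, ex$tracks)
  pos <- cons[1:15, ]
  neg <- suppressMessages(
    sample_matched_negatives(pos, gen$genome, truth$genes,
                             cons[, c("chrom", "start", "end")],
                             seed = 5L))
  expect_equal(nrow(neg), nrow(pos))
  expect_equal(neg$end - neg$start, pos$end - pos$start)

  # no negative overlaps any peak
  ov <- overlap_pairs(neg, cons)
  expect_equal(nrow(ov), 0L)

  # stratum counts match
  pos_origin <- classify_origin(pos, truth$genes)
  expect_equal(sort(c(table(neg$origin))), sort(c(table(pos_origin))))

  # seed recorded for reproducibility
  expect_equal(attr(neg, "seed"), 5L)
})

test_that("origin classification follows the precedence rule", {
  genes <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                      tss = 10000L, tts = 12000L)
  at <- function(mid) data.frame(chrom = "c", start = mid - 50L,
                                 end = mid + 50L)
  expect_equal(classify_origin(at(11000L), genes), "exon")  # gene body
  expect_equal(classify_origin(at(8000L), genes), "promoter")
  expect_equal(classify_origin(at(2000L), genes), "intergenic")

  # exon table distinguishes introns inside the body
  exons <- data.frame(chrom = "c", start = 10000L, end = 10500L)
  expect_equal(classify_origin(at(10250L), genes, exons = exons), "exon")
  expect_equal(classify_origin(at(11500L), genes, exons = exons), "intron")

  # "-" strand promoter lies beyond the (numerically larger) TSS
  gneg <- data.frame(gene_id = "g2", chrom = "c", strand = "-",
                     tss = 30000L, tts = 28000L)
  expect_equal(classify_origin(at(31000L), gneg), "promoter")
  expect_equal(classify_origin(at(27000L), gneg), "intergenic")
})

test_that("best-score comparison is a Welch test with expected behavior", {
  set.seed(79)
  pwm <- test_pwm(w = 8L)
  x <- planted_sequences(30, 50, pwm)
  same <- compare_best_scores(pwm, x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # clearly shifted score distributions separate decisively
  y <- vapply(1:50, function(i) rand_dna(50, c(.4, .1, .1, .4)),
              character(1L))
  xs <- planted_sequences(50, 50, test_pwm(w = 8L, peak = 0.95))
  shift <- compare_best_scores(test_pwm(w = 8L, peak = 0.95), xs, y)
  expect_lt(shift$p, 1e-6)
  expect_gt(shift$mean_x, shift$mean_y)

  # antisymmetry under swapping the sets
  back <- compare_best_scores(test_pwm(w = 8L, peak = 0.95), y, xs)
  expect_equal(back$t, -shift$t, tolerance = 1e-12)

  expect_error(compare_best_scores(pwm, x[1], x), "at least 2")
})

test_that("gc_fraction counts G+C over ACGT bases only", {
  expect_equal(gc_fraction(c("GGCC", "ATAT", "GCAT", "NNGC")),
               c(1, 0, 0.5, 1))
  expect_true(is.na(gc_fraction("NNNN")))
})
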