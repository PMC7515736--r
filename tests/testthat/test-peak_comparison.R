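cons_row <- function(chrom, summit, cov) {
  data.frame(chrom = chrom, start = summit - 200L, end = summit + 201L,
             summit = summit, mean_norm_cov = cov, support = 2L,
             combined_neg_log10_p = 10, stringsAsFactors = FALSE)
}

test_that("union catalogue applies the geometric commonality rule", {
  trA <- list(const_track(len = 20000L, value = 10))
  trB <- list(const_track(len = 20000L, value = 10))

  # identical peaks collapse into one entry
  u1 <- build_union_catalogue(cons_row("chr1", 1000L, 5),
                              cons_row("chr1", 1000L, 4), trA, trB)
  expect_equal(nrow(u1), 1L)

  # 300-bp offset: overlap 101/401 (~25%) -> two new-peak entries
  u2 <- build_union_catalogue(cons_row("chr1", 1000L, 5),
                              cons_row("chr1", 1300L, 4), trA, trB)
  expect_equal(nrow(u2), 2L)

  # A-only peak still gets cov_B measured over its window
  u3 <- build_union_catalogue(cons_row("chr1", 1000L, 5),
                              cons_row("chr1", 9000L, 4)[0, ], trA, trB)
  expect_equal(nrow(u3), 1L)
  expect_equal(u3$cov_B, 10)
})

test_that("specificity classification uses the fold threshold", {
  expect_equal(classify(10, 4), "A_specific")   # ratio 2.5
  expect_equal(classify(10, 6), "common")
  expect_equal(classify(4, 10), "B_specific")
  expect_equal(classify(10, 5), "A_specific")   # boundary: exactly 2-fold
  expect_warning(lab <- classify(0, 0), "zero coverage")
  expect_equal(lab, "common")
})

test_that("CFR ranking and deciles partition entries deterministically", {
  set.seed(5)
  n <- 20L
  ent <- data.frame(chrom = "chr1", start = seq(0L, by = 500L, length.out = n),
                    end = seq(401L, by = 500L, length.out = n),
                    summit = seq(200L, by = 500L, length.out = n),
                    cov_A = runif(n, 1, 9), cov_B = runif(n, 1, 9),
                    label = "common", stringsAsFactors = FALSE)
  ent$cfr <- ent$cov_A / ent$cov_B
  r <- cfr_rank_and_deciles(ent)
  expect_equal(as.integer(table(r$decile)), rep(2L, 10L))
  expect_equal(r$cfr[1], max(ent$cfr))
  expect_true(all(diff(r$cfr) <= 0))

  # all-equal CFRs: stable coordinate order
  ent$cfr <- 1
  r2 <- cfr_rank_and_deciles(ent)
  expect_equal(r2$start, sort(ent$start))

  # explicit pair: (8,2) -> 4 ranks before (2,8) -> 0.25
  e2 <- ent[1:2, ]
  e2$cov_A <- c(8, 2); e2$cov_B <- c(2, 8); e2$cfr <- c(4, 0.25)
  expect_warning(r3 <- cfr_rank_and_deciles(e2), "fewer entries")
  expect_equal(r3$cfr, c(4, 0.25))
})

test_that("labels partition the catalogue and A<->B swap inverts the CFR", {
  cfg <- synth_config(genome_length = 2e5, n_chrom = 1L,
                      n_single_sites = 30L, n_pair_sites = 15L,
                      n_genes = 0L, seed = 8L)
  gen <- generate_genome(cfg)
  di <- simulate_experiment(gen$genome, gen$truth, cfg, "dimer")
  te <- simulate_experiment(gen$genome, gen$truth, cfg, "tetramer")
  consD <- consensus_peaks(di$peaks, di$tracks)
  consT <- consensus_peaks(te$peaks, te$tracks)

  u_td <- build_union_catalogue(consT, consD, te$tracks, di$tracks)
  u_dt <- build_union_catalogue(consD, consT, di$tracks, te$tracks)

  expect_equal(sum(u_td$label == "common") +
                 sum(u_td$label == "A_specific") +
                 sum(u_td$label == "B_specific"), nrow(u_td))

  # same entries in both orientations; CFR inverts, labels swap
  key_td <- paste(u_td$chrom, u_td$start)
  key_dt <- paste(u_dt$chrom, u_dt$start)
  expect_setequal(key_td, key_dt)
  m <- match(key_td, key_dt)
  expect_equal(u_td$cfr, 1 / u_dt$cfr[m], tolerance = 1e-12)
  swap <- c(common = "common", A_specific = "B_specific",
            B_specific = "A_specific")
  expect_equal(unname(swap[u_td$label]), u_dt$label[m])
})

test_that("profile matrices are RPM-scaled and summit-centered", {
  trA <- list(const_track(len = 20000L, value = 7, lib = 1e6))
  trB <- list(const_track(len = 20000L, value = 7, lib = 2e6))
  ent <- cons_row("chr1", 1000L, 5)
  ent$cov_A <- 7; ent$cov_B <- 3.5; ent$label <- "common"; ent$cfr <- 2
  pm <- profile_matrices(ent, trA, trB, window = 1000L)
  expect_equal(dim(pm$A), c(1L, 1000L))
  expect_true(all(pm$A == 7))
  expect_true(all(pm$B == 3.5))    # doubled library halves RPM
  expect_equal(pm$mean_A, pm$A[1, ])  # single entry: mean equals the row
  expect_equal(pm$positions[1], -500L)
})
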