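test_that("site scores follow the normalized likelihood-ratio form", {
  # uniform PWM: LR = 1 at every window -> s = 0.5 exactly
  uni <- pwm_model(matrix(0.25, 4, 6))
  expect_equal(score_site(uni, "ACGTAC"), 0.5)

  # near-consensus window under a sharp model -> s close to 1;
  # anti-consensus -> close to 0
  pwm <- test_pwm(w = 8L, peak = 0.97)
  cons <- paste(BASES4[apply(pwm$probs, 2, which.max)], collapse = "")
  expect_gt(score_site(pwm, cons, "+"), 0.999)
  anti <- chartr("ACGT", "GTAC", cons)
  expect_lt(score_site(pwm, anti, "+"), 0.01)

  # windows containing N score 0
  expect_equal(score_site(pwm, paste0("N", substr(cons, 2, 8))), 0)
})

test_that("PWM scores match an independent per-position product oracle", {
  set.seed(31)
  for (i in 1:40) {
    w <- sample(4:12, 1)
    probs <- matrix(rgamma(4 * w, 1) + 0.01, 4, w)
    probs <- sweep(probs, 2, colSums(probs), "/")
    bg <- rgamma(4, 1) + 0.1; bg <- bg / sum(bg)
    m <- pwm_model(probs, bg)
    win <- rand_dna(w)
    idx <- match(strsplit(win, "")[[1]], BASES4)
    lr <- prod(probs[cbind(idx, seq_len(w))]) / prod(bg[idx])
    expect_equal(score_site(m, win, "+"), lr / (1 + lr),
                 tolerance = 1e-12)
  }
})

test_that("region scanning finds planted sites and matches a rescan oracle", {
  set.seed(37)
  pwm <- test_pwm(w = 8L, peak = 0.9)
  cons <- paste(BASES4[apply(pwm$probs, 2, which.max)], collapse = "")

  reg <- paste0(rand_dna(40, c(.4, .1, .1, .4)), cons,
                rand_dna(40, c(.4, .1, .1, .4)))
  sc <- scan_region(pwm, reg, threshold = 0.95)
  expect_equal(sc$hits$offset[which.max(sc$hits$score)], 40L)

  expect_equal(nrow(scan_region(pwm, reg, threshold = 1)$hits), 0L)

  expect_warning(empty <- scan_region(pwm, "ACGT", 0.5), "shorter")
  expect_equal(nrow(empty$hits), 0L)

  # hit count oracle: per-offset strand-max via score_site
  for (i in 1:50) {
    L <- sample(20:80, 1)
    reg <- rand_dna(L)
    th <- runif(1, 0.4, 0.9)
    oracle <- sum(vapply(0:(L - 8L), function(off)
      score_site(pwm, substr(reg, off + 1L, off + 8L), "both") >= th,
      logical(1L)))
    expect_equal(nrow(scan_region(pwm, reg, th)$hits), oracle)
  }
})

test_that("scores are invariant under reverse complement of the region", {
  set.seed(41)
  pwm <- test_pwm(w = 8L)
  tffm <- train_tffm(planted_sequences(40, 40, pwm), pwm, seed = 1,
                     trim_context = Inf)
  for (i in 1:10) {
    reg <- rand_dna(60)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(reg, "")[[1]]), collapse = ""))
    expect_equal(best_scores(pwm, reg), best_scores(pwm, rc),
                 tolerance = 1e-12)
    expect_equal(best_scores(tffm, reg), best_scores(tffm, rc),
                 tolerance = 1e-12)
  }
})

test_that("ZOOPS EM converges on degenerate and sampled training data", {
  set.seed(43)
  # 100 sequences embedding the identical 16-mer: every planted base
  # reaches probability ~1
  site <- "ACGTTGCAACGTGGCA"
  seqs <- vapply(1:100, function(i) {
    s <- rand_dna(60)
    pos <- sample.int(45, 1)
    paste0(substr(s, 1, pos - 1), site, substr(s, pos + 16, 60))
  }, character(1))
  m <- train_pwm(seqs, W = 16, palindromic = FALSE, seed = 1)
  idx <- match(strsplit(site, "")[[1]], BASES4)
  rc_site <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(site, "")[[1]]), collapse = ""))
  idx_rc <- match(strsplit(rc_site, "")[[1]], BASES4)
  # the learned orientation is arbitrary on double-stranded data
  expect_true(all(m$probs[cbind(idx, 1:16)] >= 0.99) ||
                all(m$probs[cbind(idx_rc, 1:16)] >= 0.99))

  # palindromic mode: output equals its own reverse complement exactly
  mp <- train_pwm(seqs, W = 16, palindromic = TRUE, seed = 1)
  expect_equal(unname(mp$probs), unname(mp$probs[4:1, 16:1]),
               tolerance = 1e-12)

  # ZOOPS-stage likelihood is non-decreasing
  expect_true(all(diff(attr(m, "logL")) > -1e-6))
})

test_that("PWM training recovers a known motif from sampled sites", {
  set.seed(47)
  truth <- recovery_truth()
  seqs <- planted_sequences(500, 101, truth)
  m <- train_pwm(seqs, W = 16, palindromic = FALSE, seed = 1)
  expect_lt(pwm_error(m, truth), 0.05)
})

test_that("TFFM training recovers emission structure", {
  set.seed(53)
  maxb <- sample(1:4, 16, replace = TRUE)
  cols <- vapply(1:16, function(k) {
    p <- rep(0.25 / 3, 4); p[maxb[k]] <- 0.75; p
  }, numeric(4L))
  truth0 <- pwm_model(cols)

  plant_fo <- function(n, dep = NULL, colmat = cols) {
    vapply(seq_len(n), function(i) {
      x <- integer(16); x[1] <- sample(1:4, 1, prob = colmat[, 1])
      for (k in 2:16) {
        x[k] <- if (!is.null(dep) && k == 9)
          sample(1:4, 1, prob = dep[x[8], ])
        else sample(1:4, 1, prob = colmat[, k])
      }
      site <- paste(BASES4[x], collapse = "")
      s <- rand_dna(61)
      pos <- sample.int(61 - 16 + 1, 1)
      paste0(substr(s, 1, pos - 1), site, substr(s, pos + 16, 61))
    }, character(1L))
  }

  # 0-order truth: learned conditional rows carry no dinucleotide
  # signal (occupancy-weighted TV against the position marginal)
  seqs0 <- plant_fo(2000)
  tf0 <- train_tffm(seqs0, truth0, seed = 1, orient = FALSE,
                    trim_context = Inf)
  wtv <- vapply(1:15, function(k) {
    tr <- tf0$trans[, , k]; w <- truth0$probs[, k]
    marg <- colSums(tr * w)
    sum(w * vapply(1:4, function(p) sum(abs(tr[p, ] - marg)) / 2,
                   numeric(1L)))
  }, numeric(1L))
  expect_lt(max(wtv), 0.05)

  # strong first-order dependency at one position is recovered
  dep <- matrix(0.1, 4, 4); diag(dep) <- 0.7
  cols2 <- cols; cols2[, 8] <- c(0.3, 0.25, 0.25, 0.2)
  tf1 <- train_tffm(plant_fo(2000, dep = dep, colmat = cols2),
                    pwm_model(cols2), seed = 1, orient = FALSE,
                    trim_context = Inf)
  tv_dep <- max(apply(tf1$trans[, , 8] - dep, 1,
                      function(r) sum(abs(r)) / 2))
  expect_lt(tv_dep, 0.1)

  # Baum-Welch likelihood is non-decreasing
  expect_true(all(diff(attr(tf0, "logL")) > -1e-6))
  expect_true(all(diff(attr(tf1, "logL")) > -1e-6))

  # determinism under a fixed seed (same data, same seed)
  tf0b <- train_tffm(seqs0, truth0, seed = 1, orient = FALSE,
                     trim_context = Inf)
  expect_identical(tf0$trans, tf0b$trans)
})

test_that("models serialize to JSON and MEME formats faithfully", {
  set.seed(59)
  pwm <- test_pwm(w = 6L)
  f <- withr::local_tempfile(fileext = ".json")
  model_to_json(pwm, f)
  back <- model_from_json(f)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-15)
  expect_equal(unname(back$background), unname(pwm$background))

  tffm <- train_tffm(planted_sequences(30, 30, pwm), pwm, seed = 1,
                     trim_context = Inf)
  f2 <- withr::local_tempfile(fileext = ".json")
  model_to_json(tffm, f2)
  back2 <- model_from_json(f2)
  expect_equal(back2$trans, tffm$trans, tolerance = 1e-15)
  expect_equal(score_site(back2, "ACGTAC"), score_site(tffm, "ACGTAC"))

  f3 <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwm, f3)
  lines <- readLines(f3)
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 6",
                        lines)))
  mat <- do.call(rbind, lapply(strsplit(utils::tail(lines, 6), " "),
                               as.numeric))
  expect_equal(t(mat), unname(pwm$probs), tolerance = 1e-6)
})

test_that("training selects the requested top-coverage peaks", {
  set.seed(61)
  n <- 30L
  cons <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 500L, length.out = n),
                     end = seq(401L, by = 500L, length.out = n),
                     summit = seq(200L, by = 500L, length.out = n),
                     mean_norm_cov = runif(n), stringsAsFactors = FALSE)
  genome <- c(chr1 = rand_dna(20000L))
  sel <- select_training_peaks(cons, genome, n = 10L)
  expect_equal(nrow(sel$peaks), 10L)
  expect_equal(sel$peaks$mean_norm_cov,
               sort(cons$mean_norm_cov, decreasing = TRUE)[1:10])
  expect_equal(nchar(sel$seqs), rep(401L, 10L))

  expect_warning(all30 <- select_training_peaks(cons, genome, n = 600L),
                 "only 30")
  expect_equal(nrow(all30$peaks), 30L)

  # deterministic tie-break by coordinate
  cons$mean_norm_cov <- 1
  s1 <- select_training_peaks(cons, genome, n = 5L)
  s2 <- select_training_peaks(cons, genome, n = 5L)
  expect_identical(s1$peaks, s2$peaks)
  expect_equal(s1$peaks$start, cons$start[1:5])

  expect_error(select_training_peaks(cons, NULL, 5L), "genome")
})
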