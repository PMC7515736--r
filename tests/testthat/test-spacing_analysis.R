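# consensus W-mer of a PWM (argmax per column)
consensus_of <- function(pwm) {
  paste(BASES4[apply(pwm$probs, 2, which.max)], collapse = "")
}

# build a region with sites of `pwm` planted at given 0-based center
# positions, on a fixed low-GC background that cannot score
region_with_sites <- function(centers, pwm, L = 200L) {
  s <- strsplit(paste(rep("ACAC", ceiling(L / 4)), collapse = ""), "")[[1]][1:L]
  site <- strsplit(consensus_of(pwm), "")[[1]]
  w <- pwm$W
  for (ctr in centers) {
    st <- ctr - (w - 1) / 2  # 0-based start
    s[(st + 1):(st + w)] <- site
  }
  paste(s, collapse = "")
}

test_that("pair spacing counts measure center-to-center distances", {
  pwm <- test_pwm(w = 8L)
  # sites centered at 50.5, 96.5, 107.5 -> pairwise spacings 46, 57, 11
  reg <- region_with_sites(c(50.5, 96.5, 107.5), pwm)
  C <- pair_spacing_counts(reg, pwm, threshold = 0.99, s_max = 100L)
  expect_equal(unname(C[c("46", "57", "11")]), c(1L, 1L, 1L))
  expect_equal(sum(C), 3L)

  # no region with two hits -> all zero
  C0 <- pair_spacing_counts(region_with_sites(50.5, pwm), pwm,
                            threshold = 0.99)
  expect_equal(sum(C0), 0L)
})

test_that("spacing counts equal a brute-force double-loop oracle", {
  set.seed(17)
  pwm <- test_pwm(w = 8L)
  th <- 0.8
  s_max <- 60L
  for (i in 1:50) {
    L <- sample(60:180, 1)
    reg <- rand_dna(L, prob = c(0.3, 0.2, 0.2, 0.3))
    if (runif(1) < 0.7) {  # plant 1-3 sites to make hits likely
      for (j in seq_len(sample(1:3, 1))) {
        st <- sample.int(L - 8L, 1L)
        substr(reg, st, st + 7L) <- consensus_of(pwm)
      }
    }
    # oracle: exhaustive double loop over per-offset strand-max scores
    scores <- vapply(0:(L - 8L), function(off) {
      win <- substr(reg, off + 1L, off + 8L)
      score_site(pwm, win, "both")
    }, numeric(1L))
    hits <- which(scores >= th) - 1L
    oracle <- integer(s_max + 1L)
    if (length(hits) >= 2L) {
      for (a in 1:(length(hits) - 1L)) {
        for (b in (a + 1L):length(hits)) {
          d <- abs(hits[b] - hits[a])  # equal widths: center == offset delta
          if (d <= s_max) oracle[d + 1L] <- oracle[d + 1L] + 1L
        }
      }
    }
    C <- pair_spacing_counts(reg, pwm, threshold = th, s_max = s_max)
    expect_equal(unname(C), oracle)
  }
})

test_that("frequencies normalize and enrichment is a frequency ratio", {
  C <- integer(101); C[c(40, 46, 57) + 1L] <- c(2L, 6L, 2L)
  f <- spacing_frequency(C)
  expect_equal(unname(f[47]), 0.6)
  expect_equal(sum(f), 1)

  C1 <- integer(101); C1[11] <- 5L
  expect_equal(unname(spacing_frequency(C1)[11]), 1)
  expect_error(spacing_frequency(integer(101)), "undefined")

  f_pos <- c(0.6, 0.4); f_neg <- c(0.2, 0.8)
  expect_equal(normalized_enrichment(f_pos, f_neg), c(3, 0.5))
  expect_equal(normalized_enrichment(f_pos, f_pos), c(1, 1))
  expect_message(N <- normalized_enrichment(c(0.5, 0.5), c(0, 1)),
                 "undefined")
  expect_true(is.na(N[1]))
})

test_that("removing regions never increases any spacing count", {
  set.seed(23)
  pwm <- test_pwm(w = 8L)
  regs <- vapply(1:12, function(i)
    region_with_sites(sort(sample(seq(20.5, 170.5, by = 1), 3)), pwm),
    character(1L))
  C_all <- pair_spacing_counts(regs, pwm, threshold = 0.9)
  C_sub <- pair_spacing_counts(regs[1:6], pwm, threshold = 0.9)
  expect_true(all(C_sub <= C_all))
})

test_that("KNU probe annotation reproduces the printed spacings", {
  probes <- knu_probes()
  ann <- annotate_probe(probes[["WT"]], knu_patterns)
  expect_equal(nchar(probes[["WT"]]), 96L)
  d <- ann$distances
  expect_equal(sort(d$distance[d$from == "strong" | d$to == "strong"]),
               c(45, 46))

  wt_d <- sort(d$distance[d$from == "strong" | d$to == "strong"])
  for (nm in c(minus5 = "minus5", minus10 = "minus10",
               plus5 = "plus5", plus10 = "plus10")) {
    delta <- c(minus5 = -5, minus10 = -10, plus5 = 5, plus10 = 10)[[nm]]
    dd <- annotate_probe(probes[[nm]], knu_patterns)$distances
    got <- sort(dd$distance[dd$from == "strong" | dd$to == "strong"])
    expect_equal(got, wt_d + delta)
  }

  # absent pattern: empty annotation, not an error
  none <- annotate_probe(probes[["WT"]], c(x = "GGGGGGGGGG"))
  expect_equal(nrow(none$boxes), 0L)

  # reverse-complement symmetry of the distance multiset
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(probes[["WT"]],
                                                  "")[[1]]), collapse = ""))
  rc_pat <- vapply(knu_patterns, function(p)
    chartr("ACGT", "TGCA", paste(rev(strsplit(p, "")[[1]]), collapse = "")),
    character(1L))
  ann_rc <- annotate_probe(rc, rc_pat)
  expect_setequal(ann_rc$distances$distance, ann$distances$distance)
})
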