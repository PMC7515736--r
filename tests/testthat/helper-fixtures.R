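# shared fixture builders; everything is generated in code

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(L, prob = rep(0.25, 4)) {
  paste(sample(BASES4, L, replace = TRUE, prob = prob), collapse = "")
}

# a strongly informative asymmetric test PWM of width w; the consensus
# is aperiodic and dissimilar from its own reverse complement, so
# shifted or opposite-strand self-matches cannot occur
test_pwm <- function(w = 8L, peak = 0.85) {
  consensus <- substr("ACGGTCATTGACCGTA", 1L, w)
  idx <- match(strsplit(consensus, "")[[1]], BASES4)
  cols <- vapply(idx, function(b) {
    p <- rep((1 - peak) / 3, 4L)
    p[b] <- peak
    p
  }, numeric(4L))
  pwm_model(cols)
}

# palindrome-free recovery truth of width 16: sharp columns make the
# 0.05 column-recovery requirement statistically comfortable at
# n = 500 (max-abs error across 64 cells is noise-limited), and the
# informative, asymmetric consensus identifies phase and orientation.
# The weak-column palindromic regime is covered by the CArG fixtures,
# where the palindrome constraint pins the phase.
recovery_truth <- function(peak = 0.9) {
  consensus <- "TACGGTCATTGACCGA"
  idx <- match(strsplit(consensus, "")[[1]], BASES4)
  cols <- vapply(idx, function(b) {
    p <- rep((1 - peak) / 3, 4L); p[b] <- peak; p
  }, numeric(4L))
  pwm_model(cols)
}

# orientation-resolved model-vs-truth column error: a motif learned on
# both strands is defined up to reverse complement
pwm_error <- function(model, truth) {
  min(max(abs(model$probs - truth$probs)),
      max(abs(model$probs[4:1, rev(seq_len(ncol(model$probs)))] -
                truth$probs)))
}

sample_from_pwm <- function(pwm) {
  paste(apply(pwm$probs, 2, function(p) sample(BASES4, 1, prob = p)),
        collapse = "")
}

# plant one site per sequence at a random position and strand
planted_sequences <- function(n, L, pwm, forward_only = FALSE) {
  vapply(seq_len(n), function(i) {
    s <- rand_dna(L)
    site <- sample_from_pwm(pwm)
    if (!forward_only && runif(1) < 0.5) {
      site <- paste(rev(chartr("ACGT", "TGCA",
                               strsplit(site, "")[[1]])), collapse = "")
    }
    pos <- sample.int(L - pwm$W + 1L, 1L)
    paste0(substr(s, 1, pos - 1), site, substr(s, pos + pwm$W, L))
  }, character(1L))
}

# constant-coverage track over one chromosome
const_track <- function(len = 10000L, value = 10, lib = 1e6,
                        chrom = "chr1") {
  cov <- list(rep(value, len)); names(cov) <- chrom
  coverage_track(cov, lib)
}

# minimal narrowPeak-style data.frame
peak_df <- function(chrom, start, end, neg_log10_p = 6,
                    summit_offset = (end - start) %/% 2L) {
  data.frame(chrom = chrom, start = start, end = end,
             name = paste0("p", seq_along(start)), score = 100,
             strand = ".", signal = 5, neg_log10_p = neg_log10_p,
             neg_log10_q = pmax(0, neg_log10_p - 1),
             summit_offset = summit_offset, stringsAsFactors = FALSE)
}

knu_probes <- function() {
  read_fasta(system.file("extdata", "knu_probes.fa",
                         package = "dapcompare"))
}

knu_patterns <- c(strong = "CCATGTTTGG", weak1 = "TCTTCTTTGT",
                  weak2 = "CTTCTTTGTG")
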