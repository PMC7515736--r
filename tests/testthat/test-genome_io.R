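test_that("narrowPeak fields map to called peaks and round-trip", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t501\tp1\t50\t.\t4.2\t6.0\t5.1\t200", f)
  pk <- read_narrowpeak(f)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 501L)
  expect_equal(pk$summit_offset, 200L)
  expect_equal(pk$neg_log10_p, 6)

  # round trip preserves every record
  set.seed(1)
  many <- peak_df("chr2", c(0L, 600L, 1200L), c(401L, 1001L, 1601L),
                  neg_log10_p = c(3.25, 7.5, 12.125))
  f2 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(many, f2)
  expect_equal(read_narrowpeak(f2), many)
})

test_that("narrowPeak parsing rejects malformed input and fixes -1 summits", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t501\tp1\t50\t.\t4.2\t6.0\t5.1\t200",
               "chr1\t100\t501\tp2\t50\t.\t4.2"), f)
  expect_error(read_narrowpeak(f), "line 2")

  writeLines("chr1\t500\t100\tp1\t50\t.\t4.2\t6.0\t5.1\t10", f)
  expect_error(read_narrowpeak(f), "start >= end")

  writeLines("chr1\t100\t501\tp1\t50\t.\t4.2\t6.0\t5.1\t-1", f)
  expect_warning(pk <- read_narrowpeak(f), "midpoint")
  expect_equal(pk$summit_offset, 200L)

  f0 <- withr::local_tempfile(fileext = ".narrowPeak")
  file.create(f0)
  expect_equal(nrow(read_narrowpeak(f0)), 0L)
})

test_that("FASTA reading uppercases, keeps N, and validates headers", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgT"), f)
  expect_equal(read_fasta(f), c(c1 = "ACGT"))

  writeLines(c(">c1", "ACGN", ">c2 description", "ttRa"), f)
  g <- read_fasta(f)
  expect_equal(length(g), 2L)
  expect_equal(g[["c1"]], "ACGN")   # N preserved
  expect_equal(g[["c2"]], "TTNA")   # non-ACGT letter becomes N

  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate")

  g2 <- c(chrA = "ACGTACGTNN", chrB = "TTTT")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g2, f2)
  expect_equal(read_fasta(f2), g2)
})

test_that("overlap fractions follow the geometric definition", {
  a <- data.frame(chrom = "c", start = 0L, end = 100L)
  b <- data.frame(chrom = "c", start = 50L, end = 150L)
  expect_equal(unname(overlap_fraction(a, b)[1, ]), c(0.5, 0.5))

  b2 <- data.frame(chrom = "c", start = 10L, end = 110L)
  expect_equal(unname(overlap_fraction(a, b2)[1, ]), c(0.9, 0.9))

  b3 <- data.frame(chrom = "c", start = 200L, end = 300L)
  expect_equal(unname(overlap_fraction(a, b3)[1, ]), c(0, 0))

  b4 <- data.frame(chrom = "other", start = 0L, end = 100L)
  expect_equal(unname(overlap_fraction(a, b4)[1, ]), c(0, 0))

  # symmetry under argument swap (components exchanged)
  set.seed(42)
  for (i in 1:20) {
    x <- data.frame(chrom = "c", start = s1 <- sample(0:50, 1),
                    end = s1 + sample(10:100, 1))
    y <- data.frame(chrom = "c", start = s2 <- sample(0:50, 1),
                    end = s2 + sample(10:100, 1))
    expect_equal(unname(overlap_fraction(x, y)[1, ]),
                 unname(rev(overlap_fraction(y, x)[1, ])))
  }
})

test_that("reciprocal matching reproduces -f/-F/-e semantics", {
  A <- data.frame(chrom = "c", start = 0L, end = 100L)
  B <- data.frame(chrom = "c", start = 10L, end = 110L)
  expect_equal(nrow(reciprocal_match(A, B, 0.8, "either")), 1L)

  A2 <- data.frame(chrom = "c", start = 0L, end = 1000L)
  B2 <- data.frame(chrom = "c", start = 0L, end = 100L)
  expect_equal(nrow(reciprocal_match(A2, B2, 0.8, "either")), 1L)  # via B
  expect_equal(nrow(reciprocal_match(A2, B2, 0.8, "both")), 0L)

  expect_error(reciprocal_match(A, B, 1.5), "in \\(0, 1\\]")

  # role-swap property: either-mode match set is symmetric
  set.seed(7)
  X <- data.frame(chrom = "c", start = st <- sample(0:500, 15),
                  end = st + sample(50:200, 15, replace = TRUE))
  Y <- data.frame(chrom = "c", start = st2 <- sample(0:500, 15),
                  end = st2 + sample(50:200, 15, replace = TRUE))
  mx <- reciprocal_match(X, Y, 0.6, "either")
  my <- reciprocal_match(Y, X, 0.6, "either")
  expect_setequal(paste(mx$i_a, mx$i_b), paste(my$i_b, my$i_a))
})

test_that("bedGraph round-trips through coverage tracks", {
  cov <- list(chr1 = c(0, 0, 3, 3, 3, 1.5, 0, 2, 2, 0))
  tr <- coverage_track(cov, library_size = 1e6)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  tr2 <- read_bedgraph(f, c(chr1 = 10L), library_size = 1e6)
  expect_equal(tr2$cov, tr$cov)

  # RPM scaling and zero-fill outside the chromosome
  expect_equal(track_slice(tr, "chr1", 2L, 5L, rpm = TRUE), rep(3, 3))
  expect_equal(track_slice(tr, "chr1", 8L, 12L, rpm = FALSE),
               c(2, 0, 0, 0))
})

test_that("gene models convert between native TSV and GFF3", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = c("c1", "c1"),
                  strand = c("+", "-"), tss = c(100L, 900L),
                  tts = c(500L, 600L), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(g, f)
  expect_equal(read_gene_models(f), g)

  f3 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t101\t501\t.\t+\t.\tID=g1",
               "c1\tsrc\tmRNA\t101\t501\t.\t+\t.\tID=m1;Parent=g1",
               "c1\tsrc\tgene\t601\t901\t.\t-\t.\tID=g2"), f3)
  g3 <- read_gene_models(f3, format = "gff3")
  expect_equal(g3$tss, c(100L, 900L))   # 1-based converted at boundary
  expect_equal(g3$tts, c(500L, 600L))

  bad <- g; bad$tss[1] <- 600L
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(bad, f4)
  expect_error(read_gene_models(f4), "TSS/TTS")
})
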