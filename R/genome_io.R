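# Coordinate convention: all internal coordinates are 0-based half-open
# [start, end); narrowPeak/BED/bedGraph are read and written natively in
# that convention. Gene tables may arrive 1-based (GFF-like) and are
# converted once at the read boundary. Chromosome names pass through
# verbatim (no "chr" normalisation).

#' Validate a set of genomic intervals
#'
#' Checks the 0-based half-open interval invariants (`0 <= start < end`)
#' on a data frame carrying `chrom`, `start` and `end` columns.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("%s: invalid interval(s) at row(s) %s (need 0 <= start < end)",
                 what, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  invisible(x)
}

#' Read MACS2-style narrowPeak files
#'
#' Parses the ENCODE narrowPeak 10-column format into a data frame of
#' called peaks. Column 8 is interpreted as -log10 p-value and column 10
#' as the summit offset from the peak start; a summit offset of -1
#' (summit not reported) is replaced by the interval midpoint with a
#' warning.
#'
#' @param path path to a narrowPeak file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `neg_log10_p`, `neg_log10_q`,
#'   `summit_offset`, in file order.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "neg_log10_p", "neg_log10_q", "summit_offset")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      signal = numeric(), neg_log10_p = numeric(),
                      neg_log10_q = numeric(), summit_offset = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  nf <- utils::count.fields(path, sep = "", quote = "", comment.char = "")
  bad <- which(nf != 10L)
  if (length(bad)) {
    stop(sprintf("narrowPeak parse error: line %d has %d columns (expected 10)",
                 bad[1L], nf[bad[1L]]))
  }
  x <- utils::read.table(path, sep = "", quote = "", comment.char = "",
                         col.names = cols,
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character",
                                        "numeric", "numeric", "numeric",
                                        "integer"),
                         stringsAsFactors = FALSE)
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("narrowPeak rejected record: line %d has start >= end", bad[1L]))
  }
  if (any(x$neg_log10_p < 0)) stop("narrowPeak: negative -log10 p-value")
  miss <- x$summit_offset < 0L
  if (any(miss)) {
    warning(sprintf("%d peak(s) without summit (-1); using interval midpoint",
                    sum(miss)))
    x$summit_offset[miss] <- as.integer((x$end[miss] - x$start[miss]) %/% 2L)
  }
  out_of_range <- x$summit_offset >= (x$end - x$start)
  if (any(out_of_range)) {
    stop(sprintf("narrowPeak rejected record: line %d summit offset outside peak",
                 which(out_of_range)[1L]))
  }
  x
}

#' Write peaks in narrowPeak format
#'
#' Inverse of [read_narrowpeak()]; a read -> write -> read cycle
#' reproduces identical records (numeric columns are formatted with
#' enough digits to round-trip).
#'
#' @param peaks data.frame as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks, "narrowPeak")
  fmt_num <- function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    sub("(\\.\\d*?)0+$", "\\1", s)
  }
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
                 fmt_num(peaks$score), peaks$strand, fmt_num(peaks$signal),
                 fmt_num(peaks$neg_log10_p), fmt_num(peaks$neg_log10_q),
                 peaks$summit_offset, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' Sequences are upper-cased; any letter outside A/C/G/T becomes N.
#' Headers are truncated at the first whitespace and must be unique.
#'
#' @param path FASTA file.
#' @return named character vector, one uppercase string per sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA header: ",
                              nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) stop("empty sequence for header: ",
                                   nm[nchar(seqs) == 0L][1L])
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a bedGraph coverage file into a coverage track
#'
#' A coverage track is a list with elements `cov` (named list of
#' per-chromosome per-bp numeric vectors, raw read coverage) and
#' `library_size` (total mapped reads used for reads-per-million
#' scaling). When `library_size` is not supplied it defaults to the sum
#' of the per-bp coverage.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param library_size total mapped reads; `NULL` to infer.
#' @return a coverage track list.
#' @export
read_bedgraph <- function(path, chrom_lengths, library_size = NULL) {
  x <- utils::read.table(path, sep = "", quote = "", comment.char = "#",
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"),
                         stringsAsFactors = FALSE)
  validate_intervals(x, "bedGraph")
  if (any(x$value < 0)) stop("bedGraph: negative coverage")
  cov <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    xx <- x[x$chrom == ch, , drop = FALSE]
    if (nrow(xx)) {
      if (any(xx$end > chrom_lengths[[ch]]))
        stop("bedGraph interval beyond chromosome end on ", ch)
      for (i in seq_len(nrow(xx))) {
        v[(xx$start[i] + 1L):xx$end[i]] <- xx$value[i]
      }
    }
    v
  })
  names(cov) <- names(chrom_lengths)
  coverage_track(cov, library_size)
}

#' Construct a coverage track
#'
#' @param cov named list of per-chromosome numeric coverage vectors.
#' @param library_size total mapped reads; `NULL` to use `sum(cov)`.
#' @return coverage track list with class `coverage_track`.
#' @export
coverage_track <- function(cov, library_size = NULL) {
  stopifnot(is.list(cov), !is.null(names(cov)))
  if (any(vapply(cov, function(v) any(v < 0), logical(1L))))
    stop("coverage must be non-negative")
  if (is.null(library_size)) library_size <- sum(vapply(cov, sum, numeric(1L)))
  if (library_size <= 0) stop("library_size must be > 0")
  structure(list(cov = cov, library_size = library_size),
            class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed; zero-coverage runs are omitted.
#'
#' @param track coverage track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- rle(track$cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(paste(ch, starts[keep], ends[keep],
                       format(r$values[keep], digits = 15, scientific = FALSE,
                              trim = TRUE), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Extract per-bp coverage over a window
#'
#' Positions outside the chromosome are zero-filled so the result always
#' has `end - start` entries.
#'
#' @param track coverage track.
#' @param chrom chromosome name.
#' @param start,end window, 0-based half-open.
#' @param rpm scale to reads-per-million by `library_size`?
#' @return numeric vector of length `end - start`.
#' @export
track_slice <- function(track, chrom, start, end, rpm = TRUE) {
  v <- numeric(end - start)
  cv <- track$cov[[chrom]]
  if (!is.null(cv)) {
    lo <- max(start, 0L)
    hi <- min(end, length(cv))
    if (hi > lo) v[(lo - start + 1L):(hi - start)] <- cv[(lo + 1L):hi]
  }
  if (rpm) v <- v * 1e6 / track$library_size
  v
}

#' Read a gene-model table
#'
#' The native format is a 0-based TSV with columns `gene_id`, `chrom`,
#' `strand`, `tss`, `tts`. GFF3 `gene` lines (1-based inclusive) are also
#' accepted and converted at this boundary: the 5' coordinate on the
#' annotated strand becomes the TSS.
#'
#' @param path input table.
#' @param format `"tsv"` (native 0-based) or `"gff3"`.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tts` (0-based positions).
#' @export
read_gene_models <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    g <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tts") %in% names(g)))
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(z) length(z) >= 9L && z[3L] == "gene", logical(1L))]
    if (!length(f)) stop("no gene lines in GFF3 file: ", path)
    att <- vapply(f, `[`, character(1L), 9L)
    id <- sub(".*ID=([^;]+).*", "\\1", att)
    strand <- vapply(f, `[`, character(1L), 7L)
    s1 <- as.integer(vapply(f, `[`, character(1L), 4L))  # 1-based inclusive
    e1 <- as.integer(vapply(f, `[`, character(1L), 5L))
    g <- data.frame(gene_id = id,
                    chrom = vapply(f, `[`, character(1L), 1L),
                    strand = strand,
                    tss = ifelse(strand == "+", s1 - 1L, e1 - 1L),
                    tts = ifelse(strand == "+", e1 - 1L, s1 - 1L),
                    stringsAsFactors = FALSE)
  }
  bad <- with(g, (strand == "+" & tss >= tts) | (strand == "-" & tss <= tts))
  if (any(bad)) stop("gene model invariant violated (TSS/TTS order) for: ",
                     paste(utils::head(g$gene_id[bad], 3L), collapse = ", "))
  g
}

#' Write a gene-model table (native 0-based TSV)
#'
#' @param genes data.frame as from [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss", "tts")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap fractions of two genomic intervals
#'
#' Vectorised over rows. Intervals on different chromosomes overlap by
#' zero (not an error).
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (recycled to a
#'   common length).
#' @return two-column matrix: fraction of `a` overlapped, fraction of `b`
#'   overlapped.
#' @export
overlap_fraction <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(b$end[ib], a$end[ia]) - pmax(b$start[ib], a$start[ia]))
  ov[a$chrom[ia] != b$chrom[ib]] <- 0
  cbind(frac_a = ov / (a$end[ia] - a$start[ia]),
        frac_b = ov / (b$end[ib] - b$start[ib]))
}

# Candidate overlapping row pairs between two interval data.frames,
# via IRanges (1-based closed internally, converted at this boundary).
overlap_pairs <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ja <- which(a$chrom == ch); jb <- which(b$chrom == ch)
    ra <- IRanges::IRanges(start = a$start[ja] + 1L, end = a$end[ja])
    rb <- IRanges::IRanges(start = b$start[jb] + 1L, end = b$end[jb])
    h <- IRanges::findOverlaps(ra, rb)
    if (length(h)) {
      out[[ch]] <- data.frame(i_a = ja[S4Vectors::queryHits(h)],
                              i_b = jb[S4Vectors::subjectHits(h)])
    }
  }
  if (!length(out)) return(data.frame(i_a = integer(), i_b = integer()))
  do.call(rbind, unname(out))
}

#' Extract interval sequences from a genome
#'
#' Intervals extending past a chromosome end are an error: callers clip
#' first if clipping is intended.
#'
#' @param genome named character vector from [read_fasta()].
#' @param regions interval data.frame (`chrom`, `start`, `end`).
#' @return character vector of sequences, one per row.
#' @export
get_sequences <- function(genome, regions) {
  validate_intervals(regions, "regions")
  if (!all(regions$chrom %in% names(genome)))
    stop("chromosome(s) absent from genome: ",
         paste(setdiff(unique(regions$chrom), names(genome)), collapse = ", "))
  if (any(regions$end > nchar(genome[regions$chrom])))
    stop("interval beyond chromosome end")
  substring(genome[regions$chrom], regions$start + 1L, regions$end)
}

#' Reciprocal-fraction interval matching
#'
#' Reports all pairs of intervals from `setA` and `setB` whose overlap
#' reaches fraction `f` of at least one interval (`mode = "either"`,
#' the semantics of `bedtools intersect -f -F -e`) or of both
#' (`mode = "both"`). A single interval may take part in several pairs.
#'
#' @param setA,setB interval data.frames (`chrom`, `start`, `end`).
#' @param f required overlap fraction, in (0, 1].
#' @param mode `"either"` or `"both"`.
#' @return data.frame with columns `i_a`, `i_b`, `frac_a`, `frac_b`.
#' @export
reciprocal_match <- function(setA, setB, f = 0.8, mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("f must be a single value in (0, 1]")
  validate_intervals(setA, "setA"); validate_intervals(setB, "setB")
  cand <- overlap_pairs(setA, setB)
  if (!nrow(cand)) {
    return(data.frame(i_a = integer(), i_b = integer(),
                      frac_a = numeric(), frac_b = numeric()))
  }
  fr <- overlap_fraction(setA[cand$i_a, , drop = FALSE],
                         setB[cand$i_b, , drop = FALSE])
  keep <- if (mode == "either") fr[, 1L] >= f | fr[, 2L] >= f
          else                  fr[, 1L] >= f & fr[, 2L] >= f
  data.frame(i_a = cand$i_a[keep], i_b = cand$i_b[keep],
             frac_a = fr[keep, 1L], frac_b = fr[keep, 2L],
             row.names = NULL)
}
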