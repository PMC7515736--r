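# Model evaluation: matched unbound negative sets (same length, origin
# class and GC content as the bound regions), AUROC by the rank
# statistic, and Welch comparison of best-score distributions.

#' GC fraction of sequences
#'
#' @param seqs character vector of sequences.
#' @return numeric vector in \[0, 1\] (N bases excluded from the
#'   denominator).
#' @export
gc_fraction <- function(seqs) {
  gc <- nchar(gsub("[^GC]", "", seqs))
  acgt <- nchar(gsub("[^ACGT]", "", seqs))
  ifelse(acgt > 0, gc / acgt, NA_real_)
}

#' Classify genomic origin of positions
#'
#' Assigns each interval midpoint an origin class with precedence
#' exon > intron > promoter > intergenic. Without an exon table the
#' whole gene body counts as exon; the promoter is the `promoter_bp`
#' window upstream of the TSS.
#'
#' @param regions interval data.frame.
#' @param genes gene models.
#' @param promoter_bp promoter extent upstream of the TSS (default
#'   3000, matching the regulatory-region definition).
#' @param exons optional interval data.frame of exons.
#' @return character vector: `"exon"`, `"intron"`, `"promoter"` or
#'   `"intergenic"`.
#' @export
classify_origin <- function(regions, genes, promoter_bp = 3000L,
                            exons = NULL) {
  mid <- (regions$start + regions$end) %/% 2L
  body_lo <- pmin(genes$tss, genes$tts)
  body_hi <- pmax(genes$tss, genes$tts)
  # for "-" strand genes tss > tts; upstream extends to the right
  prom_lo <- ifelse(genes$strand == "+", genes$tss - promoter_bp, genes$tss)
  prom_hi <- ifelse(genes$strand == "+", genes$tss, genes$tss + promoter_bp)
  vapply(seq_along(mid), function(i) {
    g <- genes$chrom == regions$chrom[i]
    in_body <- g & mid[i] >= body_lo & mid[i] < body_hi
    if (any(in_body)) {
      if (is.null(exons)) return("exon")
      in_ex <- exons$chrom == regions$chrom[i] & mid[i] >= exons$start &
        mid[i] < exons$end
      return(if (any(in_ex)) "exon" else "intron")
    }
    in_prom <- g & mid[i] >= prom_lo & mid[i] < prom_hi
    if (any(in_prom)) return("promoter")
    "intergenic"
  }, character(1L))
}

#' Sample an unbound negative set matched to the positives
#'
#' Each positive region is assigned its origin class and a GC bin of
#' width `gc_bin`; one unbound region of identical length is drawn
#' uniformly from the same (origin, GC-bin) stratum, without
#' replacement, avoiding any overlap with the experiment's full peak
#' set. An exhausted stratum widens its GC bin stepwise (with a
#' message) before failing.
#'
#' @param positives interval data.frame of bound regions.
#' @param genome named character vector.
#' @param genes gene models (for origin classes).
#' @param all_peaks interval data.frame of every peak to avoid.
#' @param gc_bin GC bin width (default 0.05).
#' @param seed RNG seed.
#' @param max_tries candidate draws per region before widening.
#' @param exons optional exon intervals.
#' @return data.frame of negative regions with `origin` and `gc`.
#' @export
sample_matched_negatives <- function(positives, genome, genes, all_peaks,
                                     gc_bin = 0.05, seed = 1L,
                                     max_tries = 200L, exons = NULL) {
  set.seed(seed)
  pos_seq <- get_sequences(genome, positives)
  pos_gc <- gc_fraction(pos_seq)
  pos_origin <- classify_origin(positives, genes, exons = exons)
  chrom_lengths <- nchar(genome)
  taken <- data.frame(chrom = all_peaks$chrom, start = all_peaks$start,
                      end = all_peaks$end, stringsAsFactors = FALSE)
  out <- vector("list", nrow(positives))
  for (i in seq_len(nrow(positives))) {
    len <- positives$end[i] - positives$start[i]
    widen <- 0L
    repeat {
      tol <- gc_bin / 2 + widen * gc_bin
      found <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(names(genome), 1L,
                     prob = pmax(chrom_lengths - len, 0))
        if (chrom_lengths[[ch]] <= len) next
        st <- sample.int(chrom_lengths[[ch]] - len, 1L) - 1L
        cand <- data.frame(chrom = ch, start = st, end = st + len,
                           stringsAsFactors = FALSE)
        ovl <- nrow(taken) && any(taken$chrom == ch &
                                    taken$start < cand$end &
                                    cand$start < taken$end)
        if (ovl) next
        if (classify_origin(cand, genes, exons = exons) != pos_origin[i])
          next
        gcc <- gc_fraction(get_sequences(genome, cand))
        if (is.na(gcc) || abs(gcc - pos_gc[i]) > tol) next
        cand$origin <- pos_origin[i]; cand$gc <- gcc
        out[[i]] <- cand
        taken <- rbind(taken, cand[, c("chrom", "start", "end")])
        found <- TRUE
        break
      }
      if (found) break
      widen <- widen + 1L
      if (widen > 8L) {
        stop("exhausted stratum (", pos_origin[i], ", GC ",
             round(pos_gc[i], 2), ") while sampling negatives")
      }
      message("widening GC tolerance to ", gc_bin / 2 + widen * gc_bin,
              " for stratum (", pos_origin[i], ", GC ",
              round(pos_gc[i], 2), ")")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Sample unmatched background regions
#'
#' Uniformly random regions of fixed width avoiding a peak set; used
#' where a large background (rather than a 1:1 GC/origin-matched set)
#' stabilises frequency estimates, e.g. spacing backgrounds.
#'
#' @param genome named character vector.
#' @param n number of regions.
#' @param width region width (bp).
#' @param avoid interval data.frame to avoid overlapping.
#' @param seed RNG seed.
#' @return interval data.frame.
#' @export
sample_background_regions <- function(genome, n, width = 401L,
                                      avoid = NULL, seed = 1L) {
  set.seed(seed)
  chrom_lengths <- nchar(genome)
  out <- vector("list", n)
  got <- 0L
  for (try in seq_len(n * 50L)) {
    if (got >= n) break
    ch <- sample(names(genome), 1L, prob = pmax(chrom_lengths - width, 0))
    if (chrom_lengths[[ch]] <= width) next
    st <- sample.int(chrom_lengths[[ch]] - width, 1L) - 1L
    if (!is.null(avoid) && nrow(avoid) &&
        any(avoid$chrom == ch & avoid$start < st + width &
              st < avoid$end)) next
    got <- got + 1L
    out[[got]] <- data.frame(chrom = ch, start = st, end = st + width,
                             stringsAsFactors = FALSE)
  }
  if (got < n) stop("could not sample ", n, " background regions")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' AUROC of a motif model over bound vs unbound regions
#'
#' Best score per region (both strands) under the model, then the
#' Mann-Whitney rank statistic with mid-ranked ties:
#' `AUROC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`.
#'
#' @param model motif model, or `NULL` when `pos_scores`/`neg_scores`
#'   are supplied directly.
#' @param positives,negatives region sequences (character vectors).
#' @param pos_scores,neg_scores pre-computed score vectors (bypass).
#' @return list with `auroc` and a `roc` data.frame (`fpr`, `tpr`).
#' @export
compute_auroc <- function(model = NULL, positives = NULL, negatives = NULL,
                          pos_scores = NULL, neg_scores = NULL) {
  if (is.null(pos_scores)) pos_scores <- best_scores(model, positives)
  if (is.null(neg_scores)) neg_scores <- best_scores(model, negatives)
  if (!length(pos_scores) || !length(neg_scores))
    stop("both region sets must be non-empty")
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  auroc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  # ROC points at every distinct threshold
  o <- order(c(pos_scores, neg_scores), decreasing = TRUE)
  is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))[o]
  sc <- c(pos_scores, neg_scores)[o]
  tp <- cumsum(is_pos); fp <- cumsum(!is_pos)
  last <- !duplicated(sc, fromLast = TRUE)  # collapse tied thresholds
  roc <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  list(auroc = auroc, roc = roc)
}

#' Compare best-score distributions of two region sets
#'
#' Best score per region under the model, then a Welch two-sample
#' t-test (two-sided).
#'
#' @param model motif model.
#' @param regions_x,regions_y region sequences.
#' @return list with `t`, `p`, `mean_x`, `mean_y` and the score
#'   vectors.
#' @export
compare_best_scores <- function(model, regions_x, regions_y) {
  if (length(regions_x) < 2L || length(regions_y) < 2L)
    stop("need at least 2 regions per set")
  sx <- best_scores(model, regions_x)
  sy <- best_scores(model, regions_y)
  if (stats::sd(sx) == 0 && stats::sd(sy) == 0) {
    t_stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(sx, sy, var.equal = FALSE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(t = t_stat, p = p, mean_x = mean(sx), mean_y = mean(sy),
       scores_x = sx, scores_y = sy)
}
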