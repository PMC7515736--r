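# Consensus peak determination: replicate peak calls of one experiment
# are merged into candidate regions, retained by a reproducibility rule
# (replicate support + Fisher combination of the callers' -log10
# p-values at cutoff 1e-4), scanned for subpeaks by summit clustering,
# and width-normalized to summit +/- 200 bp with a mean normalized
# (reads-per-million) coverage.

# round-half-down: 1002.5 -> 1002
round_half_down <- function(x) ceiling(x - 0.5)

#' Pool replicate peak calls into reproducible candidate regions
#'
#' Peaks from all replicates are merged wherever they overlap; a merged
#' region is retained when it has peaks from at least `min_replicates`
#' replicates and its Fisher-combined p-value (over each supporting
#' replicate's best peak) is at most `reproducibility_alpha`.
#'
#' @param replicate_peaks list of narrowPeak-style data.frames
#'   (as from [read_narrowpeak()]), one per replicate.
#' @param reproducibility_alpha combined p-value cutoff (default 1e-4).
#' @param min_replicates minimal replicate support (default 2).
#' @param allow_single bypass flag for a single replicate: the support
#'   rule degenerates to `min_replicates = 1`.
#' @return data.frame of retained regions: `chrom`, `start`, `end`,
#'   `support`, `combined_neg_log10_p`, plus a list-column `summits` of
#'   absolute summit positions carried forward.
#' @export
pool_replicates <- function(replicate_peaks, reproducibility_alpha = 1e-4,
                            min_replicates = 2L, allow_single = FALSE) {
  if (length(replicate_peaks) < 2L && !allow_single) {
    stop("pooling needs >= 2 replicates; use allow_single = TRUE to bypass")
  }
  if (allow_single) min_replicates <- min(min_replicates, 1L)
  stopifnot(reproducibility_alpha > 0, reproducibility_alpha <= 1)
  all_pk <- do.call(rbind, lapply(seq_along(replicate_peaks), function(r) {
    p <- replicate_peaks[[r]]
    if (!nrow(p)) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               summit = p$start + p$summit_offset,
               neg_log10_p = p$neg_log10_p, rep = r,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer(),
                      combined_neg_log10_p = numeric())
  empty$summits <- list()
  if (is.null(all_pk) || !nrow(all_pk)) return(empty)

  out <- list()
  for (ch in unique(all_pk$chrom)) {
    pk <- all_pk[all_pk$chrom == ch, , drop = FALSE]
    pk <- pk[order(pk$start, pk$end), , drop = FALSE]
    # merge overlapping intervals into candidate regions
    grp <- cumsum(c(TRUE, pk$start[-1L] >= cummax(pk$end)[-nrow(pk)]))
    for (g in unique(grp)) {
      m <- pk[grp == g, , drop = FALSE]
      support <- length(unique(m$rep))
      if (support < min_replicates) next
      best <- tapply(m$neg_log10_p, m$rep, max)
      stat <- 2 * log(10) * sum(best)
      p_comb <- stats::pchisq(stat, df = 2L * length(best),
                              lower.tail = FALSE)
      if (p_comb > reproducibility_alpha) next
      row <- data.frame(chrom = ch, start = min(m$start), end = max(m$end),
                        support = support,
                        combined_neg_log10_p = -log10(max(p_comb,
                                                          .Machine$double.xmin)),
                        stringsAsFactors = FALSE)
      row$summits <- list(sort(m$summit))
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a pooled region at subpeaks and width-normalize
#'
#' Summits are clustered by single-linkage with a 200-bp merge
#' distance; each cluster's representative summit is the
#' round-half-down mean of its members, and one 401-bp peak
#' `[s - 200, s + 201)` is emitted per cluster (it may extend past the
#' original region).
#'
#' @param summits absolute summit positions within one region.
#' @param merge_dist single-linkage merge distance (bp).
#' @param half_width half-width of the normalized peak (bp).
#' @return data.frame `start`, `end`, `summit`, one row per subpeak.
#' @export
split_and_normalize <- function(summits, merge_dist = 200L,
                                half_width = 200L) {
  stopifnot(length(summits) >= 1L)
  s <- sort(summits)
  grp <- cumsum(c(TRUE, diff(s) > merge_dist))
  reps <- vapply(split(s, grp), function(v) round_half_down(mean(v)),
                 numeric(1L))
  data.frame(start = reps - half_width, end = reps + half_width + 1L,
             summit = as.integer(reps), row.names = NULL)
}

#' Mean normalized coverage of a window across replicates
#'
#' For each replicate, per-bp coverage is scaled to reads-per-million
#' and summed over the window, divided by the window width; the mean
#' across replicates is returned. Windows clipped at a chromosome end
#' use the actually covered width as the divisor (with a warning).
#'
#' @param tracks list of coverage tracks (the replicates).
#' @param chrom,start,end the window.
#' @return mean RPM per bp (scalar).
#' @export
mean_normalized_coverage <- function(tracks, chrom, start, end) {
  vals <- vapply(tracks, function(tr) {
    cv <- tr$cov[[chrom]]
    if (is.null(cv)) stop("track lacks chromosome ", chrom)
    lo <- max(start, 0L); hi <- min(end, length(cv))
    if (lo != start || hi != end) {
      warning("window [", start, ",", end, ") clipped on ", chrom,
              "; using covered width as divisor")
    }
    width <- hi - lo
    if (width <= 0L) return(0)
    sum(cv[(lo + 1L):hi]) * 1e6 / tr$library_size / width
  }, numeric(1L))
  mean(vals)
}

#' Full consensus-peak pipeline for one experiment
#'
#' [pool_replicates()], then [split_and_normalize()] per region, then
#' [mean_normalized_coverage()] per 401-bp peak. Peaks running past a
#' chromosome end are clipped (the only deviation from the fixed
#' 401-bp width, logged as a warning by the coverage step).
#'
#' @param replicate_peaks list of narrowPeak-style data.frames.
#' @param tracks list of replicate coverage tracks.
#' @param reproducibility_alpha,min_replicates,allow_single passed to
#'   [pool_replicates()].
#' @param half_width summit half-width (default 200).
#' @return consensus peak data.frame: `chrom`, `start`, `end`,
#'   `summit`, `mean_norm_cov`, `support`, `combined_neg_log10_p`.
#' @export
consensus_peaks <- function(replicate_peaks, tracks,
                            reproducibility_alpha = 1e-4,
                            min_replicates = 2L, allow_single = FALSE,
                            half_width = 200L) {
  regions <- pool_replicates(replicate_peaks, reproducibility_alpha,
                             min_replicates, allow_single)
  chrom_lengths <- vapply(tracks[[1L]]$cov, length, integer(1L))
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    sub <- split_and_normalize(regions$summits[[i]],
                               merge_dist = half_width,
                               half_width = half_width)
    for (j in seq_len(nrow(sub))) {
      start <- max(0L, sub$start[j])
      end <- min(chrom_lengths[[regions$chrom[i]]], sub$end[j])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = regions$chrom[i], start = start, end = end,
        summit = sub$summit[j],
        mean_norm_cov = mean_normalized_coverage(tracks, regions$chrom[i],
                                                 start, end),
        support = regions$support[i],
        combined_neg_log10_p = regions$combined_neg_log10_p[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      mean_norm_cov = numeric(), support = integer(),
                      combined_neg_log10_p = numeric()))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write consensus peaks as BED6+
#'
#' Columns 7-9 carry `mean_norm_cov`, `support` and
#' `combined_neg_log10_p`.
#'
#' @param cons consensus peak data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_bed <- function(cons, path) {
  lines <- paste(cons$chrom, cons$start, cons$end,
                 sprintf("consensus_%d", seq_len(nrow(cons))),
                 format(cons$mean_norm_cov, digits = 10, trim = TRUE), ".",
                 format(cons$mean_norm_cov, digits = 10, trim = TRUE),
                 cons$support,
                 format(cons$combined_neg_log10_p, digits = 10, trim = TRUE),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
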