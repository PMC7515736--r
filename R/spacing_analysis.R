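# Intersite-spacing statistics. Within each bound region, every
# unordered pair of binding-site hits above the score threshold
# contributes one count at its center-to-center distance n
# (orientation-indifferent); frequencies f_n = C_n / sum(C) and the
# normalized enrichment N_n = f_pos,n / f_neg,n compare a bound set
# against a background set. Spacing is measured center-to-center,
# which reproduces the printed KNU promoter values (45-46 bp); an
# edge-to-edge option exists.

#' Pair-spacing counts over a region set
#'
#' Scans each region with the model at `threshold` and counts all
#' unordered hit pairs by center-to-center distance `n <= s_max` (any
#' strand combination). Pairs closer than `min_spacing` can be
#' excluded; by default overlapping sites are counted.
#'
#' @param seqs region sequences.
#' @param model motif model.
#' @param threshold site score threshold in (0, 1).
#' @param s_max maximal spacing (bp, default 100).
#' @param min_spacing minimal spacing counted (default 0).
#' @param measure `"center"` (default) or `"edge"` (edge-to-edge,
#'   i.e. center distance minus motif width).
#' @return integer vector `C` of length `s_max + 1`, named `0:s_max`.
#' @export
pair_spacing_counts <- function(seqs, model, threshold = 0.9,
                                s_max = 100L, min_spacing = 0L,
                                measure = c("center", "edge")) {
  measure <- match.arg(measure)
  stopifnot(threshold > 0, threshold < 1)
  C <- integer(s_max + 1L)
  for (s in seqs) {
    if (nchar(s) < model$W) next
    hits <- scan_region(model, s, threshold)$hits
    if (nrow(hits) < 2L) next
    centers <- hits$offset + (model$W - 1) / 2
    d <- abs(as.vector(stats::dist(centers)))
    if (measure == "edge") d <- d - model$W
    d <- round(d)
    d <- d[d >= min_spacing & d <= s_max]
    if (length(d)) {
      tab <- tabulate(d + 1L, nbins = s_max + 1L)
      C <- C + tab
    }
  }
  names(C) <- 0:s_max
  C
}

#' Spacing frequencies
#'
#' `f_n = C_n / sum(C)`.
#'
#' @param counts integer vector from [pair_spacing_counts()].
#' @return numeric vector summing to 1.
#' @export
spacing_frequency <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) stop("undefined spacing profile: no pairs counted")
  counts / tot
}

#' Normalized spacing enrichment
#'
#' `N_n = f_pos,n / f_neg,n` where the background frequency is
#' positive; elsewhere `N_n` is undefined (NA, not infinity).
#'
#' @param f_pos,f_neg frequency vectors sharing `s_max`.
#' @return numeric vector with NA where undefined.
#' @export
normalized_enrichment <- function(f_pos, f_neg) {
  stopifnot(length(f_pos) == length(f_neg))
  out <- ifelse(f_neg > 0, f_pos / f_neg, NA_real_)
  und <- sum(f_neg == 0 & f_pos > 0)
  if (und > 0) message(und, " spacings undefined (positive frequency, ",
                       "zero background frequency)")
  out
}

#' Full spacing-enrichment profile
#'
#' Convenience wrapper: counts and frequencies for a positive and a
#' background region set, plus their normalized enrichment.
#'
#' @param pos_seqs,neg_seqs region sequences.
#' @inheritParams pair_spacing_counts
#' @return data.frame: `n`, `C_pos`, `f_pos`, `C_neg`, `f_neg`, `N`.
#' @export
spacing_profile <- function(pos_seqs, neg_seqs, model, threshold = 0.9,
                            s_max = 100L, min_spacing = 0L) {
  C_pos <- pair_spacing_counts(pos_seqs, model, threshold, s_max,
                               min_spacing)
  C_neg <- pair_spacing_counts(neg_seqs, model, threshold, s_max,
                               min_spacing)
  f_pos <- spacing_frequency(C_pos)
  f_neg <- spacing_frequency(C_neg)
  data.frame(n = 0:s_max, C_pos = as.integer(C_pos), f_pos = f_pos,
             C_neg = as.integer(C_neg), f_neg = f_neg,
             N = normalized_enrichment(f_pos, f_neg), row.names = NULL)
}

#' Percentage of regions with a preferred spacing, per CFR decile
#'
#' A region counts as positive when it contains at least one hit pair
#' whose spacing falls in the preferred set.
#'
#' @param entries ranked union catalogue with `decile` (see
#'   [cfr_rank_and_deciles()]).
#' @param genome named character vector.
#' @param model motif model.
#' @param threshold site score threshold.
#' @param preferred preferred spacings (default `c(36, 37, 46, 47, 57)`).
#' @param s_max maximal spacing.
#' @return data.frame `decile`, `n_regions`, `percent` (NA for an
#'   empty decile).
#' @export
preferred_spacing_fraction_by_decile <- function(entries, genome, model,
                                                 threshold = 0.9,
                                                 preferred = c(36L, 37L,
                                                               46L, 47L,
                                                               57L),
                                                 s_max = 100L) {
  stopifnot(length(preferred) > 0, "decile" %in% names(entries))
  seqs <- get_sequences(genome, entries)
  has_pref <- vapply(seqs, function(s) {
    if (nchar(s) < model$W) return(FALSE)
    hits <- scan_region(model, s, threshold)$hits
    if (nrow(hits) < 2L) return(FALSE)
    centers <- hits$offset + (model$W - 1) / 2
    d <- round(abs(as.vector(stats::dist(centers))))
    any(d[d <= s_max] %in% preferred)
  }, logical(1L), USE.NAMES = FALSE)
  dec <- sort(unique(entries$decile))
  out <- data.frame(decile = dec,
                    n_regions = vapply(dec, function(d)
                      sum(entries$decile == d), integer(1L)))
  out$percent <- vapply(seq_len(nrow(out)), function(i) {
    idx <- entries$decile == out$decile[i]
    if (!any(idx)) return(NA_real_)
    100 * mean(has_pref[idx])
  }, numeric(1L))
  empty <- setdiff(1:10, dec)
  if (length(empty)) message("empty decile(s): ",
                             paste(empty, collapse = ", "))
  out
}

#' Annotate binding boxes in a probe sequence
#'
#' Locates either exact nucleotide patterns (searched on the given
#' strand) or model hits above a threshold, and reports all match
#' positions, centers and pairwise center-to-center distances. An
#' absent pattern yields an empty annotation, not an error.
#'
#' @param sequence probe sequence.
#' @param patterns character vector of exact patterns (named or not).
#' @param model optional motif model used instead of `patterns`.
#' @param threshold score threshold when scanning with a model.
#' @return list with `boxes` (data.frame `pattern`, `start` (0-based),
#'   `end`, `center`) and `distances` (data.frame `from`, `to`,
#'   `distance` for every unordered pair).
#' @export
annotate_probe <- function(sequence, patterns = NULL, model = NULL,
                           threshold = 0.9) {
  boxes <- list()
  if (!is.null(patterns)) {
    nm <- if (is.null(names(patterns))) patterns else names(patterns)
    for (i in seq_along(patterns)) {
      p <- patterns[[i]]
      hits <- gregexpr(p, sequence, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      boxes[[length(boxes) + 1L]] <- data.frame(
        pattern = nm[i], start = as.integer(hits) - 1L,
        end = as.integer(hits) - 1L + nchar(p),
        stringsAsFactors = FALSE)
    }
  } else if (!is.null(model)) {
    hits <- scan_region(model, sequence, threshold)$hits
    if (nrow(hits)) {
      boxes[[1L]] <- data.frame(pattern = "model_hit",
                                start = hits$offset,
                                end = hits$offset + model$W,
                                stringsAsFactors = FALSE)
    }
  } else stop("supply patterns or a model")
  if (!length(boxes)) {
    b <- data.frame(pattern = character(), start = integer(),
                    end = integer(), center = numeric())
    return(list(boxes = b,
                distances = data.frame(from = character(),
                                       to = character(),
                                       distance = numeric())))
  }
  b <- do.call(rbind, boxes)
  b$center <- (b$start + b$end - 1) / 2
  dd <- list()
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      for (j in (i + 1L):nrow(b)) {
        dd[[length(dd) + 1L]] <- data.frame(
          from = b$pattern[i], to = b$pattern[j],
          distance = abs(b$center[j] - b$center[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  distances <- if (length(dd)) do.call(rbind, dd) else
    data.frame(from = character(), to = character(), distance = numeric())
  list(boxes = b, distances = distances)
}
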