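# Union peak catalogue for two experiments: peaks common to both or
# specific to one, the coverage fold reduction (CFR = cov_A / cov_B),
# CFR ranking with decile partition, and summit-centered coverage
# matrices for heatmap / mean-profile displays.

#' Build the union peak catalogue of two experiments
#'
#' Consensus peaks of A and B that satisfy the geometric commonality
#' rule — overlap of at least `min_frac` (default 80%) of the smaller
#' peak AND strictly less than `max_nonoverlap` (default 50%)
#' non-overlapping fraction for each peak — collapse into one entry
#' whose summit is taken from the experiment with the higher mean
#' normalized coverage, re-windowed to the summit +/- `half_width`.
#' Unmatched peaks become entries of their own. `cov_A` and `cov_B`
#' are then recomputed over every entry's window from each
#' experiment's replicate tracks, and each entry is classified common
#' / A_specific / B_specific at the specificity `fold`.
#'
#' One peak matching several partners is resolved by largest-overlap
#' pairing (ties to the lower-coordinate partner).
#'
#' @param consA,consB consensus peak data.frames (see
#'   [consensus_peaks()]).
#' @param tracksA,tracksB replicate coverage-track lists of the two
#'   experiments.
#' @param min_frac required overlap fraction of the smaller peak.
#' @param max_nonoverlap maximal tolerated non-overlap fraction.
#' @param fold specificity fold threshold (default 2).
#' @param half_width re-windowing half-width (default 200).
#' @return data.frame: `chrom`, `start`, `end`, `summit`, `cov_A`,
#'   `cov_B`, `label`, `cfr` (NA where `cov_B` is zero, flagged and
#'   excluded from ratio-ranked outputs).
#' @export
build_union_catalogue <- function(consA, consB, tracksA, tracksB,
                                  min_frac = 0.8, max_nonoverlap = 0.5,
                                  fold = 2, half_width = 200L) {
  stopifnot(min_frac > 0, min_frac <= 1,
            max_nonoverlap > 0, max_nonoverlap <= 1)
  cand <- overlap_pairs(consA, consB)
  matched <- data.frame(i_a = integer(), i_b = integer())
  if (nrow(cand)) {
    wa <- consA$end[cand$i_a] - consA$start[cand$i_a]
    wb <- consB$end[cand$i_b] - consB$start[cand$i_b]
    ov <- pmin(consA$end[cand$i_a], consB$end[cand$i_b]) -
      pmax(consA$start[cand$i_a], consB$start[cand$i_b])
    ok <- ov >= min_frac * pmin(wa, wb) &
      (1 - ov / wa) < max_nonoverlap & (1 - ov / wb) < max_nonoverlap
    cand <- cand[ok, , drop = FALSE]; ov <- ov[ok]
    if (nrow(cand)) {
      # greedy largest-overlap pairing, ties to lower coordinate
      o <- order(-ov, consA$start[cand$i_a], consB$start[cand$i_b])
      used_a <- logical(nrow(consA)); used_b <- logical(nrow(consB))
      keep <- logical(nrow(cand))
      for (i in o) {
        if (!used_a[cand$i_a[i]] && !used_b[cand$i_b[i]]) {
          keep[i] <- TRUE
          used_a[cand$i_a[i]] <- TRUE
          used_b[cand$i_b[i]] <- TRUE
        }
      }
      matched <- cand[keep, , drop = FALSE]
    }
  }
  rows <- list()
  add_entry <- function(chrom, summit) {
    data.frame(chrom = chrom, start = summit - half_width,
               end = summit + half_width + 1L, summit = summit,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(matched))) {
    ia <- matched$i_a[i]; ib <- matched$i_b[i]
    use_a <- consA$mean_norm_cov[ia] >= consB$mean_norm_cov[ib]
    rows[[length(rows) + 1L]] <- add_entry(
      consA$chrom[ia], if (use_a) consA$summit[ia] else consB$summit[ib])
  }
  for (ia in setdiff(seq_len(nrow(consA)), matched$i_a)) {
    rows[[length(rows) + 1L]] <- add_entry(consA$chrom[ia], consA$summit[ia])
  }
  for (ib in setdiff(seq_len(nrow(consB)), matched$i_b)) {
    rows[[length(rows) + 1L]] <- add_entry(consB$chrom[ib], consB$summit[ib])
  }
  if (!length(rows)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      cov_A = numeric(), cov_B = numeric(),
                      label = character(), cfr = numeric())
    return(out)
  }
  ent <- do.call(rbind, rows)
  ent <- ent[order(ent$chrom, ent$start), , drop = FALSE]
  rownames(ent) <- NULL
  ent$cov_A <- vapply(seq_len(nrow(ent)), function(i)
    mean_normalized_coverage(tracksA, ent$chrom[i], ent$start[i], ent$end[i]),
    numeric(1L))
  ent$cov_B <- vapply(seq_len(nrow(ent)), function(i)
    mean_normalized_coverage(tracksB, ent$chrom[i], ent$start[i], ent$end[i]),
    numeric(1L))
  ent$label <- classify(ent$cov_A, ent$cov_B, fold)
  ent$cfr <- ifelse(ent$cov_B > 0, ent$cov_A / ent$cov_B, NA_real_)
  if (anyNA(ent$cfr)) {
    message(sum(is.na(ent$cfr)),
            " entries with zero denominator coverage excluded from CFR")
  }
  ent
}

#' Classify union-catalogue entries as common or complex-specific
#'
#' A-specific iff `cov_a >= fold * cov_b`; B-specific iff
#' `cov_b >= fold * cov_a`; otherwise common. Entries with both
#' coverages zero are common, with a warning.
#'
#' @param cov_a,cov_b mean normalized coverages (vectorised).
#' @param fold specificity fold (default 2).
#' @return character vector of labels.
#' @export
classify <- function(cov_a, cov_b, fold = 2) {
  stopifnot(fold >= 1)
  both_zero <- cov_a == 0 & cov_b == 0
  if (any(both_zero)) warning(sum(both_zero),
                              " entries with zero coverage in both ",
                              "experiments labelled common")
  out <- rep("common", length(cov_a))
  out[!both_zero & cov_a >= fold * cov_b] <- "A_specific"
  out[!both_zero & cov_b >= fold * cov_a] <- "B_specific"
  out
}

#' Rank entries by CFR and partition into deciles
#'
#' Entries are ordered by CFR descending (ties broken by coordinate)
#' and split into 10 equal-count bins; remainders go to the earliest
#' deciles. Decile 1 holds the strongest CFR. Entries with undefined
#' CFR are dropped with a message.
#'
#' @param entries union catalogue (see [build_union_catalogue()]).
#' @param n_bins number of bins (default 10).
#' @return `entries` (defined-CFR rows) with `cfr_rank` and `decile`.
#' @export
cfr_rank_and_deciles <- function(entries, n_bins = 10L) {
  drop <- is.na(entries$cfr)
  if (any(drop)) {
    message(sum(drop), " entries with undefined CFR dropped from ranking")
    entries <- entries[!drop, , drop = FALSE]
  }
  n <- nrow(entries)
  if (n < n_bins) warning("fewer entries than bins; deciles collapse")
  o <- order(-entries$cfr, entries$chrom, entries$start)
  entries <- entries[o, , drop = FALSE]
  entries$cfr_rank <- seq_len(n)
  sizes <- rep(n %/% n_bins, n_bins) + c(rep(1L, n %% n_bins),
                                         rep(0L, n_bins - n %% n_bins))
  entries$decile <- rep(seq_len(n_bins), sizes)[seq_len(n)]
  rownames(entries) <- NULL
  entries
}

#' Summit-centered coverage matrices and mean profiles
#'
#' One row per entry (sorted by CFR descending), one column per bp of
#' the `window` around the summit; values are RPM-scaled coverage
#' averaged across an experiment's replicates. Off-chromosome columns
#' are zero-filled.
#'
#' @param entries ranked union catalogue (needs `summit`, `cfr`).
#' @param tracksA,tracksB replicate track lists.
#' @param window total window width (bp, even; default 1000).
#' @return list with matrices `A`, `B` and mean-profile vectors
#'   `mean_A`, `mean_B`, plus `positions` (bp offsets from summit).
#' @export
profile_matrices <- function(entries, tracksA, tracksB, window = 1000L) {
  stopifnot(window %% 2L == 0L)
  o <- order(-entries$cfr, entries$chrom, entries$start)
  entries <- entries[o, , drop = FALSE]
  half <- window %/% 2L
  row_of <- function(tracks, i) {
    rowMeans(vapply(tracks, function(tr)
      track_slice(tr, entries$chrom[i], entries$summit[i] - half,
                  entries$summit[i] + half, rpm = TRUE),
      numeric(window)))
  }
  A <- t(vapply(seq_len(nrow(entries)), function(i) row_of(tracksA, i),
                numeric(window)))
  B <- t(vapply(seq_len(nrow(entries)), function(i) row_of(tracksB, i),
                numeric(window)))
  list(A = A, B = B, mean_A = colMeans(A), mean_B = colMeans(B),
       positions = seq(-half, half - 1L))
}

#' Write the union catalogue as BED6+
#'
#' @param entries ranked union catalogue.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_union_bed <- function(entries, path) {
  dec <- if ("decile" %in% names(entries)) entries$decile else NA
  lines <- paste(entries$chrom, entries$start, entries$end,
                 sprintf("union_%d", seq_len(nrow(entries))),
                 0, ".",
                 format(entries$cov_A, digits = 10, trim = TRUE),
                 format(entries$cov_B, digits = 10, trim = TRUE),
                 entries$label,
                 format(entries$cfr, digits = 10, trim = TRUE),
                 dec, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
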