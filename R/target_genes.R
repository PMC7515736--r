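# Target-gene determination: regulatory regions (3 kb upstream of the
# TSS through 1 kb past the TTS), bound genes (any peak overlap, no
# restriction), DE filtering (|logFC| > 1, FDR < 0.05) with list
# combination, and hypergeometric overlap significance.

#' Regulatory region of each gene
#'
#' `+` strand: `[TSS - upstream, TTS + downstream)`; `-` strand
#' mirrored. Regions are clipped at chromosome bounds when lengths are
#' supplied (with a message).
#'
#' @param genes gene models.
#' @param upstream bp upstream of the TSS (default 3000).
#' @param downstream bp downstream of the TTS (default 1000).
#' @param chrom_lengths optional named lengths for clipping.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
regulatory_regions <- function(genes, upstream = 3000L, downstream = 1000L,
                               chrom_lengths = NULL) {
  start <- ifelse(genes$strand == "+", genes$tss - upstream,
                  genes$tts - downstream)
  end <- ifelse(genes$strand == "+", genes$tts + downstream,
                genes$tss + upstream)
  clipped <- sum(start < 0)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    clipped <- clipped + sum(end > lim)
    end <- pmin(end, lim)
  }
  if (clipped > 0) message(clipped, " regulatory region(s) clipped at ",
                           "chromosome bounds")
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Genes bound by a peak set
#'
#' A gene is bound iff any peak overlaps its regulatory region by at
#' least 1 bp (no restriction). A peak overlapping two genes' regions
#' counts for both.
#'
#' @param peaks interval data.frame.
#' @param regions regulatory regions from [regulatory_regions()].
#' @return character vector of bound gene ids (sorted, unique).
#' @export
bound_genes <- function(peaks, regions) {
  if (!nrow(peaks)) return(character())
  hits <- overlap_pairs(regions, peaks)
  sort(unique(regions$gene_id[hits$i_a]))
}

#' Filter and combine differential-expression tables
#'
#' Each table is filtered to |logFC| > `lfc` and FDR < `fdr`; the
#' filtered lists are combined by set union ("concatenation" of
#' regulator lists). With `direction_filter = "same_direction"`, a
#' gene present in tables of two different regulators is kept only
#' when its directions agree. Conflicting directions within one
#' regulator keep the gene, flagged ambiguous.
#'
#' @param tables list of data.frames (`gene_id`, `logFC`, `FDR`),
#'   optionally named.
#' @param regulator character vector assigning each table to a
#'   regulator (default: each table its own).
#' @param lfc,fdr the DE thresholds (defaults 1 and 0.05).
#' @param direction_filter `"off"` or `"same_direction"`.
#' @return data.frame `gene_id`, `direction` (+1 / -1, 0 when
#'   ambiguous within a regulator), `ambiguous`.
#' @export
de_gene_sets <- function(tables, regulator = NULL, lfc = 1, fdr = 0.05,
                         direction_filter = c("off", "same_direction")) {
  direction_filter <- match.arg(direction_filter)
  if (is.null(regulator)) regulator <- as.character(seq_along(tables))
  stopifnot(length(regulator) == length(tables))
  per_reg <- list()
  for (reg in unique(regulator)) {
    rows <- list()
    for (k in which(regulator == reg)) {
      t <- tables[[k]]
      keep <- abs(t$logFC) > lfc & t$FDR < fdr
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = t$gene_id[keep], direction = sign(t$logFC[keep]),
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    if (is.null(d) || !nrow(d)) next
    dir <- tapply(d$direction, d$gene_id, function(v)
      if (length(unique(v)) == 1L) v[1L] else 0)
    amb <- names(dir)[dir == 0]
    if (length(amb)) message(length(amb), " gene(s) with conflicting ",
                             "direction within regulator ", reg,
                             " kept as ambiguous")
    per_reg[[reg]] <- data.frame(gene_id = names(dir),
                                 direction = as.numeric(dir),
                                 regulator = reg,
                                 stringsAsFactors = FALSE)
  }
  if (!length(per_reg)) {
    return(data.frame(gene_id = character(), direction = numeric(),
                      ambiguous = logical()))
  }
  all <- do.call(rbind, per_reg)
  ids <- sort(unique(all$gene_id))
  dir_of <- vapply(ids, function(g) {
    v <- all$direction[all$gene_id == g]
    if (all(v == v[1L])) v[1L] else 0
  }, numeric(1L))
  n_reg <- vapply(ids, function(g)
    length(unique(all$regulator[all$gene_id == g])), integer(1L))
  res <- data.frame(gene_id = ids, direction = dir_of,
                    ambiguous = dir_of == 0,
                    stringsAsFactors = FALSE)
  if (direction_filter == "same_direction") {
    drop <- res$ambiguous & n_reg > 1L
    res <- res[!drop, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Hypergeometric overlap significance of two gene sets
#'
#' Upper-tail p-value of the observed overlap under the
#' hypergeometric null (draw |B| genes from a universe containing |A|
#' marked ones), computed in log space so extreme significances do not
#' underflow.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe_size size of the gene universe.
#' @return list with `overlap`, `p` (may underflow to 0), and
#'   `neg_log10_p` (log-space, always finite).
#' @export
overlap_significance <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_union <- length(unique(c(set_a, set_b)))
  if (universe_size < n_union) stop("universe smaller than the union of sets")
  k <- length(intersect(set_a, set_b))
  log_p <- stats::phyper(k - 1, length(set_a),
                         universe_size - length(set_a), length(set_b),
                         lower.tail = FALSE, log.p = TRUE)
  list(overlap = k, p = exp(log_p), neg_log10_p = -log_p / log(10))
}

#' Bound-and-regulated target genes
#'
#' Intersects a bound-gene set with a filtered DE gene set: the
#' operational definition of a putative direct target.
#'
#' @param bound character vector from [bound_genes()].
#' @param de data.frame from [de_gene_sets()].
#' @return data.frame of target genes with direction.
#' @export
bound_and_regulated <- function(bound, de) {
  res <- de[de$gene_id %in% bound, , drop = FALSE]
  rownames(res) <- NULL
  res
}
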