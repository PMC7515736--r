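# End-to-end orchestration over a synthetic dataset: simulate ->
# pool -> compare -> motif -> evaluate -> spacing -> targets, with a
# validated parameter set, per-stage logging of counts in/out, and a
# run manifest (config snapshot, seed, file checksums) that fully
# determines reproduction.

#' Pipeline parameter set
#'
#' Every printed constant of the analysis is a named default here:
#' reproducibility cutoff 1e-4, summit half-width 200 bp, common-peak
#' overlap fraction 0.8 with < 50% non-overlap, specificity fold 2,
#' 600 training peaks, motif width 16, regulatory region 3 kb
#' upstream / 1 kb downstream, spacing range 100 bp.
#'
#' @param min_replicates replicate support for a consensus peak.
#' @param reproducibility_alpha Fisher-combined p cutoff.
#' @param half_width summit half-width (bp).
#' @param overlap_f common-peak overlap fraction.
#' @param nonoverlap_max maximal non-overlap fraction.
#' @param specificity_fold specificity fold threshold.
#' @param training_n motif training peaks.
#' @param motif_w motif width (bp).
#' @param site_threshold site score threshold for spacing analysis.
#' @param s_max maximal spacing (bp).
#' @param preferred_spacings preferred spacing set (bp).
#' @param gc_bin GC bin width for negative matching.
#' @param upstream,downstream regulatory region extents (bp).
#' @param seed master seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_replicates = 2L,
                            reproducibility_alpha = 1e-4,
                            half_width = 200L,
                            overlap_f = 0.8, nonoverlap_max = 0.5,
                            specificity_fold = 2,
                            training_n = 600L, motif_w = 16L,
                            site_threshold = 0.9, s_max = 100L,
                            preferred_spacings = c(36L, 37L, 46L, 47L, 57L),
                            gc_bin = 0.05,
                            upstream = 3000L, downstream = 1000L,
                            seed = 1L) {
  stopifnot(min_replicates >= 1L,
            reproducibility_alpha > 0, reproducibility_alpha <= 1,
            half_width > 0L,
            overlap_f > 0, overlap_f <= 1,
            nonoverlap_max > 0, nonoverlap_max <= 1,
            specificity_fold >= 1,
            training_n >= 1L, motif_w >= 4L,
            site_threshold > 0, site_threshold < 1,
            s_max >= 1L, all(preferred_spacings <= s_max),
            gc_bin > 0, gc_bin < 1,
            upstream >= 0L, downstream >= 0L)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stages <- c("simulate", "pool", "compare", "motif", "evaluate",
                     "spacing", "targets")

#' Run the analysis pipeline on a synthetic dataset
#'
#' Generates a dimer and a tetramer experiment from one synthetic
#' genome and runs the downstream stages through `stage`. Outputs are
#' written under `outdir` together with a manifest; rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config `pipeline_config`.
#' @param synth `synth_config` for the generator (its seed follows the
#'   pipeline seed unless given explicitly).
#' @param outdir run directory (created).
#' @param stage run through this stage (default `"targets"` = all).
#' @param quiet suppress stage logging.
#' @return list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         synth = synth_config(seed = config$seed),
                         outdir = NULL, stage = "targets",
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            stage %in% pipeline_stages)
  last <- match(stage, pipeline_stages)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  res <- list(config = config, synth_config = synth)
  want_out <- !is.null(outdir)
  if (want_out) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # simulate
  say("simulate: genome ", synth$genome_length, " bp, ",
      synth$n_single_sites, " single sites, ", synth$n_pair_sites,
      " pairs")
  gen <- generate_genome(synth)
  truth <- assign_regulatory_truth(gen$truth, generate_gene_models(gen$truth))
  dimer <- simulate_experiment(gen$genome, truth, synth, "dimer")
  tetramer <- simulate_experiment(gen$genome, truth, synth, "tetramer")
  res$genome <- gen$genome; res$truth <- truth
  res$dimer <- dimer; res$tetramer <- tetramer
  if (want_out) write_fasta(gen$genome, file.path(outdir, "genome.fa"))
  if (last == 1L) return(finish_run(res, outdir, quiet))

  # pool
  res$cons <- lapply(list(tetramer = tetramer, dimer = dimer), function(ex) {
    consensus_peaks(ex$peaks, ex$tracks,
                    reproducibility_alpha = config$reproducibility_alpha,
                    min_replicates = config$min_replicates,
                    half_width = config$half_width)
  })
  say("pool: ", nrow(res$cons$tetramer), " tetramer / ",
      nrow(res$cons$dimer), " dimer consensus peaks (from ",
      sum(vapply(tetramer$peaks, nrow, integer(1L))), " / ",
      sum(vapply(dimer$peaks, nrow, integer(1L))), " replicate calls)")
  if (want_out) {
    write_consensus_bed(res$cons$tetramer,
                        file.path(outdir, "consensus_tetramer.bed"))
    write_consensus_bed(res$cons$dimer,
                        file.path(outdir, "consensus_dimer.bed"))
  }
  if (last == 2L) return(finish_run(res, outdir, quiet))

  # compare (A = tetramer, B = dimer: CFR = tetramer / dimer)
  uni <- build_union_catalogue(res$cons$tetramer, res$cons$dimer,
                               tetramer$tracks, dimer$tracks,
                               min_frac = config$overlap_f,
                               max_nonoverlap = config$nonoverlap_max,
                               fold = config$specificity_fold,
                               half_width = config$half_width)
  res$union <- cfr_rank_and_deciles(uni)
  say("compare: ", nrow(uni), " union entries (",
      sum(uni$label == "common"), " common, ",
      sum(uni$label == "A_specific"), " tetramer-specific, ",
      sum(uni$label == "B_specific"), " dimer-specific)")
  if (want_out) write_union_bed(res$union, file.path(outdir, "union.bed"))
  if (last == 3L) return(finish_run(res, outdir, quiet))

  # motif (trained on the tetramer experiment's top peaks)
  train <- select_training_peaks(res$cons$tetramer, res$genome,
                                 n = config$training_n)
  res$training_peaks <- train$peaks
  res$pwm <- train_pwm(train$seqs, W = config$motif_w, palindromic = TRUE,
                       seed = config$seed)
  res$tffm <- train_tffm(train$seqs, res$pwm, seed = config$seed)
  say("motif: PWM + TFFM trained on ", length(train$seqs), " peaks")
  if (want_out) {
    model_to_json(res$pwm, file.path(outdir, "pwm.json"))
    model_to_json(res$tffm, file.path(outdir, "tffm.json"))
    write_meme(res$pwm, file.path(outdir, "pwm.meme"))
  }
  if (last == 4L) return(finish_run(res, outdir, quiet))

  # evaluate on held-out peaks vs matched negatives
  key <- paste(res$cons$tetramer$chrom, res$cons$tetramer$start)
  train_key <- paste(train$peaks$chrom, train$peaks$start)
  held <- res$cons$tetramer[!key %in% train_key, , drop = FALSE]
  if (nrow(held) < 20L) held <- res$cons$tetramer  # tiny runs: evaluate on all
  all_peaks <- rbind(res$cons$tetramer[, c("chrom", "start", "end")],
                     res$cons$dimer[, c("chrom", "start", "end")])
  res$negatives <- sample_matched_negatives(held, res$genome,
                                            res$truth$genes, all_peaks,
                                            gc_bin = config$gc_bin,
                                            seed = config$seed)
  pos_seqs <- get_sequences(res$genome, held)
  neg_seqs <- get_sequences(res$genome, res$negatives)
  res$auroc_pwm <- compute_auroc(res$pwm, pos_seqs, neg_seqs)
  res$auroc_tffm <- compute_auroc(res$tffm, pos_seqs, neg_seqs)
  say(sprintf("evaluate: AUROC PWM %.3f, TFFM %.3f (%d regions)",
              res$auroc_pwm$auroc, res$auroc_tffm$auroc, length(pos_seqs)))
  if (last == 5L) return(finish_run(res, outdir, quiet))

  # spacing
  pos_seqs_all <- get_sequences(res$genome, res$cons$tetramer)
  res$spacing <- spacing_profile(pos_seqs_all, neg_seqs, res$tffm,
                                 threshold = config$site_threshold,
                                 s_max = config$s_max)
  res$decile_spacing <- preferred_spacing_fraction_by_decile(
    res$union, res$genome, res$tffm, threshold = config$site_threshold,
    preferred = config$preferred_spacings, s_max = config$s_max)
  best_n <- res$spacing$n[which.max(res$spacing$N)]
  say("spacing: peak enrichment at n = ", best_n)
  if (want_out) {
    utils::write.table(res$spacing, file.path(outdir, "spacing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$decile_spacing,
                       file.path(outdir, "decile_spacing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (last == 6L) return(finish_run(res, outdir, quiet))

  # targets
  regions <- regulatory_regions(res$truth$genes,
                                upstream = config$upstream,
                                downstream = config$downstream,
                                chrom_lengths = res$truth$chrom_lengths)
  res$bound <- bound_genes(res$cons$tetramer, regions)
  de <- generate_de_table(res$truth, synth)
  res$de_set <- de_gene_sets(list(de))
  res$targets <- bound_and_regulated(res$bound, res$de_set)
  res$overlap_sig <- overlap_significance(res$bound, res$de_set$gene_id,
                                          nrow(res$truth$genes))
  say("targets: ", length(res$bound), " bound genes, ",
      nrow(res$de_set), " DE genes, ", nrow(res$targets),
      " bound-and-regulated (-log10 p = ",
      round(res$overlap_sig$neg_log10_p, 1), ")")
  if (want_out) {
    writeLines(res$targets$gene_id, file.path(outdir, "targets.txt"))
    writeLines(res$bound, file.path(outdir, "bound_genes.txt"))
  }
  finish_run(res, outdir, quiet)
}

# manifest: config snapshot + md5 of every written file
finish_run <- function(res, outdir, quiet) {
  if (!is.null(outdir)) {
    files <- setdiff(list.files(outdir), "manifest.json")
    sums <- tools::md5sum(file.path(outdir, files))
    manifest <- list(
      seed = res$config$seed,
      package_version = tryCatch(
        as.character(utils::packageVersion("dapcompare")),
        error = function(e) "unknown"),
      config = unclass(res$config),
      synth_config = unclass(res$synth_config[setdiff(names(res$synth_config),
                                                      "motif")]),
      checksums = as.list(stats::setNames(unname(sums), files)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    if (!quiet) message("manifest written to ",
                        file.path(outdir, "manifest.json"))
  }
  invisible(res)
}
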