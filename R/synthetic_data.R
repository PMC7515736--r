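# Synthetic seq-DAP-seq data with recorded ground truth.
#
# The generator plants binding sites sampled from a CArG-like truth
# motif into a GC-heterogeneous background genome, both as single sites
# (accessible to a dimer) and as site pairs at controlled
# center-to-center spacings whose doubly-bound state carries a
# cooperativity bonus omega(d) (accessible to a tetramer). Replicate
# coverage tracks and peak calls with summit jitter, plus
# differential-expression tables statistically coupled to binding,
# make every downstream stage testable without sequencing data.

#' Default CArG-like truth motif
#'
#' A 16-bp quasi-palindromic PWM with a CC(A/T-rich)GG core and mildly
#' A/T-leaning flanks. The numbers are generator parameters, not
#' estimates from any dataset.
#'
#' @param pseudocount passed through to [pwm_model()].
#' @return `pwm_model` of width 16.
#' @export
default_truth_motif <- function(pseudocount = 0.01) {
  strong <- function(b) { p <- rep(0.05, 4); p[match(b, BASES)] <- 0.85; p }
  at_rich <- c(0.42, 0.08, 0.08, 0.42)
  flank <- c(0.32, 0.18, 0.18, 0.32)
  probs <- matrix(flank, 4L, 16L)
  probs[, 4L] <- strong("C"); probs[, 5L] <- strong("C")
  for (k in 6:11) probs[, k] <- at_rich
  probs[, 12L] <- strong("G"); probs[, 13L] <- strong("G")
  probs <- (probs + probs[4:1, 16:1]) / 2  # exactly palindromic
  probs <- sweep(probs, 2L, colSums(probs), "/")
  pwm_model(probs, pseudocount = pseudocount)
}

#' Synthetic dataset configuration
#'
#' Collects every generator parameter with validated defaults. The
#' defaults describe the study conditions used throughout the package:
#' a 1-Mb two-chromosome genome at Arabidopsis-like GC content, 300
#' single sites, 150 site pairs at center-to-center spacings 36/46/57 bp
#' with helical-phase cooperativity, two replicates with overdispersed
#' coverage and 10-bp summit jitter.
#'
#' @param genome_length total genome length (bp).
#' @param n_chrom number of chromosomes (equal sizes).
#' @param gc_mean,gc_sd per-window target GC content (10-kb windows).
#' @param motif truth motif (`pwm_model`), default [default_truth_motif()].
#' @param n_single_sites planted single (dimer) sites.
#' @param n_pair_sites planted site pairs (tetramer loci).
#' @param n_decoy_sites motif occurrences planted in the background
#'   that generate no binding signal, emulating the unbound motif
#'   matches that pervade real genomes; they give unbound regions a
#'   realistic motif-hit rate (and hence a usable spacing background).
#' @param spacings center-to-center pair spacings (bp).
#' @param spacing_weights sampling weights for `spacings`.
#' @param omega_amplitude cooperativity peak height at the preferred
#'   spacings (omega(d) = 1 elsewhere).
#' @param binding_scale Boltzmann weight of a median-affinity site.
#'   Below 1 keeps typical sites sub-saturated so cooperativity
#'   translates into coverage fold differences.
#' @param affinity_temper exponent gamma mapping sequence likelihood
#'   ratio to binding weight, w = binding_scale *
#'   (LR / LR_median)^gamma. Below 1 compresses the site-affinity
#'   spread (binding energy scales sublinearly with log LR), keeping
#'   strong sites from saturating both complexes.
#' @param omega_sd Gaussian width (bp) of each cooperativity bump.
#' @param omega_harmonics additional bumps at +10.5 bp multiples
#'   (helical phasing); 0 disables.
#' @param n_replicates replicate experiments (2-4).
#' @param nb_size negative-binomial size (overdispersion) of per-bp
#'   coverage counts.
#' @param summit_jitter_sd per-replicate summit jitter (bp).
#' @param background_rate expected background coverage per bp (reads).
#' @param cov_scale peak coverage amplitude per unit occupancy
#'   (reads per bp at the summit).
#' @param calling_floor minimal expected amplitude for a peak call.
#' @param n_noise_peaks spurious single-replicate peaks per replicate.
#' @param library_size total mapped reads used for RPM scaling, the
#'   same for every replicate and experiment (libraries sequenced to
#'   matched depth); `NULL` defaults to 1.5 x genome_length x
#'   background_rate.
#' @param s_max maximal spacing considered downstream (bp).
#' @param n_genes gene models tiled over the genome.
#' @param reg_prob probability that a gene bound at a planted locus is
#'   truly regulated.
#' @param bg_reg_prob probability that an unbound gene is regulated.
#' @param de_sensitivity probability that a truly regulated gene passes
#'   the DE filter.
#' @param de_fp_rate probability that an unregulated gene passes it.
#' @param seed random seed fixing every draw.
#' @return validated config list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 1e6, n_chrom = 2L,
                         gc_mean = 0.36, gc_sd = 0.05,
                         motif = default_truth_motif(),
                         n_single_sites = 300L, n_pair_sites = 150L,
                         n_decoy_sites = 500L,
                         spacings = c(36L, 46L, 57L),
                         spacing_weights = c(1, 1, 1),
                         omega_amplitude = 16, omega_sd = 1.5,
                         omega_harmonics = 0L, binding_scale = 0.2,
                         affinity_temper = 0.4,
                         n_replicates = 2L, nb_size = 10,
                         summit_jitter_sd = 10,
                         background_rate = 2, cov_scale = 100,
                         calling_floor = 5, n_noise_peaks = 25L,
                         library_size = NULL,
                         s_max = 100L,
                         n_genes = 200L, reg_prob = 0.6,
                         bg_reg_prob = 0.05,
                         de_sensitivity = 0.9, de_fp_rate = 0.03,
                         seed = 1L) {
  stopifnot(genome_length >= 1e4, n_chrom >= 1L,
            gc_mean > 0, gc_mean < 1, gc_sd >= 0,
            inherits(motif, "pwm_model"),
            n_single_sites >= 0L, n_pair_sites >= 0L,
            n_decoy_sites >= 0L,
            length(spacings) == length(spacing_weights),
            all(spacings <= s_max), all(spacing_weights > 0),
            omega_amplitude >= 0, omega_sd > 0, binding_scale > 0,
            affinity_temper > 0, affinity_temper <= 1,
            n_replicates >= 1L, n_replicates <= 4L,
            nb_size > 0, summit_jitter_sd >= 0,
            background_rate > 0, cov_scale > 0, calling_floor >= 0,
            n_genes >= 0L,
            reg_prob >= 0, reg_prob <= 1, bg_reg_prob >= 0, bg_reg_prob <= 1,
            de_sensitivity >= 0, de_sensitivity <= 1,
            de_fp_rate >= 0, de_fp_rate <= 1)
  cfg <- as.list(environment())
  if (is.null(cfg$library_size)) {
    cfg$library_size <- 1.5 * genome_length * background_rate
  }
  stopifnot(cfg$library_size > 0)
  class(cfg) <- "synth_config"
  cfg
}

#' Cooperativity profile omega(d)
#'
#' Gaussian bumps of height `omega_amplitude` (above a baseline of 1) at
#' the configured spacings, optionally repeated at +10.5-bp harmonics to
#' mimic helical phasing.
#'
#' @param d spacing(s), bp.
#' @param config `synth_config`.
#' @return omega(d) >= 1, vectorised over `d`.
#' @export
omega_profile <- function(d, config) {
  centers <- config$spacings
  if (config$omega_harmonics > 0L) {
    centers <- unique(as.vector(outer(config$spacings,
                                      10.5 * 0:config$omega_harmonics, "+")))
  }
  bump <- vapply(centers, function(ct)
    exp(-(d - ct)^2 / (2 * config$omega_sd^2)), numeric(length(d)))
  bump <- if (length(d) == 1L) sum(bump) else rowSums(matrix(bump,
                                                             nrow = length(d)))
  1 + config$omega_amplitude * bump
}

sample_site_seq <- function(motif) {
  paste(apply(motif$probs, 2L, function(p) sample(BASES, 1L, prob = p)),
        collapse = "")
}

#' Generate a synthetic genome with planted sites
#'
#' Background nucleotides are drawn per 10-kb window at that window's
#' target GC; single sites and site pairs are sampled from the truth
#' motif, written on random strands at non-colliding positions, and all
#' positions recorded in the truth object.
#'
#' @param config `synth_config`.
#' @return list with `genome` (named character vector) and `truth`
#'   (class `synth_truth`: `sites` data.frame with `chrom`, `start`,
#'   `center`, `strand`, `kind`, `pair_id`, `spacing`, `loglr`; plus
#'   `config` echo and `seed`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  W <- config$motif$W
  chrom_len <- as.integer(config$genome_length / config$n_chrom)
  chroms <- paste0("chr", seq_len(config$n_chrom))

  genome <- vapply(chroms, function(ch) {
    win <- 10000L
    n_win <- ceiling(chrom_len / win)
    gc <- pmin(0.8, pmax(0.1, stats::rnorm(n_win, config$gc_mean, config$gc_sd)))
    paste(vapply(seq_len(n_win), function(i) {
      len <- min(win, chrom_len - (i - 1L) * win)
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
    }, character(1L)), collapse = "")
  }, character(1L))

  occupied <- lapply(chroms, function(ch) integer(0L))
  names(occupied) <- chroms
  place <- function(width) {
    for (try in seq_len(1000L)) {
      ch <- sample(chroms, 1L)
      start <- sample.int(chrom_len - width + 1L, 1L) - 1L
      hit <- occupied[[ch]]
      if (!length(hit) || all(start + width <= hit | start >= hit + W)) {
        occupied[[ch]] <<- c(hit, seq.int(start, start + width - W))
        return(list(chrom = ch, start = start))
      }
    }
    stop("could not place a site after 1000 attempts; genome too crowded")
  }
  write_site <- function(ch, start, site) {
    substr(genome[[ch]], start + 1L, start + W) <<- site
  }

  rows <- list()
  for (i in seq_len(config$n_single_sites)) {
    loc <- place(W)
    site <- sample_site_seq(config$motif)
    strand <- sample(c("+", "-"), 1L)
    write_site(loc$chrom, loc$start,
               if (strand == "+") site else revcomp_seq(site))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = loc$chrom, start = loc$start, center = loc$start + (W - 1) / 2,
      strand = strand, kind = "single", pair_id = NA_integer_,
      spacing = NA_real_, stringsAsFactors = FALSE)
  }
  sp_prob <- config$spacing_weights / sum(config$spacing_weights)
  for (i in seq_len(config$n_pair_sites)) {
    d <- if (length(config$spacings) == 1L) config$spacings else
      sample(config$spacings, 1L, prob = sp_prob)
    loc <- place(W + d)  # center-to-center distance d => extent W + d
    for (j in 0:1) {
      start <- loc$start + j * d
      site <- sample_site_seq(config$motif)
      strand <- sample(c("+", "-"), 1L)
      write_site(loc$chrom, start,
                 if (strand == "+") site else revcomp_seq(site))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = loc$chrom, start = start, center = start + (W - 1) / 2,
        strand = strand, kind = "pair", pair_id = i,
        spacing = d, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(config$n_decoy_sites)) {
    loc <- place(W)
    site <- sample_site_seq(config$motif)
    strand <- sample(c("+", "-"), 1L)
    write_site(loc$chrom, loc$start,
               if (strand == "+") site else revcomp_seq(site))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = loc$chrom, start = loc$start, center = loc$start + (W - 1) / 2,
      strand = strand, kind = "decoy", pair_id = NA_integer_,
      spacing = NA_real_, stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), center = numeric(),
               strand = character(), kind = character(),
               pair_id = integer(), spacing = numeric(),
               stringsAsFactors = FALSE)
  # likelihood ratio of each planted site as written (affinity truth)
  if (nrow(sites)) {
    win <- get_sequences(genome, data.frame(chrom = sites$chrom,
                                            start = sites$start,
                                            end = sites$start + W))
    sites$loglr <- vapply(win, function(w) {
      X <- seqs_to_mat(w)
      max(window_loglr(config$motif, X)[1L, 1L],
          window_loglr(config$motif, revcomp_mat(X))[1L, 1L])
    }, numeric(1L), USE.NAMES = FALSE)
  } else sites$loglr <- numeric(0L)

  truth <- structure(list(sites = sites, config = config,
                          chrom_lengths = stats::setNames(rep(chrom_len,
                                                              config$n_chrom),
                                                          chroms),
                          seed = config$seed),
                     class = "synth_truth")
  list(genome = genome, truth = truth)
}

# locus table: one row per independent binding locus with expected
# occupancy under each complex kind (thermodynamic two-site model)
locus_table <- function(truth) {
  cfg <- truth$config
  s <- truth$sites[truth$sites$kind != "decoy", , drop = FALSE]
  if (!nrow(s)) {
    return(data.frame(chrom = character(), center = numeric(),
                      occ_dimer = numeric(), occ_tetramer = numeric()))
  }
  lr_ref <- stats::median(s$loglr)   # median site: weight binding_scale
  w <- cfg$binding_scale * exp(cfg$affinity_temper * (s$loglr - lr_ref))
  singles <- s$kind == "single"
  out <- data.frame(chrom = s$chrom[singles], center = s$center[singles],
                    occ_dimer = w[singles] / (1 + w[singles]),
                    occ_tetramer = w[singles] / (1 + w[singles]),
                    stringsAsFactors = FALSE)
  for (pid in unique(s$pair_id[!is.na(s$pair_id)])) {
    pp <- s[!is.na(s$pair_id) & s$pair_id == pid, ]
    w1 <- cfg$binding_scale *
      exp(cfg$affinity_temper * (pp$loglr[1L] - lr_ref))
    w2 <- cfg$binding_scale *
      exp(cfg$affinity_temper * (pp$loglr[2L] - lr_ref))
    om <- omega_profile(pp$spacing[1L], cfg)
    occ_d <- (w1 + w2 + 2 * w1 * w2) / (1 + w1 + w2 + w1 * w2)
    occ_t <- (w1 + w2 + 2 * w1 * w2 * om) / (1 + w1 + w2 + w1 * w2 * om)
    out <- rbind(out, data.frame(chrom = pp$chrom[1L],
                                 center = mean(pp$center),
                                 occ_dimer = occ_d, occ_tetramer = occ_t,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Simulate a replicate seq-DAP-seq experiment
#'
#' Expected coverage at each planted locus follows a thermodynamic
#' two-site occupancy model: each site carries a Boltzmann weight
#' `w = LR / LR_ref`; a dimer binds sites independently while a
#' tetramer multiplies the doubly-bound state's weight by the
#' cooperativity omega(spacing). Expected per-bp coverage is background
#' plus a triangular summit kernel scaled by occupancy; replicate
#' counts are negative-binomial, summits are jittered, and peaks are
#' emitted where the expected amplitude clears the calling floor, with
#' a -log10 p from the Poisson tail of the observed window count.
#'
#' @param genome named character vector from [generate_genome()].
#' @param truth matching `synth_truth`.
#' @param config `synth_config` (usually `truth$config`).
#' @param complex_kind `"dimer"` or `"tetramer"`.
#' @return list with `peaks` (list of narrowPeak-style data.frames, one
#'   per replicate), `tracks` (list of coverage tracks) and `loci`
#'   (expected-signal table).
#' @export
simulate_experiment <- function(genome, truth, config = truth$config,
                                complex_kind = c("dimer", "tetramer")) {
  complex_kind <- match.arg(complex_kind)
  stopifnot(inherits(truth, "synth_truth"))
  set.seed(config$seed + switch(complex_kind, dimer = 1000L,
                                tetramer = 2000L))
  loci <- locus_table(truth)
  occ <- if (complex_kind == "dimer") loci$occ_dimer else loci$occ_tetramer
  amp <- config$cov_scale * occ
  chrom_lengths <- truth$chrom_lengths
  half_k <- 150L  # summit kernel half-width
  kernel <- 1 - abs(-half_k:half_k) / (half_k + 1)

  peaks <- vector("list", config$n_replicates)
  tracks <- vector("list", config$n_replicates)
  called <- amp >= config$calling_floor
  for (r in seq_len(config$n_replicates)) {
    mu <- lapply(chrom_lengths, function(len) rep(config$background_rate, len))
    for (i in seq_len(nrow(loci))) {
      ctr <- round(loci$center[i])
      lo <- max(0L, ctr - half_k); hi <- min(chrom_lengths[[loci$chrom[i]]],
                                             ctr + half_k + 1L)
      if (hi <= lo) next
      kidx <- (lo - (ctr - half_k) + 1L):(half_k * 2L + 1L - ((ctr + half_k + 1L) - hi))
      mu[[loci$chrom[i]]][(lo + 1L):hi] <-
        mu[[loci$chrom[i]]][(lo + 1L):hi] + amp[i] * kernel[kidx]
    }
    cov <- lapply(mu, function(m) as.numeric(stats::rnbinom(length(m),
                                                            size = config$nb_size,
                                                            mu = m)))
    names(cov) <- names(chrom_lengths)
    tracks[[r]] <- coverage_track(cov, library_size = config$library_size)

    # spurious single-replicate peaks near the calling floor
    n_noise <- config$n_noise_peaks
    noise <- if (n_noise > 0L) data.frame(
      chrom = sample(names(chrom_lengths), n_noise, replace = TRUE),
      center = NA_real_) else data.frame(chrom = character(),
                                         center = numeric())
    if (n_noise > 0L) {
      noise$center <- vapply(noise$chrom, function(ch)
        stats::runif(1L, 300, chrom_lengths[[ch]] - 300), numeric(1L))
    }
    all_ctr <- c(round(loci$center[called]), round(noise$center))
    all_chr <- c(loci$chrom[called], noise$chrom)
    if (length(all_ctr)) {
      summit <- all_ctr + round(stats::rnorm(length(all_ctr), 0,
                                             config$summit_jitter_sd))
      summit <- pmax(200L, pmin(summit,
                                chrom_lengths[all_chr] - 201L))
      start <- summit - 200L; end <- summit + 201L
      obs <- vapply(seq_along(summit), function(i)
        sum(tracks[[r]]$cov[[all_chr[i]]][(start[i] + 1L):end[i]]),
        numeric(1L))
      bg_mean <- config$background_rate * 401
      nlp <- -stats::ppois(obs - 1, bg_mean, lower.tail = FALSE,
                           log.p = TRUE) / log(10)
      o <- order(all_chr, start)
      peaks[[r]] <- data.frame(
        chrom = all_chr, start = start, end = end,
        name = sprintf("%s_rep%d_peak%d", complex_kind, r,
                       seq_along(summit)),
        score = round(pmin(1000, nlp * 10)), strand = ".",
        signal = obs / 401, neg_log10_p = nlp,
        neg_log10_q = pmax(0, nlp - 2), summit_offset = 200L,
        stringsAsFactors = FALSE)[o, ]
      rownames(peaks[[r]]) <- NULL
    } else {
      peaks[[r]] <- utils::read.table(text = "",
        col.names = c("chrom", "start", "end", "name", "score", "strand",
                      "signal", "neg_log10_p", "neg_log10_q",
                      "summit_offset"))
    }
  }
  list(peaks = peaks, tracks = tracks, loci = cbind(loci, amplitude = amp))
}

#' Tile gene models over a synthetic genome
#'
#' Genes of 2 kb are placed at regular intervals on alternating strands.
#'
#' @param truth `synth_truth` (for chromosome lengths and config).
#' @return gene-model data.frame (`gene_id`, `chrom`, `strand`, `tss`,
#'   `tts`).
#' @export
generate_gene_models <- function(truth) {
  cfg <- truth$config
  n <- cfg$n_genes
  if (n == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      tts = integer(), stringsAsFactors = FALSE))
  }
  chroms <- names(truth$chrom_lengths)
  per_chrom <- ceiling(n / length(chroms))
  rows <- list()
  gid <- 0L
  glen <- 2000L
  for (ch in chroms) {
    len <- truth$chrom_lengths[[ch]]
    step <- max(glen + 1000L, floor((len - 8000L) / per_chrom))
    starts <- seq(4000L, by = step, length.out = per_chrom)
    starts <- starts[starts + glen < len - 4000L]
    for (i in seq_along(starts)) {
      gid <- gid + 1L
      if (gid > n) break
      strand <- if (gid %% 2L == 1L) "+" else "-"
      rows[[gid]] <- data.frame(
        gene_id = sprintf("GENE%04d", gid), chrom = ch, strand = strand,
        tss = if (strand == "+") starts[i] else starts[i] + glen,
        tts = if (strand == "+") starts[i] + glen else starts[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Assign truth regulatory status to genes
#'
#' A gene whose regulatory region (3 kb upstream of the TSS to 1 kb past
#' the TTS) contains a planted locus is regulated with probability
#' `reg_prob`; other genes with probability `bg_reg_prob`. Direction is
#' a fair coin. Draws are fixed by the config seed.
#'
#' @param truth `synth_truth`.
#' @param genes gene models from [generate_gene_models()].
#' @return `truth` with a `genes` element (adds `bound`, `regulated`,
#'   `direction`).
#' @export
assign_regulatory_truth <- function(truth, genes) {
  cfg <- truth$config
  set.seed(cfg$seed + 3000L)
  reg <- regulatory_regions(genes, chrom_lengths = truth$chrom_lengths)
  s <- truth$sites[truth$sites$kind != "decoy", , drop = FALSE]
  bound <- vapply(seq_len(nrow(genes)), function(i) {
    any(s$chrom == reg$chrom[i] & s$center >= reg$start[i] &
          s$center < reg$end[i])
  }, logical(1L))
  regulated <- ifelse(bound, stats::runif(nrow(genes)) < cfg$reg_prob,
                      stats::runif(nrow(genes)) < cfg$bg_reg_prob)
  direction <- ifelse(stats::runif(nrow(genes)) < 0.5, 1L, -1L)
  genes$bound <- bound
  genes$regulated <- regulated
  genes$direction <- ifelse(regulated, direction, 0L)
  truth$genes <- genes
  truth
}

#' Generate a differential-expression table coupled to binding truth
#'
#' Truth-regulated genes pass the DE filter (|logFC| > 1, FDR < 0.05)
#' with probability `sensitivity`; unregulated genes pass with
#' probability `fp_rate`, by construction.
#'
#' @param truth `synth_truth` carrying `genes` (see
#'   [assign_regulatory_truth()]).
#' @param config `synth_config`.
#' @param sensitivity,fp_rate override the config values.
#' @param seed_offset differentiates several tables from one truth.
#' @return data.frame (`gene_id`, `logFC`, `FDR`).
#' @export
generate_de_table <- function(truth, config = truth$config,
                              sensitivity = config$de_sensitivity,
                              fp_rate = config$de_fp_rate,
                              seed_offset = 0L) {
  stopifnot(!is.null(truth$genes))
  set.seed(config$seed + 4000L + seed_offset)
  g <- truth$genes
  n <- nrow(g)
  pass <- ifelse(g$regulated, stats::runif(n) < sensitivity,
                 stats::runif(n) < fp_rate)
  dir <- ifelse(g$direction != 0L, g$direction,
                ifelse(stats::runif(n) < 0.5, 1L, -1L))
  logFC <- ifelse(pass, dir * stats::runif(n, 1.2, 3),
                  stats::runif(n, -0.95, 0.95))
  fdr <- ifelse(pass, 10^-stats::runif(n, 1.5, 8),
                stats::runif(n, 0.05, 1))
  data.frame(gene_id = g$gene_id, logFC = logFC, FDR = fdr,
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits FASTA, per-replicate narrowPeak and bedGraph for both complex
#' kinds, the gene-model TSV, a DE TSV and a truth JSON.
#'
#' @param dir output directory (created).
#' @param config `synth_config`.
#' @return invisibly, a list with the in-memory objects.
#' @export
write_synthetic_dataset <- function(dir, config = synth_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  truth <- assign_regulatory_truth(gen$truth, generate_gene_models(gen$truth))
  dimer <- simulate_experiment(gen$genome, truth, config, "dimer")
  tetramer <- simulate_experiment(gen$genome, truth, config, "tetramer")
  write_fasta(gen$genome, file.path(dir, "genome.fa"))
  for (r in seq_len(config$n_replicates)) {
    for (kind in c("dimer", "tetramer")) {
      ex <- get(kind)
      write_narrowpeak(ex$peaks[[r]],
                       file.path(dir, sprintf("%s_rep%d.narrowPeak", kind, r)))
      write_bedgraph(ex$tracks[[r]],
                     file.path(dir, sprintf("%s_rep%d.bedGraph", kind, r)))
    }
  }
  libs <- do.call(rbind, lapply(c("dimer", "tetramer"), function(kind) {
    ex <- get(kind)
    data.frame(file = sprintf("%s_rep%d.bedGraph", kind,
                              seq_len(config$n_replicates)),
               library_size = vapply(ex$tracks, `[[`, numeric(1L),
                                     "library_size"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(libs, file.path(dir, "library_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_models(truth$genes, file.path(dir, "genes.tsv"))
  de <- generate_de_table(truth, config)
  utils::write.table(de, file.path(dir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed,
                            sites = truth$sites,
                            chrom_lengths = as.list(truth$chrom_lengths)),
                       file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(list(genome = gen$genome, truth = truth, dimer = dimer,
                 tetramer = tetramer, de = de))
}
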