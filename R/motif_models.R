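# Binding-site models: 0-order position weight matrix (PWM) and
# first-order transcription factor flexible model (TFFM).
#
# Both models score a W-mer on the normalized likelihood-ratio scale
# s = LR / (1 + LR), LR = P_model / P_background, so s is in [0, 1] with
# 0.5 at LR = 1 and 1 the best attainable score.

BASES <- c("A", "C", "G", "T")

# ACGT -> 1:4, anything else NA
seq_to_int <- function(s) {
  code <- rep(NA_integer_, 256L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(s)]
}

# equal-length sequences -> n x L integer matrix
seqs_to_mat <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  matrix(unlist(lapply(seqs, seq_to_int), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# reverse complement of an integer matrix (1234 = ACGT)
revcomp_mat <- function(X) {
  (5L - X)[, rev(seq_len(ncol(X))), drop = FALSE]
}

revcomp_seq <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Construct a PWM model
#'
#' @param probs 4 x W probability matrix (rows A, C, G, T); columns must
#'   sum to 1.
#' @param background length-4 background nucleotide distribution.
#' @param pseudocount pseudocount used during training (metadata).
#' @return object of class `pwm_model`.
#' @export
pwm_model <- function(probs, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(nrow(probs) == 4L, all(probs > 0),
            max(abs(colSums(probs) - 1)) < 1e-9,
            length(background) == 4L, abs(sum(background) - 1) < 1e-9)
  rownames(probs) <- BASES
  names(background) <- BASES
  structure(list(W = ncol(probs), probs = probs, background = background,
                 pseudocount = pseudocount),
            class = "pwm_model")
}

#' Construct a first-order TFFM model
#'
#' @param init length-4 distribution of the first motif position.
#' @param trans 4 x 4 x (W-1) array; `trans[p, c, k-1]` is
#'   P(position k emits c | previous base p).
#' @param bg_trans 4 x 4 first-order background transition matrix.
#' @return object of class `tffm_model`. The background start
#'   distribution is the stationary distribution of `bg_trans`.
#' @export
tffm_model <- function(init, trans, bg_trans) {
  W <- dim(trans)[3L] + 1L
  stopifnot(length(init) == 4L, abs(sum(init) - 1) < 1e-9,
            dim(trans)[1L] == 4L, dim(trans)[2L] == 4L,
            max(abs(apply(trans, c(1L, 3L), sum) - 1)) < 1e-9,
            max(abs(rowSums(bg_trans) - 1)) < 1e-9)
  structure(list(W = W, init = init, trans = trans, bg_trans = bg_trans,
                 bg_init = stationary_dist(bg_trans)),
            class = "tffm_model")
}

# stationary distribution of a 4x4 stochastic matrix (power iteration)
stationary_dist <- function(P) {
  v <- rep(0.25, 4L)
  for (i in seq_len(200L)) v <- as.vector(v %*% P)
  v / sum(v)
}

# log likelihood-ratio of every window at every offset, forward strand.
# X: n x L integer matrix (NA for N); returns n x (L - W + 1) matrix with
# NA where the window contains an N.
window_loglr <- function(model, X) UseMethod("window_loglr")

#' @export
window_loglr.pwm_model <- function(model, X) {
  W <- model$W; L <- ncol(X); J <- L - W + 1L
  if (J < 1L) stop("sequences shorter than motif width")
  lodds <- log(model$probs) - log(model$background)
  S <- matrix(0, nrow(X), J)
  for (k in seq_len(W)) {
    idx <- X[, k:(k + J - 1L), drop = FALSE]
    S <- S + matrix(lodds[, k][idx], nrow(X), J)
  }
  S
}

#' @export
window_loglr.tffm_model <- function(model, X) {
  W <- model$W; L <- ncol(X); J <- L - W + 1L
  if (J < 1L) stop("sequences shorter than motif width")
  n <- nrow(X)
  # dinucleotide codes: D[, m] encodes the pair (m, m+1)
  D <- (X[, -L, drop = FALSE] - 1L) * 4L + X[, -1L, drop = FALSE]
  l_init <- log(model$init) - log(model$bg_init)
  S <- matrix(l_init[X[, seq_len(J), drop = FALSE]], n, J)
  lb <- log(as.vector(t(model$bg_trans)))  # indexed by (prev-1)*4 + cur
  for (k in 2L:W) {
    lt <- log(as.vector(t(model$trans[, , k - 1L])))
    idx <- D[, (k - 1L):(k + J - 2L), drop = FALSE]
    S <- S + matrix((lt - lb)[idx], n, J)
  }
  S
}

loglr_to_score <- function(S) {
  out <- stats::plogis(S)
  out[is.na(out)] <- 0  # windows containing N score 0
  out
}

#' Score a single site
#'
#' Computes `s = LR / (1 + LR)` for one W-mer. With `strand = "both"`
#' (the default) both orientations are scored and the maximum returned.
#' Windows containing N score 0.
#'
#' @param model `pwm_model` or `tffm_model`.
#' @param window W-length nucleotide string.
#' @param strand `"both"`, `"+"` or `"-"`.
#' @return score in \[0, 1\].
#' @export
score_site <- function(model, window, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  if (nchar(window) != model$W) stop("window length must equal model width")
  X <- seqs_to_mat(window)
  sp <- loglr_to_score(window_loglr(model, X))[1L, 1L]
  if (strand == "+") return(sp)
  sm <- loglr_to_score(window_loglr(model, revcomp_mat(X)))[1L, 1L]
  if (strand == "-") return(sm)
  max(sp, sm)
}

#' Scan a region for binding sites
#'
#' Scores every offset on both strands. Hits at the same offset on both
#' strands collapse to the higher-scoring strand (tie: `+`).
#'
#' @param model `pwm_model` or `tffm_model`.
#' @param region_seq nucleotide string.
#' @param threshold report hits with score >= threshold.
#' @return list with `best_score` and `hits` (data.frame `offset`
#'   (0-based), `strand`, `score`). Regions shorter than the motif give
#'   an empty result with a warning.
#' @export
scan_region <- function(model, region_seq, threshold = 0.9) {
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nchar(region_seq) < model$W) {
    warning("region shorter than motif width; no sites scanned")
    return(list(best_score = NA_real_, hits = empty))
  }
  sc <- scan_scores(model, region_seq)
  keep <- which(sc$score >= threshold)
  list(best_score = max(sc$score),
       hits = data.frame(offset = sc$offset[keep], strand = sc$strand[keep],
                         score = sc$score[keep], stringsAsFactors = FALSE))
}

# per-offset strand-collapsed scores for one region
scan_scores <- function(model, region_seq) {
  X <- seqs_to_mat(region_seq)
  J <- ncol(X) - model$W + 1L
  sp <- loglr_to_score(window_loglr(model, X))[1L, ]
  smr <- loglr_to_score(window_loglr(model, revcomp_mat(X)))[1L, ]
  sm <- rev(smr)  # offset j on '-' corresponds to rc offset J - 1 - j
  data.frame(offset = 0:(J - 1L),
             strand = ifelse(sp >= sm, "+", "-"),
             score = pmax(sp, sm), stringsAsFactors = FALSE)
}

#' Best score per region
#'
#' Vectorised convenience wrapper around [scan_region()]; regions of
#' equal length are scored in one matrix pass.
#'
#' @param model motif model.
#' @param seqs character vector of region sequences.
#' @return numeric vector of best strand-collapsed scores.
#' @export
best_scores <- function(model, seqs) {
  out <- numeric(length(seqs))
  for (L in unique(nchar(seqs))) {
    j <- which(nchar(seqs) == L)
    if (L < model$W) { out[j] <- NA_real_; next }
    X <- seqs_to_mat(seqs[j])
    sp <- loglr_to_score(window_loglr(model, X))
    sm <- loglr_to_score(window_loglr(model, revcomp_mat(X)))
    out[j] <- pmax(apply(sp, 1L, max), apply(sm, 1L, max))
  }
  out
}

#' Select top training peaks and extract their sequences
#'
#' Takes the `n` consensus peaks with the highest mean normalized
#' coverage (ties broken by coordinate for determinism) and returns
#' their sequences.
#'
#' @param cons consensus peak data.frame (needs `mean_norm_cov`).
#' @param genome named character vector.
#' @param n number of training peaks (default 600).
#' @return list with `peaks` (the selected rows) and `seqs`.
#' @export
select_training_peaks <- function(cons, genome, n = 600L) {
  if (is.null(genome)) stop("genome sequence required to extract peaks")
  o <- order(-cons$mean_norm_cov, cons$chrom, cons$start)
  if (nrow(cons) < n) {
    warning(sprintf("only %d peaks available (requested %d); using all",
                    nrow(cons), n))
    n <- nrow(cons)
  }
  sel <- cons[o[seq_len(n)], , drop = FALSE]
  list(peaks = sel, seqs = unname(get_sequences(genome, sel)))
}

# most background-enriched k-mer: Poisson surprise of the observed
# count (forward + reverse collapsed) against a first-order
# (dinucleotide) background expectation, which damps homopolymer and
# compositional artifacts that a 0-order ratio rewards.
top_enriched_kmer <- function(seqs, k, background) {
  wins <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1L), k:L)
  }), use.names = FALSE)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (!length(wins)) stop("no valid ", k, "-mers in training sequences")
  tab <- table(wins)
  keys <- names(tab)
  cnt <- as.integer(tab)
  codes <- lapply(keys, seq_to_int)
  # first-order background over the training sequences
  allx <- lapply(seqs, seq_to_int)
  d16 <- numeric(16L); b4 <- numeric(4L)
  for (x in allx) {
    ok <- !is.na(x)
    b4 <- b4 + tabulate(x[ok], 4L)
    p <- x[-length(x)]; q <- x[-1L]
    pq <- !is.na(p) & !is.na(q)
    d16 <- d16 + tabulate((p[pq] - 1L) * 4L + q[pq], 16L)
  }
  bg1 <- matrix(d16 + 1, 4L, 4L, byrow = TRUE)
  bg1 <- bg1 / rowSums(bg1)
  b4 <- (b4 + 1) / sum(b4 + 4)
  lp1 <- function(w) {
    log(b4[w[1L]]) + sum(log(bg1[cbind(w[-length(w)], w[-1L])]))
  }
  lp <- vapply(codes, lp1, numeric(1L))
  rc_keys <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(keys)))
  m <- match(rc_keys, keys)
  extra <- ifelse(!is.na(m) & rc_keys != keys, cnt[ifelse(is.na(m), 1L, m)], 0L)
  tot <- cnt + extra
  lp_rc <- vapply(lapply(rc_keys, seq_to_int), lp1, numeric(1L))
  lambda <- (exp(lp) + ifelse(rc_keys != keys, exp(lp_rc), 0)) * length(wins)
  surprise <- -stats::ppois(tot - 1L, lambda, lower.tail = FALSE,
                            log.p = TRUE)
  expected_enriched <- tot > lambda
  if (!any(expected_enriched))
    stop("no ", k, "-mer enriched above background; try a smaller width")
  surprise[!expected_enriched] <- -Inf
  o <- order(-surprise, keys)  # deterministic
  list(codes = codes[o], surprise = surprise[o])
}

#' Train a PWM by ZOOPS expectation-maximisation
#'
#' Zero-or-one-site-per-sequence EM over both strands. Candidate seeds
#' (background-enriched core k-mers plus the central windows of the
#' first few sequences, where summit-centered peaks concentrate their
#' sites) are screened by short EM runs and the best likelihood basin
#' is run to convergence. With `palindromic = TRUE` the count matrix
#' is averaged with its reverse complement at every M-step, i.e. the
#' motif is constrained quasi-palindromic throughout. With
#' `refine = TRUE` a final one-site-per-sequence (OOPS) EM pass over
#' the sequences confidently containing a site re-estimates the
#' matrix with equal per-sequence weight, removing the soft-ZOOPS
#' tendency to over-weight strong sites.
#'
#' @param seqs training sequences (all at least W long). Order matters
#'   only for seeding: the first sequences contribute window seeds, so
#'   passing peaks in decreasing coverage order (as
#'   [select_training_peaks()] does) seeds from the strongest peaks.
#' @param W motif width (default 16).
#' @param palindromic constrain the motif to its own reverse
#'   complement?
#' @param seed RNG seed (training is deterministic given the seed).
#' @param pseudocount added to the count matrix each M-step.
#' @param max_iter,tol EM stopping rule (mean per-sequence delta
#'   log-likelihood).
#' @param background 0-order background; `NULL` to estimate from `seqs`.
#' @param refine run the final OOPS re-estimation pass?
#' @param central_bp trim each training sequence to its central
#'   `central_bp` bases before training (summit-centered peaks
#'   concentrate their sites there, and restricting the alignment
#'   space keeps weak sites from being out-scored by background
#'   windows); `Inf` disables.
#' @return `pwm_model` with attributes `logL` (per-iteration
#'   log-likelihood of the ZOOPS stage) and `site_prob` (fitted ZOOPS
#'   site probability).
#' @export
train_pwm <- function(seqs, W = 16L, palindromic = TRUE, seed = 1L,
                      pseudocount = 0.01, max_iter = 200L, tol = 1e-4,
                      background = NULL, refine = TRUE, central_bp = 100L) {
  if (!length(seqs)) stop("no training sequences")
  if (any(nchar(seqs) < W)) stop("all sequences must be at least W long")
  set.seed(seed)
  if (is.finite(central_bp)) {
    keep_bp <- max(central_bp, W)
    seqs <- vapply(seqs, function(s) {
      L <- nchar(s)
      if (L <= keep_bp) return(s)
      lo <- (L - keep_bp) %/% 2L
      substr(s, lo + 1L, lo + keep_bp)
    }, character(1L), USE.NAMES = FALSE)
  }
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                        levels = BASES))
    background <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  }
  names(background) <- BASES
  groups <- split(seq_along(seqs), nchar(seqs))
  Xs <- lapply(groups, function(j) seqs_to_mat(seqs[j]))
  Xrcs <- lapply(Xs, revcomp_mat)

  # seeded initialisation, MEME-style: candidate seeds are (a) the
  # most surprising core k-mers placed at every offset and (b) the
  # central W-windows of the first sequences (summit-centered peaks
  # concentrate their sites there). A short EM run on a sequence
  # subset screens the candidates; the best basin is run to
  # convergence on the full data.
  k <- min(8L, W)
  cands <- top_enriched_kmer(seqs, k, background)
  n_kmer <- min(6L, length(cands$codes))
  seed_from_core <- function(core, off) {
    probs <- matrix(rep(background, W), 4L, W)
    for (i in seq_along(core)) {
      col <- rep(0.1, 4L); col[core[i]] <- 0.7
      probs[, off + i] <- col
    }
    pwm_model(sweep(probs, 2L, colSums(probs), "/"), background, pseudocount)
  }
  # anchored empirical seeds: all W-windows containing the candidate
  # core at a fixed inner offset (either strand) are averaged, so the
  # seed carries the data's own flanks in the right phase
  anchored_seeds_for_core <- function(core) {
    pat <- paste(BASES[core], collapse = "")
    ctx <- character(0L)   # match context: W - k bases each side
    pad <- W - k
    for (s in seqs) {
      for (sc in c(s, revcomp_seq(s))) {
        hits <- gregexpr(pat, sc, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        ok <- hits - pad >= 1L & hits + k - 1L + pad <= nchar(sc)
        if (any(ok)) {
          ctx <- c(ctx, substring(sc, hits[ok] - pad,
                                  hits[ok] + k - 1L + pad))
        }
      }
      if (length(ctx) >= 400L) break
    }
    ctx <- ctx[!grepl("N", ctx, fixed = TRUE)]
    lapply(0:(W - k), function(off) {
      if (length(ctx) < 5L) return(seed_from_core(core, off))
      X <- seqs_to_mat(ctx)             # width k + 2 * pad
      sub <- X[, (pad - off + 1L):(pad - off + W), drop = FALSE]
      counts <- matrix(0, 4L, W)
      for (kk in seq_len(W)) {
        counts[, kk] <- tabulate(sub[, kk], nbins = 4L)
      }
      pwm_model(sweep(counts + 0.25, 2L, colSums(counts + 0.25), "/"),
                background, pseudocount)
    })
  }
  seed_models <- list()
  for (ci in seq_len(n_kmer)) {
    seed_models <- c(seed_models, anchored_seeds_for_core(cands$codes[[ci]]))
  }
  src <- unique(round(seq(1L, length(seqs), length.out = min(12L,
                                                             length(seqs)))))
  for (i in src) {
    x <- seq_to_int(seqs[i])
    ctr <- (length(x) - W) %/% 2L
    for (sh in c(-20L, -10L, 0L, 10L, 20L)) {  # hedge summit jitter
      st <- min(max(ctr + sh, 0L), length(x) - W)
      win <- x[(st + 1L):(st + W)]
      if (anyNA(win)) next
      seed_models[[length(seed_models) + 1L]] <- seed_from_core(win, 0L)
    }
  }
  sub <- seq_len(min(200L, length(seqs)))
  sub_groups <- split(sub, nchar(seqs[sub]))
  Xs_sub <- lapply(sub_groups, function(j) seqs_to_mat(seqs[j]))
  Xrcs_sub <- lapply(Xs_sub, revcomp_mat)
  # screen candidates by short-run likelihood, requiring the fitted
  # site probability to stay substantial: the motif sought occurs in
  # most top training peaks, while repeat-lock or noise solutions fit
  # only a few sequences
  screen <- vapply(seed_models, function(m) {
    fit <- zoops_em(m, Xs_sub, Xrcs_sub, pseudocount, max_iter = 6L,
                    tol = 0, palindromic = palindromic)
    c(utils::tail(fit$logL, 1L), fit$pi_site)
  }, numeric(2L))
  eligible <- screen[2L, ] >= 0.2
  if (!any(eligible)) eligible <- rep(TRUE, ncol(screen))
  best_i <- which(eligible)[which.max(screen[1L, eligible])]
  best_seed <- seed_models[[best_i]]
  fit <- zoops_em(best_seed, Xs, Xrcs, pseudocount,
                  max_iter = max_iter, tol = tol,
                  palindromic = palindromic)
  # phase polish: a converged run can sit in a +/-1-shift (or, under
  # the palindromic constraint, a two-phase mixture) optimum; probe
  # shifted restarts to convergence and adopt the best, repeatedly,
  # while the likelihood improves.
  for (round in 1:3) {
    improved <- FALSE
    for (s in c(-2L, -1L, 1L, 2L)) {
      probs_s <- shift_pwm_probs(fit$model$probs, s, background)
      fit_s <- zoops_em(pwm_model(probs_s, background, pseudocount),
                        Xs, Xrcs, pseudocount, max_iter = 25L, tol = tol,
                        pi_site = fit$pi_site, palindromic = palindromic)
      if (utils::tail(fit_s$logL, 1L) > utils::tail(fit$logL, 1L)) {
        fit <- fit_s
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  fit <- zoops_em(fit$model, Xs, Xrcs, pseudocount, max_iter = max_iter,
                  tol = tol, pi_site = fit$pi_site,
                  palindromic = palindromic)
  model <- fit$model
  if (refine) {
    model <- oops_refine(model, Xs, Xrcs, fit$pi_site, pseudocount,
                         palindromic = palindromic, tol = 1e-4)
  }
  attr(model, "logL") <- fit$logL
  attr(model, "site_prob") <- fit$pi_site
  model
}

# shift PWM columns by s, filling vacated edge columns with background
shift_pwm_probs <- function(probs, s, background) {
  W <- ncol(probs)
  out <- matrix(rep(background, W), 4L, W)
  src <- seq_len(W) + s
  ok <- src >= 1L & src <= W
  out[, ok] <- probs[, src[ok]]
  out
}

# final re-estimation: one-site-per-sequence EM, restricted to
# sequences whose ZOOPS site posterior exceeds 1/2, each contributing
# total weight 1 (removes the strong-site over-weighting of soft
# ZOOPS counts)
oops_refine <- function(model, Xs, Xrcs, pi_site, pseudocount,
                        palindromic, tol = 1e-4, max_iter = 50L) {
  W <- model$W
  background <- model$background
  keeps <- lapply(seq_along(Xs), function(g) {
    X <- Xs[[g]]; Xrc <- Xrcs[[g]]
    J <- ncol(X) - W + 1L
    LRp <- exp(window_loglr(model, X)); LRp[is.na(LRp)] <- 0
    LRm <- exp(window_loglr(model, Xrc)); LRm[is.na(LRm)] <- 0
    tot <- rowSums(LRp) + rowSums(LRm)
    post <- (pi_site / (2 * J)) * tot /
      ((1 - pi_site) + (pi_site / (2 * J)) * tot)
    post > 0.5
  })
  if (!any(unlist(keeps))) return(model)
  for (iter in seq_len(max_iter)) {
    counts <- matrix(0, 4L, W)
    for (g in seq_along(Xs)) {
      X <- Xs[[g]][keeps[[g]], , drop = FALSE]
      Xrc <- Xrcs[[g]][keeps[[g]], , drop = FALSE]
      if (!nrow(X)) next
      J <- ncol(X) - W + 1L
      LRp <- exp(window_loglr(model, X)); LRp[is.na(LRp)] <- 0
      LRm <- exp(window_loglr(model, Xrc)); LRm[is.na(LRm)] <- 0
      tot <- rowSums(LRp) + rowSums(LRm)
      tot[tot == 0] <- Inf  # degenerate all-N rows contribute nothing
      Wp <- LRp / tot; Wm <- LRm / tot
      for (kk in seq_len(W)) {
        ip <- X[, kk:(kk + J - 1L), drop = FALSE]
        im <- Xrc[, kk:(kk + J - 1L), drop = FALSE]
        for (b in 1:4) {
          counts[b, kk] <- counts[b, kk] +
            sum(Wp[!is.na(ip) & ip == b]) + sum(Wm[!is.na(im) & im == b])
        }
      }
    }
    if (palindromic) counts <- (counts + counts[4:1, W:1, drop = FALSE]) / 2
    newp <- sweep(counts + pseudocount, 2L,
                  colSums(counts + pseudocount), "/")
    delta <- max(abs(newp - model$probs))
    model <- pwm_model(newp, background, pseudocount)
    if (delta < tol) break
  }
  model
}

# ZOOPS EM main loop over pre-encoded sequence groups. With
# palindromic = TRUE the count matrix is averaged with its reverse
# complement every M-step (the motif is constrained palindromic
# throughout, which also pins the alignment phase to the symmetric
# solution).
zoops_em <- function(model, Xs, Xrcs, pseudocount, max_iter, tol,
                     pi_site = 0.5, palindromic = FALSE) {
  W <- model$W
  background <- model$background
  n_seq <- sum(vapply(Xs, nrow, integer(1L)))
  logL_trace <- numeric(0L)
  for (iter in seq_len(max_iter)) {
    counts <- matrix(0, 4L, W)
    pi_num <- 0; logL <- 0
    for (g in seq_along(Xs)) {
      X <- Xs[[g]]; Xrc <- Xrcs[[g]]
      J <- ncol(X) - W + 1L
      LRp <- exp(window_loglr(model, X)); LRp[is.na(LRp)] <- 0
      LRm <- exp(window_loglr(model, Xrc)); LRm[is.na(LRm)] <- 0
      denom <- (1 - pi_site) + (pi_site / (2 * J)) * (rowSums(LRp) + rowSums(LRm))
      logL <- logL + sum(log(denom))
      Wp <- (pi_site / (2 * J)) * LRp / denom
      Wm <- (pi_site / (2 * J)) * LRm / denom
      pi_num <- pi_num + sum(Wp) + sum(Wm)
      for (kk in seq_len(W)) {
        ip <- X[, kk:(kk + J - 1L), drop = FALSE]
        im <- Xrc[, kk:(kk + J - 1L), drop = FALSE]
        for (b in 1:4) {
          counts[b, kk] <- counts[b, kk] +
            sum(Wp[!is.na(ip) & ip == b]) + sum(Wm[!is.na(im) & im == b])
        }
      }
    }
    logL_trace <- c(logL_trace, logL)
    pi_site <- min(max(pi_num / n_seq, 1e-6), 1 - 1e-6)
    if (palindromic) counts <- (counts + counts[4:1, W:1, drop = FALSE]) / 2
    probs <- sweep(counts + pseudocount, 2L,
                   colSums(counts + pseudocount), "/")
    model <- pwm_model(probs, background, pseudocount)
    if (iter > 1L &&
        abs(logL_trace[iter] - logL_trace[iter - 1L]) / n_seq < tol)
      break
  }
  list(model = model, logL = logL_trace, pi_site = pi_site)
}

#' Train a first-order TFFM by Baum-Welch
#'
#' Fits a hidden Markov model with a background state flanking a
#' W-position motif block whose positions 2..W emit conditionally on the
#' previous nucleotide (dinucleotide dependencies). Sequences are first
#' oriented to their best strand under `pwm_init`; emissions are
#' initialised from the PWM columns and the first-order background is
#' estimated from the training dinucleotide frequencies and held fixed.
#'
#' @param seqs training sequences.
#' @param pwm_init `pwm_model` used for orientation and initialisation.
#' @param seed RNG seed (deterministic given the seed).
#' @param pseudocount smoothing added to expected counts.
#' @param max_iter,tol Baum-Welch stopping rule (mean per-sequence delta
#'   log-likelihood).
#' @param trim_context when sequences are longer than
#'   `W + 2 * trim_context`, each is trimmed to the best PWM hit plus
#'   this much flanking context before training; `Inf` disables.
#' @param row_prior strength (pseudo-observations per previous-base row)
#'   of shrinkage of each conditional row towards the position's
#'   marginal distribution; keeps rarely-observed contexts from drifting
#'   on alignment noise.
#' @param orient flip each sequence to its best strand under `pwm_init`
#'   before training? Disable when sequences are already oriented.
#' @return `tffm_model` with attribute `logL` (per-iteration trace).
#' @export
train_tffm <- function(seqs, pwm_init, seed = 1L, pseudocount = 0.01,
                       max_iter = 100L, tol = 1e-4, trim_context = 60L,
                       row_prior = 5, orient = TRUE) {
  if (!length(seqs)) stop("no training sequences")
  W <- pwm_init$W
  if (any(nchar(seqs) < W)) stop("all sequences must be at least W long")
  set.seed(seed)
  # orient to best PWM strand; optionally trim to the hit neighbourhood
  seqs <- vapply(seqs, function(s) {
    X <- seqs_to_mat(s)
    fw <- loglr_to_score(window_loglr(pwm_init, X))[1L, ]
    if (orient) {
      rv <- loglr_to_score(window_loglr(pwm_init, revcomp_mat(X)))[1L, ]
      if (max(rv) > max(fw)) {
        s <- revcomp_seq(s)
        fw <- rv
      }
    }
    L <- nchar(s)
    if (is.finite(trim_context) && L > W + 2L * trim_context) {
      j <- which.max(fw)  # 1-based offset of best window
      lo <- max(1L, j - trim_context)
      hi <- min(L, j + W - 1L + trim_context)
      s <- substr(s, lo, hi)
    }
    s
  }, character(1L), USE.NAMES = FALSE)

  # fixed first-order background from training dinucleotides
  allx <- lapply(seqs, seq_to_int)
  dtab <- matrix(pseudocount, 4L, 4L)
  for (x in allx) {
    p <- x[-length(x)]; q <- x[-1L]
    ok <- !is.na(p) & !is.na(q)
    if (any(ok)) {
      t16 <- tabulate((p[ok] - 1L) * 4L + q[ok], nbins = 16L)
      dtab <- dtab + matrix(t16, 4L, 4L, byrow = TRUE)
    }
  }
  bg_trans <- dtab / rowSums(dtab)

  init <- pwm_init$probs[, 1L]
  trans <- array(0, c(4L, 4L, W - 1L))
  for (kk in 2L:W) trans[, , kk - 1L] <- matrix(pwm_init$probs[, kk],
                                                4L, 4L, byrow = TRUE)
  model <- tffm_model(init, trans, bg_trans)

  groups <- split(seq_along(seqs), nchar(seqs))
  Xs <- lapply(groups, function(j) seqs_to_mat(seqs[j]))
  tau <- 1 / mean(nchar(seqs))
  logL_trace <- numeric(0L)
  for (iter in seq_len(max_iter)) {
    es <- tffm_estep(model, Xs, tau)
    logL_trace <- c(logL_trace, es$logL)
    init <- (es$init_counts + pseudocount) / sum(es$init_counts + pseudocount)
    for (kk in 2L:W) {
      m <- matrix(es$trans_counts[, kk - 1L], 4L, 4L, byrow = TRUE)
      marg <- (colSums(m) + pseudocount) / (sum(m) + 4 * pseudocount)
      m <- m + rep(row_prior, 4L) %o% marg + pseudocount
      trans[, , kk - 1L] <- m / rowSums(m)
    }
    tau <- min(max(es$tau_num / es$tau_den, 1e-8), 0.5)
    model <- tffm_model(init, trans, bg_trans)
    if (iter > 1L &&
        abs(logL_trace[iter] - logL_trace[iter - 1L]) / length(seqs) < tol)
      break
  }
  attr(model, "logL") <- logL_trace
  attr(model, "tau") <- tau
  model
}

# one E-step of the ZOOPS-style motif HMM, vectorised across sequences
# of equal length; states: 1 = background-before, 2..(W+1) = motif
# positions 1..W, W+2 = background-after.
tffm_estep <- function(model, Xs, tau) {
  W <- model$W
  nst <- W + 2L
  init_counts <- numeric(4L)
  trans_counts <- matrix(0, 16L, W - 1L)
  tau_num <- 0; tau_den <- 0; logL <- 0
  lb_init <- model$bg_init
  bgv <- as.vector(t(model$bg_trans))     # (prev-1)*4 + cur
  mov <- vapply(seq_len(W - 1L),
                function(k) as.vector(t(model$trans[, , k])), numeric(16L))
  for (X in Xs) {
    n <- nrow(X); L <- ncol(X)
    if (anyNA(X)) stop("N bases are not supported in TFFM training sequences")
    D <- (X[, -L, drop = FALSE] - 1L) * 4L + X[, -1L, drop = FALSE]
    # emissions per time for each state class
    e_bg <- cbind(lb_init[X[, 1L]],
                  matrix(bgv[D], n, L - 1L))
    e_m1 <- matrix(model$init[X], n, L)
    # forward with scaling; A, B are lists of n x nst matrices over t
    A <- vector("list", L); B <- vector("list", L)
    cs <- matrix(0, n, L)
    At <- matrix(0, n, nst)
    At[, 1L] <- (1 - tau) * e_bg[, 1L]
    At[, 2L] <- tau * e_m1[, 1L]
    cs[, 1L] <- rowSums(At)
    A[[1L]] <- At / cs[, 1L]
    for (t in 2L:L) {
      Ap <- A[[t - 1L]]
      At <- matrix(0, n, nst)
      At[, 1L] <- Ap[, 1L] * (1 - tau) * e_bg[, t]
      At[, 2L] <- Ap[, 1L] * tau * e_m1[, t]
      if (W >= 2L) {
        for (k in 2L:W) {
          At[, k + 1L] <- Ap[, k] * mov[D[, t - 1L], k - 1L]
        }
      }
      At[, nst] <- (Ap[, W + 1L] + Ap[, nst]) * e_bg[, t]
      cs[, t] <- rowSums(At)
      A[[t]] <- At / cs[, t]
    }
    # backward; allowed end states: background-before (no site),
    # last motif position, background-after
    Bt <- matrix(0, n, nst)
    Bt[, c(1L, W + 1L, nst)] <- 1
    B[[L]] <- Bt
    for (t in (L - 1L):1L) {
      bnext <- B[[t + 1L]]
      Bt <- matrix(0, n, nst)
      Bt[, 1L] <- (1 - tau) * e_bg[, t + 1L] * bnext[, 1L] +
                  tau * e_m1[, t + 1L] * bnext[, 2L]
      if (W >= 2L) {
        for (k in 1L:(W - 1L)) {
          Bt[, k + 1L] <- mov[D[, t], k] * bnext[, k + 2L]
        }
      }
      Bt[, W + 1L] <- e_bg[, t + 1L] * bnext[, nst]
      Bt[, nst] <- e_bg[, t + 1L] * bnext[, nst]
      B[[t]] <- Bt / cs[, t + 1L]
    }
    r <- rowSums(A[[L]] * B[[L]])   # restricted-end mass, constant in t
    logL <- logL + sum(log(cs)) + sum(log(r))
    # expected counts
    for (t in seq_len(L)) {
      G <- A[[t]] * B[[t]] / r
      # motif position 1 emission (by current base)
      ib <- X[, t]
      init_counts <- init_counts +
        vapply(1:4, function(b) sum(G[ib == b, 2L]), numeric(1L))
      if (t >= 2L && W >= 2L) {
        Dm <- matrix(0, n, 16L)
        Dm[cbind(seq_len(n), D[, t - 1L])] <- 1
        trans_counts <- trans_counts +
          crossprod(Dm, G[, 3L:(W + 1L), drop = FALSE])
      }
      if (t < L) {
        # decision points in background-before: stay vs enter motif
        xi_enter <- A[[t]][, 1L] * tau * e_m1[, t + 1L] * B[[t + 1L]][, 2L] /
          (cs[, t + 1L] * r)
        tau_num <- tau_num + sum(xi_enter)
        tau_den <- tau_den + sum(G[, 1L])
      }
    }
    # virtual start decision
    G1 <- A[[1L]] * B[[1L]] / r
    tau_num <- tau_num + sum(G1[, 2L])
    tau_den <- tau_den + sum(G1[, 1L]) + sum(G1[, 2L])
  }
  list(init_counts = init_counts, trans_counts = trans_counts,
       tau_num = tau_num, tau_den = tau_den, logL = logL)
}

#' Serialize a motif model to JSON
#'
#' Matrices are written at full precision; [model_from_json()] restores
#' an identical model.
#'
#' @param model `pwm_model` or `tffm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  if (inherits(model, "pwm_model")) {
    obj <- list(type = "pwm", W = model$W, probs = model$probs,
                background = as.numeric(model$background),
                pseudocount = model$pseudocount)
  } else if (inherits(model, "tffm_model")) {
    obj <- list(type = "tffm", W = model$W, init = as.numeric(model$init),
                trans = model$trans, bg_trans = model$bg_trans)
  } else stop("unknown model class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a motif model from JSON
#'
#' @param path file written by [model_to_json()].
#' @return the model object.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "pwm") {
    pwm_model(matrix(unlist(obj$probs), 4L, obj$W),
              obj$background, obj$pseudocount)
  } else if (obj$type == "tffm") {
    tffm_model(obj$init, array(unlist(obj$trans), c(4L, 4L, obj$W - 1L)),
               matrix(unlist(obj$bg_trans), 4L, 4L))
  } else stop("unknown model type: ", obj$type)
}

#' Export a PWM in MEME minimal motif format
#'
#' @param model `pwm_model`.
#' @param path output path.
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(model, path, name = "motif1") {
  stopifnot(inherits(model, "pwm_model"))
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", BASES, model$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       model$W)), con)
  writeLines(apply(model$probs, 2L, function(col)
    paste(sprintf("%.6f", col), collapse = " ")), con)
  invisible(path)
}
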