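---
title: "Comparative analysis of seq-DAP-seq binding experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of seq-DAP-seq binding experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapcompare)
```

## The scientific problem

MADS-domain transcription factors bind DNA as obligate dimers at
CArG boxes (CC-[A/T-rich]-GG, quasi-palindromic), and the plant MIKC
clade additionally tetramerizes through its K domain. A tetramer
presents two dimer DNA-binding surfaces and can occupy two CArG boxes
simultaneously, looping the DNA in between, so oligomerization adds a
*syntax* criterion — the distance between two sites — on top of
per-site sequence preference. Sequential DNA-affinity purification
sequencing (seq-DAP-seq) maps the genome-wide binding of one purified
complex at a time; comparing a tetramer-competent complex with a
tetramerization-deficient (dimeric) variant of the same proteins
isolates what tetramerization contributes.

`dapcompare` implements the downstream comparative analysis of such
paired experiments:

1. **Consensus peak pooling** — replicate peak calls are collapsed
   into width-normalized consensus peaks with a mean normalized
   coverage.
2. **Union catalogue and CFR** — the two experiments' peaks are
   joined; each entry is labelled common or complex-specific, and the
   coverage fold reduction (CFR), the ratio of the two mean normalized
   coverages, ranks entries by how much they depend on
   tetramerization.
3. **Binding-site models** — a 0-order position weight matrix (PWM)
   and a first-order transcription factor flexible model (TFFM) are
   trained on the top bound regions and assessed by AUROC against
   matched unbound regions.
4. **Intersite-spacing enrichment** — pairs of predicted sites within
   each bound region are inventoried by center-to-center distance;
   enrichment against a background set reveals preferred spacings.
5. **Target genes** — binding is intersected with differential
   expression to call bound-and-regulated genes, with hypergeometric
   overlap statistics.

A synthetic-data generator with recorded ground truth stands in for
the study's raw sequencing data, so every stage is testable offline.

The package is organised as an analysis workflow: the numbered
scripts under `analysis/` are thin narrative drivers over the
exported functions, writing their tables under `results/`.

## Consensus peaks

Replicate peak calls (MACS2-style narrowPeak) are merged wherever
they overlap. A merged region is retained when

* at least `min_replicates` (default 2) replicates contribute a peak,
  and
* Fisher's combination of the supporting replicates' best
  $-\log_{10} p$ values, $X = 2\ln 10 \sum_r (-\log_{10} p_r) \sim
  \chi^2_{2k}$, gives a combined $p \le 10^{-4}$.

This reproducibility rule keeps the published cutoff semantics (a
combined peak-caller p-value at $10^{-4}$) while remaining fully
specified and dependency-free. Retained regions are scanned for
subpeaks: contributing summits are clustered by single-linkage with a
200-bp merge distance (two summits closer than half a peak width
cannot yield disjoint informative peaks), each cluster's
representative summit is the round-half-down mean of its members, and
every subpeak is width-normalized to the 401-bp window
$[s-200, s+201)$. The only exception to the fixed width is clipping
at a chromosome end, which is logged and uses the covered width as
the coverage divisor.

Coverage is normalized as reads per million (RPM) by library size —
the mean over the window, averaged across replicates, gives each
peak's `mean_norm_cov`.

## Union catalogue, specificity and CFR

Two experiments' consensus peaks are joined with a geometric rule:
peaks collapse into a *common* entry when their overlap reaches 80%
of the smaller peak and neither peak is more than 50% non-overlapping
(for equal-width normalized peaks the two clauses coincide at the
80% boundary). One peak matching several partners resolves by
largest overlap, ties to the lower coordinate. A merged entry keeps
the summit of the higher-coverage experiment, re-windowed to
$\pm 200$ bp; unmatched peaks stand alone. Both experiments'
coverages are then recomputed over every entry's window, so each
entry carries `cov_A` and `cov_B` measured identically.

An entry is *A-specific* when $\mathrm{cov}_A \ge 2\,\mathrm{cov}_B$
(and symmetrically B-specific), otherwise common. The CFR
$= \mathrm{cov}_A/\mathrm{cov}_B$ ranks entries (descending; ties by
coordinate) and partitions them into equal-count deciles, decile 1
holding the strongest CFR. Entries with a zero denominator are
excluded from ratio-ranked outputs rather than given a pseudocount
(an option exists). Swapping the experiments maps CFR to its
reciprocal and swaps the specific labels — a tested invariant.

## Binding-site models

**PWM.** A 16-bp quasi-palindromic motif is learned by ZOOPS
(zero-or-one site per sequence) expectation–maximisation over both
strands. Because external motif tools are deliberately not a
dependency, the discovery machinery addresses the classical failure
modes itself:

* *Seeding.* Candidate seeds are (a) core 8-mers ranked by a Poisson
  surprise against a first-order (dinucleotide) background — a plain
  count/expectation ratio rewards rare compositional artifacts — and
  (b) the central 16-bp windows of a spread of training sequences, at
  several offsets around the summit (summit-centered peaks
  concentrate their sites there). All candidates are screened by a
  short EM run; candidates whose fitted site probability collapses
  below 0.2 are rejected (a motif of interest occurs in most of the
  top peaks, while repeat-lock solutions fit only a few), and the
  best likelihood basin is run to convergence (mean per-sequence
  $\Delta\log L < 10^{-4}$, at most 200 iterations).
* *Palindrome constraint.* With `palindromic = TRUE` the count matrix
  is averaged with its reverse complement at every M-step, the
  analogue of a palindromic-motif option in standard motif
  discovery. This also pins the alignment phase: an off-center
  solution is not self-consistent under the constraint. A phase
  polish probes $\pm 1$–$2$-column shifts after convergence and keeps
  a shift only if it improves the likelihood.
* *Central trimming.* Training sequences are trimmed to their central
  100 bp (configurable). Besides speed, this keeps weakly matching
  true sites from being out-scored by the best of several hundred
  background windows, a censoring that otherwise sharpens the learned
  columns.
* *OOPS refinement.* Soft ZOOPS weights are proportional to each
  site's likelihood ratio, so strong sites are over-weighted. A final
  one-site-per-sequence EM pass over the sequences that confidently
  contain a site (posterior > 0.5), each with total weight 1, removes
  that selection bias.

**TFFM.** The first-order model emits position 1 from a marginal
distribution and positions $2..W$ from $4\times4$ conditionals
$P(x_k \mid x_{k-1})$ — dinucleotide dependencies — embedded in a
hidden Markov model with background states flanking the motif block.
Training is Baum–Welch, initialised from the PWM columns; the
first-order background is estimated once from the training
dinucleotide frequencies and held fixed (which keeps the EM ascent
exact; the likelihood trace is asserted non-decreasing in the tests).
Sequences are first oriented to their best PWM strand and trimmed to
the best hit $\pm 60$ bp. Each conditional row is shrunk towards the
position's marginal with five pseudo-observations, so rarely observed
previous-base contexts default to the marginal instead of drifting on
alignment noise.

**Scores.** Both models score a window as the normalized likelihood
ratio $s = LR/(1+LR)$ with $LR = P_\text{model}/P_\text{background}$,
bounded in $[0,1]$ with $s = 0.5$ at $LR = 1$ — matching the
convention in which 1.0 is the highest attainable score. Both
strands are scored and the maximum taken; windows containing N score
0 so offsets stay comparable. Site-score thresholds for spacing
analyses default to 0.9 (likelihood ratio 9), which gives a sensible
site density for a 16-bp CArG-like model on an A/T-rich genome; the
original study selected thresholds empirically and did not print
them, so the value is configuration, not a claim.

**Evaluation.** Models are trained on the 600 best peaks by mean
normalized coverage and assessed on the remaining bound regions
against an unbound set matched 1:1 for length, origin class and GC
content (bin width 0.05, widened stepwise if a stratum empties).
Origin classes use the precedence exon > intron > promoter >
intergenic, with the promoter defined as the 3-kb window upstream of
the TSS for consistency with the regulatory-region definition; with
span-only gene models the gene body counts as exon. AUROC is the
Mann–Whitney rank statistic with mid-ranked ties, which the tests
verify against trapezoidal integration of the ROC curve.

## Intersite spacing

Within each bound region, every unordered pair of site hits at or
above the threshold contributes one count $C_n$ at its
center-to-center distance $n \le S_{max}$ (default 100 bp), with site
orientation deliberately ignored (the motif is quasi-palindromic).
Frequencies $f_n = C_n / \sum_k C_k$ are computed for the bound set
and for a background set, and the normalized enrichment is the ratio
$N_n = f_{\text{pos},n} / f_{\text{neg},n}$, undefined (not infinite)
where the background frequency is zero.

Spacing is measured **center-to-center**. On the printed KNU promoter
probe this convention reproduces the published distances exactly: the
strong CArG box (CCATGTTTGG) sits 45 and 46 bp from the two adjacent
weak boxes (TCTTCTTTGT, CTTCTTTGTG), and the −5/−10/+5/+10 probe
variants shift those distances by exactly their nominal amounts.
Edge-to-edge measurement is available as a flag; for sites of one
model (fixed width) the two differ by a constant. Overlapping site
pairs are counted by default — the two weak KNU boxes overlap each
other — with a minimum-spacing flag available.

The decile view combines modules: the percentage of regions
containing at least one preferred-spacing pair (default
{36, 37, 46, 47, 57} bp) is tabulated per CFR decile; cooperative
two-site binding predicts a decreasing trend from decile 1 (most
tetramer-dependent) to decile 10.

## Target genes

A gene's regulatory region spans 3 kb upstream of the TSS to 1 kb
downstream of the TTS, strand-aware and clipped at chromosome bounds.
A gene is *bound* when any peak overlaps that region by at least one
base ("without restriction"); a peak overlapping two genes' regions
counts for both. DE tables are filtered at $|\log FC| > 1$ and
$FDR < 0.05$; multiple lists for one regulator are combined by set
union, and when two regulators are intersected, an optional
directional filter keeps only genes regulated in the same direction
by both (genes with conflicting directions within one regulator are
kept but flagged). Overlap significance is the hypergeometric upper
tail, computed in log space so values like $-\log_{10} p$ in the
hundreds do not underflow. The universe defaults to all genes in the
supplied annotation and is recorded in the output.

## The synthetic-data generator

The generator emulates the statistical structure the analysis
assumes, with every draw fixed by one seed:

* **Genome.** 1 Mb over two chromosomes; iid nucleotides with
  per-10-kb-window GC targets drawn from
  $\mathcal{N}(0.36, 0.05)$ — Arabidopsis-like composition with
  compositional heterogeneity.
* **Truth motif.** A 16-bp exactly palindromic CArG-like PWM
  (CC at positions 4–5, A/T-rich middle, GG at 12–13, mildly
  A/T-leaning flanks). These numbers are generator parameters, not
  estimates from any dataset.
* **Sites.** 300 single sites and 150 pairs sampled from the truth
  motif on random strands at non-colliding positions; pair
  center-to-center distances drawn from {36, 46, 57} bp with equal
  weight. 500 *decoy* sites generate no binding signal, emulating the
  unbound motif matches that pervade real genomes; they give unbound
  regions a realistic motif-hit rate, a usable spacing background,
  and keep AUROC away from a trivial 1.0.
* **Binding model.** Site $i$ carries a Boltzmann weight
  $w_i = \beta\,(LR_i / LR_{\text{med}})^{\gamma}$ with
  `binding_scale` $\beta = 0.2$ (the median site is sub-saturated)
  and `affinity_temper` $\gamma = 0.4$ (binding energy scales
  sublinearly with log likelihood ratio, so affinity heterogeneity
  does not saturate both complexes at strong sites). A single-site
  locus has occupancy $w/(1+w)$ under either complex. At a pair, the
  expected number of bound dimer units is
  $(w_1 + w_2 + 2 w_1 w_2 \omega)/(1 + w_1 + w_2 + w_1 w_2 \omega)$,
  where the dimeric complex has $\omega = 1$ and the tetramer
  multiplies the doubly-bound state's weight by the cooperativity
  $\omega(d) \ge 1$: Gaussian bumps (sd 1.5 bp) of height 16 above a
  baseline of 1 at the configured spacings, optionally repeated at
  +10.5-bp harmonics to mimic helical phasing. In the default
  conditions this gives tetramer/dimer coverage ratios around 2–2.4
  at cooperative pairs and ~1 at single sites, i.e. a
  complex-specific class at the 2-fold rule, while both complexes
  share the single-site repertoire.
* **Coverage and peaks.** Expected per-bp coverage is a background of
  2 reads plus a triangular summit kernel (half-width 150 bp) scaled
  by `cov_scale` × occupancy (default 100); replicate counts are
  negative-binomial (size 10). Peaks are emitted where the expected
  amplitude clears the calling floor (5), with per-replicate summit
  jitter $\mathcal{N}(0, 10\,\text{bp})$ and a $-\log_{10} p$ from
  the Poisson tail of the observed window count, so the Fisher
  combination downstream is exercised. A few spurious
  single-replicate peaks (25 per replicate) exercise the support
  rule. The RPM library size is a configured constant shared by all
  replicates and experiments (libraries sequenced to matched depth):
  on a desk-scale 1-Mb genome the planted peaks hold an unrealistic
  share of the reads, and deriving the library size from summed
  coverage would let that share deflate the stronger experiment's
  normalized coverage.
* **Genes and DE.** 2-kb genes tiled on alternating strands; a gene
  bound at a planted locus is truly regulated with probability 0.6
  (unbound genes 0.05). The DE table passes truly regulated genes
  through the $|\log FC|>1$, $FDR<0.05$ filter with probability
  `de_sensitivity` (0.9) and unregulated genes with probability
  `de_fp_rate` (0.03), exactly by construction, which makes the
  coupling testable against binomial expectations.

**What the generator does not emulate:** read-level artifacts
(mappability, duplicates, fragment-size effects), chromatin
accessibility, binding-site clustering beyond planted pairs, genuine
genomic repeats, and correlated replicate noise. Passing tests
therefore demonstrate the correctness of the analysis logic under
the stated statistical assumptions, not performance on real
sequencing data.

### Fixtures used by the recovery tests

* *Motif recovery* uses a saturating singles-only experiment (600
  single sites, `binding_scale = 50`, no pairs). At saturation every
  planted site is called regardless of its sequence draw, so the
  training peaks carry an unbiased sample of sites from the truth
  model — otherwise the calling floor itself truncates weak
  (non-consensus) sites and no estimator could match the truth
  columns. The recovery requirement is a maximum absolute column
  error below 0.05 at 500+ training peaks.
* *Spacing recovery* uses a pairs-only tetramer fixture (200 pairs,
  all at 46 bp) and scans with the generator's own motif model, so
  the spacing statistic is tested independently of motif estimation
  (which has its own recovery test); the enrichment argmax must fall
  within ±1 bp of 46 in at least 9 of 10 seeds. The background set is
  1,200 unmatched random non-peak regions: spacing enrichment needs a
  stable background frequency, and a large uniform background serves
  that better than a 1:1 matched set.
* *TFFM-vs-PWM AUROC* plants first-order motifs (strong dependencies
  at three positions) directly into short background sequences; the
  TFFM must reach at least the PWM's AUROC in 9 of 10 seeds.

## Numerical choices and degenerate inputs

* Rounding of fractional mean summits is round-half-down
  (`ceiling(x - 0.5)`), a fixed testable convention.
* Fisher combination works on $-\log_{10} p$ directly;
  $-\log_{10}$ of the combined p is capped only by the smallest
  positive double.
* EM stopping: mean per-sequence $|\Delta \log L| < 10^{-4}$; PWM at
  most 200 iterations, TFFM at most 100.
* Ties: training-peak selection, CFR ranking and seed screening all
  break ties by coordinate or lexicographic order, so every run is
  reproducible bit-for-bit under a fixed seed.
* Degenerate inputs: empty peak files give empty (typed) frames; a
  single replicate requires an explicit bypass flag; regions shorter
  than the motif scan to an empty hit set with a warning; both-zero
  coverages classify as common with a warning; an all-zero spacing
  profile is an error rather than a silent NaN.

## Problem sizes

The shipped analysis uses a 1-Mb genome, 450 signal loci and two
replicates per experiment; pooling runs in seconds and motif training
in under a minute on one core. The test suite's recovery fixtures use
0.6–1.4-Mb genomes and 2,000-sequence training sets, chosen as the
smallest sizes at which the statistical requirements (column error
0.05, TV 0.1, 9/10-seed majorities) hold with comfortable margins.

## Known limitations

* The consensus-pooling rule is a specified stand-in for the
  published multi-sample peak-calling step, preserving its cutoff
  semantics but not its internals; likewise the motif machinery
  replicates the model classes (single 16-bp quasi-palindromic PWM;
  first-order TFFM), not external tools' exact numerics.
* The TFFM score is the normalized likelihood ratio; the original
  framework's scoring internals differ in detail, so printed site
  scores from that tool (e.g. 0.87 for the strong KNU box) are not
  numerically reproducible without its trained model.
* Gene models are span-level; without an exon table, intron/exon
  distinction inside gene bodies is unavailable and the body counts
  as exon in origin matching.
* Pairwise comparison only; a three-way catalogue is composed by
  running the pairwise comparison twice.
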