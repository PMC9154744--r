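---
title: "Calling and characterising Pol II pauses from NET-seq occupancy"
author: "netseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising Pol II pauses from NET-seq occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netseqr)
```

# The data and its assumptions

NET-seq captures nascent RNA still held by elongating RNA polymerase II and
sequences from its 3' end, so the 5' end of each aligned read marks the exact
genomic position of the polymerase active site, on the strand opposite the
alignment (fr-firststrand chemistry; `record_three_prime_ends()` exposes an
`orientation` argument because library kits differ). Two artifacts matter
before any statistics:

* **RT mispriming.** The reverse-transcription primer can anneal internally
  in the nascent RNA instead of to the ligated linker. Such reads carry a
  "molecular barcode" that is not random linker sequence but a copy of the
  genomic sequence just downstream (in transcript orientation) of the
  recorded 3' end. `filter_mispriming()` removes every read whose hexamer
  barcode exactly equals that adjacent 6-mer. The orientation of "adjacent"
  is not dictated by the file formats, so it is a package decision: internal
  priming copies template downstream of the apparent 3' end, and that side is
  what we compare (covered by a strand-explicit fixture test). Genuine random
  barcodes collide with the genomic 6-mer at a rate of 4^-6 per read; these
  collisions are removed too, exactly as they would be in real data.
* **PCR duplicates** are deliberately *not* removed: with single-nucleotide
  data, true pause strength and PCR duplication are confounded, and
  deduplication would cap counts at the barcode diversity.

Counts are normalized to reads per million mapped reads only for display and
cross-sample comparison; pause calling always runs on raw per-replicate
counts because the reproducibility model consumes per-replicate read counts.

# Pause calling

Within each well-expressed gene — mean coverage strictly greater than
`min_coverage = 2` reads/bp in *both* replicates — every position is tested
against the 200 nucleotides around it (`window = 200`, i.e. ±100, truncated
at gene boundaries, the candidate itself excluded). The background counts are
treated as negative binomial and fit by the method of moments:
mu = sample mean, sd = sample standard deviation, size r = mu² / (var − mu),
falling back to Poisson (sd = sqrt(mu)) when the window is underdispersed,
and degenerating to mu = sd = 0 on an all-zero window so that the threshold
reduces to the read floor. A position is a pause iff

```
reads > mu + z * sd      (z = 3)
reads >= min_reads       (min_reads = 2, per replicate)
```

Method-of-moments rather than maximum likelihood is intentional: it is
closed-form, deterministic, and a 3-sigma exceedance rule only needs the
first two moments; an MLE would change thresholds by far less than the
window-to-window sampling noise.

Because the background is defined over positions *that do not contain
pauses*, calling is a fixed-point problem: call, refit with calls excluded,
repeat (cap `max_iter = 10`; in practice the toy genomes converge in 2–4
sweeps, and non-converged genes are flagged). The production implementation
uses running sums over the masked count vector (O(N) per sweep); a naive
per-position O(N·W) loop is kept in the test suite and must agree exactly,
gene by gene. Excluding the upper tail of a null window biases the fitted sd
downward, so the fixed point calls noticeably more positions than a single
sweep — that is inherent to the "background without pauses" definition, and
it is why downstream analyses use only replicate-reproducible pauses.

Windows with fewer than `min_informative = 50` usable background positions
are not callable: second moments on fewer points are too unstable to anchor
a 3-sigma rule. This also motivates the generator's minimum gene length
(600 bp), which must accommodate the largest region-index window as well. A
sliding per-position window is used rather than disjoint 200-nt segments;
segment boundaries would make callability depend on phase, and the sliding
choice is the natural reading of "surrounding".

# Reproducibility: the IDR model

Replicate agreement is scored with the two-component Gaussian copula mixture
behind the irreproducible discovery rate. Scores are log10 pause reads; only
their ranks matter. With n matched pairs, each rank is mapped to
u = rank/(n+1) (average ranks for ties — log10 of small integer counts
produces many ties) and pushed through the inverse of the mixture CDF
G = p·N(mu, sigma) + (1−p)·N(0, 1). On these pseudo-values an EM alternates:
posterior weight of the reproducible bivariate component (common mean mu, sd
sigma, correlation rho) against an independent standard-normal null, then
weighted-moment updates of (p, mu, sigma, rho), re-deriving the pseudo-values
each sweep. Initialisation is mu = 3, sigma = 1, rho = 0.9, p = 0.5;
convergence is a pseudo-likelihood change below 1e-6 with a 200-sweep cap
(the cap can bind on large noisy pair sets; the last iterate is returned with
a flag, and parameters are clamped to p ∈ [0.001, 0.999], sigma ≥ 0.01,
|rho| ≤ 0.999 to keep the null identifiable). The local idr of a pair is the
posterior probability of the irreproducible component; the global IDR is the
running mean of local idr over pairs ranked by it, and the 1% threshold is
applied to the *global* IDR (the ENCODE convention; `use_local = TRUE` gives
the alternative). Matching between replicates is exact single-nucleotide
coordinate identity — pauses are single bases, so ± slop would merge
neighbouring events.

Two properties are worth stating because the tests rely on them: IDR is
invariant to any strictly monotone transform of the scores (rank-based
pseudo-values), and global IDR is non-decreasing down the ranked list (a
running mean of sorted values). When the pair set contains no reproducible
signal at all, p loses identifiability — the reproducible component can
collapse onto the null — so what is testable is that p shrinks far below its
initialisation and most pairs get high local idr, not a specific limit.

# Region indices, metagenes, splicing

The pausing index of a gene for a region anchored at the TSS (offsets −50 to
+150), poly(A) site (±100) or splice sites (±10) is the region's
length-normalized density divided by that of the *remainder of the gene* —
gene-body positions outside the region. Region positions upstream of the TSS
lie outside the gene and therefore count in the numerator only; the index is
flagged undefined (never coerced to 0) when the remainder is empty of signal,
and it is invariant to any positive scaling of the track, so raw and
normalized tracks give identical tables. The antisense pausing index anchors
a TSS-style window at the antisense-unit start (opposite the host gene's
poly(A) region) on the antisense strand; the exact anchoring is not forced by
the data model, so it is exposed via the window list.

Metagene profiles average per-gene signal over fixed anchor windows (TSS
−100..+600, poly(A) −500..+200, splice sites ±25), after normalizing each
gene's window (sum-to-1 by default; `norm = "max"` is available since "signal
was normalized" admits both readings), with a 95% normal-approximation CI
across genes and a loess smooth (span 0.01, degree 1; the effective span is
widened so every local fit has at least 4 points, and degree-1 loess
reproduces a linear profile exactly, which the tests exploit).

The splicing index per intron is SI = 2·spliced / (unspliced5' +
unspliced3'), from junction reads overhanging the junction by at least 3 nt
(the simulator emits such counts directly). SI is undefined when no unspliced
reads exist; undefined introns are excluded from comparisons with a tally.
Two samples are compared by a Wilcoxon signed-rank test paired across
introns: the comparison needed a concrete test, and the signed-rank choice is
robust to the heavy right tail of ratio indices.

# Antisense transcription

Antisense units mirror each protein-coding gene ("anti" + gene id, same
span, opposite strand) and are dropped whenever they overlap — by any base —
an annotated sense unit on their own strand, so antisense signal is never
double-counted against genuine genes. Position matrices run from 250 bp
upstream of the sense TSS to 4000 bp downstream, in sense orientation, with
genes shorter than the window padded with missing values; entries are
log2(RPKM + 1) with the pseudocount added *before* the log, and differential
matrices are element-wise differences of those pseudocounted logs, which
makes them exactly antisymmetric. Per-position RPKM from a per-million track
is the per-million value × 1000 (a single base is 1/1000 kb).

# Pause features and the classifier

Shuffled control loci are drawn uniformly among non-pause positions of each
host gene, count-matched per gene — expression level is therefore identical
between the real and control arms by construction. Features are strand-aware:
the centered trinucleotide, per-offset base identity over ±10 nt, SantaLucia
nearest-neighbor duplex melting temperature and GC of the 21-mer, DNA-shape
values (twist, roll, propeller, minor-groove width) looked up for the
centered pentamer from a user-supplied table (`synthetic_shape_table()` ships
a clearly-synthetic stand-in for demonstrations — published shape tables are
data, not something to re-derive), mean signal of arbitrary occupancy tracks
in a ±25 nt window, and positional features (relative position, distances to
TSS and poly(A)). Loci within the half-window of a chromosome end keep their
row with missing sequence features and an edge flag. Real-vs-control
distributions are compared per numeric feature with Student's t-test,
Bonferroni-corrected over the tested features; categorical sequence features
are skipped with a note, as are zero-variance columns.

The classifier is a random forest (engine: the randomForest package) with
`n_trees = 2500`, `mtry = 20` and a 75/25 split. Two deliberate choices:

* `max_cat = 4`: factors up to cardinality 4 (the per-offset base columns)
  stay categorical; anything wider is one-hot encoded before fitting.
* The split is stratified at the *gene* level, so loci of one gene never
  straddle train and test. This is stricter than a plain stratified split,
  and it exists to stop gene-level covariates (expression, base composition)
  leaking from train to test.

AUC is the Mann-Whitney rank statistic over held-out predicted probabilities
(tie-averaged, hence invariant to monotone transforms of the scores);
feature importance is the out-of-bag mean decrease in accuracy when one
feature is permuted after training (unscaled). The transfer matrix trains on
100% of one strain's loci and tests on all of another's, with the diagonal
holding each strain's own 75/25 AUC. Demonstrations and tests use smaller
forests (150–300 trees): with ≤ ~60 features, null AUC and importance
behavior are tree-count-stable well below 2500, which remains the analysis
default.

# What the synthetic data emulates — and what it does not

`simulation_config()` defaults describe the study conditions end to end: 200
genes of 600–1400 bp on a 2 × 150 kb two-chromosome genome, i.i.d. sequence
at GC 0.38, per-gene expression uniform on 1–10 reads/bp shared between
replicates, negative-binomial background with size r = 10 (variance =
mean + mean²/r), planted single-nucleotide pauses at 30 per kb — the
one-pause-per-33-bp density reported for wild-type yeast — with fold
strengths uniform on 5–15, of which 70% are present in both replicates and
the rest in one, antisense units over the 3'-terminal half of 30% of genes at
0.2× host expression, and junction counts that are multinomial in
(psi, (1−psi)/2, (1−psi)/2).

Planted pause counts are drawn Poisson with mean = per-replicate strength ×
gene background mean, where the per-replicate strength multiplies a shared
latent fold by i.i.d. log-normal noise (sd 0.2 on the log scale) — this
yields the rank-correlated replicate structure the IDR model assumes.
A pause count built instead by multiplying a single NB background draw would
inherit the background's zero mass (7–10% zeros at these expression levels),
which contradicts the premise that a stereotypical pause site is occupied in
many cells and would make strong pauses undetectable in a corresponding
fraction of replicates; the Poisson choice models a deterministic site with
sampling noise only.

The generator deliberately omits: promoter-proximal enrichment and any
positional structure of real pauses (pauses are uniform within genes, so
passing positional tests says nothing about real 5' bias), sequence
determinants of pausing (planted positions ignore the underlying sequence,
so classifier AUC on synthetic pauses reflects only planted covariates, not
biology), mappability, splice-aware read placement, sequencing error, and
copy-number or rDNA artifacts. Tests passing on this generator demonstrate
that the *statistics* are implemented correctly under their own assumptions,
not that the assumptions hold for any particular real library.

# Numerical choices and degenerate inputs

* Sample variance (n−1) throughout; window moments by cumulative sums with a
  clamp at 0 against floating cancellation.
* Mixture-CDF inversion on a 4000-point monotone grid (production) vs
  per-point root finding (test oracle); both are exact to well below the
  0.02 oracle-agreement tolerance used in tests.
* All-zero background windows degrade the pause rule to the ≥2-read floor;
  zero remainder density flags PI undefined; zero unspliced reads flag SI
  undefined; zero library size is an error, as is normalizing twice.
* Scrambling and control drawing sample without replacement, so per-gene
  counts are conserved exactly and collisions are impossible; a gene with
  more pauses than positions is an error rather than a silent retry.
* Every stochastic entry point takes an explicit integer seed and is
  byte-reproducible under it.

# Problem sizes

The shipped checks run at desk scale by choice: recovery over 20 simulated
genomes (≈180 kb of transcribed sequence each), oracle equivalence on 50
genes and 500 IDR pairs, splicing power over 100 draws of 200 introns at
depth 1000, and classifier sanity over 50 forests of 250 trees on 2000 loci.
These sizes put every Monte-Carlo estimate's sampling error well inside the
asserted margins while keeping a full run in minutes on one CPU.

# Known limitations

* Exact-coordinate replicate matching will split a pause that wobbles by
  ±1 nt between replicates into two unmatched calls.
* The fixed-point caller's truncation bias (above) means per-replicate call
  lists are liberal; consumers should treat only the IDR-filtered set as the
  pause catalogue.
* The IDR EM fits a single global mixture; strong heterogeneity between
  genes (e.g. chromosome-scale coverage differences) is not modelled.
* "Sufficient coverage" in the cross-strain shared-pause matrix is proxied
  by the host gene's expression-filter status, the only coverage notion the
  pipeline defines; a per-window coverage rule would be finer-grained.
* The 51-feature catalogue of the original analyses lives in supplementary
  material; the feature registry here covers every named family
  (sequence, shape, melting temperature, position, arbitrary signal tracks)
  and accepts any number of additional track-window features, so a specific
  published list can be reproduced by configuration rather than shipped.
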