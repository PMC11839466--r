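---
title: "Multiscale footprinting of Tn5 insertion data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale footprinting of Tn5 insertion data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ATAC-style assays read out chromatin accessibility through Tn5 transposase
insertions. A protein bound to DNA shields its binding site, leaving a local
depletion of insertions — a footprint — whose width reflects the protein's
size: transcription factors protect tens of base pairs, nucleosomes about
147 bp. Two obstacles stand between raw insertion counts and footprint
calls. First, Tn5 has a strong sequence preference spanning roughly ±10 bp
of the insertion centre, producing artefactual peaks and dips larger than
many genuine footprints. Second, the sampling noise of the counts depends on
local coverage, so a fixed depletion threshold is either insensitive at low
depth or swamped by false calls at high depth. `fpkit` implements a complete
stack that addresses both: a learned sequence model of Tn5 bias, a
background-dispersion model that converts observed depletion into a
calibrated statistic, multiscale footprint scores, supervised predictors of
TF binding and nucleosome occupancy on top of those scores, and a sequence-
to-footprint neural model with per-cell-state (LoRA) adapters and per-base
attribution.

# Coordinates and counting

Fragment files are BED-convention 0-based half-open. Each fragment carries
two transposition events; their centres are recovered by shifting the ends
+4/−4 (left insertion `start + 4`, right insertion `(end − 1) − 4`),
the midpoint of Tn5's 9-bp staggered cut. Fragments shorter than 10 bp are
dropped (the shifted ends would touch or cross) and tallied. A `shift =
FALSE` path (`--pre-shifted` in the CLI wrapper) accommodates fragment files
whose ends were already centred upstream. Counts accumulate into a
group × region × position tensor; an event overlapping several regions is
counted in each, and conservation (tensor + out-of-region + 2 × dropped =
2 × fragments) is enforced by test.

# Tn5 bias model

**Target.** On deproteinized (naked) DNA the observed insertion rate is pure
bias. The per-position target is the count divided by the mean count in a
±50-bp window; positions with local mean below 20 insertions/bp, zero-count
positions (log-undefined) and positions within 50 bp of a contig end are
removed. Targets are log10-transformed and affinely standardized on the
training set; the transform is stored in the model and inverted exactly at
prediction, so predicted bias is always a positive multiplier.

**Model.** Three convolution + max-pooling stages (32 filters of width 5,
'same' padding, stride 1, ReLU, pool width 2) followed by a 32-unit ReLU
layer and a linear scalar output, on the one-hot ±50-bp context. MSE loss,
Adam, batch 64, early stopping on validation loss, with a per-epoch
learning-rate decay (default 0.94) that stabilises the later epochs.
Contigs are split 80/10/10 so no source contig spans partitions. Training
examples are binned into five equal-range bias bins and upsampled to the
largest bin; the bin range spans the 1st–99th percentile of the targets
(outer values fall into the end bins) so that a handful of extreme-noise
positions cannot stretch the range and reduce the tail bins to a few
massively duplicated examples. Reverse-complement copies are appended —
which is only label-correct because Tn5's dyad is symmetric, so its
preference table is reverse-complement symmetric; the synthetic truth is
symmetrized accordingly.

**Baselines.** k-mer tables (bias = centred foreground frequency /
background frequency, k ∈ {3, 5, 7}; unseen k-mers report bias 1 with a
warning) and a single-nucleotide PWM over a ±10-bp window (21 bp), as
per-base foreground/background log-ratios summed and exponentiated.

# Background dispersion

At footprint radius r the statistic is the one-sided insertion ratio
centre/(centre + flank), with the centre window the 2r bp at p−r … p+r−1
and a flank of equal width on one side. Because scoring performs
centre-vs-left and centre-vs-right tests, the background tables are built on
one-sided ratios (left flank; the feature space is side-symmetric), one
model per radius. Features are *sums* of per-bp bias over each window (the
ratio's expectation under pure bias is biasC/(biasC + biasF) with sums) plus
total coverage. For each sampled naked-DNA position the 500 (default;
scaled-down analyses use proportionally smaller k) nearest neighbours in
standardized feature space define the background: their ratio mean and SD.
Ties at the k-th distance break by lowest row index, making tables
deterministic; the kNN is exhaustive and is tested against a brute-force
oracle. Tables are augmented with binomially thinned replicates at 50/20/
10/5/1% of depth so the model sees the full coverage range. A single-
hidden-layer network (32 ReLU units, linear 2-output head) interpolates
(mean, SD) from the standardized features. The two outputs are standardized
during fitting — the SD target is orders of magnitude smaller than the mean
at large radii and would otherwise be ignored by the joint MSE, collapsing
the SD head onto its floor (an earlier build did exactly that and inflated
the false-positive rate at the 160-bp scale tenfold). Predicted SDs are
floored at 1e-4.

# Footprint scores

Per position and radius, z = (observed ratio − background mean) /
background SD for each side; lower-tailed normal P per side; the *higher*
of the two p-values is retained so one-sided depletion (e.g. a neighbouring
peak) is not called a footprint. Scores are −log10 P, smoothed by a running
max then a running mean (both half-width = radius by default; the exact
widths are tunable — they plateau the score across the protected span).
Positions lacking a complete centre+flank window, or with zero coverage,
are missing, and missingness poisons every smoothing window it touches.
The default scale ladder is 20/40/60/100/160/200 bp diameters; radius =
diameter/2, even diameters avoid off-centre windows.

Null behaviour deserves a note. Retaining the maximum of two one-sided
p-values is deliberately conservative: with side correlation ρ ≈ 0.5 (the
two ratios share the centre counts), the null probability that the
*retained* P falls below 0.01 is about 1.3e-3, not 0.01. The per-side
z-test itself is calibrated (its null false-positive rate at P < 0.01 sits
near 0.002–0.01 on bias-matched naked-DNA simulations); the composite rule
trades that nominal rate for robustness. Both rates are measured in the
acceptance checks.

# Footprint-to-TF and footprint-to-nucleosome predictors

The TF feature vector concatenates the six scales' scores over ±100 bp
(201 positions each, scale-major) and one motif score, empirical-CDF-
transformed against the pooled score list of the same motif — 1,207
dimensions; the footprint dimensions are standardized with stored training
statistics. (The CDF transform, rank/n with ties by ≤, maps the maximum
score to exactly 1; a rank/(n+1) estimator was considered and rejected
because the maximum must transform to 1.) The classifier has two hidden
layers (128, 32; ReLU) and a sigmoid output, trained with binary
cross-entropy, Adam, batch 128 and early stopping. TFs whose motif sites
overlap ChIP at ≤10% are excluded; negatives are balanced 1:1 with
positives per TF (sampled with replacement when scarce) and mirrored
(reverse-complement-derived) copies double the examples. Evaluation uses
precision over the top decile of ranked sites, ties at the boundary broken
by stable input order.

Nucleosome occupancy is regressed from five scales (the 200-bp scale is
excluded — it would leak the co-occupancy of adjacent nucleosomes) over the
same ±100-bp window: 1,005 inputs, hidden layers 64 and 16, linear output,
chromosome-level train/val/test split. Targets are masked where ATAC
coverage is ≤ 10 (strict) and affinely rescaled so the 5th/95th percentiles
map to 0/1; the transform inverts exactly. Summits are strict local maxima
above 0.2 × track maximum (the prominence floor is configurable; summit
detection has no canonical definition in this setting), and
precision/recall match summits within 50 or 75 bp.

# Sequence-to-footprint model

The trunk is a first convolution (width 21, GELU) followed by residual
blocks `x + pw(gelu(bn2(gconv(gelu(bn1(x))))))`, where `gconv` is a grouped
dilated convolution (width 3, dilation 2^i in block i) and `pw` a
position-wise width-1 convolution. Heads: a width-1 convolution emitting
per-position z-statistics for each scale, and an accessibility head (global
average pooling + fully connected scalar on the log(1+n) scale). The loss
is MSE on the footprint z targets plus MSE on log-counts, with the
accessibility gradient stopped before the trunk — the trunk is driven by
footprints alone, and the stop is verified bitwise by test. Training
targets are computed batched and match the scalar scoring path to 1e-13
(they stop before the P-value step; the retained value is the larger of
the two one-sided z's, which is equivalent to retaining the higher P).
Weights keep an exponential moving average (tested against the closed
form); chromosome-based 5-fold cross-validation deals chromosomes
round-robin by size, and fold predictions average at inference.

The receptive half-width is derived from the configuration as
(first_width−1)/2 + Σ dilation_i, never hard-coded; the full-scale
schedule (width 21, eight blocks) derives ±520 bp. The package's
recovery-study configuration is reduced — 32 filters, 6 blocks, groups 4,
400-bp windows, scales 20/40/60 bp — chosen under two hard constraints
discovered empirically. First, the receptive field must cover the ±3r
context that determines the z-statistic at the largest predicted scale
(±90 bp at scale 60; six blocks give ±136 bp, while a four-block schedule
sees only ±40 bp and cannot predict beyond scale ~26 by construction).
Second, the first convolutional layer is the motif detector, and whether
training escapes the scale-means plateau depends on some initial filter
aligning with a planted motif well enough to be amplified: with 16
filters the escape is a coin flip across seeds, with 32 it occurred
reliably in our runs — this is the same reason the full-scale model uses
1,024 first-layer filters. Training also needs data volume: on a
~380-kb genome (24 contigs, ~900 regions with ~550 planted sites) the
model generalises; on an eighth of that it memorises the training
regions instead. The full-scale configuration (1,024 filters, 8 blocks,
groups 8) is constructible but not exercised by the test suite.

**Attributions.** DeepLIFT rescale-rule attributions against 20
dinucleotide-shuffled references (random Eulerian paths over the
dinucleotide transition multigraph; N runs split the sequence into
independently shuffled segments). Batch normalisation is affine in
evaluation mode, convolutions are linear, and the GELU multiplier is the
exact secant (f(x)−f(ref))/(x−ref) with a derivative fallback below 1e-7,
so completeness — attributions summing to the output difference against the
reference mean — holds to numerical precision and is asserted in tests.
Footprint-head targets convert z to −log10 P before summation, either over
the whole window or a chosen scale × position window; the accessibility
scalar is attributed through the trunk (the gradient stop applies to
optimisation only). When checking that attributions concentrate on planted
motifs, the per-site readout is the peak |attribution| within the site:
positions inside a protected span but outside the motif legitimately carry
signal, so averaging over all motif bases against the background's upper
tail would understate a genuinely motif-focused model. The attribution-based TF classifier consumes 405
dimensions: 201 count-attribution and 201 footprint-attribution positions,
the CDF-transformed motif score, and one Pearson correlation per
attribution track between the track at the match site and the motif's
per-position expected log-odds pattern (a 404-dimensional reading exists if
a single correlation is used; this package uses one per track and documents
it). Constant attribution windows make the correlation undefined; the dims
are set to 0 and flagged.

**LoRA.** Each block's grouped convolution takes a per-pseudo-bulk delta
ΔW[(tap−1)·Cg + c, o] = left[c] · right[o, tap], with left = e·A1·A2
(length Cg = filters/groups) and right = e·B1·B2 (length filters × kernel)
derived from the pseudo-bulk's embedding e. The factor shapes follow the
stated A/B decomposition — (d_e×r + r×Cg) and (d_e×r + r×filters×kernel)
— so the per-layer parameter count is r(2·d_e + Cg + filters·kernel);
an alternative accounting, r×(d_p* + d_e), would count d_e once, which is
not what the factor shapes imply, and is not used here. Output factors A2/B2 are zero-initialised, so
every pseudo-bulk model starts exactly at the base model (asserted to
1e-5); only adapters train, with the base weights and batch-normalisation
statistics frozen, on the footprint loss alone.

**Motif marginalization.** Plant mode inserts a motif's consensus at the
centres of sampled regions (default 25,000, capped at availability);
scramble mode dinucleotide-shuffles existing match sites. Both report the
mean prediction difference (presence − absence) as a scales × positions
matrix with the sample size recorded.

# Population operations

Pseudo-bulk centres are chosen by sampling scaffold cells (default 10,000),
building a directed kNN graph (k = 10) among them and taking the 1,000
scaffolds with lowest in-degree — sparsely connected cells cover the state
space without oversampling dense neighbourhoods; each centre's 5,000
nearest cells over *all* cells become members (the neighbour search is not
restricted to scaffolds). Ties in in-degree and distance break by cell
index. TF-binding complexity averages a cCRE's cell-type × position score
matrix into 10-bp windows and counts the principal components needed to
reach 98% cumulative variance (a zero-variance matrix scores 1, flagged).
Binding-timing AUC min–max rescales a site's score series along
pseudo-time and integrates by the trapezoid rule on the normalised time
axis — 0.5 for a linear ramp, approaching 1 for an early riser; a constant
series has no defined timing (missing, flagged), and the AUC is invariant
to affine rescaling of the scores. The trajectory site filter retains the
documented defaults (RNA–pseudo-time correlation > 0.5, cCRE within ±50 kb
of a related TSS with accessibility correlation > 0.5, TF-score
correlation > 0); embeddings and pseudo-time are consumed as inputs.

# The synthetic truth generator

All tests run against seeded synthetic data with known ground truth, so
every number asserted is a parameter-recovery or calibration statement.

* **Genome and bias.** Contigs are i.i.d. bases at a requested GC. The
  per-5-mer log bias is composed of per-position base effects (centred;
  outer positions weighted 1/0.6/0.4/0.6/1 — transposase preference peaks a
  few bp off the dyad centre, which also keeps a centred 3-mer table from
  explaining most of the variance, as in real data where 7-mer > 5-mer >
  3-mer models) plus all pairwise position interactions (double-centred so
  they carry no positional main effects; 30% variance share), standardized
  to the requested log-SD and then symmetrized over reverse complements
  (Tn5's dyad symmetry). An unstructured `structure = "iid"` table is
  retained as a hard reference case; it is *not* learnable by the small
  bias CNN, and measuring that was what motivated the structured default.
* **Insertions.** Per-bp Poisson with rate ∝ bias × (1 − occupancy ×
  protection) inside planted occupancy events; protection is
  multiplicative on the rate, so stronger occupancy yields deeper
  footprints. Insertion events are paired into fragments by a seeded
  random matching within each contig, with coordinates chosen so the
  +4/−4 shift recovers exactly the simulated insertion centres — fragment
  lengths are arbitrary under this pairing, which is deliberate: lengths
  play no role downstream, and any length-realistic alternative would
  break count conservation between the fragment file and the simulated
  counts.
* **Sites and occupancy.** Motif consensus (optionally mutated) is planted
  at non-overlapping positions; bound sites carry occupancy events and the
  labels are the event registry. `make_chromatin_study()` assembles the
  full world — genome, bias, a TF motif with 20-bp protections, a
  nucleosome-anchoring motif with 140-bp protections, naked and chromatin
  simulations, fitted dispersion models and batched z targets — from one
  seed.

What these simulations do *not* emulate: PCR duplicates, mappability
artefacts, copy-number variation, fragment-length structure, and the
co-dependence of neighbouring cCREs. Passing tests therefore demonstrate
statistical correctness and parameter recovery under the generative model,
not performance on real sequencing data.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at reduced,
documented sizes chosen as the package's own desk-scale study conditions:
bias recovery uses ten 8-kb contigs at 250 insertions/bp of naked coverage
(a deeply covered deproteinized library) with up to 500 sampled positions
per contig; dispersion tables use 2,000 sampled positions per depth
replicate with 50–60 neighbours (preserving roughly the k/n regime of
the full-scale 500/100,000 default); the sequence-model study uses
twenty-four 16-kb contigs tiled into 400-bp regions at 100
insertions/bp. Bias-model recovery
is measured as Pearson correlation on the log scale — the bias is a
multiplicative parameter and the model is trained on log targets; the
linear-scale correlation is systematically a few points lower because
log-normal tails amplify shrinkage error.

Numerical details worth knowing: motif log-odds are integerised at 1e-4
granularity so match p-values come from an exact DP over the integer score
distribution (equal to full enumeration, which the tests verify up to
length 6); kNN ties break by row index; Adam uses the standard
bias-corrected moments (1e-8 epsilon) with an optional per-epoch
learning-rate decay that damps its late-stage parameter jitter; the
output layer of every fully connected network is initialised near zero,
which is exactly optimal for standardized targets and removes a long
constant-offset transient (without it the dispersion model's SD head can
sit several percent off a constant target after hundreds of steps); all
stochastic steps are seeded and the generators are bitwise reproducible
under a fixed seed in single-threaded BLAS execution.

# Known limitations

* The dispersion kNN inherits a mild upward SD bias from neighbour
  heterogeneity at small table sizes; combined with the retain-the-higher-P
  rule this makes the final footprint P conservative (see above). The
  acceptance checks report both the per-side and the retained-P null rates.
* The reduced sequence model shares the architecture family but not the
  capacity of the full-scale configuration; held-out correlation targets
  are set accordingly.
* Fragment-length information is not used in scoring.
* The nucleosome model is exercised on synthetic occupancy only; chemical-
  mapping supervision at genome scale is out of scope.
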