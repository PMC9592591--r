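---
title: "Methods: quantitative N-glycome atlas profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative N-glycome atlas profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoatlas)
```

# Scope and model

`glycoatlas` turns MALDI-TOF peak lists (m/z plus isotopic-envelope area,
one list per biological sample) into an annotated, absolutely quantified
N-glycome profile matrix, and runs the standard downstream analyses of a
tissue glycome atlas: biosynthesis-based glycotyping, Canberra/Ward
profile clustering, and repeated-holdout multi-class discrimination.
Everything upstream of the peak list — enzymatic glycan release,
glycoblotting bead chemistry, spectrum acquisition, isotope-pattern
fitting — is out of scope; the chemistry enters only as a mass model.

## Composition mass calculus

A glycoform is identified by its monosaccharide composition
$c = (h, n, d, a, g)$: counts of hexose, HexNAc, deoxyhexose (fucose),
Neu5Ac and Neu5Gc, written `H5N4D1A2` style. The neutral monoisotopic
mass is the sum of dehydrated residue masses plus one water,

$$M(c) = h\,m_\mathrm{Hex} + n\,m_\mathrm{HexNAc} + d\,m_\mathrm{dHex} +
 a\,m_\mathrm{Neu5Ac} + g\,m_\mathrm{Neu5Gc} + m_{\mathrm{H_2O}},$$

with the community constants (Hex 162.05282, HexNAc 203.07937, dHex
146.05791, Neu5Ac 291.09542, Neu5Gc 307.09033, water 18.01056 Da) used
by composition-matching tools such as GlycoMod. The test suite verifies
them against an independent elemental-formula oracle to $10^{-4}$ Da.

The observed m/z adds the glycoblotting chemistry:

$$m/z = \frac{M(c) + \Delta_\mathrm{tag} + (a+g)\,\Delta_\mathrm{Me} +
 m_\mathrm{carrier}}{z}.$$

* $\Delta_\mathrm{Me} = +14.01565$ Da per sialic-acid carboxyl
  (methyl-esterification protects both Neu5Ac and Neu5Gc; both carry a
  carboxyl, so the count is $a+g$).
* $\Delta_\mathrm{tag}$ is the **net** reducing-end labeling delta —
  label mass minus the condensation water — so the oxime water loss is
  never double-counted. Because the aminooxy label's elemental
  composition is a reagent property the literature does not pin down,
  the default is 0 (underivatized masses) and
  `calibrate_tag_delta()` recovers it algebraically from one known
  (composition, observed m/z) pair, with a second pair as a consistency
  check (default agreement tolerance 0.05 Da).
* The carrier is a proton or sodium cation; charge defaults to 1, the
  dominant MALDI state.

## Composition assignment

`solve_compositions()` enumerates the bounded composition grid
(defaults $h$ 3–12, $n$ 2–10, $d$ 0–5, $a$ 0–5, $g$ 0–5) filtered by
composition-level plausibility: $n \ge 2$, $h \ge 3$ (intact
chitobiose/trimannosyl core), $d \le n$ (each fucose needs a GlcNAc),
and $a + g \le \max(n-2, 0) + 1$ (sialic acids capped by antennae, the
$+1$ admitting hybrid monosialyl forms such as H5N3G1). Candidates
within tolerance (default ±0.1 Da, the scale of reflector-mode MALDI
peaks reported to two decimals; ppm selectable) are ranked by absolute
error, then fewer total residues, then canonical string — fully
deterministic.

A structural fact worth knowing: $m_\mathrm{Hex} + m_\mathrm{Neu5Ac} =
m_\mathrm{dHex} + m_\mathrm{Neu5Gc}$ *exactly* (453.14824 Da; the pairs
differ by the same O/CH$_2$ exchange). Any sialylated composition
therefore has exact isobars at every mass accuracy, e.g. H5N4D1A2 =
H3N4D3G2 = H4N4D2A1G1. De novo enumeration cannot resolve these;
matching against a library of known mammalian structures — the route
`annotate_peaklist()` tries first, and the one the atlas workflow itself
uses — is what disambiguates. This is why the annotation operation takes
a library and falls back to enumeration only for unknown peaks.

## Sialyl linkage isomers

A composition fixes neither which galactoses carry the sialic acids nor
their anomeric linkage. On a complex-type topology the inferred Gal
sites are $h - 3$; with $s = a + g$ sialic acids, each choice of sites
and per-site $\alpha2,3/\alpha2,6$ linkage is a distinct isomer:

$$N_\mathrm{iso} = \binom{h-3}{s}\, 2^{s}, \qquad s \le h-3,$$

which gives 4 for the disialylated biantennary H5N4A2. The model covers
only sialyl regiochemistry: arm position, bisecting placement and other
isomer axes are intentionally outside it, so the count is a lower bound
on structural diversity (the model is undefined off the complex type).

## Absolute quantitation and the detection filter

With a spiked internal standard of known amount $Q_\mathrm{IS}$
(default 10 pmol, the glycoblotting spike; configurable because the
acquisition protocol quotes a different reference amount), analyte
amounts are

$$Q_i = \frac{A_i}{A_\mathrm{IS}}\, Q_\mathrm{IS},$$

in pmol per 100 µg total protein. This is linear and scale-invariant in
the raw areas. A sample without a positive-area standard cannot be
quantified and fails loudly rather than silently rescaling.

Glycoforms are retained when detected in at least `min_detections`
(default 3) experiments. The counting scope is genuinely ambiguous in
prose descriptions of such filters, so both readings are implemented:
`"within-any-group"` (default — at least one class detects it in ≥ 3 of
its replicates, matching "three independent experiments") and
`"global"`. Non-detections are zeros everywhere downstream — totals,
distances, classifiers — with a Boolean mask preserved so "number of
glycoforms" counts detections, not float positivity.

## Glycotyping

The composition-level rule table follows the mammalian biosynthetic
pathway:

| rule | type |
|---|---|
| $n = 2,\ h \le 3$ | paucimannose |
| $n = 2,\ h \ge 4$ | high-mannose |
| $n \ge 3,\ (h-3) > (n-2)$ | hybrid |
| otherwise | complex |

The hybrid rule encodes "more hexoses than the antennae could carry as
galactose". H4N2 is labeled high-mannose (a Man-4 truncation) rather
than paucimannose; the rule table accepts a per-composition exception
list for the rare forms whose known structure contradicts the
heuristic. The most matured terminal sugar follows the hierarchy
Neu5Gc/Neu5Ac > Gal > GlcNAc > Man, with Gal inferred only on
complex/hybrid forms with $h \ge 4$ ($h = 3$ leaves only the
trimannosyl core). Antennae are $n - 2$ — a bisecting GlcNAc is
indistinguishable from an antenna at composition level, and the two are
deliberately conflated. Per-sample panel percentages are amounts over
the sample total (the internal standard is never in the matrix);
each panel sums to 100 by construction, and zero-total samples are
flagged and excluded from class averages rather than propagating NaN.

## Clustering

Profiles are compared with the Canberra distance

$$d(x, y) = \sum_i \frac{|x_i - y_i|}{|x_i| + |y_i|},$$

with $0/0$ terms contributing 0. Each coordinate contributes at most 1,
so low-abundance glycoforms — often the class-specific ones — carry as
much weight as dominant peaks, which is exactly why atlas work uses it.
Note `stats::dist(method = "canberra")` computes something subtly
different: it drops $0/0$ coordinates and rescales the sum by the
number of coordinates used, which distorts distances on sparse profiles
where samples share many non-detections; the package therefore computes
the textbook form itself.

Ward linkage runs on the raw absolute abundances (column z-scores are a
display scaling for deviation heatmaps, not the clustering input; a
flag switches). The squared-distance Ward update ("ward.D2") is the
default, with the legacy "ward.D" recurrence selectable because
historical pipelines differ — group-purity results are reported under
both. Merges are deterministic given row order; the cophenetic
structure is cross-checked in tests against a naive Lance–Williams
implementation. The group count for cutting (k = 18 in the atlas
analyses) is an input, not estimated.

## Classification

Each repetition holds out exactly one replicate per class (stratified
uniform draw on a private RNG stream), trains on the rest, predicts the
held-out samples and scores per-class F1 with the convention
$F1 = 0$ when $P + R = 0$. Means and standard errors
($\mathrm{SD}/\sqrt{\text{reps}}$; reported as not available at one
repetition) aggregate over repetitions, and the across-class average is
the unweighted mean. Four families mirror standard practice: a CART
tree (`rpart`), a single-hidden-layer softmax network (`nnet`), a
random forest (`randomForest`, 500 trees), and an RBF-kernel SVM
(`kernlab`, features standardized with training statistics, zero-
variance-safe). Small fixed hyper-parameter grids are searched by
stratified inner cross-validation on training data; the grid and the
chosen values are recorded in the report. By default tuning runs once
on an initial split and is reused across repetitions: with four
training replicates per class the inner-CV surface is essentially
identical across repetitions, and per-repetition search multiplies
runtime roughly tenfold without changing mean F1 measurably
(`tune = "per_rep"` restores it).

Two F1 facts the tests rely on, both computed rather than assumed:

* **Chance level is below $1/k$.** Under uniform random prediction of
  one test sample per class, the zero convention pulls the expected
  mean per-class F1 under $1/k$: exact enumeration gives 0.2654 for
  three classes (not $1/3$), and simulation gives ≈ 0.038 for 18
  classes (not 0.056). Deterministic classifiers concentrate their
  predictions and sit slightly lower still. Null checks therefore
  compare against the simulated uniform-prediction chance, not $1/k$.
* **The separability limit is algorithm-dependent.** At near-infinite
  class separation the flexible learners (forest, network, SVM) reach
  mean F1 > 0.99, but the greedy univariate tree does not: when two
  classes share an elevated marker, its split threshold between two
  noisy training values misroutes occasional test samples (the test
  suite asserts the flexible learners above 0.99 and the tree above 0.8
  at fold-change $10^4$). This matches the tree being the weakest
  family on real atlas data.

## The synthetic atlas generator

`generate_atlas()` emulates the structure of a real tissue atlas so
every stage is testable without instrument data: 18 classes × 5
replicates × 103 glycoforms by default. The library is drawn from the
plausibility grid with per-type quotas (≈ 2% paucimannose, 10%
high-mannose, 15% hybrid, rest complex) because the raw grid is
combinatorially dominated by large sialylated complex forms and a
uniform draw would contain essentially no high-mannose series, unlike
any real atlas list. Per glycoform, a baseline log-abundance
$\mu_g \sim \mathcal N(\log 0.01,\ 2.5^2)$ is shared across classes;
each class adds a deviation $\mathcal N(0, 0.6^2)$ and shifts its
`marker_count = 6` randomly chosen marker glycoforms by
$\log(\text{fold\_change} = 16)$; replicates multiply by log-normal
noise with CV 0.25 (MALDI quantitation noise is multiplicative).
Amounts below the 0.04 pmol detection limit become non-detections —
threshold dropout, matching the deterministic grey-as-absent semantics
of atlas heatmaps, with probabilistic dropout behind a flag. The
baseline places roughly a quarter of cells above the detection floor,
chosen once so the generated scale matches a real atlas: detected
abundances spanning roughly four decades above 0.04 pmol, per-class
median detected-glycoform counts in the twenties-to-thirties out of
103, and class structure strong enough to cluster but not trivially
separable. Strain variants perturb a random glycoform subset of one
class's mean profile multiplicatively, emulating multi-strain designs
on a single organ.

What the generator does **not** emulate: correlated glycoform blocks
from shared biosynthetic enzymes, batch effects, isotopic interference,
or abundance-dependent detection efficiency. Passing tests on synthetic
atlases therefore demonstrate algorithmic correctness and calibration,
not instrument-level robustness.

All generators draw from private, seed-derived RNG streams and leave
the global `.Random.seed` untouched; identical spec plus seed gives
byte-identical output.

## Numerical and degenerate-input choices

* Zero-variance columns z-score to 0, not NaN.
* Solver ties break by residue total then canonical string; merge ties
  follow `stats::hclust`'s lowest-index convention.
* Duplicate (sample, composition) records abort matrix assembly with
  the duplicates listed; duplicate library entries deduplicate with a
  warning.
* Tolerances: mass matching ±0.1 Da default; tag calibration agreement
  0.05 Da; panel normalization $10^{-6}$.
* Problem sizes in routine runs: the analysis drivers use 200 holdout
  repetitions for interactive turnaround; the full-scale 1000-repetition
  evaluation is exercised by `scripts/acceptance.R` and the acceptance
  test suite.

## Known limitations

* Composition-level only: linkage isomers beyond the sialyl counter,
  bisecting versus antennary GlcNAc, and LacNAc/Lewis/sulfation motifs
  are invisible.
* The Hex+Neu5Ac = dHex+Neu5Gc degeneracy makes de novo assignment of
  sialylated peaks inherently ambiguous; trust library matches.
* Holdout with one test replicate per class gives noisy per-repetition
  F1; many repetitions are needed for stable means (the default is
  1000).
* The generator's independence assumptions understate the correlation
  structure of real glycomes, so real-data classifier performance can
  differ from synthetic results in either direction.

# Worked example

```{r example, eval = FALSE}
atlas <- generate_atlas(synthetic_atlas_spec(seed = 1))
model <- derivatization_model(tag_delta = 389.2)
peaks <- synthetic_peaklists(atlas$profile, model)
cfg <- pipeline_config(
  derivatization = list(tag_delta = 389.2),
  annotation = list(library = colnames(atlas$profile$abundance),
                    tolerance = 0.01),
  clustering = list(k = 18),
  classification = list(n_reps = 1000),
  seed = 1
)
res <- run_pipeline(cfg, peaks, out_dir = "atlas_run")
res$evaluation
```

The `analysis/` directory decomposes the same pipeline into numbered
narrative drivers (simulate, annotate/quantify, glycotype, cluster,
classify) writing their tables under `results/`.
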