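# glycoatlas

Quantitative N-glycome atlas profiling from MALDI-TOF peak lists.

Tissue glycome atlases profile the major N-glycans of whole-organ
glycoprotein extracts: glycans are released enzymatically, enriched and
derivatized on solid phase (sialic-acid methyl-esterification plus an
aminooxy reducing-end tag), and measured by MALDI-TOF MS against a
spiked internal standard, giving absolute amounts in pmol per 100 µg
protein for each monosaccharide composition. `glycoatlas` implements
the computational side of that workflow for glycomics researchers who
have peak lists (m/z, isotopic-envelope area) and want annotated,
quantified, comparable profiles:

* **Mass calculus** — compositions `H5N4D1A2` (Hex / HexNAc / dHex /
  Neu5Ac / Neu5Gc counts); neutral mass
  `M(c) = Σ count·residue + H2O`; derivatized
  `m/z = (M + Δtag + (a+g)·14.01565 + carrier)/z`, with the tag delta
  calibratable from one known peak.
* **Annotation** — GlycoMod-style bounded enumeration of compositions
  within a mass tolerance, ranked deterministically, behind
  library-first matching; plus the sialyl-linkage isomer count
  `C(h−3, a+g)·2^(a+g)` (4 for the disialylated biantennary H5N4A2).
* **Quantitation** — `amount = area / area_IS × Q_IS` (default 10 pmol
  spike), a ≥3-detection retention filter (per-class or global
  counting), and the samples × glycoforms profile matrix with an
  explicit detected/not-detected mask.
* **Glycotyping** — paucimannose / high-mannose / hybrid / complex rule
  table, most matured terminal sugar (Neu5Gc/Neu5Ac > Gal > GlcNAc >
  Man), antennae `n−2`, sialic-acid and fucose counts, as per-sample
  percentage panels.
* **Clustering** — textbook Canberra distance (`Σ|x−y|/(|x|+|y|)`,
  0/0 → 0), Ward linkage (ward.D2/ward.D), fixed-k cuts with
  group-purity reporting, Newick export.
* **Classification** — repeated stratified one-replicate-per-class
  holdout over four families (CART, single-hidden-layer network,
  random forest, RBF SVM) with per-class F1 mean ± SE.
* **Synthetic atlas generator** — class-structured log-normal
  abundances with marker glycoforms, multiplicative replicate noise and
  detection-limit dropout, calibrated to the atlas scale
  (18 classes × 5 replicates × 103 glycoforms, ~0.04–300 pmol detected
  range), so the whole pipeline is testable without instrument data.

## Worked example

```r
library(glycoatlas)

atlas <- generate_atlas(synthetic_atlas_spec(seed = 20260101))
model <- derivatization_model(tag_delta = 389.2)
peaks <- synthetic_peaklists(atlas$profile, model)

cfg <- pipeline_config(
  derivatization = list(tag_delta = 389.2),
  annotation = list(library = colnames(atlas$profile$abundance),
                    tolerance = 0.01),
  clustering = list(k = 18),
  classification = list(n_reps = 200),
  seed = 1
)
res <- run_pipeline(cfg, peaks, out_dir = "atlas_run")
res$profile
res$purity$n_pure
res$evaluation
```

```
N-glycome profile: 90 samples x 65 glycoforms (18 classes), 42.0% detected
[1] 18
Holdout evaluation: 200 repetitions, seed 1, tuning 'once'
  decision_tree   mean F1  75.2%  (SE 0.7%)
  neural_network  mean F1 100.0%  (SE 0.0%)
  random_forest   mean F1 100.0%  (SE 0.0%)
  svm             mean F1 100.0%  (SE 0.0%)
```

Reading this: of the 103-glycoform library, 65 compositions are
detected in ≥ 3 replicates of at least one class and survive the
retention filter (the others sit below the 0.04 pmol detection limit
nearly everywhere — grey cells in heatmap terms); Canberra/Ward
clustering cut at k = 18 recovers all 18 sample classes as single-class
groups on this synthetic atlas; and the four classifier families
separate the 18 classes with mean F1 from ~75% (tree, the weakest
family here as on real atlas data) to 100% (the flexible learners),
each averaged over 200 stratified holdout repetitions with the standard
error of the repetition means.

The `analysis/` directory runs the same pipeline as numbered narrative
drivers (`01_simulate.R` … `05_classification.R`), writing tables under
`results/`. The methods vignette
(`vignettes/glycome-atlas-methods.Rmd`) documents the models, rules,
defaults and their rationale.

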