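---
title: "Predicting drug response in PDX cohorts from expression, histology, and drug descriptors"
author: "pdxmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug response in PDX cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxmm)
```

## The prediction problem

Patient-derived xenografts (PDX) are human tumors engrafted into
immunodeficient mice and expanded over passages. Drug efficacy is measured
in *group experiments*: mice carrying tumors from one specimen are split
into a vehicle control group and treatment groups, each treatment being a
single drug or a drug pair, and the median tumor volume of each group is
followed over the study. `pdxmm` models the binary response of a treatment
group from three feature modalities of the experiment:

* the tumor's **gene expression profile** (TPM values, reduced to a
  landmark panel),
* **tiles** cut from the H&E-stained whole-slide image (WSI) of the tumor,
* numeric **molecular descriptors** of the administered drug or drug pair.

PDX response datasets are small (hundreds of groups) and heavily
imbalanced (a few percent responders), which drives every design choice
below: drug-treatment data augmentation, grouped splits, class-weighted
losses, and rank-based evaluation metrics.

## Response labeling

A group's label follows a modified-RECIST regression rule
(`label_response()`): response (1) iff the median tumor volume drops to at
most $(1-f)\,V_{\text{stage}}$ for at least $c$ consecutive timepoints,
anywhere in the study, with $f = 0.30$, $c = 2$, and
$V_{\text{stage}} = 200\,\mathrm{mm}^3$ (the volume at which dosing
starts) by default. Two codified edge conventions, both exposed as
parameters:

* the $0.7\,V_{\text{stage}}$ boundary is **inclusive** ("at least 30%"
  read literally);
* "more than one consecutive time point" is read as a run of $\ge 2$
  qualifying timepoints.

Regression is measured against the staging volume, not the control arm;
the control arm informs study conduct but not this rule. The label is
scale invariant (volumes and staging volume in common units cancel), and
decreasing any volume can never turn a responder into a non-responder —
both properties are enforced in the test suite.

## Tabular features

Expression: genes are restricted to a landmark panel (the LINCS 942-gene
panel in the real setting), TPM values are mapped through
$\log_2(x + 1)$, and each gene is standardized to zero mean and unit SD.
Descriptors: any descriptor column with a missing value for any drug is
dropped, then columns are standardized across drugs.

Numerical conventions, fixed for reproducibility and exposed in the API:

* **population SD** (divisor $n$) everywhere a scaler is fitted;
* zero-variance features standardize to 0 with a warning rather than
  erroring — small cohorts routinely contain constant features;
* scalers serialize to JSON (`write_scaler()`) and reproduce transforms
  exactly after reload.

Standardization is *fold-aware by default*: `train_model()` fits the gene
scaler on the training-fold specimens only and applies it to held-out
specimens, so no test-set statistics leak into the features. Passing
`paper_mode = TRUE` fits on all specimens instead, reproducing the common
(but leak-prone) global standardization protocol. The descriptor scaler is
always fitted across all drugs: drugs are not a splitting unit — the same
small set of drugs appears in every fold — so there is no held-out drug
population to protect.

## Histology pipeline

`tile_slide()` runs extract → background filter → stain normalization →
standardization, in that order; filters never see normalized tiles.

* **Tiling** (`extract_tiles()`): a non-overlapping grid of
  $302\,\mu m \times 302\,\mu m$ windows, i.e. a stride of
  $\mathrm{round}(302/\text{mpp})$ source pixels (round half away from
  zero), anchored at the top-left of the ROI bounding box. A grid cell is
  kept iff its **center** lies inside an ROI polygon — the common
  convention when only "within annotated ROIs, in a grid" is specified.
  Kept windows are resized bilinearly to $299 \times 299$ px; at a 20x
  scan (0.5 mpp) the 604-px window becomes an effective ~10x
  magnification. A full-ROI $w \times h$ slide yields exactly
  $\lfloor w/s \rfloor \cdot \lfloor h/s \rfloor$ tiles.
* **Background filter** (`is_background()`): the tile is converted to HSV
  with hue normalized to $[0, 1)$; it is background iff strictly more
  than 60% of pixels have hue $< 0.05$. Achromatic pixels (white
  background) have hue 0 under the standard conversion, which is what
  makes a hue rule effective on background at all.
* **Stain normalization** (`reinhard_normalize()`): Reinhard color
  transfer in the Ruderman $l\alpha\beta$ opponent space reached via
  log-LMS. Each channel is mapped by
  $v' = (v - \mu_{\text{src}})\,\sigma_{\text{tgt}}/\sigma_{\text{src}} +
  \mu_{\text{tgt}}$, then transformed back to RGB and clipped to gamut.
  The normalization target defaults to the statistics of a designated
  reference tile from the cohort (the first non-background tile), and is
  overridable — there is no canonical reference, only the requirement
  that all slides share one.
* **Standardization** (`standardize_tile()`): each tile to mean 0,
  variance 1 jointly over pixels and channels (population SD), the usual
  final step before a convolutional network.

## Dataset assembly and augmentation

Single-drug treatments are **homogenized** into pseudo drug-pairs by
duplicating the drug reference (`homogenize_single_drug()`), so every
sample has the input shape (expression, drug 1, drug 2, tiles) and a
single model family covers all treatments. Because combination response
cannot depend on the order in which the two drugs are listed, every true
drug-pair sample is **swap-augmented** (`augment_pair_swap()`): one twin
per pair with the drug blocks exchanged and everything else shared, which
exactly doubles the drug-pair sample count. Pseudo-pairs are not
duplicated (the swap is the identity for them). The assembled total obeys
$n_{\text{total}} = n_{\text{single}} + 2\,n_{\text{pair}}$.

## Leakage-safe splits

`generate_splits()` produces $k$-fold cross-validation repeated with
different derived seeds (10 × 10 = 100 plans by default). Three leakage
channels are closed:

1. all samples of a treatment group share one label, so groups are never
   split across sets;
2. swap twins are the same experiment, so they share their group's fate;
3. the expression profile and slide of a specimen appear in every group
   of that specimen, so the **folding unit is the specimen**: all groups
   of a specimen travel together. This is the strongest reading of
   "tissue features are never shared across sets", and it makes the
   leakage audit pass by construction.

The validation set is the fold after the test fold (cyclically) within
each repeat — cross-validation needs a held-out validation fold for early
stopping, and this construction keeps all $k$ folds in rotation. Folds
are stratified so responder-bearing specimens spread evenly (a 4%
prevalence makes unstratified test folds frequently single-class);
`stratify = FALSE` gives the literal unstratified protocol.
`audit_leakage()` independently re-checks any plan/sample combination for
the three violation types and is itself tested against planted
violations.

## Models

All models consume the pseudo-pair sample layout:

* **MM-Net** (`mmnet`) — four branches: expression and each drug branch
  are a *single* trainable dense layer (with ~50 unique treatments and a
  few hundred unique profiles the tabular features are highly redundant;
  deeper encoders overfit), the tile branch is a convolutional backbone
  followed by trainable dense layers; branch outputs are concatenated
  into a single sigmoid output.
* **UME-Net** (`ume`) — drops the tile branch (expression + drugs).
* **UMH-Net** (`umh`) — drops the expression branch (tiles + drugs).
* **GBM** (`gbm`) — gradient boosting (xgboost) on the flat
  expression + drug-descriptor table with the same weighted logistic
  objective and early-stopping contract.

The image backbone is pluggable (`register_backbone()`). The bundled
`"small-test"` backbone is a fixed, randomly initialized two-layer CNN
(random convolutional features over a pooled input, channel means and
SDs as features) sized for CPU-scale work: only the dense layers on top
of it train. A large pretrained extractor can be registered under
`"pretrained-large"` where its weights are available; nothing in the
package or its tests depends on it.

Training (`train_model()`):

* class-weighted binary cross-entropy with inverse-frequency weights
  $w_c = N/(2N_c)$, so the rare response class is up-weighted and the
  weighted average of weights is 1;
* tile models train on **tile-level instances**: each tile inherits its
  sample's group label and is paired with the sample's tabular features.
  Only a random 10% of each slide's tiles (`tile_fraction`, floor of one
  tile) enter training; evaluation always uses every tile;
* image augmentation is a random dihedral action (0/90/180/270° rotation,
  50% horizontal flip; `augment_image()`), exactly pixel-preserving, and
  never applied on the evaluation path. The default training path
  consumes precomputed backbone features, so augmentation is applied
  where tiles are re-extracted per epoch; the operation itself is part of
  the public API and unit-tested;
* Adam (default learning rate $10^{-4}$), up to 400 epochs, early
  stopping on validation loss with strict improvement (no minimum delta)
  and patience 10 epochs (100 boosting rounds for GBM), restoring the
  best-validation weights. Encoder widths default to 512 and the image
  head to (512, 256); these are sensible stand-ins for undisclosed
  searched values, and every one is a config parameter.

## Evaluation

Tile probabilities are aggregated by their arithmetic mean over *all*
tiles of the slide to one probability per sample. Per split, all test
sample predictions are pooled and scored with MCC (threshold fixed at
0.5 — the package takes no position on deployment thresholds and exposes
the parameter), AUROC (rank/Mann-Whitney construction, midranks for
ties), and AUPRC (step-wise, non-interpolated average precision).
Single-class test folds give NA for the rank metrics with a warning and
are excluded pairwise from comparisons, with counts reported.

`compare_models()` compares models over shared splits with the paired
t-test and the two-sided Wilcoxon signed-rank test (zeros dropped, normal
approximation), plus per-split win counts. An essentially constant
difference vector short-circuits the t-test (p = 1 for all-zero, p = 0
for a constant nonzero shift) and is flagged `degenerate` — a constant
shift is maximal paired evidence, not an error.

## The synthetic cohort generator

`simulate_cohort()` generates the full input bundle — manifest with
tumor-volume series, TPM matrix, descriptor table with column-wise
missingness, landmark list, H&E-like slides with ROI polygons — with the
statistical structure the pipeline assumes. Default scale mirrors a real
PDX repository screen: 89 patients, 96 specimens, 12 single-drug + 36
drug-pair arms, 959 groups at 42/959 response prevalence, a
landmark-sized expression matrix, and 2200 descriptors of which exactly
1993 survive the missing-value filter. How profiled specimens map onto
groups is not determined by published summary tables, so the group
allocation (`n_groups`, `n_single_groups`, `n_pair_groups`) is an
explicit generator parameter.

Latent structure: each specimen has a sensitivity $s_i \sim N(0,1)$ and
each drug an efficacy $d_j \sim N(0,1)$. A group's response score is
$\min(e, 1)\,(s_i + 0.5\,\bar d) + 0.25\,\varepsilon$ where $e$ is
`effect_size`, and the top `response_prevalence` fraction of groups are
responders. The $\min(e,1)$ factor matters: a drug's descriptor
fingerprint always identifies the drug, so if labels depended on drug
efficacy at $e = 0$, per-drug response rates would remain learnable and
no true null would exist. With the scaling, $e = 0$ yields labels
independent of every feature.

The planted signal with magnitude $e$: 20 designated landmark genes gain
a $e\,s_i$ shift in log2-TPM, 10 designated descriptor columns gain a
$e\,d_j$ shift, and slides of sensitive specimens ($s_i > 0$) are drawn
darker with a higher density of nuclei-like speckles. The speckle
*density* (not just color) is deliberate: Reinhard normalization matches
per-channel moments and per-tile standardization removes global
brightness, so a purely colorimetric signal would be erased by the
pipeline itself; a texture signal survives. Growth curves are
piecewise-exponential with multiplicative log-normal noise; responder
curves dip below 70% of staging for ≥ 2 consecutive points by
construction, non-responder curves are kept above 72% so the labeling
rule recovers the planted labels exactly.

What the generator does **not** emulate: transcriptomic covariance
structure, real drug chemistry, nuclear morphology, scanner artifacts,
and intra-group response variability. Passing tests therefore demonstrate
that the pipeline's plumbing, bookkeeping, and learning dynamics are
correct — not that any particular performance level transfers to real
PDX data.

## Problem sizes used by the tests and the acceptance script

Unit and acceptance tests run on desk-scale cohorts chosen once: 48-group
(12 specimen) cohorts for training smoke tests, 96-group (24 specimen)
cohorts in the acceptance script's learnability run, slides of 512 px at
8 mpp (~20 tiles per slide), 100 genes and 30 descriptors, and a 30%
response prevalence so small test folds retain both classes. Count
arithmetic is checked at full repository scale (959 groups; a
2556-single + 2203-pair composition for the sample identity), which is
cheap because it needs no slides. Learnability checks average test AUROC
over three cross-validation folds: per-fold test sets of a desk-scale
cohort are small, and the fold average is the stable quantity.

## Known limitations

* The bundled backbone is untrained; absolute performance on real WSIs is
  meaningless without registering a pretrained extractor.
* Per-epoch re-augmentation of tiles requires feeding raw tiles rather
  than precomputed features; the provided training path favors the
  precomputed route for CPU budgets.
* Pyramidal TIFFs are read by page index; there is no automatic
  nearest-mpp level selection.
* The t-test/Wilcoxon comparison treats splits as exchangeable paired
  observations; cross-validation folds share training data, so p-values
  are anti-conservative in the usual, well-known way.
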