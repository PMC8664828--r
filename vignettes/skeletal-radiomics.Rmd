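---
title: "Skeletal PET/CT radiomics for bone marrow involvement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeletal PET/CT radiomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bone marrow involvement (BMI) in follicular lymphoma is routinely assessed
by an iliac-crest bone marrow biopsy (BMB) and a visual read of the baseline
FDG PET/CT. Both miss cases: the biopsy samples one site, and diffuse or
heterogeneous marrow uptake is hard to call visually. `skelrad` implements a
quantitative alternative: segment the skeleton on CT, transfer the mask to
PET, summarize the marrow uptake distribution with 26 conventional and
textural features, and combine a LASSO-selected subset into a linear
prediction score with a fixed decision cut-off. The package ships the frozen
published four-feature signature

\[
\text{score} = -8.134 + 0.927\,\mathrm{variance}_{GLCM}
 + 10.272\,\mathrm{correlation}_{GLCM}
 + 0.076\,\mathrm{joint\ entropy}_{GLCM}
 - 0.003\,\mathrm{busyness}_{NGLDM},
\]

classified positive when the score exceeds \(-0.190\) (strictly), plus the
univariate skewness rule (positive when SUV-histogram skewness \(> 1.20\)).
The composite reference standard labels a subject negative only when both
the biopsy and the visual PET read are negative.

Because no patient images are distributed with the package, every data-
dependent step is exercised on a seeded synthetic phantom cohort with known
ground truth. The package therefore validates the *machinery* — masks,
matrices, model fitting, evaluation — not the clinical performance figures,
which require the original cohort.

## Pipeline and assumptions

1. **Skeleton segmentation** (`segment_skeleton`): CT voxels at or above a
   bone threshold (default 120 HU) are selected; per-axial-slice
   morphological closing (3-voxel box brush) and hole filling pull the
   marrow interior of cortical shells into the mask; the largest
   26-connected component is retained. The threshold is deliberately
   config-exposed: the upstream semiautomatic method it stands in for does
   not publish its parameters.
2. **Axial cropping** (`crop_axial_extent`): the analysis extent from the
   C3 vertebra to the upper femoral thirds is approximated by fractions of
   the *skeleton's own* axial span (defaults 0.02–0.88). Anatomical landmark
   detection is out of scope; the fractions are recorded in the mask
   provenance.
3. **Prosthesis exclusion** (`exclude_prosthesis`): 26-connected components
   of CT \(\ge\) 2500 HU, dilated by a physical 10 mm margin, are removed to
   avoid attenuation-correction artefacts around hip prostheses.
4. **Resampling and transfer**: PET is trilinearly resampled to
   4 × 4 × 2 mm (x, y, z) — the axial 2 mm direction matching the scanner
   voxel description — and the binary mask follows by nearest neighbour, so
   it stays binary. No registration is modelled: phantom CT and PET share a
   grid, mirroring a PET/CT acquired in one session.
5. **Discretization** (`discretize`): absolute SUV binning,
   `level = 1 + floor((SUV - 0) / 0.46875)` with 64 bins over 0–30 SUV,
   left-closed bins, values above 30 clamped into the top bin.
6. **Features** (`extract_features`): six conventional values (SUVmax,
   SUVpeak, skewness, kurtosis, excess kurtosis, TLG), six GLCM features
   from a single co-occurrence matrix pooling all 13 distance-1 directions,
   three NGLDM features, and eleven GLZLM size-zone features over
   26-connected equal-level zones.
7. **Signature** (`fit_lasso` / `published_model`): stratified 10-fold
   cross-validated L1-penalized logistic regression selects features;
   an unpenalized logistic refit on the selected set yields original-scale
   coefficients; the training cut-off is Youden-optimal.
8. **Evaluation** (`diagnostic_eval`, `delong_test`, ...): midrank AUC,
   DeLong standard errors and paired comparisons, Youden cut-offs, confusion
   metrics, Mann–Whitney group tests with a Bonferroni threshold, Fisher
   exact tests and Spearman biomarker correlations.

## Numerical and design choices

Where the procedure left genuine freedom, the package fixes the following
conventions (all config-exposed where a user could reasonably differ):

* **Spacing order.** "2.0 × 4.0 × 4.0 mm" is read as (z, y, x) =
  (2, 4, 4) mm, i.e. 4 mm in-plane and 2 mm axial, matching the axial
  scanner voxel description.
* **GLCM.** Distance fixed at 1 voxel in index space (anisotropic spacing
  notwithstanding); the matrix is symmetrized over both orientations and
  normalized to sum 1. Entropy uses base 2 (so the 64-level bound is
  \(\log_2 64 = 6\) bits). GLCM *variance* is computed on the joint matrix,
  \(\sum_{i,j}(i-\mu)^2 p(i,j)\); by symmetry this equals the marginal form.
  A single-level mask makes correlation degenerate: it is returned as `NA`
  with a flag, never silently zeroed.
* **NGLDM.** Amadasun–King neighbourhood differences on the full
  26-neighbourhood, restricted to in-mask neighbours; voxels with no
  in-mask neighbour are skipped. On a flat region coarseness is capped at
  `1e6` (documented sentinel), busyness is `NA` with a flag, and contrast
  is 0.
* **SUVpeak.** The ~1 mL sphere is the set of voxels whose centres lie
  within the 6.2 mm equivalent-volume radius of the hottest in-mask voxel
  centre (ties: lowest linear index), restricted to the mask by default
  (`peak_in_mask`).
* **Moments.** Skewness/kurtosis use population (biased) central moments,
  the common radiomics-software convention; `sample_moments = TRUE` switches
  to the bias-adjusted form. Kurtosis minus excess kurtosis is 3 by
  construction, which doubles as a cheap integrity check. TLG is mean SUV
  times mask volume; the column keeps the conventional `TLG_mL` label
  although its unit is SUV·mL.
* **Conventional count.** Six conventional values are reported (TLG
  included), although narrative summaries of this family often say "five".
* **LASSO.** Binomial deviance loss; penalty at the minimum mean CV
  deviance by default (`rule = "min"`, which yields the denser selections a
  four-feature signature needs), with the sparser one-standard-error rule
  exposed (`rule = "1se"`). On null data the min-CV rule admits spurious
  features in a sizeable fraction of runs — that is a property of the rule,
  not a bug — while the 1-SE rule keeps the nonempty-selection rate near
  5–15%; the false-selection test exercises the 1-SE configuration.
  Features are standardized inside the penalized path and reported on the
  raw scale, since the published coefficients are evidently raw-scale (the
  reference group means map to scores straddling the cut-off). Whether the
  published coefficients came from the penalized fit or an unpenalized
  refit is not documented; both are supported, refit being the default.
* **Youden tie-break.** Candidate cut-offs are midpoints of adjacent
  distinct scores plus infinite endpoints, with the strict `>` rule. Among
  equal-J cut-offs the one with higher specificity (higher cut-off) wins —
  the lowest false-positive burden.
* **p-values.** Two-sided throughout. Mann–Whitney uses exact enumeration
  for combined \(n \le 12\) (ties included) and the tie-corrected normal
  approximation without continuity correction otherwise; measured type-I
  error at \(n = 30 + 36\) over 2000 null replicates is within [0.04,
  0.06]. The Bonferroni divisor is always explicit (`bonferroni_alpha(m,
  fwer)`) rather than guessed from a table footnote.
* **Axis symmetry.** Thresholding, component labelling, cropping and
  transfer are axis-permutation invariant; per-slice hole filling is, by
  construction, tied to the axial direction and is the one deliberate
  exception.

## What the phantom emulates — and what it does not

`generate_subject` builds a stylized skeleton — a vertical spine column with
a cortical shell (700 HU) and marrow core (60 HU), a walled pelvis slab, two
solid femoral stubs, soft tissue at 40 HU — scaled to the grid extent. The
default grid is 64 × 64 × 160 voxels at 2 mm isotropic spacing, so
resampling to 4 × 4 × 2 mm is a real operation. PET marrow uptake is
Gaussian (mean 1.5, SD 0.3 SUV) over a 0.7 SUV background with additive
0.1 SUV noise, clipped at zero.

Disease contrast has two planted mechanisms keyed to each subject's truth
record: visually-positive subjects receive focal hot spheres (default three
8 mm spheres at 6 SUV) confined to marrow, and biopsy-positive subjects
receive a diffuse inflation of marrow SUV variance (multiplier scaled by the
subject's infiltration burden). The cohort generator reproduces the study
composition — 66 subjects, 30 positive (prevalence 45.5%), positives split
4 : 14 : 12 among BMB−/PET+, BMB+/PET−, BMB+/PET+ — and plants a negative
monotone haemoglobin–burden dependence (slope −3 g/dl per unit burden over
burdens of 0.1–0.6, noise SD 1.5 g/dl), sized so a cohort of 200 recovers
the sign at p < 0.01 by Spearman correlation. Reproducibility is
subject-level: child seed `(1009·seed + 7919·i) mod (2^31 − 1)` for subject
`i`.

The phantom deliberately omits: anatomical skeleton shape, scanner
point-spread and reconstruction effects, physiological uptake gradients,
inter-scanner differences, and any registration error between CT and PET.
Its planted effects are also strong relative to tens of thousands of marrow
voxels, so the phantom cohort is close to separable — the refit signature
typically reaches an AUC near 1 on default settings, unlike the subtle
signal in patients. Passing the test suite therefore demonstrates that the
masks, matrices, selection and evaluation machinery are correct and
deterministic; it says nothing about clinical discrimination, which must be
established on real cohorts.

## Problem sizes used in validation

Texture features are verified against exhaustive brute-force oracles
(pair enumeration, per-voxel neighbourhood means, graph connected
components) on volumes up to 5 × 5 × 5 with random masks. Selection
recovery uses table-level simulations (n = 200, 26 features, 4 informative
at 1 SD, 20 seeds); null-size checks use 2000 Mann–Whitney replicates at
n = 30 + 36; the DeLong p-value is checked against a 10,000-replicate
paired bootstrap on a 12-subject toy set; and end-to-end determinism is
checked by running the full 66-subject phantom cohort twice and comparing
artifacts byte for byte. Phantom-level property checks (null uniformity,
variance monotonicity) run on reduced grids (16 × 16 × 40) to keep the
suite fast without changing the mechanisms under test.

## Known limitations

* The skeleton crop is fractional, not anatomical: "C3" and "upper femoral
  third" are not detected, only approximated on the mask span.
* Per-slice hole filling assumes the axial direction is the third array
  axis.
* The adjacent-uptake (lymph-node spill-in) check is a warning only; the
  original workflow's manual review has no automatic counterpart.
* The published model is frozen as printed (three decimals); score
  arithmetic inherits that rounding.
* DICOM/DICOM-RT are not read or written; NIfTI is the interchange format.
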