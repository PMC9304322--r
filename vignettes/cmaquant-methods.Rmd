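---
title: "Models and methods behind cmaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cmaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaquant)
```

cmaquant quantifies pharmacological activation of chaperone-mediated
autophagy (CMA) along four fronts: a transcriptomic activation index, the
expression preprocessing feeding it, image-based quantification of a
fluorescent KFERQ reporter, and the supporting biochemical/pharmacological
assay models. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where the underlying
procedures left genuine freedom. Every empirical statement here is computed
by the package's own test suite or acceptance script.

## The CMA activation index

CMA flux cannot be measured directly in most human material, but the
expression of the genes encoding CMA effectors and regulators tracks it.
The index summarizes a gene-by-sample expression matrix over a curated
network of CMA components, each with a positive weight $w_i$ and a
direction $d_i \in \{+1, -1\}$:

$$ S_{\text{sample}} \;=\; \frac{\sum_i d_i\, w_i\, z_{i,\text{sample}}}
{\sum_i w_i} $$

where $z_{i,\text{sample}}$ is the gene's normalized (z-scored) expression.
LAMP2A, the rate-limiting lysosomal receptor, carries weight 2; every other
component weight 1. Genes whose products promote CMA (the chaperone HSPA8,
LAMP2A itself, ...) enter with $d_i = +1$; inhibitors (the retinoic acid
receptor RARA axis, inhibitory TORC2 signaling, ...) with $d_i = -1$.

Design decisions:

* **Weighted denominator.** We read "weighted, directed average" as weights
  entering both numerator and normalizer ($\sum w_i$, not the gene count).
  With unit weights the two coincide; with LAMP2A at weight 2 the weighted
  normalizer keeps $|S| \le \max_i |z_i|$, a bound the suite verifies.
* **z-score input.** Published use of the index displays expression as
  z-scores, and the $\pm 1$ directions are only meaningful once genes are
  on a common scale, so `compute_cma_score()` requires a matrix in
  `zscore` state (an explicit override exists for audits).
* **Missing genes renormalize by default.** Panels and arrays rarely carry
  every network gene; dropping absent genes from numerator and denominator
  equals scoring with the reduced network (a consistency property the
  suite checks on randomized cases). A strict `missing_policy = "error"`
  mode exists for reproducibility audits.
* **The shipped 17-gene table is an editable example.** Only the weighting
  rule and sign convention are fixed by the index definition; the
  membership table is assembled from the CMA literature for demonstration
  and testing, and users should load their own curated table with
  `load_network_table()`. NCOR1 is deliberately not a member: it modulates
  CMA through the RARA axis and is analyzed separately as the NCOR1/RARA
  expression ratio (`corepressor_receptor_ratio()`), computed on linear
  scale values with zero-denominator samples flagged rather than dropped.

## Expression preprocessing

* **IQR filter** (`iqr_filter()`): keeps genes whose across-sample
  interquartile range strictly exceeds 0.5 by default, the usual
  variability screen before signature scoring. Quartiles use linear
  interpolation between order statistics (R's default type 7); the
  convention matters at the boundary, so it is fixed and documented. The
  filter sentence is implemented as *keep* variable genes — removing them
  would defeat the screen's purpose.
* **z-scoring** (`zscore_normalize()`): per-gene center/scale with the
  sample SD (n − 1). Counts are `log2(x + 1)`-transformed first.
  Zero-variance genes cannot be scaled and become all-zero with a warning
  rather than `NaN`s. An optional `reference_samples` argument anchors
  center and scale to a reference (e.g. vehicle) group, expressing treated
  samples in z-units of the control distribution.
* **ΔΔCt** (`ddct_fold_change()`): technical replicates are averaged
  *before* any differencing (the declared choice where either order is
  defensible); then ΔCt subtracts the housekeeping gene per sample, ΔΔCt
  subtracts the reference-group mean ΔCt per gene, and fold =
  $2^{-\Delta\Delta Ct}$ assuming perfect doubling per cycle (no
  efficiency correction is applied because none is defined for the data
  this serves). Per-sample plate offsets cancel exactly, which the suite
  verifies by construction.

## Synthetic expression data and the recovery oracle

`generate_expression_dataset()` emulates a treated-vs-vehicle design:
per gene, log-scale values are $x = \mu_g + \sigma_g(\varepsilon +
s_g\,\mathbb{1}[\text{treated}])$ with $\varepsilon \sim N(0,1)$, baseline
$\mu_g$ drawn once from the seed, noise SD $\sigma_g$ (default 1), and the
programmed shift $s_g$ specified in z-units. Generators are pure functions
of their arguments including the seed, and every emitted object appears in
the returned ground truth.

Because effects are defined post-normalization, the expected group
difference of the score has the closed form
$\sum_i d_i w_i s_i / \sum_i w_i$. That identity holds exactly only for
z-scores taken against the *true* baseline mean and SD: any empirical
normalization estimates them, and pooled z-scoring in particular inflates
the per-gene scale by the group effect itself, attenuating the realized
shift. The generator therefore returns both the raw log-scale matrix (to
exercise the empirical path) and a truth-normalized z matrix; recovery
checks score the latter, where the Monte-Carlo mean over 200 datasets must
sit within 3 standard errors of the closed form (default network, +1 shift
on all activating genes: expectation $12/18 = 2/3$). The suite runs
200 datasets of 10 + 10 samples; group sizes there trade Monte-Carlo
precision against runtime and are not a biological claim.

## Reporter-field simulation and puncta quantification

The KFERQ photoswitchable reporter redistributes from diffuse cytosol into
lysosome-associated puncta when CMA is active, so per-cell puncta counts
are the activity readout. The acquisition side (optics, exposure,
proprietary analysis software) is not described by any quantitative
parameters we could adopt, so the simulator declares an explicit synthetic
model, and the detector is scored against its exhaustive ground truth:

* **Geometry.** Nucleus centers by dart-throwing with a minimum-distance
  constraint (cells never overlap; impossible packings raise an error);
  each cell is a disk (nucleus radius 7 px + cytosol width 14 px), its
  cytosol the annulus between nucleus and cell edge. Pixel size defaults
  to 0.5 µm/px, a typical high-content mid-magnification scale.
* **Signal.** Nuclei at 3000 counts over a 200-count background; diffuse
  cytosolic reporter at 400 counts in expressing cells; puncta as
  symmetric Gaussians (σ = 2 px). SNR is defined as (punctum peak −
  cytosol mean)/noise SD, with Gaussian read noise (SD 60) on both
  channels. Puncta are placed with ≥ 6 px mutual separation and at least
  4σ clear of the cell boundary, so the boundary step cannot masquerade as
  a punctum; when a dense draw cannot be dart-packed the generator falls
  back to an evenly spaced ring at mid-cytosol radius.
* **Segmentation** (`segment_nuclei()`): robust threshold (median +
  5 MAD), hole filling, distance-transform watershed to split touching
  nuclei, minimum-area filter (30 px).
* **Gating** (`gate_expressing_cells()`): the cytosol proxy is a
  fixed-width annulus (5 px) just outside the nucleus, with contested
  pixels assigned to the nearest nucleus; a cell is expressing when its
  annulus mean exceeds background median + 3 background MAD. Robust
  background statistics matter because the out-of-cell region can still
  contain cell peripheries.
* **Detection** (`detect_puncta()`): difference-of-Gaussians band-pass
  (inner σ 1.5 px, outer 2×), local maxima above 5× the response-scale
  noise SD, maxima closer than 4 px merged. The inner scale sits slightly
  below the spot width: a matched filter (σ = 2) maximizes single-spot
  response but blurs punctum pairs separated by ~6 px into one peak,
  while σ = 1.5 resolves them with ample noise margin. The noise SD is
  estimated from adjacent-pixel differences of the raw image inside the
  mask (MAD/√2) and converted to response units through the DoG kernel's
  L2 gain — robust to real structure in the mask and exactly proportional
  to intensity, so all counts are invariant under multiplicative gain.
  Detector defaults were calibrated once against the simulator and are
  frozen; on seeded fields the suite requires ≥ 95% exact per-cell count
  agreement at SNR 8 and punctum-level precision and recall ≥ 0.9 at
  SNR 5 (both are met with margin).
* **Classification and QC.** A cell is CMA-positive when its count
  *strictly* exceeds 3 (i.e. ≥ 4), the percentage taken over expressing
  cells only; baseline counts of common cell types (3–4 puncta/cell in
  fibroblast lines, ~5 in primary human fibroblasts) are documentation,
  not gates. A field passes QC when its nuclei count is at least 1/10 of
  the mean control-field count (boundary inclusive, applied per field and
  switchable) — the exclusion that guards against out-of-focus fields
  after drug-induced changes in cell volume or adherence. The tandem
  mCherry-GFP flux reporter is handled by `classify_tandem_puncta()`:
  puncta detected on the red channel are autophagosomes (dual) when their
  green disk mean exceeds the green background gate, autolysosomes
  (red-only) otherwise, and the two classes always sum to the total.

What passing these tests does *not* show: the simulator has flat
backgrounds, disk-shaped cells, ideal Gaussian spots and no out-of-focus
light, debris, or autofluorescence. Performance on real micrographs will
be worse and must be validated per dataset; numerical agreement with
published counts produced by proprietary high-content software is not
claimable.

## Assay models

* **FP binding EC50** (`fit_binding_ec50()`): receptor titrations of a
  fluorescent co-repressor peptide (probe default 5 nM; concentrations a
  two-fold series from 10 µM, 12 points — the point count is a
  configuration default, not a protocol claim). The default model is the
  four-parameter logistic on log10 concentration (Hill slope fixed at 1 by
  default, i.e. the one-site hyperbola); the alternative
  `one_site_depletion` model solves the quadratic equilibrium for probe
  fraction bound, relevant when probe and receptor are commensurate at the
  curve foot, with EC50 = $K_d$ + probe/2. Fitting is Levenberg–Marquardt
  least squares parameterized in log10 EC50 (Wald CI on that scale);
  plateaus absorb affine transforms of the mP axis, so the EC50 is
  invariant to gain and offset. Fits are flagged `extrapolated` (EC50
  outside the tested range) or `unreliable` (dynamic range under 3
  residual SDs, or optimizer failure).
* **Non-compartmental PK** (`nca_parameters()`): Cmax/Tmax by inspection,
  AUC by the linear trapezoid, terminal slope by least squares on log
  concentration over an *explicit* number of terminal points (default 3;
  explicit selection was chosen over automated best-fit for
  reproducibility), $t_{1/2} = \ln 2 / \lambda_z$, and
  $AUC_\infty = AUC_{last} + C_{last}/\lambda_z$. A non-declining terminal
  phase leaves the half-life undefined and flagged. On any noiseless
  mono-exponential the half-life is exact regardless of the grid.
* **Unit conversion** (`ng_per_g_to_micromolar()`):
  µM = ng/g × density / MW, with tissue density defaulting to 1 g/mL
  (the conversion assumption is not otherwise specified); molecular
  weights are inputs. The round trip is identity to 1e-12 relative.
* **Proteolysis** (`percent_proteolysis()`, `pathway_fraction()`): percent
  degradation at a time point is 100 × soluble/(soluble + precipitable),
  the standard pulse-chase convention of taking the same-time total as
  denominator. The inhibitor-sensitive share (lysosomal inhibitors for
  lysosomal degradation, an ULK1/2 inhibitor for macroautophagy) is the
  difference in percentage points and its fraction of total; negative
  differences are flagged, never silently clamped.

## Numerical conventions and degenerate inputs

* Quartiles: type 7. z-scores: sample SD (n − 1). Strict inequalities at
  the IQR and CMA+ thresholds; inclusive boundary at field QC.
* Image coordinates are 1-based (row, col) in R structures and 0-based in
  JSON sidecars (stated in the sidecar itself). Images are 16-bit
  multichannel TIFF.
* Degenerate inputs fail loudly and specifically: duplicate gene ids name
  the gene, constant genes warn and zero out, empty cell lists error in
  classification but not in gating, zero denominators flag the sample.
* Simulation sizes in the suite (200 score-recovery datasets of 10 + 10
  samples; 12-cell 320×320 fields; 100 noisy binding replicates) were
  chosen once as the smallest designs whose Monte-Carlo error is clearly
  below the tested tolerances.

## Known limitations

* The shipped network table is illustrative; published index values from
  specific datasets are not reproducible without the original curated
  membership/direction table and data.
* The imaging model is 2-D, single-plane, noise-homoscedastic; no
  deconvolution, no learned segmentation, no tissue registration.
* The ΔΔCt model assumes perfect amplification efficiency.
* The depletion binding model treats a single site with no cooperativity;
  EC50s are operational, not thermodynamic $K_d$s, under ligand-induced
  stabilization.
* PK noise is log-normal and independent across time points; no
  animal-level variance structure is simulated.
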