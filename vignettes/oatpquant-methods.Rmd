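---
title: "Methods: simulation-validated quantification of OATP expression in tumor tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-validated quantification of OATP expression in tumor tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Organic anion transporting polypeptides (OATPs, gene family *SLCO*) are
solute-carrier uptake transporters with broad substrate ranges that include
several anti-cancer agents. In glioblastoma (GBM) their protein-level
expression across tumor cell types — myeloid cells, tumor/astrocyte
parenchyma, stromal cells, and vasculature — is of direct interest for drug
delivery across the blood–tumor barrier. The measurement instrument is
multiplexed fluorescent immunohistochemistry: for each case, serial sections
are labeled with one OATP isoform antibody alongside cell-type markers
(IBA1 for myeloid cells, GFAP for astrocytes/tumor, UEA-1 lectin for
endothelium, PDGFRB for stroma) and a Hoechst nuclear counterstain, and the
scanned channels are quantified tissue-wide and per segmented cell.

`oatpquant` implements that quantification chain as reusable, tested code,
and pairs it with a synthetic image generator with complete ground truth.
Patient images are not required anywhere: every stage is validated by
parameter-recovery — configure a known group difference, run the pipeline
blind, and require the measured statistic to come back.

## Measures

For a case image with tissue mask $T$ and OATP-positive mask $M$ (both from
the segmentation stage):

* **integrated intensity**: $\sum_{p \in M} I(p)$, the channel sum over the
  OATP-positive mask;
* **mean integrated intensity**: the same sum divided by $|T|$, i.e.
  normalized to tissue (ROI) area. Both raw and normalized forms are
  reported; the normalized form is the headline tissue-wide measure;
* **percent area coverage**: $100\,|M \cap T| / |T|$;
* **single-cell OATP intensity**: the mean OATP value over each labeled
  IBA1+ or lectin+ object; cases are summarized by the mean of their
  object means;
* **positivity**: an object is OATP-positive when its mean exceeds the
  pooled control-cohort 99th percentile of single-cell OATP means
  (strictly greater; an object exactly at the threshold is negative).
  The percentile convention reflects that tumor and control sections are
  stained in one batch, so control tissue defines the reference
  distribution. The quantile is configurable (`positivity_q`).

Group contrasts are ratios of group means (GBM over control), chosen to
match "x-fold" reporting conventions; medians are available via
`group_fold_change(..., location = "median")`. When a case contributes
several images, their measures are averaged first — each case enters every
statistic exactly once.

## Segmentation conventions

The mask-building stage replaces an interactive commercial workflow whose
exact operator sequence is not reproducible from published text; it is a
declared stand-in validated against simulation ground truth, not against
the original software.

* Thresholds are Otsu per channel per case by default: the threshold is
  the observed value maximizing between-class variance, with *strictly
  greater* pixels as foreground. Candidates are the distinct observed
  values, so the operator is exact for float data, not only 8-bit. A fixed
  per-channel threshold and a pooled-control percentile mode
  (`control_thresholds()`) are provided.
* The tissue mask is the union of per-channel above-background pixels,
  closed and hole-filled. Background is the channel mode (unit-resolution
  binning); the tolerance is four background noise standard deviations
  estimated from the *below-mode* tail, which object signal cannot
  inflate. (A whole-channel MAD was tried first and proved unstable under
  16-bit quantization of otherwise identical images.)
* Connected components are 8-connected; coordinates are 0-based
  (row, col) with origin top-left in all exported tables.
* Objects smaller than `min_object_area` (default 30 px, about 3 µm² at
  0.325 µm/px) are discarded as fragments.
* Nuclei: Gaussian smoothing (sigma 1 px), Otsu, watershed split on the
  distance transform, area filter. A blank raster yields zero nuclei.
* Myeloid objects are IBA1+ components, watershed-split like nuclei:
  touching cells otherwise merge into single components whose centroids
  match neither cell. Vessels are lectin+ components (tubes are elongated,
  so no splitting). Pixels positive for both IBA1 and lectin are assigned
  to vessels (`vessel_priority`), preventing peri-vascular double
  counting; interactive workflows rarely pin this convention down, so it
  is explicit and configurable here.
* Degenerate inputs: a single-valued channel under Otsu falls back to the
  fixed threshold when provided, otherwise errors; an empty tissue mask
  makes area-normalized measures errors ("empty ROI"), never silent zeros.

## Statistics

The statistical layer is deliberately self-contained (mid-ranks,
Mann–Whitney U, Spearman, Benjamini–Hochberg), with base R's
implementations used only as independent cross-checks in the test suite.

* **Mann–Whitney U** uses joint mid-ranks; U is reported for the first
  sample. Exact two-sided p-values (double the smaller tail, capped at 1)
  come from full enumeration of rank assignments for small samples
  (including tied data) and from the exact tie-free null distribution of
  U — computed by the classical rank-sum counting recursion — for larger
  samples up to $n_1 n_2 \le 2000$. Larger or tied samples use the normal
  approximation with tie-corrected variance and continuity correction.
  The exact path exists because the approximation is visibly conservative
  at this package's central design point (25 vs 8 cases): simulated null
  rejection at $\alpha = 0.05$ is 0.037 under the corrected approximation
  but 0.044–0.049 exact, and a calibrated test is a stated design target.
  If all values in both groups coincide the comparison is degenerate:
  U = $n_1 n_2/2$, p = 1, flagged.
* **Spearman** rho is the Pearson correlation of mid-ranks; p uses the
  t approximation with n − 2 df, flagged approximate below n = 10. Zero
  rank variance leaves rho undefined (NA), never 0. Reported p-values are
  floored at the smallest positive double so downstream FDR adjustment
  stays within its (0, 1] domain.
* **BH adjustment** is the step-up: sort ascending, $q_i = p_i m / i$,
  enforce monotonicity from the top, cap at 1, return in input order.
  Correlation matrices adjust across the upper triangle only; raw and
  adjusted columns are both exported since multiplicity handling for
  marker correlation panels is a reporting choice.

## The synthetic cohort generator

The generator emulates the structure the analyses assume — not tissue
realism. Defaults are the emulated study design: 25 GBM and 8 control
cases, 512×512 px at 0.325 µm/px (a typical 20x slide-scanner sampling;
bit depth and pixel size are configurable, not asserted).

Scene model: cells are filled disks (myeloid radius 4–7 px,
astrocyte/tumor 5–8 px, stromal 4–6 px) with a co-located Hoechst nucleus
disk at half the cell radius; vessels are random-walk tubes of width 5 px
carrying lectin, with a 2 px PDGFRB-positive pericyte rim. Each tube has
a fixed total path length (twice the longer image side) and reflects at
the frame boundary, so per-case vessel area is controlled by the count
and width parameters rather than by how quickly a walk happens to exit
the frame — without this, true coverage varied more than two-fold
between cases. Densities
default to 1200 (myeloid), 2000 (astrocyte/tumor) and 600 (stromal)
cells/mm², giving a few dozen objects per type per frame — enough overlap
to exercise splitting without saturating the frame. Later-drawn objects
*replace* earlier pixels (vessels drawn last), and ground-truth footprints
are the surviving owned pixels, so per-object means over ground-truth
masks are exactly the configured means when blur and noise are off.

Intensity model: each control-tissue cell type has a per-channel mean
(arbitrary units over a background of 20). GBM cases multiply the OATP
channel by a per-compartment fold; a single number configures a uniform
tissue-level fold. The defaults follow the OATP1A2-like profile (myeloid
18, parenchyma 6.1, vessel 6). Two unit-mean log-normal factors add
variation without biasing folds: a per-case, per-channel batch factor
(log-sd 0.1, a moderate inter-case staining/section effect) and a
per-object factor (log-sd 0.2, cell-to-cell heterogeneity). Rendering is
blur (Gaussian PSF, sigma 1 px) → Poisson shot noise → Gaussian read noise
(sd 8) → clip at zero; floats are kept internally and quantized to 16 bits
only on TIFF export.

Necrosis (optional, GBM only, off by default so fold-recovery cohorts stay
homogeneous): an acellular core disk, a pseudo-palisading (PPN) band of
elevated cell density around it, a peri-necrotic (PNZ) band beyond, and an
OATP multiplier $1 + A e^{-d/\lambda}$ in the distance $d$ from the core
edge — greatest immediately adjacent to necrosis and fading towards the
periphery, as described for OATP4A1.

What the generator does **not** emulate: 3D structure, spectral
bleed-through, autofluorescence texture, stitching artifacts, realistic
cell morphology, or inter-batch staining drift. Passing recovery tests
therefore demonstrates that the measurement chain is unbiased and
calibrated under the generative assumptions, not that it is robust to
every property of scanned patient tissue.

## Niche expression stage

The region-annotated expression generator uses a single latent hypoxia
factor: sample $s$ in region $r$ has $f_s = \mu_r + N(0, 1)$ with
$\mu = 0$ in cellular tumor (CT) and $\mu = 2$ in the PPN/PNZ niches, and
gene $g$ has expression $b_g \exp(\ell_g f_s + \varepsilon)$,
$\varepsilon \sim N(0, 0.3)$. In the default panel, SLCO4A1 and the
hypoxia/immunogenic program genes (CA9, VEGFA, BNIP3, PDK1, NDRG1,
ANGPTL4, EGLN3, CXCL8, IL1R1, TREM1, ATF3) load on the factor; the other
SLCO genes do not.

Differential expression between a niche and CT is a fully specified
in-package statistic — $\log_2(\text{mean}+1)$ ratio, Mann–Whitney across
samples, BH across genes — rather than a count-model fit; results on real
atlas data are therefore not expected to reproduce published DEG lists.
Selection applies both cutoffs conjunctively as configured (defaults
FDR < 0.01 *and* raw p < 0.1 — kept as stated even though the FDR cutoff
is the stricter of the two). The "top DEGs" carried into the OATP
correlation matrix default to 40 (configurable; the source material is
internally inconsistent between 30 and 40). Correlation heatmap ordering
uses average-linkage clustering on $1-\rho$ with genes pre-sorted
alphabetically, so the order is a deterministic function of the
correlation matrix.

## What the recovery experiments measure

`fold_recovery_experiment()` reports, for the tissue-wide design, the
ratio of group mean integrated OATP intensities (the channel sum over
the OATP-positive mask). The simulated section fills the fixed imaging
field, so this ratio is identical to the ratio of means normalized to
ROI area while avoiding an intensity-derived section-area denominator —
that estimate exists for ingested slides whose fields include
off-section glass, and on full-frame tissue it adds sampling noise
without information. Compartment designs report the fold of the
per-case mean of per-object OATP means within the segmented IBA1+ or
lectin+ objects.

Two residual effects bound what recovery can show. First, the measured
OATP mask includes part of each object's PSF skirt, and the Otsu
threshold lands at slightly different relative heights in bright versus
dim cohorts; decomposition against ground truth puts this at about +4–5%
on the tissue-wide fold. Second, the realized cohort contrast at any
given seed differs from the configured fold by the sampling noise of the
per-case intensity factors (ratio sd ≈ 4–5% at 25 vs 8 cases), so
recovered folds are expected to match configured ones to roughly 10–15%
relative error at study scale, and much more tightly as cohorts grow.

## Reproducibility and problem sizes

Per-case seeds derive from the master seed by a documented
multiplicative-congruential hash (`derive_case_seed()`), so any case can
be regenerated in isolation and cohorts are reproducible bit-for-bit.
The test suite exercises structural properties on 128–192 px images and
small cohorts; the acceptance-scale experiments (`scripts/acceptance.R`
and the acceptance test file) run the full 25 + 8 design at 512×512 px,
which completes in a few minutes per cohort on a single CPU. Null
calibration uses 2000 simulated two-group comparisons at the design sizes.

```{r example}
library(oatpquant)
res <- fold_recovery_experiment(6.1, "tissue", seed = 42L)
res$fold_measured   # close to 6.1
```

## Known limitations

* Absolute intensities are arbitrary units; no calibration to fluorophore
  counts or inter-batch normalization is attempted.
* The tissue-wide fold is recovered cleanly because both groups share the
  same geometry distribution; coverage differences between groups (e.g.
  hypercellularity) would mix intensity and area effects in the
  normalized measure, as they would in real data.
* Heavily overlapped cells whose surviving footprint falls below
  `min_object_area` are undetectable by construction; recall is defined
  over detectable objects.
* The Spearman p-value is a t approximation even at small n (flagged);
  exact permutation is not implemented outside the test oracles.
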