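# oatpquant

Quantifying **OATP transporter expression** in multiplexed fluorescent
immunohistochemistry images of glioblastoma (GBM) versus non-tumor brain
tissue — as a reproducible, simulation-validated R pipeline.

Organic anion transporting polypeptides (OATPs; genes *SLCO1A2*,
*SLCO2B1*, *SLCO1C1*, *SLCO4A1*) are solute-carrier uptake transporters
whose substrates include several anti-cancer agents, making their
expression on GBM tumor cells, myeloid cells and vasculature a candidate
drug-delivery route. The measurement chain this package implements:

1. **simulate** — a synthetic multiplexed IHC generator (6 channels:
   Hoechst, OATP, IBA1, GFAP, UEA-1 lectin, PDGFRβ) with complete ground
   truth: disk cells, random-walk vessels, configurable per-compartment
   GBM:control OATP fold changes, optional peri-necrotic OATP gradients,
   and a realistic blur → Poisson → Gaussian noise model;
2. **segment** — tissue mask, Hoechst nuclei (Otsu + watershed), and
   marker-positive objects (IBA1⁺ myeloid cells, lectin⁺ vessels, OATP⁺
   masks) with explicit, reproducible parameters;
3. **quantify** — tissue-wide integrated intensity (raw and normalized to
   tissue area), percent area coverage, per-object OATP means, per-case
   aggregation, group fold changes, positivity fractions, per-niche
   (CT/PPN/PNZ) means;
4. **stats** — self-contained tie-corrected Mann–Whitney U (exact null
   distribution where feasible), Spearman correlation matrices, and
   Benjamini–Hochberg adjustment;
5. **niche expression** — differential expression between anatomical
   niches of a region-annotated expression table and correlation of
   *SLCO* genes with the selected genes.

The central statistic is the group fold change
`fold = mean(measure | GBM) / mean(measure | control)` with a two-sided
Mann–Whitney U test on per-case values. Because no image data accompany
the measurements being emulated, every stage is validated by **parameter
recovery**: configure a known fold, run the pipeline blind to the ground
truth, and require the measured fold back within sampling tolerance.

## Worked example

Simulate a reduced two-group cohort with a uniform tissue-level OATP fold
of 6.1, then segment and quantify it blind:

```r
library(oatpquant)
cfg <- generator_config(cohort_sizes = c(gbm = 6L, control = 4L),
                        image_shape = c(256L, 256L),
                        oatp_fold = 6.1, seed = 42L)
cases <- generate_cohort(cfg)
res <- analyze_cohort(cases)
res$folds[, c("measure", "fold", "U", "p")]
#>                            measure fold  U       p
#> 1      tissue_integrated_intensity 7.03 24 0.00952
#> 2 tissue_mean_integrated_intensity 6.43 24 0.00952
#> 3            percent_area_coverage 1.05 13 0.91429
#> 4                myeloid_mean_oatp 6.45 24 0.00952
#> 5                 vessel_mean_oatp 6.44 24 0.00952
```

The configured 6.1-fold enrichment is recovered in the intensity
measures (6.4–7.0 at this reduced cohort size; closer at the full
25 + 8 design) while percent area coverage stays near 1 — the simulated
groups differ in intensity, not geometry. U = 24 is the maximum for
6 vs 4 cases (complete separation); p = 0.0095 is the exact two-sided
tail. Per-object single-cell measurements are in `res$objects`, per-case
summaries in `res$cases`, and OATP positivity against the control
99th-percentile single-cell threshold in `res$positivity` (here 100% of
GBM myeloid objects exceed the control threshold of 161 a.u.).

`run_pipeline(pipeline_config(...))` wraps the same chain with CSV/JSON
outputs, YAML configuration (`run_config_from_yaml()`), an ingest mode
for external TIFF cohorts, and an optional niche-expression stage; a thin
CLI lives at `inst/scripts/oatpquant-cli.R`.

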