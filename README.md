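# lipidpipe

Quantitative tissue lipidomics from class-separation MS feature tables, as
a tidyverse-native R package. `lipidpipe` covers the computational workflow
of a pancreatic-tissue lipidomics study end to end:

* **Lipid registry** — species-level shorthand parsing (`PC 34:2`,
  `Cer 38:1;O2`, `PC P-36:1 d9`), elemental compositions anchored on
  published structural formulas, and adduct m/z values following the
  observed ionization rules (PI as [M+NH4]+, Cer as [M+H−H2O]+, acetate
  adducts for choline lipids in negative mode, …).
* **Isotopic correction** — isotopologue envelopes by convolution of
  natural abundances, and the type I/II corrections for class
  co-elution: `T(S) = (area(S) − T(L)·p2(L)) / p0(S)`, where L is the
  same-carbon species with one more double bond whose +2 isotopologue
  falls inside the monoisotopic extraction window.
* **Quantification** — one-point calibration against a per-class
  deuterated internal standard, `c = (area/area_IS) × amount_IS` in
  nmol per mg wet tissue, with a secondary-standard back-calculation as a
  per-class error estimate.
* **QC curation** — the three-step cascade (blank ≤ 20% of QC intensity,
  QC CV < 20% with full QC detection, ≥ 80% prevalence) plus group-wise
  imputation at 80% of the group minimum.
* **Stability statistics** — lysophospholipid hydrolysis ratios
  (Σ degradation-class area / Σ precursor-class area, baseline = 100%),
  Dunnett many-to-one tests over storage time, Welch t, volcano (FC ≥ 2,
  p ≤ 0.05) and PCA.
* **Fractionation statistics** — hexane/methanol partition fractions per
  class and water content, percent change against the anhydrous
  reference, Tukey HSD with compact letter displays.
* **Synthetic data** — a seeded generator producing ground-truth
  lipidomes, first-order hydrolysis time courses, partition experiments
  and rendered feature tables (IS spikes, isotope overlap, noise,
  censoring, QCs, blanks), so that every stage is verifiable offline.

All user-facing functions take a data frame first and return tibbles;
results ship with `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
displays.

## Worked example

Simulate a six-mouse cohort at 10% measurement CV, render feature tables,
run the pipeline, and curate:

```r
library(lipidpipe)
library(dplyr)

truth <- simulate_ground_truth(seed = 1)          # 54.18 nmol/mg polar lipidome
cohort <- purrr::map_dfr(1:6, function(i) tibble::tibble(
  sample_id = sprintf("S%d", i), group = ifelse(i <= 3, "female", "male"),
  species = truth$species$species, conc_nmol_mg = truth$species$conc_nmol_mg))
ren <- render_feature_table(cohort, truth, noise_cv = 0.10, seed = 1)

res <- lipid_pipeline(ren$features, ren$metadata,
                      candidate_species = truth$species$species)
flt <- qc_filter(res$annotated |> filter(status == "matched", label_d == 0) |>
                   select(species, sample_id, area),
                 res$quant, ren$metadata)
flt
#> QC filter cascade (blank > robustness > prevalence)
#>   thresholds: blank ratio 0.20, QC CV 0.20, prevalence 0.80
#>   step       n_retained
#> 1 input              42
#> 2 blank              42
#> 3 robustness         32
#> 4 prevalence         32
```

With only three QC injections and ~14% concentration CV (analyte and IS
noise combine), the robustness step prunes a quarter of the panel — the
same behavior that real curation shows. The surviving quant table recovers
the class make-up of the generating lipidome:

```r
res$quant |>
  filter(species %in% flt$retained, grepl("^S", sample_id)) |>
  group_by(class_label) |> summarise(nmol_mg = sum(conc_nmol_mg) / 6)
#>   class_label nmol_mg
#> 1 PC            28.4
#> 2 PE             4.15
#> 3 PE O-          3.28
#> 4 PI             2.92
#> 5 PS             1.47
#> # 8 more rows
```

(PC sits at 28.4 nmol/mg ≈ its generating share of 52.4% × 54.18; PE reads
low here because robustness-filtered species drop out of the class sum.)

A stability experiment — storage on ice with a hydrolysis rate that
doubles the LPC pool by 120 min — is flagged by the Dunnett comparison:

```r
tc <- simulate_hydrolysis_timecourse(
  truth, k = c("LPC/PC" = rate_for_conversion(0.01, 120)), seed = 2)
meas <- simulate_measured_areas(tc, truth, cv = 0.10, seed = 3)
hr <- hydrolysis_ratios(class_totals(meas, value = "area")) |>
  left_join(distinct(meas, sample_id, time_min), by = "sample_id")
nr <- normalize_baseline(hr) |> filter(pair == "LPC/PC")
anova_dunnett(nr, value = "normalized_pct", group = "time_min", control = 0)
#> One-way ANOVA with Dunnett comparisons vs '0'
#>   F(3, 8) = 67.974, p = 4.922e-06
#>   comparison estimate statistic        adj_p significant
#> 1 120 - 0       113.      13.6  0.0000000125 TRUE
#> 2 30 - 0         25.1      3.01 0.0411       TRUE
#> 3 60 - 0         52.8      6.32 0.000623     TRUE
```

The normalized ratio climbs from 100% at baseline to ≈ 213% at 120 min
(estimate 113 above the control), matching the first-order mass balance
built into the generator.

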