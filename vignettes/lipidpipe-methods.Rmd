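---
title: "Methods: quantitative tissue lipidomics with lipidpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative tissue lipidomics with lipidpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidpipe)
library(dplyr)
```

## The problem

Pancreatic tissue is lipolytically aggressive: phospholipase A2 and related
enzymes keep working during sample handling, converting glycerophospholipids
(GPLs) into lysophospholipids within minutes to hours even on ice. A tissue
lipidomics workflow therefore needs, besides quantification itself, a way to
*measure* lipidome stability (the hydrolysis ratio), rigorous QC-based
curation, and — because triacylglycerol-rich extracts overload class
separation chromatography — a liquid–liquid fractionation step whose
partitioning behavior must be characterized.

`lipidpipe` implements the computational side of such a workflow, starting
from exported feature tables (m/z, retention time, per-sample peak areas).
Raw-spectrum processing (noise reduction, centroiding, peak picking) is out
of scope; the synthetic renderer emulates the behavior of a 20 mDa
extraction window with a 3,000-count intensity threshold instead.

## Species model and annotation

Lipids are handled at the species level, `CLASS C:D(;On)` with `O-`/`P-`
linkage prefixes and `dK` deuterium labels. Each class is anchored by one
reference species with a published structural formula (e.g. PC 34:2 =
C42H80NO8P); the class series then follows by +CH2 per acyl carbon and
−H2 per double bond. Ether linkage replaces an ester oxygen (−O +H2) and a
plasmalogen is an ether with one more double-bond equivalent (net −O).
Sphingolipid classes (SM, Cer, HexCer) default to the `;O2` backbone when
the suffix is omitted, so `SM 42:1` and `Cer 38:1;O2` both resolve; the
canonical printed form always carries the suffix. Nonstandard
internal-standard names (`Cer C18 d7`, `GlcCer 36:1 d5`) are accepted
through a small alias table.

Adducts follow the observed ionization behavior of class separation with
ammonium acetate modifiers: protonated molecules in positive mode except PI
(ammoniated) and Cer (water loss); deprotonated LPE/PE/PG/PI/PS and acetate
adducts of Cer/HexCer/LPC/PC/SM in negative mode. PG and PS ionize only in
negative mode, the neutral classes only in positive mode. m/z values
include the electron mass (protonation adds 1.007276 Da), which matters for
holding 10 ppm consistency at low m/z.

Annotation matches a feature to a candidate when the relative mass error is
within the tolerance (default 10 ppm), the retention time falls inside the
class window, and the polarity agrees. Because manual chromatogram review
is not reproducible, ties are broken deterministically: smallest absolute
ppm error, then the class whose window center is nearest. One species keeps
one feature per polarity (best ppm); displaced features are reported as
`shadowed` for audit. Class windows default to windows anchored on the
spiked internal standards' own features; ether classes without a dedicated
standard inherit the ester class window, since ether and ester forms elute
in the same class region.

## Isotopic corrections

Envelopes are computed by convolving per-element natural-abundance
distributions, aggregated by nominal mass shift, with deuterium label
positions fixed. The envelope is truncated at +K (default K = 4 for
corrections, 6 for reporting); for lipid-sized molecules the retained mass
exceeds 0.999, and the truncated tail is deliberately not renormalized.

Under class separation all species of a class co-elute, so the
monoisotopic extraction window of species S (carbons n, double bonds d)
also captures the +2 isotopologue of the species L = (n, d+1): the spacing
between one double bond (2.01565 Da) and two nucleons (2.00671 Da) is
8.9 mDa, well inside a 20 mDa window. Species are processed from most to
least unsaturated within each carbon number, and

    T(S) = (area(S) − T(L) · p2(L)) / p0(S)

removes the interference (type II) before rescaling by the monoisotopic
fraction (type I). A species without an interferer reduces to
`T = area / p0`. Negative intermediates are clamped to zero with a warning.
Correction is applied within class × adduct × polarity × label; classes are
chromatographically separated, so no cross-class correction is attempted,
and only the +2 overlap is corrected (a possible +4 overlap from a
two-double-bond difference is out of scope).

## Quantification

One-point calibration per class: `c = (area / area_IS) × amount_IS`, with
both areas isotope-corrected and the IS amount in nmol per mg wet tissue
taken verbatim from the mix sheet's per-mg column (the per-mL and per-mg
columns of the shipped sheet are mutually inconsistent for MG and Chol;
the per-mg value is what the formula consumes, so it is used as printed).
A missing or zero IS area flags the species unquantifiable in that sample
rather than producing a silent zero. When a species is measured in both
polarities the positive-mode value is reported and the other kept in
provenance (most classes' primary detection is the positive-mode
protonated/ammoniated form); `prefer_polarity` flips the rule. The
secondary (nondeuterated) standard of each class is back-calculated
against the primary and its deviation from the nominal spiked amount is
reported as a per-class percentage error; cholesterol, PC O- and PE O-
have no secondary standard and report a reason instead. An advisory check
warns when the largest analyte/IS area ratio leaves the 2–3 design band.

Dosing bookkeeping helpers cover the bead-homogenization arithmetic: a
1:25 (w/v) tissue-to-solvent ratio gives 40 mg/ml, and a 75 µl aliquot of
that homogenate carries 3 mg of tissue.

## QC curation

Three steps in fixed order, each evaluated only on survivors of the
previous one:

1. **Blank**: excluded if mean blank *intensity* > 20% of mean QC
   intensity (strict inequality; a ratio of exactly 0.20 is retained).
   The blank step runs on pre-quantification intensities, the later steps
   on concentrations, following the distinct wording of the two rules.
2. **Robustness**: retained only if detected in *all* QC samples with a
   concentration CV below 20%.
3. **Prevalence**: retained if detected in at least 80% of study samples
   (inclusive). Prevalence is evaluated across all study samples by
   default, with a per-group option, since the rule does not specify a
   grouping.

"Detected" means non-missing; a measured zero counts as detected, a value
censored below the detection limit does not. Missing values are then
imputed as 80% of the minimum observed concentration of that species
within the sample's biological group (sex, handling arm, time point; QCs
form their own group); a species with no observed value in a group stays
missing and is reported.

## Stability statistics

The hydrolysis ratio of a degradation/precursor class pair is the summed
corrected area of the degradation class divided by that of the precursor
class, per sample; deuterated standards never enter class totals. Ratios
use raw corrected areas (not IS-normalized values): the IS factors cancel
within a class and the ratio is a within-run quantity; an IS-normalized
variant can be produced by feeding quantified values instead. Series are
normalized so the baseline (0 min) mean is exactly 100%. Default pairs:
LPC/PC, LPC(O-)/PC(O-), LPE/PE, LPE(O-)/PE(O-), plus DG/TG, MG/DG and
Chol/CE.

Group comparisons use one-way ANOVA with Dunnett many-to-one contrasts
against the control time point (`multcomp`, single-step multivariate-t
adjustment, which the test suite cross-checks against a seeded Monte-Carlo
max-|t| reference to two decimals), Welch's unpaired t with Satterthwaite
degrees of freedom (identical zero-variance groups give p = 1 by
convention), and a volcano analysis flagging species with fold change ≥ 2
and p ≤ 0.05. Volcano p-values are computed on log-transformed
concentrations by default — lipid concentration noise is multiplicative —
with a raw-scale option; the fold change itself is always a ratio of raw
group means. PCA is centered and unit-variance scaled by default (the
scaling convention of common metabolomics web tools; pareto scaling is not
offered), with zero-variance species dropped before scaling.

## Fractionation statistics

Partition observations are tidy (class, water content, phase, replicate,
area). The MeOH-rich fraction is `A_MeOH / (A_MeOH + A_hexane)`;
negative-mode-only classes (PG, PI, PS), for which only the MeOH-rich
phase is analyzed, report no fraction. Percent changes are taken against
the anhydrous (0% water) reference, positive for reductions. Water-content
effects are tested within each class × phase by one-way ANOVA with Tukey
HSD; the compact letter display is produced by insert-and-absorb over the
significance graph: start with one set holding all groups, split any set
containing a significantly different pair, absorb sets contained in
larger ones, and label the surviving sets with letters.

## The synthetic generator

The generator's defaults are the study conditions. The polar-lipidome
profile puts 57.4% of the total in PC-type and 30.4% in PE-type lipids
(ether forms included within each), PI/PS/SM at 5.61/2.68/1.47%, and the
remainder over the minor classes, at a default total of 54.18 nmol/mg wet
tissue; the total-extract profile adds TG-dominant neutral classes.
Species within a class are drawn lognormally (sdlog 0.8) and rescaled so
class totals match the profile exactly. Species carbon/double-bond grids
deliberately include same-carbon double-bond ladders so the +2 overlap —
and hence the type II correction — is real in every rendered table.

Hydrolysis time courses follow first-order kinetics: each precursor
species loses `c0 (1 − e^{−kt})`, and the transferred moles are
mass-balanced into the paired degradation class pro rata over its baseline
species (the class-level ratio fully determines the statistic; routing
within the class is a generator choice). Default storage times are 0, 30,
60, 120 min with 3 replicates. Measurement noise is a mean-one
multiplicative lognormal (CV parameter, default 10%); tissue heterogeneity
is a separate per-replicate lognormal multiplier, since between-animal
spatial heterogeneity and instrument noise are different phenomena.

The renderer maps concentrations to areas via `concentration × tissue
mass × response factor × scale` (response factors default to 1.0 and are
synthetic — true per-species response factors are unknowable from peak
areas alone), distributes ions over the envelope, adds the +2 interference
from the co-eluting neighbor, spikes internal standards at their nominal
per-mg amounts, renders QCs as the pooled mean of the study truths and
blanks at a configurable carryover fraction, then applies noise, the
detection limit and the 3,000-count intensity threshold; censored values
are missing, not zero. Retention times come from a fixed synthetic
class → RT map with within-class co-elution.

What the generator does *not* emulate — chromatographic peak shapes,
retention drift, in-source fragmentation, ion suppression, nonlinear
detector response, enzyme substrate preferences beyond a single rate
constant per class pair — bounds what passing tests show: they verify the
pipeline's arithmetic and statistics against a known data-generating
process, not the instrument physics of real data.

## Verification at a glance

```{r verify}
# noise-free rendering inverts exactly through the full pipeline
truth <- simulate_ground_truth(total_class_profile(), seed = 7)
cohort <- purrr::map_dfr(1:2, function(i) {
  tibble::tibble(sample_id = sprintf("S%d", i),
                 species = truth$species$species,
                 conc_nmol_mg = truth$species$conc_nmol_mg)
})
ren <- render_feature_table(cohort, truth, noise_cv = 0, lod = 0,
                            intensity_threshold = 0, carryover = 0, seed = 7)
res <- lipid_pipeline(ren$features, ren$metadata,
                      candidate_species = truth$species$species,
                      include_nonquant = TRUE)
q <- dplyr::inner_join(res$quant[grepl("^S", res$quant$sample_id), ],
                       truth$species, by = "species", suffix = c("", "_t"))
max(abs(q$conc_nmol_mg - q$conc_nmol_mg_t) / q$conc_nmol_mg_t)
```

The shipped test suite runs the same checks at fixed problem sizes chosen
to keep the default run light while leaving the statistics meaningful: a
4-sample noise-free cohort for the inversion identity, 10 compositions
against a brute-force enumeration oracle for the envelopes, 200 seeded
repeats of the 3-replicate phase-I design for Dunnett power and type-I
error, and 100 repeats of the 3-replicate partition experiment for
recovery bias. `scripts/acceptance.R` recomputes all of these from scratch
and writes them as JSON.

## Known limitations

* Species-level only: sn-positions, double-bond positions and oxidized
  lipids beyond `;On` are not modeled, and MS/MS evidence is not used.
* Only the +2 isotopic overlap is corrected; fine isotope structure and
  resolution-dependent envelope merging are ignored.
* One-point calibration assumes equal response of analyte and standard
  within a class; no response-factor modeling across chain length.
* Single adduct per class and polarity; multiply charged species are not
  supported.
* The Dunnett adjustment relies on `multcomp`'s multivariate-t
  integration, which is stochastic at the 1e-4 level between runs.
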