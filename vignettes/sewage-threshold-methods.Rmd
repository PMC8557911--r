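---
title: "Methods: source partitioning, HB quantification, and the mass-balance threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source partitioning, HB quantification, and the mass-balance threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sewerseq)
```

`sewerseq` assesses human sewage pollution in rivers from two independent
lines of evidence: the composition of the 16S rRNA ASV community, and a
human *Bacteroides* (HB) qPCR marker already used in health-risk
benchmarks. This vignette documents the models, the tunable parameters, the
numerical choices, and the design decisions behind each stage, together
with what the synthetic-data validation does and does not demonstrate.

## Source partitioning

### Model

Every ASV is assigned to exactly one of four source categories by exact,
full-length, case-insensitive string equality against labelled reference
databases, with a fixed precedence:

1. **freshwater** — matches the freshwater reference set (or carries an
   upstream freshwater flag). Freshwater assignment is final: an ASV
   matching both a freshwater and a sewage-side reference is freshwater.
   Core freshwater taxa also circulate through sewers, so a
   freshwater match is the more parsimonious explanation for a river ASV.
2. **human_fecal** — matches a human-stool reference and passes the
   inclusion filter below. Stool origin takes precedence over sewer origin
   because it is the more specific claim about the organism's habitat.
3. **sewer** — matches a sewer-community reference and passes the filter.
4. **uncategorized** — everything else (terrestrial and other sources),
   including sewage-side matches that fail the filter.

Matching is exact because amplicon sequence variants are already
denoised, single-nucleotide-resolution units; percent-identity alignment
would re-blur distinctions the upstream inference worked to establish. No
reverse-complement search is done: amplicons are orientation-fixed by the
primer protocol. Sequences containing IUPAC ambiguity codes are rejected
rather than fuzzily matched.

### The percentile inclusion filter

A sewage-side match alone is weak evidence when the same sequence is
abundant in rivers at large. An ASV matching a sewer or stool reference is
therefore admitted only if

> 5th-percentile relative abundance across river samples
> **<** 95th-percentile relative abundance of the matched reference across
> raw sewage samples (strict inequality).

Three conventions had to be fixed and are recorded as attributes of every
`partition_result` so results are auditable:

* **Quantile definition.** Linear interpolation between closest order
  statistics (`stats::quantile` type 7, the inclusive convention).
* **Zeros count.** Samples where the ASV is undetected contribute zeros to
  the river percentile; they are observations, not missing values. For rare
  ASVs the 5th percentile is then typically 0, making the filter permissive
  for exactly the ASVs whose river abundance provides no counter-evidence —
  the filter's intent.
* **Failure is terminal.** A stool match that fails the filter falls to
  `uncategorized`; it is not retried against the sewer database.

`partition_sources(..., apply_filter = FALSE)` disables the filter; the
ground-truth validation uses this permissive mode because synthetic
references are disjoint by construction.

## HB quantification

The standard curve is ordinary least squares of Cq on log10 copies per
reaction; efficiency is `10^(-1/slope) - 1` and values outside 90–110%
warn. Concentrations convert to copies per 100 ml of original water via

```
CN/100 ml = CN/reaction × extract_to_reactions × reporting_basis_ml / volume_filtered_ml
```

The defaults (250 ml filtered, 30 reaction-equivalents per extract, 100 ml
basis) give an aggregate factor of 12, reproducing the assay's printed LOQ
pair: 15 CN/reaction ≡ 180 CN/100 ml. The per-step elution and template
volumes behind `extract_to_reactions` are assay-specific and not separately
recoverable; only their aggregate matters, and it is a configuration field,
never a hard-coded constant.

Censoring and categories: non-detects carry no numeric value (arithmetic on
them errors; nothing is zero-imputed, since downstream analysis is
categorical), detected values below 180 CN/100 ml are `unquantifiable`,
values in [180, 7,800) are `quantifiable`, and values ≥ 7,800 CN/100 ml —
the concentration associated with an excess illness risk of 0.03 — are
`risk`. Both boundaries are inclusive on their upper category. Replicate Cq
values are averaged on the Cq scale (a sample is non-detect only if all
replicates are); averaging on the concentration scale would weight the
exponential tail.

## The mass-balance threshold

### Equations

With `f` the volumetric fraction of sewage in river water,

* `f = C_river,HB / C_sewage,HB` — all river HB is attributed to the sewage
  fraction;
* `r = C_sewage,cells · f / (C_river,cells · (1 − f))` (`"ratio"` variant) —
  the expected relative abundance of sewage-derived sequences, assuming a
  sequence's library share reflects its cell share in the volume analysed.

The `"composition"` variant, `r = C_s·f / (C_s·f + C_r·(1 − f))`, is the
exact mixture proportion: bounded in [0, 1], never exceeding the ratio
form, and agreeing with it to first order in `f` (their relative difference
equals the ratio value itself). The ratio form is the default for threshold
derivation, mirroring the printed equation; the composition form is what
the synthetic generator uses to build actual compositions, where a
proportion above 1 would be meaningless.

### Monte Carlo propagation

`C_river,HB` is fixed at the 7,800 CN/100 ml risk benchmark. The other
three concentrations are log-normal — the standard model for environmental
concentration data — specified by geometric mean and geometric SD, and
drawn independently (no correlation structure is claimed by the model).
Per draw, `f` then `r` is computed; draws with `f ≥ 1` are physically
meaningless and are **rejected, not clamped** (clamping would bias `r`
upward); more than 10% rejections aborts as a misconfiguration. The
distribution of `r` is summarised by its geometric mean (equal to the
median under log-normality; configurable to median or arithmetic mean, and
the choice is recorded in the output) and geometric SD, reported as the
`central/GSD` to `central×GSD` interval.

### Analytic oracle

For `f ≪ 1`, `ln(1 − f) ≈ 0` and `ln r` is a sum of independent normals,
so `r` is exactly log-normal with

```
GM(r)  = exp(mu_scells − mu_rcells + ln C_river,HB − mu_shb)
GSD(r) = exp( sqrt(sigma_scells² + sigma_rcells² + sigma_shb²) )
```

`analytic_threshold()` returns this closed form and is the independent
oracle for the simulation: the tests require the simulated log-central
estimate within the CLT bound `3σ/√n` (plus the exact `E[f]` bias the
small-`f` approximation carries) and the simulated GSD within 1% of the
analytic GSD, for configurations whose 99th percentile of `f` stays below
0.05 — the oracle's validity domain.

### Example configuration

`example_threshold_config()` ships illustrative, literature-plausible
distributions — sewage HB at GM 7.8×10⁶ CN/100 ml (GSD 3), so `f` at the
risk benchmark centres on 10⁻³; sewage total cells at GM 1.8×10¹⁰
cells/100 ml (GSD 2); river total cells at GM 10⁸ cells/100 ml (GSD 7),
river-cell variability being the dominant error source. These are defaults
for the example workflow, not measured values; a site-specific threshold
requires substituting locally measured concentration distributions through
`monte_carlo_config()`.

```{r mc}
mc <- run_monte_carlo(example_threshold_config(seed = 1))
mc
analytic_threshold(example_threshold_config())
```

## Dual-threshold concordance

`classify_quadrant()` cross-classifies samples by HB exceedance
(quantified and ≥ 7,800 CN/100 ml; non-detects and unquantifiable results
never exceed, because exceedance requires a quantified value) and sequence
exceedance (proportion ≥ threshold, inclusive to mirror the HB side).
`concordance_table()` tabulates the four quadrants and the agreement
fraction.

## Indicator ASVs

For a grouping of samples (typically the HB contamination categories,
restricted to urban sites where land use does not confound the signal), an
ASV's association with a group is scored by two components:

* **specificity** `A` — the ASV's mean relative abundance in the group
  divided by the sum of its group-mean abundances. Group means (the
  group-size-corrected convention) rather than pooled sums are the default
  because HB category sizes are strongly unbalanced; `mode = "pooled"`
  switches.
* **sensitivity** `B` — the fraction of the group's samples in which the
  ASV is detected.

Each ASV is reported for its best group (maximal `A·B`); strong indicators
have both components ≥ 0.8. The inclusive boundary is used (the
alternative strict form differs only on exact-0.8 ties); both thresholds
are arguments. No permutation p-values are computed — the selection rule is
the two-component filter itself. One group label per sample; combined
"site-group" unions of the full indicator-value machinery are out of scope.

## Community metrics

Shannon (`−Σ p ln p`, nats; base configurable) and Simpson (`1 − Σ p²`;
inverse form available) diversity, and Bray-Curtis dissimilarity computed
on relative abundances by default so sequencing depth does not masquerade
as community difference. PERMANOVA is one-factor: pseudo-F from the
among/within partition of squared dissimilarities, p-value
`(1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` under random label permutation,
or the exact proportion over all `N!` relabelings (identity included) with
`exhaustive = TRUE`, feasible to `N = 9`. F-comparisons use a `1e-12`
slack so exact ties in degenerate data count as exceedances. The tests
verify the p-value against full enumeration at `N = 6`, the pseudo-F
against an algebraically independent hat-matrix formulation and against
`vegan::adonis2`, and type-I error calibration (rejection rate 0.05 within
three binomial SEs over 1,000 null replicates at 99 permutations, where
attainable p-values make the nominal level exact).

## The synthetic-data generator

`simulate_pollution_study()` emulates a mixed urban/rural monitoring
campaign, by default 16 sites × 5 dates, and is a pure function of its
configuration (seed included); the RNG state of the caller is never
touched. The generative model:

* **References.** Random disjoint DNA strings (370 bp by default, ≥ 50
  enforced) for freshwater, sewer, and stool databases, plus an unlabelled
  terrestrial pool exercising the `uncategorized` fallback. Sewage-side
  references carry simulated 95th-percentile sewage abundances, log-uniform
  over a recorded range (default 10⁻⁴–10⁻¹).
* **Sewage fractions.** Per-sample `f` is log-normal, GM 3×10⁻⁴ with GSD 3,
  truncated by redraw at 0.99 to avoid the `r` singularity. The defaults
  are chosen so sewage-sequence proportions span roughly 0.3%–30%, the
  regime of interest for threshold work; the spatial distribution of
  pollution across a real basin is not modelled. `sewage_fraction_spec =
  NULL` yields an unpolluted control campaign (`f = 0` exactly).
* **Compositions and reads.** Fixed log-normal community profiles for the
  background (freshwater + terrestrial) and sewage (sewer + stool) pools
  are mixed as `(1 − r_true) : r_true`, with `r_true` the composition-form
  map of the sample's `f` and its drawn cell concentrations; reads are
  multinomial at fixed depth (50,000 by default). Optional Dirichlet
  overdispersion adds compositional noise; the default is plain multinomial
  sampling, the simplest model consistent with the
  abundance-reflects-volume assumption.
* **HB coupling.** True HB is `f × C_sewage,HB` (per-sample draw) with
  multiplicative log-normal measurement noise (GSD 1.2 by default);
  censoring applies an LOQ of 180 CN/100 ml and an LOD of half the LOQ — a
  conventional placement, since only the LOQ has a printed anchor.

What passing on synthetic data shows — and does not. Ground-truth recovery
(≥ 99% of ASVs with reads correctly assigned; in practice 100%, misses
arising only from zero-count ASVs) demonstrates the partition logic, not
real-world reference quality: real freshwater and sewer databases overlap,
real communities contain sequences absent from every reference, and real
ASVs carry sequencing errors. Likewise the noise-free concordance check
(matched thresholds through the same deterministic map ⇒ zero discordant
samples) validates the quadrant logic by construction; with realistic
noise, discordance reflects genuine measurement disagreement, as in the
field data the model targets.

## Problem sizes used in validation

The shipped tests simulate 16 × 5 campaigns at depth 50,000, run the Monte
Carlo at 100,000 draws, compare the partition against a brute-force oracle
on 100 random instances (≤ 50 ASVs × 10 samples), enumerate PERMANOVA
exactly at `N = 6`, and calibrate its type-I error over 1,000 null
replicates — sizes at which every oracle is exact or its sampling error is
far below the asserted tolerances.

## Known limitations

* Exact matching cannot absorb sequencing error or length variation; it
  presumes upstream denoising did.
* The threshold model treats the three concentrations as independent
  log-normals and river total cells as stationary; a coincident influx of
  another biological contaminant would violate both.
* The `"ratio"` threshold form can exceed 1 at large `f`; interpret it only
  in the small-`f` regime it was derived for.
* Per-filter elution/template volumes are folded into one aggregate
  conversion constant.
* PERMANOVA is one-factor; no strata, no multi-factor designs.
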