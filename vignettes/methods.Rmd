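---
title: "Methods: road-dust metal risk assessment with roaddust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: road-dust metal risk assessment with roaddust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roaddust)
```

This vignette documents the models implemented in `roaddust`, the choices
made where the underlying methodology admits more than one reading, and
what the synthetic-data generator does and does not emulate.

## The assessment chain

The package assesses eight trace metals (As, Cd, Cr, Pb, Cu, Zn, Ni, V) in
road dust, sampled from three urban functional zones (industrial, traffic,
agricultural). Concentrations are mg/kg dry dust throughout; no unit
inference is performed.

### Contamination indices

The geoaccumulation index compares a measured concentration to 1.5x the
geochemical background, on a log2 scale; the factor 1.5 absorbs natural
lithologic variability. Classes are the standard seven-class scheme with
half-open bins at 0,1,...,5 (a value of exactly 2 falls in the third
class). The improved Nemerow index aggregates the per-metal indices of one
sample as the quadratic mean of their maximum and average; its class cuts
sit at 1,...,5. The ecological risk index weights each metal's
contamination factor C/B by a toxicity coefficient (Cu 5, Cr 2, Ni 5,
Zn 1, Pb 5, Cd 30, As 10, V 2) and sums. Published class schemes print the
value 150 as the boundary of both the "low" and "moderate" bands; we
resolve every such overlap as half-open intervals, so 150 is "moderate".
Display rounding is one decimal place; all internal computation is full
precision.

### Speciation accounting

Sequential extraction partitions a metal into exchangeable (F1),
carbonate-bound/specifically adsorbed (F2), Fe/Mn-oxide (F3),
organic/sulfide (F4), and residual (F5) pools, with F5 defined by
subtraction from the pseudo-total digest. Analytical over-recovery
(F1+...+F4 exceeding the pseudo-total) is possible in real data; we clamp
F5 at zero and *flag* the record rather than renormalising, preserving the
subtraction definition while keeping every percentage profile summing to
100 (shares use the reconstructed sum F1+...+F5 as denominator). How the
original assay handled over-recovery is not documented anywhere we know
of; the clamp rule is this package's convention. The "mobile" fraction is
F1+F2, the pools most easily dissolved by pH shifts.

### IVG bioaccessibility

The two-stage in vitro gastrointestinal assay digests 1 g of dust in
150 mL of gastric fluid (pepsin, pH 2.5), removes 10% of the supernatant
for analysis, then adjusts the remainder to pH 5.5 with bile/pancreatin.
The gastric-stage bioaccessible fraction is dissolved mass over total
metal mass; the intestinal-stage fraction credits the removed aliquot as
already accessible, so equal phase concentrations give equal stage
fractions. The rule combining the stages into a single BA is genuinely
ambiguous in the assay literature, so three modes are provided:
`max_phase` (default), `intestinal_final`, and `gastric_only`. We default
to the maximum of the two stages because gastric-phase dissolution
typically dominates (re-adsorption and Fe coprecipitation lower the
intestinal values) and taking the maximum is the risk-protective reading.
Fractions above 1 (measurement noise) are clamped with a warning, never
silently. Metals with no IVG measurement fall back to BA = 1 — the
total-content scenario — with a prominent message.

### Exposure and risk model

Doses follow the USEPA soil-exposure equations for three populations
(children, adult women, adult men) and three routes. Bioaccessibility
multiplies the ingestion dose only: inhaled particles and dust adhering to
skin are not conditioned on gastrointestinal solubility. Noncarcinogenic
doses average over the exposure duration (AT = ED x 365 days);
carcinogenic doses average over a 70-year lifetime (AT = 25,550 days).
HQ = ADD/RfD, HI sums HQ over routes and metals; CR = LADD x SF per route
with a configured slope factor (routes without one contribute zero, which
is logged), TCR sums over the five carcinogens As, Pb, Ni, Cr, Cd. HI > 1
flags possible noncarcinogenic effects; CR bands are < 1e-6 negligible and
> 1e-4 unacceptable.

Two deliberate choices here:

- Some published formulations divide the *ingestion* lifetime dose by the
  particle emission factor (PEF, m^3/kg), a unit-inconsistent carry-over
  from the inhalation route that suppresses cancer risks by roughly nine
  orders of magnitude relative to reported urban-dust values. The default
  is the standard USEPA form without PEF; `include_pef = TRUE` restores
  the literal variant for comparison.
- Lifetime doses are computed per population (each with its own
  IngR x ED / BW bracket), which is what per-population cancer-risk tables
  require; the combined childhood+adulthood receptor is available
  separately as `ladd_lifetime()`.

All exposure parameters, RfDs, and SFs live in a YAML registry
(`default_registry()` ships USEPA-convention values) that should be logged
with every run; absolute risk numbers are only meaningful relative to the
registry used. Tables published for any particular survey can be matched
in structure and magnitude, but digit-level reproduction is not expected
unless that survey's exact parameter appendix is transcribed into the
registry.

### Monte Carlo layer

Following common practice (Crystal Ball-style), the varied inputs are the
per-metal concentration, body weight, and inhalation rate, each log-normal;
all other parameters are fixed. Concentration distributions are fitted to
the sample table by moment matching; BW and InhR use coefficients of
variation 0.15 and 0.20 around the registry means — the source surveys
state log-normality but not the spreads, so these are fixed, documented
defaults. Inputs are drawn independently (no correlation information is
available). Each variable draws from its own seed substream derived from
the master seed, so adding or removing a variable never perturbs the
others' draws. The default is 10,000 iterations. Quantiles use the type-7
(linear interpolation) convention; sensitivity is the Spearman rank
correlation between input and output draws, with zero-variance inputs
reported as 0 and flagged. With all spreads at zero the simulation
reproduces the deterministic engine exactly — this degeneracy is the core
oracle test of the implementation.

## The synthetic-data generator

The raw per-sample data of the emulated survey are unpublished, so the
generator reproduces the survey's *summary structure*: per-zone sample
counts (23 industrial, 20 traffic, 5 agricultural) and per-metal mean, SD,
and observed range.

**Calibrated truncation.** Concentrations are log-normal. When an observed
range is supplied, naive moment matching followed by truncation biases the
moments (for the industrial-zone Zn targets the mean drops by ~10%), so
the generator instead solves for parameters such that the *truncated*
distribution has the target mean and SD, using closed-form truncated
log-normal moments (an inner monotone root in the location parameter
nested in an outer solve for the scale). Several published cells are
mutually inconsistent — the mean lies outside the printed range, or the
printed SD exceeds what any distribution on that interval can reach (the
agricultural zone, with n = 5, is affected throughout). When the
calibration cannot reach 1% relative error on both moments, the bounds are
dropped for that metal, the row is flagged `range_consistent = FALSE`, and
the unbounded moment-matched log-normal is used; the inconsistency is
reported, not resolved. A consequence worth knowing: for the flagged
heavy-tailed cells (coefficient of variation near or above 1) the *sample*
SD of even 10,000 draws has a relative standard error of 4-7%, so
empirical SD recovery beyond ~3% cannot be guaranteed there by any
faithful sampler; empirical means recover within 3% throughout.

**Speciation and BA.** Fraction shares are Dirichlet draws around
per-metal expected profiles shaped after reported road-dust patterns
(residual-dominated As/Cr/Ni, oxide/carbonate-dominated Pb/Cd/Zn,
organic-dominated Cu), with concentration parameter 50 by default.
Bioaccessible fractions are beta draws matched to reported mean ± SD
values (beta, because BA is bounded in [0,1]); gastric-stage BA carries
the draw and the intestinal stage multiplies it by a Beta(8,2) retention
factor, reproducing the observed gastric ≥ intestinal ordering. BA targets
for Cr and V are not reported and are set to a low 5 ± 3% as a synthetic
convention. Phase concentrations are obtained by inverting the assay mass
balance, so recomputing BA from the emitted table recovers the drawn
values exactly.

**What the generator does not emulate:** inter-metal correlation (each
metal is drawn independently; real dust shows strong Cu-Zn-Pb
correlation), spatial structure and hotspots, zone differences in
speciation or BA, and analytical over-recovery. Tests passing on synthetic
data therefore validate the *computational chain*, not field-data claims.

## Problem sizes used in the test-suite

Unit tests run on 3-48-sample tables; distributional checks use 1,000-2,000
samples for Dirichlet/beta mean recovery, 10,000 draws per zone for
concentration moment recovery, 10,000 Monte Carlo iterations for the
linearity check, and 100,000 draws for the quantile oracle. These sizes
keep each check's Monte Carlo error well inside its assertion band.

## Known limitations

- Dermal absorption uses a single ABS per population rather than per-metal
  values (As is often given 0.03); edit the registry's exposure section if
  per-metal dermal absorption matters for your study.
- No Sobol/variance-based sensitivity and no correlated-input copulas; the
  Spearman ranking assumes monotone input-output relations (true here,
  since every dose is monotone in every varied input).
- Cancer risk for Pb via ingestion uses a slope factor by convention; Pb
  dose-response is not linear in reality (no IEUBK-style blood-lead
  modelling is attempted).
- The Monte Carlo concentration distribution pools all zones by default;
  filter the sample table per zone for zone-specific simulations.
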