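---
title: "Modelling crop-rotation effects on cotton yield and Lygus pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crop-rotation effects on cotton yield and Lygus pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotabayes)
```

## The problem

Commercial cotton growers and their pest control advisers (PCAs) keep
detailed field records: lint yield, the crop grown in the field in each of
the previous years, the crops in the eight adjacent fields, and roughly
weekly sweep-net counts of *Lygus hesperus*, a key early-season cotton
pest. Because such records span many fields, years and rotation histories,
they can answer questions that small-plot experiments cannot — in
particular, whether the crop grown in a field the year before is
associated with the following cotton crop's yield, and whether any such
association is mediated by *L. hesperus* pressure building up in the
surrounding landscape.

`rotabayes` implements that analysis as a reusable, tested pipeline:

* **Model 1** — lint yield (kg/ha) on the identity of the previous year's
  crop (cotton as the reference category), cotton species (Pima vs
  upland), and the 15 surrounding-crop counts;
* **Model 2** — mean June *L. hesperus* density (insects/sweep) on the
  same covariates;
* **Model 3** — a second-stage linear regression of the 14 posterior-mean
  yield contrasts on the 14 posterior-mean *Lygus* contrasts;
* **Model 4/5** — yield (or June *Lygus*) on the number of consecutive
  prior cotton plantings (1–4), species, and the adjacent-cotton count.

The commercial database behind the original analysis is proprietary, so
the package ships a synthetic-data generator with the same statistical
structure and known ground truth; every claim the test suite makes about
the pipeline is made against that generator.

## The model

All field-level models share one form. For record $i$ in field $f(i)$ and
year $t(i)$,

$$ y_i = x_i^\top \beta + u_{f(i)} + v_{t(i)} + \varepsilon_i, \qquad
   \varepsilon_i \sim \mathrm N(0, \sigma^2), $$

with crossed random effects $u_f \sim \mathrm N(0, \sigma_f^2)$ and
$v_t \sim \mathrm N(0, \sigma_y^2)$. Field effects absorb persistent
differences in yield potential (soil, management); year effects absorb
season-wide weather. Priors follow the standard protocol for this
analysis: every fixed effect gets $\mathrm N(0, 100^2)$, and all three
variances get $\mathrm{IG}(0.001, 0.001)$. The random-effect means are
fixed at zero — letting them float would be unidentifiable against the
fixed effects.

Because the likelihood and all priors are Gaussian/inverse-gamma, the
model is fully conjugate, and the package samples the posterior by Gibbs
sampling: $\beta$ jointly from its Gaussian full conditional
($\Sigma = (X^\top X/\sigma^2 + I/100^2)^{-1}$,
$m = \Sigma X^\top(y - u - v)/\sigma^2$), each $u_f$ and $v_t$ from its
univariate Gaussian conditional, and each variance from its inverse-gamma
conditional (shape $a + n/2$, scale $b + \mathrm{SS}/2$). The original
analysis used a Hamiltonian (NUTS) sampler; the posterior is identical,
and the conjugate sampler needs no tuning, so we regard sampler choice as
an implementation detail. The exported `beta_full_conditional()` and
`variance_full_conditional()` are the analytic building blocks, and the
test suite checks the compiled sampling loop against them directly (with
random effects disabled and $\sigma^2$ pinned, the sampler's draws must
match the closed-form Gaussian posterior).

The MCMC protocol defaults to 3 chains × 10,000 iterations, the first
5,000 of each discarded, no thinning; inference pools the remaining
15,000 draws. Chains are initialised at $\beta = 0$, $u = v = 0$, with
variances jittered around the response variance using per-chain substream
seeds derived from the master seed, so every fit is bit-reproducible.
Convergence is monitored with the classic (non-split) Gelman–Rubin
$\hat R$; the pipeline warns when any *reported* effect parameter — the
crop contrasts, the species contrast, the consecutive-cotton slope —
reaches 1.1. The intercept and the adjacency nuisance coefficients are
monitored but excluded from that gate: the 15 surrounding-crop counts sum
to 8 by construction, so the intercept/adjacency block is only identified
through the prior, and its mixing says nothing about the contrasts the
analysis reports. Variance draws are floored at $10^{-12}$ as a numerical
guard; floor hits are counted and reported (they do not occur at realistic
problem sizes).

## Responses and design choices

**Mean June density.** PCAs sample on irregular dates, so successive sweep
counts are converted to a mean by integrating the piecewise-linear
interpolant of density versus time (trapezoid rule) and dividing by the
days covered. The June window is calendar June in a non-leap year
(days 152–181). Samples outside the window contribute only through
interpolated values at a window boundary they straddle; this uses all
local information without letting July data leak into a "June" mean.
Records whose samples do not cover any part of the window get a missing
response and drop out of Models 2/5.

**Consecutive cotton.** The Model-4/5 predictor is the length of the
unbroken run of cotton years immediately before the focal season, capped
at 4, computed only for records whose rotation record is complete for the
previous 4 years. Records whose previous crop was not cotton (run 0) are
excluded by default, matching the predictor's stated 1–4 range; a
`include_zero = TRUE` switch admits them, since the source description
leaves this ambiguous.

**Complete-case filtering.** Yield is recorded for only part of the
records and adjacency for another part; all four field-level models use
complete cases, the only defensible default when no imputation procedure
is given. Every dropped row is counted under exactly one reason
(`missing_response`, `missing_prior_crop`, `incomplete_history`,
`zero_consecutive_cotton`, `missing_adjacency`), and the tests assert
rows kept + rows dropped = rows in.

**Reference coding.** Prior crop is coded with cotton as the reference,
so each crop coefficient *is* the reported contrast "crop X vs cotton";
the implied cotton-vs-cotton contrast is exactly zero. A crop with no
kept records has its column dropped and is reported as unavailable rather
than silently estimated from nothing. Rows are canonically sorted by
(field, year) before design construction, which makes fits bitwise
invariant to input row order.

**HPDIs and sign probabilities.** Effects are summarised by the posterior
mean, the 95% highest-posterior-density interval (narrowest contiguous
window containing 95% of the pooled draws; leftmost window on ties), and
the fraction of draws strictly below zero. Draws are pooled across chains
before summarising. `hpdi()` is tested against an exhaustive
minimal-width window search on thousands of randomised inputs.

**Percent change per year.** The consecutive-cotton slope (kg/ha per
year) is converted to percent by dividing by a baseline yield. No
denominator is stated for the original "−2.4 %/yr" figure; the default
here is the mean observed yield among the records entering Model 4 — the
only denominator computable from the model's own data — and it can be
overridden.

**Model 3.** The second stage regresses the 14 posterior-mean yield
contrasts on the 14 posterior-mean *Lygus* contrasts, with the same
Normal/inverse-gamma priors, implemented as the degenerate mixed model
with no random-effect groups (so the same Gibbs code is reused, and the
regression inherits the sampler's tests). Regressing point estimates
ignores first-stage uncertainty — that is a deliberate fidelity choice,
not an endorsement; `effect_regression_draws()` provides a sensitivity
mode that pairs random first-stage draws instead. Crops are unweighted
(no weighting by record count is described for the original analysis).

## The synthetic-data generator

`simulate_records()` draws record sets from the generative counterpart of
the fitted models, with the source database's marginal structure: 1498
field-year records from 566 fields over 1997–2008, yield observed for
about 1240, adjacency for about 1026, and a complete 4-year rotation
record for about 782. Rotation histories come from a repeat-or-redraw
chain (repeat last year's crop with probability 0.5, otherwise redraw
from a landscape frequency vector in which cotton has weight 0.55 — a
cotton-dominated landscape, consistent with most eligible records having
cotton as the previous crop). Yield is built exactly as Model 1/4 assume:
base Pima yield 1500 kg/ha, +160 for upland, a per-crop prior-year
effect, −40 kg/ha per consecutive prior cotton year, crossed field/year
effects (SD 150 and 100 kg/ha) and residual noise (SD 200 kg/ha, ≈13%
CV). Latent June *Lygus* density gets its own crop effects, a 0.037
insects/sweep-per-year consecutive-cotton term, and field/year
perturbations; weekly sweep samples are drawn around a piecewise-linear
seasonal tent (truncated-at-zero Normal noise by default, a
Poisson-count option for robustness work). Default crop effect vectors
follow the signs and magnitudes reported for this system — garlic,
tomatoes and melons positive on yield; alfalfa, safflower and sugarbeets
negative on yield and positive on *Lygus*; garlic the known exception,
positive on both. All of this is configuration, not constants, and
identical configurations generate byte-identical records.

What the generator does *not* emulate: real spatial layout (adjacency
counts are drawn, not derived from a map), weather, within-field
trends, over-dispersed scouting error beyond the Poisson option, and any
dependence of missingness on the response (masking is completely at
random). Passing recovery tests therefore demonstrate that the pipeline
correctly inverts its own assumed data-generating process — they cannot
certify behaviour under real-world violations of those assumptions.

A deliberate subtlety in recovery scoring: in the generative model the
consecutive-cotton penalty acts on every record whose previous crop was
cotton, so the estimand Model 1 identifies for "crop X vs cotton" is
`crop_effect − consec_effect × mean(consecutive cotton years among the
cotton-reference rows)`, not the raw `crop_effect`. `run_recovery()`
computes that implied truth from each realised simulation.

## Problem sizes used by the tests

The packaged fixture is a seeded 220-record simulation (80 fields,
2001–2006) chosen so that every non-cotton crop survives Model-1
filtering. Unit tests use fits of a few hundred iterations — enough for
the structural and arithmetic properties they check. The calibration
suite uses 50 replicates of 1,100 records (200 fields × 6 years) fit
with 3 chains × 2,000 iterations (1,000 burn-in), and the sampler-exactness
check uses 15,000 draws; the acceptance script runs the full
3 × 10,000/5,000 protocol on a full-scale (1,498-record) simulation.

## Known limitations

* **The protocol prior is informative at this response scale.** A
  $\mathrm N(0, 100^2)$ prior is "noninformative" for effects of tens of
  kg/ha but not for coefficients of several hundred. In the default
  generative regime the cotton-reference offset (≈ +112 kg/ha, see above)
  pushes the true values of large crop coefficients far into the prior's
  tail (melons: ≈ 550 kg/ha ≈ 5.5 prior SDs), and with only 10–30
  records for the rare crops the posterior visibly shrinks them toward
  zero. Fixed truths that far outside the prior cannot be covered at the
  nominal 95% rate by any correctly computed credible interval, and the
  calibration suite reports exactly that: pooled HPDI coverage ≈ 0.86
  under the default regime, driven almost entirely by the largest crop
  effects, while the consecutive-cotton slope is unbiased and covered.
  When the generative truths are compatible with the prior (the
  zero-effect suite), coverage is nominal — the interval machinery
  itself is calibrated. Users analysing data on the kg/ha scale should
  treat the protocol's fixed prior SD as a modelling decision to revisit,
  not a neutral default.
* **Two-stage uncertainty.** Model 3's point-estimate regression
  understates uncertainty in the crop effects; use the draw-paired
  sensitivity mode to gauge the difference.
* **Observational data.** Nothing in the pipeline turns association into
  causation; confounders beyond field, year, species and the measured
  landscape remain possible in any real application.
* **No imputation.** Complete-case filtering is transparent but can bias
  estimates if missingness is informative in real records.

## A worked example

```{r example, eval = FALSE}
library(rotabayes)

sim <- simulate_records(sim_config(n_fields = 80, years = 2001:2006,
                                   n_records = 220, master_seed = 3))
m1 <- run_model(1, sim$records, mcmc = mcmc_config(seed = 1))
m2 <- run_model(2, sim$records, mcmc = mcmc_config(seed = 2))
m3 <- run_model(3, fits = list(m1 = m1, m2 = m2),
                mcmc = mcmc_config(seed = 3))
m4 <- run_model(4, sim$records, mcmc = mcmc_config(seed = 4))

m1$contrasts                  # crop-vs-cotton yield contrasts with 95% HPDIs
m3$slope                      # second-stage slope summary
m4$percent_change$summary     # yield loss in %/yr of consecutive cotton
plot_contrasts(m1$contrasts)
```
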