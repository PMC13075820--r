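---
title: "Models and methods: haplodiploid resistance heritability and its costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: haplodiploid resistance heritability and its costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostresist)
```

## The scientific setting

A haplodiploid pest (males develop from unfertilized haploid eggs) is
attacked by a parasitoid wasp used as a biocontrol agent. Some host nymphs
survive attack. Two questions drive the analysis this package implements:

1. **Is survival after attack heritable?** Families of known parentage are
   split into parasitoid-exposed and control replicates; mortality at day 10
   is scored per clutch. Variance among sires and dams is converted into a
   narrow-sense heritability adjusted for haplodiploid transmission.
2. **What does surviving cost?** Adults that survived attack as nymphs are
   paired and their egg laying (4 daily leaf disks) and egg hatching
   (checked daily over a window after laying) are compared with unexposed
   controls.

## The variance-component model

For one treatment arm, the response is the per-replicate proportion of
nymphs dead at day 10, modelled as

$$y = \mu + u_{dam} + u_{sire} + u_{block} + u_{plant} + e,$$

with each $u$ an independent Gaussian random intercept and all variances
constrained non-negative. Fitting is restricted maximum likelihood (REML)
so variance estimates account for the estimated mean. This is a Gaussian
model for a proportion: simple, the standard choice in sib-analysis
practice, and exactly the model the simulator's identity-link mode
generates from, so the estimator can be tested under its own assumptions.

### Haplodiploid conversion

Haploid sires transmit their entire genome to daughters, so under an
additive–dominance model without epistasis, with dosage compensation in
males and near Hardy–Weinberg structure:

$$\mathrm{Var}_{sire} = V_A/2, \qquad
  \mathrm{Var}_{dam} = V_A/4 + V_D/2 + V_{Ec}.$$

`h2_pipeline()` inverts these: $V_A = 2\,\mathrm{Var}_{sire}$;
$V_{Ec}$ is taken as the block + plant components (the design's shared
rearing environment); $V_D = 2(\mathrm{Var}_{dam} - V_A/4 - V_{Ec})$,
truncated at zero when sampling noise drives it negative (flagged
`dominance_truncated` — method-of-moments dominance estimates are
routinely negative in small designs); and

$$h^2 = V_A / V_P, \qquad V_P = V_A + V_D + V_e.$$

$V_P$ here follows the conversion formulas literally and excludes the
block/plant variance. That choice is debatable — those components are part
of the observed variance — so `v_p_mode = "broad"` adds them for
sensitivity analysis. Both modes are reported with full provenance of each
formula step.

### Identifiability: what a full-sib design cannot tell you

Two structural confoundings matter and the package makes both visible
rather than hiding them:

* **Dam vs sire.** In a purely full-sib design every family has one dam and
  one sire, so the two terms group the rows identically. Their variance sum
  is identifiable; the split is not. `fit_reml()` detects identical
  partitions and flags `aliased_terms`; the EM estimator then returns an
  even split along the flat ridge (a deterministic consequence of its
  symmetric updates). Any full-sib heritability should therefore be read as
  an upper-bound-style diagnostic, not an estimate — the half-sib design
  (`n_dams_per_sire > 1`) is what identifies the sire variance.
* **Family vs residual.** With a single replicate clutch per family and arm,
  the dam (= family) term and the residual are both row-level and equally
  confounded. The configuration therefore has `n_reps_per_family`; the
  paper-anchored default `paper_survival_config()` uses two replicate
  clutches per family and arm so the family variance is identifiable.

## EM-REML: the numerical machinery

`fit_reml()` maximises the restricted likelihood with the classical EM
algorithm on Henderson's mixed-model equations: each iteration solves the
penalized least-squares system for the BLUPs, then updates each variance
from the BLUP sum of squares plus its trace correction. This update is
monotone — the restricted log-likelihood never decreases — and every fit
stores its `loglik_trace` so the property is asserted in the tests, not
assumed. Convergence is declared when the relative parameter change drops
below `tol` (default 1e-8), with a cap of 10,000 iterations.

Plain EM is slow near boundaries and on weakly identified components, so
three guarded refinements are layered on top. Each preserves monotonicity
because every candidate step is accepted only if the restricted
log-likelihood does not decrease:

* **Squared extrapolation (SQUAREM-style).** After two EM steps the
  trajectory is extrapolated; the jump is kept only if the likelihood at
  the landing point (after one stabilising EM step) is no worse.
* **Boundary drops with verification.** A small, still-shrinking component
  is trially removed; the reduced model runs a few catch-up EM steps and
  the drop is committed only if it reaches the current likelihood. At
  convergence every dropped component is re-tested by trial re-entry at a
  small value: if one EM step grows it (positive score) it comes back.
  Committed drops are flagged `boundary:<term>`.
* **Quasi-Newton polish.** If EM has not terminated after several hundred
  iterations (the sub-linear crawl of a weakly identified component), the
  same restricted likelihood is refined directly by L-BFGS-B on the
  log-variances, and EM then verifies the result. Fits that terminate
  because the likelihood has fully stalled (change < 1e-10 per cycle with
  parameters stable to 1e-5 relative) while the strict parameter criterion
  is unmet are flagged `converged_ll_stall`; on a flat ridge further
  iteration cannot change the supported answer.

Degenerate inputs: a constant response returns all-zero variances with a
`degenerate` flag; a random term with fewer than two levels, or a
rank-deficient fixed design, is an explicit error.

`restricted_loglik()` evaluates the same objective by a dense Cholesky
factorisation of the full covariance — an independent code path from the
mixed-model-equation identities the EM uses — and the test suite maximises
it directly (grid multi-start plus Nelder-Mead) as an oracle that the EM
estimates must match to 1e-4 on every packaged fixture.

## The treatment-effect model

`fit_binomial_mixed()` tests exposure on the (dead, surviving) two-vector
response with a logit-link binomial mixed model fitted by penalized
quasi-likelihood: iterated weighted EM-REML fits of the working response
with a free multiplicative dispersion. The treatment test is a Wald
chi-square on the log-odds effect — asymptotically equivalent to a
likelihood-ratio test, and used because PQL's working-model restricted
likelihood is not comparable across fixed-effect structures. The object
carries the caveat explicitly: PQL approximates, and does not replicate, a
Laplace-fit GLMM. Under the null (identical arms, realistic family
variance) its size is within [0.03, 0.07] at the 0.05 level over 1000
simulated datasets — that calibration runs in the acceptance tests.
Working means are floored at 1e-4 so separation cannot zero out the
working weights; a fully separated arm short-circuits to a capped estimate
(±15 log-odds, flags `separation`, `effect_capped`) with a 2×2 chi-square
on pooled counts.

## Life-history models

* **Fecundity.** Egg counts per disk are modelled by negative-binomial
  regression with a log link (`MASS::glm.nb`'s alternating
  coefficient/dispersion maximum likelihood). The pair-within-plant
  cluster structure is handled either by a fitted random intercept
  (`mode = "pql"`, via `MASS::glmmPQL`) or by cluster-robust standard
  errors (`mode = "robust"`); the mode is recorded in the result.
  Likelihood-ratio tests always use the marginal maximum-likelihood fit,
  whose log-likelihood is a true likelihood.
* **Hatch success.** Extra-binomial variation is absorbed by a
  beta-binomial likelihood rather than an observation-level Gaussian random
  intercept. The two devices play the same role — each row's probability
  wobbles around the mean — but the beta-binomial integrates in closed
  form, which makes the model testable exactly: at overdispersion
  $\rho = 0$ its likelihood *is* the binomial likelihood (asserted in the
  tests), and the fit falls back to the binomial GLM when the data carry no
  overdispersion. The optimizer is bounded L-BFGS-B over coefficients and
  log-precision; the precision cap (θ ≤ e¹²) marks the binomial limit,
  beyond which the beta-function evaluation loses numerical meaning.
* **Intervals.** `binom_ci()` implements Clopper-Pearson (default;
  conservative, exact beta-quantile closed form, bounds exactly 0/1 at the
  boundaries) and Wilson intervals. The cost summary reports raw means —
  whether published group means are raw or model-adjusted is often
  ambiguous, so `summarize_costs()` is explicitly raw and the model fits
  report model-scale effects.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the anchoring study's conditions: 35
full-sib families, a 1:5 wasp:nymph exposure for 48 h implied by the
survival baselines (97% control, 30% exposed at day 10), about 25 nymphs
counted per clutch (Poisson), replicates assigned round-robin to plants
within blocks; and for the second experiment 15 plants per arm, 2 pairs per
plant, 4 daily disks, mean total eggs 37.27 (control) vs 21.47 (exposed),
hatch probabilities 0.283 vs 0.16, and hatching concentrated late in a
day-4-to-8 observation window. Where the study prints no value the
defaults are one-time realism choices: negative-binomial size 2 and a
log-normal pair effect of SD 0.6 (together reproducing the spread implied
by the published confidence intervals), hatch overdispersion ρ = 0.05, a
laying pattern peaking on days 2–3, and a 40/60 block/plant split of
common-environment variance (`ec_share`, configurable, with a dam share
available because family-common environment can also be modelled as
sticking to the family itself).

Latent-scale choice: family survival is generated on the logit scale by
default (effects cannot push probabilities outside [0, 1] — the
liability-style view), while the identity link generates from exactly the
Gaussian model the estimator fits, with probabilities clamped to [0, 1].
Recovery tests use the identity link deliberately: they test the estimator
under its own model, so "truth" is well defined. `paper_survival_config()`
is identity-scale with components chosen so the *estimated* decomposition
lands at the published one (dam 45%, sire 13%, block 9%, plant 6%,
residual 24% of total variance, and h² ≈ 0.27 when the conversion is
re-run on those shares). One subtlety is worth spelling out: the
conversion subtracts $V_{Ec}$ (block + plant) from the dam component, which
is only unbiased if the family-common environment shows up in the *dam*
term. When block and plant terms already capture it — as in this
simulator's default, where families sit on shared plants — the subtraction
removes variance that was never in the dam component, biasing $V_D$ down
by $2V_{Ec}$ and h² up correspondingly. The anchored config absorbs that
bias into its $V_D$ so the published numbers are reproduced; analysts
applying the conversion to their own designs should decide which situation
they are in (the `ec_share` dam option exists to simulate the other one).

The measured trait is a proportion from ~25 nymphs, so binomial counting
noise is part of its phenotypic variance. `config_for_h2()` therefore
defines its estimand on the measured scale: the binomial noise term
$E[p(1-p)]\,E[1/n]$ is computed and budgeted into $V_P$, and the latent
residual is set so that $V_A / V_P$ equals the requested heritability.
Recovery simulations (500 half-sib datasets across true h² of 0.1, 0.3 and
0.5; 50 sires × 3 dams × 25 nymphs, two replicate clutches) show mean
estimates within ±0.05 of truth — sizes chosen to give Monte-Carlo
standard errors near 0.01 in a few minutes of compute.

Not emulated: wasp behaviour and host choice, within-nymph immune
dynamics, melanisation scoring, maternal effects beyond the dam variance,
selection or inbreeding in the source colony, and any relatedness between
families (each family is founded by unrelated parents). Passing tests
therefore certify the estimators under the stated stochastic model, not
the biology of any particular colony.

## Gating and reporting

`run_pipeline()` attempts the heritability conversion per arm but gates
it: an arm whose response variance is below a floor (default 1e-6, the
almost-no-mortality control case) or whose fit is degenerate reports
"not estimable" rather than a number. Reports order variance shares in
descending order; shares are percentages of the total and sum to 100
(published share tables that total slightly off 100 are rounding
artifacts). The JSON results record is validated against a shipped schema,
and the run manifest stores the config snapshot, seed and md5 digests of
every output so a rerun with identical inputs is verifiably identical.

## Known limitations

* The additive–dominance assumptions behind the conversion cannot be
  checked from a single-generation sib design (a joint scaling test across
  generations would be required); epistasis and maternal effects are
  absorbed into whichever component they resemble.
* PQL is biased for binomial mixed models with small cluster sizes; the
  package reports it as an approximation and calibrates its test size by
  simulation rather than claiming equivalence to integrated-likelihood
  fits.
* A full-sib design yields no defensible sire variance (see
  identifiability above) — the package flags this rather than refusing,
  because flagged estimates from such designs are still useful as
  diagnostics.
* The Gaussian proportion model ignores the mean-variance coupling of
  binomial data; with ~25 nymphs per clutch the approximation is mild, but
  clutches of very few nymphs would warrant a threshold-model treatment
  that is out of scope here.
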