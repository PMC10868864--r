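---
title: "Methods: twin-based variance decomposition for early alcohol-use traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based variance decomposition for early alcohol-use traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The problem and the design

Children around age 9–10 rarely drink, but a sizeable minority have already
tried a sip of alcohol, and among those who have not, a minority report
curiosity about or willingness to try it. Both behaviours — **alcohol sips**
(initiation) and **alcohol intent** (susceptibility among never-users) — are
binary phenotypes whose familial aggregation can be decomposed with the
classical twin design: monozygotic (MZ) pairs share all their segregating
genes, dizygotic (DZ) same-sex pairs share half on average, and both kinds of
pair share a family environment. Comparing MZ with DZ within-pair similarity
therefore separates three variance sources:

* **A** — additive genetic effects (proportion $h^2$),
* **C** — common (shared) environment ($c^2$),
* **E** — unique environment, including measurement error ($e^2$),

with $h^2 + c^2 + e^2 = 1$. The package implements the full pipeline around
this decomposition: phenotype derivation from gated questionnaire items,
zygosity-based exclusions, clustered descriptive statistics, zygosity-specific
correlations, moment and maximum-likelihood variance-component estimation, and
a synthetic-cohort generator plus power simulation that make every stage
testable without access to any restricted cohort data.

## Phenotype derivation

The questionnaire is gated. Children are first asked whether they have heard
of alcohol; only those answering *yes* are asked whether they have ever tried
a sip. `derive_sips()` codes a *yes* sip as 1, a *no* as 0, and treats
children who never heard of alcohol as never-users (they were never exposed to
the sip question, not refusing it). Never-sippers are asked three
susceptibility items (curiosity, intention to try soon, accepting a drink from
a best friend), each on a four-level scale. `derive_intent()` applies the
floor rule: a child is *not susceptible* (0) only when all three items sit at
their floor level ("Not at all curious" / "Definitely not" twice); any answer
above a floor codes susceptible (1). Two conventions deserve note:

* a single non-floor answer is sufficient for intent = 1 even when the other
  items are blank — one such answer already falsifies the all-floor condition;
* children who answered *no* to the hearing gate are treated as never-users
  eligible for intent classification. The alternative (treating them as
  ineligible) is a one-line change in `derive_intent()`'s input subset; the
  package keeps the inclusive convention because the susceptibility items are
  about future behaviour, not about alcohol knowledge.

Intent is *not applicable* for ever-sippers; it is coded `NA` and all intent
denominators are never-user subsets. This is why intent prevalence is always
reported "among never-users".

## Exclusions

`apply_exclusions()` removes families in a fixed order — missing zygosity for
any member, then within-family discordant zygosity labels, then families
without exactly two member rows — so every family is counted under exactly one
rule. "Inconsistent zygosity" is interpreted as a within-family label
conflict (the plausible alternative, conflict between inference methods, is
not representable in a single-label schema). Triplets and larger sets fall
under the two-member rule: the analysis is defined for pairs.

## Similarity statistics

For each zygosity group, `twin_correlations()` reports the Pearson correlation
of member-1 versus member-2 values (for 0/1 traits this is the phi
coefficient), the one-way ANOVA intraclass correlation
$\mathrm{ICC}(1) = (MS_B - MS_W)/(MS_B + MS_W)$, and, for binary traits, the
tetrachoric correlation — the correlation of the latent bivariate normal that
would produce the observed 2×2 concordance table, with thresholds fixed at the
margin quantiles and the correlation maximized by 1-D search to tolerance
1e-8. The default ordering is single-entry in `member_index` order; a
double-entry option (each pair entered in both orders) gives order-invariant
estimates and agrees with ICC(1) up to $O(1/n)$. Phi is attenuated relative
to the tetrachoric correlation whenever prevalence is away from 50%, which is
why an observed-scale correlation of 0.44 can coexist with a much larger
latent-scale correlation.

## Variance-component estimation

**Moment (Falconer) estimator.** `falconer()` computes
$h^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = 2 r_{DZ} - r_{MZ}$, truncates negative
components to zero, and sets $e^2 = 1 - h^2 - c^2$. It is the transparent
arithmetic behind statements like "MZ correlation 0.19 versus DZ 0.05 implies
28% heritability", and it seeds the likelihood optimizer.

**Maximum likelihood, continuous traits.** Each pair contributes a bivariate
Gaussian likelihood with common mean (optionally a covariate regression
$X\beta$), total variance $\sigma^2_a + \sigma^2_c + \sigma^2_e$, and
within-pair covariance $\sigma^2_a + \sigma^2_c$ (MZ) or
$\sigma^2_a/2 + \sigma^2_c$ (DZ). This is the mixed model
$y_{ij} = X_{ij}\beta + a_{ij} + c_i + \epsilon_{ij}$ with the standard
zygosity-specific correlation of the additive effects.

**Maximum likelihood, binary traits.** The default scale is the liability
(probit) scale: a pair's cell probabilities are bivariate-normal orthant
probabilities with liability correlation $h^2 + c^2$ (MZ) or $h^2/2 + c^2$
(DZ) and threshold $\tau - x'\beta$, and the unit-variance constraint makes
$h^2 + c^2 + e^2 = 1$ exact by construction. An observed-scale Gaussian fit
on the 0/1 values is available (`scale = "observed"`) as a sensitivity
analysis; the two scales answer different questions and neither is privileged
by the data, so results always carry their `scale` label. The orthant kernel
(`orthant_probability()`) reduces the bivariate integral to a 1-D integral
over the correlation and evaluates it adaptively to better than 1e-10
absolute accuracy — accurate enough that quadrature error is invisible next
to statistical error.

**Numerical choices.** Components are optimized through unconstrained square
/ squared-ratio transforms so the nonnegativity constraints are built into
the parameterization and zero is attainable; three deterministic starts are
used (the moment estimate plus two fixed interior points), Nelder-Mead
followed by a BFGS polish at relative tolerance 1e-12; standard errors come
from the delta method on the observed information, and failures to invert the
information are reported as missing SEs rather than numbers of unknown
quality. Wald intervals are deliberately untruncated
($\hat\theta \pm 1.96\,\mathrm{SE}$, so a lower bound may be negative even
though point estimates are constrained nonnegative) — this mirrors how such
tables are conventionally printed and keeps the interval a faithful image of
the quadratic approximation. Component p-values are two-sided Wald; at the
zero boundary they are conservative, which is documented rather than
corrected because the boundary-aware mixture reference is only implemented
for the likelihood-ratio power machinery.

**Model comparison.** `compare_and_reduce()` reports the AE model when the
full ACE fit puts $c^2$ on the zero boundary (and CE symmetrically for
$h^2$); otherwise the BIC-minimizing candidate wins, with
$\mathrm{BIC} = -2\log L + k\ln(n_{\text{pairs}})$ and the number of twin
pairs (independent units) as the BIC sample size. BIC values are therefore
comparable within this package but not with software that uses the number of
individuals. Dominance (ADE) decompositions are out of scope: with twins
reared together, A, D and C are not jointly identifiable. For stratified
tables, `stratified_ace(..., model = "ACE")` reports the full
three-component decomposition per stratum, since BIC reduction at small
$h^2$ would otherwise fold a real but weak genetic component into $c^2$.

## Clustered descriptives

Twins come in pairs, so individual-level proportions are not independent.
`prevalence()` uses a Taylor-linearized variance with the family as the
sampling cluster; `rao_scott_test()` applies the first-order Rao-Scott
correction to the Pearson chi-square, estimating the mean generalized design
effect by the trace formula (cell design effects minus margin design
effects), with design effects taken as ratios of clustered to
unit-as-cluster linearized variances so that the correction is exactly 1 when
every family has one member. This version, rather than a plain mean of cell
design effects, is the one that holds its nominal size: under simulated
clustered nulls (within-pair liability correlation 0.5) its type-I error sits
near 0.05, where the plain mean-cell version is noticeably conservative. The
second-order (Satterthwaite) correction is not implemented.

`cronbach_alpha()` is the standard internal-consistency coefficient used for
multi-item scales such as the family-difficulty and neighborhood-safety
instruments.

## The synthetic cohort generator

`simulate_cohort()` generates the data structure the analysis assumes — and
is itself first-class, tested code. Per pair: a sex-by-race stratum, a
zygosity (DZ with probability `dz_fraction`), one shared age draw, and per
trait a latent liability $\sqrt{a^2}A_j + \sqrt{c^2}C + \sqrt{e^2}E_j$ with
$(A_1, A_2)$ correlated 1 (MZ) or 0.5 (DZ). Binary traits are thresholded at
the normal quantile of the target prevalence. Traits named `sips` and
`intent` are emitted as raw gated questionnaire items (including a 5%
never-heard fraction) so the phenotype module is exercised end to end; the
direct 0/1 columns are withheld to force derivation through the same code
path real data would take.

The defaults are the study conditions the pipeline was designed around, fixed
once: 886 pairs, 60.4% DZ, age 121.2 (SD 6.7) months, sex split 51.1/48.9,
race/ethnicity 65.4/13.9/10.8/9.9, intent prevalence 23.5% with components
(0.28, 0, 0.72), sips prevalence 25.4% with components (0.04, 0.62, 0.34).
The sips components are published as 0.04/0.62/0.35, which sums to 1.01 by
rounding; the generator uses 0.34 for unique environment so the simplex
invariant holds exactly. Stratum-specific components default to the marginal
values — subgroup-specific truths are supported but not asserted as
calibrated claims, because subgroup margins alone do not identify them.

Record defects — blanked zygosity, discordant labels, dropped second members
— are injected after generation at configured rates, with the pristine table
retained in an attribute so recovery tests can compare against truth.
`exclusion_fixture()` is a deterministic 1,069-pair instance carrying exactly
169 missing-zygosity pairs, 12 inconsistent pairs and 2 singletons, with the
886 clean pairs fixed at 535 DZ / 351 MZ.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real cohorts: item-level nonresponse beyond the simple
gate, informative missingness, assortative mating, opposite-sex pairs,
survey sampling weights, covariate effects on the traits (covariate defaults
are none), longitudinal waves, and any genotype-level structure. Zygosity is
a label here; its measurement error is represented only through the
inconsistent-label defect.

**Reproducibility.** Every stochastic entry point takes a seed;
`simulate_cohort()` draws all quantities in a fixed vectorized order under
that seed, so identical configurations are bit-identical, and global RNG
state is restored afterwards. Derived seeds stay below $2^{31}$.

## Power analysis

`estimate_power()` runs the explicit protocol: simulate replicate cohorts at
an exact zygosity split, fit alternative and null models, and reject when the
likelihood-ratio statistic exceeds the $\chi^2_1$ critical value. Testing a
variance component on its boundary makes $\chi^2_1$ conservative (the
asymptotic null is a 50:50 mixture of $\chi^2_0$ and $\chi^2_1$); the mixture
reference is available via `reference = "mixture"`. At the design of
interest — 800 pairs split 400/400, a continuous trait with $a^2 = 0.3$,
AE-versus-E at $\alpha = 0.05$ — simulated power is effectively 1, so the
design claim "power above 0.8 when heritable variation exceeds 0.3" holds
with a wide margin even under the conservative reference. Binary traits at
25% prevalence yield less power at matched truth, as thresholding discards
liability information. Defaults (500 replicates) put the Monte-Carlo SE of a
power near 0.8 at about 0.018.

## Problem sizes used by the test suite

Simulation-heavy checks were sized to keep the full suite in the low minutes
while leaving Monte-Carlo error well inside the asserted tolerances:
correlation-convergence and prevalence checks at 50,000 pairs; ML recovery at
5,000 (continuous) and 10,000 (binary) pairs with 17 replicate cohorts per
truth setting; Rao-Scott calibration at 5,000 replicates of 250 pairs;
likelihood-nesting on 50 cohorts of 400 pairs; power at 500 replicates. These
sizes are choices, not limits of the method.

## Known limitations

* Same-sex pairs only; no sex-limitation, gene-environment interaction,
  bivariate or longitudinal models.
* Binary covariate fits loop over pairs and are slow for large cohorts;
  covariate-free fits use concordance-table sufficient statistics and are
  fast.
* Wald p-values at the zero boundary are conservative; likelihood-ratio
  p-values for components are not exposed outside the power machinery.
* The tetrachoric SE comes from the profile information with thresholds held
  fixed, slightly understating uncertainty in small tables.
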