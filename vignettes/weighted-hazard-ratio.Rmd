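---
title: "Methods: estimating and testing the weighted all-cause hazard ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and testing the weighted all-cause hazard ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wahr)
```

## The model

A two-arm trial compares an intervention `I` against a control `C` on a
composite time-to-first-event endpoint with $k$ components $EP_1, \dots,
EP_k$ observed over $[0, \tau]$. Each component $j$ has a cause-specific
hazard $\lambda^g_{EP_j}(t)$ in arm $g$; the hazard of the composite is
their sum. The *weighted all-cause hazard* replaces the sum by a weighted
sum with fixed, pre-specified relevance weights $w_{EP_j} \ge 0$:

$$\lambda^{g,w}_{CE}(t) = \sum_{j=1}^{k} w_{EP_j}\,\lambda^g_{EP_j}(t),
\qquad
\theta^w_{CE}(t) = \frac{\lambda^{I,w}_{CE}(t)}{\lambda^{C,w}_{CE}(t)}.$$

With unit weights $\theta^w_{CE}$ is the ordinary all-cause hazard ratio.
The ratio is constant in time only when all components share one baseline
hazard shape; otherwise it is a time-dependent quantity, and the package
follows the convention of reporting it at the end of follow-up, $t = \tau$.
The time-average $\Theta^w_{CE}(\tau) = \tau^{-1}\int_0^\tau
\theta^w_{CE}(t)\,dt$ is available separately (`integrated_whr()`), but the
pointwise value at $\tau$ is what the estimators target and what
`run_study()` uses as the true effect of a scenario: recomputation of the
benchmark scenarios' tabulated true effects confirms that convention.

Superiority means fewer (weighted) events under the intervention, so the
test problem is one-sided: $H_0: \theta^w_{CE} \ge 1$ against
$H_1: \theta^w_{CE} < 1$, at a default one-sided $\alpha = 0.025$.

## Point estimators

**Non-parametric.** When the components share a baseline hazard shape the
ratio of weighted sums of *cumulative* cause-specific hazards equals
$\theta^w_{CE}$, which motivates

$$\tilde\theta^w_{CE}(t) =
\frac{\sum_j w_{EP_j}\hat\Lambda^I_{EP_j}(t)}
     {\sum_j w_{EP_j}\hat\Lambda^C_{EP_j}(t)},
\qquad
\hat\Lambda^g_{EP_j}(t) = \sum_{t_l \le t} \frac{d^g_{EP_j,l}}{n^g_l},$$

with $d^g_{EP_j,l}$ the type-$j$ events of arm $g$ at the $l$-th distinct
event time and $n^g_l$ the arm's at-risk count just before it
(`nelson_aalen()`). No distributional assumption is needed; when baseline
shapes differ across components the estimator is defined but biased for
$\theta^w_{CE}(\tau)$, which the benchmark scenarios probe deliberately.

**Parametric.** The original proposal estimates each cause-specific hazard
from a Weibull model and plugs the fitted hazards
$\hat\lambda^g_{EP_j}(\tau)$ into the weighted ratio. The fitting strategy
is a genuine design choice: the cited approach rests on *proportional
cause-specific hazards*, and for two Weibull hazards proportionality is
exactly the statement that the two arms share the shape parameter. We
therefore fit, per cause, a two-group Weibull proportional-hazards model

$$\lambda(t \mid g) = \kappa_g\,\nu\,t^{\nu-1}$$

with a common shape $\nu$ and arm-specific scales (`fit_weibull_ph()`),
treating competing events and censoring as right-censoring at their
observed times. We also implemented the alternative — independent
free-shape fits per arm and cause (`fit_weibull_mle()` applied per arm) —
and found in simulation that it inflates the estimator's replicate spread
by 30–50% and attenuates its mean in the benchmark scenarios, while the
shared-shape fit reproduces the reference benchmark behaviour closely; the
shared-shape model is therefore the default and the free-shape fit remains
exported for single-sample use. Both fits profile the scale(s) out of the
likelihood analytically, leaving a monotone one-dimensional score in
$\nu$ solved by bracketed root-finding (`uniroot`, tolerance `1e-12`, with
the gradient required to be below `1e-6` at the solution). A diverging
shape (all informative event times equal), fewer than two events, or a
non-vanishing score are reported as non-convergence — never clipped — and
make the whole estimate non-estimable; simulation summaries exclude such
replicates and report the count, mirroring standard practice.

Both estimators are invariant to rescaling all weights by a positive
constant and map to their reciprocal when the arm labels are swapped; the
test suite asserts both properties to machine precision.

## Tests

**Standard log-rank** (`logrank_test()`): at each distinct event time the
observed arm-`I` event count is centred at its hypergeometric expectation
and standardized by the summed hypergeometric variances
(`hypergeometric_moments()`); the statistic is asymptotically standard
normal and $H_0$ is rejected when it falls below $-z_{1-\alpha}$.

**Weight-based log-rank** (`weight_based_logrank_test()`): observed and
expected counts are weighted per event *type* — this is not the classical
"weighted log-rank" that weights time points — and the variance sums
$w_j^2$-weighted hypergeometric variances,

$$\frac{n^I_l n^C_l\left(n_l\sum_j w_j^2 d_{EP_j,l}
 - \sum_j w_j^2 d^2_{EP_j,l}\right)}{n_l^2 (n_l - 1)}.$$

At unit weights the statistic reduces *exactly* to the standard log-rank
statistic (asserted in the tests). The variance derivation assumes that
events of different types never coincide; with continuous event times this
holds almost surely, and a cross-type tie in user data triggers a warning
while the formula is applied as printed. The statistic is a Wald-type
quantity, not a Cox score test, so no confidence interval accompanies it.
Under an exchangeable null with equal cause-specific hazards the
implementation is well calibrated (empirical null SD within a few percent
of 1 in the test suite); when only the *weighted sums* of unequal
cause-specific hazards coincide, the hypergeometric argument no longer
applies exactly and the achieved level can deviate from nominal — a known
property of the method, probed by the constant-hazard benchmark scenario
with opposing component effects.

**Permutation test** (`permutation_test()`): the statistic is the observed
log estimate (either estimator); the null distribution is rebuilt by
re-partitioning the subjects into arms of the original sizes uniformly at
random, times and causes riding along. Conventions, chosen where the
method description leaves them open:

* one-sided p-value with the add-one correction
  $(1 + \#\{\text{perm} \le \text{obs}\})/(B + 1)$, which guarantees
  validity at any $B$; a complete-enumeration mode (`exact = TRUE`)
  replaces sampling by all $\binom{n}{n_I}$ assignments and uses the exact
  proportion;
* the standard deviation of the permutation sample doubles as a standard
  error of the log estimate, giving the normal-theory interval
  $\text{obs} \pm 1.959964\,\widehat{se}$ used for coverage;
* non-estimable permutations are dropped with a count; fewer than 10
  estimable permutations refuse inference.

## Choosing the weights

The planning-stage recipe implemented in `severity_to_weights()`: give the
clinically most relevant component weight 1 and derive every other weight
from a severity equivalence — if $m_j$ events of type $j$ are judged as
harmful as $r_j$ reference events, then $w_j = r_j/m_j$. Keeping all other
weights at or below 1 preserves comparability with the unweighted
analysis; schemes mixing weights above and below 1 can reproduce the
unweighted all-cause hazard by accident (the package warns but does not
refuse). The implied *modified hazards* $w_j\lambda_{EP_j}(t)$ stay inside
the supported parametric families (`modified_hazard()`), and
`weight_scheme_curves()` tabulates the weighted survival function
$S^w_{CE}(t) = \exp(-\sum_j w_j \Lambda_{EP_j}(t))$ for candidate schemes
so their effect on the event-time distribution can be inspected before the
trial; down-weighting flattens the curve, monotonically in each weight.

## The simulator

`simulate_trial()` draws, per subject and component, a latent event time by
inversion, $T_j = \Lambda_j^{-1}(-\ln U_j)$ with independent standard
uniforms; the observed outcome is the earliest latent time and its
component, or an administrative censoring at $\tau$ when no latent event
falls inside the observational period. This latent-competing-risks
construction is distributionally equivalent to simulating the composite
from the all-cause hazard and assigning causes proportionally to the
cause-specific hazards. The Weibull inverse is closed-form; the
Gompertz-Makeham inverse uses monotone bisection in $\Lambda$-space
(bracket doubled until it covers the target, then 110 halvings, residuals
far below the `1e-10` working tolerance). "Minimal follow-up $\tau$" is
read as administrative censoring of every subject at $\tau$ — no staggered
accrual and no random dropout — the reading under which the simulator
reproduces the benchmark scenarios' event-count profiles.

The registry (`list_scenarios()`) encodes ten two-component scenarios with
Weibull ($\lambda = \kappa\nu t^{\nu-1}$) and Gompertz-Makeham
($\lambda = \kappa e^{\nu t} + \epsilon$, $\epsilon \ge -\kappa$)
cause-specific hazards, flagged by which assumptions (proportional hazards
for components/composite, equal baseline shapes) each satisfies.
Reproducibility: `run_study()` derives one child seed per replicate from
the root seed, so a single replicate can be regenerated in isolation and
identical configurations give identical studies; within a replicate both
estimators see the same permutation draws.

What the generator does **not** emulate: random (non-administrative)
censoring, staggered entry, covariate-driven heterogeneity, more than two
arms, recurrent or interval-censored events, and tied event times
(continuous draws make cross-type ties a null event). Passing tests on
these data therefore show correctness of the estimators and tests under
clean competing-risks sampling, not robustness to the messiness of real
trial data.

## Performance metrics

For the log estimates of each method over estimable replicates:
bias $= \overline{\ln\hat\theta} - \ln\theta_{true}$, the sample SD with
$n-1$ denominator, standardized bias $=$ bias/SD, root-MSE with
$\text{MSE} = \text{bias}^2 + \text{SD}^2$ (an exact identity asserted in
the tests), relative efficiency $= \text{MSE}_{par}/\text{MSE}_{nonpar}$
(values above 1 favour the non-parametric estimator), coverage $=$ the
percentage of replicates whose interval
$\ln\hat\theta \pm 1.959964\,\widehat{se}_{perm}$ contains
$\ln\theta_{true}$, and empirical power $=$ the rejection fraction (the
type-I error under a null scenario). Replicates missing an estimate or a
permutation SE are excluded with counts. `study_table2()` and
`study_table3()` assemble these into the two standard report tables at
full precision; rounding to the customary two decimals is left to the
print method.

## Numerical choices and degenerate inputs

* Closed-form cumulative hazards are cross-checked against adaptive
  quadrature to `1e-8` relative tolerance; inversion round-trips are exact
  to well below `1e-6` in time.
* A Weibull hazard with $\nu < 1$ diverges at $t = 0$: evaluation raises a
  domain error there, while cumulative quantities remain defined (the
  singularity is integrable).
* Risk sets are left-continuous ("just before $t_l$"), so a subject
  censored exactly at an event time is still at risk at that time — the
  standard log-rank convention; cause codes are 1-based with 0 for
  censoring.
* Risk-set cells with fewer than two subjects carry no information and
  contribute zero to log-rank numerators and variances; a zero total
  variance raises a degenerate-test error, as does a dataset without
  events.
* An empty weighted cumulative hazard in either arm (or any non-converged
  component fit) yields a non-estimable `whr_estimate` with the reason
  recorded, rather than an infinite or imputed value.
* `hazard_model()` accepts $\kappa = 0$ (needed for weight-0 modified
  hazards); the resulting flat cumulative hazard is rejected at inversion
  time, the only operation it breaks.

## Scale of the shipped checks

The test suite runs the full estimator/test stack at reduced Monte-Carlo
sizes chosen to keep the default run in the minutes range while leaving
the Monte-Carlo error well below the effects being checked: 1000
replicates for estimator means and test levels, 200 replicates with
200–500 permutations for permutation power and coverage, and n = 50,000
single trials for simulator marginals (each cause-specific Nelson-Aalen
estimate within three standard errors of its analytic cumulative hazard
across the whole registry). The acceptance script reruns the headline
quantities from scratch at the same sizes under a caller-supplied seed.

## Known limitations

* The weight-based test's variance is exact only under equal
  cause-specific hazards across arms; its level under weighted-null
  configurations with unequal components is a known open issue of the
  method itself.
* No variance formula exists for either point estimator; interval
  estimates require the permutation machinery (or a bootstrap, which the
  package does not provide).
* The parametric estimator is Weibull-specific by construction; under
  non-Weibull data it estimates the best Weibull approximation's ratio,
  and the benchmark scenarios show when that is and is not acceptable.
* Arm labels are fixed at `"I"`/`"C"` and allocation at one dataset per
  estimate; multi-arm designs, covariate adjustment and stratified tests
  are out of scope.
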