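---
title: "Meta-analysis of shrubland vegetation responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of shrubland vegetation responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrubmeta)
```

## The problem

Manipulation experiments in shrublands — open-top-chamber or infrared
warming, rain-out shelters (drought), irrigation (increased
precipitation), and fertiliser addition — are scattered across sites
that differ in climate, duration, replication, and the intensity of the
manipulation itself. Synthesising them requires (i) an effect size that
is comparable across metrics measured in different units, (ii) a
pooling model that admits real between-site variation in the true
effect, (iii) protection against the selective publication of
significant results, and (iv) a way to ask whether site climate
moderates the response. shrubmeta implements that pipeline end to end
and ships a generator of synthetic experiment networks with known truth
so each property of the machinery can be verified by simulation.

## Effect sizes

For arm summaries $(\bar X_t, SD_t, n_t)$ and $(\bar X_c, SD_c, n_c)$
the log response ratio and its sampling variance are

$$RR = \ln(\bar X_t / \bar X_c), \qquad
  v = \frac{SD_t^2}{n_t \bar X_t^2} + \frac{SD_c^2}{n_c \bar X_c^2}.$$

Both arms enter the variance through their squared relative error over
their own replicate count — the standard delta-method form, in which
each arm is scaled by its own $n$. Results are reported as percentage
changes $100(e^{RR}-1)$, always derived from $RR$ so the two scales
can never disagree. Records with a non-positive mean are excluded
rather than offset-corrected: the log ratio is undefined there and any
offset rule would be arbitrary.

When a study reports several timepoints, each arm is collapsed to the
arithmetic mean of the timepoint means and the arithmetic mean of the
timepoint SDs. Averaging SDs (rather than taking the SD of the means)
keeps the within-plot replication scale and avoids folding a temporal
trend into sampling error; the alternative would conflate the two and
systematically inflate $v$ for trending studies.

### Sensitivities

To compare experiments of different intensity the percentage change is
divided by the net driver change: per °C for warming, per
g N m⁻² yr⁻¹ for nitrogen, and per 10 mm of precipitation change
(using the absolute change, so drought sensitivities keep the sign of
the response). No sensitivity is defined for the two combination
treatments — a ratio over two heterogeneous drivers has no unit.
Warming studies report annual and growing-season temperature changes
separately; when one site × metric has both, their sensitivities are
averaged into a single row before pooling so the site is not counted
twice.

Sensitivity-scale analyses stay inside the inverse-variance framework
using the delta rule
$\mathrm{var}(sens) = (100\,e^{RR})^2\, v / c^2$, where $c$ is the
driver divisor. This is the first-order propagation of the
effect-size variance through the percent transform and the (known)
divisor; it ignores uncertainty in the reported driver magnitude
itself, which studies do not quantify.

## Pooling

Within each metric × treatment stratum the model is
$y_i \sim N(\mu, v_i + \tau^2)$. $\tau^2$ is estimated by REML —
the profiled restricted likelihood is maximised over $\tau^2 \ge 0$ by
golden-section/parabolic search to a tolerance of $10^{-10}$, with the
$\tau^2 = 0$ boundary checked explicitly — or by the DerSimonian–Laird
moment estimator, which the test suite uses as a closed-form
cross-check (together with a grid search of the restricted likelihood
and the independent `metafor` implementation). The pooled mean uses
weights $1/(v_i+\tau^2)$; significance is the Wald z test
$\mu/SE(\mu)$ against the standard normal, and the interval is
$\mu \pm 1.96\,SE$. Studies with $v_i = 0$ (zero SD in both arms) are
excluded at pooling: their weight would be infinite and no floor rule
is defensible. Single-study strata are reported as the study itself
with $\tau^2 = 0$ and no test.

Alongside the Wald interval the package computes a bias-corrected
(BC, no acceleration) bootstrap percentile interval: studies are
resampled with replacement $B = 2000$ times (configurable, minimum
1000), each replicate re-pooled with its own $\tau^2$, and the
percentile bounds shifted by $z_0 = \Phi^{-1}(\text{fraction of
replicates below the point estimate})$, clamped away from 0 and 1 by
$1/(B+1)$. Acceleration is omitted deliberately: the BC correction is
what handles median bias of the pooled mean, and the jackknife
acceleration adds cost without changing the conclusions at the stratum
sizes involved (tested at $k = 200$, where the BC width agrees with the
Wald width to within 20%). Both intervals are always reported.

### Duration subgroups

Experiments are split at 5 years — short-term $\le 5$, long-term
$> 5$ — pooled separately, and contrasted with
$z = (\mu_s - \mu_l)/\sqrt{SE_s^2 + SE_l^2}$. An empty subgroup
(common for long-term drought) is reported absent and the contrast
marked unavailable rather than dropped silently.

## Publication bias

Egger's test is implemented in its classical form: OLS of the
standardised effect $y_i/se_i$ on precision $1/se_i$; the intercept,
its SE, and a two-sided normal p-value are returned. PEESE regresses
$y_i$ on $v_i$ with weights $1/v_i$; its intercept is the
bias-corrected pooled effect (the limit of an infinitely precise
study). The workflow conditions the correction on the Egger test at
$\alpha = 0.10$ — a deliberately liberal trigger, since the Egger test
is underpowered at typical stratum sizes — but always reports both the
naive and the corrected estimate so the conditioning is reversible
downstream. Strata with $k < 3$ get no diagnostics (the regressions
have no residual degrees of freedom) and keep the naive estimate.

PEESE corrects bias at a variance cost: its intercept extrapolates to
$v = 0$ and is therefore noisier than the naive mean, especially when
the $v_i$ span a narrow range. Simulations with the package's
censoring generator (drop each non-significant study with probability
0.8) show the PEESE estimator's *bias* is roughly half the naive
estimator's, while its mean absolute error can exceed it — which is
exactly why the headline switches to PEESE only on Egger evidence of
asymmetry.

## Moderator meta-regression

The mixed-effects meta-regression is
$y_i \sim N(\beta_0 + \beta_1 g(x_i),\, v_i + \tau^2)$ with $g$ the
identity or the natural log (the log base only rescales $\beta_1$, so
natural log is used throughout). Coefficients are reported from the
REML fit; model comparison uses ML refits, because restricted
likelihoods are not comparable across fixed-effect structures. The
AIC counts $p + 1$ parameters (coefficients plus $\tau^2$) and matches
`metafor`'s ML AIC exactly. For a single moderator the omnibus
statistic is $Q_M = z_1^2$.

Warming sensitivities are screened against three candidates — MAT
linear, AI linear, AI log — by lowest ML AIC (ties broken by candidate
order); the other single-driver treatments use the aridity index only,
keeping whichever of the linear and log forms fits better. Slopes are
labelled significant at $p < 0.05$ and marginal at $p < 0.10$. Strata
with $k < 3$ appear in the gradient report as `not_estimable` rows.

## The synthetic experiment generator

`simulate_dataset()` builds the statistical structure the analysis
assumes, nothing more: per site, a climate moderator drawn uniformly on
its support; a true effect
$\theta_i = \beta_0 + \beta_1 g(x_i) + N(0, \tau^2)$; a control mean
$\mu_c$ on 50–500 (native units) and treatment mean $\mu_c e^{\theta_i}$;
then *observed* arm summaries with multiplicative noise — sample mean
$\sim N(\mu, (\sigma_{rel}\mu)^2/n)$ (redrawn in the vanishingly rare
non-positive case) and sample SD from the exact
$\sigma_{rel}\mu\sqrt{\chi^2_{n-1}/(n-1)}$ law, so the sampling noise
of the SDs that feed $v$ is honestly present. One global seed drives
fixed per-site substreams, so enlarging a network appends sites without
rewriting earlier ones.

Defaults were fixed once at values a field ecologist would call
typical of shrubland manipulation networks: ~30 sites per treatment,
3–6 plot replicates per arm, within-plot relative SD 0.2,
between-site $\tau^2 = 0.02$ (≈ ±15% site-to-site spread of true
effects), warming +0.5–4 °C, increased precipitation +30–120 mm yr⁻¹,
drought −120 to −30 mm yr⁻¹, nitrogen 2–10 g N m⁻² yr⁻¹, aridity
index 0.05–1.5, MAT −5–20 °C, and 30% of sites running longer than
5 years. `apply_publication_censoring()` drops each study that is
non-significant at the per-study level with a configurable
probability, never touching significant ones — the file-drawer
mechanism the funnel/Egger/PEESE stack must detect.

What the generator does **not** emulate: temporal autocorrelation
within studies, spatially correlated site climates, interaction
structure in combination treatments, non-normal plot noise, and
driver magnitudes correlated with climate. Passing tests therefore
demonstrate that the estimators do what they claim under the model's
own assumptions — not that real shrubland data satisfy those
assumptions.

## Numerical choices and verified properties

The test suite verifies, among others: DL against the hand moment
formula and REML against a two-stage grid search of the restricted
likelihood (coarse $10^{-3}$, fine $10^{-6}$) on dozens of random
strata; exactness of the worked three-study example
($y = (0.1, 0.3, 0.5)$, $v = 0.01$: $Q = 8$, $\tau^2_{DL} = 0.03$,
$\mu = 0.3$, $SE = \sqrt{0.04/3}$); transform round-trips and the
degree-−1 homogeneity of sensitivities in the driver magnitude; 95%
Wald coverage within [0.90, 0.96] over 1000 simulated meta-analyses
($k = 20$, $\tau^2 = 0.02$); Egger's type-I rate within [0.03, 0.08]
on 1000 effect-level null meta-analyses ($k = 30$); PEESE halving the
censoring-induced bias over 500 generator replicates ($k = 60$,
censoring 0.8); slope coverage and ≥80% AI-over-MAT selection for a
$\beta_1 = -0.5$ ln(AI) signal at $k = 40$; ≥80% power of the duration
contrast at a 0.2 rr gap ($k = 30 + 30$); and byte-identical pipeline
reruns. Replicate counts (200–1000 per property) keep the whole suite
under two minutes on one core while leaving the binomial error of each
rate well inside its acceptance band.

One calibration caveat is worth stating. With very small plot counts
(2–3 replicates) the sample SDs entering $v$ are themselves so noisy
that standardised effects $y/\hat{se}$ are heavy-tailed, and the
normal-reference Egger test becomes mildly liberal (~0.09 at
$n_{reps} \in [3,6]$). That is a property of the classical test under
estimated variances, not of the implementation; the size check is
therefore run at the effect level, where the test's assumptions hold,
and small-$n$ Egger p-values on real data should be read with the same
caution.

## Known limitations

- No site-nested or multivariate random effects: sites contributing
  several metrics are treated as independent within each stratum, as
  strata are analysed separately.
- No Knapp–Hartung adjustment; with small $k$ the Wald intervals are
  mildly anticonservative, which is why the bootstrap interval is
  reported alongside.
- Missing SDs are not imputed from SEs or CIs; such records are simply
  excluded.
- The delta-rule variance on the sensitivity scale treats the driver
  magnitude as known.
- Combination treatments are pooled but never standardised to
  sensitivities or regressed on climate.
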