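---
title: "Unequal-variance SDT from response times: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unequal-variance SDT from response times: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvsdt)
```

## The model

A yes/no detection trial is modeled as a draw of internal evidence $x$:
$x \sim N(0, 1)$ when the target is absent and $x \sim N(\mu, \sigma)$ when
it is present. The observer answers "yes" when $x$ exceeds the decision
criterion, and grades the answer (by confidence, or implicitly by speed)
according to $2n - 1$ ordered criteria $c_1 < \dots < c_{2n-1}$ that
partition the evidence axis; the middle criterion $c_n$ is the yes/no
cutpoint. The probability of each of the $2n$ response categories is the
Gaussian mass between consecutive criteria (`cell_probabilities()`), and a
subject's $2 \times 2n$ response-frequency table is multinomial in those
probabilities, giving the log-likelihood
$\sum_{\text{cells}} f \log p$ (`uvsdt_loglik()`).

Sensitivity is summarized two ways:

* $d' = z(\text{hit}) - z(\text{FA})$ from the single yes/no operating
  point — the conventional equal-variance index;
* $d_a = \mu \sqrt{2 / (1 + \sigma^2)}$ from the fitted model — the mean
  separation standardized by the root-mean-square of the two SDs, equal to
  $d'$ when $\sigma = 1$ and independent of criterion placement.

With $\sigma > 1$ (the typical detection-task asymmetry) $d'$ is
criterion-dependent: for a $\mu = \sigma = 1.5$ observer,
$d_a = `r round(d_a(1.5, 1.5), 2)`$, yet the single-point $d'$ is
`r round(d_prime(1 - pnorm((1 - 1.5)/1.5), 1 - pnorm(1)), 2)` at the
conservative criterion $+1$ and
`r round(d_prime(1 - pnorm((-1 - 1.5)/1.5), 1 - pnorm(-1)), 2)` at the
lenient criterion $-1$. The difference $d' - d_a$ is the *misevaluation
index*: positive for conservative observers, negative for lenient ones.
Two useful identities follow from the bi-Gaussian form and are enforced by
the test suite: the zROC (both ROC axes $z$-transformed) is a straight line
with slope $1/\sigma$ and intercept $\mu/\sigma$, and the area under the
model ROC equals $\Phi(d_a/\sqrt2)$.

## From trials to rating tables

**Confidence.** Ordinal scales are used as-is. Continuous scales are
discretized per subject at the $i/n$ type-7 quantiles of that subject's own
ratings (tertiles for $n = 3$); a value exactly on a cutpoint takes the
lower level. A subject with fewer distinct values than levels is an error —
their scale cannot support the requested resolution.

**Response time.** RTs are discretized per subject into $n$ type-7 quantile
bins, and the bin is used as the rating: the fastest bin is the strongest
evidence for the chosen option, the slowest the weakest. By default the
quantile cutpoints pool yes and no responses (`scheme = "pooled"`): speed
is read on a common clock, which is the direct operationalization of
"faster = stronger indication". A `within_response` scheme (separate
cutpoints per response) is available for designs where the two responses
have different motor demands. Ties at a cutpoint go to the slower, weaker
bin; equal RTs always share a bin, so the assignment is order-stable.

**Table and padding.** Trials are tabulated into a $2 \times 2n$ table with
columns ordered from strongest "yes" to strongest "no". Before fitting,
$1/N$ ($N$ = the subject's total trial count) is added to every cell. This
keeps every cumulative rate strictly inside $(0,1)$ — required by the
$z$-transform and by the likelihood at extreme criteria — while moving the
rates only at order $1/N$; empirically the fitted $\mu$ shifts by well
under 0.05 for $N \ge 200$. Padding happens *before* the below-chance
screen, so that screen sees the same rates the fit will see.

**Exclusions.** Subjects whose padded midpoint rates give
$z(\text{hit}) - z(\text{FA}) \le 0$ are flagged as not above chance and
excluded from fitting; the boundary (hit = FA) counts as excluded. Fits
that do not converge (optimizer failure, or $\hat\sigma$ outside
$[0.05, 20]$) are likewise dropped from cohort summaries.

## Maximum-likelihood fitting

`fit_uvsdt()` maximizes the multinomial log-likelihood over
$(\mu, \log\sigma, c_1, \log\Delta_2, \dots, \log\Delta_{2n-1})$ — an
unconstrained vector in which $\sigma > 0$ and strict criterion ordering
hold by construction (gaps are floored at $10^{-4}$). Choices, all
package defaults rather than anything forced by the model:

* **Optimizer**: Nelder-Mead simplex via `stats::optim()` (derivative-free,
  robust to the mild ridge between $\mu$ and the criteria), relative
  tolerance $10^{-8}$ on the log-likelihood, at most 5000 evaluations;
  BFGS available via `method = "BFGS"`.
* **Starting values** (`initialize_params()`): $\sigma_0$ = reciprocal of
  the zROC least-squares slope clipped to $[0.2, 5]$, $\mu_0$ = intercept
  $\times\ \sigma_0$, criteria from the normal quantiles of the cumulative
  FA rates nudged to strict ordering (minimum gap $10^{-3}$); a degenerate
  zROC falls back to $\mu_0 = 1$, $\sigma_0 = 1$, equally spaced criteria.
* **Restarts**: the initializer plus 3 restarts jittered by $N(0, 0.1)$ on
  the working scale; the best optimum is kept. The `seed` argument makes
  the jitter reproducible and is recorded in the result.
* **Degenerate-fit guard**: $\hat\sigma$ outside $[0.05, 20]$ marks the fit
  non-converged instead of returning an absurd $d_a$.
* **Probability floor**: predicted cell probabilities are floored at
  $10^{-300}$ inside the log (with a warning) so the search stays finite
  without materially moving any optimum.

Verification in the test suite: recovery of generating parameters from
exact-probability tables and from simulated cohorts (100 subjects × 1000
trials: mean $\hat\mu$ within 0.05 and mean $\hat\sigma$ within 0.07 of
truth), and the fitted optimum beating a $21^3$ brute-force grid over
$(\mu, \sigma, \text{criterion shift})$ on every random table tried.

## The synthetic observer

`simulate_observer()` generates stimulus, evidence, response and confidence
exactly per the model above, plus response times from

$$\mathrm{rt} = \exp\!\big(a - b\,|x - c_n| + \varepsilon\big),
\qquad \varepsilon \sim N(0, \tau^2).$$

The log-linear form with log-normal noise is this package's own choice: the
analysis only assumes RT decreases monotonically with evidence distance
from the decision criterion, and any strictly monotone form yields the same
quantile bins at $\tau = 0$. Defaults: $a = \log 0.7$ (0.7 s at the
criterion, a typical speeded-detection latency), $b = 0.35$ per evidence
unit (about a 30% speed-up per SD of evidence), $\tau = 0.25$ (log-normal
noise giving a realistic right-skewed RT spread of roughly ±25%).
$\tau$ is the lever that mimics real RT sloppiness: at $\tau = 0$ RT bins
reproduce confidence categories exactly (given matching criteria placement)
and RT- and confidence-based $d_a$ agree to Monte-Carlo error; increasing
$\tau$ progressively attenuates RT-based $\hat\sigma$ toward 1 while
leaving confidence-based estimates untouched — the mechanism behind the
small RT-vs-confidence gap in real data. Cohorts
(`simulate_cohort()`) add between-subject spread: normal on $\mu$ and on
the criterion placement (the whole criterion vector shifts rigidly, gaps
default to 0.5), log-normal on $\sigma$ and on $b$.

What the simulator does **not** emulate: sequential-sampling RT dynamics
(no drift-diffusion shape, no speed-accuracy trade-off), staircase
difficulty titration, lapses/fast guesses, base-rate or payoff
manipulations, and any dependence of RT precision on task design. Passing
tests therefore certify the statistical machinery under the model's own
assumptions, not the behavior of any particular empirical dataset.

## Cohort summaries

`summarize_cohort()` aligns converged fits across the two rating
dimensions and reports group means/SDs, two-sided paired $t$-tests
(uncorrected — comparisons are few and planned), Pearson correlations
between sources, and the correlation between criterion $c$ and the
misevaluation index. Percent differences between sources use the
confidence-based mean as denominator. With fewer than three matched
subjects, or zero variance in a correlate, correlations are left unset
with a warning rather than fabricated.

Study-condition scale used in the heavier checks: 100 subjects × 1000
trials for recovery and RT/confidence agreement; 10 replicate 40-subject
cohorts (criterion spread SD 0.5 around a conservative $c_0 = +1$) for the
$d'$-inflation and criterion-correlation pattern, which reproduces at sign
level in every replicate.

## Known limitations

* The fit reports no standard errors or confidence intervals on
  $(\hat\mu, \hat\sigma)$; inference is across subjects, not within.
* Only the bi-Gaussian ROC family is implemented — no dual-process,
  threshold, or model-comparison (AIC/BIC) machinery.
* $c$ is an equal-variance bias index; under $\sigma \ne 1$ it tracks the
  evidence-axis criterion with slope $(1 + 1/\sigma)/2$, so its
  between-subject SD understates the criterion spread for $\sigma > 1$.
* RT-based estimation inherits whatever noise the task injects into RT;
  the $\tau$ lever models this only phenomenologically.
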