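---
title: "Real-time changepoint monitoring for nonlinear expectile regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time changepoint monitoring for nonlinear expectile regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expectmon)
```

## The model and the monitoring problem

We observe a univariate response generated by a nonlinear parametric
regression $Y_i = f(x_i, \beta) + \varepsilon_i$ with i.i.d. errors and a
fixed design. The first $m$ observations (the *historical data*) are assumed
changepoint-free; observations $m+1, m+2, \dots$ (the *online data*) arrive
one at a time, and after each arrival we ask whether the parameter vector is
still the historical $\beta^0$ or has changed. Monitoring may run over a
bounded horizon of $T_m$ observations (*closed-end*) or indefinitely
(*open-end*).

Estimation uses conditional expectiles (asymmetric least squares): for an
asymmetry index $\tau \in (0,1)$ the loss is
$\rho_\tau(x) = |\tau - 1\{x<0\}|\, x^2$, with derivative
$g_\tau(x) = 2\tau x$ for $x \ge 0$ and $2(1-\tau) x$ for $x < 0$. At
$\tau = 1/2$ this is ordinary least squares; away from $1/2$ it targets an
asymmetric location functional, which keeps the estimating equations valid
for error laws whose mean is not the natural centre (expectiles are the only
coherent and elicitable risk measure, hence their role in risk monitoring).
The historical fit solves
$\hat\beta_m = \arg\min_\beta \sum_{i=1}^m \rho_\tau(Y_i - f(x_i,\beta))$
over a compact parameter box $\Gamma$.

The detector is a CUSUM of scores. With residuals
$\hat\varepsilon_i = Y_i - f(x_i, \hat\beta_m)$,
$$
S(m,k) = J_m^{-1/2} \sum_{i=m+1}^{m+k} \nabla f(x_i, \hat\beta_m)\,
          g_{\hat\tau}(\hat\varepsilon_i), \qquad
J_m = \frac{S^2_{g}}{m} \sum_{i=1}^m \nabla f \nabla^\top f ,
$$
where $S^2_g$ is the sample variance of the historical scores and
$J_m^{-1/2}$ is the inverse lower Cholesky factor. The running statistic is
$\|S(m,k)\|_\infty / z(m,k,\gamma)$ with boundary function
$z(m,k,\gamma) = m^{1/2}(1 + k/m)(k/(k+m))^\gamma$, $\gamma \in [0, 1/2)$,
and the alarm is raised the first time it exceeds a critical value
$c_\alpha(\gamma)$. Under no change the supremum converges to
$\sup_{0<t<L} \|W_p(t)\|_\infty / t^\gamma$ for a $p$-dimensional Wiener
process, with $L = 1$ (open-end) or $L = T/(1+T)$, $T = \lim T_m/m$
(closed-end) — independent of $f$ and of $\beta^0$, which is what makes one
simulated table of critical values serve every model.

A point worth recording because it is easy to misread in experiments: the
estimation error of $\hat\beta_m$ is *part* of the limit. The online score
sum behaves like $\sum \nabla f\, g_\tau(\varepsilon_i) - (k/m) \sum_{hist}
\nabla f\, g_\tau(\varepsilon_j)$; the second term — present only because
$\hat\beta_m$ was estimated — lifts the variance from the bridge-type
$k\,(1-t)$ to the Wiener $k$. Plugging the true $\beta^0$ into the detector
(tempting as an "oracle" check) therefore produces a *conservative* test
whose level collapses with the horizon (essentially to zero at the
open-end horizon in our experiments), while the properly estimated fit
holds the nominal level at the short horizon.

## Fitting: iterative grid search

The expectile risk need not be convex in $\beta$, so the fit is a
refining grid search ([search_control()]): each stage lays 41 points per
dimension on a box centred at the incumbent, the span shrinking by the
factor 0.12 per stage (clipped to $\Gamma$), for 3 stages by default,
stopping early once the per-coordinate step falls below $10^{-3}$ of the box
width. An optional *polish* stage runs box-constrained L-BFGS-B (analytic
gradient $-\sum \nabla f\, g_\tau$) from the grid incumbent; it can only
lower the same objective. Polish is off by default in `fit_expectile()` but
on in the study driver `study_design()`, because the Monte-Carlo experiments
below are sensitive to optimisation error: the residual-based estimate of
$\tau$ in particular inherits a co-adaptation bias from an under-optimised
fit, visible at the study's historical sizes.

Ties and degeneracies: at a zero residual the non-negative branch of
$g_\tau$ and $h_\tau$ applies; if the Cholesky factorisation of $J_m$
fails, one ridge of $10^{-10}\,\mathrm{tr}(J)/p$ is added before failing
loudly; grid stages are deterministic, so fits are exactly reproducible.

When the error law is asymmetric the index $\tau$ is unknown. Following the
moment condition $m^{-1}\sum_i g_\tau(\hat\varepsilon_i) = 0$ (whose root is
available in closed form, `tau_hat()`, because the sum is linear in
$\tau$), `fit_expectile(tau = "estimate")` alternates fitting at the current
$\tau$ with re-solving the moment condition, from $\tau = 1/2$, until the
index moves less than $10^{-4}$ (at most 20 rounds). The first round is the
full grid search; subsequent refits continue from the incumbent with the
box-constrained quasi-Newton step on the same objective — the optimum moves
only slightly per $\tau$ update, and on simulated study data the
continuation tracks re-running the full grid at every round to well
inside the index tolerance, at a small fraction of the cost. The alternation is a
fixed-point iteration on a monotone map and converges in 10–20 rounds.

## Critical values

`critical_value()` simulates $\sup_{0<t<L}\|W_p(t)\|_\infty/t^\gamma$ by
cumulative sums of Gaussian increments on $10^4$ equispaced points of
$(0,1]$ (the first point $1/n_{grid}$ keeps the weight finite; the discrete
maximum is a lower bound on the continuum supremum, which at this
resolution biases the 95% quantile by well under 1%). A general $L$ uses
the exact distributional scaling $L^{1/2-\gamma}$ of the unit-interval
supremum rather than a re-simulation, so open- and closed-end values share
one set of paths and differ by no grid artefacts. Samples are cached per
configuration within the session. For $p=1,\ \gamma=0$ the classical
reflection series for $P(\sup_{(0,1)}|W| \le b)$ gives an analytic oracle
(`sup_abs_wiener_quantile()`, 2.2414 at $\alpha=0.05$) against which the
simulation is tested to 2%.

Defaults: $2\times 10^4$ paths for routine use; the acceptance checks use
$10^5$ paths where the oracle comparison demands it.

## The synthetic study

`study_design()` reproduces the structure of the level/power experiments:
two-parameter Gompertz curve $f(x,\beta) = \exp(-\beta_1 e^{-\beta_2 x})$
with $\beta^0 = (10, 5)$, design points i.i.d. Uniform$(0,1)$, historical
sizes $m \in \{20, 50, 200\}$, horizons $T_m \in \{10, \lfloor m/2\rfloor,
\lfloor m \ln m\rfloor\}$ (the first two closed-end with $T = T_m/m$, the
last treated as open-end), $\gamma = 0.1$, $\alpha = 0.05$, and error laws
N(0,1), N(1,1) and Laplace(0,1) with unit variance (scale $1/\sqrt 2$).
$\tau$ is fixed at $1/2$ for the symmetric laws and re-estimated per
replication for N(1,1) by the coupled fit/moment alternation. The
population index of the N(1,1) law is available analytically
($\tau^* = 0.071416$, from $\tau A + (1-\tau)B = 0$ with
$A = \Phi(1) + \phi(1)$, $B = 1 - A$) and anchors the estimation check.
Re-estimating, rather than fixing the index at its population value, is
not cosmetic: the empirical moment condition re-centres the historical
scores, and fixing the index instead inflated the false-alarm rate to
roughly twice the nominal level in our experiments. Even with
re-estimation this cell runs somewhat hot (the estimated index's upward
finite-sample bias leaves a small systematic drift in the online scores),
which is the least well calibrated corner of the study. Power cells double $\beta_2$ (5 to 10), either from
the first online observation ("immediate") or from online index
$\lfloor T_m/2\rfloor + 1$ ("midpoint"); under the midpoint rule,
exceedances in the first half are false alarms and are discarded, and
detection timing is summarised by the location index
$(\hat k_m - 1)/(T_m - 1)$.

Two study conditions are not fixed by the study design itself and had to be
chosen once:

* **The parameter box.** The study fits search the package default
  $\Gamma = [0.1, 30] \times [0.5, 15]$. On this data $\beta_1$'s profile
  is nearly flat (the historical design carries little information about
  the left tail of the curve), so estimates spread widely whatever the
  sample size, and the box choice is consequential. We keep the wide box
  because the detector's *calibration* demands it: where a fit is clipped
  at a bound, its first-order condition fails, and with it part of the
  estimation-error compensation that produces the Wiener-type null
  fluctuation — with a tight width-10 box around the truth the empirical
  level at the two longer horizons collapsed to a fraction of the nominal
  5% in our exploration. The price of the wide box is estimator dispersion
  well above what a tighter search region would report; we treat the
  reported estimator spreads of such studies as box-dependent and do not target them.
* **Monte-Carlo sizes.** The package's own experiments run at 400–1000
  replications per cell (reported alongside every result), with
  $2\times10^4$ paths behind each critical value; these sizes put the
  binomial error of a 5% level at about $\pm 0.7$–1.4 points.

What the generator does *not* emulate: serially dependent errors (visible
in the real epidemic data's residual autocorrelation), heteroscedastic
counts, or design drift between the historical and online windows. Passing
tests therefore certify the estimator, detector, limit law and their
interplay under the stated i.i.d. conditions — not robustness to dependence.

## Reproduction notes and known limitations

* Empirical levels at the short horizon reproduce the reference values of the study design
  within Monte-Carlo error for the symmetric error laws; the asymmetric
  cell runs 2–3 points hot (see above). The acceptance suite computes all
  three.
* The power cells for the immediate $\beta_2$-doubling sit in a knife-edge
  regime: the deterministic drift path of the statistic peaks at 1.72
  against a closed-end threshold of 1.63 at $T_m = m/2$, so a few percent
  of drift or threshold shift moves power by tens of points. Our
  reconstruction gives higher power at $T_m = m/2$ and lower at
  $T_m = 10$ than the reference values (the open-end long-horizon cell
  agrees closely); no single configuration choice moves both horizons in
  the reference direction, which points to unrecorded details of the
  original implementation's search region, optimiser and critical-value simulation. We
  report our computed values as-is rather than calibrating toward the
  reference values.
* The per-replication estimate of $\tau$ under N(1,1) is consistent (its
  mean approaches the analytic moment-condition index 0.0714 as $m$
  grows) but carries an upward finite-sample bias at $m = 200$, around
  +0.01 to +0.015, from the co-adaptation of $\hat\beta$ and $\hat\tau$
  on weakly identifying data; the acceptance run reports the biased
  finite-sample average it actually computes.
* Null calibration weakens with the horizon at $m = 200$: the short
  closed-end horizon holds the 5% level, but the open-end horizon is
  conservative in our reconstruction, where the reference results report
  mild anti-conservativeness instead. The gap reflects how closely the
  fitted parameters obey the first-order condition — optimiser and
  search-region details that finite samples are sensitive to at large
  $k/m$.
* The three-parameter Gompertz model (unknown saturation $K$) is provided
  for cumulative-count applications; its $K$ is weakly identified before
  the inflection point, so monitoring verdicts early in a growth process
  should be read with care.
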