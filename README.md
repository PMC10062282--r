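# expectmon

Real-time (online) changepoint detection for nonlinear parametric
regression estimated by conditional expectiles.

## What problem this solves

You have a stream of observations following a nonlinear regression
`Y = f(x, β) + ε` — say a Gompertz growth curve tracking cumulative
epidemic incidence — and a block of *historical data* known to be free of
structural change. As new observations arrive you want to know, in real
time, whether the parameter vector has changed (a wave accelerating after
a policy change, a bioprocess drifting off its growth trajectory), with a
guaranteed false-alarm rate over the whole monitoring period.

`expectmon` fits the historical block by **asymmetric least squares**
(conditional expectiles, index `τ ∈ (0,1)`; `τ = 1/2` is ordinary least
squares), which stays valid under asymmetric and heavy-tailed error laws,
then monitors with a **normalized CUSUM of scores**

```
S(m,k) = J_m^{-1/2} Σ_{i=m+1..m+k} ∇f(x_i, β̂_m) g_τ(ε̂_i),
stat_k = ‖S(m,k)‖_∞ / z(m,k,γ),   z(m,k,γ) = √m (1+k/m) (k/(k+m))^γ,
```

raising an alarm the first time `stat_k` exceeds a critical value. Under
no change the supremum of `stat_k` converges to
`sup_{0<t<L} ‖W_p(t)‖_∞ / t^γ` — a weighted Wiener supremum that does not
depend on `f` or `β` — with `L = 1` for open-end monitoring and
`L = T/(1+T)` for a bounded horizon `T_m ≈ T·m`. Critical values are
simulated once (`critical_value()`) and cached.

## Worked example

Historical block of 200 points from a Gompertz curve with β = (10, 5),
then an online stream whose growth-rate parameter doubles:

```r
library(expectmon)
set.seed(1)
model <- gompertz2_model()
x_h <- runif(200); y_h <- eval_model(model, x_h, c(10, 5)) + rnorm(200)
fit <- fit_expectile(model, x_h, y_h, tau = 0.5,
                     control = search_control(polish = TRUE))
fit
#> Expectile regression fit (model: gompertz2, m = 200)
#>   beta_hat: 5.29828, 3.73209
#>   tau: 0.5 (fixed)
#>   score variance S^2: 0.984995
#>   objective: 98.007

thr <- critical_value(p = 2, gamma = 0.1, L = L_of_T(0.5, closed_end = TRUE))
x_o <- runif(100); y_o <- eval_model(model, x_o, c(10, 10)) + rnorm(100)
run_monitor(fit, x_o, y_o, gamma = 0.1, threshold = thr)
#> Sequential expectile changepoint test (m = 200, gamma = 0.1)
#>   observations monitored: 95
#>   max statistic T(m): 1.66398  threshold: 1.63597
#>   CHANGE DETECTED at online index k_hat = 95 (absolute index 295)
```

The curve is barely identified at this noise level (a unit-variance error
on a response confined to (0,1)), so the fitted parameters scatter widely
around the truth — that is a property of the study design, not a failure
of the search, and the detector's normalization absorbs it. The monitor
consumes the stream one observation at a time and stops at the first
boundary crossing — here after 95 post-change observations, i.e. the model
governing the stream is declared changed at absolute index 295.

A thin command-line front-end wraps the same functions
(`inst/cli/expectmon.R`; commands `fit`, `monitor`, `critval`,
`simulate`), reading CSV streams and writing JSON/NDJSON artifacts.

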