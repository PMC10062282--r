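# Shared fixtures: small models and a deterministic micro fit used across
# test files.

intercept_model <- function(box = cbind(-100, 100)) {
  model_spec("intercept", p = 1L, q = 1L, param_box = box,
             evaluator = function(X, beta) rep(beta[1L], nrow(X)),
             gradient = function(X, beta) matrix(1, nrow(X), 1L))
}

# Hand-computable monitoring setup: intercept-only model, m = 2 historical
# residuals (+1, -1) at tau = 0.5, so S^2 = 2, V = 1, J = 2, J^{-1/2} =
# 1/sqrt(2).
micro_fit <- function() {
  fit_expectile(intercept_model(), X = c(0, 0), Y = c(1, -1), tau = 0.5)
}

# Independent scalar tau-expectile via root-finding on the moment equation.
scalar_expectile <- function(y, tau) {
  stats::uniroot(function(b) sum(g_tau(tau, y - b)), range(y) + c(-1, 1),
                 tol = 1e-12)$root
}

gompertz2_curve <- function(x, b) exp(-b[1L] * exp(-b[2L] * x))
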