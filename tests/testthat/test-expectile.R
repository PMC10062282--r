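test_that("loss, score and curvature follow their piecewise definitions", {
  expect_equal(rho_tau(0.3, 0), 0)
  expect_equal(rho_tau(0.5, 2), 2)
  expect_equal(rho_tau(0.25, -2), 3)          # |0.25 - 1| * 4
  # symmetry rho_tau(x) = rho_{1-tau}(-x)
  for (tau in c(0.1, 0.37, 0.8)) {
    x <- c(-2.5, -0.3, 0, 1.7)
    expect_equal(rho_tau(tau, x), rho_tau(1 - tau, -x))
  }

  expect_equal(g_tau(0.5, c(-3, 0, 7)), c(-3, 0, 7))
  expect_equal(g_tau(0.25, -2), -3)           # 2 * 0.75 * (-2)
  expect_equal(h_tau(0.5, c(-1, 0, 1)), c(1, 1, 1))
  expect_equal(h_tau(0.1, -1), 1.8)
  expect_equal(h_tau(0.3, 0), 0.6)            # x = 0 on the nonnegative branch

  expect_error(rho_tau(0, 1), "tau")
  expect_error(g_tau(1, 1), "tau")
})

test_that("score is the derivative of the loss away from zero", {
  d <- 1e-6
  for (tau in c(0.1, 0.5, 0.9)) {
    for (x in c(-2, -0.5, 0.5, 3)) {
      fd <- (rho_tau(tau, x + d) - rho_tau(tau, x - d)) / (2 * d)
      expect_equal(fd, g_tau(tau, x), tolerance = 1e-6)
    }
  }
})

test_that("closed-form tau_hat solves the moment condition and matches bisection", {
  expect_equal(tau_hat(c(1, -1)), 0.5)
  expect_equal(tau_hat(c(3, -1)), 0.25)
  expect_error(tau_hat(c(5, 5)), "both signs")

  bisect_tau <- function(e) {
    f <- function(t) sum(g_tau(t, e))
    lo <- 1e-12; hi <- 1 - 1e-12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  set.seed(11)
  for (i in 1:100) {
    e <- stats::rnorm(sample(5:60, 1), mean = stats::runif(1, -1, 1))
    if (all(e >= 0) || all(e <= 0)) next
    th <- tau_hat(e)
    expect_equal(th, bisect_tau(e), tolerance = 1e-10)
    expect_equal(mean(g_tau(th, e)), 0, tolerance = 1e-10)
  }
})

test_that("score variance matches its definition and scales quadratically", {
  expect_equal(var_g(c(1, -1), 0.5), 2)       # (1 + 1) / 1
  expect_equal(var_g(numeric(5), 0.3), 0)
  set.seed(3)
  e <- stats::rnorm(20)
  expect_equal(var_g(3 * e, 0.2), 9 * var_g(e, 0.2))
  expect_error(var_g(1, 0.5), "at least two")
})

test_that("J matrix matches an explicit cross-product and the Cholesky inverse root reconstructs", {
  lin <- linear_model()
  set.seed(4)
  x <- stats::runif(9)
  beta <- c(1, 2)
  Jd <- J_matrix(lin, x, beta, var_g = 1.7)
  D <- cbind(1, x)
  expect_equal(Jd, 1.7 * crossprod(D) / 9, ignore_attr = TRUE,
               tolerance = 1e-12)

  # intercept-only: gradient is 1, so J is the score variance itself
  expect_equal(J_matrix(intercept_model(), c(0, 0), 0.3, var_g = 2),
               matrix(2), ignore_attr = TRUE)
  expect_equal(J_matrix(lin, x, beta, var_g = 0),
               matrix(0, 2, 2), ignore_attr = TRUE)

  expect_equal(inv_sqrt_cholesky(diag(2)), diag(2))
  expect_equal(inv_sqrt_cholesky(diag(c(4, 9))), diag(c(1 / 2, 1 / 3)))
  for (i in 1:20) {
    A <- matrix(stats::rnorm(9), 3)
    J <- crossprod(A) + diag(0.1, 3)
    M <- inv_sqrt_cholesky(J)
    expect_equal(M %*% J %*% t(M), diag(3), tolerance = 1e-8)
    expect_true(all(abs(M[upper.tri(M)]) < 1e-12))   # lower triangular
  }
  expect_error(inv_sqrt_cholesky(matrix(c(1, 0, 0, -1), 2)),
               "positive definite")
})

test_that("expectile fit interpolates exactly solvable linear data", {
  fit <- fit_expectile(linear_model(), c(0, 1), c(1, 3), tau = 0.5,
                       control = search_control(polish = TRUE))
  expect_equal(fit$beta_hat, c(1, 2), tolerance = 1e-6)
  expect_equal(fit$objective, 0, tolerance = 1e-10)
  expect_equal(fit$residuals, c(0, 0), tolerance = 1e-6)
})

test_that("tau = 0.5 linear fit equals the least-squares solution", {
  set.seed(7)
  for (i in 1:5) {
    x <- stats::runif(30)
    y <- 1 + 2 * x + stats::rnorm(30, sd = 0.5)
    ols <- as.numeric(stats::coef(stats::lm(y ~ x)))
    fit <- fit_expectile(linear_model(), x, y, tau = 0.5,
                         control = search_control(polish = TRUE))
    expect_equal(fit$beta_hat, ols, tolerance = 1e-5)
  }
})

test_that("intercept-only fit recovers the sample expectile at any tau", {
  expect_equal(
    fit_expectile(intercept_model(), rep(0, 4), c(0, 0, 0, 1), tau = 0.5,
                  control = search_control(polish = TRUE))$beta_hat,
    0.25, tolerance = 1e-6)
  set.seed(8)
  y <- stats::rnorm(40)
  for (tau in c(0.1, 0.35, 0.5, 0.8)) {
    fit <- fit_expectile(intercept_model(), rep(0, 40), y, tau = tau,
                         control = search_control(polish = TRUE))
    expect_equal(fit$beta_hat, scalar_expectile(y, tau), tolerance = 1e-6)
  }
})

test_that("fit assembles internally consistent plug-in quantities", {
  set.seed(9)
  x <- stats::runif(60)
  y <- gompertz2_curve(x, c(10, 5)) + stats::rnorm(60, sd = 0.3)
  fit <- fit_expectile(gompertz2_model(), x, y, tau = 0.5)
  expect_equal(fit$residuals,
               y - gompertz2_curve(x, fit$beta_hat), tolerance = 1e-12)
  expect_equal(fit$J_m, fit$var_g * fit$V_m, tolerance = 1e-12)
  expect_equal(fit$J_inv_sqrt %*% fit$J_m %*% t(fit$J_inv_sqrt), diag(2),
               tolerance = 1e-8)
  expect_true(isSymmetric(fit$J_m, tol = 1e-10))
  expect_true(all(eigen(fit$J_m, only.values = TRUE)$values > 0))
})

test_that("estimated tau satisfies the empirical moment condition at the fit", {
  set.seed(10)
  x <- stats::runif(120)
  y <- gompertz2_curve(x, c(10, 5)) + stats::rnorm(120, 1, 1)
  fit <- fit_expectile(gompertz2_model(), x, y, tau = "estimate")
  expect_true(fit$tau > 0 && fit$tau < 1)
  expect_equal(mean(g_tau(fit$tau, fit$residuals)), 0, tolerance = 1e-8)
})

test_that("fit rejects degenerate inputs", {
  expect_error(fit_expectile(linear_model(), 1, 2), "at least")
  expect_error(fit_expectile(linear_model(), c(0, 1), c(1, NA)),
               "non-finite")
  expect_error(fit_expectile(linear_model(), c(0, 1), c(1, 2), tau = 1.2),
               "tau")
})

test_that("fits survive a JSON round trip", {
  set.seed(12)
  x <- stats::runif(40)
  y <- gompertz2_curve(x, c(10, 5)) + stats::rnorm(40, sd = 0.5)
  fit <- fit_expectile(gompertz2_model(), x, y, tau = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  back <- fit_from_json(path)
  expect_equal(back$beta_hat, fit$beta_hat, tolerance = 1e-12)
  expect_equal(back$J_inv_sqrt, fit$J_inv_sqrt, tolerance = 1e-12)
  expect_equal(back$tau, fit$tau)
  expect_equal(back$m, fit$m)
})
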