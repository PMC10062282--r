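test_that("error distributions match their stated moments", {
  set.seed(31)
  for (d in list(error_dist("gaussian", 0, 1), error_dist("gaussian", 1, 1),
                 error_dist("laplace", 0, 1))) {
    x <- d$sample(2e5)
    expect_equal(mean(x), d$mean, tolerance = 0.02)
    expect_equal(stats::var(x), d$variance, tolerance = 0.03)
  }
  # Laplace excess kurtosis is 3 (vs 0 for the normal)
  set.seed(32)
  xl <- error_dist("laplace", 0, 1)$sample(2e5)
  expect_equal(mean(xl^4) / stats::var(xl)^2, 6, tolerance = 0.25)
})

test_that("design derives horizons, limit ranges and change indices", {
  mod <- gompertz2_model()
  d1 <- sim_design(mod, c(10, 5), m = 200, horizon_rule = "fixed10",
                   k0_rule = "none", n_reps = 10)
  expect_equal(d1$T_m, 10L)
  expect_equal(d1$L, (10 / 200) / (1 + 10 / 200))
  d2 <- sim_design(mod, c(10, 5), beta1 = c(10, 10), m = 200,
                   horizon_rule = "half_m", k0_rule = "immediate",
                   n_reps = 10)
  expect_equal(d2$T_m, 100L)
  expect_equal(d2$k_change, 1L)
  expect_equal(d2$L, 0.5 / 1.5)
  d3 <- sim_design(mod, c(10, 5), beta1 = c(10, 10), m = 200,
                   horizon_rule = "m_log_m", k0_rule = "midpoint",
                   n_reps = 10)
  expect_equal(d3$T_m, as.integer(floor(200 * log(200))))
  expect_true(d3$open_end)
  expect_equal(d3$L, 1)
  expect_equal(d3$k_change, as.integer(floor(d3$T_m / 2) + 1L))
  expect_error(sim_design(mod, c(10, 5), m = 200, k0_rule = "immediate",
                          n_reps = 10), "beta1")
  expect_error(sim_design(mod, c(10, 5), beta1 = c(10, 10), m = 200,
                          k0_rule = "none", n_reps = 10), "absent")
})

test_that("generated datasets are reproducible and honor the change index", {
  mod <- gompertz2_model()
  des <- sim_design(mod, c(10, 5), beta1 = c(10, 10), m = 30,
                    horizon_rule = "fixed10", k0_rule = "midpoint",
                    n_reps = 5, seed = 1)
  d1 <- gen_dataset(des, 42L)
  d2 <- gen_dataset(des, 42L)
  expect_identical(d1, d2)
  expect_equal(dim(d1$X_hist), c(30L, 1L))
  expect_equal(length(d1$Y_online), 10L)

  # noiseless: online block matches direct evaluation under beta0 / beta1
  quiet <- error_dist("gaussian", 0, 1e-20)
  des0 <- sim_design(mod, c(10, 5), beta1 = c(10, 10), m = 20,
                     horizon_rule = "fixed10", k0_rule = "midpoint",
                     dist = quiet, n_reps = 5, seed = 1)
  d <- gen_dataset(des0, 7L)
  kc <- des0$k_change
  pre <- seq_len(kc - 1L)
  post <- kc:des0$T_m
  expect_equal(d$Y_online[pre],
               eval_model(mod, d$X_online[pre, , drop = FALSE], c(10, 5)),
               tolerance = 1e-8)
  expect_equal(d$Y_online[post],
               eval_model(mod, d$X_online[post, , drop = FALSE], c(10, 10)),
               tolerance = 1e-8)

  # no change rule: everything under beta0
  desn <- sim_design(mod, c(10, 5), m = 20, horizon_rule = "fixed10",
                     k0_rule = "none", dist = quiet, n_reps = 5, seed = 1)
  dn <- gen_dataset(desn, 7L)
  expect_equal(dn$Y_online, eval_model(mod, dn$X_online, c(10, 5)),
               tolerance = 1e-8)
})

test_that("an infinite threshold yields zero rejections", {
  des <- sim_design(gompertz2_model(), c(10, 5), m = 25,
                    horizon_rule = "fixed10", k0_rule = "none",
                    n_reps = 8, seed = 3)
  res <- run_level_experiment(des, threshold = Inf)
  expect_equal(res$rejection_rate, 0)
  expect_true(all(!is.finite(res$k_hats)))
})

test_that("a noiseless immediate large shift is caught at the first observation", {
  quiet <- error_dist("gaussian", 0, 1e-12)
  des <- sim_design(gompertz2_model(), c(10, 5), beta1 = c(10, 15), m = 40,
                    horizon_rule = "fixed10", k0_rule = "immediate",
                    dist = quiet, n_reps = 6, seed = 4)
  res <- run_power_experiment(des, threshold = 2.5)
  expect_equal(res$rejection_rate, 1)
  expect_true(all(res$k_hats == 1))
  expect_equal(res$mean_location, 0)
})

test_that("degenerate beta1 = beta0 power run behaves like a level run", {
  mod <- gompertz2_model()
  base <- list(model = mod, beta0 = c(10, 5), m = 30,
               horizon_rule = "fixed10", n_reps = 25, seed = 5)
  lev <- run_level_experiment(
    do.call(sim_design, c(base, list(k0_rule = "none"))), threshold = 2)
  pow <- run_power_experiment(
    do.call(sim_design, c(base, list(k0_rule = "immediate",
                                     beta1 = c(10, 5)))), threshold = 2)
  # same seeds, same data, same detector: identical stopping behavior
  expect_identical(lev$k_hats, pow$k_hats)
})

test_that("midpoint-rule detections are confined to the second half", {
  set.seed(6)
  des <- sim_design(gompertz2_model(), c(10, 5), beta1 = c(10, 10), m = 50,
                    horizon_rule = "half_m", k0_rule = "midpoint",
                    n_reps = 30, seed = 6)
  res <- run_power_experiment(des, threshold = 1.5)
  det <- is.finite(res$k_hats)
  if (any(det)) {
    expect_true(all(res$k_hats[det] > floor(des$T_m / 2)))
    expect_gt(res$mean_location, 0.5)
    expect_gt(res$median_location, 0.5)
  }
})
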