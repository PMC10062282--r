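#' Error distribution for synthetic data
#'
#' The three error laws of the Monte-Carlo experiments: a symmetric standard
#' normal, an asymmetric normal with mean one and variance one (for which
#' the moment condition forces an asymmetry index far from 1/2), and a
#' heavy-tailed Laplace with zero mean and unit variance (scale
#' \eqn{b = \sqrt{variance/2}}).
#'
#' @param family \code{"gaussian"} or \code{"laplace"}.
#' @param mean Error mean.
#' @param variance Error variance (positive).
#' @return A list of class \code{error_dist} with a \code{$sample(n)} draw
#'   function.
#' @export
error_dist <- function(family = c("gaussian", "laplace"), mean = 0,
                       variance = 1) {
  family <- match.arg(family)
  stopifnot(is.finite(mean), variance > 0)
  sample_fun <- switch(
    family,
    gaussian = function(n) stats::rnorm(n, mean = mean, sd = sqrt(variance)),
    laplace = {
      b <- sqrt(variance / 2)
      function(n) mean + b * (stats::rexp(n) - stats::rexp(n))
    })
  structure(list(family = family, mean = mean, variance = variance,
                 sample = sample_fun),
            class = "error_dist")
}

#' Specify one Monte-Carlo experiment cell
#'
#' One cell of the level or power study: a model with true parameters, a
#' historical sample size, a horizon rule, a changepoint rule, and the test
#' settings. Horizons follow the three study scenarios: a short fixed
#' horizon \eqn{T_m = 10} and \eqn{T_m = \lfloor m/2 \rfloor} are monitored
#' closed-end (limit range \eqn{T_m/m / (1 + T_m/m)}), while the long
#' horizon \eqn{T_m = \lfloor m \ln m \rfloor} mimics open-end monitoring
#' (limit range 1).
#'
#' @param model A [model_spec()].
#' @param beta0 True pre-change parameter vector.
#' @param beta1 Post-change parameter vector (required unless
#'   \code{k0_rule = "none"}).
#' @param m Historical sample size.
#' @param horizon_rule \code{"fixed10"}, \code{"half_m"} or
#'   \code{"m_log_m"}.
#' @param k0_rule \code{"none"} (no change; level experiment),
#'   \code{"immediate"} (every online observation already post-change) or
#'   \code{"midpoint"} (first post-change observation at online index
#'   \eqn{\lfloor T_m/2 \rfloor + 1}).
#' @param dist An [error_dist()].
#' @param gamma Boundary exponent in [0, 1/2).
#' @param alpha Nominal test level.
#' @param tau Asymmetry index in (0, 1), or \code{"estimate"} to re-estimate
#'   it per replication from the historical residuals.
#' @param n_reps Monte-Carlo replications.
#' @param seed Master seed; per-replication seeds are derived from it by a
#'   counter.
#' @param design_points \code{"uniform"} for i.i.d. Uniform(0,1) covariates
#'   (the study default) or \code{"equispaced"}.
#' @param control A [search_control()] for the per-replication fits.
#' @return A list of class \code{sim_design} (with derived fields
#'   \code{T_m}, \code{open_end}, \code{L}, \code{k_change}).
#' @export
sim_design <- function(model, beta0, beta1 = NULL, m,
                       horizon_rule = c("half_m", "fixed10", "m_log_m"),
                       k0_rule = c("none", "immediate", "midpoint"),
                       dist = error_dist("gaussian"),
                       gamma = 0.1, alpha = 0.05, tau = 0.5,
                       n_reps = 1000L, seed = 1L,
                       design_points = c("uniform", "equispaced"),
                       control = search_control()) {
  stopifnot(inherits(model, "model_spec"), inherits(dist, "error_dist"),
            m >= model$p, n_reps >= 1L)
  horizon_rule <- match.arg(horizon_rule)
  k0_rule <- match.arg(k0_rule)
  design_points <- match.arg(design_points)
  check_gamma(gamma)
  beta0 <- check_beta(model, beta0)
  if (k0_rule != "none") {
    if (is.null(beta1)) stop("'beta1' is required when a change is simulated")
    beta1 <- check_beta(model, beta1)
  } else if (!is.null(beta1))
    stop("'beta1' must be absent for the no-change (level) design")
  T_m <- switch(horizon_rule,
                fixed10 = 10L,
                half_m = as.integer(floor(m / 2)),
                m_log_m = as.integer(floor(m * log(m))))
  open_end <- horizon_rule == "m_log_m"
  k_change <- switch(k0_rule,
                     none = NA_integer_,
                     immediate = 1L,
                     midpoint = as.integer(floor(T_m / 2) + 1L))
  structure(
    list(model = model, beta0 = beta0, beta1 = beta1, m = as.integer(m),
         horizon_rule = horizon_rule, T_m = T_m, open_end = open_end,
         L = L_of_T(T_m / m, closed_end = !open_end),
         k0_rule = k0_rule, k_change = k_change, dist = dist,
         gamma = gamma, alpha = alpha, tau = tau,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         design_points = design_points, control = control),
    class = "sim_design")
}

rep_seed_for <- function(seed, rep) {
  as.integer((as.numeric(seed) %% 65521 * 1000003 + rep) %% 2147483647 + 1)
}

#' Generate one synthetic dataset
#'
#' Draws the historical block \eqn{Y_i = f(x_i, \beta^0) + \varepsilon_i}
#' (\eqn{i = 1, \dots, m}) and the online block of \eqn{T_m} observations;
#' under a change design, online observations with index \eqn{\ge k_{change}}
#' are generated under \eqn{\beta^1}, earlier ones under \eqn{\beta^0}.
#' Identical \code{rep_seed} gives bitwise-identical output.
#'
#' @param design A [sim_design()].
#' @param rep_seed Integer seed for this replication.
#' @return List with \code{X_hist}, \code{Y_hist}, \code{X_online},
#'   \code{Y_online}, \code{k_change}.
#' @export
gen_dataset <- function(design, rep_seed) {
  stopifnot(inherits(design, "sim_design"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rep_seed)
  m <- design$m; T_m <- design$T_m
  draw_x <- function(n) {
    if (design$design_points == "uniform") stats::runif(n)
    else seq(0, 1, length.out = n + 2L)[2:(n + 1L)]
  }
  X_hist <- matrix(draw_x(m), ncol = 1L)
  X_online <- matrix(draw_x(T_m), ncol = 1L)
  mu_online <- eval_model(design$model, X_online, design$beta0)
  if (design$k0_rule != "none") {
    post <- seq_len(T_m) >= design$k_change
    if (any(post))
      mu_online[post] <- eval_model(design$model,
                                    X_online[post, , drop = FALSE],
                                    design$beta1)
  }
  list(X_hist = X_hist,
       Y_hist = eval_model(design$model, X_hist, design$beta0) +
         design$dist$sample(m),
       X_online = X_online,
       Y_online = mu_online + design$dist$sample(T_m),
       k_change = design$k_change)
}

run_experiment <- function(design, threshold = NULL, threshold_paths = 2e4,
                           threshold_grid = 1e4) {
  p <- design$model$p
  if (is.null(threshold))
    threshold <- critical_value(
      p = p, gamma = design$gamma, L = design$L, alpha = design$alpha,
      n_paths = threshold_paths, n_grid = threshold_grid,
      seed = rep_seed_for(design$seed, 0L))
  half <- floor(design$T_m / 2)
  discard_first_half <- design$k0_rule == "midpoint"

  betas <- matrix(NA_real_, design$n_reps, p)
  taus <- numeric(design$n_reps)
  k_hats <- rep(Inf, design$n_reps)
  for (r in seq_len(design$n_reps)) {
    d <- gen_dataset(design, rep_seed_for(design$seed, r))
    fit <- fit_expectile(design$model, d$X_hist, d$Y_hist, tau = design$tau,
                         control = design$control)
    betas[r, ] <- fit$beta_hat
    taus[r] <- fit$tau
    if (discard_first_half) {
      # exceedances before the midpoint change are false alarms: scan the
      # full path and keep the first exceedance after T_m/2 only
      res <- run_monitor(fit, d$X_online, d$Y_online, gamma = design$gamma,
                         threshold = Inf)
      later <- which(res$stat_path > threshold &
                       seq_along(res$stat_path) > half)
      k <- if (length(later)) later[1L] else Inf
    } else {
      res <- run_monitor(fit, d$X_online, d$Y_online, gamma = design$gamma,
                         threshold = threshold)
      k <- res$k_hat
    }
    k_hats[r] <- k
  }
  detected <- is.finite(k_hats)
  loc <- if (design$k0_rule == "none" || !any(detected)) NULL
  else (k_hats[detected] - 1) / (design$T_m - 1)
  structure(
    list(design = design, threshold = threshold,
         rejection_rate = mean(detected),
         est_mean = colMeans(betas), est_sd = apply(betas, 2L, stats::sd),
         tau_mean = mean(taus),
         mean_location = if (is.null(loc)) NA_real_ else mean(loc),
         median_location = if (is.null(loc)) NA_real_ else stats::median(loc),
         k_hats = k_hats, n_valid = design$n_reps),
    class = "sim_result")
}

#' Monte-Carlo level experiment (no change)
#'
#' Runs \code{n_reps} replications of generate / fit / monitor under the
#' null (no parameter change) and reports the empirical rejection
#' (false-alarm) rate together with the mean and standard deviation of the
#' parameter estimates across replications.
#'
#' @param design A [sim_design()] with \code{k0_rule = "none"}.
#' @param threshold Optional pre-computed critical value; by default it is
#'   simulated once per experiment via [critical_value()].
#' @param threshold_paths,threshold_grid Monte-Carlo size for the critical
#'   value when it is not supplied.
#' @return A \code{sim_result}: \code{rejection_rate}, \code{est_mean},
#'   \code{est_sd}, \code{tau_mean}, \code{threshold}, \code{k_hats}.
#' @export
run_level_experiment <- function(design, threshold = NULL,
                                 threshold_paths = 2e4,
                                 threshold_grid = 1e4) {
  stopifnot(inherits(design, "sim_design"))
  if (design$k0_rule != "none")
    stop("level experiment requires k0_rule = 'none'")
  run_experiment(design, threshold, threshold_paths, threshold_grid)
}

#' Monte-Carlo power experiment (with changepoint)
#'
#' As [run_level_experiment()] but the online stream contains a parameter
#' change. Under the \code{"midpoint"} rule, exceedances in the first half
#' of the online data (before the change) are false alarms and are
#' discarded: only detections after \eqn{\lfloor T_m/2 \rfloor} count. The
#' result additionally carries the mean and median changepoint location
#' index \eqn{(\hat k_m - 1)/(T_m - 1)} over retained detections (0 = first
#' online observation, 1 = last).
#'
#' @inheritParams run_level_experiment
#' @param design A [sim_design()] with \code{k0_rule != "none"}.
#' @return A \code{sim_result} including \code{mean_location} and
#'   \code{median_location}.
#' @export
run_power_experiment <- function(design, threshold = NULL,
                                 threshold_paths = 2e4,
                                 threshold_grid = 1e4) {
  stopifnot(inherits(design, "sim_design"))
  if (design$k0_rule == "none")
    stop("power experiment requires a changepoint rule")
  run_experiment(design, threshold, threshold_paths, threshold_grid)
}

#' @export
print.sim_result <- function(x, ...) {
  d <- x$design
  cat("Monte-Carlo experiment (", if (d$k0_rule == "none") "level" else
    "power", "): model ", d$model$name, ", m = ", d$m, ", T_m = ", d$T_m,
    ", ", if (d$open_end) "open-end" else "closed-end", "\n", sep = "")
  cat("  reps: ", d$n_reps, "  threshold: ", signif(x$threshold, 5),
      "  (gamma = ", d$gamma, ", alpha = ", d$alpha, ")\n", sep = "")
  cat("  rejection rate: ", sprintf("%.2f%%", 100 * x$rejection_rate), "\n",
      sep = "")
  cat("  beta_hat mean (sd): ",
      paste(sprintf("%.3f (%.3f)", x$est_mean, x$est_sd), collapse = ", "),
      "\n", sep = "")
  if (!identical(d$tau, 0.5))
    cat("  mean tau: ", signif(x$tau_mean, 4), "\n", sep = "")
  if (d$k0_rule != "none" && !is.na(x$mean_location))
    cat("  location index mean | median: ",
        sprintf("%.2f | %.2f", x$mean_location, x$median_location), "\n",
        sep = "")
  invisible(x)
}
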