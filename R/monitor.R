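#' Boundary (regularization) function of the sequential detector
#'
#' \eqn{z(m, k, \gamma) = m^{1/2} (1 + k/m) (k/(k+m))^\gamma}: the
#' deterministic normalizer that keeps the CUSUM-of-scores detector bounded
#' under the null. It is strictly increasing in \code{k}; larger
#' \eqn{\gamma \in [0, 1/2)} sharpens sensitivity to early changes at the
#' price of heavier weighting near \eqn{k = 0}.
#'
#' @param m Historical sample size (positive integer).
#' @param k Online observation count (positive integer, vectorized).
#' @param gamma Boundary exponent in [0, 1/2).
#' @return Numeric vector of normalizer values.
#' @export
z_norm <- function(m, k, gamma) {
  if (m < 1) stop("'m' must be a positive integer")
  if (any(k < 1)) stop("'k' must be a positive integer")
  check_gamma(gamma)
  sqrt(m) * (1 + k / m) * (k / (k + m))^gamma
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0 || gamma >= 0.5)
    stop("'gamma' must lie in [0, 1/2)")
  gamma
}

#' Initialize a monitoring state
#'
#' Freezes a historical fit (parameters, asymmetry index, score variance and
#' the normalizing matrix are all computed from historical data only) and
#' prepares the running cumulative score vector for one-pass online
#' monitoring via [detector_step()].
#'
#' @param fit An [fit_expectile()] result.
#' @param gamma Boundary exponent in [0, 1/2).
#' @param threshold Critical value \eqn{c_\alpha(\gamma)} the running
#'   statistic is compared against (see [critical_value()]); \code{Inf}
#'   monitors without ever stopping.
#' @return An object of class \code{monitor_state}.
#' @export
new_monitor <- function(fit, gamma = 0.1, threshold = Inf) {
  stopifnot(inherits(fit, "expectile_fit"))
  check_gamma(gamma)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("'threshold' must be a single numeric value")
  structure(
    list(fit = fit, m = fit$m, gamma = gamma, threshold = threshold,
         k = 0L, cumsum = numeric(fit$model$p), stat_path = numeric(0),
         stopped_at = NA_integer_),
    class = "monitor_state")
}

#' Advance the detector by one online observation
#'
#' Computes the online residual \eqn{e = y - f(x, \hat\beta_m)}, adds the
#' score \eqn{\nabla f(x, \hat\beta_m) g_{\hat\tau}(e)} to the cumulative
#' score vector, and evaluates the standardized statistic
#' \eqn{\| J_m^{-1/2} \sum_{i=m+1}^{m+k} \nabla f(x_i, \hat\beta_m)
#' g_{\hat\tau}(e_i) \|_\infty / z(m, k, \gamma)}.
#' The update is strictly incremental: after any number of steps the
#' statistic equals a from-scratch batch evaluation of the same prefix.
#'
#' @param state A [new_monitor()] state.
#' @param x Covariate vector for the new observation.
#' @param y Response value.
#' @return Updated \code{monitor_state}; the new statistic value is the last
#'   entry of \code{$stat_path} (and \code{$stat}).
#' @export
detector_step <- function(state, x, y) {
  stopifnot(inherits(state, "monitor_state"))
  if (!is.finite(y) || any(!is.finite(x))) stop("non-finite online observation")
  fit <- state$fit
  X1 <- matrix(as.numeric(x), nrow = 1L)
  e <- y - fit$model$evaluator(as_design(X1, fit$model$q), fit$beta_hat)
  score <- as.numeric(grad_model(fit$model, X1, fit$beta_hat)) *
    g_tau(fit$tau, e)
  state$cumsum <- state$cumsum + score
  state$k <- state$k + 1L
  stat <- if (is.null(fit$J_inv_sqrt)) {
    if (abs(e) > 1e-6 * (1 + abs(y)))
      stop("historical fit is noiseless (zero residual variance); ",
           "the detector is undefined for streams with nonzero residuals")
    0
  } else {
    max(abs(fit$J_inv_sqrt %*% state$cumsum)) /
      z_norm(state$m, state$k, state$gamma)
  }
  state$stat_path <- c(state$stat_path, stat)
  state$stat <- stat
  if (is.na(state$stopped_at) && stat > state$threshold)
    state$stopped_at <- state$k
  state
}

#' Run the sequential changepoint test over an online stream
#'
#' Consumes the online observations in order, computing the standardized
#' CUSUM statistic after each one, and stops at the first exceedance of the
#' threshold (the stopping time \eqn{\hat k_m}). Internally the cumulative
#' scores are accumulated in a single vectorized pass, which is numerically
#' identical to repeated [detector_step()] calls.
#'
#' @param fit An [fit_expectile()] result (all plug-ins frozen from
#'   historical data).
#' @param X Online design matrix (\code{n x q}) or vector for \code{q = 1},
#'   in arrival order.
#' @param Y Online response vector.
#' @param gamma Boundary exponent in [0, 1/2).
#' @param threshold Critical value; \code{Inf} never detects.
#' @param horizon Optional cap \eqn{T_m} on the number of observations
#'   consumed (defaults to all of them).
#' @return An object of class \code{detection_result}: \code{detected},
#'   \code{k_hat} (first exceedance index in online numbering, \code{Inf} if
#'   none), \code{max_stat} (the running supremum statistic up to the
#'   stopping point), \code{stat_path}, \code{threshold}, \code{gamma},
#'   \code{m}.
#' @export
run_monitor <- function(fit, X, Y, gamma = 0.1, threshold, horizon = NULL) {
  stopifnot(inherits(fit, "expectile_fit"))
  check_gamma(gamma)
  Y <- as.numeric(Y)
  if (length(Y) == 0L) stop("empty online stream")
  X <- as_design(X, fit$model$q)
  if (nrow(X) != length(Y)) stop("X and Y disagree on the stream length")
  if (!is.null(horizon)) {
    if (horizon < 1) stop("'horizon' must be a positive integer")
    n <- min(length(Y), as.integer(horizon))
    X <- X[seq_len(n), , drop = FALSE]
    Y <- Y[seq_len(n)]
  }
  n <- length(Y)
  e <- Y - fit$model$evaluator(X, fit$beta_hat)
  if (any(!is.finite(e))) stop("non-finite online residuals")
  if (is.null(fit$J_inv_sqrt)) {
    if (any(abs(e) > 1e-6 * (1 + abs(Y))))
      stop("historical fit is noiseless (zero residual variance); ",
           "the detector is undefined for streams with nonzero residuals")
    return(structure(
      list(detected = FALSE, k_hat = Inf, max_stat = 0,
           stat_path = numeric(n), threshold = threshold, gamma = gamma,
           m = fit$m),
      class = "detection_result"))
  }
  scores <- grad_model(fit$model, X, fit$beta_hat) * g_tau(fit$tau, e)
  cums <- apply(scores, 2L, cumsum)
  if (n == 1L) cums <- matrix(cums, nrow = 1L)
  S <- abs(tcrossprod(cums, fit$J_inv_sqrt))     # n x p
  sup_abs <- S[, 1L]
  for (j in seq_len(ncol(S))[-1L]) sup_abs <- pmax(sup_abs, S[, j])
  stat <- sup_abs / z_norm(fit$m, seq_len(n), gamma)
  hit <- which(stat > threshold)
  if (length(hit)) {
    k_hat <- hit[1L]
    stat <- stat[seq_len(k_hat)]
  } else k_hat <- Inf
  structure(
    list(detected = is.finite(k_hat), k_hat = k_hat,
         max_stat = max(stat), stat_path = stat,
         threshold = threshold, gamma = gamma, m = fit$m),
    class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("Sequential expectile changepoint test (m = ", x$m, ", gamma = ",
      x$gamma, ")\n", sep = "")
  cat("  observations monitored: ", length(x$stat_path), "\n", sep = "")
  cat("  max statistic T(m): ", signif(x$max_stat, 6),
      "  threshold: ", signif(x$threshold, 6), "\n", sep = "")
  if (x$detected)
    cat("  CHANGE DETECTED at online index k_hat = ", x$k_hat,
        " (absolute index ", x$m + x$k_hat, ")\n", sep = "")
  else
    cat("  no change detected (k_hat = infinity)\n")
  invisible(x)
}
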