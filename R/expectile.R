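#' Expectile loss and its derivatives
#'
#' The asymmetric squared (expectile) loss
#' \eqn{\rho_\tau(x) = |\tau - 1\{x < 0\}| x^2} with asymmetry index
#' \eqn{\tau \in (0,1)}, its first derivative
#' \eqn{g_\tau(x) = 2\tau x} for \eqn{x \ge 0} and \eqn{2(1-\tau)x} for
#' \eqn{x < 0}, and its second derivative
#' \eqn{h_\tau(x) = 2\tau} for \eqn{x \ge 0} and \eqn{2(1-\tau)} otherwise.
#' At \eqn{\tau = 1/2} the loss is half the squared error, \eqn{g} is the
#' identity and \eqn{h \equiv 1}: minimizing it reproduces least squares.
#' The boundary \eqn{x = 0} belongs to the nonnegative branch.
#'
#' @param tau Asymmetry index in (0, 1).
#' @param x Numeric vector of residuals.
#' @return Numeric vector of the same length as \code{x}.
#' @name expectile_loss
NULL

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1)
    stop("'tau' must be a single number strictly between 0 and 1")
  tau
}

#' @rdname expectile_loss
#' @export
rho_tau <- function(tau, x) {
  check_tau(tau)
  abs(tau - (x < 0)) * x^2
}

#' @rdname expectile_loss
#' @export
g_tau <- function(tau, x) {
  check_tau(tau)
  2 * ifelse(x >= 0, tau * x, (1 - tau) * x)
}

#' @rdname expectile_loss
#' @export
h_tau <- function(tau, x) {
  check_tau(tau)
  2 * ifelse(x >= 0, tau, 1 - tau)
}

#' Estimate the expectile index from residuals
#'
#' Returns the \eqn{\tau} at which the empirical moment condition
#' \eqn{m^{-1} \sum_i g_\tau(e_i) = 0} holds. Because the sum is linear in
#' \eqn{\tau}, the root has the closed form \eqn{\tau = -B / (A - B)} with
#' \eqn{A = \sum_{e_i \ge 0} e_i} and \eqn{B = \sum_{e_i < 0} e_i}; the
#' moment condition is satisfied exactly at the returned value.
#'
#' @param residuals Numeric vector containing at least one strictly positive
#'   and one strictly negative value (otherwise no root exists in (0, 1)).
#' @return The estimated index, a number in (0, 1).
#' @export
tau_hat <- function(residuals) {
  e <- as.numeric(residuals)
  if (any(!is.finite(e))) stop("non-finite residuals")
  A <- sum(e[e >= 0])
  B <- sum(e[e < 0])
  if (A <= 0 || B >= 0)
    stop("the expectile index is undefined: residuals must take both signs")
  -B / (A - B)
}

#' Sample variance of the score g_tau(residual)
#'
#' The plug-in estimate \eqn{S^2 = (m-1)^{-1} \sum_i g_\tau(e_i)^2} of
#' \eqn{Var[g_\tau(\varepsilon)]}, used to scale the detector's normalizing
#' matrix. When \eqn{\tau} solves the empirical moment condition the scores
#' have mean zero, so no centering term appears.
#'
#' @param residuals Numeric vector of length at least 2.
#' @param tau Asymmetry index in (0, 1).
#' @return Nonnegative scalar.
#' @export
var_g <- function(residuals, tau) {
  e <- as.numeric(residuals)
  if (length(e) < 2L) stop("need at least two residuals")
  sum(g_tau(tau, e)^2) / (length(e) - 1L)
}

#' Gradient cross-product and normalizing matrices
#'
#' \code{V_matrix} computes \eqn{V_m(\beta) = m^{-1} \sum_i \nabla f(x_i,
#' \beta) \nabla^\top f(x_i, \beta)}; \code{J_matrix} scales it by the score
#' variance, \eqn{J_m = S^2 \cdot V_m}, the matrix whose Cholesky inverse
#' square root standardizes the detector.
#'
#' @param model A [model_spec()].
#' @param X Design matrix.
#' @param beta Parameter vector.
#' @param var_g Nonnegative score-variance scalar.
#' @return A symmetric positive semi-definite \code{p x p} matrix.
#' @export
V_matrix <- function(model, X, beta) {
  G <- grad_model(model, X, beta)
  crossprod(G) / nrow(G)
}

#' @rdname V_matrix
#' @export
J_matrix <- function(model, X, beta, var_g) {
  if (var_g < 0) stop("'var_g' must be nonnegative")
  var_g * V_matrix(model, X, beta)
}

#' Inverse of the lower Cholesky factor of an SPD matrix
#'
#' For \eqn{J = L L^\top} (lower Cholesky) returns \eqn{M = L^{-1}}, so that
#' \eqn{M J M^\top = I}. If the factorization fails, one ridge of
#' \code{1e-10 * trace(J)/p} is added to the diagonal before failing loudly.
#'
#' @param J Symmetric positive definite matrix.
#' @return Lower-triangular matrix \eqn{L^{-1}}.
#' @export
inv_sqrt_cholesky <- function(J) {
  J <- as.matrix(J)
  p <- nrow(J)
  if (ncol(J) != p || any(abs(J - t(J)) > 1e-8 * (1 + max(abs(J)))))
    stop("'J' must be a symmetric square matrix")
  R <- tryCatch(chol(J), error = function(e) {
    ridge <- 1e-10 * sum(diag(J)) / p
    tryCatch(chol(J + diag(ridge, p)), error = function(e2)
      stop("matrix is not positive definite (even after ridge)"))
  })
  # J = t(R) %*% R, so L = t(R) and M = L^{-1}
  forwardsolve(t(R), diag(p))
}

#' Grid-search control parameters
#'
#' Settings for the iterative grid search that minimizes the empirical
#' expectile risk. Each stage lays a regular grid of \code{n_points} per
#' dimension, centered on the incumbent, with a span shrunk by \code{shrink}
#' relative to the previous stage and clipped to the parameter box; the
#' search stops early once the per-coordinate grid step falls below
#' \code{step_tol} times the box width.
#'
#' @param n_stages Number of refinement stages (default 3).
#' @param n_points Grid points per dimension per stage (default 41).
#' @param shrink Span contraction factor between stages (default 0.12).
#' @param step_tol Relative step size below which refinement stops
#'   (default 1e-3).
#' @param polish If \code{TRUE}, run a derivative-based local optimization
#'   (box-constrained quasi-Newton on the smooth risk) from the grid
#'   incumbent. Off by default.
#' @return A list of class \code{search_control}.
#' @export
search_control <- function(n_stages = 3L, n_points = 41L, shrink = 0.12,
                           step_tol = 1e-3, polish = FALSE) {
  stopifnot(n_stages >= 1L, n_points >= 3L, shrink > 0, shrink < 1,
            step_tol > 0)
  structure(list(n_stages = as.integer(n_stages),
                 n_points = as.integer(n_points),
                 shrink = shrink, step_tol = step_tol,
                 polish = isTRUE(polish)),
            class = "search_control")
}

# Objective values for a G x p matrix of candidates; chunked so the n x G
# intermediate never exceeds ~5e6 cells.
grid_objective <- function(model, X, Y, tau, B) {
  n <- length(Y)
  G <- nrow(B)
  out <- numeric(G)
  block <- max(1L, floor(5e6 / n))
  start <- 1L
  while (start <= G) {
    idx <- start:min(G, start + block - 1L)
    FV <- if (!is.null(model$eval_grid)) model$eval_grid(X, B[idx, , drop = FALSE])
    else vapply(idx, function(g) model$evaluator(X, B[g, ]), numeric(n))
    E <- Y - FV
    E2 <- E * E
    nG <- length(idx)
    # |tau - I(E<0)| = tau + (1-2*tau) * I(E<0)
    out[idx] <- tau * .colSums(E2, n, nG) +
      (1 - 2 * tau) * .colSums(E2 * (E < 0), n, nG)
    start <- start + block
  }
  out
}

grid_search <- function(model, X, Y, tau, control) {
  box <- model$param_box
  p <- model$p
  width <- box[, 2L] - box[, 1L]
  center <- rowMeans(box)
  span <- width
  best <- center
  best_obj <- Inf
  for (s in seq_len(control$n_stages)) {
    axes <- lapply(seq_len(p), function(j) {
      g <- seq(center[j] - span[j] / 2, center[j] + span[j] / 2,
               length.out = control$n_points)
      unique(pmin(pmax(g, box[j, 1L]), box[j, 2L]))
    })
    B <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    obj <- grid_objective(model, X, Y, tau, B)
    i <- which.min(obj)
    if (obj[i] < best_obj) {
      best_obj <- obj[i]
      best <- B[i, ]
    }
    center <- best
    step_used <- span / (control$n_points - 1L)
    if (all(step_used < control$step_tol * width)) break
    span <- span * control$shrink
  }
  if (control$polish) {
    fn <- function(b) sum(rho_tau(tau, Y - model$evaluator(X, b)))
    gr <- function(b) {
      e <- Y - model$evaluator(X, b)
      -colSums(grad_model(model, X, b) * g_tau(tau, e))
    }
    opt <- tryCatch(
      stats::optim(best, fn, gr, method = "L-BFGS-B",
                   lower = box[, 1L], upper = box[, 2L]),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value <= best_obj) {
      best <- opt$par
      best_obj <- opt$value
    }
  }
  list(beta = as.numeric(best), objective = best_obj)
}

#' Fit a nonlinear expectile regression on historical data
#'
#' Minimizes the empirical expectile risk \eqn{\sum_{i=1}^m \rho_\tau(Y_i -
#' f(x_i, \beta))} over the model's parameter box by an iterative grid
#' search (see [search_control()]), then assembles every plug-in quantity the
#' sequential detector needs: residuals, the score variance \eqn{S^2}, the
#' gradient cross-product \eqn{V_m}, the normalizer \eqn{J_m = S^2 V_m} and
#' its Cholesky inverse square root.
#'
#' When \code{tau = "estimate"} the asymmetry index is estimated jointly with
#' the parameters: the fit alternates between minimizing at the current
#' \eqn{\tau} and re-solving the moment condition \eqn{\sum_i g_\tau(e_i) =
#' 0} on the new residuals ([tau_hat()]), starting from \eqn{\tau = 1/2},
#' until the index moves by less than \code{1e-4} (at most 20 rounds).
#'
#' @param model A [model_spec()].
#' @param X Design matrix (\code{m x q}) or vector for \code{q = 1}.
#' @param Y Response vector of length \code{m >= p}.
#' @param tau Asymmetry index in (0, 1), or \code{"estimate"}.
#' @param control A [search_control()].
#' @return An object of class \code{expectile_fit} with components
#'   \code{beta_hat}, \code{tau}, \code{tau_estimated}, \code{residuals},
#'   \code{var_g}, \code{V_m}, \code{J_m}, \code{J_inv_sqrt},
#'   \code{objective}, \code{m}, \code{model}, \code{control}. A fit that
#'   interpolates the data exactly (zero residual variance) is flagged
#'   \code{degenerate} and carries no \code{J_inv_sqrt}; it can only
#'   monitor residual-free streams.
#' @export
fit_expectile <- function(model, X, Y, tau = 0.5, control = search_control()) {
  stopifnot(inherits(model, "model_spec"))
  Y <- as.numeric(Y)
  if (any(!is.finite(Y))) stop("non-finite response values")
  X <- as_design(X, model$q)
  if (nrow(X) != length(Y)) stop("X and Y disagree on the sample size")
  m <- length(Y)
  if (m < model$p) stop("need at least p = ", model$p, " observations")

  estimate_tau <- identical(tau, "estimate")
  cur_tau <- if (estimate_tau) 0.5 else check_tau(tau)
  sol <- grid_search(model, X, Y, cur_tau, control)
  resid <- Y - model$evaluator(X, sol$beta)
  if (estimate_tau) {
    # Alternate fitting with re-solving the moment condition. The first fit
    # is the full grid search; refits continue from the incumbent with the
    # box-constrained quasi-Newton step (same objective, warm start), which
    # tracks the slowly moving optimum as tau drifts.
    box <- model$param_box
    for (it in seq_len(20L)) {
      new_tau <- tau_hat(resid)
      if (abs(new_tau - cur_tau) < 1e-4) {
        cur_tau <- new_tau
        break
      }
      cur_tau <- new_tau
      fn <- function(b) sum(rho_tau(cur_tau, Y - model$evaluator(X, b)))
      gr <- function(b) {
        e <- Y - model$evaluator(X, b)
        -colSums(grad_model(model, X, b) * g_tau(cur_tau, e))
      }
      opt <- tryCatch(
        stats::optim(sol$beta, fn, gr, method = "L-BFGS-B",
                     lower = box[, 1L], upper = box[, 2L]),
        error = function(e) NULL)
      if (!is.null(opt) && all(is.finite(opt$par)))
        sol <- list(beta = as.numeric(opt$par), objective = opt$value)
      resid <- Y - model$evaluator(X, sol$beta)
    }
    # keep (tau, residuals) mutually consistent even if the round cap hit
    cur_tau <- tau_hat(resid)
  }

  s2 <- var_g(resid, cur_tau)
  Vm <- V_matrix(model, X, sol$beta)
  Jm <- s2 * Vm
  # an (near-)interpolating fit has no residual variance: the normalizer is
  # singular and the detector is only defined for residual-free streams
  degenerate <- s2 <= 1e-10 * (1 + stats::var(Y))
  structure(
    list(beta_hat = sol$beta, tau = cur_tau, tau_estimated = estimate_tau,
         residuals = resid, var_g = s2, V_m = Vm, J_m = Jm,
         J_inv_sqrt = if (degenerate) NULL else inv_sqrt_cholesky(Jm),
         degenerate = degenerate, objective = sol$objective,
         m = m, model = model, control = control),
    class = "expectile_fit")
}

#' @export
print.expectile_fit <- function(x, ...) {
  cat("Expectile regression fit (model: ", x$model$name, ", m = ", x$m,
      ")\n", sep = "")
  cat("  beta_hat: ", paste(signif(x$beta_hat, 6), collapse = ", "), "\n",
      sep = "")
  cat("  tau: ", signif(x$tau, 4),
      if (x$tau_estimated) " (estimated via the moment condition)" else
        " (fixed)", "\n", sep = "")
  cat("  score variance S^2: ", signif(x$var_g, 6), "\n", sep = "")
  cat("  objective: ", signif(x$objective, 6), "\n", sep = "")
  invisible(x)
}

#' Population linearization ingredients
#'
#' Bundles \eqn{E[h_\tau(\varepsilon)]} and the limiting gradient
#' cross-product \eqn{V(\beta^0)} into the matrix \eqn{\Omega =
#' E[h_\tau(\varepsilon)] V(\beta^0)} that drives the first-order
#' (Bahadur-type) expansion of the expectile estimator,
#' \eqn{\hat\beta_m \approx \beta^0 + \Omega^{-1} m^{-1} \sum_i \nabla
#' f(x_i, \beta^0) g_\tau(\varepsilon_i)}.
#'
#' @param E_h Expected second derivative of the loss at a generic error,
#'   \eqn{2\tau P(\varepsilon \ge 0) + 2(1-\tau) P(\varepsilon < 0)}.
#' @param V0 Limiting \code{p x p} gradient cross-product matrix.
#' @return List with components \code{E_h}, \code{V0}, \code{Omega}.
#' @export
asymptotic_approx <- function(E_h, V0) {
  stopifnot(is.numeric(E_h), length(E_h) == 1L, E_h > 0)
  V0 <- as.matrix(V0)
  list(E_h = E_h, V0 = V0, Omega = E_h * V0)
}

#' Serialize / restore a fit as JSON
#'
#' Round-trips every quantity monitoring needs. Only fits of built-in models
#' can be restored (the model is stored by name).
#'
#' @param fit An \code{expectile_fit}.
#' @param path File path; for \code{fit_to_json}, where to write.
#' @return \code{fit_from_json} returns the restored \code{expectile_fit}.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "expectile_fit"))
  obj <- list(
    model = fit$model$name, beta_hat = fit$beta_hat, tau = fit$tau,
    tau_estimated = fit$tau_estimated, residuals = fit$residuals,
    var_g = fit$var_g, V_m = fit$V_m, J_m = fit$J_m,
    J_inv_sqrt = fit$J_inv_sqrt, degenerate = isTRUE(fit$degenerate),
    objective = fit$objective, m = fit$m,
    control = unclass(fit$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_to_json
#' @export
fit_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- get_model(obj$model)
  ctl <- do.call(search_control, as.list(obj$control))
  structure(
    list(beta_hat = as.numeric(obj$beta_hat), tau = obj$tau,
         tau_estimated = isTRUE(obj$tau_estimated),
         residuals = as.numeric(obj$residuals), var_g = obj$var_g,
         V_m = as.matrix(obj$V_m), J_m = as.matrix(obj$J_m),
         J_inv_sqrt = if (length(obj$J_inv_sqrt) == 0L) NULL else
           as.matrix(obj$J_inv_sqrt),
         degenerate = isTRUE(obj$degenerate), objective = obj$objective,
         m = as.integer(obj$m), model = model, control = ctl),
    class = "expectile_fit")
}
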