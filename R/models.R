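#' Define a parametric regression model
#'
#' A model specification bundles a mean function \eqn{f(x, \beta)}, its
#' gradient with respect to the parameter vector, and a compact parameter box
#' over which the fitting grid search operates. The response is univariate;
#' covariates are treated as a fixed design.
#'
#' @param name Identifier used in printouts, serialized fits and the CLI.
#' @param p Parameter dimension (positive integer).
#' @param q Covariate dimension (positive integer).
#' @param param_box Numeric \code{p x 2} matrix of finite \code{lower < upper}
#'   bounds, one row per parameter.
#' @param evaluator Function \code{(X, beta)} returning the fitted mean for
#'   each row of the \code{n x q} design matrix \code{X} (an \code{n}-vector).
#' @param gradient Function \code{(X, beta)} returning the \code{n x p} matrix
#'   of partial derivatives \eqn{\partial f/\partial \beta_j}, or \code{NULL}
#'   to fall back on central finite differences.
#' @param eval_grid Optional fast path: function \code{(X, B)} with \code{B} a
#'   \code{G x p} matrix of candidate parameters, returning the \code{n x G}
#'   matrix of fitted means. Used by the grid search when present.
#'
#' @return An object of class \code{model_spec}.
#' @seealso [linear_model()], [gompertz2_model()], [gompertz3_model()]
#' @export
model_spec <- function(name, p, q, param_box, evaluator, gradient = NULL,
                       eval_grid = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            p >= 1L, q >= 1L, is.function(evaluator))
  param_box <- as.matrix(param_box)
  if (!is.numeric(param_box) || nrow(param_box) != p || ncol(param_box) != 2L)
    stop("'param_box' must be a numeric ", p, " x 2 matrix")
  if (any(!is.finite(param_box)))
    stop("'param_box' bounds must be finite")
  if (any(param_box[, 1L] >= param_box[, 2L]))
    stop("'param_box' requires lower < upper in every row")
  structure(
    list(name = name, p = as.integer(p), q = as.integer(q),
         param_box = param_box, evaluator = evaluator, gradient = gradient,
         eval_grid = eval_grid, hessian_available = FALSE),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Parametric regression model: ", x$name,
      " (p = ", x$p, ", q = ", x$q, ")\n", sep = "")
  cat("Parameter box:\n")
  box <- x$param_box
  dimnames(box) <- list(paste0("beta", seq_len(x$p)), c("lower", "upper"))
  print(box)
  cat("Analytic gradient: ", if (is.null(x$gradient)) "no (finite differences)"
      else "yes", "\n", sep = "")
  invisible(x)
}

as_design <- function(X, q) {
  X <- as.matrix(X)
  if (ncol(X) != q) {
    if (ncol(X) == 1L || nrow(X) == 1L) X <- matrix(as.vector(X), ncol = q)
    else stop("design matrix has ", ncol(X), " columns; model expects ", q)
  }
  if (any(!is.finite(X))) stop("non-finite values in the design matrix")
  X
}

check_beta <- function(model, beta) {
  beta <- as.numeric(beta)
  if (length(beta) != model$p)
    stop("'beta' has length ", length(beta), "; model expects ", model$p)
  if (any(!is.finite(beta))) stop("non-finite parameter vector")
  beta
}

#' Evaluate a model's mean function
#'
#' @param model A [model_spec()].
#' @param X Design matrix (\code{n x q}) or a length-\code{q} vector for a
#'   single point.
#' @param beta Parameter vector of length \code{p}.
#' @return Numeric vector of fitted means, one per design row.
#' @export
eval_model <- function(model, X, beta) {
  beta <- check_beta(model, beta)
  X <- as_design(X, model$q)
  f <- model$evaluator(X, beta)
  if (any(!is.finite(f))) stop("model evaluation returned non-finite values")
  as.numeric(f)
}

#' Gradient of the mean function with respect to the parameters
#'
#' Uses the model's analytic gradient when available, otherwise central finite
#' differences via [numeric_gradient()].
#'
#' @inheritParams eval_model
#' @return \code{n x p} matrix of partial derivatives.
#' @export
grad_model <- function(model, X, beta) {
  beta <- check_beta(model, beta)
  X <- as_design(X, model$q)
  if (is.null(model$gradient)) return(numeric_gradient(model, X, beta))
  G <- model$gradient(X, beta)
  G <- matrix(as.numeric(G), nrow = nrow(X), ncol = model$p)
  if (any(!is.finite(G))) stop("model gradient returned non-finite values")
  G
}

#' Central-difference gradient of the mean function
#'
#' Fallback for user-supplied models without an analytic gradient, and the
#' oracle the built-in gradients are tested against.
#'
#' @inheritParams eval_model
#' @param step Finite-difference half-width (default \code{1e-6} times the
#'   parameter scale). The truncation error is \eqn{O(step^2)}.
#' @return \code{n x p} matrix of partial derivatives.
#' @export
numeric_gradient <- function(model, X, beta, step = NULL) {
  beta <- check_beta(model, beta)
  X <- as_design(X, model$q)
  if (is.null(step)) step <- 1e-6 * pmax(abs(beta), 1)
  else {
    if (any(step <= 0)) stop("'step' must be positive")
    step <- rep_len(step, model$p)
  }
  G <- matrix(0, nrow(X), model$p)
  for (j in seq_len(model$p)) {
    bp <- beta; bm <- beta
    bp[j] <- beta[j] + step[j]
    bm[j] <- beta[j] - step[j]
    G[, j] <- (model$evaluator(X, bp) - model$evaluator(X, bm)) / (2 * step[j])
  }
  G
}

#' Built-in models
#'
#' Three ready-made model specifications:
#' \describe{
#'   \item{\code{linear_model()}}{\eqn{f(x, \beta) = \beta_1 + \beta_2 x},
#'     the simple linear regression line.}
#'   \item{\code{gompertz2_model()}}{\eqn{f(x, \beta) = \exp(-\beta_1
#'     e^{-\beta_2 x})}, a two-parameter Gompertz growth curve normalized to
#'     saturation level one; the workhorse of the simulation experiments.}
#'   \item{\code{gompertz3_model()}}{\eqn{f(x, \beta) = K \exp(-\beta_1
#'     e^{-\beta_2 x})} with \eqn{\beta = (\beta_1, \beta_2, K)}, the
#'     three-parameter Gompertz curve for cumulative counts with unknown
#'     saturation \eqn{K} (e.g. cumulative epidemic incidence).}
#' }
#' All carry analytic gradients and vectorized grid evaluators. The default
#' parameter boxes are generous compact sets; override \code{param_box} to
#' tighten or widen the search region.
#'
#' @param param_box Optional replacement \code{p x 2} bounds matrix.
#' @param K_max Upper bound for the saturation parameter of the
#'   three-parameter curve (set it to roughly ten times the largest observed
#'   response).
#' @return A [model_spec()].
#' @name builtin_models
NULL

#' @rdname builtin_models
#' @export
linear_model <- function(param_box = cbind(c(-100, -100), c(100, 100))) {
  model_spec(
    name = "linear", p = 2L, q = 1L, param_box = param_box,
    evaluator = function(X, beta) beta[1L] + beta[2L] * X[, 1L],
    gradient  = function(X, beta) cbind(1, X[, 1L]),
    eval_grid = function(X, B) outer(rep(1, nrow(X)), B[, 1L]) +
      outer(X[, 1L], B[, 2L]))
}

#' @rdname builtin_models
#' @export
gompertz2_model <- function(param_box = cbind(c(0.1, 0.5), c(30, 15))) {
  model_spec(
    name = "gompertz2", p = 2L, q = 1L, param_box = param_box,
    evaluator = function(X, beta) exp(-beta[1L] * exp(-beta[2L] * X[, 1L])),
    gradient  = function(X, beta) {
      e2 <- exp(-beta[2L] * X[, 1L])
      f <- exp(-beta[1L] * e2)
      cbind(-f * e2, f * beta[1L] * X[, 1L] * e2)
    },
    eval_grid = function(X, B) {
      # candidate grids are tensor products, so exp(-b2 * x) repeats: compute
      # it once per distinct rate value
      u <- unique(B[, 2L])
      Eu <- exp(-outer(X[, 1L], u))             # n x length(u)
      E <- Eu[, match(B[, 2L], u), drop = FALSE]
      exp(-E * rep(B[, 1L], each = nrow(X)))
    })
}

#' @rdname builtin_models
#' @export
gompertz3_model <- function(K_max = 1e6,
                            param_box = cbind(c(0.1, 1e-4, 1),
                                              c(100, 1, K_max))) {
  model_spec(
    name = "gompertz3", p = 3L, q = 1L, param_box = param_box,
    evaluator = function(X, beta)
      beta[3L] * exp(-beta[1L] * exp(-beta[2L] * X[, 1L])),
    gradient  = function(X, beta) {
      e2 <- exp(-beta[2L] * X[, 1L])
      g <- exp(-beta[1L] * e2)
      cbind(-beta[3L] * g * e2, beta[3L] * g * beta[1L] * X[, 1L] * e2, g)
    },
    eval_grid = function(X, B) {
      u <- unique(B[, 2L])
      Eu <- exp(-outer(X[, 1L], u))
      E <- Eu[, match(B[, 2L], u), drop = FALSE]
      G <- exp(-E * rep(B[, 1L], each = nrow(X)))
      G * rep(B[, 3L], each = nrow(X))
    })
}

#' Look up a built-in model by name
#'
#' @param name One of \code{"linear"}, \code{"gompertz2"}, \code{"gompertz3"}.
#' @param ... Passed to the model constructor.
#' @return A [model_spec()].
#' @export
get_model <- function(name, ...) {
  switch(name,
         linear = linear_model(...),
         gompertz2 = gompertz2_model(...),
         gompertz3 = gompertz3_model(...),
         stop("unknown model '", name, "'; built-ins: linear, gompertz2, gompertz3"))
}
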