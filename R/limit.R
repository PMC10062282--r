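#' Limit range of the monitoring horizon
#'
#' The weighted Wiener supremum that the detector converges to runs over
#' \eqn{t \in (0, L)}: \eqn{L = 1} for open-end monitoring (horizon growing
#' faster than the historical sample) and \eqn{L = T/(1+T)} for closed-end
#' monitoring with horizon ratio \eqn{T = \lim T_m / m}.
#'
#' @param T Horizon ratio \eqn{T_m/m} (positive, finite) for closed-end;
#'   ignored for open-end.
#' @param closed_end Logical; \code{FALSE} gives the open-end value 1.
#' @return A number in (0, 1].
#' @export
L_of_T <- function(T = Inf, closed_end = FALSE) {
  if (!closed_end) return(1)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("closed-end monitoring needs a finite positive horizon ratio T")
  T / (1 + T)
}

#' Simulation settings for the limit law
#'
#' Describes one Monte-Carlo simulation of
#' \eqn{\sup_{0 < t < L} \|W_p(t)\|_\infty / t^\gamma} for a
#' \eqn{p}-dimensional standard Wiener process \eqn{W_p}.
#'
#' @param p Wiener dimension (the model's parameter dimension).
#' @param gamma Boundary exponent in [0, 1/2).
#' @param L Limit range in (0, 1]; see [L_of_T()].
#' @param n_grid Discretization points on (0, 1] (at least 100).
#' @param n_paths Monte-Carlo sample paths (at least 1000).
#' @param seed Integer seed.
#' @return A list of class \code{limit_spec}.
#' @export
limit_spec <- function(p, gamma, L = 1, n_grid = 1e4, n_paths = 2e4,
                       seed = 1L) {
  stopifnot(p >= 1L)
  check_gamma(gamma)
  if (!is.numeric(L) || L <= 0 || L > 1) stop("'L' must lie in (0, 1]")
  if (n_grid < 100) stop("'n_grid' must be at least 100")
  if (n_paths < 1000) stop("'n_paths' must be at least 1000")
  structure(list(p = as.integer(p), gamma = gamma, L = L,
                 n_grid = as.integer(n_grid), n_paths = as.integer(n_paths),
                 seed = as.integer(seed)),
            class = "limit_spec")
}

# Samples of sup over the unit-interval grid; L enters by exact Brownian
# scaling afterwards, so the cache only ever holds L = 1 draws.
.limit_cache <- new.env(parent = emptyenv())

simulate_sup_unit <- function(p, gamma, n_grid, n_paths, seed) {
  key <- paste(p, gamma, n_grid, n_paths, seed, sep = "|")
  if (!is.null(.limit_cache[[key]])) return(.limit_cache[[key]])
  tg <- (seq_len(n_grid) / n_grid)^gamma
  sd_inc <- sqrt(1 / n_grid)
  out <- numeric(n_paths)
  block <- max(1L, min(n_paths, floor(2e7 / n_grid)))
  done <- 0L
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  while (done < n_paths) {
    nb <- min(block, n_paths - done)
    M <- matrix(0, n_grid, nb)
    for (j in seq_len(p)) {
      W <- apply(matrix(stats::rnorm(n_grid * nb, sd = sd_inc), n_grid, nb),
                 2L, cumsum)
      M <- pmax(M, abs(W))
    }
    out[done + seq_len(nb)] <- apply(M / tg, 2L, max)
    done <- done + nb
  }
  .limit_cache[[key]] <- out
  out
}

#' Simulate the weighted Wiener supremum
#'
#' Draws \code{n_paths} Monte-Carlo samples of
#' \eqn{\sup_{0 < t < L} \max_{j \le p} |W_j(t)| / t^\gamma}. Paths are
#' built as cumulative sums of Gaussian increments on an equispaced grid of
#' (0, 1] (first point \eqn{1/n_{grid}}, so the weight stays finite); a
#' general \eqn{L} is obtained by the exact distributional scaling
#' \eqn{L^{1/2 - \gamma}} of the unit-interval supremum, which removes any
#' grid-resolution difference between open- and closed-end values.
#'
#' @param spec A [limit_spec()].
#' @return Numeric vector of \code{n_paths} supremum samples.
#' @export
simulate_sup <- function(spec) {
  stopifnot(inherits(spec, "limit_spec"))
  spec$L^(0.5 - spec$gamma) *
    simulate_sup_unit(spec$p, spec$gamma, spec$n_grid, spec$n_paths,
                      spec$seed)
}

#' Critical value of the sequential test
#'
#' The \eqn{(1-\alpha)}-quantile \eqn{c_\alpha(\gamma)} of the limit
#' distribution \eqn{\sup_{0 < t < L} \|W_p(t)\|_\infty / t^\gamma},
#' estimated by Monte Carlo ([simulate_sup()]). Samples are cached per
#' \code{(p, gamma, n_grid, n_paths, seed)} within the session, so asking
#' for several \code{alpha} or \code{L} values costs one simulation.
#'
#' @param p Wiener (parameter) dimension.
#' @param gamma Boundary exponent in [0, 1/2).
#' @param L Limit range in (0, 1]; see [L_of_T()].
#' @param alpha Significance level in (0, 1).
#' @param n_paths,n_grid,seed Monte-Carlo settings, see [limit_spec()].
#' @return The estimated critical value (positive scalar).
#' @export
critical_value <- function(p, gamma, L = 1, alpha = 0.05, n_paths = 2e4,
                           n_grid = 1e4, seed = 20260929L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  spec <- limit_spec(p, gamma, L, n_grid, n_paths, seed)
  as.numeric(stats::quantile(simulate_sup(spec), 1 - alpha, names = FALSE))
}

#' Analytic null quantile for the unweighted scalar case
#'
#' For \eqn{p = 1}, \eqn{\gamma = 0}, \eqn{L = 1} the limit is the supremum
#' of a reflected Brownian motion's absolute value over the unit interval,
#' whose CDF has the classical reflection series
#' \eqn{P(\sup |W| \le b) = (4/\pi) \sum_k (-1)^k (2k+1)^{-1}
#' \exp(-\pi^2 (2k+1)^2 / (8 b^2))}. This closed form serves as an
#' independent oracle for the Monte-Carlo quantiles.
#'
#' @param alpha Significance level in (0, 1).
#' @param terms Series truncation (the tail decays super-geometrically).
#' @return The exact \eqn{(1-\alpha)}-quantile.
#' @export
sup_abs_wiener_quantile <- function(alpha = 0.05, terms = 100L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  cdf <- function(b) {
    k <- 0:(terms - 1L)
    (4 / pi) * sum((-1)^k / (2 * k + 1) *
                     exp(-pi^2 * (2 * k + 1)^2 / (8 * b^2)))
  }
  stats::uniroot(function(b) cdf(b) - (1 - alpha), c(0.1, 10),
                 tol = 1e-10)$root
}
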