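#' Genetic architecture of a linear reaction norm
#'
#' The phenotype follows \deqn{P = \mu + b x + A_{int} + A_{sl} x + E,}
#' where \eqn{x} is the standardized environmental covariate, \eqn{A_{int}}
#' and \eqn{A_{sl}} are the additive-genetic intercept and slope
#' (environmental sensitivity) with variances `var_int`, `var_sl` and
#' correlation `cor_int_sl`, and \eqn{E} is a residual with constant
#' variance `var_e` across environments.
#'
#' @param var_int additive genetic variance of the intercept.
#' @param var_sl additive genetic variance of the slope.
#' @param cor_int_sl genetic correlation between intercept and slope; the
#'   covariance is derived as `cor_int_sl * sqrt(var_int * var_sl)`.
#' @param var_e residual variance (constant over environments).
#' @param mu overall mean.
#' @param slope fixed (population) slope of the reaction norm.
#' @return An object of class `rn_params`.
#' @examples
#' p <- rn_params()                      # basic parameter set
#' heritability(p, 0)                    # 0.3 in the average environment
#' genetic_correlation(p, 0, 2.37)       # decay towards extreme environments
#' @export
rn_params <- function(var_int = 0.3, var_sl = 0.05, cor_int_sl = 0,
                      var_e = 0.7, mu = 0, slope = 1) {
  if (var_int < 0 || var_sl < 0) stop("genetic variances must be >= 0")
  if (var_e <= 0) stop("'var_e' must be > 0")
  if (abs(cor_int_sl) > 1) stop("'cor_int_sl' must be in [-1, 1]")
  cov_int_sl <- cor_int_sl * sqrt(var_int * var_sl)
  structure(
    list(var_int = var_int, var_sl = var_sl, cov_int_sl = cov_int_sl,
         cor_int_sl = cor_int_sl, var_e = var_e, mu = mu, slope = slope),
    class = "rn_params")
}

#' @export
print.rn_params <- function(x, ...) {
  cat("Linear reaction-norm genetic parameters\n")
  cat(sprintf("  var(A_int) = %g, var(A_sl) = %g, cov = %g (r = %g)\n",
              x$var_int, x$var_sl, x$cov_int_sl, x$cor_int_sl))
  cat(sprintf("  var(E) = %g, mu = %g, fixed slope = %g\n",
              x$var_e, x$mu, x$slope))
  invisible(x)
}

#' Genetic variance at a point on the environmental gradient
#'
#' \eqn{\sigma^2_A(x) = \sigma^2_{A,int} + 2x\,\sigma_{A,int,sl} +
#' x^2 \sigma^2_{A,sl}}.  Non-negative whenever the intercept--slope
#' covariance respects its Cauchy--Schwarz bound.
#'
#' @param params an [rn_params()] object.
#' @param x environmental gradient value(s).
#' @return Genetic variance(s), vectorized over `x`.
#' @export
genetic_variance <- function(params, x) {
  stopifnot(inherits(params, "rn_params"))
  params$var_int + 2 * x * params$cov_int_sl + x^2 * params$var_sl
}

#' Genetic covariance between performances in two environments
#'
#' \eqn{\sigma_A(x_i, x_j) = \sigma^2_{A,int} + (x_i + x_j)
#' \sigma_{A,int,sl} + x_i x_j \sigma^2_{A,sl}}; symmetric in its
#' arguments and equal to [genetic_variance()] on the diagonal.
#'
#' @inheritParams genetic_variance
#' @param xi,xj environmental gradient values (vectorized).
#' @export
genetic_covariance <- function(params, xi, xj) {
  stopifnot(inherits(params, "rn_params"))
  params$var_int + (xi + xj) * params$cov_int_sl + xi * xj * params$var_sl
}

#' Genetic correlation between performances in two environments
#'
#' @inheritParams genetic_covariance
#' @return Correlation(s) in `[-1, 1]`; exactly 1 everywhere when there is
#'   no genetic variance in slope.
#' @export
genetic_correlation <- function(params, xi, xj) {
  vi <- genetic_variance(params, xi)
  vj <- genetic_variance(params, xj)
  if (any(vi <= 0) || any(vj <= 0))
    stop("genetic correlation undefined: zero genetic variance in an environment")
  genetic_covariance(params, xi, xj) / sqrt(vi * vj)
}

#' Heritability at a point on the environmental gradient
#'
#' \eqn{h^2(x) = \sigma^2_A(x) / (\sigma^2_A(x) + \sigma^2_e)}.  Because
#' the residual variance is constant while the genetic variance changes
#' along the gradient, heritability varies across environments.
#'
#' @inheritParams genetic_variance
#' @export
heritability <- function(params, x) {
  va <- genetic_variance(params, x)
  va / (va + params$var_e)
}

#' Between-environment genetic covariance matrix over a grid
#'
#' Builds the \eqn{n \times n} covariance matrix of breeding values across
#' the environment classes of a grid.  The matrix has rank at most 2
#' (there are only two underlying breeding values, intercept and slope).
#'
#' @inheritParams genetic_variance
#' @param grid an [env_grid()] object.
#' @return A symmetric positive semi-definite matrix.
#' @export
genetic_covmatrix <- function(params, grid) {
  x <- grid$x_mean
  outer(x, x, function(a, b) genetic_covariance(params, a, b))
}

# env design matrix: A_e = A_int + x_e A_sl, used to move between the
# 2x2 (intercept, slope) scale and the per-environment scale
env_design <- function(grid) cbind(1, grid$x_mean)

# 2x2 (intercept, slope) covariance matrix of an rn_params object
params_cov2 <- function(params) {
  matrix(c(params$var_int, params$cov_int_sl,
           params$cov_int_sl, params$var_sl), 2, 2)
}

# rn_params from a 2x2 covariance matrix, keeping residual/mean/slope
params_from_cov2 <- function(C2, template) {
  r <- if (C2[1, 1] > 0 && C2[2, 2] > 0)
    C2[1, 2] / sqrt(C2[1, 1] * C2[2, 2]) else 0
  rn_params(var_int = C2[1, 1], var_sl = C2[2, 2], cor_int_sl = r,
            var_e = template$var_e, mu = template$mu, slope = template$slope)
}
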