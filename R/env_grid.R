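#' Discretize a standard-normal environmental gradient
#'
#' Divides the real line into `n_inner` equal-width classes between
#' `-inner_bound` and `inner_bound` plus the two tails, giving
#' `n_inner + 2` environment classes in total.  The environmental
#' covariate \eqn{x} is assumed standard normal, so each class carries the
#' normal probability mass of its interval, and the class value
#' \eqn{\bar x_i} is the conditional (truncated-normal) mean of \eqn{x}
#' within the interval, computed analytically as a ratio of
#' \eqn{\phi}-differences over \eqn{\Phi}-differences (inverse Mills ratio
#' in the tails).
#'
#' With the defaults (11 inner classes between -2 and 2) the grid has 13
#' classes; the central class spans (-0.18, 0.18) with mass 0.14 and mean
#' 0, and the tail classes have conditional means of about \eqn{\pm 2.37}.
#'
#' @param n_inner number of equal-width classes between the inner bounds
#'   (default 11).
#' @param inner_bound positive half-width of the inner range (default 2).
#' @return An object of class `env_grid`: a list with `n_classes`,
#'   `lower`, `upper` (class bounds, first/last infinite), `proportion`
#'   (probability mass per class) and `x_mean` (conditional mean of the
#'   gradient per class).  Animal counts are added by
#'   [allocate_animals()].
#' @examples
#' g <- env_grid()
#' as.data.frame(allocate_animals(g, total_reference = 5000,
#'                                total_progeny = 100))
#' @seealso [allocate_animals()], [rn_params()]
#' @export
env_grid <- function(n_inner = 11, inner_bound = 2) {
  if (!is.numeric(inner_bound) || length(inner_bound) != 1 || inner_bound <= 0)
    stop("'inner_bound' must be a single positive number")
  if (!is.numeric(n_inner) || length(n_inner) != 1 || n_inner < 1 ||
      n_inner != round(n_inner))
    stop("'n_inner' must be a positive whole number")
  if (is.finite(inner_bound)) {
    cuts <- seq(-inner_bound, inner_bound, length.out = n_inner + 1)
    lower <- c(-Inf, cuts)
    upper <- c(cuts, Inf)
  } else {
    # degenerate request: one class covering the whole line
    lower <- -Inf
    upper <- Inf
  }
  proportion <- stats::pnorm(upper) - stats::pnorm(lower)
  # E[x | a < x < b] for standard normal: (phi(a) - phi(b)) / (Phi(b) - Phi(a))
  x_mean <- (stats::dnorm(lower) - stats::dnorm(upper)) / proportion
  x_mean[proportion == 0] <- NA_real_
  # enforce exact mirror symmetry (guards against tiny asymmetric round-off)
  n <- length(proportion)
  proportion <- (proportion + rev(proportion)) / 2
  x_mean <- (x_mean - rev(x_mean)) / 2
  structure(
    list(n_classes = n, lower = lower, upper = upper,
         proportion = proportion, x_mean = x_mean,
         counts_reference = NULL, counts_progeny = NULL),
    class = "env_grid")
}

#' Allocate animals to environment classes
#'
#' Distributes a reference population (for genomic prediction) and a group
#' of progeny or sibs over the environment classes proportionally to the
#' class probability masses.  Counts are kept real-valued: they enter
#' downstream variance formulas as group sizes and rounding them would
#' distort the algebra.
#'
#' @param grid an [env_grid()] object.
#' @param total_reference total size of the reference population.
#' @param total_progeny total number of progeny (or sibs) in the group
#'   that is spread across environments.
#' @return The grid with `counts_reference` and/or `counts_progeny`
#'   filled in.
#' @export
allocate_animals <- function(grid, total_reference = NULL, total_progeny = NULL) {
  stopifnot(inherits(grid, "env_grid"))
  if (!is.null(total_reference)) {
    if (total_reference < 0) stop("'total_reference' must be >= 0")
    grid$counts_reference <- grid$proportion * total_reference
  }
  if (!is.null(total_progeny)) {
    if (total_progeny < 0) stop("'total_progeny' must be >= 0")
    grid$counts_progeny <- grid$proportion * total_progeny
  }
  grid
}

#' @export
as.data.frame.env_grid <- function(x, ...) {
  d <- data.frame(
    environment = seq_len(x$n_classes),
    x_lower = x$lower,
    x_upper = x$upper,
    proportion = x$proportion,
    x_average = x$x_mean)
  if (!is.null(x$counts_reference)) d$n_reference <- x$counts_reference
  if (!is.null(x$counts_progeny)) d$n_progeny <- x$counts_progeny
  d
}

#' @export
print.env_grid <- function(x, digits = 2, ...) {
  cat("Environmental gradient discretized into", x$n_classes, "classes\n")
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Export an environment grid as CSV
#'
#' Writes the grid (with any allocated counts) in the classic tabular
#' layout: class index, bounds, proportion, conditional mean, counts.
#'
#' @param grid an [env_grid()] object.
#' @param file path of the CSV file to write.
#' @return The data frame written, invisibly.
#' @export
write_env_grid <- function(grid, file) {
  d <- as.data.frame(grid)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}
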