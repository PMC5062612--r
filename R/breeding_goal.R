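#' Profit as a function of phenotype level
#'
#' Diminishing-returns profit equation \eqn{Profit = 1 - e^{-rate \cdot P}}:
#' concave and increasing, approaching 1 as performance grows.  Its
#' derivative with respect to the environment supplies the economic values
#' of the resilience breeding goal.
#'
#' @param P phenotype level(s).
#' @param rate curvature of the profit equation (default 0.3).
#' @export
profit <- function(P, rate = 0.3) 1 - exp(-rate * P)

#' Construct a breeding goal over environment classes
#'
#' The aggregate genotype is \eqn{H = v'a = \sum_i v_i A_i} with one
#' breeding value per environment class.  Two standard goals:
#'
#' * `"proportional"` -- economic values equal to the class frequencies
#'   (a linear profit equation): improve performance wherever animals are.
#' * `"resilience"` -- economic values are the derivative of the
#'   diminishing-returns [profit()] equation at the expected phenotype of
#'   each class, \eqn{v_i = rate \cdot e^{-rate(\mu + b \bar x_i)}}:
#'   strictly decreasing in the environment, so performance under poor
#'   (perturbed) conditions is weighted most.  With the default rate the
#'   weights of the extreme classes differ by about a factor four.
#'
#' @param grid an [env_grid()] object.
#' @param type `"proportional"` or `"resilience"`.
#' @param rate curvature of the profit equation (resilience goal).
#' @param mu,slope mean and fixed slope of the reaction norm used to map
#'   environment to expected phenotype (resilience goal).
#' @return A numeric vector of economic values of class `breeding_goal`
#'   with a `label` attribute.
#' @examples
#' g <- env_grid()
#' breeding_goal(g, "resilience")
#' @export
breeding_goal <- function(grid, type = c("proportional", "resilience"),
                          rate = 0.3, mu = 0, slope = 1) {
  stopifnot(inherits(grid, "env_grid"))
  type <- match.arg(type)
  v <- switch(type,
    proportional = grid$proportion,
    resilience = {
      if (rate <= 0) stop("'rate' must be > 0")
      rate * exp(-rate * (mu + slope * grid$x_mean))
    })
  structure(as.numeric(v), label = type, class = "breeding_goal")
}

#' Custom breeding goal from explicit economic values
#'
#' @param values numeric vector of economic values, one per environment
#'   class.
#' @param label name for the goal.
#' @export
custom_goal <- function(values, label = "custom") {
  if (!all(is.finite(values))) stop("economic values must be finite")
  if (all(values == 0)) stop("at least one economic value must be nonzero")
  structure(as.numeric(values), label = label, class = "breeding_goal")
}

#' @export
print.breeding_goal <- function(x, ...) {
  cat("Breeding goal:", attr(x, "label"), "\n")
  print(round(as.numeric(x), 4))
  invisible(x)
}

#' Breeding goal expressed on the intercept/slope scale
#'
#' Any per-environment goal \eqn{v} is equivalent to a goal on the two
#' reaction-norm breeding values, with weights \eqn{v_{int} = \sum_i v_i}
#' and \eqn{v_{sl} = \sum_i v_i \bar x_i}.
#'
#' @param goal a [breeding_goal()] vector.
#' @param grid the [env_grid()] the goal was built on.
#' @return Named numeric vector with elements `intercept` and `slope`.
#' @export
goal_components <- function(goal, grid) {
  c(intercept = sum(as.numeric(goal)),
    slope = sum(as.numeric(goal) * grid$x_mean))
}
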