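#' The discretized-gradient table
#'
#' Thirteen-class layout of the environmental gradient: bounds,
#' proportions, conditional means and the allocation of a reference
#' population and a progeny group.
#'
#' @param total_reference reference population size.
#' @param total_progeny progeny/sib group size.
#' @param grid optionally, a pre-built [env_grid()].
#' @return Data frame with one row per environment class.
#' @export
gradient_table <- function(total_reference = 5000, total_progeny = 100,
                           grid = env_grid()) {
  as.data.frame(allocate_animals(grid, total_reference, total_progeny))
}

# the six pseudo-BLUP scenarios: heritabilities realized by scaling the
# genetic architecture against the residual (correlation profile invariant)
scenario_params <- function(h2, r_int_sl = 0) {
  stopifnot(h2 > 0, h2 < 1)
  scale <- h2 / 0.3
  rn_params(var_int = 0.3 * scale, var_sl = 0.05 * scale,
            cor_int_sl = r_int_sl, var_e = 1 - h2)
}

#' Genomic-selection response relative to traditional schemes
#'
#' Runs the pseudo-BLUP engine for the genomic, sib-testing and
#' progeny-testing schemes under the resilience breeding goal for a set of
#' heritabilities and reference-population sizes, and tabulates the ratio
#' of the genomic response to each traditional scheme's response in the
#' lowest, middle and highest environment class, as well as the ratios of
#' the intercept and slope (environmental sensitivity) responses.
#'
#' @param h2 heritabilities in the average environment.
#' @param ref_size genomic reference population sizes.
#' @param goal_type breeding goal, `"resilience"` by default.
#' @param r_int_sl genetic correlation between intercept and slope.
#' @param grid an [env_grid()].
#' @param ... further arguments passed to [breeding_scheme()].
#' @return Data frame with columns `comparison` (`GS/sib`, `GS/progeny`),
#'   `h2`, `ref_size`, `low`, `middle`, `high`, `intercept`, `slope`.
#' @examples
#' \donttest{scheme_comparison_table(h2 = 0.3, ref_size = 5000)}
#' @export
scheme_comparison_table <- function(h2 = c(0.1, 0.3, 0.5),
                                    ref_size = c(5000, 1e6),
                                    goal_type = "resilience",
                                    r_int_sl = 0,
                                    grid = env_grid(), ...) {
  lo <- 1; mid <- (grid$n_classes + 1) / 2; hi <- grid$n_classes
  rows <- list()
  for (h in h2) {
    p <- scenario_params(h, r_int_sl)
    goal <- breeding_goal(grid, goal_type)
    sib <- breeding_scheme("sib", p, grid, goal, ...)
    prg <- breeding_scheme("progeny", p, grid, goal, ...)
    for (N in ref_size) {
      gs <- breeding_scheme("genomic", p, grid, goal, ref_size = N, ...)
      for (den in list(sib = sib, progeny = prg)) {
        cmp <- compare_schemes(gs, den)
        rows[[length(rows) + 1]] <- data.frame(
          comparison = paste0("GS/", den$scheme), h2 = h, ref_size = N,
          low = cmp$response_ratio[lo], middle = cmp$response_ratio[mid],
          high = cmp$response_ratio[hi],
          intercept = cmp$intercept_ratio, slope = cmp$slope_ratio)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Data behind the profit/economic-value, correlation, accuracy and
#' response figures
#'
#' @name figure_data
#' @param grid an [env_grid()].
#' @param rate profit curvature.
#' @param params an [rn_params()] object.
#' @return Tidy data frames.
NULL

#' @rdname figure_data
#' @export
profit_curve_data <- function(grid = env_grid(), rate = 0.3) {
  x <- grid$x_mean
  data.frame(x = x, profit = profit(x, rate),
             economic_value = as.numeric(breeding_goal(grid, "resilience",
                                                       rate = rate)))
}

#' @rdname figure_data
#' @export
correlation_profile_data <- function(params = rn_params(),
                                     grid = env_grid()) {
  data.frame(x = grid$x_mean,
             r_with_average = genetic_correlation(params, grid$x_mean, 0))
}

#' Accuracy profiles over models and evaluators
#'
#' Combines [accuracy_profile()] calls into one tidy table (the data
#' behind the accuracy-versus-environment comparisons of reaction-norm and
#' conventional evaluations).
#'
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()] (counts will be allocated).
#' @param ref_size reference population size.
#' @param n_progeny progeny-group size.
#' @param Me effective chromosome segments.
#' @export
accuracy_table <- function(params = rn_params(), grid = env_grid(),
                           ref_size = 5000, n_progeny = 100, Me = 1200) {
  grid <- allocate_animals(grid, ref_size, n_progeny)
  out <- rbind(
    accuracy_profile(params, grid, "progeny", "rn", ref_size, Me),
    accuracy_profile(params, grid, "progeny", "conventional", ref_size, Me),
    accuracy_profile(params, grid, "gebv", "rn", ref_size, Me),
    accuracy_profile(params, grid, "gebv", "conventional", ref_size, Me))
  out$ref_size <- ref_size
  out$n_progeny <- n_progeny
  out
}

#' Response profiles of all schemes under one goal
#'
#' @param goal_type `"proportional"` or `"resilience"`.
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()].
#' @param ref_sizes genomic reference sizes to include.
#' @param nucleus include nucleus information (`FALSE` reproduces the
#'   plain sib/progeny variants of the response figures).
#' @export
response_table <- function(goal_type = c("resilience", "proportional"),
                           params = rn_params(), grid = env_grid(),
                           ref_sizes = c(5000, 1e6), nucleus = FALSE) {
  goal_type <- match.arg(goal_type)
  goal <- breeding_goal(grid, goal_type)
  fits <- c(
    list(sib = breeding_scheme("sib", params, grid, goal, nucleus = nucleus),
         progeny = breeding_scheme("progeny", params, grid, goal,
                                   nucleus = nucleus)),
    stats::setNames(
      lapply(ref_sizes, function(N)
        breeding_scheme("genomic", params, grid, goal, ref_size = N)),
      paste0("genomic_", format(ref_sizes, scientific = FALSE, trim = TRUE))))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    data.frame(scheme = nm, goal = goal_type, x = grid$x_mean,
               response = fits[[nm]]$response)
  }))
  rownames(out) <- NULL
  out
}

#' Write the package's standard result tables to CSV files
#'
#' Regenerates the gradient table, the accuracy profiles, the response
#' profiles under both goals and the scheme-comparison ratio tables, and
#' writes them under `dir`.
#'
#' @param dir output directory (created if needed).
#' @param quick if `TRUE`, restrict the comparison table to the basic
#'   heritability.
#' @return Invisibly, the list of data frames written.
#' @export
reproduce_tables <- function(dir = ".", quick = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    gradient = gradient_table(),
    accuracy = accuracy_table(),
    response_resilience = response_table("resilience"),
    response_proportional = response_table("proportional"),
    comparison = scheme_comparison_table(
      h2 = if (quick) 0.3 else c(0.1, 0.3, 0.5)))
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(tabs)
}

#' Read a run configuration file
#'
#' YAML configuration mirroring the engine's parameter names.  Unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path path to a YAML file.
#' @return Named list of parameters.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  allowed <- c("var_int", "var_sl", "cor_int_sl", "var_e", "mu", "slope",
               "n_inner", "inner_bound", "scheme", "goal", "rate",
               "ref_size", "Me", "p_male", "p_female", "n_nucleus",
               "n_progeny_per_dam", "n_commercial", "L_male", "L_female",
               "nucleus", "bulmer", "seed", "out")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  cfg
}
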