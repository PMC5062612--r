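#' Simulate a hierarchical half-sib/full-sib population under the
#' reaction-norm model
#'
#' Individual-based generator used as an independent check of the
#' deterministic index algebra: sires are mated to unrelated dams,
#' breeding values for intercept and slope follow the bivariate-normal
#' architecture of [rn_params()], each progeny is assigned to an
#' environment class multinomially by the grid proportions, and its
#' phenotype is \eqn{P = \mu + b x + A_{int} + A_{sl} x + E}.
#'
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()] object.
#' @param n_sires number of sires.
#' @param n_dams_per_sire dams mated to each sire.
#' @param n_prog_per_dam progeny per dam.
#' @param seed RNG seed (required for reproducibility).
#' @param allocation `"multinomial"` assigns each progeny to a class
#'   independently with the grid proportions (the population-structure
#'   view); `"fixed"` gives every sire the same integer class counts
#'   (largest-remainder rounding of the expected allocation), the design
#'   the deterministic index algebra conditions on -- use this when
#'   validating predicted accuracies.
#' @return A list of class `sim_population`: `parents` (data frame of sire
#'   and dam breeding values) and `progeny` (data frame with ids,
#'   breeding values, environment class, gradient value and phenotype).
#' @examples
#' pop <- simulate_families(rn_params(), env_grid(), 50, 4, 5, seed = 1)
#' head(pop$progeny)
#' @export
simulate_families <- function(params, grid, n_sires, n_dams_per_sire,
                              n_prog_per_dam, seed,
                              allocation = c("multinomial", "fixed")) {
  stopifnot(n_sires >= 1, n_dams_per_sire >= 1, n_prog_per_dam >= 1)
  allocation <- match.arg(allocation)
  set.seed(seed)
  Sig <- params_cov2(params)
  L <- chol_psd(Sig)
  draw_bv <- function(n) {
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
    colnames(z) <- c("a_int", "a_sl")
    z
  }
  n_dams <- n_sires * n_dams_per_sire
  bs <- draw_bv(n_sires)
  bd <- draw_bv(n_dams)
  parents <- data.frame(
    id = c(paste0("s", seq_len(n_sires)), paste0("d", seq_len(n_dams))),
    sex = rep(c("m", "f"), c(n_sires, n_dams)),
    a_int = c(bs[, 1], bd[, 1]), a_sl = c(bs[, 2], bd[, 2]))
  n_prog <- n_dams * n_prog_per_dam
  sire_i <- rep(seq_len(n_sires), each = n_dams_per_sire * n_prog_per_dam)
  dam_i <- rep(seq_len(n_dams), each = n_prog_per_dam)
  ms <- draw_bv(n_prog) * sqrt(0.5)   # Mendelian sampling: half the variance
  a_int <- 0.5 * bs[sire_i, 1] + 0.5 * bd[dam_i, 1] + ms[, 1]
  a_sl <- 0.5 * bs[sire_i, 2] + 0.5 * bd[dam_i, 2] + ms[, 2]
  env <- if (allocation == "multinomial") {
    sample.int(grid$n_classes, n_prog, replace = TRUE,
               prob = grid$proportion)
  } else {
    per_sire <- fixed_counts(grid$proportion,
                             n_dams_per_sire * n_prog_per_dam)
    rep(rep.int(seq_len(grid$n_classes), per_sire), n_sires)
  }
  x <- grid$x_mean[env]
  phen <- params$mu + params$slope * x + a_int + a_sl * x +
    stats::rnorm(n_prog, 0, sqrt(params$var_e))
  progeny <- data.frame(
    id = paste0("p", seq_len(n_prog)),
    sire = sire_i, dam = dam_i,
    a_int = a_int, a_sl = a_sl,
    env = env, x = x, phenotype = phen)
  structure(list(parents = parents, progeny = progeny, seed = seed,
                 grid = grid, params = params),
            class = "sim_population")
}

# Cholesky-like factor that tolerates a singular 2x2 covariance
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(ev) * t(e$vectors)))
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d sires, %d progeny (seed %s)\n",
              nrow(x$parents[x$parents$sex == "m", ]),
              nrow(x$progeny), format(x$seed)))
  invisible(x)
}

# per-sire index values from progeny means per environment with weights b:
# returns matrix of sire index values and the per-env progeny means used
sire_progeny_index <- function(pop, b) {
  grid <- pop$grid
  pr <- pop$progeny
  params <- pop$params
  n_sires <- max(pr$sire)
  # work on deviations from the known fixed effects so that an empty class
  # contributes its unconditional expectation (zero) rather than a bias
  dev <- pr$phenotype - params$mu - params$slope * pr$x
  env_f <- factor(pr$env, levels = seq_len(grid$n_classes))
  idx <- numeric(n_sires)
  for (s in seq_len(n_sires)) {
    sel <- pr$sire == s
    m <- tapply(dev[sel], env_f[sel], mean)
    m[is.na(m)] <- 0
    idx[s] <- sum(b * m)
  }
  idx
}

#' Realized accuracy of a progeny-mean index in a simulated population
#'
#' Each sire's index is computed from his progeny's phenotype means per
#' environment class with the supplied weights; the realized accuracy per
#' class is the Pearson correlation between the index and the sires' true
#' breeding values \eqn{A_{int} + A_{sl}\bar x_i}.
#'
#' @param pop a [simulate_families()] population.
#' @param b index weights, one per environment class.
#' @return Numeric vector of per-class correlations.
#' @export
empirical_accuracy <- function(pop, b) {
  if (all(b == 0)) stop("zero-weight index: accuracy undefined")
  idx <- sire_progeny_index(pop, b)
  sires <- pop$parents[pop$parents$sex == "m", ]
  vapply(pop$grid$x_mean, function(xi) {
    stats::cor(idx, sires$a_int + sires$a_sl * xi)
  }, numeric(1))
}

#' Realized single-generation response in a simulated population
#'
#' Selects the top fraction `p_male` of sires on an index computed from
#' their progeny means and returns the per-class genetic superiority
#' transmitted to offspring: half the selected sires' mean breeding value
#' in each class (the dam path is left unselected).
#'
#' @inheritParams empirical_accuracy
#' @param p_male selected proportion of sires.
#' @return Numeric vector of per-class realized responses.
#' @export
empirical_response <- function(pop, b, p_male) {
  if (p_male <= 0 || p_male > 1) stop("'p_male' must be in (0, 1]")
  sires <- pop$parents[pop$parents$sex == "m", ]
  if (p_male == 1) return(rep(0, pop$grid$n_classes))
  idx <- sire_progeny_index(pop, b)
  n_sel <- max(1, round(p_male * nrow(sires)))
  sel <- order(idx, decreasing = TRUE)[seq_len(n_sel)]
  vapply(pop$grid$x_mean, function(xi) {
    bv <- sires$a_int + sires$a_sl * xi
    0.5 * (mean(bv[sel]) - mean(bv))
  }, numeric(1))
}

#' Simulate realized responses from a fitted breeding scheme
#'
#' Draws `nsim` independent populations under the scheme's base genetic
#' parameters, evaluates sires with a progeny-mean index built from the
#' scheme's grid and goal (base-population weights, no Bulmer reduction),
#' and returns realized per-class responses for comparison with the
#' deterministic single-generation prediction.
#'
#' @param object a [breeding_scheme()] fit.
#' @param nsim number of replicate populations.
#' @param seed RNG seed.
#' @param n_sires,n_dams_per_sire,n_prog_per_dam simulated family
#'   structure.
#' @param ... unused.
#' @return A matrix with `nsim` columns of per-class realized responses.
#' @export
simulate.breeding_scheme <- function(object, nsim = 1, seed = 1,
                                     n_sires = 500, n_dams_per_sire = 2,
                                     n_prog_per_dam = 10, ...) {
  grid <- object$grid; params <- object$params
  npe <- grid$proportion * n_dams_per_sire * n_prog_per_dam
  P <- progeny_P(grid, params, npe)
  G <- progeny_G(grid, params)
  idx <- solve_index(P, G, object$goal, genetic_covmatrix(params, grid))
  out <- vapply(seq_len(nsim), function(k) {
    pop <- simulate_families(params, grid, n_sires, n_dams_per_sire,
                             n_prog_per_dam, seed = seed + k - 1)
    empirical_response(pop, idx$b, object$inputs$p_male %||% 0.05)
  }, numeric(grid$n_classes))
  matrix(out, nrow = grid$n_classes)
}

#' Integer class allocation by largest remainder
#'
#' Rounds the expected per-class allocation `proportions * total` to
#' integers that sum exactly to `total`, assigning leftover units to the
#' classes with the largest fractional remainders.
#'
#' @param proportions class probability masses.
#' @param total total count to allocate.
#' @export
fixed_counts <- function(proportions, total) {
  target <- proportions * total
  n <- floor(target)
  left <- round(total - sum(n))
  if (left > 0) {
    up <- order(target - n, decreasing = TRUE)[seq_len(left)]
    n[up] <- n[up] + 1
  }
  as.integer(n)
}
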