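#' Variance matrix of per-environment progeny (or sib) means
#'
#' For a group of \eqn{n_i} paternal half sibs recorded in environment
#' \eqn{i}, the variance of the group mean is
#' \deqn{var(\bar P_i) = \left(\sigma^2_A(x_i) + \sigma^2_e +
#'   (n_i - 1)\,0.25\,\sigma^2_A(x_i)\right) / n_i,}
#' and the covariance between group means in environments \eqn{i} and
#' \eqn{j} is \eqn{0.25\,\sigma_A(x_i, x_j)} (the members of different
#' groups are half sibs of each other).
#'
#' @param grid an [env_grid()] object.
#' @param params an [rn_params()] object.
#' @param n_per_env group size per class; defaults to the grid's
#'   `counts_progeny`.
#' @return The \eqn{n \times n} source variance matrix.
#' @export
progeny_P <- function(grid, params, n_per_env = grid$counts_progeny) {
  if (is.null(n_per_env)) stop("no progeny counts: allocate_animals() first")
  if (any(n_per_env <= 0)) stop("progeny group sizes must be > 0")
  x <- grid$x_mean
  P <- 0.25 * genetic_covmatrix(params, grid)
  diag(P) <- (genetic_variance(params, x) + params$var_e +
                (n_per_env - 1) * 0.25 * genetic_variance(params, x)) / n_per_env
  P
}

#' Covariance of progeny means with candidate breeding values
#'
#' Entry \eqn{(i, j)} is \eqn{cov(\bar P_i, A_j) =
#' 0.5\,\sigma_A(x_i, x_j)}: the group in environment \eqn{i} consists of
#' the candidate's own progeny (additive relationship 0.5).
#'
#' @inheritParams progeny_P
#' @export
progeny_G <- function(grid, params) {
  0.5 * genetic_covmatrix(params, grid)
}

#' Accuracy of a genomic breeding value from reference-population size
#'
#' \eqn{r = \sqrt{N h^2 / (N h^2 + M_e)}}, where \eqn{N} is the number of
#' phenotyped and genotyped reference animals, \eqn{h^2} the trait
#' heritability in that environment and \eqn{M_e} the effective number of
#' independent chromosome segments.
#'
#' @param N reference population size(s).
#' @param h2 heritability (in `(0,1)`).
#' @param Me effective number of chromosome segments.
#' @return Accuracy in `[0, 1)`, increasing in `N` and `h2`.
#' @examples
#' gebv_accuracy(721.37, 0.3, 1200)   # about 0.39
#' @export
gebv_accuracy <- function(N, h2, Me = 1200) {
  if (any(N < 0)) stop("'N' must be >= 0")
  if (any(h2 <= 0) || any(h2 >= 1)) stop("'h2' must be in (0, 1)")
  if (Me <= 0) stop("'Me' must be > 0")
  sqrt(N * h2 / (N * h2 + Me))
}

#' Variance matrix of unit-scaled genomic breeding values
#'
#' GEBV are scaled to unit variance, so the matrix has a unit diagonal and
#' off-diagonals \eqn{r_{g,ij} r_i r_j}: the genetic correlation between
#' the two environments attenuated by both accuracies.
#'
#' @param accuracies per-class GEBV accuracies.
#' @param rg between-class genetic correlation matrix.
#' @export
gebv_P <- function(accuracies, rg) {
  if (any(accuracies < 0 | accuracies > 1))
    stop("accuracies must be in [0, 1]")
  P <- rg * outer(accuracies, accuracies)
  diag(P) <- 1
  P
}

#' Covariance of unit-scaled GEBV with breeding values
#'
#' Entry \eqn{(i, j)} is \eqn{r_{g,ij}\, r_i\, \sigma_A(x_j)}: the
#' covariance of the unit-variance GEBV for environment \eqn{i} with the
#' true breeding value in environment \eqn{j}.
#'
#' @inheritParams gebv_P
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()] object.
#' @export
gebv_G <- function(accuracies, params, grid) {
  x <- grid$x_mean
  rg <- outer(x, x, function(a, b) genetic_correlation(params, a, b))
  sd_a <- sqrt(genetic_variance(params, x))
  rg * accuracies * matrix(sd_a, length(x), length(x), byrow = TRUE)
}

#' Solve a selection index
#'
#' Optimal index weights \eqn{b = P^{-1} G v} for information sources with
#' variance matrix `P`, source-by-goal-environment covariance matrix `G`
#' and economic values `v`.  Near-duplicate sources (pairwise correlation
#' above `1 - 1e-8`, the classic singularity of stacking redundant
#' estimated breeding values) are pruned with a warning before inversion.
#'
#' @param P source variance--covariance matrix.
#' @param G covariance matrix of sources (rows) with breeding values per
#'   goal environment (columns).
#' @param v economic values (a [breeding_goal()] or numeric vector).
#' @param C genetic covariance matrix of the goal environments; needed for
#'   the accuracy `r_IH` of the index for the aggregate genotype.
#' @param sources optional character vector of source names.
#' @return An object of class `selection_index` with elements `b`
#'   (weights), `sigma_I` (index standard deviation), `r_IH` (accuracy for
#'   the aggregate genotype, if `C` given), `gI` (covariance of the index
#'   with the breeding value in each goal environment), and the pruned
#'   `P`, `G`.
#' @export
solve_index <- function(P, G, v, C = NULL, sources = NULL) {
  P <- as.matrix(P)
  G <- matrix(as.numeric(G), nrow = nrow(P))
  v <- as.numeric(v)
  if (is.null(sources)) sources <- rownames(P)
  if (is.null(sources)) sources <- paste0("source", seq_len(nrow(P)))
  # drop empty sources, then prune near-duplicates
  keep <- diag(P) > 1e-12
  if (!all(keep)) {
    P <- P[keep, keep, drop = FALSE]; G <- G[keep, , drop = FALSE]
    sources <- sources[keep]
  }
  repeat {
    R <- stats::cov2cor(P)
    dup <- which(abs(R) > 1 - 1e-8 & upper.tri(R), arr.ind = TRUE)
    if (nrow(dup) == 0) break
    drop_i <- max(dup[1, ])
    warning(sprintf(
      "pruning near-singular source '%s' (duplicate of '%s')",
      sources[drop_i], sources[min(dup[1, ])]), call. = FALSE)
    P <- P[-drop_i, -drop_i, drop = FALSE]
    G <- G[-drop_i, , drop = FALSE]
    sources <- sources[-drop_i]
  }
  b <- tryCatch(solve(P, G %*% v), error = function(e)
    stop("source variance matrix is singular after pruning: ",
         conditionMessage(e)))
  sigma_I <- sqrt(drop(t(b) %*% P %*% b))
  gI <- drop(t(G) %*% b)          # cov(I, A_e) for each goal environment
  r_IH <- if (!is.null(C)) {
    sH <- sqrt(drop(t(v) %*% C %*% v))
    sum(gI * v) / (sigma_I * sH)
  } else NA_real_
  structure(
    list(sources = sources, P = P, G = G, v = v, b = drop(b),
         sigma_I = sigma_I, gI = gI, r_IH = r_IH),
    class = "selection_index")
}

#' @export
print.selection_index <- function(x, ...) {
  cat("Selection index with", length(x$b), "information sources\n")
  cat(sprintf("  sigma_I = %.4f", x$sigma_I))
  if (!is.na(x$r_IH)) cat(sprintf(", r_IH = %.4f", x$r_IH))
  cat("\n")
  invisible(x)
}

#' Accuracy of an index for the breeding value in one environment
#'
#' \eqn{r_{i} = b' g_i / (\sigma_I \sqrt{\sigma^2_A(x_i)})} with
#' \eqn{g_i} the covariance of the sources with the breeding value in
#' environment \eqn{i}.
#'
#' @param index a [solve_index()] object.
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()] object.
#' @param i environment class index (vectorized; default all classes).
#' @param var_a optional genetic variances to use in the denominator
#'   (defaults to [genetic_variance()] at the class means; the
#'   conventional genomic collapse sets them to 1).
#' @export
env_accuracy <- function(index, params, grid, i = seq_len(grid$n_classes),
                         var_a = NULL) {
  if (is.null(var_a)) var_a <- genetic_variance(params, grid$x_mean)
  index$gI[i] / (index$sigma_I * sqrt(var_a[i]))
}

#' Collapse per-environment progeny information to one pooled source
#'
#' A conventional genetic evaluation that ignores genotype-by-environment
#' interaction effectively uses a single progeny mean pooled over
#' environments.  All elements of `P` are averaged with weights
#' \eqn{n_i n_j / (\sum n)^2} and each column of `G` is averaged with
#' weights \eqn{n_i / \sum n}, giving a one-source index.
#'
#' @param P,G matrices from [progeny_P()] / [progeny_G()].
#' @param n_per_env per-class group sizes used for the weights.
#' @return A list with scalar `P` (1x1 matrix) and 1-row matrix `G`.
#' @export
conventional_collapse_progeny <- function(P, G, n_per_env) {
  w <- n_per_env / sum(n_per_env)
  Pbar <- drop(t(w) %*% P %*% w)
  Gbar <- drop(t(w) %*% G)
  list(P = matrix(Pbar, 1, 1), G = matrix(Gbar, nrow = 1))
}

#' Conventional (GxE-ignoring) combination of genomic breeding values
#'
#' The univariate GEBV of all environments are combined into one index
#' maximizing response in the reaction-norm intercept while ignoring
#' genotype-by-environment interaction: the source correlation matrix is
#' \eqn{[r_i r_j]} with unit diagonal and the goal covariances are simply
#' \eqn{g_i = r_i}.  Per-environment accuracy is then computed with the
#' genetic variance in each environment set to one.
#'
#' @param accuracies per-class GEBV accuracies.
#' @return A list with `P`, `G` (one goal column) ready for
#'   [solve_index()], and the convention that accuracies are evaluated
#'   with unit genetic variance.
#' @export
conventional_collapse_gebv <- function(accuracies) {
  P <- outer(accuracies, accuracies)
  diag(P) <- 1
  list(P = P, G = matrix(accuracies, ncol = 1))
}

#' Per-environment accuracy profiles of reaction-norm and conventional
#' evaluations
#'
#' Computes the accuracy of environment-specific (G)EBV for every class of
#' the grid, for progeny-based or genomic evaluation, under the
#' reaction-norm model (per-environment index, breeding goal set to the
#' environment of interest) and the conventional model that ignores
#' genotype-by-environment interaction.
#'
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()] object (counts allocated as needed).
#' @param evaluator `"progeny"` or `"gebv"`.
#' @param model `"rn"` or `"conventional"`.
#' @param ref_size reference population size (genomic evaluator).
#' @param Me effective number of chromosome segments.
#' @return Data frame with columns `environment`, `x`, `model`,
#'   `evaluator`, `accuracy`.
#' @examples
#' g <- allocate_animals(env_grid(), 5000, 100)
#' accuracy_profile(rn_params(), g, "gebv", "rn", ref_size = 5000)
#' @export
accuracy_profile <- function(params, grid,
                             evaluator = c("progeny", "gebv"),
                             model = c("rn", "conventional"),
                             ref_size = 5000, Me = 1200) {
  evaluator <- match.arg(evaluator)
  model <- match.arg(model)
  x <- grid$x_mean
  n <- grid$n_classes
  if (evaluator == "progeny") {
    npe <- grid$counts_progeny
    if (is.null(npe)) stop("allocate_animals() with total_progeny first")
    P <- progeny_P(grid, params, npe)
    G <- progeny_G(grid, params)
    if (model == "conventional") {
      cc <- conventional_collapse_progeny(P, G, npe)
      P <- cc$P; G <- cc$G
    }
    var_a <- NULL
  } else {
    Ni <- grid$counts_reference
    if (is.null(Ni)) stop("allocate_animals() with total_reference first")
    r <- gebv_accuracy(Ni, heritability(params, x), Me)
    if (model == "rn") {
      rg <- outer(x, x, function(a, b) genetic_correlation(params, a, b))
      P <- gebv_P(r, rg)
      G <- gebv_G(r, params, grid)
      var_a <- NULL
    } else {
      # one fixed index whose weights come from the GxE-ignoring model
      # (source correlations r_i r_j, goal covariances r_i); its *realized*
      # accuracy per environment is evaluated under the true reaction-norm
      # covariance structure of the GEBV
      cc <- conventional_collapse_gebv(r)
      b <- solve(cc$P, cc$G)
      rg <- outer(x, x, function(a, b) genetic_correlation(params, a, b))
      P_true <- gebv_P(r, rg)
      G_true <- gebv_G(r, params, grid)
      sigma_I <- sqrt(drop(t(b) %*% P_true %*% b))
      acc <- drop(t(G_true) %*% b) /
        (sigma_I * sqrt(genetic_variance(params, x)))
      return(data.frame(environment = seq_len(n), x = x, model = model,
                        evaluator = evaluator, accuracy = acc))
    }
  }
  acc <- vapply(seq_len(n), function(i) {
    v <- as.numeric(seq_len(n) == i)
    idx <- solve_index(P, G, v)
    env_accuracy(idx, params, grid, i, var_a = var_a)
  }, numeric(1))
  data.frame(environment = seq_len(n), x = x, model = model,
             evaluator = evaluator, accuracy = acc)
}
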