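#' Finite-population selection intensity
#'
#' Standardized selection differential for truncation selection of a
#' proportion `p`, corrected for a finite number of candidates (Burrows'
#' adjustment) and for correlated index values among relatives.  The
#' correlation correction replaces the candidate number by an effective
#' number \eqn{n_{eff} = n / (1 + (n - 1)\bar\rho)}, where
#' \eqn{\bar\rho} is the mean pairwise correlation of index values over
#' all candidate pairs, before applying Burrows' formula
#' \eqn{i_n = i - (1 - p) / (2\,i\,p\,(n_{eff} + 1))}.
#'
#' @param p selected proportion in `(0, 1]`.
#' @param n_candidates number of selection candidates (default infinite).
#' @param rho_index mean correlation of index values among candidates, in
#'   `[0, 1)`.
#' @return Selection intensity; 0 when `p = 1`.
#' @examples
#' selection_intensity(0.05)              # about 2.063
#' selection_intensity(0.05, 1000, 0.02)  # finite, correlated candidates
#' @export
selection_intensity <- function(p, n_candidates = Inf, rho_index = 0) {
  if (p <= 0 || p > 1) stop("'p' must be in (0, 1]")
  if (n_candidates < 1) stop("'n_candidates' must be >= 1")
  if (rho_index < 0 || rho_index >= 1) stop("'rho_index' must be in [0, 1)")
  if (p == 1) return(0)
  z <- stats::qnorm(1 - p)
  i_inf <- stats::dnorm(z) / p
  if (!is.finite(n_candidates)) return(i_inf)
  n_eff <- n_candidates / (1 + (n_candidates - 1) * rho_index)
  max(i_inf - (1 - p) / (2 * i_inf * p * (n_eff + 1)), 0)
}

# variance-reduction coefficient of truncation selection, k = i (i - z)
bulmer_k <- function(p) {
  if (p >= 1) return(0)
  z <- stats::qnorm(1 - p)
  i <- stats::dnorm(z) / p
  i * (i - z)
}

# ---------------------------------------------------------------------------
# Internal pseudo-BLUP engine.
#
# All information-source (co)variances are decomposed into selection paths:
# candidate breeding values are A = 0.5 A_sire* + 0.5 A_dam* + m, where the
# starred terms are breeding values of *selected* parents (variance reduced
# by selection on each sex's index) and m is Mendelian sampling with half
# the base-generation variance.  On the environment scale this gives, for
# each pair of classes, a sire-path matrix S, a dam-path matrix D and a
# Mendelian matrix M; relatives' covariances are sums of the paths they
# share.  Parental estimated breeding values enter through the matrix
# B = G' P^-1 G of the parent-generation index (B[e,e'] is at once the
# covariance of the parent's EBV for environments e and e' and the
# covariance of the EBV for e with the parent's true breeding value in e'),
# adjusted for selection on the parent's index I by
# cov*(u, w) = cov(u, w) - k cov(u, I) cov(w, I) / var(I).
# ---------------------------------------------------------------------------

# build P, G and candidate-pair cross-covariance matrices for one sex.
# st: engine state (see scheme_engine); returns list(P, G, Pfs, Phs, sources)
build_sources <- function(scheme, sex, st) {
  ne <- st$ne; nuc <- st$nuc
  S <- st$S; D <- st$D; M <- st$M; C <- st$C
  ve <- st$params$var_e
  female <- sex == "f"
  prog_m <- scheme == "progeny" && sex == "m"

  if (scheme == "genomic") {
    vA <- diag(C)
    r <- st$r_gebv
    rg <- C / sqrt(outer(vA, vA))
    P <- rg * outer(r, r); diag(P) <- 1
    G <- rg * r * matrix(sqrt(vA), ne, ne, byrow = TRUE)
    scl <- outer(r / sqrt(vA), r / sqrt(vA))
    Kfs <- 0.25 * S + 0.25 * D
    Pfs <- scl * Kfs; Phs <- scl * (0.25 * S)
    return(list(P = P, G = G, Pfs = Pfs, Phs = Phs,
                sources = paste0("gebv", seq_len(ne))))
  }

  n_grp <- st$n_commercial_per_env
  n_src <- ne + if (st$nucleus_info) 1 + female + 5 else 0
  P <- matrix(0, n_src, n_src)
  G <- matrix(0, n_src, ne)
  Pfs <- matrix(0, n_src, n_src)   # cross-cov, full-sib candidate pair
  Phs <- matrix(0, n_src, n_src)   # cross-cov, half-sib candidate pair
  sources <- character(n_src)

  # per-environment group means: commercial half sibs of the candidate, or
  # (progeny-tested males) the candidate's own half-sib progeny
  sources[1:ne] <- paste0(if (prog_m) "progeny_mean" else "halfsib_mean",
                          seq_len(ne))
  if (!prog_m) {
    between <- 0.25 * S                       # groups share the selected sire
    var_mem <- 0.25 * diag(S) + 0.25 * diag(C) + diag(M) + ve
    G[1:ne, ] <- 0.25 * S
    grp_fs <- grp_hs <- between               # same groups for both candidates
  } else {
    between <- 0.25 * C                       # groups share the candidate
    var_mem <- 0.5 * diag(C) + diag(M) + ve
    G[1:ne, ] <- 0.5 * C
    grp_fs <- 0.25 * (0.25 * S + 0.25 * D)    # progeny of two full sibs
    grp_hs <- 0.25 * (0.25 * S)               # progeny of two half sibs
  }
  P[1:ne, 1:ne] <- between
  diag(P)[1:ne] <- (var_mem + (n_grp - 1) * diag(between)) / n_grp
  Pfs[1:ne, 1:ne] <- grp_fs; Phs[1:ne, 1:ne] <- grp_hs
  if (!prog_m) {  # shared groups: cross-cov on the diagonal equals the var
    diag(Pfs)[1:ne] <- diag(P)[1:ne]; diag(Phs)[1:ne] <- diag(P)[1:ne]
  }

  if (st$nucleus_info) {
    fsG <- 0.25 * S + 0.25 * D   # cov among full sibs / with candidate
    fs <- ne + 1
    sources[fs] <- "fullsib_mean"
    nf <- st$n_fullsib
    P[fs, fs] <- (fsG[nuc, nuc] + M[nuc, nuc] + ve +
                    (nf - 1) * fsG[nuc, nuc]) / nf
    cross_fs_grp <- if (!prog_m) 0.25 * S[nuc, ] else 0.5 * fsG[nuc, ]
    P[fs, 1:ne] <- P[1:ne, fs] <- cross_fs_grp
    G[fs, ] <- fsG[nuc, ]
    # candidate pairs: full sibs share the group; half sibs' groups share
    # only the sire
    Pfs[fs, fs] <- P[fs, fs]
    Phs[fs, fs] <- 0.25 * S[nuc, nuc]
    Pfs[fs, 1:ne] <- Pfs[1:ne, fs] <- cross_fs_grp
    Phs[fs, 1:ne] <- Phs[1:ne, fs] <-
      if (!prog_m) 0.25 * S[nuc, ] else 0.5 * 0.25 * S[nuc, ]

    k <- fs
    if (female) {
      k <- fs + 1
      sources[k] <- "own_performance"
      P[k, k] <- C[nuc, nuc] + ve
      own_grp <- if (!prog_m) 0.25 * S[nuc, ] else 0.5 * C[nuc, ]
      P[k, 1:ne] <- P[1:ne, k] <- own_grp
      P[k, fs] <- P[fs, k] <- fsG[nuc, nuc]
      G[k, ] <- C[nuc, ]
      Pfs[k, k] <- fsG[nuc, nuc]; Phs[k, k] <- 0.25 * S[nuc, nuc]
      Pfs[k, 1:ne] <- Pfs[1:ne, k] <- own_grp
      Phs[k, 1:ne] <- Phs[1:ne, k] <- if (!prog_m) 0.25 * S[nuc, ] else
        0.5 * 0.25 * S[nuc, ]
      Pfs[k, fs] <- Pfs[fs, k] <- fsG[nuc, nuc]
      Phs[k, fs] <- Phs[fs, k] <- 0.25 * S[nuc, nuc]
    }

    # parental EBV: sire and dam, best and worst environment
    envs <- c(st$best, st$worst)
    lbl <- c("sire_ebv_best", "sire_ebv_worst", "dam_ebv_best", "dam_ebv_worst")
    EBm <- st$EBm; EBf <- st$EBf
    for (q in 1:4) {
      s <- k + q
      sources[s] <- lbl[q]
      e <- envs[if (q %% 2 == 1) 1 else 2]
      EB <- if (q <= 2) EBm else EBf
      P[s, s] <- EB[e, e]
      G[s, ] <- 0.5 * EB[e, ]
      cov_grp <- if (q <= 2) {
        if (!prog_m) 0.5 * EB[e, ] else 0.25 * EB[e, ]
      } else {
        if (!prog_m) rep(0, ne) else 0.25 * EB[e, ]
      }
      P[s, 1:ne] <- P[1:ne, s] <- cov_grp
      P[s, fs] <- P[fs, s] <- if (!prog_m) 0.5 * EB[e, nuc] else
        0.25 * EB[e, nuc]
      if (female) P[s, k] <- P[k, s] <- 0.5 * EB[e, nuc]
      # pair cross-covariances: sire EBV shared always; dam EBV shared only
      # between full sibs (half sibs have unrelated dams)
      shared_fs <- TRUE
      shared_hs <- q <= 2
      Pfs[s, ] <- Pfs[, s] <- if (shared_fs) P[s, ] else 0
      Phs[s, ] <- Phs[, s] <- if (shared_hs) P[s, ] else 0
      if (shared_fs) Pfs[s, s] <- P[s, s]
      if (shared_hs) Phs[s, s] <- P[s, s]
    }
    P[k + 1, k + 2] <- P[k + 2, k + 1] <- EBm[envs[1], envs[2]]
    P[k + 3, k + 4] <- P[k + 4, k + 3] <- EBf[envs[1], envs[2]]
    Pfs[k + 1, k + 2] <- Pfs[k + 2, k + 1] <- EBm[envs[1], envs[2]]
    Phs[k + 1, k + 2] <- Phs[k + 2, k + 1] <- EBm[envs[1], envs[2]]
    Pfs[k + 3, k + 4] <- Pfs[k + 4, k + 3] <- EBf[envs[1], envs[2]]

    # pooled EBV of the dams of the commercial groups (unselected commercial
    # females, one per group member); unrelated to the candidate, so it only
    # sharpens the group means
    s <- k + 5
    sources[s] <- "group_dam_ebv"
    Bf <- st$Bf
    ntot <- st$n_commercial
    P[s, s] <- sum(st$prop * diag(Bf)) / ntot
    P[s, 1:ne] <- P[1:ne, s] <- 0.5 * diag(Bf) / ntot
    G[s, ] <- 0
    shared <- !prog_m   # progeny-tested males use their own mates
    Pfs[s, ] <- Pfs[, s] <- if (shared) P[s, ] else 0
    Phs[s, ] <- Phs[, s] <- if (shared) P[s, ] else 0
    if (shared) { Pfs[s, s] <- P[s, s]; Phs[s, s] <- P[s, s] }
  }
  list(P = P, G = G, Pfs = Pfs, Phs = Phs, sources = sources)
}

# solve one sex's index within the engine; returns weights, index moments and
# the EBV second-moment matrix B = G' P^-1 G of the full system
engine_solve <- function(src, v) {
  keep <- diag(src$P) > 1e-12
  P <- src$P[keep, keep, drop = FALSE]
  G <- src$G[keep, , drop = FALSE]
  b <- solve(P, G %*% v)
  sI2 <- drop(t(b) %*% P %*% b)
  gI <- drop(t(G) %*% b)
  B <- t(G) %*% solve(P, G)
  bfull <- numeric(length(keep)); bfull[keep] <- b
  rho_fs <- drop(t(bfull) %*% src$Pfs %*% bfull) / sI2
  rho_hs <- drop(t(bfull) %*% src$Phs %*% bfull) / sI2
  list(b = bfull, keep = keep, sI2 = sI2, gI = gI, B = B,
       rho_fs = min(max(rho_fs, 0), 1), rho_hs = min(max(rho_hs, 0), 1))
}

# full equilibrium engine; see breeding_scheme() for the public interface
scheme_engine <- function(scheme, params, grid, v, ref_size, Me,
                          p_male, p_female, n_nucleus, n_progeny_per_dam,
                          n_commercial, nucleus_info, bulmer,
                          max_iter, tol) {
  ne <- grid$n_classes
  x <- grid$x_mean
  X <- env_design(grid)
  env_of <- function(C2) X %*% C2 %*% t(X)
  C0_2 <- params_cov2(params)
  M <- 0.5 * env_of(C0_2)
  km <- if (bulmer) bulmer_k(p_male) else 0
  kf <- if (bulmer) bulmer_k(p_female) else 0
  # GEBV accuracies from base-generation heritabilities (the reference
  # population is commercial and treated as unselected)
  h2_base <- heritability(params, x)
  r_gebv <- gebv_accuracy(grid$proportion * ref_size, h2_base, Me)

  st <- list(ne = ne, nuc = which.max(x), best = which.max(x),
             worst = which.min(x), prop = grid$proportion,
             params = params, M = M,
             n_commercial = n_commercial,
             n_commercial_per_env = grid$proportion * n_commercial,
             n_fullsib = n_progeny_per_dam - 1,
             nucleus_info = nucleus_info, r_gebv = r_gebv)

  C2 <- C0_2
  st$S <- st$D <- env_of(C0_2)
  st$EBm <- st$EBf <- st$Bf <- matrix(0, ne, ne)
  sm <- sf <- NULL
  iter <- 0L; converged <- FALSE
  C2_hist <- list()   # for Aitken extrapolation of the fixed point
  for (it in seq_len(max_iter)) {
    iter <- it
    st$C <- env_of(C2)
    srm <- build_sources(scheme, "m", st)
    srf <- build_sources(scheme, "f", st)
    sm <- engine_solve(srm, v); sm$sources <- srm$sources
    sf <- engine_solve(srf, v); sf$sources <- srf$sources
    # selection reduces the 2x2 (intercept, slope) covariance through each
    # sex's index; offspring regain half the base variance by Mendelian
    # sampling
    ab <- function(gI) drop(solve(crossprod(X), crossprod(X, gI)))
    cm <- ab(sm$gI); cf <- ab(sf$gI)
    Cs2 <- C2 - if (sm$sI2 > 0) km * outer(cm, cm) / sm$sI2 else 0
    Cd2 <- C2 - if (sf$sI2 > 0) kf * outer(cf, cf) / sf$sI2 else 0
    C2_new <- 0.25 * Cs2 + 0.25 * Cd2 + 0.5 * C0_2
    delta <- max(abs(C2_new - C2))
    C2 <- C2_new
    # the recurrence contracts geometrically; an occasional elementwise
    # Aitken delta-squared step removes most of the remaining geometric tail
    C2_hist <- c(C2_hist, list(C2))
    if (length(C2_hist) == 3) {
      d1 <- C2_hist[[2]] - C2_hist[[1]]
      d2 <- C2_hist[[3]] - C2_hist[[2]]
      den <- d2 - d1
      ok <- abs(den) > 1e-14
      acc <- C2
      acc[ok] <- C2_hist[[3]][ok] - d2[ok]^2 / den[ok]
      acc <- (acc + t(acc)) / 2
      # accept only a contraction-consistent extrapolation
      if (all(is.finite(acc)) && all(abs(d2) < abs(d1))) C2 <- acc
      C2_hist <- list()
    }
    st$S <- env_of(Cs2); st$D <- env_of(Cd2)
    st$EBm <- sm$B - if (sm$sI2 > 0) km * outer(sm$gI, sm$gI) / sm$sI2 else 0
    st$EBf <- sf$B - if (sf$sI2 > 0) kf * outer(sf$gI, sf$gI) / sf$sI2 else 0
    st$Bf <- sf$B
    if (delta < tol) { converged <- TRUE; break }
  }
  st$C <- env_of(C2)
  list(C2 = C2, C = st$C, sm = sm, sf = sf, st = st,
       iterations = iter, converged = converged)
}

#' Deterministic evaluation of a breeding scheme under reaction-norm GxE
#'
#' Predicts per-environment response to selection and accuracies of a
#' sib-testing, progeny-testing or genomic-selection breeding scheme with
#' a pseudo-BLUP selection index: per-environment group means (commercial
#' half sibs or half-sib progeny), full-sib and own-performance records in
#' the nucleus environment, parental estimated breeding values in the best
#' and worst environment, or per-environment genomic breeding values.  The
#' calculation iterates to the Bulmer equilibrium: selection on each sex's
#' index reduces the intercept/slope genetic covariance, parental EBV
#' accuracies are those of the previous generation's equilibrium index,
#' and all information-source covariances are decomposed into
#' selected-sire, selected-dam and Mendelian-sampling paths.
#'
#' Response per environment class is
#' \deqn{R_e = \frac{i_m\,cov(I_m, A_e)/\sigma_{I_m} +
#'   i_f\,cov(I_f, A_e)/\sigma_{I_f}}{L_m + L_f},}
#' with finite-population selection intensities corrected for correlated
#' index values among sibs and relative generation intervals \eqn{L}.
#' Because the reaction norm is linear, the responses lie exactly on a
#' line in the environment: the intercept response equals the response in
#' the average environment and the slope response is
#' \eqn{(R_e - R_{int})/\bar x_e} for any non-central class.
#'
#' @param scheme `"genomic"`, `"sib"` or `"progeny"` (progeny-tested
#'   males carry a longer generation interval).
#' @param params an [rn_params()] object.
#' @param grid an [env_grid()] object.
#' @param goal a [breeding_goal()] (or plain numeric vector of economic
#'   values per class).
#' @param ref_size genomic reference population size, spread over classes
#'   by the grid proportions.
#' @param Me effective number of chromosome segments.
#' @param p_male,p_female selected proportions.
#' @param n_nucleus nucleus candidates per generation (both sexes).
#' @param n_progeny_per_dam nucleus full-sib family size.
#' @param n_commercial commercial half sibs (sib scheme) or half-sib
#'   progeny (progeny-tested males) spread over classes.
#' @param L_male,L_female relative generation intervals; `L_male` defaults
#'   to 1.6 for the progeny scheme and 1 otherwise.
#' @param nucleus include nucleus information (full sibs, female own
#'   performance, parental EBV)?  `FALSE` gives the plain
#'   sibs/progeny-only variant used for response-profile figures.
#' @param bulmer apply the Bulmer equilibrium? `FALSE` evaluates the
#'   index in the unselected base population.
#' @param max_iter,tol equilibrium iteration control (change in the
#'   2x2 intercept/slope covariance).
#' @return An object of class `breeding_scheme`; see [print.breeding_scheme()],
#'   [coef.breeding_scheme()], [predict.breeding_scheme()],
#'   [simulate.breeding_scheme()].
#' @examples
#' g <- env_grid()
#' fit <- breeding_scheme("genomic", rn_params(), g,
#'                        breeding_goal(g, "proportional"))
#' fit
#' coef(fit)
#' @export
breeding_scheme <- function(scheme = c("genomic", "sib", "progeny"),
                            params = rn_params(), grid = env_grid(),
                            goal = breeding_goal(grid, "proportional"),
                            ref_size = 5000, Me = 1200,
                            p_male = 0.05, p_female = 0.20,
                            n_nucleus = 2000, n_progeny_per_dam = 10,
                            n_commercial = 100,
                            L_male = NULL, L_female = 1,
                            nucleus = TRUE, bulmer = TRUE,
                            max_iter = 200, tol = 1e-8) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "rn_params"), inherits(grid, "env_grid"))
  if (p_male <= 0 || p_male > 1 || p_female <= 0 || p_female > 1)
    stop("selected proportions must be in (0, 1]")
  v <- as.numeric(goal)
  attr(v, "label") <- attr(goal, "label")
  if (length(v) != grid$n_classes)
    stop("goal length must match the number of environment classes")
  if (is.null(L_male)) L_male <- if (scheme == "progeny") 1.6 else 1

  if (all(v == 0)) {
    # degenerate goal: nothing to select on
    zero <- rep(0, grid$n_classes)
    return(structure(list(
      scheme = scheme, response = zero, R_int = 0, R_sl = 0,
      r_IH = c(male = 0, female = 0), env_accuracy = NULL,
      intensity = c(male = 0, female = 0), equilibrium = params,
      iterations = 0L, converged = TRUE, goal = v, grid = grid,
      params = params, inputs = list()), class = "breeding_scheme"))
  }

  eng <- scheme_engine(scheme, params, grid, v, ref_size, Me,
                       p_male, p_female, n_nucleus, n_progeny_per_dam,
                       n_commercial, nucleus, bulmer, max_iter, tol)
  sm <- eng$sm; sf <- eng$sf
  sH <- sqrt(drop(t(v) %*% eng$C %*% v))
  r_IH <- c(male = sum(sm$gI * v) / (sqrt(sm$sI2) * sH),
            female = sum(sf$gI * v) / (sqrt(sf$sI2) * sH))
  vA_eq <- pmax(diag(eng$C), .Machine$double.eps)
  env_acc <- cbind(male = sm$gI / (sqrt(sm$sI2) * sqrt(vA_eq)),
                   female = sf$gI / (sqrt(sf$sI2) * sqrt(vA_eq)))

  # finite-population intensities with family-correlation correction;
  # candidates per sex, full-sib and paternal half-sib family sizes per sex
  n_cand <- n_nucleus / 2
  m_fs <- n_progeny_per_dam / 2
  n_dams <- p_female * n_cand
  n_sires <- max(p_male * n_cand, 1)
  m_sire <- n_dams / n_sires * m_fs
  mean_rho <- function(s) {
    ((m_fs - 1) * s$rho_fs + (m_sire - m_fs) * s$rho_hs) / (n_cand - 1)
  }
  i_m <- selection_intensity(p_male, n_cand, min(mean_rho(sm), 0.999))
  i_f <- selection_intensity(p_female, n_cand, min(mean_rho(sf), 0.999))

  resp <- (i_m * sm$gI / sqrt(sm$sI2) + i_f * sf$gI / sqrt(sf$sI2)) /
    (L_male + L_female)
  X <- env_design(grid)
  ab <- drop(solve(crossprod(X), crossprod(X, resp)))

  structure(list(
    scheme = scheme, response = resp, R_int = ab[1], R_sl = ab[2],
    r_IH = r_IH, env_accuracy = env_acc,
    intensity = c(male = i_m, female = i_f),
    rho_index = c(male = mean_rho(sm), female = mean_rho(sf)),
    equilibrium = params_from_cov2(eng$C2, params),
    iterations = eng$iterations, converged = eng$converged,
    index_male = sm, index_female = sf,
    goal = v, grid = grid, params = params,
    inputs = list(ref_size = ref_size, Me = Me, p_male = p_male,
                  p_female = p_female, n_nucleus = n_nucleus,
                  n_progeny_per_dam = n_progeny_per_dam,
                  n_commercial = n_commercial, L_male = L_male,
                  L_female = L_female, nucleus = nucleus, bulmer = bulmer)),
    class = "breeding_scheme")
}

#' @export
print.breeding_scheme <- function(x, ...) {
  cat(sprintf("Breeding scheme: %s (goal: %s)\n", x$scheme,
              attr(x$goal, "label") %||% "numeric"))
  cat(sprintf("  accuracy r_IH: male %.3f, female %.3f\n",
              x$r_IH["male"], x$r_IH["female"]))
  cat(sprintf("  response: intercept %.4f, slope %.4f per generation\n",
              x$R_int, x$R_sl))
  cat(sprintf("  Bulmer equilibrium after %d iterations (var_int %.3f -> %.3f)\n",
              x$iterations, x$params$var_int, x$equilibrium$var_int))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.breeding_scheme <- function(object, ...) {
  d <- data.frame(environment = seq_len(object$grid$n_classes),
                  x = object$grid$x_mean,
                  response = object$response)
  if (!is.null(object$env_accuracy)) {
    d$accuracy_male <- object$env_accuracy[, "male"]
    d$accuracy_female <- object$env_accuracy[, "female"]
  }
  structure(list(fit = object, table = d), class = "summary.breeding_scheme")
}

#' @export
print.summary.breeding_scheme <- function(x, ...) {
  print(x$fit)
  cat("\nPer-environment predictions:\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Intercept and slope response of a fitted scheme
#'
#' @param object a [breeding_scheme()] fit.
#' @param ... unused.
#' @return Named vector: response in the reaction-norm intercept (equal to
#'   the response in the average environment) and in the slope
#'   (environmental sensitivity).
#' @export
coef.breeding_scheme <- function(object, ...) {
  c(intercept = object$R_int, slope = object$R_sl)
}

#' Predict response or accuracy along the environmental gradient
#'
#' Because the reaction norm is linear, the response profile is a line in
#' the environmental covariate and can be evaluated at any `x`; per-class
#' accuracies are returned at the grid classes.
#'
#' @param object a [breeding_scheme()] fit.
#' @param x gradient values at which to predict the response (default the
#'   grid class means).
#' @param what `"response"` or `"accuracy"`.
#' @param ... unused.
#' @export
predict.breeding_scheme <- function(object, x = object$grid$x_mean,
                                    what = c("response", "accuracy"), ...) {
  what <- match.arg(what)
  if (what == "response") return(object$R_int + object$R_sl * x)
  if (is.null(object$env_accuracy)) stop("no accuracies in a zero-goal fit")
  object$env_accuracy
}

#' Plot the response profile of a fitted scheme
#'
#' @param x a [breeding_scheme()] fit.
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @export
plot.breeding_scheme <- function(x, y, ...) {
  graphics::plot(x$grid$x_mean, x$response, type = "b", pch = 16,
                 xlab = "environment (x)",
                 ylab = "response to selection per generation",
                 main = sprintf("%s scheme", x$scheme), ...)
  graphics::abline(x$R_int, x$R_sl, lty = 3)
  invisible(x)
}

#' Extract one sex's selection index from a fitted scheme
#'
#' @param object a [breeding_scheme()] fit.
#' @param sex `"male"` or `"female"`.
#' @return A `selection_index`-like list with the equilibrium weights,
#'   index variance and covariances with the per-environment breeding
#'   values.
#' @export
scheme_index <- function(object, sex = c("male", "female")) {
  sex <- match.arg(sex)
  s <- if (sex == "male") object$index_male else object$index_female
  structure(list(sources = s$sources, b = s$b, sigma_I = sqrt(s$sI2),
                 gI = s$gI, r_IH = unname(object$r_IH[sex])),
            class = "selection_index")
}

#' Ratio of responses between two fitted schemes
#'
#' @param numerator,denominator [breeding_scheme()] fits sharing a grid
#'   and goal.
#' @return List with per-environment response ratios and intercept/slope
#'   response ratios; cells with a near-zero denominator are flagged `NA`.
#' @export
compare_schemes <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "breeding_scheme"),
            inherits(denominator, "breeding_scheme"))
  safe_ratio <- function(a, b) ifelse(abs(b) < 1e-12, NA_real_, a / b)
  list(response_ratio = safe_ratio(numerator$response, denominator$response),
       intercept_ratio = safe_ratio(numerator$R_int, denominator$R_int),
       slope_ratio = safe_ratio(numerator$R_sl, denominator$R_sl))
}
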