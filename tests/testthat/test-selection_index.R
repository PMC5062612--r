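test_that("progeny-mean variances cover the single-record and family limits", {
  g <- default_grid(); p <- basic_params()
  P1 <- progeny_P(g, p, rep(1, 13))
  expect_equal(diag(P1), genetic_variance(p, g$x_mean) + p$var_e)
  Pbig <- progeny_P(g, p, rep(1e9, 13))
  expect_equal(diag(Pbig), 0.25 * genetic_variance(p, g$x_mean),
               tolerance = 1e-6)
  # central class with the standard 100-progeny allocation
  P <- progeny_P(g, p, rep(14.43, 13))
  expect_equal(P[7, 7], (0.3 + 0.7 + 13.43 * 0.25 * 0.3) / 14.43,
               tolerance = 1e-12)
  expect_equal(P[7, 7], 0.13910, tolerance = 1e-4)
  expect_error(progeny_P(g, p, rep(0, 13)), "> 0")
})

test_that("progeny goal covariances carry the parent-offspring relationship", {
  g <- env_grid(); p <- basic_params()
  G <- progeny_G(g, p)
  expect_equal(G[7, 7], 0.15)
  expect_equal(G[which.min(abs(g$x_mean + 1)), ],
               0.5 * genetic_covariance(p, g$x_mean[which.min(abs(g$x_mean + 1))],
                                        g$x_mean))
  Gflat <- progeny_G(g, rn_params(var_sl = 0))
  expect_true(all(abs(Gflat - 0.5 * 0.3) < 1e-12))
})

test_that("genomic accuracy follows the reference-size formula", {
  expect_equal(gebv_accuracy(0, 0.3), 0)
  expect_equal(gebv_accuracy(1200 / 0.3, 0.3), sqrt(0.5))
  expect_equal(gebv_accuracy(721.37, 0.3, 1200), 0.3909, tolerance = 1e-4)
  expect_true(all(diff(gebv_accuracy(c(10, 100, 1000, 1e6), 0.3)) > 0))
  expect_error(gebv_accuracy(-1, 0.3), ">= 0")
})

test_that("GEBV variance and goal matrices scale with accuracy", {
  g <- env_grid(); p <- basic_params()
  x <- g$x_mean
  rg <- outer(x, x, function(a, b) genetic_correlation(p, a, b))
  expect_equal(gebv_P(rep(1, 13), rg), { m <- rg; diag(m) <- 1; m })
  P0 <- gebv_P(c(0, rep(0.5, 12)), rg)
  expect_true(all(P0[1, -1] == 0) && all(P0[-1, 1] == 0))
  # two-class spot value: rg * r_i * r_j
  expect_equal(gebv_P(c(0.39, 0.74), matrix(c(1, .719, .719, 1), 2))[1, 2],
               0.719 * 0.39 * 0.74)
  G <- gebv_G(rep(1, 13), p, g)
  expect_equal(diag(G), sqrt(genetic_variance(p, x)))
  expect_equal(gebv_G(rep(0.3909, 13), p, g)[7, 7], 0.3909 * sqrt(0.3),
               tolerance = 1e-6)
})

test_that("index solving reduces to regression for one source and is exact
           for orthonormal systems", {
  idx1 <- solve_index(matrix(2), matrix(0.5), 1)
  expect_equal(idx1$b, 0.25)
  I13 <- diag(13)
  idx <- solve_index(I13, I13, rep(1, 13), C = I13)
  expect_equal(idx$b, rep(1, 13))
  expect_equal(idx$r_IH, 1)
})

test_that("near-duplicate sources are pruned with a warning", {
  P <- matrix(c(1, 1, 0.5,
                1, 1, 0.5,
                0.5, 0.5, 1), 3, 3)
  G <- matrix(c(0.4, 0.4, 0.2), ncol = 1)
  expect_warning(idx <- solve_index(P, G, 1), "pruning")
  expect_equal(length(idx$b), 2)
})

test_that("adding an information source never lowers the goal accuracy", {
  g <- default_grid(); p <- basic_params()
  P <- progeny_P(g, p); G <- progeny_G(g, p)
  C <- genetic_covmatrix(p, g)
  v <- as.numeric(breeding_goal(g, "proportional"))
  r_sub <- vapply(3:13, function(k) {
    solve_index(P[1:k, 1:k], G[1:k, ], v, C)$r_IH
  }, numeric(1))
  expect_true(all(diff(r_sub) > -1e-9))
})

test_that("per-environment accuracy behaves at its limits", {
  g <- default_grid(); p <- basic_params()
  # a perfect single source for class 7: the breeding value itself
  C <- genetic_covmatrix(p, g)
  idx <- solve_index(matrix(C[7, 7]), matrix(C[7, ], nrow = 1),
                     as.numeric(1:13 == 7))
  expect_equal(env_accuracy(idx, p, g, 7), 1, tolerance = 1e-9)
  # enormous progeny groups drive accuracy to one in every class
  Pb <- progeny_P(g, p, rep(1e8, 13)); Gb <- progeny_G(g, p)
  acc <- vapply(1:13, function(i)
    env_accuracy(solve_index(Pb, Gb, as.numeric(1:13 == i)), p, g, i),
    numeric(1))
  expect_true(all(acc > 0.999))
})

test_that("conventional collapse is lossless without GxE", {
  g <- allocate_animals(env_grid(), 5000, 100)
  pflat <- rn_params(var_sl = 0)
  rn <- accuracy_profile(pflat, g, "progeny", "rn")
  cv <- accuracy_profile(pflat, g, "progeny", "conventional")
  expect_equal(rn$accuracy, cv$accuracy, tolerance = 1e-9)
  rng <- accuracy_profile(pflat, g, "gebv", "rn")
  cvg <- accuracy_profile(pflat, g, "gebv", "conventional")
  expect_equal(rng$accuracy, cvg$accuracy, tolerance = 1e-9)
})

test_that("conventional accuracy factorizes into intercept accuracy times
           the genetic correlation with the average environment", {
  g <- default_grid(); p <- basic_params()
  for (ev in c("progeny", "gebv")) {
    cv <- accuracy_profile(p, g, ev, "conventional")$accuracy
    expect_equal(cv, cv[7] * genetic_correlation(p, g$x_mean, 0),
                 tolerance = 1e-9)
  }
})

test_that("reaction-norm accuracies dominate conventional ones across the
           standard parameter sets", {
  g <- default_grid()
  for (p in list(basic_params(), rn_params(cor_int_sl = 0.5),
                 rn_params(var_int = 0.1, var_sl = 0.1 / 6, var_e = 0.9),
                 rn_params(var_int = 0.5, var_sl = 0.5 / 6, var_e = 0.5))) {
    for (ev in c("progeny", "gebv")) {
      rn <- accuracy_profile(p, g, ev, "rn")$accuracy
      cv <- accuracy_profile(p, g, ev, "conventional")$accuracy
      expect_true(all(rn >= cv - 1e-9))
    }
  }
})

test_that("accuracy profiles are symmetric without intercept-slope
           correlation and tilted with it", {
  g <- default_grid()
  a0 <- accuracy_profile(basic_params(), g, "gebv", "rn")$accuracy
  expect_equal(a0, rev(a0), tolerance = 1e-9)
  p5 <- rn_params(cor_int_sl = 0.5)
  gap <- accuracy_profile(p5, g, "gebv", "rn")$accuracy -
    accuracy_profile(p5, g, "gebv", "conventional")$accuracy
  expect_equal(which.max(gap), 1)   # largest advantage in the worst class
})
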