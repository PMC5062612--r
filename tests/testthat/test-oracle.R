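test_that("simulated populations reproduce the configured architecture", {
  g <- env_grid()
  pflat <- rn_params(var_sl = 0)
  pop <- simulate_families(pflat, g, 400, 5, 4, seed = 11)
  # without slope variance the phenotypic variance is var_int + var_e in
  # every (occupied) class
  pr <- pop$progeny
  for (i in c(4, 7, 10)) {
    v <- var(pr$phenotype[pr$env == i])
    n <- sum(pr$env == i)
    se <- (0.3 + 0.7) * sqrt(2 / (n - 1))
    expect_lt(abs(v - 1), 3 * se)
  }
  # intercept/slope covariance of drawn breeding values matches the input
  p5 <- rn_params(cor_int_sl = 0.5)
  pop5 <- simulate_families(p5, g, 2000, 1, 1, seed = 12)
  S <- cov(pop5$parents[pop5$parents$sex == "m", c("a_int", "a_sl")])
  expect_lt(abs(S[1, 1] - 0.3), 3 * 0.3 * sqrt(2 / 1999))
  expect_lt(abs(S[1, 2] - p5$cov_int_sl), 3 * sqrt((0.3 * 0.05 +
    p5$cov_int_sl^2) / 1999))
})

test_that("a fixed seed reproduces the population bit for bit", {
  g <- env_grid(); p <- rn_params()
  a <- simulate_families(p, g, 50, 2, 3, seed = 99)
  b <- simulate_families(p, g, 50, 2, 3, seed = 99)
  expect_identical(a$progeny, b$progeny)
  c2 <- simulate_families(p, g, 50, 2, 3, seed = 100)
  expect_false(identical(a$progeny$phenotype, c2$progeny$phenotype))
})

test_that("fixed allocation distributes exact integer counts", {
  g <- env_grid()
  n <- fixed_counts(g$proportion, 100)
  expect_equal(sum(n), 100)
  expect_true(all(abs(n - g$proportion * 100) <= 1))
  pop <- simulate_families(rn_params(), g, 10, 100, 1, seed = 3,
                           allocation = "fixed")
  expect_equal(as.integer(table(factor(pop$progeny$env[pop$progeny$sire == 1],
                                       levels = 1:13))), n)
})

test_that("realized index accuracy tracks the deterministic prediction", {
  g <- env_grid(); p <- rn_params()
  pop <- simulate_families(p, g, 600, 100, 1, seed = 5, allocation = "fixed")
  ni <- fixed_counts(g$proportion, 100)
  idx <- solve_index(progeny_P(g, p, ni), progeny_G(g, p),
                     as.numeric(breeding_goal(g, "proportional")),
                     genetic_covmatrix(p, g))
  emp <- empirical_accuracy(pop, idx$b)
  pred <- env_accuracy(idx, p, g)
  se <- (1 - pred^2) / sqrt(600)
  expect_true(all(abs(emp - pred) < 3 * se))
})

test_that("degenerate oracle inputs are rejected or trivial", {
  g <- env_grid(); p <- rn_params()
  pop <- simulate_families(p, g, 20, 2, 2, seed = 1)
  expect_error(empirical_accuracy(pop, rep(0, 13)), "zero-weight")
  expect_equal(empirical_response(pop, rep(1, 13), 1), rep(0, 13))
})

test_that("one-class truncation recovers the classic i * accuracy * sigma_A
           response", {
  g1 <- env_grid(1, Inf)
  p <- rn_params(var_sl = 0)
  pop <- simulate_families(p, g1, 2000, 50, 1, seed = 21)
  idx <- solve_index(progeny_P(g1, p, 50), progeny_G(g1, p),
                     1, genetic_covmatrix(p, g1))
  emp <- empirical_response(pop, idx$b, 0.1)
  pred <- 0.5 * selection_intensity(0.1, 2000, 0) * idx$gI / idx$sigma_I
  se <- 0.5 * sqrt(0.3) / sqrt(200)
  expect_lt(abs(emp - pred), 3 * se)
})

test_that("simulate() on a fitted scheme returns seeded replicate responses", {
  g <- env_grid()
  fit <- breeding_scheme("progeny", rn_params(), g,
                         breeding_goal(g, "proportional"))
  r1 <- simulate(fit, nsim = 2, seed = 7, n_sires = 60,
                 n_dams_per_sire = 10, n_prog_per_dam = 1)
  expect_equal(dim(r1), c(13, 2))
  r2 <- simulate(fit, nsim = 2, seed = 7, n_sires = 60,
                 n_dams_per_sire = 10, n_prog_per_dam = 1)
  expect_identical(r1, r2)
})
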