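test_that("selection intensity covers the textbook limits", {
  expect_equal(selection_intensity(1), 0)
  expect_equal(selection_intensity(0.05), dnorm(qnorm(0.95)) / 0.05)
  expect_equal(selection_intensity(0.05), 2.063, tolerance = 1e-3)
  # decreasing in the index correlation and in 1/n
  i0 <- selection_intensity(0.05, 1000, 0)
  i1 <- selection_intensity(0.05, 1000, 0.02)
  i2 <- selection_intensity(0.05, 100, 0)
  expect_true(i1 < i0 && i2 < i0 && i0 < selection_intensity(0.05))
  expect_error(selection_intensity(1.2), "\\(0, 1\\]")
  expect_error(selection_intensity(0.05, 10, 1), "\\[0, 1\\)")
})

test_that("no selection means no Bulmer reduction and no response", {
  g <- env_grid(); p <- rn_params()
  fit <- breeding_scheme("sib", p, g, breeding_goal(g, "proportional"),
                         p_male = 1, p_female = 1)
  expect_equal(fit$equilibrium$var_int, p$var_int, tolerance = 1e-7)
  expect_equal(fit$equilibrium$var_sl, p$var_sl, tolerance = 1e-7)
  expect_equal(max(abs(fit$response)), 0, tolerance = 1e-12)
})

test_that("selection erodes genetic variance at equilibrium", {
  g <- env_grid(); p <- rn_params()
  for (sc in c("genomic", "sib", "progeny")) {
    fit <- breeding_scheme(sc, p, g, breeding_goal(g, "proportional"))
    expect_lt(fit$equilibrium$var_int, p$var_int)
    expect_true(fit$converged)
  }
})

test_that("equilibrium accuracies sit below their base-population values", {
  g <- env_grid(); p <- rn_params()
  goal <- breeding_goal(g, "proportional")
  for (sc in c("genomic", "sib", "progeny")) {
    eq <- breeding_scheme(sc, p, g, goal)
    base <- breeding_scheme(sc, p, g, goal, bulmer = FALSE)
    expect_lt(eq$r_IH["male"], base$r_IH["male"])
    expect_lt(eq$r_IH["female"], base$r_IH["female"])
  }
})

test_that("responses lie exactly on a line in the environment", {
  g <- env_grid(); p <- rn_params()
  for (sc in c("genomic", "sib", "progeny")) {
    fit <- breeding_scheme(sc, p, g, breeding_goal(g, "resilience"))
    slopes <- (fit$response[-7] - fit$R_int) / g$x_mean[-7]
    expect_true(all(abs(slopes - fit$R_sl) < 1e-6))
    # predict() interpolates the same line
    expect_equal(predict(fit), fit$response, tolerance = 1e-9)
  }
})

test_that("a proportional goal with uncorrelated intercept and slope gives a
           flat response profile for every scheme", {
  g <- env_grid(); p <- rn_params()
  goal <- breeding_goal(g, "proportional")
  for (sc in c("genomic", "sib", "progeny")) {
    fit <- breeding_scheme(sc, p, g, goal, nucleus = FALSE)
    expect_lt(abs(fit$R_sl) / abs(fit$R_int), 1e-6)
  }
})

test_that("zero economic values give zero response", {
  g <- env_grid()
  fit <- breeding_scheme("genomic", rn_params(), g, rep(0, 13))
  expect_equal(fit$response, rep(0, 13))
  expect_equal(unname(coef(fit)), c(0, 0))
})

test_that("a scheme compared with itself gives unit ratios", {
  g <- env_grid()
  fit <- breeding_scheme("sib", rn_params(), g, breeding_goal(g, "resilience"))
  cmp <- compare_schemes(fit, fit)
  expect_equal(cmp$response_ratio, rep(1, 13))
  expect_equal(cmp$intercept_ratio, 1)
  expect_equal(cmp$slope_ratio, 1)
})

test_that("near-zero denominators are flagged rather than divided", {
  g <- env_grid()
  a <- breeding_scheme("genomic", rn_params(), g, breeding_goal(g, "resilience"))
  z <- breeding_scheme("genomic", rn_params(), g, rep(0, 13))
  cmp <- compare_schemes(a, z)
  expect_true(all(is.na(cmp$response_ratio)))
})

test_that("huge reference populations make the index nearly perfect for
           the aggregate goal", {
  g <- env_grid(); p <- rn_params()
  fit <- breeding_scheme("genomic", p, g, breeding_goal(g, "proportional"),
                         ref_size = 1e8)
  # with near-perfect per-class genomic values the single goal index
  # recovers the aggregate genotype itself
  expect_true(all(fit$r_IH > 0.999))
})

test_that("scheme fits expose their index systems and methods work", {
  g <- env_grid()
  fit <- breeding_scheme("sib", rn_params(), g, breeding_goal(g, "proportional"))
  im <- scheme_index(fit, "male")
  expect_s3_class(im, "selection_index")
  expect_true("fullsib_mean" %in% im$sources)
  expect_false("own_performance" %in% im$sources)
  expect_true("own_performance" %in% scheme_index(fit, "female")$sources)
  expect_output(print(fit), "accuracy r_IH")
  s <- summary(fit)
  expect_equal(nrow(s$table), 13)
})

test_that("female information is identical in sib and progeny schemes at
           fixed genetic parameters", {
  g <- env_grid(); p <- rn_params()
  goal <- breeding_goal(g, "proportional")
  # without Bulmer feedback the two schemes' female indices coincide
  sib <- breeding_scheme("sib", p, g, goal, bulmer = FALSE)
  prg <- breeding_scheme("progeny", p, g, goal, bulmer = FALSE)
  expect_equal(unname(sib$r_IH["female"]), unname(prg$r_IH["female"]),
               tolerance = 1e-6)
  # with Bulmer, the more accurate male path erodes more variance and the
  # progeny-scheme females lose accuracy relative to sib-scheme females
  sib_eq <- breeding_scheme("sib", p, g, goal)
  prg_eq <- breeding_scheme("progeny", p, g, goal)
  expect_lt(prg_eq$r_IH["female"], sib_eq$r_IH["female"])
})
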