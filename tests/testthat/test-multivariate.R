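test_that("the reference design has the expected shape", {
  d <- fixture_entries()
  dm <- build_design(d, c("sulfates_per_disaccharide", "solute_molarity",
                          "protein_gag_molar_ratio"),
                     quadratic = "protein_gag_molar_ratio")
  expect_equal(dim(dm$X), c(39L, 5L))
  expect_equal(colnames(dm$X)[1], "(Intercept)")
  expect_true("I(protein_gag_molar_ratio^2)" %in% colnames(dm$X))
  # intercept-only design
  dm0 <- build_design(d, character(0))
  expect_equal(ncol(dm0$X), 1L)
  # duplicated column fails the exact rank check
  expect_error(build_design(d, c("solute_molarity", "solute_molarity")),
               "collinear")
  # quadratic without linear term and for categorical variables are refused
  expect_error(build_design(d, "solute_molarity", quadratic = "gag_mw"),
               "linear term")
  expect_error(build_design(d, "uronic_acid", quadratic = "uronic_acid"),
               "continuous")
})

test_that("ols_fit matches the explicit normal-equations oracle to 1e-10", {
  set.seed(20)
  X <- cbind("(Intercept)" = 1, a = rnorm(20), b = rnorm(20))
  y <- drop(X %*% c(1, 2, -0.5)) + rnorm(20)
  fit <- ols_fit(X, y)
  oracle <- normal_equations_oracle(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-10)
  expect_equal(fit$residuals, oracle$residuals, tolerance = 1e-10)
})

test_that("ols_fit agrees with lm, car::vif and lmtest::bptest", {
  d <- fixture_entries()
  dm <- build_design(d, c("sulfates_per_disaccharide", "solute_molarity",
                          "protein_gag_molar_ratio"),
                     quadratic = "protein_gag_molar_ratio")
  fit <- ols_fit(dm$X, dm$y)
  df <- as.data.frame(dm$X[, -1])
  names(df) <- c("ps", "pb", "pmr", "pmr2")
  df$G <- dm$y
  ref <- stats::lm(G ~ ps + pb + pmr + pmr2, data = df)
  sm <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sm$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(unname(fit$p), unname(sm$coefficients[, 4]), tolerance = 1e-10)
  expect_equal(fit$r2, sm$r.squared, tolerance = 1e-12)
  expect_equal(fit$r2_adj, sm$adj.r.squared, tolerance = 1e-12)
  expect_equal(fit$model_p,
               stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                         lower.tail = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(fit$vif), unname(car::vif(ref)), tolerance = 1e-8)
  expect_equal(fit$heteroscedasticity_p,
               lmtest::bptest(ref)$p.value, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("an exactly linear response is fitted perfectly", {
  set.seed(8)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(15), x2 = runif(15))
  y <- drop(X %*% c(0.5, -2, 3))
  fit <- ols_fit(X, y)
  expect_equal(fit$r2, 1)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_error(ols_fit(cbind(X, x3 = X[, "x1"]), y), "singular|rank")
})

test_that("adjusted R2 does not reward pure-noise columns on average", {
  set.seed(99)
  deltas <- replicate(100, {
    X <- cbind("(Intercept)" = 1, x = rnorm(50))
    y <- 1 + 0.8 * X[, "x"] + rnorm(50)
    base <- ols_fit(X, y)$r2_adj
    aug <- ols_fit(cbind(X, junk = rnorm(50)), y)$r2_adj
    aug - base
  })
  expect_lt(mean(deltas), 0.005)
})

test_that("refitting the fixture recovers the generating coefficients", {
  d <- fixture_entries()
  m <- fit_gag_model(d)
  expect_equal(sign(unname(eq_coefficients(m))), sign(unname(eq_truth)))
  expect_true(all(abs(unname(eq_coefficients(m)) - unname(eq_truth)) <=
                    4 * unname(m$se)))
  expect_true(all(m$coef_table$p < 0.05))
  expect_gt(m$r2_adj, 0.55)
  expect_lt(m$r2_adj, 0.90)
})

test_that("generating coefficients are recovered within 2 SEs across seeds", {
  counts <- rep(0L, 5)
  for (s in 1:100) {
    m <- fit_gag_model(generate_gag_entries(n = 39, seed = s))
    counts <- counts + (abs(unname(m$coefficients) - unname(eq_truth)) <=
                          2 * unname(m$se))
  }
  expect_true(all(counts >= 90L))
})

test_that("prediction follows the linear-quadratic form exactly", {
  # hand evaluation: 2.0 + 0.30*2 - 0.016*100 + 0.11*10 - 0.0020*100 = 1.9
  expect_equal(predict_G(P_S = 2, P_B = 100, P_MR = 10), 1.9)
  # intercept and molarity cancel: 2.0 - 0.016*125 = 0
  expect_equal(predict_G(P_S = 0, P_B = 125, P_MR = 0), 0)
  zero <- published_gag_model()
  zero$coefficients[] <- 0
  expect_equal(predict_G(3, 50, 7, model = zero), 0)
  expect_error(predict_G(-1, 100, 10), "non-negative")
  # superposition: prediction is linear in each coefficient
  m1 <- published_gag_model(); m2 <- published_gag_model()
  m2$coefficients[] <- runif(5)
  m3 <- published_gag_model()
  m3$coefficients <- m1$coefficients + m2$coefficients
  pts <- list(c(0, 20, 1), c(2, 100, 10), c(3, 300, 60))
  for (p in pts)
    expect_equal(predict_G(p[1], p[2], p[3], model = m3),
                 predict_G(p[1], p[2], p[3], model = m1) +
                   predict_G(p[1], p[2], p[3], model = m2))
})

test_that("the optimal molar ratio is the quadratic vertex", {
  opt <- optimal_molar_ratio(published_gag_model())
  expect_equal(opt$ratio, 27.5)   # -0.11 / (2 * -0.0020)
  # brute-force grid oracle
  grid <- seq(0.1, 100, by = 0.01)
  gg <- predict_G(P_S = 0, P_B = 0, P_MR = grid)
  expect_equal(grid[which.max(gg)], opt$ratio, tolerance = 0.011)
  # degenerate quadratics
  m <- published_gag_model()
  m$coefficients["protein_gag_molar_ratio"] <- 0
  expect_equal(optimal_molar_ratio(m)$ratio, 0)
  m$coefficients["I(protein_gag_molar_ratio^2)"] <- 0.001
  expect_error(optimal_molar_ratio(m), "no interior maximum")
})

test_that("selection identifies the generating specification at n = 200", {
  d <- generate_gag_entries(n = 200, seed = 1)
  sel <- select_model(d)
  expect_equal(sort(sel$terms), reference_terms)
  expect_true(isTRUE(sel$methods_agree) || is.na(sel$methods_agree))
  expect_gt(sel$best$r2_adj, 0.65)
})

test_that("a pure-noise response yields a no-model error at the nominal rate", {
  # With a single candidate predictor the screen admits a noise response only
  # at the 5% false-positive rate of its significance test, so the no-model
  # error must occur in the overwhelming majority of seeded noise datasets.
  # (Over a large candidate universe some spurious subset clears the screen
  # much more often - the same multiple-testing arithmetic bounds exact
  # recovery under the selection rule.)
  universe <- list(linear = "solute_molarity", categorical = character(0),
                   quadratic = character(0))
  errs <- 0L
  for (s in 1:40) {
    d <- generate_gag_entries(n = 60, seed = 400 + s)
    set.seed(500 + s)
    d$G <- rnorm(60)
    d$t_half_with_gag <- 24 * exp(-d$G)   # keep entries self-consistent
    out <- tryCatch(select_model(d, universe = universe),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      expect_match(out, "no candidate model")
      errs <- errs + 1L
    }
  }
  expect_gte(errs, 30L)
})

test_that("noiseless responses are refit exactly", {
  d <- generate_gag_entries(n = 39, noise_sd = 0, seed = 21)
  m <- fit_gag_model(d)
  expect_equal(unname(eq_coefficients(m)), unname(eq_truth),
               tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-10)
})

test_that("model methods expose the standard generics", {
  d <- fixture_entries()
  m <- fit_gag_model(d)
  expect_equal(length(coef(m)), 5L)
  expect_equal(length(residuals(m)), 39L)
  expect_equal(fitted(m) + residuals(m), m$y)
  expect_equal(predict(m, newdata = d), fitted(m))
  sims <- simulate(m, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(39L, 3L))
  expect_identical(sims, simulate(m, nsim = 3, seed = 5))
  expect_output(print(summary(m)), "adj R2")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
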