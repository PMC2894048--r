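test_that("correlate reports exact Pearson r, p and the fitted line", {
  d <- data.frame(x = 1:10, G = 2 * (1:10) - 3)
  r <- correlate(d, "x")
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-10)
  expect_equal(r$slope, 2)
  expect_equal(r$x_intercept, 1.5)  # 2x - 3 = 0
  # against the textbook t transform on an imperfect relation
  set.seed(31)
  d2 <- data.frame(x = rnorm(25), G = rnorm(25))
  r2 <- correlate(d2, "x")
  tstat <- r2$r * sqrt((r2$n - 2) / (1 - r2$r^2))
  expect_equal(r2$p, 2 * stats::pt(abs(tstat), r2$n - 2, lower.tail = FALSE))
})

test_that("correlate is invariant to affine rescaling of x", {
  d <- fixture_entries()
  a <- correlate(d, "solute_molarity")
  d$solute_molarity <- 3.5 * d$solute_molarity + 11
  b <- correlate(d, "solute_molarity")
  expect_equal(b$r, a$r)
  expect_equal(b$p, a$p)
  expect_equal(b$slope, a$slope / 3.5)
})

test_that("degenerate univariate inputs error informatively", {
  d <- fixture_entries()
  expect_error(correlate(d[1:2, ], "solute_molarity"), "insufficient")
  d2 <- d; d2$solute_molarity <- 5
  expect_error(correlate(d2, "solute_molarity"), "constant")
  d3 <- d; d3$sulfates_per_disaccharide <- rep(c(0, 1), length.out = 39)
  expect_error(mean_G_by_level(d3, "sulfates_per_disaccharide"),
               "3 distinct levels")
  expect_error(mean_G_by_bin(d, "solute_molarity",
                             breaks = range(d$solute_molarity)),
               "3 non-empty bins")
})

test_that("permutation null agrees with the analytic p-value", {
  d <- fixture_entries()
  obs <- correlate(d, "sulfates_per_disaccharide")
  set.seed(123)
  n_perm <- 1000
  exceed <- 0
  for (i in seq_len(n_perm)) {
    dp <- d; dp$G <- sample(d$G)
    if (abs(correlate(dp, "sulfates_per_disaccharide")$r) >= abs(obs$r))
      exceed <- exceed + 1
  }
  p_perm <- exceed / n_perm
  se <- sqrt(obs$p * (1 - obs$p) / n_perm)
  expect_lt(abs(p_perm - obs$p), 4 * se + 0.005)
})

test_that("level means reduce to raw values with one entry per level", {
  d <- data.frame(x = c(0, 1, 2, 3), G = c(0.1, 0.5, 0.4, 1.2))
  out <- mean_G_by_level(d, "x")
  expect_equal(out$groups$mean_G, d$G)
  expect_true(all(is.na(out$groups$sd_G)))
  expect_equal(out$groups$n, rep(1L, 4))
})

test_that("a generator with zero sulfation effect yields null level-means", {
  null_cf <- c(2.0, 0, -0.016, 0.11, -0.0020)
  sig <- 0
  for (s in 1:100) {
    d <- generate_gag_entries(n = 39, coefficients = null_cf, seed = 200 + s)
    out <- mean_G_by_level(d, "sulfates_per_disaccharide")
    if (out$correlation$p <= 0.05) sig <- sig + 1
  }
  expect_lte(sig, 10)   # nominal 5% false-positive rate
})

test_that("binned means recover the sign of a generating molarity effect", {
  d <- generate_gag_entries(n = 200, seed = 77)
  out <- mean_G_by_bin(d, "solute_molarity")
  expect_lt(out$correlation$slope, 0)
  expect_equal(sum(out$groups$n), 200L)
  expect_true(all(diff(out$breaks) > 0))
})

test_that("identical groups are not distinguished; separated groups are", {
  g <- c(0.2, 0.5, 0.9, 1.4, 0.7)
  d <- data.frame(grp = rep(c("A", "B"), each = 5), G = c(g, g))
  res <- compare_two_groups(d, "grp", "A", "B")
  expect_equal(res$p, 1)
  expect_equal(diff(res$groups$mean_G), 0)
  # power: groups offset by 3 pooled SDs, n = 10 each
  hits <- 0
  set.seed(55)
  for (i in 1:100) {
    dd <- data.frame(grp = rep(c("A", "B"), each = 10),
                     G = c(rnorm(10, 0, 1), rnorm(10, 3, 1)))
    if (compare_two_groups(dd, "grp", "A", "B")$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("tiny groups return summaries without a test", {
  d <- data.frame(grp = c("A", "A", "B"), G = c(0.1, 0.4, 0.9))
  res <- compare_two_groups(d, "grp", "A", "B")
  expect_true(is.na(res$p))
  expect_equal(res$groups$n, c(2L, 1L))
  expect_error(compare_two_groups(d, "grp", "A", "C"), "empty group")
})

test_that("matching restricts the comparison to fixed covariate values", {
  d <- fixture_entries()
  res <- compare_two_groups(d, "uronic_acid", "iduronic", "glucuronic",
                            match = list(sulfates_per_disaccharide = 2))
  expect_equal(sum(res$groups$n),
               sum(d$sulfates_per_disaccharide == 2 &
                     d$uronic_acid %in% c("iduronic", "glucuronic")))
})

test_that("sulfation line passes near the origin, charge line near one", {
  # population diagnostics of the generating model, evaluated at large n:
  # no sulfates -> no acceleration; with ~1 carboxylate charge per
  # disaccharide the charge line crosses zero near charge 1
  d <- generate_gag_entries(n = 10000, seed = 7)
  cs <- correlate(d, "sulfates_per_disaccharide")
  cc <- correlate(d, "charges_per_disaccharide")
  expect_lte(abs(cs$x_intercept), 0.5)
  expect_lte(abs(cc$x_intercept - 1), 0.5)
  # the two slopes agree within their joint standard errors
  expect_lte(abs(cs$slope - cc$slope),
             2 * sqrt(cs$se_slope^2 + cc$se_slope^2))
})
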