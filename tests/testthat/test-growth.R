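# Fixed-asymptote sigmoid fitting, peak rate, DME and model comparison.

test_that("noiseless parameters are recovered to high precision", {
  ages <- seq(2, 28, length.out = 8)
  obs <- data.frame(age = ages, mass = growth_curve(ages, -0.55, 16, 9502))
  f <- fit_growth(obs, 9502)
  expect_lt(abs(f$a + 0.55), 1e-6)
  expect_lt(abs(f$b - 16), 1e-6)
  # the fitted curve passes through half max (plus offset) at age b
  expect_equal(growth_curve(f$b, f$a, f$b, 9502), 9502 / 2 + 5)
  expect_error(fit_growth(obs[1:2, ], 9502), "at least 3")
})

test_that("refined SS does not increase with multi-start grid density", {
  set.seed(9)
  ages <- seq(1, 30, length.out = 9)
  obs <- data.frame(age = ages,
                    mass = growth_curve(ages, -0.4, 14, 8000) +
                      rnorm(9, 0, 250))
  ss <- vapply(c(8, 16, 32, 64),
               function(g) fit_growth(obs, 8000, grid_n = g)$ss, 0)
  # refinement from denser grids never loses ground (up to solver jitter)
  expect_true(all(diff(ss) <= 1e-6 * ss[1]))
})

test_that("peak growth rate matches the closed form and a numeric oracle", {
  f <- list(a = -0.4, b = 15, max_mass = 10000, hatchling_mass = 5)
  class(f) <- "growth_fit"
  expect_equal(peak_growth_rate(f), 1000)
  num <- numeric_peak_rate(function(t) growth_curve(t, -0.4, 15, 10000),
                           0, 40)
  expect_equal(num, 1000, tolerance = 1e-6)
  # linear in the asymptote at fixed slope
  f2 <- f
  f2$max_mass <- 20000
  expect_equal(peak_growth_rate(f2), 2 * peak_growth_rate(f))
  # |a| is recoverable from the closed form
  expect_equal(peak_growth_rate(f) * 4 / f$max_mass, abs(f$a))
})

test_that("age at half max is b, equivariant under age shifts", {
  ages <- seq(2, 28, length.out = 8)
  obs <- data.frame(age = ages, mass = growth_curve(ages, -0.5, 13.5, 9502))
  f <- fit_growth(obs, 9502)
  expect_equal(age_at_half_max(f), 13.5, tolerance = 1e-6)
  # root-finding oracle: solve mass(t) = max/2 + 5
  root <- uniroot(function(t) growth_curve(t, f$a, f$b, 9502) - (9502 / 2 + 5),
                  c(0, 40), tol = 1e-10)$root
  expect_equal(root, age_at_half_max(f), tolerance = 1e-6)
  shifted <- obs
  shifted$age <- shifted$age + 2
  f2 <- fit_growth(shifted, 9502)
  expect_equal(age_at_half_max(f2), age_at_half_max(f) + 2, tolerance = 1e-6)
})

test_that("DME masses follow the femoral cube law", {
  fl <- c(Jane = 0.788, Sue = 1.312)
  d <- dme_masses(fl, "Sue", 9502)
  expect_equal(unname(d["Sue"]), 9502)
  # arithmetic oracle computed directly from the printed inputs
  expect_equal(unname(d["Jane"]), 9502 * (0.788 / 1.312)^3, tolerance = 1e-12)
  half <- dme_masses(c(A = 0.5, Apex = 1), "Apex", 800)
  expect_equal(unname(half["A"]), 100)
  # scale equivariance: units of femoral length cancel
  d2 <- dme_masses(fl * 100, "Sue", 9502)
  expect_equal(unname(d2), unname(d))
  expect_error(dme_masses(fl, "Stan", 9502), "not found")
})

test_that("identical series yield F near zero and a common-model preference", {
  set.seed(3)
  ages <- seq(2, 28, length.out = 8)
  obs <- data.frame(age = ages,
                    mass = growth_curve(ages, -0.5, 15, 9502) +
                      rnorm(8, 0, 150))
  cmp <- compare_growth_models(obs, obs, 9502)
  expect_lt(cmp$F, 1e-6)
  expect_equal(cmp$preferred, "common")
  expect_equal(sum(cmp$akaike_weights), 1)
  # AICc values match a brute-force recomputation from stored SS and k
  n <- 2 * nrow(obs)
  expect_equal(cmp$aicc_common,
               n * log(cmp$ss_common / n) + 4 + 12 / (n - 3))
  expect_equal(cmp$aicc_separate,
               n * log(cmp$ss_separate / n) + 8 + 40 / (n - 5))
})

test_that("clearly different sigmoids are detected as separate", {
  set.seed(11)
  ages <- seq(2, 28, length.out = 8)
  a_series <- data.frame(age = ages,
                         mass = growth_curve(ages, -0.5, 12, 9502) +
                           rnorm(8, 0, 100))
  b_series <- data.frame(age = ages,
                         mass = growth_curve(ages, -0.5, 17, 9502) +
                           rnorm(8, 0, 100))
  cmp <- compare_growth_models(a_series, b_series, 9502)
  expect_equal(cmp$preferred, "separate")
  expect_gt(cmp$akaike_weights[["separate"]], 0.95)
  expect_lt(cmp$p_value, 0.01)
})

test_that("confidence band collapses at level zero and covers the curve", {
  set.seed(21)
  ages <- seq(2, 28, length.out = 10)
  obs <- data.frame(age = ages,
                    mass = growth_curve(ages, -0.5, 15, 9502) +
                      rnorm(10, 0, 200))
  f <- fit_growth(obs, 9502)
  grid <- seq(0, 35, by = 1)
  b0 <- confidence_band(f, 0, grid)
  expect_equal(b0$lo, b0$fit)
  expect_equal(b0$hi, b0$fit)
  b <- confidence_band(f, 0.95, grid)
  expect_true(all(b$lo <= b$fit & b$fit <= b$hi))
  # uncertainty concentrates around the steep growth phase and pinches
  # toward the imposed asymptote
  w <- b$hi - b$lo
  expect_gt(w[grid == round(f$b)], w[grid == 35])
  expect_gt(max(w), 0)
})

test_that("band coverage is near nominal over replicated simulations", {
  set.seed(42)
  ages <- seq(2, 28, length.out = 10)
  truth <- growth_curve(ages, -0.5, 15, 9502)
  cov <- replicate(200, {
    obs <- data.frame(age = ages, mass = truth + rnorm(10, 0, 300))
    f <- fit_growth(obs, 9502, grid_n = 24)
    b <- confidence_band(f, 0.95, ages)
    mean(truth >= b$lo & truth <= b$hi)
  })
  expect_gt(mean(cov), 0.88)
  expect_lt(mean(cov), 0.99)
})

test_that("simulated growth series are seeded and unbiased", {
  s1 <- generate_growth_series(-0.5, 15, 9502, 200, seq(2, 28, 2), seed = 5)
  s2 <- generate_growth_series(-0.5, 15, 9502, 200, seq(2, 28, 2), seed = 5)
  expect_identical(s1, s2)
  exact <- generate_growth_series(-0.5, 15, 9502, 0, c(5, 15, 25), seed = 1)
  expect_equal(exact$mass, growth_curve(c(5, 15, 25), -0.5, 15, 9502))
  big <- generate_growth_series(-0.5, 15, 9502, 100, rep(15, 1e4), seed = 2)
  resid <- big$mass - growth_curve(15, -0.5, 15, 9502)
  expect_lt(abs(mean(resid)), 3 * 100 / sqrt(1e4))
  expect_error(generate_growth_series(-0.5, 15, 9502, 0, numeric(0)),
               "non-empty")
})
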