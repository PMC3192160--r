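# CFL loop construction, loft mass, validation harness and the
# segment-minus-bone extensor estimates.

circle_loop <- function(station, r, n = 64) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  structure(list(station = station, landmarks = NULL,
                 points = cbind(r * sin(th), r * cos(th))),
            class = "cfl_loop")
}

test_that("loops pass through their landmarks and honour the transition", {
  skel <- tyranno_fixture()$skeleton
  series <- skel$caudal_series
  loops <- cfl_loops(series)
  expect_length(loops, series$transition_point - 1)
  for (i in c(1, length(loops))) {
    lm <- series$vertebrae[[i]]$landmarks
    for (nm in c("transverse_process_tip", "chevron_tip")) {
      p <- lm[[nm]][c(2, 3)]
      d <- sqrt(colSums((t(loops[[i]]$points) - p)^2))
      expect_lt(min(d), 0.01)    # resampled curve passes through the node
    }
  }
  # a vertebra without a chevron landmark is reported by index
  broken <- series
  broken$vertebrae[[2]]$landmarks$chevron_tip <- NULL
  expect_error(cfl_loops(broken), "vertebra 2.*chevron_tip")
})

test_that("elliptical loop areas match the closed form", {
  ck <- generate_skeleton(crocodile_params())
  loops <- cfl_loops(ck$caudal_series)
  for (i in c(1, 5, length(loops))) {
    ab <- ck$caudal_series$vertebrae[[i]]$semi_axes
    expect_equal(loop_area(loops[[i]]), pi * ab[1] * ab[2],
                 tolerance = 0.01)
  }
})

test_that("lofted loop mass matches the cylinder closed form", {
  loops <- list(circle_loop(0, 0.1), circle_loop(-0.5, 0.1))
  res <- cfl_mass(loops, density = 1000, bilateral = FALSE)
  expect_equal(res$mass, 1000 * pi * 0.01 * 0.5, tolerance = 0.005)
  # linear in density
  res1060 <- cfl_mass(loops, density = 1060, bilateral = FALSE)
  expect_equal(res1060$mass / res$mass, 1.06, tolerance = 1e-12)
  # bilateral doubles the mass
  resb <- cfl_mass(loops, density = 1000, bilateral = TRUE)
  expect_equal(resb$mass, 2 * res$mass)
  expect_error(cfl_mass(loops[1]), "at least 2")
})

test_that("CFL reconstruction is invariant under rigid motion of landmarks", {
  skel <- tyranno_fixture()$skeleton
  series <- skel$caudal_series
  m0 <- cfl_mass(cfl_loops(series), bilateral = FALSE)$mass
  th <- 0.6
  rot <- function(p) c(p[1],
                       cos(th) * p[2] - sin(th) * p[3],
                       sin(th) * p[2] + cos(th) * p[3]) + c(0, 0.4, -0.2)
  moved <- series
  moved$vertebrae <- lapply(series$vertebrae, function(v) {
    v$landmarks <- lapply(v$landmarks, rot)
    v
  })
  m1 <- cfl_mass(cfl_loops(moved), bilateral = FALSE)$mass
  expect_equal(m1, m0, tolerance = 1e-9)
})

test_that("blind reconstruction of the crocodile-like tail is within 5%", {
  ck <- generate_skeleton(crocodile_params())
  est <- cfl_mass(cfl_loops(ck$caudal_series), bilateral = FALSE)
  truth <- ck$ground_truth$cfl_territory_volume
  expect_lt(abs(est$volume - truth) / truth, 0.05)
})

test_that("density correction reproduces the printed validation numbers", {
  v <- cfl_validation(0.311, 0.316, 1000, 1060)
  expect_equal(v$corrected_mass, 0.330, tolerance = 5e-4)
  expect_equal(v$overestimate_pct, 4.4, tolerance = 0.05)
})

test_that("maximal CFL scaling and body-mass fractions match printed cells", {
  expect_equal(cfl_max(189, 3477, 1171), 561, tolerance = 1)
  expect_equal(cfl_max(187, 2383, 858), 520, tolerance = 1)
  expect_equal(cfl_max(50, 70, 70), 50)
  expect_error(cfl_max(-1, 2, 1), "> 0")
  expect_equal(cfl_fraction(34.0, 639), 5.32, tolerance = 0.005)
  expect_equal(cfl_fraction(192, 5934), 3.24, tolerance = 0.005)
  expect_equal(cfl_fraction(0, 5934), 0)
})

test_that("tendon extension is reported separately and is negligible", {
  skel <- tyranno_fixture()$skeleton
  res <- cfl_mass(cfl_loops(skel$caudal_series),
                  fourth_trochanter = skel$caudal_series$fourth_trochanter)
  expect_gt(res$tendon_mass, 0)
  expect_lt(res$tendon_mass / res$mass, 0.01)
})

test_that("extensor masses reproduce printed columns and conserve totals", {
  stan <- extensor_masses(1026, 342, 0.0340, 0.0238, 192, 5934)
  pct <- stats::setNames(stan$pct_body_mass, stan$joint)
  expect_equal(unname(pct["hip"]), 12.3, tolerance = 0.05)
  expect_equal(unname(pct["knee"]), 5.68, tolerance = 0.05)
  expect_equal(unname(pct["ankle"]), 2.52, tolerance = 0.05)
  expect_equal(unname(pct["total"]), 20.5, tolerance = 0.05)
  mass <- stats::setNames(stan$mass_kg, stan$joint)
  expect_equal(unname(mass["total"]),
               unname(mass["hip"] + mass["knee"] + mass["ankle"]),
               tolerance = 1e-12)
  carn <- extensor_masses(935, 410, 0.0430, 0.0438, 187, 7394)
  cpct <- stats::setNames(carn$pct_body_mass, carn$joint)
  expect_equal(unname(cpct["hip"]), 9.045, tolerance = 0.01)
  expect_equal(unname(cpct["knee"]), 4.10, tolerance = 0.05)
  expect_equal(unname(cpct["ankle"]), 2.33, tolerance = 0.05)
  # dropping the CFL lowers only the hip share, by exactly cfl/body x 100
  no_cfl <- extensor_masses(1026, 342, 0.0340, 0.0238, 0, 5934)
  npct <- stats::setNames(no_cfl$pct_body_mass, no_cfl$joint)
  expect_equal(unname(pct["hip"] - npct["hip"]), 100 * 192 / 5934,
               tolerance = 1e-9)
  expect_equal(unname(npct["knee"]), unname(pct["knee"]))
  expect_equal(unname(npct["ankle"]), unname(pct["ankle"]))
  expect_error(extensor_masses(30, 342, 0.0340, 0.0238, 0, 5934),
               "not smaller")
  expect_error(extensor_coefficients(hip = 1.2), "in \\(0, 1\\)")
})

test_that("caudal series round-trips through JSON", {
  skel <- tyranno_fixture()$skeleton
  f <- tempfile(fileext = ".json")
  write_caudal_series(skel$caudal_series, f)
  back <- read_caudal_series(f)
  expect_equal(back$transition_point, skel$caudal_series$transition_point)
  m0 <- cfl_mass(cfl_loops(skel$caudal_series), bilateral = FALSE)$mass
  m1 <- cfl_mass(cfl_loops(back), bilateral = FALSE)$mass
  expect_equal(m1, m0, tolerance = 1e-9)
})
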