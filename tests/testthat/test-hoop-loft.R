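# Hoop fitting, profile transforms and lofting.

axes_x <- cbind(c(0, 1, 0), c(0, 0, 1))
circ_hoop <- function(x, r) hoop(x, c(x, 0, 0), axes_x, "ellipse", a = r, b = r)
oct_hoop <- function(x, r) hoop(x, c(x, 0, 0), axes_x, "octagon",
                                radii = rep(r, 8))

test_that("lofted primitives match closed-form volumes at default resolution", {
  cyl <- loft_segment(list(circ_hoop(0, 0.5), circ_hoop(2, 0.5)))
  expect_true(validate_mesh(cyl))
  expect_equal(signed_volume(cyl), pi * 0.25 * 2, tolerance = 0.005)
  fru <- loft_segment(list(circ_hoop(0, 0.5), circ_hoop(1.5, 0.2)))
  expect_equal(signed_volume(fru),
               pi * 1.5 * (0.25 + 0.1 + 0.04) / 3, tolerance = 0.005)
  # octagonal prism is exact: the resampled ring lies on the octagon
  pri <- loft_segment(list(oct_hoop(0, 0.7), oct_hoop(1.3, 0.7)))
  expect_equal(signed_volume(pri), 2 * sqrt(2) * 0.49 * 1.3,
               tolerance = 1e-12)
})

test_that("loft volume error decreases as O(n^-2) in ring resolution", {
  truth <- pi * 0.25 * 2
  err <- vapply(c(16, 32, 64), function(n)
    abs(signed_volume(loft_segment(list(circ_hoop(0, 0.5), circ_hoop(2, 0.5)),
                                   n_ring = n)) - truth), 0)
  expect_gt(err[1] / err[2], 3.5)
  expect_lt(err[1] / err[2], 4.5)
  expect_gt(err[2] / err[3], 3.5)
  expect_lt(err[2] / err[3], 4.5)
})

test_that("loft input validation catches bad hoop stacks", {
  expect_error(loft_segment(list(circ_hoop(0, 1))), "at least 2")
  expect_error(loft_segment(list(circ_hoop(0, 1), circ_hoop(0, 1))),
               "strictly increasing")
})

test_that("fit_hoop recovers supports, applies offsets and checks degeneracy", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  pts <- cbind(0, 0.8 * sin(th + pi / 2), 0.8 * sin(th))  # circle radius 0.8
  # dorsal direction is +y: radius along every control direction is 0.8
  h <- fit_hoop(0, c(0, 0, 0), axes_x, pts, profile = "octagon",
                offset_fraction = 0)
  expect_equal(h$radii, rep(0.8, 8), tolerance = 1e-9)
  h12 <- fit_hoop(0, c(0, 0, 0), axes_x, pts, profile = "octagon",
                  offset_fraction = 0.2)
  expect_equal(h12$radii, rep(0.96, 8), tolerance = 1e-9)
  expect_equal(h12$bone_radii, rep(0.8, 8), tolerance = 1e-9)
  line <- cbind(0, seq(-1, 1, length.out = 5), 0)
  expect_error(fit_hoop(0, c(0, 0, 0), axes_x, line, "octagon"), "collinear")
})

test_that("a fitted hoop contains a vertebra-and-ribs section", {
  # neural spine tip (dorsal), rib tips (lateral/ventrolateral), centrum
  bone <- rbind(c(0, 0.9, 0), c(0, 0.55, 0.6), c(0, 0.55, -0.6),
                c(0, -0.1, 0.75), c(0, -0.1, -0.75), c(0, -0.6, 0.5),
                c(0, -0.6, -0.5), c(0, -0.75, 0), c(0, 0.2, 0.1))
  h <- fit_hoop(0, c(0, 0, 0), axes_x, bone, "octagon", offset_fraction = 0.1)
  poly <- volumass:::ring_points(h, 256)[, c(2, 3)]
  for (i in seq_len(nrow(bone)))
    expect_true(point_in_polygon(bone[i, c(2, 3)], poly))
})

test_that("scale_hoop scales radii only and is invertible", {
  h <- oct_hoop(0.3, 1)
  expect_equal(scale_hoop(h, 1)$radii, h$radii)
  # r^2 area scaling on a circle profile
  hc <- circ_hoop(0, 1)
  s <- scale_hoop(hc, 1.2)
  a0 <- shoelace_area(volumass:::ring_points(hc, 128)[, c(2, 3)])
  a1 <- shoelace_area(volumass:::ring_points(s, 128)[, c(2, 3)])
  expect_equal(a1 / a0, 1.44, tolerance = 1e-12)
  back <- scale_hoop(scale_hoop(h, 0.8), 1 / 0.8)
  expect_equal(back$radii, h$radii, tolerance = 1e-12)
  expect_equal(s$station, hc$station)
  expect_equal(s$center, hc$center)
  expect_error(scale_hoop(h, 0), "> 0")
  expect_error(scale_hoop(h, -1), "> 0")
})

test_that("diamondize shrinks area by exactly the diagonal factor", {
  h <- oct_hoop(0, 1)
  hd <- diamondize(h, 0.853)
  a0 <- shoelace_area(volumass:::ring_points(h, 64)[, c(2, 3)])
  a1 <- shoelace_area(volumass:::ring_points(hd, 64)[, c(2, 3)])
  # shoelace oracle: alternating-radius octagon area is linear in the
  # diagonal radii, so the ratio equals the factor itself
  expect_equal(a1 / a0, 0.853, tolerance = 1e-12)
  expect_lt(a1, a0)
  expect_equal(diamondize(h, 1)$radii, h$radii)
  expect_error(diamondize(circ_hoop(0, 1)), "octagon")
  # diamondize and scale_hoop commute
  h1 <- diamondize(scale_hoop(h, 1.2), 0.853)
  h2 <- scale_hoop(diamondize(h, 0.853), 1.2)
  expect_equal(h1$radii, h2$radii, tolerance = 1e-12)
})

test_that("air cavities displace mass but not external volume", {
  # 1 x 1 x 1 square-section segment (octagon degenerate to a square)
  sq <- function(x, r) hoop(x, c(x, 0, 0), axes_x, "octagon",
                            radii = r * c(1, sqrt(2), 1, sqrt(2),
                                          1, sqrt(2), 1, sqrt(2)) / 2)
  seg <- segment_model("body", list(sq(0, 1), sq(1, 1)))
  p_solid <- segment_mass_properties(seg)
  expect_equal(p_solid$mass, 1000, tolerance = 1e-9)
  cav <- list(circ_hoop(0.25, 0.2), circ_hoop(0.75, 0.2))
  seg2 <- add_cavity(seg, cav)
  p <- segment_mass_properties(seg2)
  cav_vol <- signed_volume(loft_segment(cav))
  expect_equal(p$mass, 1000 * (1 - cav_vol), tolerance = 1e-9)
  expect_equal(p$volume, 1, tolerance = 1e-9)       # external volume kept
  expect_lt(p$density, 1000)                        # apparent density drops
  # a cavity poking outside the flesh only warns
  out_cav <- list(circ_hoop(0.4, 0.2),
                  hoop(0.98, c(0.98, 0.45, 0), axes_x, "ellipse",
                       a = 0.2, b = 0.2))
  expect_warning(add_cavity(seg, out_cav), "outside")
})

test_that("segment construction enforces ordering and roster names", {
  expect_error(segment_model("body", list(circ_hoop(0, 1))), "at least 2")
  expect_error(segment_model("body", list(circ_hoop(1, 1), circ_hoop(0, 1))),
               "increasing")
  expect_error(segment_model("wing", list(circ_hoop(0, 1), circ_hoop(1, 1))))
})
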