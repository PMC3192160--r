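# Exact polyhedral mass properties and mesh handling.

test_that("cube mass properties match the closed forms", {
  m <- box_mesh()
  p <- mass_properties(m, density = 1000)
  expect_equal(p$mass, 1000)
  expect_equal(p$volume, 1)
  expect_equal(p$com, c(0.5, 0.5, 0.5))
  expect_equal(p$inertia, diag(1000 / 6, 3), tolerance = 1e-12)
  # zero density: massless but geometrically defined
  p0 <- mass_properties(m, density = 0)
  expect_equal(p0$mass, 0)
  expect_equal(p0$volume, 1)
  expect_equal(p0$com, c(0.5, 0.5, 0.5))
})

test_that("sphere-of-revolution volume converges to 4/3 pi at O(n^-2)", {
  sphere_vol <- function(n_st, n_ring) {
    t <- seq(-1, 1, length.out = n_st)
    # clip the poles: capped loft closes the ends
    t <- t * (1 - 1e-9)
    ax <- cbind(c(0, 1, 0), c(0, 0, 1))
    hoops <- lapply(t, function(x)
      hoop(x, c(x, 0, 0), ax, "ellipse",
           a = sqrt(1 - x^2) + 1e-12, b = sqrt(1 - x^2) + 1e-12))
    signed_volume(loft_segment(hoops, n_ring = n_ring))
  }
  truth <- 4 * pi / 3
  err <- vapply(c(16, 32, 64), function(n) abs(sphere_vol(n, n) - truth), 0)
  expect_lt(err[3] / truth, 0.005)
  # halving the resolution roughly quadruples the error
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5.5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5.5)
})

test_that("watertightness and orientation violations are reported", {
  m <- box_mesh()
  open <- trimesh(m$vertices, m$faces[-1, ])
  expect_error(validate_mesh(open), "not watertight")
  flipped <- m
  flipped$faces[3, ] <- flipped$faces[3, c(1, 3, 2)]
  expect_error(validate_mesh(flipped), "not consistently oriented")
  inverted <- m
  inverted$faces <- inverted$faces[, c(1, 3, 2)]
  expect_error(validate_mesh(inverted), "non-positive signed volume")
})

test_that("degenerate faces are dropped with a warning", {
  m <- box_mesh()
  v <- rbind(m$vertices, c(0, 0, 0))
  f <- rbind(m$faces, c(1, 1, 9))
  expect_warning(out <- trimesh(v, f), "degenerate")
  expect_equal(nrow(out$faces), 12)
})

test_that("compose combines masses, COMs and inertia consistently", {
  p1 <- mass_properties(box_mesh(), 1000)
  p2 <- mass_properties(box_mesh(origin = c(2, 0, 0)), 1000)
  comp <- compose_mass_properties(list(p1, p2))
  expect_equal(comp$mass, 2000)
  expect_equal(comp$com[1], 1.5)   # midpoint of the two centroids
  # identity on a single part
  expect_identical(compose_mass_properties(list(p1)), p1)
  # matches direct integration of the union mesh (disjoint solids)
  union <- merge_meshes(list(box_mesh(), box_mesh(origin = c(2, 0, 0))))
  pu <- mass_properties(union, 1000)
  expect_equal(comp$mass, pu$mass, tolerance = 1e-12)
  expect_equal(comp$com, pu$com, tolerance = 1e-12)
  expect_equal(comp$inertia, pu$inertia, tolerance = 1e-9)
  # volume additivity for disjoint meshes
  expect_equal(pu$volume, p1$volume + p2$volume, tolerance = 1e-12)
  # zero-mass parts add volume but not COM weight
  cav <- mass_properties(box_mesh(origin = c(10, 10, 10)), 0)
  comp2 <- compose_mass_properties(list(p1, cav))
  expect_equal(comp2$com, p1$com)
  expect_equal(comp2$volume, 2)
  expect_error(compose_mass_properties(list()), "at least one")
  expect_error(compose_mass_properties(list(cav, cav)), "total mass is zero")
})

test_that("inertia_about implements the parallel-axis theorem", {
  p <- mass_properties(box_mesh(), 1000)
  expect_equal(inertia_about(p, p$com), p$inertia)
  corner <- inertia_about(p, c(0, 0, 0))
  expect_equal(diag(corner), rep(2 / 3 * 1000, 3), tolerance = 1e-12)
  expect_equal(corner[1, 2], -1000 / 4, tolerance = 1e-12)
  # direct-integration oracle: shift the mesh so the corner is the origin
  shifted <- transform_mesh(box_mesh(), translation = c(0, 0, 0))
  acc <- mass_properties(shifted, 1000)
  expect_equal(inertia_about(acc, c(0, 0, 0)), corner, tolerance = 1e-12)
})

test_that("mass and inertia eigenvalues are rigid-motion invariant", {
  m <- random_loft_solid(11)
  p <- mass_properties(m, 1000, validate = FALSE)
  th <- 0.7; ph <- 1.2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  mt <- transform_mesh(m, Rz %*% Rx, c(3, -2, 5))
  pt <- mass_properties(mt, 1000, validate = FALSE)
  expect_equal(pt$mass, p$mass, tolerance = 1e-9)
  expect_equal(sort(eigen(pt$inertia, symmetric = TRUE)$values),
               sort(eigen(p$inertia, symmetric = TRUE)$values),
               tolerance = 1e-9)
})

test_that("divergence-theorem properties match the voxel oracle", {
  m <- random_loft_solid(3)
  p <- mass_properties(m, 1000, validate = FALSE)
  vx <- voxel_mass_properties(m, n = 28)
  tol <- mesh_area(m) * max(vx$cell)
  expect_lt(abs(p$volume - vx$volume), tol)
  expect_lt(max(abs(p$com - vx$com)), max(vx$cell))
})

test_that("OBJ and PLY round-trips preserve geometry", {
  m <- random_loft_solid(5)
  fo <- tempfile(fileext = ".obj")
  fp <- tempfile(fileext = ".ply")
  write_obj(m, fo)
  write_ply(m, fp)
  mo <- read_obj(fo)
  mp <- read_ply(fp)
  expect_equal(mo$vertices, m$vertices, tolerance = 1e-7)
  expect_identical(mo$faces, m$faces)
  expect_equal(mp$vertices, m$vertices, tolerance = 1e-7)
  expect_identical(mp$faces, m$faces)
  expect_equal(signed_volume(mo), signed_volume(m), tolerance = 1e-7)
})

test_that("mass properties serialise to JSON with explicit units", {
  p <- mass_properties(box_mesh(), 1000)
  js <- jsonlite::fromJSON(mass_properties_json(p))
  expect_equal(js$mass, 1000)
  expect_equal(js$mass_unit, "kg")
  expect_equal(js$com, c(0.5, 0.5, 0.5))
  expect_equal(js$volume_unit, "m^3")
})

test_that("ray-cast containment classifies interior and exterior points", {
  m <- box_mesh()
  pts <- rbind(c(0.5, 0.5, 0.5), c(0.1, 0.9, 0.2), c(1.5, 0.5, 0.5),
               c(-0.1, 0.5, 0.5), c(0.5, 0.5, 1.7))
  expect_identical(points_in_mesh(pts, m), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})
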