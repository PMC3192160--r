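# Independent oracles and shared fixtures for the test suite.
# The oracles deliberately avoid the package's divergence-theorem path:
# voxel counting via vertical ray crossings, shoelace polygon areas and
# Simpson/numeric differentiation are separate routes.

# voxel (grid-counting) volume and COM oracle: for every (x, y) grid
# column, collect the z values where triangles cross the column, then mark
# cell centres with an odd number of crossings above them as inside
voxel_mass_properties <- function(mesh, n = 24) {
  V <- mesh$vertices
  F <- mesh$faces
  lo <- apply(V, 2, min)
  hi <- apply(V, 2, max)
  pad <- (hi - lo) * 1e-6 + 1e-9
  lo <- lo - pad
  hi <- hi + pad
  h <- (hi - lo) / n
  # slight irrational offset avoids rays grazing shared edges/vertices
  xs <- lo[1] + (seq_len(n) - 0.4937562) * h[1]
  ys <- lo[2] + (seq_len(n) - 0.5063111) * h[2]
  zs <- lo[3] + (seq_len(n) - 0.5) * h[3]
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  d <- (B[, 2] - C[, 2]) * (A[, 1] - C[, 1]) +
       (C[, 1] - B[, 1]) * (A[, 2] - C[, 2])
  ok <- abs(d) > 1e-14
  cell <- prod(h)
  vol <- 0
  mom <- c(0, 0, 0)
  for (ix in seq_len(n)) {
    for (iy in seq_len(n)) {
      px <- xs[ix]
      py <- ys[iy]
      l1 <- ((B[, 2] - C[, 2]) * (px - C[, 1]) +
             (C[, 1] - B[, 1]) * (py - C[, 2])) / d
      l2 <- ((C[, 2] - A[, 2]) * (px - C[, 1]) +
             (A[, 1] - C[, 1]) * (py - C[, 2])) / d
      l3 <- 1 - l1 - l2
      hit <- ok & l1 >= 0 & l2 >= 0 & l3 >= 0
      if (!any(hit)) next
      zc <- l1[hit] * A[hit, 3] + l2[hit] * B[hit, 3] + l3[hit] * C[hit, 3]
      crossings_above <- colSums(outer(zc, zs, `>`))
      ins <- crossings_above %% 2 == 1
      nin <- sum(ins)
      if (nin == 0) next
      vol <- vol + nin * cell
      mom <- mom + c(px * nin, py * nin, sum(zs[ins])) * cell
    }
  }
  list(volume = vol, com = mom / vol, cell = h)
}

# shoelace area of a closed 2D polygon (oracle copy, kept independent)
shoelace_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  0.5 * abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]))
}

# 2D point-in-polygon by crossing number
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[i2, 1]; y2 <- poly[i2, 2]
  cross <- ((y1 > pt[2]) != (y2 > pt[2])) &
    (pt[1] < (x2 - x1) * (pt[2] - y1) / (y2 - y1) + x1)
  sum(cross) %% 2 == 1
}

# numeric derivative maximum of a function on a grid (oracle for the
# closed-form peak growth rate)
numeric_peak_rate <- function(f, lo, hi, n = 20001) {
  t <- seq(lo, hi, length.out = n)
  y <- f(t)
  max(diff(y) / diff(t))
}

# axis-aligned unit-cube-like box mesh [0,a]x[0,b]x[0,c]
box_mesh <- function(a = 1, b = 1, c = 1, origin = c(0, 0, 0)) {
  v <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, b, 0), c(0, b, 0),
             c(0, 0, c), c(a, 0, c), c(a, b, c), c(0, b, c))
  v <- sweep(v, 2, origin, `+`)
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(4, 8, 7), c(4, 7, 3),
             c(1, 5, 8), c(1, 8, 4), c(2, 3, 7), c(2, 7, 6))
  trimesh(v, f)
}

# randomly tapered octagonal loft solid (seeded)
random_loft_solid <- function(seed, n_hoops = 5, n_ring = 16) {
  set.seed(seed)
  base <- runif(8, 0.3, 1.0)
  scales <- runif(n_hoops, 0.5, 1.2)
  len <- runif(1, 1, 2.5)
  ax <- cbind(c(0, 1, 0), c(0, 0, 1))
  st <- seq(0, len, length.out = n_hoops)
  yoff <- runif(n_hoops, -0.2, 0.2)
  hoops <- lapply(seq_len(n_hoops), function(i)
    hoop(st[i], c(st[i], yoff[i], 0), ax, "octagon", radii = base * scales[i]))
  loft_segment(hoops, n_ring = n_ring)
}

# shared synthetic tyrannosaur model and variant suite (built once)
.fixture_cache <- new.env(parent = emptyenv())

tyranno_fixture <- function(n_ring = 64) {
  key <- paste0("suite_", n_ring)
  if (is.null(.fixture_cache[[key]])) {
    skel <- generate_skeleton(tyrannosaur_params())
    body <- build_body_model(skel)
    .fixture_cache[[key]] <- list(
      skeleton = skel, body = body,
      suite = com_extreme_suite(body, n_ring = n_ring))
  }
  .fixture_cache[[key]]
}

# small fast tyrannosaur (fewer hoops) for structural tests
small_tyranno_body <- function() {
  if (is.null(.fixture_cache$small)) {
    p <- tyrannosaur_params(
      seed = 7, irregularity = 0.02,
      n_hoops = list(body = 5, neck = 3, head = 4, tail = 6, thigh = 3,
                     shank = 3, foot = 3, forelimb = 3))
    .fixture_cache$small <- build_body_model(generate_skeleton(p))
  }
  .fixture_cache$small
}
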