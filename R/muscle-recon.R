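# Reconstruction of M. caudofemoralis longus (CFL) from caudal vertebral
# landmarks, and per-joint extensor muscle masses by the segment-minus-bone
# coefficient method.
#
# Per vertebra, a smooth periodic curve is drawn through the lateral tip of
# the transverse process, the ventral tip of the chevron and the ventral and
# lateral borders of the centrum and chevron, forming a closed loop; the
# loops are lofted along the tail into a solid muscle volume. A small space
# lateral to the sacrum/ilium (M. caudofemoralis brevis territory) is left
# unfilled because the medial boundary tracks the bone borders.

#' Caudal landmark series for CFL reconstruction
#'
#' @param vertebrae list with one entry per caudal vertebra (ordered
#'   proximal to distal). Each entry is a list with `station` (x position,
#'   m) and `landmarks`: a named list of 3D points that must include
#'   `transverse_process_tip` and `chevron_tip`; additional ordered border
#'   points (centrum/chevron lateral and ventral borders) refine the loop.
#'   Points describe the right side; the left is mirrored.
#' @param transition_point index (1-based) of the first vertebra excluded
#'   distally (the tail's transition point); loops are built for vertebrae
#'   `1..(transition_point - 1)`.
#' @param fourth_trochanter 3D point of the femoral fourth trochanter, the
#'   CFL insertion reached by the tendon extension.
#' @return an object of class `caudal_series`.
#' @export
caudal_series <- function(vertebrae, transition_point,
                          fourth_trochanter = NULL) {
  n <- length(vertebrae)
  if (n < 2) stop("caudal series needs at least 2 vertebrae")
  if (transition_point < 3 || transition_point > n + 1)
    stop("transition_point must leave >= 2 vertebrae before it")
  st <- vapply(vertebrae, function(v) v$station, 0)
  if (any(diff(st) >= 0))
    stop("vertebral stations must decrease proximal to distal (tail extends caudally, -x)")
  structure(list(vertebrae = vertebrae, transition_point = transition_point,
                 fourth_trochanter = fourth_trochanter),
            class = "caudal_series")
}

#' Read a caudal landmark series from JSON
#'
#' Expects the structure written by the skeleton generator: fields
#' `transition_point`, `fourth_trochanter` and `vertebrae`, each vertebra
#' with `station` and named 3D `landmarks` in metres (model frame).
#'
#' @param path JSON file.
#' @return a `caudal_series`.
#' @export
read_caudal_series <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  verts <- lapply(obj$vertebrae, function(v)
    list(station = as.numeric(v$station),
         landmarks = lapply(v$landmarks, function(p) as.numeric(unlist(p)))))
  caudal_series(verts, transition_point = as.numeric(obj$transition_point),
                fourth_trochanter =
                  if (!is.null(obj$fourth_trochanter))
                    as.numeric(unlist(obj$fourth_trochanter)) else NULL)
}

# periodic cubic spline through an ordered closed set of 2D points,
# resampled to n points by cumulative chord-length parameter
periodic_spline_loop <- function(pts, n = 64) {
  pts <- rbind(pts)
  k <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  d <- sqrt(rowSums(diff(closed)^2))
  t <- c(0, cumsum(d))
  total <- t[k + 1]
  tout <- seq(0, total, length.out = n + 1)[-(n + 1)]
  y <- stats::spline(t, closed[, 1], method = "periodic", xout = tout)$y
  z <- stats::spline(t, closed[, 2], method = "periodic", xout = tout)$y
  cbind(y, z)
}

#' Build per-vertebra CFL cross-section loops
#'
#' @param series a `caudal_series`.
#' @param n points per loop after spline resampling.
#' @return list of loops (class `cfl_loop`): each carries `station`, the
#'   ordered landmark points and the resampled closed curve (in the
#'   transverse y-z plane).
#' @export
cfl_loops <- function(series, n = 64) {
  idx <- seq_len(series$transition_point - 1)
  if (length(idx) < 2) stop("need >= 2 vertebrae before the transition point")
  lapply(idx, function(i) {
    v <- series$vertebrae[[i]]
    lm <- v$landmarks
    for (need in c("transverse_process_tip", "chevron_tip"))
      if (is.null(lm[[need]]))
        stop(sprintf("vertebra %d is missing landmark '%s'", i, need))
    pts3 <- do.call(rbind, lm)
    pts <- pts3[, c(2, 3), drop = FALSE]   # (y, z) in the transverse plane
    curve <- periodic_spline_loop(pts, n = n)
    structure(list(station = v$station, landmarks = lm, points = curve),
              class = "cfl_loop")
  })
}

# shoelace area of a closed polygon (n x 2)
polygon_area <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  0.5 * abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]))
}

#' Area of a CFL loop
#' @param loop a `cfl_loop`.
#' @return area of the closed curve, m^2.
#' @export
loop_area <- function(loop) polygon_area(loop$points)

# loft cfl loops (stations on x, loop points in y-z) into a closed mesh
loft_loops <- function(loops, stations = NULL) {
  n <- nrow(loops[[1]]$points)
  if (is.null(stations)) stations <- vapply(loops, function(l) l$station, 0)
  ord <- order(stations)
  stations <- stations[ord]
  loops <- loops[ord]
  hoops_like <- Map(function(l, s) cbind(s, l$points), loops, stations)
  verts <- do.call(rbind, hoops_like)
  k <- length(loops)
  faces <- list()
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(k - 1)) {
    o1 <- (i - 1) * n
    o2 <- i * n
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o2 + j, o2 + jn)
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o2 + jn, o1 + jn)
  }
  c1 <- colMeans(hoops_like[[1]])
  c2 <- colMeans(hoops_like[[k]])
  verts <- rbind(verts, c1, c2)
  i1 <- nrow(verts) - 1L
  i2 <- nrow(verts)
  faces[[length(faces) + 1L]] <- cbind(rep(i1, n), j, jn)
  o <- (k - 1) * n
  faces[[length(faces) + 1L]] <- cbind(rep(i2, n), o + jn, o + j)
  m <- trimesh(verts, do.call(rbind, faces))
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' CFL muscle volume and mass from lofted loops
#'
#' Loops are lofted into a watertight solid; mass is volume times density.
#' The thin tendon extension to the fourth trochanter is modelled as a
#' narrow tube and reported separately (its contribution is negligible).
#'
#' @param loops list of `cfl_loop`s (>= 2), e.g. from [cfl_loops()].
#' @param spacing optional uniform loop spacing (m) overriding the loop
#'   stations.
#' @param density muscle density, kg m^-3 (the homogeneous-model
#'   convention uses 1000; actual muscle is about 1060).
#' @param bilateral double the single-side volume to count both left and
#'   right muscle bellies; the default reports one muscle, the convention
#'   used when quoting CFL mass per hindlimb.
#' @param fourth_trochanter optional 3D insertion point for the tendon
#'   extension.
#' @param tendon_radius_fraction tendon tube radius as a fraction of the
#'   mean terminal loop radius (default 0.01).
#' @return an object of class `cfl_result`: `volume` (m^3, per side),
#'   `mass` (kg, both sides when `bilateral`), `tendon_volume`,
#'   `tendon_mass`, `mesh`, `loops`, `density`.
#' @export
cfl_mass <- function(loops, spacing = NULL, density = 1000, bilateral = FALSE,
                     fourth_trochanter = NULL, tendon_radius_fraction = 0.01) {
  if (length(loops) < 2) stop("cfl_mass: need at least 2 loops")
  stations <- if (!is.null(spacing))
    -(seq_along(loops) - 1) * spacing else NULL
  mesh <- loft_loops(loops, stations = stations)
  validate_mesh(mesh)
  vol <- signed_volume(mesh)
  sides <- if (bilateral) 2 else 1
  tendon_volume <- 0
  if (!is.null(fourth_trochanter)) {
    first <- loops[[which.max(vapply(loops, function(l) l$station, 0))]]
    centre2 <- colMeans(first$points)
    origin <- c(first$station, centre2)
    rbar <- mean(sqrt(rowSums(sweep(first$points, 2, centre2)^2)))
    rt <- tendon_radius_fraction * rbar
    len <- sqrt(sum((as.numeric(fourth_trochanter) - origin)^2))
    tendon_volume <- pi * rt^2 * len
  }
  structure(list(volume = vol, mass = sides * density * vol,
                 tendon_volume = tendon_volume,
                 tendon_mass = sides * density * tendon_volume,
                 mesh = mesh, loops = loops, density = density,
                 bilateral = bilateral),
            class = "cfl_result")
}

#' Maximal-model CFL mass by tail-mass scaling
#'
#' The minimal (initial) CFL mass is multiplied by the ratio of maximal to
#' minimal tail segment masses.
#'
#' @param cfl_min_mass minimal-model CFL mass (kg).
#' @param tail_max_mass,tail_min_mass tail segment masses (kg).
#' @return maximal-model CFL mass (kg).
#' @export
cfl_max <- function(cfl_min_mass, tail_max_mass, tail_min_mass) {
  if (any(c(cfl_min_mass, tail_max_mass, tail_min_mass) <= 0))
    stop("masses must be > 0")
  cfl_min_mass * (tail_max_mass / tail_min_mass)
}

#' CFL mass as a percentage of body mass
#' @param cfl_mass CFL mass (kg).
#' @param body_mass whole-body mass (kg, > 0).
#' @return percentage of body mass.
#' @export
cfl_fraction <- function(cfl_mass, body_mass) {
  if (body_mass <= 0) stop("body mass must be > 0")
  100 * cfl_mass / body_mass
}

#' Density-corrected validation of a CFL estimate against dissection
#'
#' Rescales a muscle mass estimated at an assumed density to the likely
#' actual density and reports the percentage overestimate relative to the
#' dissected mass. The corrected estimate is rounded to the measurement
#' precision of the balance before comparison, so the reported error is at
#' the precision of the dissection data.
#'
#' @param estimated_mass reconstructed mass at `assumed_density` (kg).
#' @param measured_mass dissected mass (kg).
#' @param assumed_density density used in the reconstruction (kg m^-3).
#' @param actual_density likely real muscle density (kg m^-3).
#' @param precision balance precision (kg) used to round the corrected
#'   estimate; `NULL` disables rounding.
#' @return list with `corrected_mass` (kg) and `overestimate_pct`.
#' @export
cfl_validation <- function(estimated_mass, measured_mass,
                           assumed_density = 1000, actual_density = 1060,
                           precision = 0.001) {
  corrected <- estimated_mass * actual_density / assumed_density
  if (!is.null(precision)) corrected <- round(corrected / precision) * precision
  list(corrected_mass = corrected,
       overestimate_pct = 100 * (corrected / measured_mass - 1))
}

#' Extensor muscle mass coefficients
#'
#' Fractions of non-bone segment mass dedicated to extensor muscles in
#' extant Sauria: hip 0.54 of thigh (plus the CFL mass), knee 0.34 of
#' thigh, ankle 0.47 of shank.
#'
#' @param hip,knee,ankle coefficients in (0, 1).
#' @return an object of class `extensor_coefficients`.
#' @export
extensor_coefficients <- function(hip = 0.54, knee = 0.34, ankle = 0.47) {
  v <- c(hip = hip, knee = knee, ankle = ankle)
  if (any(v <= 0) || any(v >= 1))
    stop("extensor coefficients must lie in (0, 1)")
  structure(as.list(v), class = "extensor_coefficients")
}

#' Per-joint extensor muscle masses by the segment-minus-bone method
#'
#' Bone volumes are first subtracted from the thigh and shank segment
#' masses (bone mass = bone volume times the homogeneous flesh density,
#' the modelling convention); the non-bony remainders are multiplied by
#' the extensor coefficients. The CFL mass is added to the hip extensors.
#'
#' @param thigh_mass,shank_mass segment masses (kg).
#' @param femur_volume,tibiotarsus_volume bone volumes (m^3).
#' @param cfl_mass CFL muscle mass (kg) added to the hip extensor total.
#' @param body_mass whole-body mass (kg) for percentage normalisation.
#' @param coeffs an [extensor_coefficients()].
#' @param flesh_density homogeneous model density (kg m^-3).
#' @return data frame with rows hip, knee, ankle, total and columns
#'   `mass_kg` and `pct_body_mass`.
#' @export
extensor_masses <- function(thigh_mass, shank_mass, femur_volume,
                            tibiotarsus_volume, cfl_mass, body_mass,
                            coeffs = extensor_coefficients(),
                            flesh_density = 1000) {
  femur_bone <- femur_volume * flesh_density
  tibio_bone <- tibiotarsus_volume * flesh_density
  if (femur_bone >= thigh_mass)
    stop("femur bone mass is not smaller than the thigh segment mass")
  if (tibio_bone >= shank_mass)
    stop("tibiotarsus bone mass is not smaller than the shank segment mass")
  if (body_mass <= 0) stop("body mass must be > 0")
  hip <- (thigh_mass - femur_bone) * coeffs$hip + cfl_mass
  knee <- (thigh_mass - femur_bone) * coeffs$knee
  ankle <- (shank_mass - tibio_bone) * coeffs$ankle
  total <- hip + knee + ankle
  mass <- c(hip = hip, knee = knee, ankle = ankle, total = total)
  data.frame(joint = names(mass), mass_kg = unname(mass),
             pct_body_mass = unname(100 * mass / body_mass))
}
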