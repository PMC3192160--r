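# Cross-section hoops on skeletal landmarks, lofted into fleshed segment
# meshes with optional zero-density air cavities.
#
# A hoop is a planar profile (ellipse or octagon) at a station along a
# segment axis. Octagons carry 8 control radii ordered from dorsal,
# proceeding right-lateral (45 degree steps); they are resampled to the
# ring resolution before lofting by ray/polygon intersection, so octagon
# control points and edges are preserved exactly.

OCT_ANGLES <- (0:7) * pi / 4

#' Construct a cross-section hoop
#'
#' @param station scalar position along the segment axis (m).
#' @param center 3D centre of the section plane (m).
#' @param axes 3 x 2 matrix of orthonormal in-plane unit vectors; column 1
#'   is the dorsal direction of the section, column 2 the right-lateral.
#' @param profile `"octagon"` or `"ellipse"`.
#' @param radii for octagons: 8 radial distances (m) ordered from dorsal,
#'   proceeding right-lateral.
#' @param a,b for ellipses: semi-axes (m) along `axes[,1]` and `axes[,2]`.
#' @param bone_radii optional bone-hugging radii (the offset-free skeletal
#'   support distances) retained so "tight to bone" variants can be derived.
#' @return an object of class `hoop`.
#' @export
hoop <- function(station, center, axes, profile = c("octagon", "ellipse"),
                 radii = NULL, a = NULL, b = NULL, bone_radii = NULL) {
  profile <- match.arg(profile)
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3, 2))) stop("axes must be a 3 x 2 matrix")
  g <- crossprod(axes)
  if (max(abs(g - diag(2))) > 1e-8) stop("hoop axes must be orthonormal")
  if (profile == "octagon") {
    radii <- as.numeric(radii)
    if (length(radii) != 8) stop("octagon profile needs 8 radial distances")
    if (any(radii <= 0)) stop("hoop radial distances must be > 0")
  } else {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
      stop("ellipse profile needs positive semi-axes a and b")
  }
  structure(list(station = as.numeric(station), center = as.numeric(center),
                 axes = axes, profile = profile, radii = radii,
                 a = a, b = b, bone_radii = bone_radii),
            class = "hoop")
}

# radius of the profile along in-plane angle theta (from dorsal toward
# right-lateral); vectorised over theta
hoop_radius <- function(h, theta) {
  theta <- theta %% (2 * pi)
  if (h$profile == "ellipse") {
    a <- h$a
    b <- h$b
    return(a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2))
  }
  # octagon: intersect the ray with the polygon edge spanning theta's sector
  k <- pmin(floor(theta / (pi / 4)), 7)
  a1 <- OCT_ANGLES[k + 1]
  r1 <- h$radii[k + 1]
  k2 <- (k + 1) %% 8
  a2 <- OCT_ANGLES[k2 + 1] + ifelse(k2 == 0, 2 * pi, 0)
  r2 <- h$radii[k2 + 1]
  p1x <- r1 * cos(a1); p1y <- r1 * sin(a1)
  p2x <- r2 * cos(a2); p2y <- r2 * sin(a2)
  dx <- cos(theta); dy <- sin(theta)
  num <- p1x * p2y - p1y * p2x
  den <- dx * (p2y - p1y) - dy * (p2x - p1x)
  num / den
}

# 3D ring of n points on the hoop boundary, starting dorsal; with n a
# multiple of 8 the octagon control vertices are sampled exactly and the
# other samples lie on the octagon edges, so polygon area is exact.
ring_points <- function(h, n) {
  theta <- (seq_len(n) - 1) * 2 * pi / n
  r <- hoop_radius(h, theta)
  outer(rep(1, n), h$center) +
    outer(r * cos(theta), h$axes[, 1]) +
    outer(r * sin(theta), h$axes[, 2])
}

#' Fit a hoop around skeletal extreme points
#'
#' The profile radius in each control direction is the directional support
#' distance of the skeletal extreme points (the outermost bone points in
#' the section plane), multiplied by `1 + offset_fraction`. An offset of 0
#' is a bone-hugging hoop.
#'
#' @param station station along the segment axis (m).
#' @param center 3D centre of the section plane.
#' @param axes 3 x 2 orthonormal in-plane axes (dorsal, right-lateral).
#' @param extremes matrix of 3D skeletal extreme points (>= 3, not
#'   collinear in the section plane).
#' @param profile `"octagon"` or `"ellipse"`.
#' @param offset_fraction fractional flesh offset outside the bone.
#' @return a `hoop` with `bone_radii` recorded.
#' @export
fit_hoop <- function(station, center, axes, extremes,
                     profile = c("octagon", "ellipse"), offset_fraction = 0) {
  profile <- match.arg(profile)
  extremes <- rbind(extremes)
  if (nrow(extremes) < 3) stop("fit_hoop: need at least 3 extreme points")
  rel <- sweep(extremes, 2, as.numeric(center))
  xy <- rel %*% as.matrix(axes)   # in-plane coordinates (dorsal, lateral)
  if (qr(scale(xy, scale = FALSE))$rank < 2)
    stop("fit_hoop: extreme points are collinear/degenerate in the section plane")
  support <- function(theta) {
    vapply(theta, function(t) max(xy[, 1] * cos(t) + xy[, 2] * sin(t)), 0)
  }
  if (profile == "octagon") {
    r <- support(OCT_ANGLES)
    if (any(r <= 0))
      stop("fit_hoop: section centre lies outside the skeletal extremes")
    hoop(station, center, axes, "octagon", radii = r * (1 + offset_fraction),
         bone_radii = r)
  } else {
    a <- max(abs(xy[, 1]))
    b <- max(abs(xy[, 2]))
    hoop(station, center, axes, "ellipse",
         a = a * (1 + offset_fraction), b = b * (1 + offset_fraction),
         bone_radii = c(a, b))
  }
}

#' Scale all radial dimensions of a hoop
#'
#' Stations, centres and hence segment lengths are never altered; only the
#' in-plane radii change (the sensitivity-analysis radial scaling rule).
#'
#' @param h a `hoop`.
#' @param radial_factor positive scale factor.
#' @return scaled `hoop`.
#' @export
scale_hoop <- function(h, radial_factor) {
  if (!is.numeric(radial_factor) || radial_factor <= 0)
    stop("radial_factor must be > 0")
  if (h$profile == "octagon") {
    h$radii <- h$radii * radial_factor
  } else {
    h$a <- h$a * radial_factor
    h$b <- h$b * radial_factor
  }
  h
}

#' Diamondise an octagonal hoop
#'
#' Multiplies the four diagonal (oblique) control radii by `factor`,
#' leaving the dorsal, ventral and lateral radii unchanged; with the
#' conventional factor 0.853 the cross-section approximates a diamond and
#' its area shrinks by exactly that factor.
#'
#' @param h an octagonal `hoop` (elliptical hoops must be converted with
#'   [as_octagon()] first).
#' @param factor multiplier for the diagonal radii.
#' @return modified `hoop`.
#' @export
diamondize <- function(h, factor = 0.853) {
  if (h$profile != "octagon")
    stop("diamondize: profile must be an octagon; convert with as_octagon()")
  if (factor <= 0) stop("factor must be > 0")
  h$radii[c(2, 4, 6, 8)] <- h$radii[c(2, 4, 6, 8)] * factor
  h
}

#' Convert an elliptical hoop to an octagonal one
#' @param h a `hoop`.
#' @return octagonal `hoop` sampling the ellipse at the 8 control angles.
#' @export
as_octagon <- function(h) {
  if (h$profile == "octagon") return(h)
  hoop(h$station, h$center, h$axes, "octagon",
       radii = hoop_radius(h, OCT_ANGLES), bone_radii = h$bone_radii)
}

#' Loft ordered hoops into a watertight segment mesh
#'
#' Hoops are resampled to a common ring resolution and joined by ruled
#' (linear) interpolation; end caps are triangle fans from the ring
#' centroid, guaranteeing watertightness.
#'
#' @param hoops list of >= 2 hoops with strictly increasing stations.
#' @param n_ring ring vertex count (default 64; multiples of 8 keep
#'   octagon profiles exact).
#' @param cap_ends close the ends with centroid fans.
#' @return a `trimesh` with outward winding (positive volume).
#' @export
loft_segment <- function(hoops, n_ring = 64, cap_ends = TRUE) {
  if (length(hoops) < 2) stop("loft_segment: need at least 2 hoops")
  st <- vapply(hoops, function(h) h$station, 0)
  if (any(diff(st) <= 0))
    stop("loft_segment: hoop stations must be strictly increasing")
  rings <- lapply(hoops, ring_points, n = n_ring)
  k <- length(rings)
  verts <- do.call(rbind, rings)
  faces <- list()
  for (i in seq_len(k - 1)) {
    o1 <- (i - 1) * n_ring
    o2 <- i * n_ring
    j <- seq_len(n_ring)
    jn <- c(seq_len(n_ring)[-1], 1L)
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o2 + j, o2 + jn)
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o2 + jn, o1 + jn)
  }
  if (cap_ends) {
    c1 <- colMeans(rings[[1]])
    c2 <- colMeans(rings[[k]])
    verts <- rbind(verts, c1, c2)
    i1 <- nrow(verts) - 1L
    i2 <- nrow(verts)
    j <- seq_len(n_ring)
    jn <- c(seq_len(n_ring)[-1], 1L)
    faces[[length(faces) + 1L]] <- cbind(rep(i1, n_ring), j, jn)
    o <- (k - 1) * n_ring
    faces[[length(faces) + 1L]] <- cbind(rep(i2, n_ring), o + jn, o + j)
  }
  m <- trimesh(verts, do.call(rbind, faces))
  if (cap_ends && signed_volume(m) < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Construct a body segment model
#'
#' @param name segment name, one of head, neck, body, tail, forelimb,
#'   thigh, shank, foot.
#' @param hoops ordered list of hoops (>= 2, strictly increasing stations).
#' @param cavities list of zero-density cavity definitions (each an ordered
#'   hoop list), registered with [add_cavity()].
#' @param density flesh density, kg m^-3 (default 1000).
#' @param paired whether the segment is one of a bilateral pair (limb
#'   segments); paired segments are counted twice, mirrored across the
#'   median plane, in whole-body composites.
#' @return an object of class `segment_model`.
#' @export
segment_model <- function(name, hoops,
                          cavities = list(), density = 1000, paired = FALSE) {
  name <- match.arg(name, c("head", "neck", "body", "tail", "forelimb",
                            "thigh", "shank", "foot"))
  if (length(hoops) < 2) stop("segment needs at least 2 hoops")
  st <- vapply(hoops, function(h) h$station, 0)
  if (any(diff(st) <= 0)) stop("hoops must be ordered by strictly increasing station")
  structure(list(name = name, hoops = hoops, cavities = cavities,
                 density = density, paired = paired),
            class = "segment_model")
}

#' Register a zero-density air cavity with a segment
#'
#' The cavity displaces flesh mass (segment mass = flesh mass minus flesh
#' density times cavity volume) while the external volume is unchanged.
#' Containment inside the flesh surface is checked by sampled ray casting;
#' a cavity poking outside triggers a warning, not an error.
#'
#' @param segment a `segment_model`.
#' @param cavity an ordered hoop list (lofted at evaluation time) or a
#'   closed `trimesh`.
#' @param check_containment sample cavity surface points against the flesh
#'   mesh.
#' @param n_ring ring resolution used for the containment check.
#' @return the segment with the cavity registered.
#' @export
add_cavity <- function(segment, cavity, check_containment = TRUE, n_ring = 32) {
  cav_mesh <- if (inherits(cavity, "trimesh")) cavity else
    loft_segment(cavity, n_ring = n_ring)
  validate_mesh(cav_mesh)
  if (check_containment) {
    flesh <- loft_segment(segment$hoops, n_ring = n_ring)
    pts <- cav_mesh$vertices
    pts <- pts[seq(1, nrow(pts), length.out = min(nrow(pts), 96)), , drop = FALSE]
    inside <- points_in_mesh(pts, flesh)
    if (!all(inside))
      warning(sprintf(
        "cavity extends outside the flesh mesh of segment '%s' (%d/%d sampled points outside)",
        segment$name, sum(!inside), length(inside)))
  }
  segment$cavities <- c(segment$cavities, list(cavity))
  segment
}

# loft (or pass through) a cavity definition
cavity_mesh <- function(cavity, n_ring = 64) {
  if (inherits(cavity, "trimesh")) cavity else loft_segment(cavity, n_ring)
}

#' Flesh mesh of a segment
#' @param segment a `segment_model`.
#' @param n_ring ring resolution.
#' @return a `trimesh`.
#' @export
segment_mesh <- function(segment, n_ring = 64) {
  loft_segment(segment$hoops, n_ring = n_ring)
}

#' Mass properties of a segment with its cavities
#'
#' Flesh is integrated at the segment density; each cavity removes flesh
#' (mass and moments) while leaving the external volume untouched, so the
#' segment's apparent density mass/volume drops below the flesh density.
#'
#' @param segment a `segment_model`.
#' @param n_ring ring resolution.
#' @return `mass_properties`; `volume` is the external volume.
#' @export
segment_mass_properties <- function(segment, n_ring = 64) {
  flesh <- loft_segment(segment$hoops, n_ring = n_ring)
  acc <- .mesh_integrals(flesh)
  vol_ext <- acc$volume
  mom <- acc$moment
  sec <- acc$second
  vol_net <- vol_ext
  for (cav in segment$cavities) {
    cm <- cavity_mesh(cav, n_ring = n_ring)
    cacc <- .mesh_integrals(cm)
    vol_net <- vol_net - cacc$volume
    mom <- mom - cacc$moment
    sec <- sec - cacc$second
  }
  if (vol_net <= 0) stop("cavities exceed the flesh volume")
  mass <- segment$density * vol_net
  com <- mom / vol_net
  C <- segment$density * sec
  I0 <- diag(sum(diag(C)), 3) - C
  Icom <- I0 - .point_mass_inertia(mass, com)
  dens <- if (vol_ext > 0) mass / vol_ext else NA_real_
  p <- new_mass_properties(mass = mass, com = com, inertia = Icom,
                           volume = vol_ext, density = dens)
  p
}
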