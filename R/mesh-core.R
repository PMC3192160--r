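# Closed triangle meshes and exact polyhedral mass properties.
#
# Conventions: vertices in metres, faces as 1-based index triples with
# counter-clockwise (outward) winding, right-handed frame with +x cranial,
# +y dorsal, +z right-lateral.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (n x 3), vertex coordinates in metres.
#' @param faces integer matrix (m x 3), 1-based vertex indices per triangle,
#'   wound counter-clockwise viewed from outside.
#' @param drop_degenerate drop faces with area below `area_tol` (slivers can
#'   be emitted by loft caps); a warning reports how many were removed.
#' @param area_tol face area tolerance in square metres.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, drop_degenerate = TRUE, area_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (drop_degenerate && nrow(faces) > 0) {
    a <- face_areas(vertices, faces)
    bad <- a < area_tol
    if (any(bad)) {
      warning(sprintf("dropping %d degenerate face(s) with area < %g m^2",
                      sum(bad), area_tol))
      faces <- faces[!bad, , drop = FALSE]
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh a `trimesh`.
#' @return area in square metres.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Validate that a mesh is watertight and consistently oriented
#'
#' Every undirected edge must be shared by exactly two faces and every
#' directed edge must occur exactly once (consistent winding). Edges are
#' matched by vertex index, not coordinate proximity. The check accepts
#' multi-component meshes (each component closed).
#'
#' @param mesh a `trimesh`.
#' @param require_positive_volume error if the signed volume is not > 0
#'   (i.e. the winding points inward).
#' @return `TRUE`, invisibly; errors describe offending edges.
#' @export
validate_mesh <- function(mesh, require_positive_volume = TRUE) {
  f <- mesh$faces
  if (nrow(f) < 4L) stop("mesh has too few faces to enclose a volume")
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("mesh is not consistently oriented; repeated directed edge(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  ukey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(ukey)
  open_edges <- names(cnt)[cnt != 2L]
  if (length(open_edges) > 0)
    stop("mesh is not watertight; open/non-manifold edge(s) between vertices: ",
         paste(utils::head(open_edges, 5), collapse = ", "))
  if (require_positive_volume && signed_volume(mesh) <= 0)
    stop("mesh has non-positive signed volume; face winding is inverted")
  invisible(TRUE)
}

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedra spanned by the origin and each face
#' (divergence theorem); positive for outward winding.
#'
#' @param mesh a `trimesh`.
#' @return volume in cubic metres.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  detj <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
          a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
          a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(detj) / 6
}

#' Mass properties of a homogeneous closed mesh
#'
#' Volume, centre of mass and inertia tensor by signed-tetrahedron
#' (divergence-theorem) accumulation about the origin: exact for polyhedra,
#' no voxelisation error. The inertia tensor is returned about the centre
#' of mass. A zero density is legal (air cavities): the mass is zero but
#' volume and the geometric centroid remain defined.
#'
#' @param mesh a `trimesh`, watertight and consistently wound.
#' @param density density in kg per cubic metre (default 1000, the
#'   homogeneous flesh density).
#' @param validate run `validate_mesh()` first.
#' @return an object of class `mass_properties` with fields `mass` (kg),
#'   `com` (m), `inertia` (3 x 3, kg m^2, about the COM), `volume` (m^3)
#'   and `density`.
#' @export
mass_properties <- function(mesh, density = 1000, validate = TRUE) {
  if (validate) validate_mesh(mesh)
  if (density < 0) stop("density must be >= 0")
  acc <- .mesh_integrals(mesh)
  vol <- acc$volume
  com <- acc$moment / vol
  mass <- density * vol
  # inertia about origin from the second-moment (covariance) integrals,
  # then parallel-axis shift to the COM
  C <- density * acc$second
  I0 <- diag(sum(diag(C)), 3) - C
  Icom <- I0 - .point_mass_inertia(mass, com)
  new_mass_properties(mass = mass, com = com, inertia = Icom,
                      volume = vol, density = density)
}

# Raw volume, first and second moment integrals over the solid.
# For each face (a,b,c): detJ = a . (b x c); the tetrahedron (0,a,b,c)
# contributes detJ/6 to volume, detJ*(a+b+c)/24 to the first moment and
# detJ/120 * (aa' + bb' + cc' + ss') with s = a+b+c to int(x x') dV.
.mesh_integrals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  detj <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
          a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
          a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  s <- a + b + c
  vol <- sum(detj) / 6
  mom <- colSums(detj * s) / 24
  sec <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in i:3) {
      val <- sum(detj * (a[, i] * a[, j] + b[, i] * b[, j] +
                         c[, i] * c[, j] + s[, i] * s[, j])) / 120
      sec[i, j] <- val
      sec[j, i] <- val
    }
  }
  list(volume = vol, moment = mom, second = sec)
}

.point_mass_inertia <- function(mass, d) {
  mass * (diag(sum(d * d), 3) - outer(d, d))
}

new_mass_properties <- function(mass, com, inertia, volume, density = NA_real_) {
  structure(list(mass = mass, com = as.numeric(com), inertia = inertia,
                 volume = volume, density = density),
            class = "mass_properties")
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("mass properties: mass %.6g kg, volume %.6g m^3\n",
              x$mass, x$volume))
  cat(sprintf("  COM (m): %.6g %.6g %.6g\n", x$com[1], x$com[2], x$com[3]))
  cat("  inertia about COM (kg m^2):\n")
  print(signif(x$inertia, 6))
  invisible(x)
}

#' Combine mass properties of component solids
#'
#' Total mass is the sum of part masses; the COM is the mass-weighted mean
#' of part COMs (zero-mass parts contribute volume but are excluded from
#' the COM); inertia tensors are combined with the parallel-axis theorem.
#'
#' @param parts list of `mass_properties`.
#' @return composite `mass_properties`.
#' @export
compose_mass_properties <- function(parts) {
  if (length(parts) < 1) stop("compose_mass_properties: need at least one part")
  if (length(parts) == 1) return(parts[[1]])
  mass <- sum(vapply(parts, function(p) p$mass, 0))
  volume <- sum(vapply(parts, function(p) p$volume, 0))
  if (mass <= 0) stop("compose_mass_properties: total mass is zero; COM undefined")
  mom <- Reduce(`+`, lapply(parts, function(p) p$mass * p$com))
  com <- mom / mass
  inertia <- matrix(0, 3, 3)
  for (p in parts) {
    if (p$mass == 0) next
    d <- p$com - com
    inertia <- inertia + p$inertia + .point_mass_inertia(p$mass, d)
  }
  dens <- if (volume > 0) mass / volume else NA_real_
  new_mass_properties(mass = mass, com = com, inertia = inertia,
                      volume = volume, density = dens)
}

#' Inertia tensor about an arbitrary point
#'
#' Parallel-axis shift of the central tensor; shifting to the COM itself
#' returns the central tensor unchanged.
#'
#' @param props a `mass_properties`.
#' @param point 3D point (m).
#' @return 3 x 3 inertia tensor (kg m^2) about `point`.
#' @export
inertia_about <- function(props, point) {
  d <- props$com - as.numeric(point)
  props$inertia + .point_mass_inertia(props$mass, d)
}

#' Rigid-motion transform of a mesh
#'
#' @param mesh a `trimesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (m).
#' @return transformed `trimesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, as.numeric(translation), `+`)
  trimesh(v, mesh$faces, drop_degenerate = FALSE)
}

#' Point containment test by ray casting
#'
#' Casts a fixed oblique ray from each query point and counts triangle
#' crossings (Moeller-Trumbore); an odd count means inside. Used for cavity
#' containment checks.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a closed `trimesh`.
#' @return logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- rbind(points)
  dirv <- c(0.2357023, 0.3141593, 0.9189385)
  dirv <- dirv / sqrt(sum(dirv^2))
  v <- mesh$vertices
  f <- mesh$faces
  counts <- integer(nrow(points))
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]
    e1 <- v[f[k, 2], ] - a
    e2 <- v[f[k, 3], ] - a
    pvec <- c(dirv[2] * e2[3] - dirv[3] * e2[2],
              dirv[3] * e2[1] - dirv[1] * e2[3],
              dirv[1] * e2[2] - dirv[2] * e2[1])
    det <- sum(e1 * pvec)
    if (abs(det) < 1e-14) next
    tv <- sweep(points, 2, a)
    u <- (tv %*% pvec) / det
    qv <- cbind(tv[, 2] * e1[3] - tv[, 3] * e1[2],
                tv[, 3] * e1[1] - tv[, 1] * e1[3],
                tv[, 1] * e1[2] - tv[, 2] * e1[1])
    vv <- (qv %*% dirv) / det
    tt <- (qv %*% e2) / det
    hit <- u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-12
    counts <- counts + as.integer(hit)
  }
  counts %% 2L == 1L
}

#' Merge meshes into one multi-component mesh
#' @param meshes list of `trimesh` objects.
#' @return single `trimesh` whose components are the inputs.
#' @export
merge_meshes <- function(meshes) {
  offs <- 0L
  vs <- list()
  fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + offs
    offs <- offs + nrow(m$vertices)
  }
  trimesh(do.call(rbind, vs), do.call(rbind, fs), drop_degenerate = FALSE)
}

#' Write a mesh as ASCII Wavefront OBJ
#' @param mesh a `trimesh`.
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# volumass OBJ export (metres; +x cranial, +y dorsal, +z right)",
             con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read an ASCII Wavefront OBJ mesh
#' @param path OBJ file (triangular faces; metres).
#' @return a `trimesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"),
    function(x) as.integer(sub("/.*$", "", x[1:3]))))
  trimesh(v, f, drop_degenerate = FALSE)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `trimesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment volumass export (metres)",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file (ascii format, triangular faces).
#' @return a `trimesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not an ascii PLY file (no end_header)")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  trimesh(v, f, drop_degenerate = FALSE)
}

#' Serialise mass properties to JSON with explicit units
#' @param props a `mass_properties`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
mass_properties_json <- function(props, path = NULL) {
  obj <- list(
    mass = props$mass, mass_unit = "kg",
    com = as.numeric(props$com), com_unit = "m",
    inertia = props$inertia, inertia_unit = "kg m^2",
    inertia_frame = "about COM",
    volume = props$volume, volume_unit = "m^3",
    density = props$density, density_unit = "kg m^-3")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
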