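# Sensitivity-analysis body models: minimal, maximal and the four
# COM-extreme variants, derived from an initial model by fixed radial
# scaling rules. Segment lengths (hoop stations) are never altered.

VARIANT_NAMES <- c("initial", "minimal", "maximal", "most_cranial",
                   "most_caudal", "most_dorsal", "most_ventral")
SEGMENT_ROSTER <- c("head", "neck", "body", "tail", "forelimb",
                    "thigh", "shank", "foot")
# head and forelimb dimensions are never varied: the head is constrained by
# anatomical landmarks and the forelimb is a negligible mass fraction
FIXED_SEGMENTS <- c("head", "forelimb")
HINDLIMB_SEGMENTS <- c("thigh", "shank", "foot")

#' Construct a whole-body model
#'
#' @param specimen specimen identifier.
#' @param segments named list of `segment_model`s covering the roster
#'   head, neck, body, tail, forelimb, thigh, shank, foot (limb segments
#'   flagged `paired` are mirrored across the median plane and counted
#'   twice in composites).
#' @param variant variant name (default "initial").
#' @param hip_origin 3D position of the right hip joint centre; all COM
#'   values are reported relative to it (+x cranial, +y dorsal).
#' @param metrics optional `skeletal_metrics` for COM normalisation.
#' @return an object of class `body_model`.
#' @export
body_model <- function(specimen, segments, variant = "initial",
                       hip_origin = c(0, 0, 0), metrics = NULL) {
  nm <- vapply(segments, function(s) s$name, "")
  names(segments) <- nm
  missing <- setdiff(SEGMENT_ROSTER, nm)
  if (length(missing) > 0)
    stop("body model is missing segment(s): ", paste(missing, collapse = ", "))
  structure(list(specimen = specimen, variant = variant, segments = segments,
                 hip_origin = as.numeric(hip_origin), metrics = metrics),
            class = "body_model")
}

#' Variant specification from the standard scaling rules
#'
#' Rules per variant: the minimal model fits torso boundaries tightly to
#' the skeletal extremes, scales neck/tail/limb radii by 0.80, diamondises
#' every varied hoop (diagonal radii x 0.853) and enlarges airspaces; the
#' maximal model scales all varied radii by 1.2 and shrinks airspaces. The
#' four COM-extreme variants combine maximal and minimal segment rules:
#' dorsal = maximal trunk/neck/tail with minimal hindlimbs, cranial =
#' maximal neck/trunk with minimal tail and hindlimbs, and ventral/caudal
#' vice versa. Head and forelimb are never varied.
#'
#' @param name one of initial, minimal, maximal, most_cranial, most_caudal,
#'   most_dorsal, most_ventral.
#' @return named character vector of per-segment rules
#'   ("unchanged", "minimal", "maximal") with the airspace rule as an
#'   attribute ("initial", "largest", "smallest", "per_segment").
#' @export
variant_spec <- function(name = VARIANT_NAMES) {
  name <- match.arg(name)
  rule <- setNames(rep("unchanged", length(SEGMENT_ROSTER)), SEGMENT_ROSTER)
  varied <- setdiff(SEGMENT_ROSTER, FIXED_SEGMENTS)
  rule[varied] <- switch(name,
    initial = "unchanged",
    minimal = "minimal",
    maximal = "maximal",
    most_cranial = ifelse(varied %in% c("neck", "body"), "maximal", "minimal"),
    most_caudal  = ifelse(varied %in% c("neck", "body"), "minimal", "maximal"),
    most_dorsal  = ifelse(varied %in% c("neck", "body", "tail"), "maximal", "minimal"),
    most_ventral = ifelse(varied %in% c("neck", "body", "tail"), "minimal", "maximal"))
  attr(rule, "variant") <- name
  # airspaces follow their host segment: a minimal segment gets the largest
  # airspaces (x1.2 radial), a maximal one the smallest (x0.8)
  attr(rule, "airspaces") <- "per_segment"
  rule
}

# apply a single-segment rule; diamondize_torso controls whether the
# tight-to-bone torso is also diamondised in minimal-rule segments
apply_segment_rule <- function(segment, rule, diamondize_torso = TRUE,
                               diamond_factor = 0.853) {
  if (rule == "unchanged") return(segment)
  scale_cavities <- function(seg, f) {
    seg$cavities <- lapply(seg$cavities, function(cav) {
      if (inherits(cav, "trimesh"))
        stop("mesh-valued cavities cannot be rescaled; supply hoop cavities")
      lapply(cav, scale_hoop, radial_factor = f)
    })
    seg
  }
  if (rule == "maximal") {
    segment$hoops <- lapply(segment$hoops, scale_hoop, radial_factor = 1.2)
    segment <- scale_cavities(segment, 0.8)
  } else if (rule == "minimal") {
    if (segment$name == "body") {
      segment$hoops <- lapply(segment$hoops, function(h) {
        if (is.null(h$bone_radii))
          stop("torso hoops lack bone radii; cannot fit tightly to bone")
        if (h$profile == "octagon") h$radii <- h$bone_radii
        else { h$a <- h$bone_radii[1]; h$b <- h$bone_radii[2] }
        h
      })
      if (diamondize_torso)
        segment$hoops <- lapply(segment$hoops,
          function(h) diamondize(as_octagon(h), diamond_factor))
    } else {
      segment$hoops <- lapply(segment$hoops, function(h)
        diamondize(as_octagon(scale_hoop(h, 0.8)), diamond_factor))
    }
    segment <- scale_cavities(segment, 1.2)
  } else stop("unknown rule: ", rule)
  segment
}

#' Derive a sensitivity variant from an initial body model
#'
#' @param initial a complete `body_model` (the initial/preferred model).
#' @param spec a [variant_spec()] or a variant name.
#' @param diamondize_torso also diamondise the tight-to-bone torso hoops in
#'   minimal-rule segments (configuration switch; default TRUE).
#' @return a new `body_model`; segment lengths are bit-identical to the
#'   initial model's.
#' @export
derive_variant <- function(initial, spec, diamondize_torso = TRUE) {
  if (is.character(spec) && is.null(attr(spec, "variant")) &&
      length(spec) == 1 && is.null(names(spec)))
    spec <- variant_spec(spec)
  unknown <- setdiff(names(spec), SEGMENT_ROSTER)
  if (length(unknown) > 0)
    stop("unknown segment name(s) in variant spec: ",
         paste(unknown, collapse = ", "))
  if (any(spec[FIXED_SEGMENTS] != "unchanged"))
    stop("head and forelimb dimensions are fixed across variants")
  out <- initial
  out$variant <- attr(spec, "variant") %||% "custom"
  for (nm in names(spec)) {
    out$segments[[nm]] <- apply_segment_rule(initial$segments[[nm]], spec[[nm]],
                                             diamondize_torso = diamondize_torso)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mirror mass properties across the median (z = 0) plane
mirror_props_z <- function(p) {
  com <- p$com * c(1, 1, -1)
  S <- diag(c(1, 1, -1))
  new_mass_properties(mass = p$mass, com = com,
                      inertia = S %*% p$inertia %*% S,
                      volume = p$volume, density = p$density)
}

#' Per-segment and whole-body mass properties of a body model
#'
#' Paired limb segments contribute twice: the built mesh and its mirror
#' image across the median plane. COM is reported in the hip frame
#' (relative to `hip_origin`).
#'
#' @param body a `body_model`.
#' @param n_ring ring resolution for lofting.
#' @return list with `segments` (named list of `mass_properties`, pairs
#'   already combined), `total` (composite `mass_properties`) and
#'   `com_hip` (total COM relative to the hip origin).
#' @export
body_mass_properties <- function(body, n_ring = 64) {
  seg_props <- list()
  for (s in body$segments) {
    p <- segment_mass_properties(s, n_ring = n_ring)
    if (isTRUE(s$paired)) p <- compose_mass_properties(list(p, mirror_props_z(p)))
    seg_props[[s$name]] <- p
  }
  total <- compose_mass_properties(seg_props)
  list(segments = seg_props, total = total,
       com_hip = total$com - body$hip_origin)
}

#' Build the six-variant sensitivity suite
#'
#' Derives the minimal, maximal and four COM-extreme models from an
#' initial body model and computes mass properties for all of them,
#' including the initial model.
#'
#' @param initial a `body_model` (initial/preferred reconstruction).
#' @param n_ring ring resolution.
#' @param diamondize_torso passed to [derive_variant()].
#' @return list with `models` (named list of `body_model`s), `props`
#'   (their [body_mass_properties()] results) and `summary` (data frame of
#'   variant, mass_kg, comx_m, comy_m, comz_m in the hip frame).
#' @export
com_extreme_suite <- function(initial, n_ring = 64, diamondize_torso = TRUE) {
  models <- list(initial = initial)
  for (nm in setdiff(VARIANT_NAMES, "initial"))
    models[[nm]] <- derive_variant(initial, variant_spec(nm),
                                   diamondize_torso = diamondize_torso)
  props <- lapply(models, body_mass_properties, n_ring = n_ring)
  summary <- data.frame(
    variant = names(models),
    mass_kg = vapply(props, function(p) p$total$mass, 0),
    comx_m = vapply(props, function(p) p$com_hip[1], 0),
    comy_m = vapply(props, function(p) p$com_hip[2], 0),
    comz_m = vapply(props, function(p) p$com_hip[3], 0),
    row.names = NULL)
  list(models = models, props = props, summary = summary)
}
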