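# Summary metrics: skeletal measurements, segment mass tables, min/max
# ranges, normalised COM positions and whole-body density.

#' Skeletal metrics of a specimen
#'
#' @param femur_length femoral length (m).
#' @param body_length total head-to-tail-tip body length (m).
#' @param gad gleno-acetabular distance (m), shoulder to hip joint centres.
#' @param leg_length pelvic limb length (m).
#' @param tail_length tail length from the first free caudal (m).
#' @return an object of class `skeletal_metrics` including the derived
#'   GAD/body-length and tail/body-length ratios.
#' @export
skeletal_metrics <- function(femur_length, body_length, gad, leg_length,
                             tail_length) {
  vals <- c(femur_length, body_length, gad, leg_length, tail_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all skeletal metrics must be positive")
  out <- list(femur_length = femur_length, body_length = body_length,
              gad = gad, leg_length = leg_length, tail_length = tail_length,
              gad_body_ratio = gad / body_length,
              tail_body_ratio = tail_length / body_length)
  if (out$gad_body_ratio >= 1 || out$tail_body_ratio >= 1)
    stop("GAD and tail length must be smaller than body length")
  structure(out, class = "skeletal_metrics")
}

#' Segment mass table
#'
#' @param body a `body_model`, or a precomputed [body_mass_properties()]
#'   result.
#' @param n_ring ring resolution when `body` is a model.
#' @return data frame of segment, mass_kg and fraction of whole-body mass
#'   (paired limb segments are counted twice, so fractions sum to 1).
#' @export
segment_table <- function(body, n_ring = 64) {
  props <- if (inherits(body, "body_model"))
    body_mass_properties(body, n_ring = n_ring) else body
  missing <- setdiff(SEGMENT_ROSTER, names(props$segments))
  if (length(missing) > 0)
    stop("missing segment(s): ", paste(missing, collapse = ", "))
  mass <- vapply(props$segments, function(p) p$mass, 0)[SEGMENT_ROSTER]
  data.frame(segment = SEGMENT_ROSTER, mass_kg = unname(mass),
             fraction = unname(mass / props$total$mass))
}

#' Ratio of maximal to minimal model values
#' @param min_val minimal-model value (> 0).
#' @param max_val maximal-model value.
#' @return `max_val / min_val`.
#' @export
max_min_ratio <- function(min_val, max_val) {
  if (any(min_val <= 0)) stop("minimal value must be > 0")
  max_val / min_val
}

#' Normalise a hip-frame COM position by skeletal metrics
#'
#' Expresses the craniocaudal (x, cranial positive) and dorsoventral
#' (y, ventral negative) COM offsets from the hip joint as percentages of
#' femur length, body length, GAD and pelvic limb length.
#'
#' @param com COM position relative to the right hip joint: a length-2 or
#'   length-3 numeric vector (x, y[, z]) in metres.
#' @param metrics a `skeletal_metrics`.
#' @return data frame with one row per normalising metric and columns
#'   `metric`, `length_m`, `comx_pct`, `comy_pct`.
#' @export
normalize_com <- function(com, metrics) {
  com <- as.numeric(com)
  lens <- c(femur_length = metrics$femur_length,
            body_length = metrics$body_length,
            gad = metrics$gad,
            leg_length = metrics$leg_length)
  if (any(lens <= 0)) stop("normalising metrics must be > 0")
  data.frame(metric = names(lens), length_m = unname(lens),
             comx_pct = unname(100 * com[1] / lens),
             comy_pct = unname(100 * com[2] / lens))
}

#' Average and range of minimal and maximal model masses
#' @param min_mass minimal-model body mass (kg).
#' @param max_mass maximal-model body mass (kg).
#' @return list with `average` (arithmetic mean) and `ratio` (max/min).
#' @export
average_and_range <- function(min_mass, max_mass) {
  list(average = (min_mass + max_mass) / 2,
       ratio = max_min_ratio(min_mass, max_mass))
}

#' Whole-body density of a model
#'
#' Total mass over total external volume; air cavities inside the body
#' outline count toward volume but not mass, so models with airspaces fall
#' below the flesh density.
#'
#' @param body a `body_model` or a [body_mass_properties()] result.
#' @param n_ring ring resolution when `body` is a model.
#' @return density in kg m^-3.
#' @export
whole_body_density <- function(body, n_ring = 64) {
  props <- if (inherits(body, "body_model"))
    body_mass_properties(body, n_ring = n_ring) else body
  if (props$total$volume <= 0) stop("total volume must be > 0")
  props$total$mass / props$total$volume
}

#' Round masses the way the summary tables print them
#'
#' Three significant figures for masses of 1000 kg and above, otherwise
#' the value is left at full precision.
#'
#' @param x numeric masses (kg).
#' @return display-rounded values.
#' @export
display_mass <- function(x) ifelse(abs(x) >= 1000, signif(x, 3), x)

#' COM summary table for a variant suite
#'
#' @param suite result of [com_extreme_suite()].
#' @param metrics a `skeletal_metrics`.
#' @return data frame, one row per variant: body mass, hip-frame COM and
#'   the four normalised COM percentage pairs.
#' @export
com_summary <- function(suite, metrics) {
  rows <- lapply(seq_len(nrow(suite$summary)), function(i) {
    s <- suite$summary[i, ]
    nc <- normalize_com(c(s$comx_m, s$comy_m), metrics)
    data.frame(variant = s$variant, mass_kg = s$mass_kg,
               comx_m = s$comx_m, comy_m = s$comy_m,
               comx_pct_femur = nc$comx_pct[1], comy_pct_femur = nc$comy_pct[1],
               comx_pct_body = nc$comx_pct[2], comy_pct_body = nc$comy_pct[2],
               comx_pct_gad = nc$comx_pct[3], comy_pct_gad = nc$comy_pct[3],
               comx_pct_leg = nc$comx_pct[4], comy_pct_leg = nc$comy_pct[4])
  })
  do.call(rbind, rows)
}
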