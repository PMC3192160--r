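# Sigmoidal growth-curve fitting with a fixed asymptote, peak growth rate,
# developmental mass extrapolation (DME) and AICc / extra-sum-of-squares
# F-test comparison of growth series.
#
# The growth model is
#   mass(age) = max_mass / (1 + exp(a * (age - b))) + hatchling_mass
# with the asymptote max_mass imposed (not fitted) and hatchling_mass the
# assumed mass at hatching (5 kg). Growth requires a < 0; b is the age at
# which half of the maximum mass is reached.

#' Evaluate the sigmoidal growth curve
#' @param age age in years (vectorised).
#' @param a slope constant (1/years; negative for growth).
#' @param b age at 50% of maximum mass (years).
#' @param max_mass asymptotic mass above the hatchling offset (kg).
#' @param hatchling_mass assumed mass at hatching (kg).
#' @return mass in kg.
#' @export
growth_curve <- function(age, a, b, max_mass, hatchling_mass = 5) {
  max_mass / (1 + exp(a * (age - b))) + hatchling_mass
}

.growth_ss <- function(par, age, mass, max_mass, hatchling_mass) {
  sum((mass - growth_curve(age, par[1], par[2], max_mass, hatchling_mass))^2)
}

#' Fit the fixed-asymptote sigmoidal growth curve
#'
#' Least squares over (a, b) with the asymptote imposed. A fixed
#' multi-start grid (a in [-2, -0.01], b in [1, 30]) makes the fit
#' deterministic on multimodal small-sample problems; the best grid point
#' seeds Levenberg-Marquardt refinement (falling back to Nelder-Mead).
#'
#' @param obs data frame with columns `age` and `mass` (or `age_yr`,
#'   `mass_kg`), or a numeric vector of ages when `mass` is given.
#' @param max_mass fixed asymptote (kg).
#' @param mass optional numeric masses when `obs` is an age vector.
#' @param hatchling_mass fixed hatchling offset (kg, default 5).
#' @param grid_n number of grid points per parameter for the multi-start.
#' @return an object of class `growth_fit` with elements `a`, `b`,
#'   `abs_a`, `max_mass`, `hatchling_mass`, `ss`, `n`, `sigma2`,
#'   `cov` (delta-method covariance of (a, b)), `fitted`, `residuals`,
#'   `age`, `mass`.
#' @export
fit_growth <- function(obs, max_mass, mass = NULL, hatchling_mass = 5,
                       grid_n = 48) {
  if (is.data.frame(obs)) {
    age <- obs$age %||% obs$age_yr
    mass <- obs$mass %||% obs$mass_kg
  } else age <- as.numeric(obs)
  if (length(age) < 3) stop("fit_growth: need at least 3 observations")
  if (length(age) != length(mass)) stop("age and mass lengths differ")
  grid_a <- seq(-2, -0.01, length.out = grid_n)
  grid_b <- seq(1, 30, length.out = grid_n)
  best <- c(NA, NA)
  best_ss <- Inf
  for (aa in grid_a) {
    pred0 <- 1 / (1 + exp(aa * outer(age, grid_b, `-`)))
    ss <- colSums((mass - hatchling_mass - max_mass * pred0)^2)
    i <- which.min(ss)
    if (ss[i] < best_ss) {
      best_ss <- ss[i]
      best <- c(aa, grid_b[i])
    }
  }
  par <- best
  refined <- tryCatch({
    df <- data.frame(age = age, mass = mass)
    fit <- minpack.lm::nlsLM(
      mass ~ max_mass / (1 + exp(a * (age - b))) + hatchling_mass,
      data = df, start = list(a = par[1], b = par[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)
  }, error = function(e) NULL)
  if (!is.null(refined) &&
      .growth_ss(refined, age, mass, max_mass, hatchling_mass) <= best_ss + 1e-12) {
    par <- as.numeric(refined)
  } else {
    opt <- stats::optim(par, .growth_ss, age = age, mass = mass,
                        max_mass = max_mass, hatchling_mass = hatchling_mass,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (opt$value <= best_ss) par <- opt$par
  }
  ss <- .growth_ss(par, age, mass, max_mass, hatchling_mass)
  n <- length(age)
  fitted <- growth_curve(age, par[1], par[2], max_mass, hatchling_mass)
  resid <- mass - fitted
  k <- 2L
  sigma2 <- if (n > k) ss / (n - k) else NA_real_
  J <- .growth_jacobian(age, par[1], par[2], max_mass)
  covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  structure(list(a = par[1], b = par[2], abs_a = abs(par[1]),
                 max_mass = max_mass, hatchling_mass = hatchling_mass,
                 ss = ss, n = n, sigma2 = sigma2, cov = covm,
                 fitted = fitted, residuals = resid, age = age, mass = mass),
            class = "growth_fit")
}

.growth_jacobian <- function(age, a, b, max_mass) {
  e <- exp(a * (age - b))
  den <- (1 + e)^2
  cbind(a = -max_mass * (age - b) * e / den,
        b = max_mass * a * e / den)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoidal growth fit (asymptote %.6g kg + %.3g kg hatchling offset)\n",
    x$max_mass, x$hatchling_mass))
  cat(sprintf("  a = %.6g /yr (|a| = %.6g), b = %.6g yr, SS = %.6g, n = %d\n",
              x$a, x$abs_a, x$b, x$ss, x$n))
  cat(sprintf("  peak growth rate %.6g kg/yr at age b\n", peak_growth_rate(x)))
  invisible(x)
}

#' Peak (exponential-stage) growth rate
#'
#' The analytic maximum of d(mass)/d(age), attained at age b:
#' |a| * max_mass / 4.
#'
#' @param fit a `growth_fit`.
#' @return kg per year.
#' @export
peak_growth_rate <- function(fit) abs(fit$a) * fit$max_mass / 4

#' Age at which half of maximum body mass is reached
#' @param fit a `growth_fit`.
#' @return years (the fitted constant b).
#' @export
age_at_half_max <- function(fit) fit$b

#' Developmental mass extrapolation from cubed femoral lengths
#'
#' Each specimen's mass is the apex specimen's mass scaled by the cube of
#' the femoral length ratio.
#'
#' @param femur_lengths named numeric vector of femoral lengths (m).
#' @param apex_specimen name of the apex (growth-curve top) specimen.
#' @param apex_mass mass assigned to the apex specimen (kg).
#' @return named numeric vector of DME masses (kg).
#' @export
dme_masses <- function(femur_lengths, apex_specimen, apex_mass) {
  if (!apex_specimen %in% names(femur_lengths))
    stop("apex specimen '", apex_specimen, "' not found in femur lengths")
  fl_apex <- femur_lengths[[apex_specimen]]
  if (!is.finite(fl_apex) || fl_apex <= 0) stop("apex femur length must be > 0")
  apex_mass * (femur_lengths / fl_apex)^3
}

#' Compare one common growth curve against separate curves
#'
#' Fits a single (a, b) to the pooled observations (k = 2 parameters) and
#' separate (a, b) per series (k = 4), then compares them with the
#' small-sample Akaike Information Criterion,
#' AICc = n ln(SS/n) + 2k + 2k(k+1)/(n-k-1), Akaike weights, and the
#' extra-sum-of-squares F-test
#' F = ((SS_common - SS_separate)/2) / (SS_separate/(n-4)).
#'
#' @param series_a,series_b data frames with `age` and `mass` columns.
#' @param max_mass fixed asymptote shared by all fits (kg).
#' @param hatchling_mass fixed hatchling offset (kg).
#' @return an object of class `growth_model_comparison`: fits, SS values,
#'   `aicc_common`, `aicc_separate`, `akaike_weights`, `F`, `df`,
#'   `p_value`, `preferred`.
#' @export
compare_growth_models <- function(series_a, series_b, max_mass,
                                  hatchling_mass = 5) {
  pooled <- data.frame(age = c(series_a$age, series_b$age),
                       mass = c(series_a$mass, series_b$mass))
  n <- nrow(pooled)
  if (n <= 5) stop("need pooled n > 5 for the 4-parameter comparison")
  fit_common <- fit_growth(pooled, max_mass, hatchling_mass = hatchling_mass)
  fit_a <- fit_growth(series_a, max_mass, hatchling_mass = hatchling_mass)
  fit_b <- fit_growth(series_b, max_mass, hatchling_mass = hatchling_mass)
  ss_common <- fit_common$ss
  ss_separate <- fit_a$ss + fit_b$ss
  aicc <- function(ss, k) n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  aicc_c <- aicc(ss_common, 2)
  aicc_s <- aicc(ss_separate, 4)
  delta <- c(common = aicc_c, separate = aicc_s)
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  Fstat <- max(0, ((ss_common - ss_separate) / 2) / (ss_separate / (n - 4)))
  p <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  structure(list(fit_common = fit_common, fit_a = fit_a, fit_b = fit_b,
                 ss_common = ss_common, ss_separate = ss_separate,
                 aicc_common = aicc_c, aicc_separate = aicc_s,
                 akaike_weights = w, F = Fstat, df = c(2, n - 4), p_value = p,
                 preferred = names(which.max(w))),
            class = "growth_model_comparison")
}

#' @export
print.growth_model_comparison <- function(x, ...) {
  cat("growth model comparison (common vs separate curves)\n")
  cat(sprintf("  SS common %.6g (k=2), separate %.6g (k=4)\n",
              x$ss_common, x$ss_separate))
  cat(sprintf("  AICc common %.4f, separate %.4f; weights %.3f / %.3f\n",
              x$aicc_common, x$aicc_separate,
              x$akaike_weights["common"], x$akaike_weights["separate"]))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g; preferred: %s\n",
              x$df[1], x$df[2], x$F, x$p_value, x$preferred))
  invisible(x)
}

#' Pointwise confidence band for a fitted growth curve
#'
#' Delta-method band from the (a, b) covariance: fitted curve plus/minus
#' the t quantile times the propagated standard error. The band is widest
#' where the curve is sensitive to the fitted constants (around the steep
#' growth phase) and pinches toward the imposed asymptote and hatchling
#' anchor, which the model treats as known.
#'
#' @param fit a `growth_fit` (with n > 2).
#' @param level confidence level (default 0.95; 0 collapses the band onto
#'   the curve).
#' @param ages numeric grid of ages (years).
#' @return data frame with `age`, `fit`, `lo`, `hi`.
#' @export
confidence_band <- function(fit, level = 0.95, ages) {
  if (fit$n <= 2) stop("confidence_band: need n > number of parameters (2)")
  if (is.null(fit$cov)) stop("parameter covariance unavailable (singular fit)")
  g <- .growth_jacobian(ages, fit$a, fit$b, fit$max_mass)
  se <- sqrt(pmax(0, rowSums((g %*% fit$cov) * g)))
  q <- stats::qt((1 + level) / 2, df = fit$n - 2)
  f <- growth_curve(ages, fit$a, fit$b, fit$max_mass, fit$hatchling_mass)
  data.frame(age = ages, fit = f, lo = f - q * se, hi = f + q * se)
}

#' Simulate growth observations from a known sigmoid
#'
#' @param a,b,max_mass sigmoid parameters (see [growth_curve()]).
#' @param noise_sd Gaussian noise standard deviation (kg, >= 0).
#' @param ages numeric vector of observation ages (years).
#' @param seed RNG seed for reproducible draws.
#' @param hatchling_mass hatchling offset (kg).
#' @param source label recorded in the `source` column.
#' @return data frame with `specimen`, `age`, `mass`, `source`.
#' @export
generate_growth_series <- function(a, b, max_mass, noise_sd, ages, seed = 1,
                                   hatchling_mass = 5, source = "model_based") {
  if (length(ages) == 0) stop("ages must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  mu <- growth_curve(ages, a, b, max_mass, hatchling_mass)
  mass <- mu + stats::rnorm(length(ages), 0, noise_sd)
  data.frame(specimen = sprintf("sim%02d", seq_along(ages)),
             age = ages, mass = mass, source = source)
}
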