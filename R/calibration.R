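#' Brightness levels at which the screen is photometered
#'
#' Calibration measures physical luminance at six HSB brightness levels,
#' 0, 20, ..., 100 percent, on a patch of fixed hue and saturation.
#' @keywords internal
CALIBRATION_LEVELS <- c(0L, 20L, 40L, 60L, 80L, 100L)

#' Fit a luminance scale from photometer measurements
#'
#' Builds the calibrated mapping from HSB brightness percent to physical
#' luminance in cd/m2. A second-degree polynomial is fitted by least squares
#' to six photometer measurements taken at brightness 0, 20, 40, 60, 80 and
#' 100 percent, and evaluated at every integer brightness 0..100 to give a
#' 101-element fitted-luminance vector. Fit quality is summarised by a
#' Pearson chi-squared statistic over the six calibration points, its
#' upper-tail p-value at 5 degrees of freedom, and the sample standard
#' deviation of the residuals.
#'
#' @param measurements data frame with columns `brightness_pct` (exactly the
#'   six levels 0, 20, 40, 60, 80, 100, in any order, no duplicates) and
#'   `luminance` (cd/m2, non-negative).
#' @param name human-readable scale name.
#' @param hue HSB hue of the calibrated patch, 0-360.
#' @param saturation HSB saturation, 0-100.
#' @param id scale identifier; generated with [generate_id()] when `NULL`.
#' @param notes free-text notes (photometer model, ambient light, ...).
#' @return an object of class `luminance_scale`: a list with the polynomial
#'   `coefficients` (intercept, linear, quadratic), the 101-element
#'   `fitted_vector`, `chi2`, `p_value`, `residual_sd`, the original
#'   `measurements`, and the metadata fields.
#' @examples
#' m <- data.frame(brightness_pct = seq(0, 100, 20),
#'                 luminance = 0.01 * seq(0, 100, 20)^2 + 0.5)
#' sc <- fit_luminance_scale(m, name = "example")
#' brightness_to_luminance(sc, 100)
#' @export
fit_luminance_scale <- function(measurements, name = "", hue = 0,
                                saturation = 0, id = NULL, notes = "") {
  if (!is.data.frame(measurements) ||
      !all(c("brightness_pct", "luminance") %in% names(measurements))) {
    stop("`measurements` must be a data frame with columns ",
         "`brightness_pct` and `luminance`")
  }
  b <- as.numeric(measurements$brightness_pct)
  l <- as.numeric(measurements$luminance)
  if (length(b) != 6L || anyDuplicated(b) ||
      !setequal(b, CALIBRATION_LEVELS)) {
    stop("calibration requires exactly six measurements, one at each of ",
         "brightness 0, 20, 40, 60, 80, 100 %")
  }
  if (any(!is.finite(l)) || any(l < 0)) {
    stop("luminance measurements must be finite and non-negative")
  }
  ord <- order(b)
  b <- b[ord]
  l <- l[ord]

  fit <- stats::lm(l ~ b + I(b^2))
  coefs <- unname(stats::coef(fit))

  poly_at <- function(x) coefs[1] + coefs[2] * x + coefs[3] * x^2
  fitted_vec <- poly_at(0:100)
  if (any(fitted_vec < 0)) {
    warning("fitted luminance negative at some brightness levels; clamped to 0")
    fitted_vec <- pmax(fitted_vec, 0)
  }

  gof <- goodness_of_fit(l, poly_at(b))

  structure(
    list(
      id = if (is.null(id)) generate_id("S") else id,
      name = name,
      hue = hue,
      saturation = saturation,
      coefficients = coefs,
      fitted_vector = fitted_vec,
      chi2 = gof$chi2,
      p_value = gof$p_value,
      residual_sd = gof$residual_sd,
      measurements = data.frame(brightness_pct = b, luminance = l),
      notes = notes
    ),
    class = "luminance_scale"
  )
}

#' @export
print.luminance_scale <- function(x, ...) {
  cat("<luminance_scale>", x$id, if (nzchar(x$name)) paste0("(", x$name, ")"),
      "\n")
  cat(sprintf("  f(b) = %.4g + %.4g b + %.4g b^2  [cd/m2]\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  range: %.2f - %.2f cd/m2\n",
              min(x$fitted_vector), max(x$fitted_vector)))
  cat(sprintf("  fit: chi2 = %.3g, p = %.3f, residual SD = %.3g cd/m2\n",
              x$chi2, x$p_value, x$residual_sd))
  invisible(x)
}

#' Goodness of fit of a luminance calibration
#'
#' Pearson chi-squared statistic over paired observed and fitted luminances,
#' `sum((obs - fit)^2 / fit)`, with the upper-tail p-value of a chi-squared
#' distribution on `length(observed) - 1` degrees of freedom (5 for the
#' standard six-point calibration), and the sample (n-1) standard deviation
#' of the residuals.
#'
#' @param observed observed luminances (cd/m2).
#' @param fitted fitted luminances, strictly positive (they divide).
#' @return list with `chi2`, `p_value`, `residual_sd`.
#' @export
goodness_of_fit <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    stop("`observed` and `fitted` must be paired vectors of length >= 2")
  }
  if (any(fitted <= 0)) {
    stop("degenerate scale: fitted luminance must be strictly positive ",
         "for the chi-squared statistic")
  }
  chi2 <- sum((observed - fitted)^2 / fitted)
  list(
    chi2 = chi2,
    p_value = stats::pchisq(chi2, df = length(observed) - 1L,
                            lower.tail = FALSE),
    residual_sd = stats::sd(observed - fitted)
  )
}

#' Look up fitted luminance for an integer brightness percent
#'
#' The exam engine addresses the scale only through its 101-element
#' fitted-luminance vector, so brightness must be a whole percent 0..100.
#' For continuous evaluation of the underlying polynomial see
#' [eval_luminance()].
#'
#' @param scale a `luminance_scale`.
#' @param brightness_pct integer-valued brightness percent(s) in 0..100.
#' @return fitted luminance(s) in cd/m2.
#' @export
brightness_to_luminance <- function(scale, brightness_pct) {
  stopifnot(inherits(scale, "luminance_scale"))
  b <- brightness_pct
  if (any(!is.finite(b)) || any(b < 0) || any(b > 100) ||
      any(b != round(b))) {
    stop("`brightness_pct` must be integer-valued and within 0..100")
  }
  scale$fitted_vector[as.integer(round(b)) + 1L]
}

#' Evaluate the calibration polynomial at arbitrary brightness
#'
#' Continuous convenience around the quadratic fit; not used by the exam
#' engine, which indexes the integer fitted vector.
#' @inheritParams brightness_to_luminance
#' @export
eval_luminance <- function(scale, brightness_pct) {
  stopifnot(inherits(scale, "luminance_scale"))
  if (any(brightness_pct < 0) || any(brightness_pct > 100)) {
    stop("`brightness_pct` must be within 0..100")
  }
  co <- scale$coefficients
  co[1] + co[2] * brightness_pct + co[3] * brightness_pct^2
}

#' Luminance attenuation in decibels
#'
#' Sensitivity in perimetry is expressed as the attenuation of the threshold
#' luminance relative to the instrument's maximum stimulus luminance:
#' `dB = 10 * log10(l_max / l_t)`. 0 dB means the threshold sits at the
#' maximum; larger values mean dimmer stimuli were detected.
#'
#' @param l_t threshold (or minimum) luminance, cd/m2, `0 < l_t <= l_max`.
#' @param l_max maximum stimulus luminance of the scale in use, cd/m2.
#' @return decibel value(s) >= 0.
#' @examples
#' luminance_to_db(3.64, 154.46) # dB range of a calibrated scale
#' @export
luminance_to_db <- function(l_t, l_max) {
  if (any(l_t <= 0)) stop("`l_t` must be strictly positive")
  if (any(l_t > l_max)) stop("`l_t` must not exceed `l_max`")
  10 * log10(l_max / l_t)
}

#' Invert a decibel attenuation back to luminance
#'
#' Exact inverse of [luminance_to_db()]: `l_max / 10^(db/10)`.
#'
#' @param db attenuation in decibels, >= 0.
#' @param l_max maximum stimulus luminance of the scale, cd/m2, > 0.
#' @export
db_to_luminance <- function(db, l_max) {
  if (any(db < 0)) stop("`db` must be non-negative")
  if (any(l_max <= 0)) stop("`l_max` must be strictly positive")
  l_max / 10^(db / 10)
}

#' Re-express a decibel value on another instrument's scale
#'
#' Different instruments attenuate from different maximum luminances, so the
#' same physical threshold maps to different dB values. This converts a dB
#' value on one scale to the dB value the same physical luminance would get
#' on a scale with a different maximum (e.g. a 154.46 cd/m2 screen scale
#' versus a 318 cd/m2 projection perimeter scale).
#'
#' @param db decibel value on the source scale.
#' @param l_max_from maximum luminance of the source scale, cd/m2.
#' @param l_max_to maximum luminance of the target scale, cd/m2.
#' @return decibel value on the target scale (may be negative if the
#'   luminance exceeds the target maximum).
#' @export
convert_db_scale <- function(db, l_max_from, l_max_to) {
  l <- db_to_luminance(db, l_max_from)
  10 * log10(l_max_to / l)
}

#' Read photometer calibration measurements from CSV
#'
#' Expects a header `brightness_pct,luminance_cd_m2` and six rows.
#' @param path CSV file path.
#' @return data frame with columns `brightness_pct`, `luminance`, suitable
#'   for [fit_luminance_scale()].
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("brightness_pct", "luminance_cd_m2") %in% names(d))) {
    stop("calibration CSV must have header `brightness_pct,luminance_cd_m2`")
  }
  data.frame(brightness_pct = d$brightness_pct, luminance = d$luminance_cd_m2)
}
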