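# Fixation monitoring. Two complementary checks exist: a control stimulus
# flashed at the assumed blind-spot location (Heijl-Krakau style -- a
# response means the eye was NOT on the fixation point), and a transient
# change of the fixation point's appearance (a response means the eye WAS
# on it). "both" mixes the two; accuracies are tallied per technique.

#' Configure fixation monitoring
#'
#' @param technique `"blindspot"`, `"fixation_point_change"` or `"both"`.
#' @param blindspot_location field location of the control stimulus,
#'   `c(x_deg, y_deg)`; defaults to the physiological blind spot of the
#'   chosen `eye`.
#' @param eye used only to pick the default blind-spot side.
#' @param check_frequency integer interval `c(a, b)`: one fixation check is
#'   inserted after every `k` ordinary stimuli with `k` drawn uniformly
#'   from `a..b`.
#' @param control_brightness_pct brightness of the blind-spot control
#'   stimulus on the stimulus luminance scale (whole percent).
#' @param feedback_enabled show a feedback message on fixation loss.
#' @param feedback_text,feedback_position,feedback_color,feedback_font_size
#'   appearance of that message (logged, not rendered).
#' @return object of class `fixation_config`.
#' @export
fixation_config <- function(technique = c("blindspot",
                                          "fixation_point_change", "both"),
                            blindspot_location = NULL,
                            eye = c("left", "right"),
                            check_frequency = c(5L, 10L),
                            control_brightness_pct = 100L,
                            feedback_enabled = FALSE,
                            feedback_text = "Please maintain fixation",
                            feedback_position = "center",
                            feedback_color = "white",
                            feedback_font_size = 24) {
  technique <- match.arg(technique)
  eye <- match.arg(eye)
  if (is.null(blindspot_location)) blindspot_location <- default_blindspot(eye)
  a <- as.integer(check_frequency[1]); b <- as.integer(check_frequency[2])
  if (is.na(a) || is.na(b) || a < 1L || a > b) {
    stop("check_frequency must be an integer interval [a, b] with 1 <= a <= b")
  }
  if (control_brightness_pct < 0 || control_brightness_pct > 100) {
    stop("control stimulus brightness must lie within the scale range 0..100")
  }
  structure(
    list(technique = technique,
         blindspot_location = blindspot_location,
         check_frequency = c(a, b),
         control_brightness_pct = as.integer(control_brightness_pct),
         feedback_enabled = isTRUE(feedback_enabled),
         feedback_text = feedback_text,
         feedback_position = feedback_position,
         feedback_color = feedback_color,
         feedback_font_size = feedback_font_size),
    class = "fixation_config"
  )
}

#' Interpret the response to a fixation check
#'
#' A blind-spot control stimulus falls on the optic disc while fixation is
#' held, so a response means fixation was lost and silence means it was
#' held. A fixation-point change is at fixation itself, so the logic
#' inverts: a response means fixation was held.
#'
#' @param kind `"blindspot_check"` or `"fixation_point_change"`.
#' @param responded logical.
#' @return `"fixating"` or `"lost"`.
#' @export
evaluate_check <- function(kind, responded) {
  kind <- match.arg(kind, c("blindspot_check", "fixation_point_change"))
  stopifnot(is.logical(responded), length(responded) == 1L)
  held <- if (kind == "blindspot_check") !responded else responded
  if (held) "fixating" else "lost"
}

#' Draw the kind of the next fixation check
#'
#' Single-technique modes always use their own check; `"both"` draws
#' uniformly between the two so both accumulate counts.
#'
#' @param technique as in [fixation_config()].
#' @return `"blindspot_check"` or `"fixation_point_change"`.
#' @export
next_check_kind <- function(technique) {
  switch(technique,
    blindspot = "blindspot_check",
    fixation_point_change = "fixation_point_change",
    both = sample(c("blindspot_check", "fixation_point_change"), 1L),
    stop("unknown fixation technique: ", technique))
}

#' Build the feedback record for a fixation-check verdict
#'
#' Returns a message record when the verdict is `"lost"` and feedback is
#' enabled, otherwise `NULL`. Feedback is purely a log entry: it never
#' touches any staircase.
#'
#' @param verdict `"fixating"` or `"lost"`.
#' @param config a [fixation_config()].
#' @export
emit_feedback <- function(verdict, config) {
  stopifnot(inherits(config, "fixation_config"))
  if (identical(verdict, "lost") && config$feedback_enabled) {
    list(text = config$feedback_text,
         position = config$feedback_position,
         color = config$feedback_color,
         font_size = config$feedback_font_size)
  } else {
    NULL
  }
}
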