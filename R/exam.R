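# The examination loop. Locations are interleaved: at each step an
# unfinished location is drawn uniformly at random and probed at its
# staircase's current brightness index. Inter-stimulus intervals are drawn
# uniformly from [isi_min, isi_max]. After every k ordinary stimuli
# (k redrawn uniformly from the configured integer interval) a fixation
# check is inserted. Time is virtual: summed display times and intervals.

#' Assemble an examination configuration
#'
#' @param grid a [generate_grid()] stimulus grid.
#' @param stimulus_scale [fit_luminance_scale()] scale for the stimuli.
#' @param vector a [make_brightness_vector()] brightness vector.
#' @param fixation a [fixation_config()].
#' @param background_scale optional scale for the background.
#' @param background_brightness_pct background brightness on its scale.
#' @param stimulus_shape `"ellipse"` or `"polygon"`.
#' @param stimulus_width_deg,stimulus_height_deg stimulus size, degrees.
#' @param stimulus_inclination_deg inclination for polygon stimuli, degrees.
#' @param display_time_ms stimulus display time, ms.
#' @param isi_min_ms,isi_max_ms inter-stimulus interval bounds, ms
#'   (equal values give a constant interval).
#' @param eye `"left"` or `"right"`.
#' @return object of class `exam_config`.
#' @export
exam_config <- function(grid, stimulus_scale, vector,
                        fixation = fixation_config(),
                        background_scale = NULL,
                        background_brightness_pct = 0L,
                        stimulus_shape = c("ellipse", "polygon"),
                        stimulus_width_deg = 0.43,
                        stimulus_height_deg = 0.43,
                        stimulus_inclination_deg = 0,
                        display_time_ms = 200,
                        isi_min_ms = 1000, isi_max_ms = 1500,
                        eye = c("left", "right")) {
  stopifnot(inherits(grid, "stimulus_grid"),
            inherits(stimulus_scale, "luminance_scale"),
            inherits(vector, "brightness_vector"),
            inherits(fixation, "fixation_config"))
  stimulus_shape <- match.arg(stimulus_shape)
  eye <- match.arg(eye)
  if (display_time_ms <= 0) stop("display_time_ms must be positive")
  if (isi_min_ms > isi_max_ms) stop("isi_min_ms must not exceed isi_max_ms")
  structure(
    list(grid = grid, stimulus_scale = stimulus_scale, vector = vector,
         fixation = fixation, background_scale = background_scale,
         background_brightness_pct = as.integer(background_brightness_pct),
         stimulus_shape = stimulus_shape,
         stimulus_width_deg = stimulus_width_deg,
         stimulus_height_deg = stimulus_height_deg,
         stimulus_inclination_deg = stimulus_inclination_deg,
         display_time_ms = display_time_ms,
         isi_min_ms = isi_min_ms, isi_max_ms = isi_max_ms,
         eye = eye),
    class = "exam_config"
  )
}

#' @export
print.exam_config <- function(x, ...) {
  cat(sprintf(
    "<exam_config> %s eye, %d locations, vector length %d (%s), %s fixation\n",
    x$eye, nrow(x$grid$locations), x$vector$length, x$vector$spread,
    x$fixation$technique))
  invisible(x)
}

#' Run a full simulated examination
#'
#' Drives the staircase at every grid location to completion against a
#' simulated observer, inserting fixation checks and tallying response
#' counters, and returns the finished session. All randomness (location
#' order, intervals, check timing and kinds, observer noise) comes from one
#' RNG stream, so a given `seed` reproduces the presentation log exactly.
#'
#' @param config an [exam_config()].
#' @param observer a [make_observer()] simulated observer whose truth map
#'   covers the grid.
#' @param seed optional integer seed.
#' @return object of class `exam_session`: `presentations` (data frame
#'   `seq`, `time_ms`, `kind`, `loc_index`, `brightness_index`,
#'   `brightness_pct`, `luminance_cd_m2`, `response`, `verdict`),
#'   `staircases`, `thresholds` (per-location data frame), `counters`,
#'   `feedback` (list of emitted messages), `duration_ms`, `config`,
#'   `cancelled`.
#' @export
run_exam <- function(config, observer, seed = NULL) {
  stopifnot(inherits(config, "exam_config"), inherits(observer, "sim_observer"))
  n_loc <- nrow(config$grid$locations)
  if (length(observer$truth_map) != n_loc) {
    stop("observer truth map covers ", length(observer$truth_map),
         " locations but the grid has ", n_loc)
  }
  if (!is.null(seed)) set.seed(seed)

  vec <- config$vector
  scale <- config$stimulus_scale
  fix <- config$fixation
  staircases <- lapply(seq_len(n_loc), function(i) staircase_init(vec))
  unfinished <- seq_len(n_loc)

  counters <- list(
    positives = 0L, false_positives = 0L,
    blindspot_total = 0L, blindspot_correct = 0L,
    point_change_total = 0L, point_change_correct = 0L)
  feedback_log <- list()

  draw_gap <- function() sample(seq(fix$check_frequency[1],
                                    fix$check_frequency[2]), 1L)
  until_check <- draw_gap()

  rows <- vector("list", n_loc * vec$length * 2L)
  n_rows <- 0L
  time_ms <- 0
  push <- function(kind, loc, bidx, bpct, lum, resp, verdict) {
    n_rows <<- n_rows + 1L
    rows[[n_rows]] <<- data.frame(
      seq = n_rows, time_ms = time_ms, kind = kind,
      loc_index = loc, brightness_index = bidx, brightness_pct = bpct,
      luminance_cd_m2 = lum, response = resp, verdict = verdict,
      stringsAsFactors = FALSE)
  }

  while (length(unfinished) > 0L) {
    loc <- if (length(unfinished) == 1L) unfinished else sample(unfinished, 1L)
    st <- staircases[[loc]]
    bidx <- st$current
    bpct <- vec$values[bidx]
    lum <- brightness_to_luminance(scale, round(bpct))
    resp <- respond_stimulus(observer, loc, lum)
    if (resp) counters$positives <- counters$positives + 1L
    push("stimulus", loc, bidx, bpct, lum, resp, NA_character_)

    st <- staircase_step(st, resp)
    staircases[[loc]] <- st
    if (st$finished) unfinished <- setdiff(unfinished, loc)

    time_ms <- time_ms + config$display_time_ms +
      stats::runif(1, config$isi_min_ms, config$isi_max_ms)
    # a response arriving during the interval has no open window -> F
    if (respond_blank(observer)) {
      counters$false_positives <- counters$false_positives + 1L
    }

    until_check <- until_check - 1L
    if (until_check <= 0L) {
      kind <- next_check_kind(fix$technique)
      responded <- respond_fixation_check(observer, kind)
      verdict <- evaluate_check(kind, responded)
      if (kind == "blindspot_check") {
        counters$blindspot_total <- counters$blindspot_total + 1L
        if (verdict == "fixating") {
          counters$blindspot_correct <- counters$blindspot_correct + 1L
        }
        lum_c <- brightness_to_luminance(scale, fix$control_brightness_pct)
        push("blindspot_check", NA_integer_, NA_integer_,
             as.numeric(fix$control_brightness_pct), lum_c, responded, verdict)
      } else {
        counters$point_change_total <- counters$point_change_total + 1L
        if (verdict == "fixating") {
          counters$point_change_correct <- counters$point_change_correct + 1L
        }
        push("fixation_change", NA_integer_, NA_integer_, NA_real_, NA_real_,
             responded, verdict)
      }
      msg <- emit_feedback(verdict, fix)
      if (!is.null(msg)) feedback_log[[length(feedback_log) + 1L]] <- msg
      time_ms <- time_ms + config$display_time_ms +
        stats::runif(1, config$isi_min_ms, config$isi_max_ms)
      until_check <- draw_gap()
    }
  }

  thresholds <- do.call(rbind, lapply(seq_len(n_loc), function(i) {
    th <- staircase_threshold(staircases[[i]], vec, scale)
    data.frame(index = i,
               threshold_index = staircases[[i]]$threshold_index,
               brightness_pct = th$brightness_pct,
               luminance_cd_m2 = th$luminance)
  }))

  structure(
    list(presentations = do.call(rbind, rows[seq_len(n_rows)]),
         staircases = staircases, thresholds = thresholds,
         counters = counters, feedback = feedback_log,
         duration_ms = time_ms, config = config, cancelled = FALSE),
    class = "exam_session"
  )
}

#' @export
print.exam_session <- function(x, ...) {
  s <- session_summary(x)
  cat(sprintf("<exam_session> %d presentations over %d locations, %.1f s\n",
              nrow(x$presentations), nrow(x$thresholds),
              x$duration_ms / 1000))
  cat(sprintf("  positives %d, false positives %d (FPRR %s)\n",
              x$counters$positives, x$counters$false_positives,
              if (is.na(s$fprr)) "n/a" else sprintf("%.1f%%", s$fprr)))
  if (x$counters$blindspot_total > 0) {
    cat(sprintf("  blindspot fixation accuracy %d/%d (%.0f%%)%s\n",
                x$counters$blindspot_correct, x$counters$blindspot_total,
                s$blindspot_accuracy,
                if (isTRUE(s$blindspot_unreliable)) " [unreliable]" else ""))
  }
  if (x$counters$point_change_total > 0) {
    cat(sprintf("  point-change fixation accuracy %d/%d (%.0f%%)\n",
                x$counters$point_change_correct, x$counters$point_change_total,
                s$point_change_accuracy))
  }
  invisible(x)
}

#' False-positive response rate
#'
#' `FPRR = F / (F + P) * 100`, where F counts responses made with no open
#' response window and P counts positive responses to presented stimuli.
#' `NA` when no responses were recorded. (Raw F and P are always kept on
#' the session counters, so the alternative F/P convention can be
#' recomputed.)
#'
#' @param counters an `exam_session` or its `counters` list.
#' @return percent, or `NA_real_` when F + P = 0.
#' @export
false_positive_rate <- function(counters) {
  if (inherits(counters, "exam_session")) counters <- counters$counters
  f <- counters$false_positives
  p <- counters$positives
  if (f + p == 0L) return(NA_real_)
  f / (f + p) * 100
}

#' Fixation accuracy
#'
#' Correct responses to fixation checks over the total number of checks,
#' as a percentage; `NA` when no checks were made.
#'
#' @param correct,total counts.
#' @export
fixation_accuracy <- function(correct, total) {
  if (total == 0L) return(NA_real_)
  correct / total * 100
}

#' Summarise a finished session
#'
#' Duration, per-technique fixation accuracy, FPRR, and a reliability flag:
#' blind-spot fixation accuracy below 75% suggests the assumed blind-spot
#' location missed the subject's optic disc, making that index unreliable.
#'
#' @param session an `exam_session`.
#' @return list of summary quantities.
#' @export
session_summary <- function(session) {
  stopifnot(inherits(session, "exam_session"))
  cn <- session$counters
  bs <- fixation_accuracy(cn$blindspot_correct, cn$blindspot_total)
  pc <- fixation_accuracy(cn$point_change_correct, cn$point_change_total)
  list(
    duration_ms = session$duration_ms,
    n_presentations = nrow(session$presentations),
    positives = cn$positives,
    false_positives = cn$false_positives,
    fprr = false_positive_rate(cn),
    blindspot_checks = cn$blindspot_total,
    blindspot_correct = cn$blindspot_correct,
    blindspot_accuracy = bs,
    blindspot_unreliable = !is.na(bs) && bs < 75,
    point_change_checks = cn$point_change_total,
    point_change_correct = cn$point_change_correct,
    point_change_accuracy = pc
  )
}

#' Export the presentation log as CSV
#'
#' Columns `seq,time_ms,kind,loc_index,brightness_pct,luminance_cd_m2,
#' response,latency_ms` (latency is not modelled in virtual time and is
#' written as NA).
#'
#' @param session an `exam_session`.
#' @param path output CSV path.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "exam_session"))
  d <- session$presentations
  d$latency_ms <- NA_real_
  utils::write.csv(
    d[, c("seq", "time_ms", "kind", "loc_index", "brightness_pct",
          "luminance_cd_m2", "response", "latency_ms")],
    path, row.names = FALSE)
  invisible(path)
}
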