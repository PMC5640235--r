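# The Basic adaptive procedure: a bracketing staircase over a discrete,
# ascending brightness vector. The search keeps a candidate interval
# [lo, hi] of vector indices; a miss discards everything up to and
# including the current index and jumps up by two, a detection moves the
# ceiling down to the current index and probes one step dimmer. The
# estimated threshold is the lowest index answered "seen" whose dimmer
# neighbour was answered "not seen" or eliminated.

#' Construct the brightness vector tested at every location
#'
#' Ascending brightness percents from `min_pct` to `max_pct`. The stepping
#' rule of the staircase admits only lengths of the form `5 + 4n` (9, 13,
#' 17, 21, ...). Values are spread equally (arithmetic progression) or
#' logarithmically (geometric progression; requires `min_pct > 0`).
#'
#' @param min_pct,max_pct endpoints in percent, `0 <= min < max <= 100`.
#' @param length vector length, one of 9, 13, 17, 21, ...
#' @param spread `"equal"` or `"logarithmic"`.
#' @return object of class `brightness_vector` with fields `values`,
#'   `spread`, `length`.
#' @examples
#' make_brightness_vector(0, 100, 9)$values
#' @export
make_brightness_vector <- function(min_pct, max_pct, length,
                                   spread = c("equal", "logarithmic")) {
  spread <- match.arg(spread)
  if (length < 9 || (length - 5) %% 4 != 0) {
    stop("brightness vector length must be of the form 5 + 4n, ",
         "which gives 9, 13, 17, 21 etc.")
  }
  if (min_pct < 0 || max_pct > 100 || min_pct >= max_pct) {
    stop("need 0 <= min_pct < max_pct <= 100")
  }
  values <- switch(spread,
    equal = seq(min_pct, max_pct, length.out = length),
    logarithmic = {
      if (min_pct <= 0) stop("logarithmic spread requires min_pct > 0")
      exp(seq(log(min_pct), log(max_pct), length.out = length))
    })
  structure(list(values = values, spread = spread, length = as.integer(length)),
            class = "brightness_vector")
}

#' @export
print.brightness_vector <- function(x, ...) {
  cat(sprintf("<brightness_vector> length %d, %s spread: %s\n", x$length,
              x$spread, paste(signif(x$values, 4), collapse = " ")))
  invisible(x)
}

#' Initialise a staircase over a brightness vector
#'
#' Testing starts from the middle of the vector, with the whole index range
#' still a candidate.
#'
#' @param vector a [make_brightness_vector()] result, or a bare admissible
#'   length.
#' @return object of class `staircase` with fields `lo`, `hi`, `current`,
#'   `history` (data frame `index`, `seen`), `threshold_index`
#'   (NA until finished; NA on finish means no response at any brightness),
#'   `finished`, `length`.
#' @export
staircase_init <- function(vector) {
  len <- if (inherits(vector, "brightness_vector")) vector$length
         else as.integer(vector)
  if (len < 9 || (len - 5) %% 4 != 0) {
    stop("staircase requires a brightness vector of length 5 + 4n")
  }
  structure(
    list(lo = 1L, hi = len, current = (len + 1L) %/% 2L,
         history = data.frame(index = integer(), seen = logical()),
         threshold_index = NA_integer_, finished = FALSE, length = len),
    class = "staircase"
  )
}

#' Advance a staircase by one response
#'
#' Not seen: indices up to the current one are discarded (`lo <- current + 1`)
#' and the probe jumps two steps brighter, capped at the ceiling; if nothing
#' remains the location finishes with no response. Seen: the ceiling drops
#' to the current index and the probe moves one step dimmer; if no dimmer
#' candidate remains the current index is the estimated threshold.
#'
#' @param state an unfinished `staircase`.
#' @param seen logical response to the presentation at `state$current`.
#' @return the updated `staircase`.
#' @export
staircase_step <- function(state, seen) {
  stopifnot(inherits(state, "staircase"))
  if (state$finished) stop("cannot step a finished staircase")
  stopifnot(is.logical(seen), length(seen) == 1L, !is.na(seen))

  state$history <- rbind(state$history,
                         data.frame(index = state$current, seen = seen))
  if (!seen) {
    state$lo <- state$current + 1L
    if (state$lo > state$hi) {
      state$finished <- TRUE
      state$threshold_index <- NA_integer_
    } else {
      state$current <- min(state$current + 2L, state$hi)
    }
  } else {
    state$hi <- state$current
    if (state$current - 1L >= state$lo) {
      state$current <- state$current - 1L
    } else {
      state$finished <- TRUE
      state$threshold_index <- state$current
    }
  }
  state
}

#' Map a finished staircase to threshold brightness and luminance
#'
#' @param state a finished `staircase`.
#' @param vector the `brightness_vector` it ran over.
#' @param scale optional [fit_luminance_scale()] result; when given, the
#'   threshold brightness is converted to fitted luminance. Brightness is
#'   rounded to the nearest whole percent for the fitted-vector lookup.
#' @return list `brightness_pct`, `luminance` (both `NA` for a no-response
#'   location).
#' @export
staircase_threshold <- function(state, vector, scale = NULL) {
  stopifnot(inherits(state, "staircase"),
            inherits(vector, "brightness_vector"))
  if (!state$finished) stop("staircase has not finished")
  if (is.na(state$threshold_index)) {
    return(list(brightness_pct = NA_real_, luminance = NA_real_))
  }
  b <- vector$values[state$threshold_index]
  lum <- if (is.null(scale)) NA_real_
         else brightness_to_luminance(scale, round(b))
  list(brightness_pct = b, luminance = lum)
}

#' Exhaustively estimate a deterministic observer's threshold
#'
#' Reference sweep used to validate the staircase: present every vector
#' index in ascending order to a deterministic response function and return
#' the lowest index answered "seen" (NA if none). For an observer whose
#' seen-set is upward-closed this is the true threshold index.
#'
#' @param length vector length.
#' @param sees function(index) -> logical.
#' @return lowest seen index or NA.
#' @export
sweep_threshold <- function(length, sees) {
  for (i in seq_len(length)) if (isTRUE(sees(i))) return(i)
  NA_integer_
}

#' Run a staircase against a deterministic response function
#'
#' @param length vector length.
#' @param sees function(index) -> logical.
#' @return the finished `staircase`.
#' @export
run_staircase <- function(length, sees) {
  st <- staircase_init(length)
  while (!st$finished) st <- staircase_step(st, isTRUE(sees(st$current)))
  st
}
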