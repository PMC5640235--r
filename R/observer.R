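# Simulated observer: a configurable stand-in for the patient so the whole
# examination loop can run headlessly. Detection is a step function of
# luminance at each location's true threshold, optionally corrupted by a
# guess rate (responding to something unseen) and a lapse rate (missing
# something seen). Fixation loss is i.i.d. per check with probability q.

#' Create a simulated observer
#'
#' @param truth_map numeric vector of true threshold luminances (cd/m2),
#'   one per grid location index; `NA` or `Inf` marks a blind location that
#'   never sees any stimulus.
#' @param guess_rate gamma, probability of responding to an unseen stimulus
#'   (also the per-interval probability of a spurious response between
#'   stimuli, which the engine counts as a false positive).
#' @param lapse_rate lambda, probability of missing a seen stimulus.
#' @param fixation_loss_prob q, probability that any given fixation check
#'   happens while fixation is lost.
#' @return object of class `sim_observer`.
#' @export
make_observer <- function(truth_map, guess_rate = 0, lapse_rate = 0,
                          fixation_loss_prob = 0) {
  probs <- c(guess_rate, lapse_rate, fixation_loss_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("guess, lapse and fixation-loss probabilities must lie in [0, 1]")
  }
  if (guess_rate + lapse_rate >= 1) {
    stop("guess_rate + lapse_rate must be < 1")
  }
  tm <- as.numeric(truth_map)
  tm[is.na(tm)] <- Inf
  if (any(tm[is.finite(tm)] <= 0)) {
    stop("true thresholds must be positive (or NA/Inf for blind)")
  }
  structure(
    list(truth_map = tm, guess_rate = guess_rate, lapse_rate = lapse_rate,
         fixation_loss_prob = fixation_loss_prob),
    class = "sim_observer"
  )
}

#' @export
print.sim_observer <- function(x, ...) {
  cat(sprintf(
    "<sim_observer> %d locations (%d blind), gamma=%.3g lambda=%.3g q=%.3g\n",
    length(x$truth_map), sum(is.infinite(x$truth_map)),
    x$guess_rate, x$lapse_rate, x$fixation_loss_prob))
  invisible(x)
}

#' Observer response to a stimulus presentation
#'
#' The stimulus is detectable when the location is not blind and its
#' luminance reaches the true threshold. A detectable stimulus is responded
#' to with probability `1 - lambda`; an undetectable one with probability
#' `gamma`. Draws come from the session RNG stream, so a seeded run is
#' reproducible.
#'
#' @param observer a [make_observer()] result.
#' @param loc_index grid location index.
#' @param luminance presented stimulus luminance, cd/m2.
#' @return logical: did the observer respond.
#' @export
respond_stimulus <- function(observer, loc_index, luminance) {
  stopifnot(inherits(observer, "sim_observer"))
  if (loc_index < 1 || loc_index > length(observer$truth_map)) {
    stop("unknown location index ", loc_index)
  }
  seen <- luminance >= observer$truth_map[loc_index]
  p <- if (seen) 1 - observer$lapse_rate else observer$guess_rate
  stats::runif(1) < p
}

#' Observer response to a fixation check
#'
#' With probability `1 - q` fixation is held: the blind-spot control falls
#' on the optic disc and draws no response (except a gamma guess), while a
#' fixation-point change is seen and answered (except a lambda lapse). With
#' probability `q` fixation is lost: the control stimulus lands on seeing
#' retina and is answered; the point change goes unnoticed.
#'
#' @param observer a [make_observer()] result.
#' @param kind `"blindspot_check"` or `"fixation_point_change"`.
#' @return logical: did the observer respond.
#' @export
respond_fixation_check <- function(observer, kind) {
  stopifnot(inherits(observer, "sim_observer"))
  kind <- match.arg(kind, c("blindspot_check", "fixation_point_change"))
  lost <- stats::runif(1) < observer$fixation_loss_prob
  if (kind == "blindspot_check") {
    if (lost) TRUE else stats::runif(1) < observer$guess_rate
  } else {
    if (lost) FALSE else stats::runif(1) < 1 - observer$lapse_rate
  }
}

#' Spurious observer response during an inter-stimulus interval
#'
#' One Bernoulli(gamma) draw per interval; a response here arrives with no
#' open response window and is counted as a false positive by the engine.
#'
#' @param observer a [make_observer()] result.
#' @return logical.
#' @export
respond_blank <- function(observer) {
  stopifnot(inherits(observer, "sim_observer"))
  stats::runif(1) < observer$guess_rate
}

# ---- truth-map presets -------------------------------------------------

#' Truth-map presets for common visual-field conditions
#'
#' Convenience constructors for [make_observer()] truth maps over a
#' [generate_grid()] grid. `observer_uniform` sees everywhere at one
#' threshold; `observer_hemianopia` is blind in one half-field (e.g. the
#' homonymous hemianopia of a post-chiasmatic stroke); `observer_tunnel`
#' is blind outside a central radius (advanced retinitis pigmentosa);
#' `observer_scotoma` is blind inside a patch, by default at the
#' physiological blind-spot location.
#'
#' @param grid a `stimulus_grid`.
#' @param threshold_luminance true threshold (cd/m2) at seeing locations.
#' @param blind_side `"left"` or `"right"`: which half-field is blind.
#' @param radius_deg radius of the preserved (tunnel) or blind (scotoma)
#'   region, degrees.
#' @param center `c(x_deg, y_deg)` centre of the scotoma patch.
#' @param ... passed on to [make_observer()] (guess/lapse/fixation-loss).
#' @return a `sim_observer`.
#' @name observer_presets
NULL

#' @rdname observer_presets
#' @export
observer_uniform <- function(grid, threshold_luminance, ...) {
  stopifnot(inherits(grid, "stimulus_grid"))
  make_observer(rep(threshold_luminance, nrow(grid$locations)), ...)
}

#' @rdname observer_presets
#' @export
observer_hemianopia <- function(grid, threshold_luminance,
                                blind_side = c("right", "left"), ...) {
  stopifnot(inherits(grid, "stimulus_grid"))
  blind_side <- match.arg(blind_side)
  x <- grid$locations$x_deg
  blind <- if (blind_side == "right") x > 0 else x < 0
  tm <- rep(threshold_luminance, nrow(grid$locations))
  tm[blind] <- Inf
  make_observer(tm, ...)
}

#' @rdname observer_presets
#' @export
observer_tunnel <- function(grid, threshold_luminance, radius_deg = 10, ...) {
  stopifnot(inherits(grid, "stimulus_grid"))
  r <- sqrt(grid$locations$x_deg^2 + grid$locations$y_deg^2)
  tm <- rep(threshold_luminance, nrow(grid$locations))
  tm[r > radius_deg] <- Inf
  make_observer(tm, ...)
}

#' @rdname observer_presets
#' @export
observer_scotoma <- function(grid, threshold_luminance,
                             center = default_blindspot("left"),
                             radius_deg = 3, ...) {
  stopifnot(inherits(grid, "stimulus_grid"))
  r <- sqrt((grid$locations$x_deg - center[1])^2 +
            (grid$locations$y_deg - center[2])^2)
  tm <- rep(threshold_luminance, nrow(grid$locations))
  tm[r <= radius_deg] <- Inf
  make_observer(tm, ...)
}

#' Export an observer's truth map as CSV
#'
#' Columns `index,x_deg,y_deg,true_threshold_cd_m2` (blank for blind), for
#' comparison with an estimated map.
#' @param observer a `sim_observer`.
#' @param grid the `stimulus_grid` it is defined over.
#' @param path output CSV path.
#' @export
write_truth_csv <- function(observer, grid, path) {
  stopifnot(inherits(observer, "sim_observer"),
            inherits(grid, "stimulus_grid"))
  tm <- observer$truth_map
  tm[is.infinite(tm)] <- NA_real_
  utils::write.csv(
    data.frame(index = grid$locations$index,
               x_deg = grid$locations$x_deg, y_deg = grid$locations$y_deg,
               true_threshold_cd_m2 = tm),
    path, row.names = FALSE)
  invisible(path)
}
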