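# Decibel sensitivity maps. Each location's threshold luminance is
# expressed as attenuation from the scale's maximum stimulus luminance;
# a location with no response at maximum luminance is 0 dB by convention.

#' Build a dB sensitivity map from a finished session
#'
#' Per location, `db = 10 log10(l_max / threshold)`, with `l_max` the
#' fitted luminance at the brightness vector's maximum. A location that
#' never responded (threshold `NA`) is assigned 0 dB.
#'
#' @param session a finished, non-cancelled `exam_session`.
#' @param scale the stimulus `luminance_scale`; defaults to the one in the
#'   session's config.
#' @param metadata optional named list (patient id, result id, ...).
#' @return object of class `vf_map`: list with `locations` (data frame
#'   `index`, `x_deg`, `y_deg`, `db`), `l_max`, `vector_length`, `eye`,
#'   `metadata`.
#' @export
build_map <- function(session, scale = NULL, metadata = list()) {
  stopifnot(inherits(session, "exam_session"))
  if (isTRUE(session$cancelled)) {
    stop("cancelled session stores no results")
  }
  if (is.null(scale)) scale <- session$config$stimulus_scale
  vec <- session$config$vector
  l_max <- brightness_to_luminance(scale, round(max(vec$values)))
  th <- session$thresholds$luminance_cd_m2
  db <- numeric(length(th))
  ok <- !is.na(th)
  db[ok] <- luminance_to_db(pmin(pmax(th[ok], 1e-12), l_max), l_max)
  locs <- session$config$grid$locations
  structure(
    list(locations = data.frame(index = locs$index, x_deg = locs$x_deg,
                                y_deg = locs$y_deg, db = db),
         l_max = l_max, vector_length = vec$length,
         eye = session$config$eye,
         fixation_control = session$config$fixation$blindspot_location,
         metadata = metadata),
    class = "vf_map"
  )
}

#' @export
print.vf_map <- function(x, ...) {
  cat(sprintf(
    "<vf_map> %s eye, %d locations, l_max %.2f cd/m2 (0-%.2f dB scale)\n",
    x$eye, nrow(x$locations), x$l_max, max(x$locations$db)))
  cat(sprintf("  mean %.2f dB, %d location(s) at 0 dB\n",
              mean(x$locations$db), sum(x$locations$db == 0)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  nrow(a$locations) == nrow(b$locations) &&
    max(abs(a$locations$x_deg - b$locations$x_deg)) < tol &&
    max(abs(a$locations$y_deg - b$locations$y_deg)) < tol
}

#' Aggregate repeated maps: mean, SD, variance, SEM per location
#'
#' All maps must come from the same settings (identical location grids and
#' `l_max`). SD uses the sample (n-1) denominator; `variance = SD^2` and
#' `SEM = SD / sqrt(n)`.
#'
#' @param maps list of `vf_map` objects, length >= 2.
#' @return object of class `vf_aggregate` with a `locations` data frame
#'   (`index`, `x_deg`, `y_deg`, `mean`, `sd`, `variance`, `sem`), `n`,
#'   `l_max`, `eye`.
#' @export
aggregate_maps <- function(maps) {
  if (!is.list(maps) || length(maps) < 2L ||
      !all(vapply(maps, inherits, logical(1), "vf_map"))) {
    stop("aggregation needs a list of at least two vf_map objects")
  }
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!same_grid(ref, m) || abs(ref$l_max - m$l_max) > 1e-9) {
      stop("maps to aggregate must share the same grid and l_max")
    }
  }
  vals <- vapply(maps, function(m) m$locations$db,
                 numeric(nrow(ref$locations)))
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  n <- length(maps)
  structure(
    list(locations = data.frame(
           index = ref$locations$index,
           x_deg = ref$locations$x_deg, y_deg = ref$locations$y_deg,
           mean = mu, sd = sdv, variance = sdv^2, sem = sdv / sqrt(n)),
         n = n, l_max = ref$l_max, eye = ref$eye,
         fixation_control = ref$fixation_control),
    class = "vf_aggregate"
  )
}

#' @export
print.vf_aggregate <- function(x, ...) {
  cat(sprintf("<vf_aggregate> of %d maps, %d locations\n", x$n,
              nrow(x$locations)))
  cat(sprintf("  mean variance %.3f dB^2, mean SEM %.3f dB\n",
              mean(x$locations$variance), mean(x$locations$sem)))
  invisible(x)
}

#' Compare two results by subtraction
#'
#' Per-location `db(a) - db(b)`; positive values mean higher sensitivity in
#' `a`. Refused unless the two maps were produced with the same settings:
#' identical grids, identical `l_max` and identical brightness-vector
#' length.
#'
#' @param map_a,map_b `vf_map` objects.
#' @return a `vf_map` whose `db` column holds the signed difference, with
#'   class `c("vf_difference", "vf_map")`.
#' @export
subtract_maps <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "vf_map"), inherits(map_b, "vf_map"))
  if (!same_grid(map_a, map_b)) {
    stop("incompatible results: location grids differ")
  }
  if (abs(map_a$l_max - map_b$l_max) > 1e-9) {
    stop("incompatible results: maximum stimulus luminances differ")
  }
  if (map_a$vector_length != map_b$vector_length) {
    stop("incompatible results: brightness vector lengths differ")
  }
  out <- map_a
  out$locations$db <- map_a$locations$db - map_b$locations$db
  class(out) <- c("vf_difference", "vf_map")
  out
}

#' Monotone grayscale lookup for dB values
#'
#' Larger dB (better sensitivity) maps to a lighter gray, linearly between
#' the map's limits.
#' @param db dB values.
#' @param db_max top of the scale (defaults to `max(db)`).
#' @return hex colors.
#' @keywords internal
db_grayscale <- function(db, db_max = max(db, 1e-9)) {
  grDevices::gray(pmin(pmax(db / db_max, 0), 1))
}

#' Render a sensitivity, aggregate or difference map
#'
#' Cell-per-location raster (no interpolation by default) with axes
#' crossing at the fixation point, tick marks every 10 degrees, the
#' blind-spot / fixation-control location marked with a white X, and a dB
#' (or dB^2) color bar.
#'
#' @param map a `vf_map`, `vf_difference` or `vf_aggregate`.
#' @param palette `"grayscale"` or `"color"`.
#' @param statistic for aggregates: which per-location statistic to show.
#' @return a ggplot object; write it out with [ggplot2::ggsave()].
#' @export
render_map <- function(map, palette = c("grayscale", "color"),
                       statistic = c("mean", "sd", "variance", "sem")) {
  palette <- match.arg(palette)
  if (inherits(map, "vf_aggregate")) {
    statistic <- match.arg(statistic)
    d <- map$locations
    d$value <- d[[statistic]]
    lab <- if (statistic == "variance") "dB^2" else "dB"
  } else {
    d <- map$locations
    d$value <- d$db
    lab <- "dB"
  }
  ticks <- function(v) {
    r <- range(v)
    seq(10 * floor(r[1] / 10), 10 * ceiling(r[2] / 10), by = 10)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = x_deg, y = y_deg,
                                       fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = 0, color = "grey40", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, color = "grey40", linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = ticks(d$x_deg)) +
    ggplot2::scale_y_continuous(breaks = ticks(d$y_deg)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "degrees", y = "degrees", fill = lab) +
    ggplot2::theme_minimal()
  p <- p + if (palette == "grayscale") {
    ggplot2::scale_fill_gradient(low = "black", high = "white")
  } else {
    ggplot2::scale_fill_viridis_c(option = "inferno")
  }
  fx <- map$fixation_control
  if (!is.null(fx)) {
    p <- p + ggplot2::annotate("point", x = fx[1], y = fx[2], shape = 4,
                               color = "white", size = 4, stroke = 1.2)
  }
  p
}

#' Map CSV input/output
#'
#' `write_map_csv()` writes `x_deg,y_deg,db`; `read_map_csv()` rebuilds a
#' `vf_map` from such a file (plus the stored `l_max`, vector length and
#' eye, which travel in a comment-free header row written by
#' [save_result()]'s `summary.json` instead -- pass them explicitly here).
#'
#' @param map a `vf_map`.
#' @param path CSV path.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "vf_map"))
  utils::write.csv(map$locations[, c("x_deg", "y_deg", "db")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param l_max,vector_length,eye map attributes not stored in the CSV.
#' @export
read_map_csv <- function(path, l_max, vector_length, eye = "left") {
  d <- utils::read.csv(path)
  stopifnot(all(c("x_deg", "y_deg", "db") %in% names(d)))
  structure(
    list(locations = data.frame(index = seq_len(nrow(d)), x_deg = d$x_deg,
                                y_deg = d$y_deg, db = d$db),
         l_max = l_max, vector_length = vector_length, eye = eye,
         fixation_control = NULL, metadata = list()),
    class = "vf_map"
  )
}

#' Export aggregate statistics, one CSV per statistic
#'
#' Writes `mean.csv`, `sd.csv`, `variance.csv`, `sem.csv` into `dir`, each
#' with columns `x_deg,y_deg,value`.
#' @param aggregate a `vf_aggregate`.
#' @param dir output directory (created if missing).
#' @export
write_aggregate_csv <- function(aggregate, dir) {
  stopifnot(inherits(aggregate, "vf_aggregate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (stat in c("mean", "sd", "variance", "sem")) {
    utils::write.csv(
      data.frame(x_deg = aggregate$locations$x_deg,
                 y_deg = aggregate$locations$y_deg,
                 value = aggregate$locations[[stat]]),
      file.path(dir, paste0(stat, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
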