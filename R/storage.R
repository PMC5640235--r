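# Plain-text persistence. Registries (.s files) are append-only text
# databases, one tab-delimited record per line; settings templates (.sset)
# are a sectioned key=value format; each examination's results live in
# their own R_yyyyMMdd_xxxx folder under Results/<patient-id>/.

ID_ALPHABET <- c(letters, LETTERS, 0:9)

#' Generate a registry record identifier
#'
#' Identifiers follow the pattern `X_yyyyMMdd_xxxx` where X is P (patient),
#' S (scale) or R (result) and xxxx is four random characters from
#' lower/upper case letters and digits. Collisions with `existing` ids
#' trigger regeneration.
#'
#' @param prefix `"P"`, `"S"` or `"R"`.
#' @param date a `Date` (defaults to today).
#' @param existing character vector of ids already in the registry.
#' @return a single id string.
#' @examples
#' generate_id("P", as.Date("2017-10-13"))
#' @export
generate_id <- function(prefix = c("P", "S", "R"), date = Sys.Date(),
                        existing = character()) {
  prefix <- match.arg(prefix)
  repeat {
    id <- paste0(prefix, "_", format(date, "%Y%m%d"), "_",
                 paste(sample(ID_ALPHABET, 4L, replace = TRUE),
                       collapse = ""))
    if (!id %in% existing) return(id)
  }
}

escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_field <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "")[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, t = "\t", n = "\n", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1L
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

#' Read a plain-text registry
#'
#' One record per line, fields tab-delimited with backslash escaping.
#'
#' @param path registry file; a missing file reads as an empty registry.
#' @param n_fields expected field count per record; a line with a different
#'   count raises a parse error naming the line number.
#' @return list of character vectors, one per record.
#' @export
read_registry <- function(path, n_fields = NULL) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  records <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; pad to tabs + 1
    n_expected <- lengths(regmatches(
      lines[i], gregexpr("\t", lines[i], fixed = TRUE))) + 1L
    if (length(fields) < n_expected) {
      fields <- c(fields, rep("", n_expected - length(fields)))
    }
    if (!is.null(n_fields) && length(fields) != n_fields) {
      stop(sprintf("parse error in %s line %d: expected %d fields, found %d",
                   path, i, n_fields, length(fields)))
    }
    unescape_field(fields)
  })
  records
}

#' Append a record to a registry
#'
#' Appends are atomic: the new content is written to a temporary file in
#' the same directory and swapped into place, so a crash mid-write never
#' corrupts previously stored lines.
#'
#' @param path registry file; created when missing.
#' @param record character vector of fields.
#' @return the record, invisibly.
#' @export
append_record <- function(path, record) {
  record <- as.character(record)
  if (length(record) == 0L) stop("record must have at least one field")
  line <- paste(escape_field(record), collapse = "\t")
  old <- if (file.exists(path)) readLines(path, warn = FALSE) else character()
  tmp <- tempfile(tmpdir = dirname(normalizePath(path, mustWork = FALSE)))
  writeLines(c(old, line), tmp)
  file.rename(tmp, path)
  invisible(record)
}

#' Patient and scale registry records
#'
#' `patient_record()` builds the 3-field record stored in `patients.s`
#' (id, personal information, additional information). `scale_record()`
#' flattens a fitted [fit_luminance_scale()] into the 11-field record
#' stored in `screenLuminanceScales.s` (id, name, hue, saturation, the six
#' measured luminances at brightness 0..100 in steps of 20, notes);
#' `parse_scale_record()` refits and returns the `luminance_scale`.
#'
#' @param id record id (see [generate_id()]).
#' @param personal_info,additional_info free text.
#' @export
patient_record <- function(id, personal_info = "", additional_info = "") {
  c(id, personal_info, additional_info)
}

#' @rdname patient_record
#' @param scale a `luminance_scale`.
#' @export
scale_record <- function(scale) {
  stopifnot(inherits(scale, "luminance_scale"))
  c(scale$id, scale$name, format(scale$hue), format(scale$saturation),
    sprintf("%.17g", scale$measurements$luminance), scale$notes)
}

#' @rdname patient_record
#' @param record an 11-field character vector as stored in the registry.
#' @export
parse_scale_record <- function(record) {
  if (length(record) != 11L) {
    stop("scale record must have 11 fields, found ", length(record))
  }
  fit_luminance_scale(
    data.frame(brightness_pct = CALIBRATION_LEVELS,
               luminance = as.numeric(record[5:10])),
    name = record[2], hue = as.numeric(record[3]),
    saturation = as.numeric(record[4]), id = record[1], notes = record[11])
}

# ---- settings templates (.sset) ----------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

scale_section <- function(scale) {
  c(paste0("id=", scale$id),
    paste0("name=", scale$name),
    paste0("hue=", fmt_num(scale$hue)),
    paste0("saturation=", fmt_num(scale$saturation)),
    paste0("luminances=",
           paste(fmt_num(scale$measurements$luminance), collapse = ",")),
    paste0("notes=", gsub("\n", " ", scale$notes)))
}

scale_from_section <- function(kv) {
  fit_luminance_scale(
    data.frame(brightness_pct = CALIBRATION_LEVELS,
               luminance = as.numeric(strsplit(kv[["luminances"]], ",")[[1]])),
    name = kv[["name"]], hue = as.numeric(kv[["hue"]]),
    saturation = as.numeric(kv[["saturation"]]), id = kv[["id"]],
    notes = kv[["notes"]])
}

#' Save an examination configuration as a settings template
#'
#' Writes a sectioned `key=value` text file (`.sset`) holding every
#' parameter of the configuration: grid, stimulus, background, luminance
#' scales (as their six calibration measurements, refitted on load),
#' fixation monitoring and procedure. [load_settings()] reproduces the
#' configuration exactly.
#'
#' @param config an [exam_config()].
#' @param path output `.sset` path.
#' @export
save_settings <- function(config, path) {
  stopifnot(inherits(config, "exam_config"))
  g <- config$grid
  fx <- config$fixation
  v <- config$vector
  lines <- c(
    "[grid]",
    paste0("n_x=", g$n_x), paste0("n_y=", g$n_y),
    paste0("spacing_x_deg=", fmt_num(g$spacing_x_deg)),
    paste0("spacing_y_deg=", fmt_num(g$spacing_y_deg)),
    paste0("fixation_x_deg=", fmt_num(g$fixation[1])),
    paste0("fixation_y_deg=", fmt_num(g$fixation[2])),
    paste0("sphericity=", if (g$sphericity) "true" else "false"),
    "[stimulus]",
    paste0("shape=", config$stimulus_shape),
    paste0("width_deg=", fmt_num(config$stimulus_width_deg)),
    paste0("height_deg=", fmt_num(config$stimulus_height_deg)),
    paste0("inclination_deg=", fmt_num(config$stimulus_inclination_deg)),
    paste0("display_time_ms=", fmt_num(config$display_time_ms)),
    paste0("isi_min_ms=", fmt_num(config$isi_min_ms)),
    paste0("isi_max_ms=", fmt_num(config$isi_max_ms)),
    "[stimulus_scale]", scale_section(config$stimulus_scale),
    "[background]",
    paste0("brightness_pct=", config$background_brightness_pct),
    if (!is.null(config$background_scale))
      c("[background_scale]", scale_section(config$background_scale)),
    "[fixation]",
    paste0("technique=", fx$technique),
    paste0("blindspot_x_deg=", fmt_num(fx$blindspot_location[1])),
    paste0("blindspot_y_deg=", fmt_num(fx$blindspot_location[2])),
    paste0("check_frequency_min=", fx$check_frequency[1]),
    paste0("check_frequency_max=", fx$check_frequency[2]),
    paste0("control_brightness_pct=", fx$control_brightness_pct),
    paste0("feedback_enabled=", if (fx$feedback_enabled) "true" else "false"),
    paste0("feedback_text=", fx$feedback_text),
    paste0("feedback_position=", fx$feedback_position),
    paste0("feedback_color=", fx$feedback_color),
    paste0("feedback_font_size=", fmt_num(fx$feedback_font_size)),
    "[procedure]",
    "type=basic",
    paste0("eye=", config$eye),
    paste0("vector_min_pct=", fmt_num(min(v$values))),
    paste0("vector_max_pct=", fmt_num(max(v$values))),
    paste0("vector_length=", v$length),
    paste0("vector_spread=", v$spread)
  )
  writeLines(lines, path)
  invisible(path)
}

parse_sset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(sections[[current]])) sections[[current]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) stop("settings entry outside any section: ", ln)
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      sections[[current]][[key]] <- val
    } else {
      stop("malformed settings line: ", ln)
    }
  }
  sections
}

KNOWN_SSET_KEYS <- list(
  grid = c("n_x", "n_y", "spacing_x_deg", "spacing_y_deg", "fixation_x_deg",
           "fixation_y_deg", "sphericity"),
  stimulus = c("shape", "width_deg", "height_deg", "inclination_deg",
               "display_time_ms", "isi_min_ms", "isi_max_ms"),
  stimulus_scale = c("id", "name", "hue", "saturation", "luminances",
                     "notes"),
  background = "brightness_pct",
  background_scale = c("id", "name", "hue", "saturation", "luminances",
                       "notes"),
  fixation = c("technique", "blindspot_x_deg", "blindspot_y_deg",
               "check_frequency_min", "check_frequency_max",
               "control_brightness_pct", "feedback_enabled", "feedback_text",
               "feedback_position", "feedback_color", "feedback_font_size"),
  procedure = c("type", "eye", "vector_min_pct", "vector_max_pct",
                "vector_length", "vector_spread")
)

#' Load a settings template
#'
#' Reads a `.sset` file written by [save_settings()] and rebuilds the full
#' [exam_config()]; loading sets every parameter. Unknown keys produce a
#' warning; missing required sections are an error.
#'
#' @param path `.sset` file path.
#' @return an `exam_config`.
#' @export
load_settings <- function(path) {
  s <- parse_sset(path)
  required <- c("grid", "stimulus", "stimulus_scale", "fixation", "procedure")
  missing <- setdiff(required, names(s))
  if (length(missing) > 0L) {
    stop("settings file is missing required section(s): ",
         paste(missing, collapse = ", "))
  }
  for (sec in names(s)) {
    unknown <- setdiff(names(s[[sec]]),
                       KNOWN_SSET_KEYS[[sec]] %||% character())
    if (length(unknown) > 0L) {
      warning("ignoring unknown settings key(s) in [", sec, "]: ",
              paste(unknown, collapse = ", "))
    }
  }
  g <- s$grid
  n_x <- as.integer(g[["n_x"]]); n_y <- as.integer(g[["n_y"]])
  sx <- as.numeric(g[["spacing_x_deg"]]); sy <- as.numeric(g[["spacing_y_deg"]])
  grid <- generate_grid(c(n_x * sx, n_y * sy), sx, sy,
                        fixation = c(as.numeric(g[["fixation_x_deg"]]),
                                     as.numeric(g[["fixation_y_deg"]])),
                        sphericity = identical(g[["sphericity"]], "true"))
  st <- s$stimulus
  p <- s$procedure
  fx <- s$fixation
  exam_config(
    grid = grid,
    stimulus_scale = scale_from_section(s$stimulus_scale),
    vector = make_brightness_vector(as.numeric(p[["vector_min_pct"]]),
                                    as.numeric(p[["vector_max_pct"]]),
                                    as.integer(p[["vector_length"]]),
                                    p[["vector_spread"]]),
    fixation = fixation_config(
      technique = fx[["technique"]],
      blindspot_location = c(x_deg = as.numeric(fx[["blindspot_x_deg"]]),
                             y_deg = as.numeric(fx[["blindspot_y_deg"]])),
      check_frequency = c(as.integer(fx[["check_frequency_min"]]),
                          as.integer(fx[["check_frequency_max"]])),
      control_brightness_pct = as.integer(fx[["control_brightness_pct"]]),
      feedback_enabled = identical(fx[["feedback_enabled"]], "true"),
      feedback_text = fx[["feedback_text"]],
      feedback_position = fx[["feedback_position"]],
      feedback_color = fx[["feedback_color"]],
      feedback_font_size = as.numeric(fx[["feedback_font_size"]])),
    background_scale = if ("background_scale" %in% names(s))
      scale_from_section(s$background_scale),
    background_brightness_pct =
      as.integer((s$background %||% list())[["brightness_pct"]] %||% 0L),
    stimulus_shape = st[["shape"]],
    stimulus_width_deg = as.numeric(st[["width_deg"]]),
    stimulus_height_deg = as.numeric(st[["height_deg"]]),
    stimulus_inclination_deg = as.numeric(st[["inclination_deg"]]),
    display_time_ms = as.numeric(st[["display_time_ms"]]),
    isi_min_ms = as.numeric(st[["isi_min_ms"]]),
    isi_max_ms = as.numeric(st[["isi_max_ms"]]),
    eye = p[["eye"]]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- result folders ----------------------------------------------------

#' Save a finished examination into a result folder
#'
#' Creates `Results/<patient-id>/<R-id>/` under `base_dir` holding
#' `session.csv` (presentation log), `map.csv` (dB map), `settings.sset`
#' (the full configuration snapshot), `scale.csv` (the six calibration
#' measurements) and `summary.json` (counters, duration, map attributes) --
#' enough to rebuild the sensitivity map exactly.
#'
#' @param session a finished `exam_session`.
#' @param map its [build_map()] result.
#' @param patient_id the patient's registry id.
#' @param base_dir root directory containing `Results/`.
#' @param result_id optional result id; generated when `NULL`.
#' @param date date used when generating the result id.
#' @return the result folder path, invisibly.
#' @export
save_result <- function(session, map, patient_id, base_dir,
                        result_id = NULL, date = Sys.Date()) {
  stopifnot(inherits(session, "exam_session"), inherits(map, "vf_map"))
  if (isTRUE(session$cancelled)) stop("cancelled session stores no results")
  pdir <- file.path(base_dir, "Results", patient_id)
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(result_id)) {
    result_id <- generate_id("R", date, existing = list.files(pdir))
  }
  rdir <- file.path(pdir, result_id)
  dir.create(rdir, showWarnings = FALSE)
  write_session_csv(session, file.path(rdir, "session.csv"))
  write_map_csv(map, file.path(rdir, "map.csv"))
  save_settings(session$config, file.path(rdir, "settings.sset"))
  sc <- session$config$stimulus_scale
  utils::write.csv(
    data.frame(brightness_pct = sc$measurements$brightness_pct,
               luminance_cd_m2 = sc$measurements$luminance),
    file.path(rdir, "scale.csv"), row.names = FALSE)
  smry <- session_summary(session)
  smry$l_max <- map$l_max
  smry$vector_length <- map$vector_length
  smry$eye <- map$eye
  smry$patient_id <- patient_id
  smry$result_id <- result_id
  jsonlite::write_json(smry, file.path(rdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rdir)
}

#' Load a saved result folder back into a sensitivity map
#'
#' @param rdir a result folder written by [save_result()].
#' @return a `vf_map` rebuilt from `map.csv` + `summary.json`.
#' @export
load_result <- function(rdir) {
  smry <- jsonlite::read_json(file.path(rdir, "summary.json"),
                              simplifyVector = TRUE)
  read_map_csv(file.path(rdir, "map.csv"), l_max = smry$l_max,
               vector_length = smry$vector_length, eye = smry$eye)
}
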