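# Shared fixtures, all built in code.

# Measurements lying exactly on a quadratic L(b) = c0 + c1 b + c2 b^2.
quad_measurements <- function(c0 = 0.5, c1 = 0.1, c2 = 0.01) {
  b <- seq(0, 100, 20)
  data.frame(brightness_pct = b, luminance = c0 + c1 * b + c2 * b^2)
}

exact_scale <- function(...) {
  fit_luminance_scale(quad_measurements(...), name = "exact quadratic",
                      id = "S_20200101_test")
}

# Small grid for fast closed-loop runs: 4 x 2 = 8 locations.
small_grid <- function() generate_grid(c(40, 20), 10, 10)

small_config <- function(grid = small_grid(), scale = exact_scale(),
                         vector = make_brightness_vector(0, 100, 9),
                         technique = "both",
                         check_frequency = c(5L, 10L), ...) {
  exam_config(grid, scale, vector,
              fixation = fixation_config(technique,
                                         check_frequency = check_frequency),
              ...)
}

# Least-squares oracle: normal equations, independent of lm().
ls_quadratic_oracle <- function(b, l) {
  X <- cbind(1, b, b^2)
  as.numeric(solve(t(X) %*% X, t(X) %*% l))
}

# Exhaustive-sweep threshold oracle for a deterministic response function:
# the lowest vector index the observer sees, NA if none. Independent of
# the staircase implementation.
sweep_oracle <- function(len, sees) {
  seen <- which(vapply(seq_len(len), sees, logical(1)))
  if (length(seen) == 0L) NA_integer_ else min(seen)
}
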