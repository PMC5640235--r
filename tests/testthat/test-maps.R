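run_small_exam <- function(observer_fn = observer_uniform, seed = 1, ...) {
  cfg <- small_config()
  obs <- observer_fn(cfg$grid, 30, ...)
  s <- run_exam(cfg, obs, seed = seed)
  list(session = s, map = build_map(s))
}

test_that("no-response and at-maximum locations are 0 dB", {
  sc <- exact_scale()
  vec <- make_brightness_vector(0, 100, 9)
  grid <- small_grid()
  cfg <- small_config(grid = grid, scale = sc, vector = vec)
  l_max <- brightness_to_luminance(sc, 100)
  # half the field blind (never responds), the rest threshold at l_max
  tm <- rep(l_max, nrow(grid$locations))
  tm[grid$locations$x_deg > 0] <- NA
  s <- run_exam(cfg, make_observer(tm), seed = 2)
  map <- build_map(s)
  expect_true(all(map$locations$db == 0))
  expect_equal(map$l_max, l_max)
})

test_that("map dB values reproduce the attenuation of each threshold", {
  out <- run_small_exam(seed = 3)
  th <- out$session$thresholds$luminance_cd_m2
  expect_equal(out$map$locations$db, 10 * log10(out$map$l_max / th))
  expect_true(all(out$map$locations$db >= 0))
})

test_that("a hemianopic noiseless observer maps 0 dB on exactly the blind
           half-field", {
  out <- run_small_exam(observer_hemianopia, seed = 4, blind_side = "right")
  blind <- out$map$locations$x_deg > 0
  expect_true(all(out$map$locations$db[blind] == 0))
  expect_true(all(out$map$locations$db[!blind] > 0))
})

test_that("cancelled sessions refuse to produce a map", {
  out <- run_small_exam(seed = 5)
  s <- out$session
  s$cancelled <- TRUE
  expect_error(build_map(s), "cancelled")
})

test_that("aggregation computes per-location mean, SD, variance and SEM", {
  maps <- lapply(1:3, function(seed) {
    run_small_exam(seed = seed, guess_rate = 0.1)$map
  })
  agg <- aggregate_maps(maps)
  vals <- vapply(maps, function(m) m$locations$db,
                 numeric(nrow(maps[[1]]$locations)))
  expect_equal(agg$locations$mean, rowMeans(vals))
  expect_equal(agg$locations$sd, apply(vals, 1, sd))
  expect_equal(agg$locations$variance, agg$locations$sd^2, tolerance = 1e-12)
  expect_equal(agg$locations$sem, agg$locations$sd / sqrt(3))
})

test_that("a two-point sample aggregates to the textbook values", {
  m1 <- run_small_exam(seed = 6)$map
  m2 <- m1
  m1$locations$db <- rep(1, nrow(m1$locations))
  m2$locations$db <- rep(3, nrow(m2$locations))
  agg <- aggregate_maps(list(m1, m2))
  expect_equal(unique(agg$locations$mean), 2)
  expect_equal(unique(agg$locations$sd), sqrt(2))
  expect_equal(unique(agg$locations$variance), 2)
  expect_equal(unique(agg$locations$sem), 1)
})

test_that("aggregating copies of one map gives that map with zero spread", {
  m <- run_small_exam(seed = 7)$map
  agg <- aggregate_maps(list(m, m, m, m))
  expect_equal(agg$locations$mean, m$locations$db)
  expect_true(all(agg$locations$sd == 0))
})

test_that("aggregation refuses mismatched grids and tiny samples", {
  m <- run_small_exam(seed = 8)$map
  expect_error(aggregate_maps(list(m)), "at least two")
  other <- build_map(run_exam(
    small_config(grid = generate_grid(c(20, 20), 10, 10)),
    observer_uniform(generate_grid(c(20, 20), 10, 10), 30), seed = 1))
  expect_error(aggregate_maps(list(m, other)), "same grid")
})

test_that("subtraction is antisymmetric, zero on self, and guarded", {
  a <- run_small_exam(seed = 9)$map
  b <- run_small_exam(seed = 10, guess_rate = 0.2)$map
  expect_true(all(subtract_maps(a, a)$locations$db == 0))
  expect_equal(subtract_maps(a, b)$locations$db,
               -subtract_maps(b, a)$locations$db)
  # different vector length -> incompatible
  cfg13 <- small_config(vector = make_brightness_vector(0, 100, 13))
  c13 <- build_map(run_exam(cfg13, observer_uniform(cfg13$grid, 30),
                            seed = 1))
  expect_error(subtract_maps(a, c13), "vector lengths")
})

test_that("subtraction commutes with aggregation of means", {
  as <- lapply(1:3, function(s) run_small_exam(seed = s)$map)
  bs <- lapply(4:6, function(s) run_small_exam(seed = s,
                                               guess_rate = 0.1)$map)
  agg_diff <- subtract_maps_mean <- aggregate_maps(as)$locations$mean -
    aggregate_maps(bs)$locations$mean
  diffs <- mapply(function(a, b) subtract_maps(a, b)$locations$db,
                  as, bs)
  expect_equal(rowMeans(diffs), agg_diff)
})

test_that("grayscale palette is monotone: more dB, lighter pixel", {
  cols <- campimetr:::db_grayscale(seq(0, 16, length.out = 20), db_max = 16)
  lum <- colSums(col2rgb(cols))
  expect_true(all(diff(lum) >= 0))
  expect_gt(lum[20], lum[1])
})

test_that("rendering returns a deterministic ggplot for maps and
           aggregates", {
  out <- run_small_exam(seed = 11)
  p1 <- render_map(out$map)
  expect_s3_class(p1, "ggplot")
  p2 <- render_map(out$map)
  expect_identical(p1$data, p2$data)
  agg <- aggregate_maps(lapply(1:2, function(s) run_small_exam(seed = s)$map))
  expect_s3_class(render_map(agg, statistic = "sem"), "ggplot")
  expect_s3_class(render_map(subtract_maps(out$map, out$map),
                             palette = "color"), "ggplot")
})

test_that("map CSV round-trips through the documented columns", {
  m <- run_small_exam(seed = 12)$map
  path <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(m, path)
  d <- read.csv(path)
  expect_named(d, c("x_deg", "y_deg", "db"))
  back <- read_map_csv(path, l_max = m$l_max,
                       vector_length = m$vector_length, eye = m$eye)
  expect_equal(back$locations$db, m$locations$db)
})

test_that("dB re-expression between instrument scales matches the direct
           formula", {
  # a threshold luminance keeps its physical value across scales
  db_a <- luminance_to_db(3.64, 154.46)
  db_b <- convert_db_scale(db_a, 154.46, 318)
  expect_equal(db_to_luminance(db_b, 318), 3.64, tolerance = 1e-9)
  expect_equal(convert_db_scale(0, 154.46, 318),
               10 * log10(318 / 154.46))
})
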