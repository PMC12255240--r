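test_that("a single tile stitches to itself and measures exactly", {
  mu <- make_pseudo_ultrasound(400, 150, seed = 2)
  st <- stitch_tiles(list(mu$image))
  expect_identical(st$panorama, mu$image)
  expect_identical(st$offsets_px, 0L)
  m <- measure_distance(st, list(c(1, 1), c(301, 401 - 300)), 100)
  expect_equal(m$distance_px, sqrt(300^2 + 100^2))
})

test_that("exact-crop tiles are registered to the planted offsets", {
  mu <- make_pseudo_ultrasound(900, 200, seed = 7)
  ts <- generate_tile_set(tile_set_spec(mu$image, 360, c(0, 250, 500),
                                        mu$landmarks, 80))
  st <- stitch_tiles(ts)
  expect_true(all(abs(st$offsets_px - ts$true_offsets_px) <= 1))
  expect_gte(ncol(st$panorama), 360)
})

test_that("stitch-then-measure recovers the planted distance within 1%", {
  mu <- make_pseudo_ultrasound(1200, 220, seed = 9)
  ts <- generate_tile_set(tile_set_spec(mu$image, 512, c(0, 300, 600),
                                        mu$landmarks, 80))
  st <- stitch_tiles(ts)
  expect_gte(ncol(st$panorama), 1112)  # exact-crop geometry
  m <- measure_distance(st, mu$landmarks, 80)
  expect_lt(abs(m$distance_cm - ts$true_distance_cm) / ts$true_distance_cm, 0.01)
})

test_that("uncorrelated tile pairs raise a stitch failure naming the pair", {
  set.seed(1)
  a <- matrix(runif(100 * 100), 100)
  b <- matrix(runif(100 * 100), 100)
  expect_error(stitch_tiles(list(a, b)), "stitch failure between tiles 1 and 2")
})

test_that("measurement scales with the calibration factor and checks bounds", {
  img <- matrix(0.5, 400, 500)
  lm <- list(c(1, 1), c(401, 301))  # 3-4-5 triangle, 500 px
  expect_equal(measure_distance(img, lm, 100)$distance_cm, 5)
  expect_equal(measure_distance(img, lm, 50)$distance_cm, 10)
  expect_equal(measure_distance(img, list(c(5, 5), c(5, 5)), 80)$distance_cm, 0)
  expect_error(measure_distance(img, list(c(0, 1), c(10, 10)), 80), "bounds")
})

test_that("frame extraction subsamples to the requested rate in order", {
  frames <- lapply(1:30, function(i) matrix(i / 30, 4, 4))
  seq10 <- extract_frames(frames, rate_fps = 10, source_fps = 30)
  expect_length(seq10, 10)
  expect_equal(seq10[[2]][1, 1], 4 / 30)  # order preserved
  expect_error(extract_frames(list()), "no frames")
})

test_that("png round trip preserves tile ordering and content", {
  dir <- withr::local_tempdir()
  mu <- make_pseudo_ultrasound(500, 100, seed = 4)
  ts <- generate_tile_set(tile_set_spec(mu$image, 200, c(0, 150, 300),
                                        mu$landmarks, 80))
  write_tiles_png(ts$tiles, dir)
  back <- extract_frames(dir)
  expect_length(back, 3)
  # 8-bit quantisation bounds the round-trip error
  expect_lt(max(abs(back[[1]] - ts$tiles[[1]])), 1 / 255)
})

test_that("midcondylar scaling applies the gender ratio", {
  expect_equal(to_midcondylar(4.5, "female", model), 4.5 * model$condylar_ratio$female)
  expect_equal(to_midcondylar(4.5, "female", model) / 4.5,
               model$condylar_ratio$female)
  expect_error(to_midcondylar(-1, "male", model), "positive")
})

test_that("per-subject aggregation takes the grand mean and flags missing raters", {
  tb <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 6),
    rater = rep(rep(c("r1", "r2"), each = 3), 2),
    distance_cm = c(4.8, 4.9, 5.0, 4.8, 4.9, 5.0, rep(5.2, 6)))
  agg <- aggregate_measurements(tb)
  expect_equal(agg$distance_cm[agg$subject == "s1"], 4.9)
  # one rater missing for one subject: mean of available plus a warning
  tb2 <- tb[-(4:6), ]
  expect_warning(agg2 <- aggregate_measurements(tb2), "missing raters")
  expect_equal(agg2$distance_cm[agg2$subject == "s1"], mean(c(4.8, 4.9, 5.0)))
})
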