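# Gabor stimulus synthesis: luminance equation, contour-path construction,
# field assembly and the CT -> NCT transform.

test_that("gabor luminance follows the carrier-times-envelope equation", {
  p <- gabor_params(contrast = 0.9, spatial_freq = 3, envelope_sd = 0.25,
                    background_luminance = 1, orientation = 0)
  # carrier zero-crossing at the origin
  expect_identical(gabor_luminance(0, 0, p), 1.0)
  # envelope kills the deviation far from the centre
  far <- gabor_luminance(10 * 0.25, 0, p)
  expect_lt(abs(far - 1), 1e-10 * 0.9)
  # theta = 0: pick x so the carrier argument is pi/2; independent evaluation
  # of L = L0 * (1 + C * exp(-x^2 / (2 sigma^2)))
  x <- (pi / 2) / (2 * pi * 3)
  expected <- 1 * (1 + 0.9 * exp(-x^2 / (2 * 0.25^2)))
  expect_equal(gabor_luminance(x, 0, p), expected, tolerance = 1e-12)
  # oriented carrier: argument is k*(x cos + y sin); evaluate directly
  p45 <- gabor_params(orientation = 45)
  xy <- c(0.05, -0.02)
  k <- 2 * pi * 3
  arg <- k * xy[1] * cos(pi / 4) + k * xy[2] * sin(pi / 4)
  manual <- 1 + 0.9 * sin(arg) * exp(-sum(xy^2) / (2 * 0.25^2))
  expect_equal(gabor_luminance(xy[1], xy[2], p45), manual, tolerance = 1e-12)
})

test_that("grid cell size derives from the element separation", {
  spec <- stimulus_spec(condition = "CT", element_separation = 2)
  expect_equal(round(spec$cell_size, 2), 1.66)
  spec3 <- stimulus_spec(condition = "CT", element_separation = 3)
  expect_equal(spec3$cell_size, 2 * 3 / (1 + sqrt(2)), tolerance = 1e-12)
})

test_that("degenerate paths are straight or turn by exactly the path angle", {
  circ_diff <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
  }
  spec0 <- stimulus_spec(condition = "CT", path_angle = 0,
                         orientation_jitter_bound = 0,
                         separation_jitter = 0)
  path0 <- build_contour_path(spec0, seed = 3)
  expect_equal(nrow(path0), 10L)
  expect_true(all(circ_diff(path0$orientation[-1], path0$orientation[-10]) <
                    1e-9))
  spec30 <- stimulus_spec(condition = "CT", path_angle = 30,
                          orientation_jitter_bound = 0)
  path30 <- build_contour_path(spec30, seed = 3)
  d <- circ_diff(path30$orientation[-1], path30$orientation[-10])
  expect_equal(d, rep(30, 9), tolerance = 1e-9)
})

test_that("seeded contour paths satisfy every placement constraint", {
  spec <- stimulus_spec(condition = "CT", path_angle = 25)
  pitch <- spec$cell_size
  half <- 5 * pitch
  n_paths <- 300L
  for (seed in seq_len(n_paths)) {
    p <- build_contour_path(spec, seed = seed)
    # brute-force constraint checker, independent index arithmetic
    col <- floor((p$x + half) / pitch)  # 0-based
    row <- floor((p$y + half) / pitch)
    expect_true(all(col >= 0 & col <= 9 & row >= 0 & row <= 9))
    in22 <- col >= 4 & col <= 5 & row >= 4 & row <= 5
    expect_false(any(in22))
    in66 <- col >= 2 & col <= 7 & row >= 2 & row <= 7
    expect_gte(sum(in66), 4L)
    sep <- sqrt(diff(p$x)^2 + diff(p$y)^2)
    expect_true(all(sep >= 1.45 - 1e-9 & sep <= 2.55 + 1e-9))
  }
})

test_that("assembled stimuli keep 90-100 elements and NCT preserves geometry", {
  spec <- stimulus_spec(condition = "CT", path_angle = 25)
  for (seed in 1:40) {
    f <- generate_stimulus(spec, seed = seed)
    expect_true(nrow(f$elements) >= 90 && nrow(f$elements) <= 100)
    expect_identical(sum(f$elements$on_path), 10L)
    n <- make_noncontour(f, seed = seed)
    expect_identical(n$condition, "NCT")
    expect_identical(n$elements$x, f$elements$x)
    expect_identical(n$elements$y, f$elements$y)
    expect_identical(nrow(n$elements), nrow(f$elements))
    rot <- (n$elements$orientation - f$elements$orientation) %% 180
    expect_true(all(abs(rot[f$elements$on_path] - 45) < 1e-9 |
                      abs(rot[f$elements$on_path] - 135) < 1e-9))
    expect_true(all(rot[!f$elements$on_path] == 0))
  }
})

test_that("stimulus generation is reproducible and rendering is sane", {
  spec <- stimulus_spec(condition = "CT", path_angle = 25)
  f1 <- generate_stimulus(spec, seed = 99)
  f2 <- generate_stimulus(spec, seed = 99)
  expect_identical(f1$elements, f2$elements)
  # render a small patch: luminance stays within the contrast range
  small <- stimulus_spec(condition = "CT", path_angle = 25, raster_ppd = 6)
  fr <- generate_stimulus(small, seed = 2)
  raster <- render_stimulus(fr)
  expect_true(all(is.finite(raster)))
  expect_gt(max(raster), 1)   # carrier swings above background
  expect_lt(min(raster), 1)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(raster, pgm)
  expect_identical(readLines(pgm, n = 1L), "P2")
  js <- withr::local_tempfile(fileext = ".json")
  write_stimulus_json(fr, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$elements), nrow(fr$elements))
})

test_that("path construction failure is signalled, not silent", {
  # an impossible geometry: neighbour separation far below the visible
  # element diameter, so every candidate path violates the overlap rule
  spec <- stimulus_spec(condition = "CT", path_angle = 25,
                        element_separation = 0.3, separation_jitter = 0)
  expect_error(build_contour_path(spec, seed = 1, attempts = 20),
               class = "erm_path_failure")
})
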