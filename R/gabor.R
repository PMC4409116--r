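#' Contour-integration Gabor stimulus synthesis
#'
#' Builds the stimulus fields used in contour-integration experiments: odd
#' Gabor elements on an invisible 10 x 10 grid, with a chain of ten
#' near-collinear elements (the contour path) embedded among randomly
#' oriented distractors for the contour (CT) condition, and an orientation-
#' scrambled twin for the non-contour (NCT) condition.
#'
#' @name gabor_stimuli
NULL

#' Gabor element parameters
#'
#' @param contrast Michelson contrast C (dimensionless, in \[0, 1\]).
#' @param spatial_freq carrier spatial frequency f (cycles/deg).
#' @param envelope_sd Gaussian envelope standard deviation sigma (deg).
#' @param background_luminance L0 (cd/m^2).
#' @param orientation carrier orientation theta from vertical (deg).
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(contrast = 0.9, spatial_freq = 3, envelope_sd = 0.25,
                         background_luminance = 1, orientation = 0) {
  if (contrast < 0 || contrast > 1) stopf("erm_bad_input", "contrast must be in [0,1]")
  if (spatial_freq <= 0) stopf("erm_bad_input", "spatial_freq must be > 0")
  if (envelope_sd <= 0) stopf("erm_bad_input", "envelope_sd must be > 0")
  structure(
    list(contrast = contrast, spatial_freq = spatial_freq,
         envelope_sd = envelope_sd,
         background_luminance = background_luminance,
         orientation = orientation),
    class = "gabor_params"
  )
}

#' Luminance of a Gabor element at a point
#'
#' `L(x, y) = L0 * (1 + s(x, y) * g(x, y))` where the carrier is
#' `s(x, y) = C * sin(k * x * cos(theta) + k * y * sin(theta))` with
#' `k = 2 * pi * f`, and `g` is an isotropic Gaussian envelope with standard
#' deviation `envelope_sd`. The carrier argument is the literal form above
#' (not the conventional rotated-coordinate Gabor); for theta = 0 the two
#' coincide.
#'
#' @param x,y coordinates relative to the element centre (deg of visual
#'   angle); vectorized.
#' @param params a [gabor_params()].
#' @return luminance values (cd/m^2), same length as `x`.
#' @export
#' @examples
#' gabor_luminance(0, 0, gabor_params())  # carrier zero-crossing: L0
gabor_luminance <- function(x, y, params = gabor_params()) {
  stopifnot(inherits(params, "gabor_params"))
  th <- params$orientation * pi / 180
  k <- 2 * pi * params$spatial_freq
  s <- params$contrast * sin(k * x * cos(th) + k * y * sin(th))
  g <- exp(-(x^2 + y^2) / (2 * params$envelope_sd^2))
  params$background_luminance * (1 + s * g)
}

#' Stimulus field specification
#'
#' Geometry and condition of one stimulus: the invisible grid, the contour
#' path angle and its orientation jitter, element separation along the path,
#' positional jitter of distractors, and the raster resolution at which the
#' overlap rule is applied. The grid cell size is derived from the element
#' separation as `2 * s / (1 + sqrt(2))`, which makes the mean distractor
#' spacing match the mean path-element spacing.
#'
#' @param condition `"CT"` (contour) or `"NCT"` (non-contour).
#' @param path_angle path angle alpha between adjacent segments (deg, >= 0).
#' @param orientation_jitter_bound bound of the uniform orientation jitter
#'   added to each turn (deg, default 1).
#' @param element_separation separation between neighbouring path elements
#'   (deg, default 2).
#' @param separation_jitter half-range of the uniform separation jitter
#'   (deg, default 0.55).
#' @param cell_jitter half-range of the distractor positional jitter per axis
#'   (deg, default 0.55).
#' @param grid_rows,grid_cols grid dimensions (default 10 x 10).
#' @param field_extent nominal field size (deg, default 16.6).
#' @param raster_ppd raster resolution (pixels/deg); defaults to the
#'   projector geometry, 800 px across the field.
#' @param gabor a [gabor_params()] describing every element.
#' @param path_elements number of elements on the contour path (default 10).
#' @return object of class `stimulus_spec` (includes derived `cell_size`).
#' @export
stimulus_spec <- function(condition = c("CT", "NCT"), path_angle = 25,
                          orientation_jitter_bound = 1,
                          element_separation = 2, separation_jitter = 0.55,
                          cell_jitter = 0.55, grid_rows = 10L, grid_cols = 10L,
                          field_extent = 16.6,
                          raster_ppd = 800 / 16.6,
                          gabor = gabor_params(), path_elements = 10L) {
  condition <- match.arg(condition)
  if (path_angle < 0) stopf("erm_bad_input", "path_angle must be >= 0")
  if (element_separation <= 0) stopf("erm_bad_input", "element_separation must be > 0")
  cell_size <- 2 * element_separation / (1 + sqrt(2))
  if (grid_rows * grid_cols < 90) {
    stopf("erm_bad_input", "grid too small for the expected element count")
  }
  structure(
    list(condition = condition, path_angle = path_angle,
         orientation_jitter_bound = orientation_jitter_bound,
         element_separation = element_separation,
         separation_jitter = separation_jitter, cell_jitter = cell_jitter,
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         field_extent = field_extent, cell_size = cell_size,
         raster_ppd = raster_ppd, gabor = gabor,
         path_elements = as.integer(path_elements)),
    class = "stimulus_spec"
  )
}

# Grid-cell index (row, col) of a point, or NA when outside the grid.
# Cells are indexed 1..rows/1..cols; the grid is centred on the origin with
# pitch spec$cell_size.
cell_of <- function(x, y, spec) {
  half_w <- spec$grid_cols * spec$cell_size / 2
  half_h <- spec$grid_rows * spec$cell_size / 2
  col <- floor((x + half_w) / spec$cell_size) + 1L
  row <- floor((y + half_h) / spec$cell_size) + 1L
  col[x <= -half_w | x >= half_w] <- NA_integer_
  row[y <= -half_h | y >= half_h] <- NA_integer_
  cbind(row = row, col = col)
}

# TRUE when the cell lies in the centred `inner` x `inner` block.
in_inner_block <- function(cells, spec, inner) {
  lo_r <- (spec$grid_rows - inner) / 2
  lo_c <- (spec$grid_cols - inner) / 2
  cells[, "row"] > lo_r & cells[, "row"] <= lo_r + inner &
    cells[, "col"] > lo_c & cells[, "col"] <= lo_c + inner
}

#' Construct the invisible contour path
#'
#' Builds a chain of `path_elements` segment centres with neighbour
#' separation `element_separation` plus uniform jitter, turning at each joint
#' by `+/-(path_angle + jitter)` with a random turn direction. The chain must
#' satisfy the placement constraints: every centre inside the grid, none in
#' the inner 2 x 2 cells (so the path avoids fixation), at least four centres
#' in the inner 6 x 6 cells (bounded eccentricity), and all centres in
#' distinct grid cells. Construction is retried with fresh randomness up to
#' `attempts` times before failing.
#'
#' @param spec a [stimulus_spec()] with `condition = "CT"`.
#' @param seed integer seed fixing the construction.
#' @param attempts number of whole-path attempts before giving up.
#' @return data.frame with one row per path element: `x`, `y` (deg),
#'   `orientation` (deg, mod 180), `on_path = TRUE`.
#' @export
build_contour_path <- function(spec, seed = 1L, attempts = 500L) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$condition != "CT") {
    stopf("erm_bad_input", "contour paths are only built for condition CT")
  }
  local_seed(derive_seed(seed, 1L), build_contour_path_impl(spec, attempts))
}

build_contour_path_impl <- function(spec, attempts) {
  m <- spec$path_elements
  half <- spec$grid_cols * spec$cell_size / 2
  for (a in seq_len(attempts)) {
    x <- y <- numeric(m)
    x[1L] <- stats::runif(1, -half, half)
    y[1L] <- stats::runif(1, -half, half)
    heading <- stats::runif(1, 0, 360)
    dir <- numeric(m)
    dir[1L] <- heading
    for (i in 2:m) {
      turn <- sample(c(-1, 1), 1L) *
        (spec$path_angle + stats::runif(1, -spec$orientation_jitter_bound,
                                        spec$orientation_jitter_bound))
      heading <- heading + turn
      dir[i] <- heading
      step <- spec$element_separation +
        stats::runif(1, -spec$separation_jitter, spec$separation_jitter)
      x[i] <- x[i - 1L] + step * cos(heading * pi / 180)
      y[i] <- y[i - 1L] + step * sin(heading * pi / 180)
    }
    cells <- cell_of(x, y, spec)
    if (anyNA(cells)) next
    if (any(in_inner_block(cells, spec, 2L))) next
    if (sum(in_inner_block(cells, spec, 6L)) < 4L) next
    if (anyDuplicated(paste(cells[, 1L], cells[, 2L]))) next
    # reject rare curled paths whose non-adjacent elements would violate the
    # visible-part overlap rule
    if (min(stats::dist(cbind(x, y))) < 2 * visible_radius(spec)) next
    return(data.frame(x = x, y = y, orientation = dir %% 180, on_path = TRUE))
  }
  stopf("erm_path_failure",
        "no valid contour path found in %d attempts", attempts)
}

# Radius (deg) of the visible part of one element: where the Gaussian
# envelope exceeds exp(-2) of its peak, i.e. 2 * sigma.
visible_radius <- function(spec) 2 * spec$gabor$envelope_sd

# Number of raster pixels shared by two visible discs of radius r_px whose
# centres are d_px apart (integer lattice count, matching the raster rule).
disc_overlap_pixels <- function(d_px, r_px) {
  if (d_px >= 2 * r_px) return(0L)
  r_ceil <- ceiling(r_px)
  gx <- seq(-r_ceil, r_ceil + ceiling(d_px))
  gy <- seq(-r_ceil, r_ceil)
  px <- expand.grid(x = gx, y = gy)
  in1 <- px$x^2 + px$y^2 <= r_px^2
  in2 <- (px$x - d_px)^2 + px$y^2 <= r_px^2
  sum(in1 & in2)
}

# Centre distance (deg) below which two elements' visible parts overlap by
# more than `max_px` raster pixels. Monotone in distance, so found once by
# bisection and cached per (radius, resolution).
overlap_threshold_deg <- function(spec, max_px = 5L) {
  r_px <- visible_radius(spec) * spec$raster_ppd
  lo <- 0
  hi <- 2 * r_px
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (disc_overlap_pixels(mid, r_px) > max_px) lo <- mid else hi <- mid
  }
  hi / spec$raster_ppd
}

#' Assemble a full contour stimulus field
#'
#' Places the path elements, then fills every grid cell not holding a path
#' element with a randomly oriented distractor at the cell centre jittered by
#' `+/- cell_jitter` per axis. A new element is skipped when its visible part
#' would overlap an already placed element by more than 5 raster pixels; the
#' whole stimulus is withdrawn (an error of class `erm_stimulus_withdrawn`)
#' when more than 10 elements cannot be drawn. Valid fields therefore contain
#' 90-100 elements.
#'
#' @param path a path from [build_contour_path()].
#' @param spec a [stimulus_spec()] with `condition = "CT"`.
#' @param seed integer seed fixing distractor placement.
#' @return object of class `gabor_field`: `elements` (data.frame `x`, `y`,
#'   `orientation`, `on_path`), `condition`, `spec`, `n_skipped`.
#' @export
assemble_stimulus <- function(path, spec, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"), is.data.frame(path))
  if (spec$condition != "CT") {
    stopf("erm_bad_input", "assemble_stimulus builds CT fields; derive NCT with make_noncontour()")
  }
  local_seed(derive_seed(seed, 2L), assemble_stimulus_impl(path, spec))
}

assemble_stimulus_impl <- function(path, spec) {
  thr <- overlap_threshold_deg(spec)
  pitch <- spec$cell_size
  half_w <- spec$grid_cols * pitch / 2
  half_h <- spec$grid_rows * pitch / 2
  path_cells <- cell_of(path$x, path$y, spec)
  occupied <- paste(path_cells[, 1L], path_cells[, 2L])

  ex <- path$x
  ey <- path$y
  eo <- path$orientation
  ep <- rep(TRUE, nrow(path))
  n_skipped <- 0L
  for (row in seq_len(spec$grid_rows)) {
    for (col in seq_len(spec$grid_cols)) {
      if (paste(row, col) %in% occupied) next
      cx <- -half_w + (col - 0.5) * pitch +
        stats::runif(1, -spec$cell_jitter, spec$cell_jitter)
      cy <- -half_h + (row - 0.5) * pitch +
        stats::runif(1, -spec$cell_jitter, spec$cell_jitter)
      ori <- stats::runif(1, 0, 180)
      # overlap rule against everything already drawn
      if (length(ex) && min(sqrt((ex - cx)^2 + (ey - cy)^2)) < thr) {
        n_skipped <- n_skipped + 1L
        if (n_skipped > 10L) {
          stopf("erm_stimulus_withdrawn",
                "stimulus withdrawn: more than 10 elements could not be drawn")
        }
        next
      }
      ex <- c(ex, cx)
      ey <- c(ey, cy)
      eo <- c(eo, ori)
      ep <- c(ep, FALSE)
    }
  }
  structure(
    list(elements = data.frame(x = ex, y = ey, orientation = eo, on_path = ep),
         condition = "CT", spec = spec, n_skipped = n_skipped),
    class = "gabor_field"
  )
}

#' @export
print.gabor_field <- function(x, ...) {
  cat(sprintf("<gabor_field> %s, %d elements (%d on path, %d skipped)\n",
              x$condition, nrow(x$elements), sum(x$elements$on_path),
              x$n_skipped))
  invisible(x)
}

#' Derive the non-contour twin of a contour field
#'
#' Keeps every element position and the element count, and rotates the path
#' elements by alternating +45 / -45 degrees (random starting sign), which
#' destroys the collinear chain while preserving spacing and density.
#'
#' @param field a CT [assemble_stimulus()] result.
#' @param seed integer seed fixing the starting sign.
#' @return a `gabor_field` with `condition = "NCT"`.
#' @export
make_noncontour <- function(field, seed = 1L) {
  stopifnot(inherits(field, "gabor_field"))
  if (field$condition != "CT") {
    stopf("erm_bad_input", "make_noncontour expects a CT field")
  }
  out <- field
  idx <- which(field$elements$on_path)
  s0 <- local_seed(derive_seed(seed, 3L), sample(c(-1, 1), 1L))
  signs <- s0 * (-1)^(seq_along(idx) - 1L)
  out$elements$orientation[idx] <-
    (field$elements$orientation[idx] + 45 * signs) %% 180
  out$condition <- "NCT"
  out
}

#' Generate a stimulus, retrying withdrawn fields
#'
#' Builds a contour path and assembles the field, drawing fresh randomness
#' whenever the withdrawal rule fires, up to `max_retries` complete attempts.
#' For `condition = "NCT"` the CT field is built first and then scrambled
#' with [make_noncontour()].
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed; every retry derives a fresh substream from it.
#' @param max_retries complete stimulus attempts (default 50).
#' @return a `gabor_field`.
#' @export
generate_stimulus <- function(spec, seed = 1L, max_retries = 50L) {
  ct_spec <- spec
  ct_spec$condition <- "CT"
  for (r in seq_len(max_retries)) {
    sub <- derive_seed(seed, 17L, r)
    field <- tryCatch({
      path <- build_contour_path(ct_spec, seed = sub)
      assemble_stimulus(path, ct_spec, seed = sub)
    },
    erm_stimulus_withdrawn = function(e) NULL,
    erm_path_failure = function(e) NULL)
    if (!is.null(field)) {
      if (spec$condition == "NCT") field <- make_noncontour(field, seed = sub)
      return(field)
    }
  }
  stopf("erm_stimulus_withdrawn",
        "no acceptable stimulus in %d attempts", max_retries)
}

#' Render a stimulus field to a luminance raster
#'
#' Evaluates the summed Gabor luminance deviations of all elements on a pixel
#' grid at the spec's raster resolution. Deviations superpose additively on
#' the background.
#'
#' @param field a `gabor_field`.
#' @param ppd pixels/deg (defaults to the spec's raster resolution).
#' @return numeric matrix of luminance (rows = y, increasing upwards).
#' @export
render_stimulus <- function(field, ppd = field$spec$raster_ppd) {
  spec <- field$spec
  half <- spec$grid_cols * spec$cell_size / 2
  px <- seq(-half, half, by = 1 / ppd)
  raster <- matrix(0, nrow = length(px), ncol = length(px))
  g <- spec$gabor
  r_vis <- 3 * g$envelope_sd  # beyond 3 sigma the deviation is negligible
  for (i in seq_len(nrow(field$elements))) {
    el <- field$elements[i, ]
    xi <- which(abs(px - el$x) <= r_vis)
    yi <- which(abs(px - el$y) <= r_vis)
    if (!length(xi) || !length(yi)) next
    gp <- gabor_params(g$contrast, g$spatial_freq, g$envelope_sd,
                       g$background_luminance, el$orientation)
    loc <- outer(px[yi] - el$y, px[xi] - el$x,
                 function(yy, xx) gabor_luminance(xx, yy, gp))
    raster[yi, xi] <- raster[yi, xi] + (loc - g$background_luminance)
  }
  raster + g$background_luminance
}

#' Write a luminance raster as a plain-text PGM image
#'
#' @param raster numeric matrix from [render_stimulus()].
#' @param path output file path.
#' @param max_val grey levels (default 255).
#' @export
write_pgm <- function(raster, path, max_val = 255L) {
  lo <- min(raster)
  hi <- max(raster)
  scaled <- if (hi > lo) round((raster - lo) / (hi - lo) * max_val) else
    matrix(0L, nrow(raster), ncol(raster))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(raster), nrow(raster)),
               as.character(max_val)), con)
  # write top row first (raster rows increase upwards)
  apply(scaled[rev(seq_len(nrow(scaled))), , drop = FALSE], 1L,
        function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Write a stimulus element list as JSON
#'
#' @param field a `gabor_field`.
#' @param path output file path.
#' @export
write_stimulus_json <- function(field, path) {
  jsonlite::write_json(
    list(format_version = 1L, condition = field$condition,
         cell_size_deg = field$spec$cell_size,
         elements = field$elements),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
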