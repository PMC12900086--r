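# Evaluate an expression with a locally seeded RNG, leaving the caller's
# random state untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Default palettes. Vegetation colours keep the discriminant index >= 140
# and backgrounds <= 128, leaving a margin either side of the 134
# classification boundary so generator truth and classifier output always
# coincide; boundary behaviour is exercised separately with hand-built
# pixels.
default_vegetation_palette <- function() {
  list(c(40L, 150L, 30L),   # dark leaf green
       c(60L, 190L, 50L),   # bright leaf green
       c(35L, 120L, 45L),   # shaded green
       c(80L, 200L, 90L))   # sunlit green
}

default_background_palette <- function() {
  list(c(120L, 120L, 120L), # gray (index exactly 128)
       c(140L, 115L, 95L),  # dry soil
       c(100L, 85L, 70L),   # wet soil
       c(90L, 80L, 140L))   # standing water
}

#' Specification of a synthetic canopy scene
#'
#' Describes a renderable test scene: image size, the exact vegetation
#' fraction to realize, a hill grid (default 4 x 4, the usual 16-hill
#' framing of a nadir canopy photograph), and colour palettes. Palettes
#' are validated at construction: every vegetation colour must have
#' discriminant index >= 140 and every background colour <= 128, so that
#' segmentation at the operational threshold of 134 recovers the
#' constructed mask exactly.
#'
#' @param width,height Image size in pixels.
#' @param target_fraction Vegetation fraction in \[0, 1\]; realized as an
#'   exact pixel count `round(target_fraction * width * height)`.
#' @param grid_rows,grid_cols Hill grid dimensions; default 4 x 4.
#' @param vegetation_palette,background_palette Lists of RGB triplets
#'   (integers in \[0, 255\]).
#' @param seed RNG seed controlling colour choice and hill shapes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, target_fraction,
                       grid_rows = 4L, grid_cols = 4L,
                       vegetation_palette = default_vegetation_palette(),
                       background_palette = default_background_palette(),
                       seed = 1L) {
  if (!is.numeric(width) || !is.numeric(height) ||
      width < 1 || height < 1 ||
      width != round(width) || height != round(height)) {
    stop("width and height must be positive whole numbers", call. = FALSE)
  }
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      is.na(target_fraction) || target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (grid_rows < 1 || grid_cols < 1) {
    stop("hill grid must have at least one cell", call. = FALSE)
  }
  check_palette <- function(pal, what, lo, hi) {
    for (col in pal) {
      if (length(col) != 3L || any(col < 0) || any(col > 255)) {
        stop(what, " palette entries must be RGB triplets in [0, 255]",
             call. = FALSE)
      }
      idx <- discriminant_index(col[1], col[2])
      if (idx < lo || idx > hi) {
        stop(what, " colour (", paste(col, collapse = ","),
             ") has discriminant index ", format(idx),
             ", outside the required [", lo, ", ", hi, "] band",
             call. = FALSE)
      }
    }
  }
  if (length(vegetation_palette) < 1L || length(background_palette) < 1L) {
    stop("palettes must be non-empty", call. = FALSE)
  }
  check_palette(vegetation_palette, "vegetation", 140, 256)
  check_palette(background_palette, "background", 0, 128)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         target_fraction = target_fraction,
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         vegetation_palette = vegetation_palette,
         background_palette = background_palette,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Render a synthetic canopy image with exactly known vegetation fraction
#'
#' Draws exactly `round(target_fraction * width * height)` vegetation
#' pixels, clustered into `grid_rows x grid_cols` roughly circular blobs
#' ("hills") centred on a regular grid with small random jitter; all
#' remaining pixels take background colours. Because the palettes keep a
#' margin around the classification boundary, [segment_canopy()] on the
#' rendered image reproduces the returned ground-truth mask pixel for
#' pixel, and the pipeline cover equals `100 * round(f * N) / N`.
#'
#' Placement ranks every pixel by distance to its nearest hill centre and
#' takes the closest `k`, so blobs stay disjoint at low fractions and
#' merge gracefully as the fraction approaches 1; the exact pixel count is
#' preserved in all cases. Deterministic for a fixed spec (including
#' seed).
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` ([rgb_image()]), `mask` (logical
#'   ground-truth matrix) and `true_fraction` (the realized fraction,
#'   `vegetation pixels / total pixels`).
#' @examples
#' sc <- render_canopy(scene_spec(20, 20, 0.5, seed = 7))
#' cover_ratio(segment_canopy(sc$image))$cover_percent  # exactly 50
#' @export
render_canopy <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  n <- w * h
  k <- round(spec$target_fraction * n)
  with_local_seed(spec$seed, {
    mask <- matrix(FALSE, nrow = h, ncol = w)
    if (k > 0) {
      # hill centres: regular grid plus jitter, one blob per cell
      cells <- spec$grid_rows * spec$grid_cols
      cx <- (rep(seq_len(spec$grid_cols), times = spec$grid_rows) - 0.5) *
        w / spec$grid_cols
      cy <- (rep(seq_len(spec$grid_rows), each = spec$grid_cols) - 0.5) *
        h / spec$grid_rows
      cx <- cx + stats::runif(cells, -0.08, 0.08) * w / spec$grid_cols
      cy <- cy + stats::runif(cells, -0.08, 0.08) * h / spec$grid_rows
      # rank every pixel by distance to its nearest hill centre and take
      # the k closest: yields disjoint blobs that merge gracefully as the
      # fraction grows, with the count exact by construction
      px <- rep(seq_len(w), each = h)
      py <- rep(seq_len(h), times = w)
      d2min <- rep(Inf, n)
      for (i in seq_len(cells)) {
        d2 <- (px - 0.5 - cx[i])^2 + (py - 0.5 - cy[i])^2
        d2min <- pmin(d2min, d2)
      }
      chosen <- order(d2min, stats::runif(n))[seq_len(k)]
      mask[cbind(py[chosen], px[chosen])] <- TRUE
    }
    pix <- array(0L, dim = c(h, w, 3L))
    veg_idx <- which(mask)
    bg_idx <- which(!mask)
    vp <- spec$vegetation_palette
    bp <- spec$background_palette
    vpick <- sample.int(length(vp), length(veg_idx), replace = TRUE)
    bpick <- sample.int(length(bp), length(bg_idx), replace = TRUE)
    for (ch in 1:3) {
      plane <- matrix(0L, nrow = h, ncol = w)
      plane[veg_idx] <- vapply(vp, `[[`, integer(1), ch)[vpick]
      plane[bg_idx] <- vapply(bp, `[[`, integer(1), ch)[bpick]
      pix[, , ch] <- plane
    }
    list(image = rgb_image(pix), mask = mask, true_fraction = k / n)
  })
}

#' Specification of a synthetic calibration dataset
#'
#' @param true_model The generating [quadratic_model()].
#' @param cover_min,cover_max Cover range in percent, `cover_min < cover_max`,
#'   both in \[0, 100\].
#' @param n_points Number of calibration points (>= 3).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   tiller values, in tillers m^-2 (>= 0).
#' @param seed RNG seed.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(true_model, cover_min, cover_max,
                             n_points, noise_sd, seed = 1L) {
  stopifnot(inherits(true_model, "quadratic_model"))
  if (!is.numeric(cover_min) || !is.numeric(cover_max) ||
      cover_min >= cover_max || cover_min < 0 || cover_max > 100) {
    stop("need cover_min < cover_max within [0, 100]", call. = FALSE)
  }
  if (!is.numeric(n_points) || n_points < 3) {
    stop("n_points must be at least 3", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  structure(
    list(true_model = true_model, cover_min = cover_min,
         cover_max = cover_max, n_points = as.integer(n_points),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "calibration_spec"
  )
}

#' Simulate a calibration dataset from a known quadratic
#'
#' Covers are evenly spaced on \[`cover_min`, `cover_max`\]; tiller values
#' are the true quadratic plus i.i.d. Gaussian noise. Deterministic for a
#' fixed spec. With `noise_sd = 0` and >= 3 distinct covers,
#' [fit_model()] recovers the generating coefficients to numerical
#' precision.
#'
#' @param spec A [calibration_spec()].
#' @return Data frame with columns `cover_percent` and `tillers_per_m2`.
#' @export
simulate_calibration <- function(spec) {
  stopifnot(inherits(spec, "calibration_spec"))
  cov <- seq(spec$cover_min, spec$cover_max, length.out = spec$n_points)
  m <- spec$true_model
  truth <- m$a * cov^2 + m$b * cov + m$c
  noise <- with_local_seed(spec$seed, stats::rnorm(spec$n_points, 0, spec$noise_sd))
  data.frame(cover_percent = cov, tillers_per_m2 = truth + noise)
}

#' Specification of a linear tillering growth series
#'
#' @param initial_tillers Tiller density at day 0 (tillers m^-2).
#' @param daily_rate Tiller increase rate in tillers m^-2 day^-1 (> 0);
#'   reported rates around mid-season drainage are roughly 12.0-24.3.
#' @param days Number of days in the series (>= 1).
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(initial_tillers, daily_rate, days) {
  if (!is.numeric(daily_rate) || daily_rate <= 0) {
    stop("daily_rate must be positive", call. = FALSE)
  }
  if (!is.numeric(days) || days < 1 || days != round(days)) {
    stop("days must be a positive whole number", call. = FALSE)
  }
  structure(
    list(initial_tillers = initial_tillers, daily_rate = daily_rate,
         days = as.integer(days)),
    class = "growth_spec"
  )
}

#' Simulate a daily tiller growth series
#'
#' Linear growth: `initial + rate * day` for days `0 .. days - 1`. Used to
#' check the days-of-growth interpretation of estimation error: biasing
#' the series by a constant offset shifts the day it crosses a cultivar
#' target by `offset / rate` days.
#'
#' @param spec A [growth_spec()].
#' @return Data frame with columns `day` (0-based) and `tillers_per_m2`.
#' @export
simulate_growth <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  day <- seq_len(spec$days) - 1L
  data.frame(day = day,
             tillers_per_m2 = spec$initial_tillers + spec$daily_rate * day)
}

#' First day a growth series reaches a target tiller number
#'
#' @param series Data frame from [simulate_growth()].
#' @param target Target tiller density.
#' @return The first `day` with `tillers_per_m2 >= target`, or `NA` if
#'   never reached within the series.
#' @export
crossing_day <- function(series, target) {
  hit <- which(series$tillers_per_m2 >= target)
  if (length(hit) == 0L) return(NA_integer_)
  series$day[hit[1L]]
}
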