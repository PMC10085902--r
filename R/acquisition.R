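# Field-of-view acquisition geometry: transectial and scatter plans on the
# membrane disc, with exact square-in-disc area clipping for rim fields.

# antiderivative of sqrt(R^2 - x^2); x must satisfy |x| <= R
.chord_int <- function(x, R) {
  x <- pmin(pmax(x, -R), R)
  0.5 * (x * sqrt(pmax(R^2 - x^2, 0)) + R^2 * asin(x / R))
}

# Exact area of the intersection of the axis-aligned square
# [x0,x1] x [y0,y1] with the disc of radius R centred at the origin.
# Piecewise-analytic: the vertical section length
#   g(x) = max(0, min(y1, +c(x)) - max(y0, -c(x))),  c(x) = sqrt(R^2 - x^2),
# changes functional form only where c(x) crosses |y0| or |y1|; integrating
# each piece in closed form gives machine-precision areas.
square_disc_area <- function(x0, x1, y0, y1, R) {
  a <- max(x0, -R)
  b <- min(x1, R)
  if (a >= b) return(0)
  cuts <- c(a, b)
  for (y in c(y0, y1)) {
    if (abs(y) < R) {
      xc <- sqrt(R^2 - y^2)
      cuts <- c(cuts, -xc, xc)
    }
  }
  cuts <- sort(unique(pmin(pmax(cuts, a), b)))
  area <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    if (hi - lo <= 0) next
    xm <- (lo + hi) / 2
    cm <- sqrt(max(R^2 - xm^2, 0))
    up_flat <- y1 <= cm    # upper bound is the square edge on this piece
    lo_flat <- y0 >= -cm   # lower bound is the square edge
    up_mid <- if (up_flat) y1 else cm
    lo_mid <- if (lo_flat) y0 else -cm
    if (up_mid <= lo_mid) next
    piece <- 0
    piece <- piece + if (up_flat) y1 * (hi - lo) else .chord_int(hi, R) - .chord_int(lo, R)
    piece <- piece - if (lo_flat) y0 * (hi - lo) else -(.chord_int(hi, R) - .chord_int(lo, R))
    area <- area + piece
  }
  area
}

#' Area of a field of view clipped to the membrane disc
#'
#' Fields at the membrane rim extend beyond the disc; extrapolation must use
#' the area actually on the membrane. The square-disc intersection is
#' evaluated in closed form (piecewise-analytic chord integration), accurate
#' to machine precision.
#'
#' @param field A one-row data frame (or list) with `x_mm`, `y_mm` and
#'   `width_mm`, as found in the `fields` table of an acquisition plan.
#' @param spec The [membrane_spec()] defining the disc.
#' @return The clipped area in mm^2 (0 when the field misses the disc).
#' @examples
#' spec <- membrane_spec()
#' clipped_area(list(x_mm = 0, y_mm = 0, width_mm = 0.25), spec)  # 0.0625
#' @export
clipped_area <- function(field, spec) {
  if (!is_membrane_spec(spec)) stop("`spec` must be a membrane_spec", call. = FALSE)
  w <- field$width_mm
  if (w > spec$diameter_mm) stop("field width exceeds the membrane diameter", call. = FALSE)
  square_disc_area(field$x_mm - w / 2, field$x_mm + w / 2,
                   field$y_mm - w / 2, field$y_mm + w / 2,
                   spec$radius_mm)
}

new_acquisition_plan <- function(strategy, level, centers, spec) {
  w <- spec$field_width_mm
  n <- nrow(centers)
  areas <- vapply(seq_len(n), function(i) {
    square_disc_area(centers[i, 1L] - w / 2, centers[i, 1L] + w / 2,
                     centers[i, 2L] - w / 2, centers[i, 2L] + w / 2,
                     spec$radius_mm)
  }, numeric(1))
  fields <- data.frame(
    index = seq_len(n),
    x_mm = centers[, 1L],
    y_mm = centers[, 2L],
    width_mm = w,
    clipped_area_mm2 = areas
  )
  structure(
    list(strategy = strategy, level = level, n_images = n,
         fields = fields, spec = spec),
    class = "acquisition_plan"
  )
}

# centers of a full transect along one diameter: fields_per_diameter
# contiguous squares; `vertical` swaps the axis
transect_centers <- function(spec, vertical = FALSE) {
  w <- spec$field_width_mm
  pos <- -spec$radius_mm + w * (seq_len(spec$fields_per_diameter) - 0.5)
  if (vertical) cbind(rep(0, length(pos)), pos) else cbind(pos, rep(0, length(pos)))
}

#' Transectial acquisition plan
#'
#' Builds the contiguous field-of-view sequence along the membrane diameter:
#' quarter, half and full transects take the central 10, 20 and 40 fields of
#' one diameter (for the default 40-field spec); the double transect adds the
#' full perpendicular diameter for 80 images in total. The two central
#' squares of the perpendicular run overlap the first run geometrically; both
#' acquisitions are kept, as the double-transect image count is defined by
#' the number of images taken, and the extrapolation uses their counts and
#' areas twice alike.
#'
#' @param spec A [membrane_spec()].
#' @param level One of `"quarter"`, `"half"`, `"full"`, `"double"`.
#' @return An `acquisition_plan` with `strategy`, `level`, `n_images` and a
#'   `fields` data frame (`index`, `x_mm`, `y_mm`, `width_mm`,
#'   `clipped_area_mm2`).
#' @examples
#' make_transect_plan(membrane_spec(), "quarter")$n_images  # 10
#' @export
make_transect_plan <- function(spec, level = c("quarter", "half", "full", "double")) {
  if (!is_membrane_spec(spec)) stop("`spec` must be a membrane_spec", call. = FALSE)
  level <- match.arg(level)
  full <- transect_centers(spec)
  n <- nrow(full)
  centers <- switch(level,
    quarter = {
      k <- n / 4
      full[(n / 2 - k / 2 + 1):(n / 2 + k / 2), , drop = FALSE]
    },
    half = {
      k <- n / 2
      full[(n / 2 - k / 2 + 1):(n / 2 + k / 2), , drop = FALSE]
    },
    full = full,
    double = rbind(full, transect_centers(spec, vertical = TRUE))
  )
  new_acquisition_plan("transect", level, centers, spec)
}

# Vogel / sunflower lattice: n approximately equidistant points on a disc of
# radius rmax, deterministic, in increasing radius order
sunflower_points <- function(n, rmax) {
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- rmax * sqrt((k - 0.5) / n)
  theta <- k * golden
  cbind(r * cos(theta), r * sin(theta))
}

scatter_ladder <- c(eighth = 8L, quarter = 16L, half = 32L, full = 69L)

#' Scatter acquisition plan
#'
#' Places fields of view at deterministic, approximately equidistant
#' coordinates spread over the whole membrane, the alternative to scanning
#' along a diameter. The ladder is eighth (8 images), quarter (16), half (32)
#' and full (69). A sunflower (Fibonacci/Vogel) lattice is used, scaled so
#' every centre stays at least one field width inside the rim: it is the
#' standard reproducible construction for uniform coverage of a disc.
#' `n_images` overrides the ladder for budget-matched comparisons (e.g. 10
#' scattered images against a 10-image quarter transect).
#'
#' @param spec A [membrane_spec()].
#' @param level One of `"eighth"`, `"quarter"`, `"half"`, `"full"`. Ignored
#'   when `n_images` is given.
#' @param n_images Optional explicit image count (level becomes `"custom"`).
#' @return An `acquisition_plan`; see [make_transect_plan()].
#' @examples
#' make_scatter_plan(membrane_spec(), "full")$n_images  # 69
#' @export
make_scatter_plan <- function(spec, level = c("eighth", "quarter", "half", "full"),
                              n_images = NULL) {
  if (!is_membrane_spec(spec)) stop("`spec` must be a membrane_spec", call. = FALSE)
  if (is.null(n_images)) {
    level <- match.arg(level)
    n_images <- scatter_ladder[[level]]
  } else {
    n_images <- as.integer(n_images)
    if (is.na(n_images) || n_images < 1L) stop("`n_images` must be a positive integer", call. = FALSE)
    level <- "custom"
  }
  rmax <- spec$radius_mm - spec$field_width_mm
  new_acquisition_plan("scatter", level, sunflower_points(n_images, rmax), spec)
}

#' Full-coverage reference plan
#'
#' Tiles the membrane bounding square with contiguous fields and keeps every
#' field that intersects the disc. The clipped areas of the kept fields
#' partition the disc exactly, so extrapolation from this plan returns the
#' true total count: it serves as the exhaustive-coverage reference that
#' manual SEM imaging avoids (well over a thousand images on the default
#' spec).
#'
#' @param spec A [membrane_spec()].
#' @return An `acquisition_plan` with strategy `"grid"`, level `"coverage"`.
#' @export
make_grid_plan <- function(spec) {
  if (!is_membrane_spec(spec)) stop("`spec` must be a membrane_spec", call. = FALSE)
  w <- spec$field_width_mm
  pos <- -spec$radius_mm + w * (seq_len(spec$fields_per_diameter) - 0.5)
  centers <- as.matrix(expand.grid(x = pos, y = pos))
  keep <- vapply(seq_len(nrow(centers)), function(i) {
    square_disc_area(centers[i, 1L] - w / 2, centers[i, 1L] + w / 2,
                     centers[i, 2L] - w / 2, centers[i, 2L] + w / 2,
                     spec$radius_mm) > 0
  }, logical(1))
  new_acquisition_plan("grid", "coverage", centers[keep, , drop = FALSE], spec)
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("Acquisition plan: %s / %s, %d images (sampled area %.3f of disc)\n",
              x$strategy, x$level, x$n_images,
              sum(x$fields$clipped_area_mm2) / x$spec$area_mm2))
  invisible(x)
}

#' @export
as.data.frame.acquisition_plan <- function(x, ...) x$fields

#' @export
plot.acquisition_plan <- function(x, border = "steelblue", ...) {
  R <- x$spec$radius_mm
  plot(NA, asp = 1, xlim = c(-R, R), ylim = c(-R, R),
       xlab = "x (mm)", ylab = "y (mm)",
       main = sprintf("%s / %s (%d images)", x$strategy, x$level, x$n_images), ...)
  theta <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(R * cos(theta), R * sin(theta))
  w <- x$spec$field_width_mm
  graphics::rect(x$fields$x_mm - w / 2, x$fields$y_mm - w / 2,
                 x$fields$x_mm + w / 2, x$fields$y_mm + w / 2, border = border)
  invisible(x)
}
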