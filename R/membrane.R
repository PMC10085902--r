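# Synthetic diatom deposition on a circular filtration membrane.

#' Membrane filter geometry
#'
#' Describes the circular PVDF filtration membrane onto which digested
#' samples are filtered, together with the tiling implied by the SEM field
#' of view. The field width is fixed by the convention that a full transect
#' across one diameter comprises `fields_per_diameter` contiguous images, so
#' the default 10 mm membrane scanned as 40 images per diameter gives
#' 0.25 mm square fields (one image at 1000x magnification).
#'
#' @param diameter_mm Membrane diameter in mm. Default 10 (a 1.0 cm filter).
#' @param fields_per_diameter Number of contiguous fields spanning one
#'   diameter. Default 40.
#'
#' @return An object of class `membrane_spec` with elements `diameter_mm`,
#'   `fields_per_diameter`, `field_width_mm` (derived), `radius_mm` and
#'   `area_mm2`.
#' @examples
#' spec <- membrane_spec()
#' spec$field_width_mm   # 0.25 mm
#' @export
membrane_spec <- function(diameter_mm = 10, fields_per_diameter = 40L) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be a single positive number", call. = FALSE)
  }
  fields_per_diameter <- as.integer(fields_per_diameter)
  if (is.na(fields_per_diameter) || fields_per_diameter < 2L) {
    stop("`fields_per_diameter` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(
      diameter_mm = diameter_mm,
      fields_per_diameter = fields_per_diameter,
      field_width_mm = diameter_mm / fields_per_diameter,
      radius_mm = diameter_mm / 2,
      area_mm2 = pi * (diameter_mm / 2)^2
    ),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "Membrane: diameter %.3g mm (area %.4g mm^2), %d fields/diameter (field width %.4g mm)\n",
    x$diameter_mm, x$area_mm2, x$fields_per_diameter, x$field_width_mm
  ))
  invisible(x)
}

is_membrane_spec <- function(x) inherits(x, "membrane_spec")

# uniform points on a disc of radius R, centred at the origin
runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(x_mm = r * cos(theta), y_mm = r * sin(theta))
}

#' Simulate diatom deposition on a membrane
#'
#' Generates a spatial point pattern of diatom positions on the membrane
#' disc. Two deposition regimes are available: `"homogeneous"` is a uniform
#' Poisson process (complete spatial randomness, the idealised case of a
#' perfectly mixed filtrate), and `"clustered"` is a Neyman-Scott process
#' emulating diatoms deposited in clusters or layers, as observed on real
#' membranes where a regular distribution is not granted. Cluster parents
#' follow a homogeneous Poisson process on the disc dilated by
#' `4 * cluster_sd_mm` (so clusters seated just outside the rim still shed
#' points onto it); each parent receives a Poisson number of offspring
#' displaced by an isotropic Gaussian, and offspring falling outside the
#' disc are discarded, keeping the recorded total exact.
#'
#' @param spec A [membrane_spec()].
#' @param process `"homogeneous"` or `"clustered"`.
#' @param intensity Expected points per mm^2 (homogeneous process only).
#' @param cluster_rate Expected cluster parents per mm^2 (clustered only).
#' @param cluster_size_mean Mean offspring count per cluster (clustered only).
#' @param cluster_sd_mm Isotropic Gaussian dispersion of offspring around
#'   their parent, in mm (clustered only).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   pattern exactly. The caller's RNG state is left untouched.
#'
#' @return An object of class `point_pattern`: a list with `coordinates`
#'   (two-column matrix, mm from the membrane centre), `true_total`, `spec`
#'   and `generator_params`.
#' @examples
#' pat <- simulate_membrane(membrane_spec(), "homogeneous",
#'                          intensity = 5, seed = 1)
#' pat$true_total
#' @export
simulate_membrane <- function(spec, process = c("homogeneous", "clustered"),
                              intensity = NULL, cluster_rate = NULL,
                              cluster_size_mean = NULL, cluster_sd_mm = NULL,
                              seed) {
  if (!is_membrane_spec(spec)) stop("`spec` must be a membrane_spec", call. = FALSE)
  process <- match.arg(process)
  if (missing(seed)) stop("`seed` is required: all randomness is explicit", call. = FALSE)
  R <- spec$radius_mm

  coords <- withr::with_seed(seed, {
    if (process == "homogeneous") {
      if (is.null(intensity) || !is.finite(intensity) || intensity < 0) {
        stop("homogeneous process needs `intensity` >= 0 (points per mm^2)", call. = FALSE)
      }
      n <- stats::rpois(1L, intensity * spec$area_mm2)
      runif_disc(n, R)
    } else {
      if (is.null(cluster_rate) || cluster_rate <= 0 ||
          is.null(cluster_size_mean) || cluster_size_mean <= 0 ||
          is.null(cluster_sd_mm) || cluster_sd_mm <= 0) {
        stop(paste("clustered process needs positive `cluster_rate`,",
                   "`cluster_size_mean` and `cluster_sd_mm`"), call. = FALSE)
      }
      # dilate the parent window so rim clusters are not under-represented
      Rp <- R + 4 * cluster_sd_mm
      n_parents <- stats::rpois(1L, cluster_rate * pi * Rp^2)
      if (n_parents == 0L) {
        matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x_mm", "y_mm")))
      } else {
        parents <- runif_disc(n_parents, Rp)
        sizes <- stats::rpois(n_parents, cluster_size_mean)
        m <- sum(sizes)
        off <- cbind(
          x_mm = rep(parents[, 1L], sizes) + stats::rnorm(m, 0, cluster_sd_mm),
          y_mm = rep(parents[, 2L], sizes) + stats::rnorm(m, 0, cluster_sd_mm)
        )
        off[off[, 1L]^2 + off[, 2L]^2 <= R^2, , drop = FALSE]
      }
    }
  })

  structure(
    list(
      coordinates = coords,
      true_total = nrow(coords),
      spec = spec,
      generator_params = list(
        process = process, intensity = intensity,
        cluster_rate = cluster_rate, cluster_size_mean = cluster_size_mean,
        cluster_sd_mm = cluster_sd_mm, seed = seed
      )
    ),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d diatoms on a %.3g mm membrane (%s process, seed %s)\n",
              x$true_total, x$spec$diameter_mm,
              x$generator_params$process, x$generator_params$seed))
  invisible(x)
}

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  as.data.frame(x$coordinates)
}

#' @export
plot.point_pattern <- function(x, pch = 16, cex = 0.4, ...) {
  R <- x$spec$radius_mm
  plot(x$coordinates, asp = 1, xlim = c(-R, R), ylim = c(-R, R),
       pch = pch, cex = cex, xlab = "x (mm)", ylab = "y (mm)", ...)
  theta <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(R * cos(theta), R * sin(theta))
  invisible(x)
}

#' Simulate a forensic case with known true concentrations
#'
#' Draws replicate aliquot counts for a synthetic drowning case. Each tissue
#' sample of mass m grams yields a Poisson(m * true_lung_conc) diatom count;
#' each medium aliquot of v ml yields Poisson(v * true_medium_conc). This
#' mirrors the structure of real case data (tissue weight / count triples and
#' per-ml medium counts) with a controllable true L/D ratio, so the
#' downstream classification pipeline can be validated against ground truth.
#'
#' @param true_lung_conc True diatoms per gram of lung tissue (>= 0).
#' @param true_medium_conc True diatoms per ml of drowning medium (>= 0).
#' @param tissue_masses Vector of tissue sample masses in g (all > 0).
#' @param medium_volumes Vector of medium aliquot volumes in ml (all > 0).
#' @param seed Integer seed.
#'
#' @return An object of class `synthetic_case`: `tissue_samples` and
#'   `medium_samples` data frames (size, observed_count), the true
#'   concentrations, and `true_ld = true_lung_conc / true_medium_conc`
#'   (`NA` when the medium concentration is zero).
#' @examples
#' sc <- simulate_case(200, 100, tissue_masses = c(0.5, 1, 1.5),
#'                     medium_volumes = 10, seed = 7)
#' sc$true_ld   # 2
#' @export
simulate_case <- function(true_lung_conc, true_medium_conc,
                          tissue_masses, medium_volumes, seed) {
  if (true_lung_conc < 0 || true_medium_conc < 0) {
    stop("true concentrations must be >= 0", call. = FALSE)
  }
  if (length(tissue_masses) == 0L || length(medium_volumes) == 0L) {
    stop("`tissue_masses` and `medium_volumes` must be non-empty", call. = FALSE)
  }
  if (any(tissue_masses <= 0) || any(medium_volumes <= 0)) {
    stop("all masses and volumes must be positive", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  counts <- withr::with_seed(seed, {
    list(
      tissue = stats::rpois(length(tissue_masses), tissue_masses * true_lung_conc),
      medium = stats::rpois(length(medium_volumes), medium_volumes * true_medium_conc)
    )
  })

  structure(
    list(
      true_lung_conc = true_lung_conc,
      true_medium_conc = true_medium_conc,
      true_ld = if (true_medium_conc > 0) true_lung_conc / true_medium_conc else NA_real_,
      tissue_samples = data.frame(mass_g = as.numeric(tissue_masses),
                                  observed_count = counts$tissue),
      medium_samples = data.frame(volume_ml = as.numeric(medium_volumes),
                                  observed_count = counts$medium),
      seed = seed
    ),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "Synthetic case: true L/D %s (%g per g lung / %g per ml medium); %d tissue, %d medium samples\n",
    format(x$true_ld, digits = 3), x$true_lung_conc, x$true_medium_conc,
    nrow(x$tissue_samples), nrow(x$medium_samples)
  ))
  invisible(x)
}
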