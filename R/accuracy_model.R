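# Logarithmic accuracy-vs-image-count model and minimum-image solver.

#' Logarithmic accuracy curve
#'
#' Container for the model `accuracy = a * ln(n_images) + b`, the form used
#' to summarise how extrapolation accuracy grows with the number of images
#' acquired. Construct directly from known coefficients (e.g. a previously
#' reported regression) or fit from data with [fit_log_curve()].
#'
#' @param a Slope on the natural log of the image count (percentage points
#'   per ln-image).
#' @param b Intercept: predicted accuracy (%) at one image.
#' @param strategy Optional label (e.g. `"transect"`, `"scatter"`).
#' @param fit_points Optional data frame (`n_images`, `accuracy_pct`) the
#'   coefficients were fitted on.
#' @param se Optional named numeric vector of coefficient standard errors.
#' @return An object of class `accuracy_curve`.
#' @examples
#' curve <- accuracy_curve(6.5832, 66.32, strategy = "transect")
#' images_needed(curve, 95)  # 78
#' @export
accuracy_curve <- function(a, b, strategy = NA_character_,
                           fit_points = NULL, se = NULL) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b)) {
    stop("`a` and `b` must be single finite numbers", call. = FALSE)
  }
  structure(list(a = a, b = b, strategy = strategy,
                 fit_points = fit_points, se = se),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("Accuracy curve%s: accuracy = %.4f * ln(images) + %.2f\n",
              if (is.na(x$strategy)) "" else paste0(" (", x$strategy, ")"),
              x$a, x$b))
  invisible(x)
}

#' Fit the logarithmic accuracy model
#'
#' Ordinary least squares of accuracy on the natural log of the image count.
#' Unweighted: every (n_images, accuracy) point counts equally, whether it is
#' a per-replicate measurement or a per-level aggregate.
#'
#' @param points Data frame with columns `n_images` (>= 1) and
#'   `accuracy_pct`, or two numeric vectors given as `n_images` and
#'   `accuracy_pct` columns. At least two distinct image counts are required.
#'   Accuracies above 100 are fitted as-is; clamping is a reporting concern.
#' @param strategy Optional label stored on the curve.
#' @return An `accuracy_curve` with slope `a`, intercept `b`, coefficient
#'   standard errors in `$se`, and the fitted points in `$fit_points`.
#' @examples
#' pts <- data.frame(n_images = c(10, 20, 40, 80),
#'                   accuracy_pct = c(79.8, 87.1, 92.2, 95.6))
#' fit_log_curve(pts, strategy = "transect")
#' @export
fit_log_curve <- function(points, strategy = NA_character_) {
  if (!is.data.frame(points) || !all(c("n_images", "accuracy_pct") %in% names(points))) {
    stop("`points` must be a data frame with columns n_images and accuracy_pct", call. = FALSE)
  }
  if (any(points$n_images < 1)) stop("all n_images must be >= 1", call. = FALSE)
  if (length(unique(points$n_images)) < 2L) {
    stop("need at least two distinct n_images values to fit", call. = FALSE)
  }
  fit <- stats::lm(accuracy_pct ~ log(n_images), data = points)
  cf <- stats::coef(fit)
  ses <- sqrt(diag(suppressWarnings(stats::vcov(fit))))  # exact fits warn in summary.lm
  accuracy_curve(
    a = unname(cf[["log(n_images)"]]),
    b = unname(cf[["(Intercept)"]]),
    strategy = strategy,
    fit_points = points[, c("n_images", "accuracy_pct")],
    se = c(a = unname(ses[["log(n_images)"]]), b = unname(ses[["(Intercept)"]]))
  )
}

#' Predicted accuracy at a given image count
#'
#' @param curve An [accuracy_curve()].
#' @param n_images Image count(s), all >= 1.
#' @return Predicted accuracy percentage `a * ln(n_images) + b` (not
#'   clamped).
#' @export
predict_accuracy <- function(curve, n_images) {
  if (!inherits(curve, "accuracy_curve")) stop("`curve` must be an accuracy_curve", call. = FALSE)
  if (any(n_images < 1)) stop("`n_images` must be >= 1", call. = FALSE)
  curve$a * log(n_images) + curve$b
}

#' Minimum number of images to reach a target accuracy
#'
#' Solves `a * ln(n) + b >= target` for the smallest whole number of images,
#' i.e. the ceiling of `exp((target - b) / a)`, with an explicit integer
#' check to guard the ceiling against floating-point grazing. A target at or
#' below the intercept is met by a single image. For a flat or decreasing
#' curve a target above the intercept is unreachable and raises an error.
#'
#' @param curve An [accuracy_curve()].
#' @param target_pct Target accuracy percentage (default 95, the
#'   representative-quantification benchmark).
#' @return The smallest integer `n` with `predict_accuracy(curve, n) >=
#'   target_pct`.
#' @examples
#' images_needed(accuracy_curve(6.5832, 66.32), 95)  # 78 transect images
#' images_needed(accuracy_curve(4.3587, 77.99), 95)  # 50 scatter images
#' @export
images_needed <- function(curve, target_pct = 95) {
  if (!inherits(curve, "accuracy_curve")) stop("`curve` must be an accuracy_curve", call. = FALSE)
  if (target_pct <= curve$b) return(1L)
  if (curve$a <= 0) {
    stop(sprintf("target %.4g%% is unreachable: curve is non-increasing (a = %.4g)",
                 target_pct, curve$a), call. = FALSE)
  }
  n <- as.integer(ceiling(exp((target_pct - curve$b) / curve$a)))
  while (n > 1L && predict_accuracy(curve, n - 1L) >= target_pct) n <- n - 1L
  while (predict_accuracy(curve, n) < target_pct) n <- n + 1L
  n
}
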