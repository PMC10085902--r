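# Per-field diatom counting, whole-membrane extrapolation and accuracy
# scoring -- the computational core of the acquisition-strategy comparison.

#' Count pattern points falling in each field of view
#'
#' Simulated stand-in for manual per-image diatom counting. Field membership
#' is half-open (`[lo, hi)` on both axes) so a point sitting exactly on the
#' shared edge of two contiguous transect fields is counted once. Fields of a
#' double transect overlap near the centre; a point there is counted in both
#' runs, matching how the two acquisitions would each image it.
#'
#' @param pattern A `point_pattern` from [simulate_membrane()].
#' @param plan An `acquisition_plan` built on the same membrane spec.
#' @return A `field_counts` object: list with `counts` (integer vector
#'   aligned with `plan$fields`), `plan` and `spec`.
#' @export
count_fields <- function(pattern, plan) {
  if (!inherits(pattern, "point_pattern")) stop("`pattern` must be a point_pattern", call. = FALSE)
  if (!inherits(plan, "acquisition_plan")) stop("`plan` must be an acquisition_plan", call. = FALSE)
  if (!isTRUE(all.equal(pattern$spec$diameter_mm, plan$spec$diameter_mm)) ||
      !isTRUE(all.equal(pattern$spec$field_width_mm, plan$spec$field_width_mm))) {
    stop("pattern and plan were built on different membrane specs", call. = FALSE)
  }
  x <- pattern$coordinates[, 1L]
  y <- pattern$coordinates[, 2L]
  f <- plan$fields
  h <- f$width_mm / 2
  counts <- vapply(seq_len(nrow(f)), function(i) {
    sum(x >= f$x_mm[i] - h[i] & x < f$x_mm[i] + h[i] &
        y >= f$y_mm[i] - h[i] & y < f$y_mm[i] + h[i])
  }, integer(1))
  new_field_counts(counts, plan)
}

new_field_counts <- function(counts, plan) {
  counts <- as.integer(counts)
  if (length(counts) != plan$n_images) {
    stop(sprintf("expected %d counts (one per field), got %d",
                 plan$n_images, length(counts)), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be non-negative integers", call. = FALSE)
  structure(list(counts = counts, plan = plan, spec = plan$spec),
            class = "field_counts")
}

#' Attach manual per-image counts to a plan
#'
#' Wraps externally obtained counts (e.g. manual SEM counts read with
#' [read_counts_csv()]) in the container [extrapolate_total()] expects,
#' validating length and sign against the plan.
#'
#' @param counts Non-negative integer vector, one entry per plan field, in
#'   field-index order.
#' @param plan The `acquisition_plan` the images were taken under.
#' @return A `field_counts` object.
#' @export
field_counts <- function(counts, plan) {
  if (!inherits(plan, "acquisition_plan")) stop("`plan` must be an acquisition_plan", call. = FALSE)
  new_field_counts(counts, plan)
}

#' @export
print.field_counts <- function(x, ...) {
  cat(sprintf("Field counts: %d fields (%s/%s), total %d diatoms\n",
              length(x$counts), x$plan$strategy, x$plan$level, sum(x$counts)))
  invisible(x)
}

#' Extrapolate the whole-membrane diatom count
#'
#' Compiles per-field counts to a total number of diatoms per filter by
#' area-proportional scaling: the sampled density (sum of counts over the sum
#' of on-disc field areas) times the full membrane area. Rim fields
#' contribute their clipped areas, so rim-heavy plans are not biased
#' downward; overlapping double-transect fields contribute both their counts
#' and their areas. The estimator is exact under full coverage and unbiased
#' under complete spatial randomness.
#'
#' @param counts A `field_counts` object (or a bare numeric vector when
#'   `plan` is supplied).
#' @param plan Optional `acquisition_plan`; defaults to the one stored in
#'   `counts`.
#' @param reference Optional reference total (true count, or a combined
#'   high-coverage estimate) against which to score accuracy.
#' @return An `abundance_estimate`: `estimated_total`, `sampled_area_mm2`,
#'   `membrane_area_mm2`, `sampling_fraction`, and `accuracy_pct` when a
#'   reference was given.
#' @examples
#' spec <- membrane_spec()
#' pat <- simulate_membrane(spec, "homogeneous", intensity = 20, seed = 1)
#' est <- extrapolate_total(count_fields(pat, make_scatter_plan(spec, "full")),
#'                          reference = pat$true_total)
#' est$accuracy_pct
#' @export
extrapolate_total <- function(counts, plan = NULL, reference = NULL) {
  if (inherits(counts, "field_counts")) {
    if (is.null(plan)) plan <- counts$plan
    counts <- counts$counts
  }
  if (!inherits(plan, "acquisition_plan")) stop("an acquisition_plan is required", call. = FALSE)
  if (length(counts) != plan$n_images) stop("counts do not match the plan", call. = FALSE)
  sampled <- sum(plan$fields$clipped_area_mm2)
  if (sampled <= 0) stop("plan samples zero membrane area; cannot extrapolate", call. = FALSE)
  total_area <- plan$spec$area_mm2
  est <- sum(counts) / sampled * total_area
  structure(
    list(
      estimated_total = est,
      sampled_area_mm2 = sampled,
      membrane_area_mm2 = total_area,
      sampling_fraction = sampled / total_area,
      reference = reference,
      accuracy_pct = if (!is.null(reference)) accuracy_pct(est, reference) else NA_real_
    ),
    class = "abundance_estimate"
  )
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance estimate: %.1f diatoms (sampled %.1f%% of membrane)%s\n",
              x$estimated_total, 100 * x$sampling_fraction,
              if (!is.na(x$accuracy_pct)) sprintf(", accuracy %.1f%%", x$accuracy_pct) else ""))
  invisible(x)
}

#' Extrapolation accuracy against a reference total
#'
#' Accuracy is one hundred times one minus the relative absolute deviation
#' from the reference, floored at zero: 100% means perfect agreement, and an
#' estimate off by more than the reference itself scores 0 rather than going
#' negative (keeping the downstream logarithmic regression well-behaved).
#' The metric is scale-invariant.
#'
#' @param estimate Estimated total count.
#' @param reference Reference total count (> 0).
#' @return Accuracy percentage in `[0, 100]`.
#' @examples
#' accuracy_pct(110, 100)  # 90
#' @export
accuracy_pct <- function(estimate, reference) {
  if (any(reference <= 0)) stop("`reference` must be positive", call. = FALSE)
  pmax(0, 100 * (1 - abs(estimate - reference) / reference))
}

default_plan_ladder <- function(spec) {
  plans <- c(
    lapply(c("quarter", "half", "full", "double"),
           function(l) make_transect_plan(spec, l)),
    lapply(c("eighth", "quarter", "half", "full"),
           function(l) make_scatter_plan(spec, l))
  )
  names(plans) <- vapply(plans, function(p) paste(p$strategy, p$level, sep = "_"), "")
  plans
}

#' Monte-Carlo comparison of acquisition strategies
#'
#' Simulates `n_replicates` membranes, applies every plan to each, scores the
#' extrapolated total against the pattern's true count, and aggregates. This
#' is the in-silico analogue of evaluating transectial versus scatter imaging
#' on diluted water samples: it reproduces the design of that comparison, not
#' its empirical numbers (which depend on the particular membranes imaged).
#'
#' @param spec A [membrane_spec()].
#' @param plans Named list of `acquisition_plan`s; defaults to the standard
#'   transect (quarter/half/full/double) and scatter (eighth/quarter/half/
#'   full) ladders.
#' @param process,intensity,cluster_rate,cluster_size_mean,cluster_sd_mm
#'   Deposition model passed to [simulate_membrane()].
#' @param n_replicates Number of simulated membranes (>= 1).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return A data frame with one row per plan: `strategy`, `level`,
#'   `n_images`, `mean_accuracy_pct`, `se_accuracy_pct`,
#'   `mean_abs_rel_error_pct`, `se_abs_rel_error_pct`, `n_replicates`.
#' @export
run_strategy_experiment <- function(spec, plans = default_plan_ladder(spec),
                                    process = "homogeneous",
                                    intensity = NULL, cluster_rate = NULL,
                                    cluster_size_mean = NULL, cluster_sd_mm = NULL,
                                    n_replicates = 100L, seed) {
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_replicates))

  acc <- matrix(NA_real_, n_replicates, length(plans))
  err <- matrix(NA_real_, n_replicates, length(plans))
  for (r in seq_len(n_replicates)) {
    pat <- simulate_membrane(spec, process, intensity = intensity,
                             cluster_rate = cluster_rate,
                             cluster_size_mean = cluster_size_mean,
                             cluster_sd_mm = cluster_sd_mm, seed = rep_seeds[r])
    if (pat$true_total == 0L) next  # no reference total to score against
    for (j in seq_along(plans)) {
      est <- extrapolate_total(count_fields(pat, plans[[j]]))
      rel <- abs(est$estimated_total - pat$true_total) / pat$true_total
      err[r, j] <- 100 * rel
      acc[r, j] <- max(0, 100 * (1 - rel))
    }
  }

  ok <- stats::complete.cases(acc)
  acc <- acc[ok, , drop = FALSE]
  err <- err[ok, , drop = FALSE]
  n_used <- nrow(acc)
  se <- function(m) apply(m, 2L, stats::sd) / sqrt(n_used)
  data.frame(
    strategy = vapply(plans, `[[`, "", "strategy"),
    level = vapply(plans, `[[`, "", "level"),
    n_images = vapply(plans, `[[`, 0L, "n_images"),
    mean_accuracy_pct = colMeans(acc),
    se_accuracy_pct = se(acc),
    mean_abs_rel_error_pct = colMeans(err),
    se_abs_rel_error_pct = se(err),
    n_replicates = n_used,
    row.names = NULL
  )
}
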