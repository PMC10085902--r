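# Shared fixtures and independent oracles used across the suite.

test_spec <- membrane_spec()  # the standard 10 mm / 40-field membrane

# Monte-Carlo rejection oracle for the square-in-disc clipped area:
# independent of the analytic geometry in the package.
mc_clipped_area <- function(cx, cy, w, R, n = 2e6, seed = 1) {
  withr::with_seed(seed, {
    x <- runif(n, cx - w / 2, cx + w / 2)
    y <- runif(n, cy - w / 2, cy + w / 2)
    w^2 * mean(x^2 + y^2 <= R^2)
  })
}

# Brute-force point-in-rectangle membership oracle (per point, per field),
# mirroring count_fields' half-open convention but via an explicit loop.
brute_force_counts <- function(pattern, plan) {
  f <- plan$fields
  out <- integer(nrow(f))
  for (i in seq_len(nrow(f))) {
    h <- f$width_mm[i] / 2
    for (k in seq_len(nrow(pattern$coordinates))) {
      px <- pattern$coordinates[k, 1L]
      py <- pattern$coordinates[k, 2L]
      if (px >= f$x_mm[i] - h && px < f$x_mm[i] + h &&
          py >= f$y_mm[i] - h && py < f$y_mm[i] + h) {
        out[i] <- out[i] + 1L
      }
    }
  }
  out
}

# Closed-form OLS of y on ln(x) via the normal equations, independent of lm.
ols_log_oracle <- function(n_images, y) {
  lx <- log(n_images)
  a <- sum((lx - mean(lx)) * (y - mean(y))) / sum((lx - mean(lx))^2)
  c(a = a, b = mean(y) - a * mean(lx))
}

# Pooled L/D estimate from a synthetic case.
case_ld_estimate <- function(sc) {
  lpg <- sum(sc$tissue_samples$observed_count) / sum(sc$tissue_samples$mass_g)
  mpm <- sum(sc$medium_samples$observed_count) / sum(sc$medium_samples$volume_ml)
  if (mpm <= 0) return(NA_real_)
  lpg / mpm
}
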