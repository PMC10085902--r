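test_that("membrane spec derives field width and rejects bad geometry", {
  spec <- membrane_spec(10, 40)
  expect_equal(spec$field_width_mm, 0.25)
  expect_equal(spec$field_width_mm * spec$fields_per_diameter, spec$diameter_mm)
  expect_equal(spec$area_mm2, pi * 25)
  expect_error(membrane_spec(-1), "positive")
  expect_error(membrane_spec(10, 1), ">= 2")
})

test_that("zero-intensity process yields an empty pattern", {
  pat <- simulate_membrane(test_spec, "homogeneous", intensity = 0, seed = 1)
  expect_equal(pat$true_total, 0L)
  expect_equal(nrow(pat$coordinates), 0L)
})

test_that("all simulated points stay on the disc, for both processes", {
  for (s in 1:50) {
    hom <- simulate_membrane(test_spec, "homogeneous", intensity = 3, seed = s)
    clu <- simulate_membrane(test_spec, "clustered", cluster_rate = 0.1,
                             cluster_size_mean = 20, cluster_sd_mm = 0.5, seed = s)
    for (pat in list(hom, clu)) {
      if (pat$true_total > 0) {
        expect_lte(max(sqrt(rowSums(pat$coordinates^2))), test_spec$radius_mm)
      }
      expect_equal(pat$true_total, nrow(pat$coordinates))
    }
  }
})

test_that("homogeneous counts are Poisson-calibrated to intensity * area", {
  n_rep <- 1000
  lambda <- 10 * test_spec$area_mm2  # approx 785.4
  totals <- vapply(seq_len(n_rep), function(s) {
    simulate_membrane(test_spec, "homogeneous", intensity = 10, seed = s)$true_total
  }, 0L)
  se <- sqrt(lambda / n_rep)
  expect_lt(abs(mean(totals) - lambda), 3 * se)
  # Poisson: variance equals the mean; chi-square band on the sample variance
  expect_lt(abs(var(totals) / lambda - 1), 3 * sqrt(2 / (n_rep - 1)))
})

test_that("identical parameters and seed reproduce patterns byte-identically", {
  a <- simulate_membrane(test_spec, "clustered", cluster_rate = 0.2,
                         cluster_size_mean = 30, cluster_sd_mm = 0.3, seed = 99)
  b <- simulate_membrane(test_spec, "clustered", cluster_rate = 0.2,
                         cluster_size_mean = 30, cluster_sd_mm = 0.3, seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  d <- simulate_membrane(test_spec, "clustered", cluster_rate = 0.2,
                         cluster_size_mean = 30, cluster_sd_mm = 0.3, seed = 100)
  expect_false(identical(a$coordinates, d$coordinates))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_membrane(test_spec, "homogeneous", intensity = 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(simulate_membrane(test_spec, "homogeneous", intensity = -1, seed = 1), "intensity")
  expect_error(simulate_membrane(test_spec, "clustered", cluster_rate = 0,
                                 cluster_size_mean = 10, cluster_sd_mm = 0.3, seed = 1))
  expect_error(simulate_membrane(test_spec, "homogeneous", intensity = 1), "seed")
})

test_that("synthetic cases draw Poisson counts at mass- and volume-scaled means", {
  zero <- simulate_case(0, 100, tissue_masses = c(0.5, 1), medium_volumes = 10, seed = 1)
  expect_true(all(zero$tissue_samples$observed_count == 0L))

  sc <- simulate_case(200, 100, tissue_masses = c(0.5, 1, 1.5), medium_volumes = 10, seed = 2)
  expect_equal(sc$true_ld, 2)

  n_rep <- 2000
  masses <- c(0.5, 1.0, 1.5)
  draws <- vapply(seq_len(n_rep), function(s) {
    simulate_case(100, 50, masses, 10, seed = s)$tissue_samples$observed_count
  }, integer(3))
  mu <- 100 * masses
  se <- sqrt(mu / n_rep)
  expect_true(all(abs(rowMeans(draws) - mu) < 3 * se))
})

test_that("synthetic case inputs are validated", {
  expect_error(simulate_case(-1, 1, 1, 1, seed = 1), ">= 0")
  expect_error(simulate_case(1, 1, numeric(0), 1, seed = 1), "non-empty")
  expect_error(simulate_case(1, 1, c(1, 0), 1, seed = 1), "positive")
})
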