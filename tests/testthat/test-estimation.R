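test_that("count_fields matches a brute-force membership oracle", {
  pat <- simulate_membrane(test_spec, "homogeneous", intensity = 8, seed = 17)
  for (plan in list(make_transect_plan(test_spec, "full"),
                    make_scatter_plan(test_spec, "quarter"))) {
    fc <- count_fields(pat, plan)
    expect_equal(fc$counts, brute_force_counts(pat, plan))
  }
})

test_that("counting respects basic bounds and spec agreement", {
  empty <- simulate_membrane(test_spec, "homogeneous", intensity = 0, seed = 1)
  plan <- make_scatter_plan(test_spec, "eighth")
  expect_true(all(count_fields(empty, plan)$counts == 0L))

  pat <- simulate_membrane(test_spec, "homogeneous", intensity = 20, seed = 2)
  # scatter fields are disjoint, so sampled counts cannot exceed the total
  expect_lte(sum(count_fields(pat, make_scatter_plan(test_spec, "full"))$counts),
             pat$true_total)

  other <- simulate_membrane(membrane_spec(8, 40), "homogeneous", intensity = 1, seed = 1)
  expect_error(count_fields(other, plan), "different membrane specs")
})

test_that("extrapolation is exact under full coverage and zero for empty counts", {
  grid <- make_grid_plan(test_spec)
  pat <- simulate_membrane(test_spec, "homogeneous", intensity = 15, seed = 5)
  est <- extrapolate_total(count_fields(pat, grid))
  expect_equal(est$estimated_total, pat$true_total)

  plan <- make_transect_plan(test_spec, "half")
  zero <- extrapolate_total(field_counts(rep(0L, 20), plan))
  expect_equal(zero$estimated_total, 0)
})

test_that("extrapolation is unbiased under complete spatial randomness", {
  n_rep <- 200
  plan <- make_scatter_plan(test_spec, "full")
  rel <- vapply(seq_len(n_rep), function(s) {
    pat <- simulate_membrane(test_spec, "homogeneous", intensity = 20, seed = 1000 + s)
    est <- extrapolate_total(count_fields(pat, plan))
    (est$estimated_total - pat$true_total) / pat$true_total
  }, 0)
  expect_lt(abs(mean(rel)), 3 * sd(rel) / sqrt(n_rep))
  expect_lt(abs(mean(rel)), 0.02)
})

test_that("accuracy_pct implements the floored relative-deviation score", {
  expect_equal(accuracy_pct(100, 100), 100)
  expect_equal(accuracy_pct(0, 100), 0)
  expect_equal(accuracy_pct(110, 100), 90)
  expect_equal(accuracy_pct(250, 100), 0)  # floored, not negative
  # scale invariance
  for (k in c(0.5, 3, 117)) {
    expect_equal(accuracy_pct(k * 83, k * 100), accuracy_pct(83, 100))
  }
  expect_error(accuracy_pct(10, 0), "positive")
})

test_that("zero sampled area is an unusable plan", {
  plan <- make_transect_plan(test_spec, "quarter")
  plan$fields$clipped_area_mm2[] <- 0
  expect_error(extrapolate_total(rep(0L, 10), plan), "zero membrane area")
})

test_that("strategy experiment matches the closed-form CSR sampling expectation", {
  # Under CSR with a disjoint plan sampling fraction p, the sampled count is
  # binomial-thinned: E|est - N| / N has the closed form of a folded
  # binomial deviation. Compare the simulated mean absolute relative error
  # with that expectation, computed by direct enumeration over N and k.
  plan <- make_scatter_plan(test_spec, "half")
  p <- sum(plan$fields$clipped_area_mm2) / test_spec$area_mm2
  intensity <- 20
  lambda <- intensity * test_spec$area_mm2

  n_grid <- qpois(c(1e-10, 1 - 1e-10), lambda)
  Ns <- n_grid[1]:n_grid[2]
  wN <- dpois(Ns, lambda); wN <- wN / sum(wN)
  expected_abs_rel <- sum(vapply(seq_along(Ns), function(i) {
    N <- Ns[i]
    k <- 0:N
    sum(dbinom(k, N, p) * abs(k / p - N) / N) * wN[i]
  }, 0))

  res <- run_strategy_experiment(test_spec, plans = list(scatter_half = plan),
                                 process = "homogeneous", intensity = intensity,
                                 n_replicates = 300, seed = 77)
  expect_lt(abs(res$mean_abs_rel_error_pct / 100 - expected_abs_rel),
            3 * res$se_abs_rel_error_pct / 100)
})

test_that("strategy experiment is deterministic under its seed", {
  plans <- list(q = make_transect_plan(test_spec, "quarter"))
  a <- run_strategy_experiment(test_spec, plans, process = "homogeneous",
                               intensity = 10, n_replicates = 20, seed = 5)
  b <- run_strategy_experiment(test_spec, plans, process = "homogeneous",
                               intensity = 10, n_replicates = 20, seed = 5)
  expect_identical(a, b)
})
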