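test_that("per-gram and per-ml concentrations are plain validated ratios", {
  expect_equal(per_gram(57, 0.5), 114)
  expect_equal(per_gram(0, 1), 0)
  expect_equal(per_gram(207, 1), 207)
  expect_equal(per_ml(3150, 10), 315)
  expect_error(per_gram(10, 0), "positive")
  expect_error(per_ml(10, -1), "positive")
  expect_error(per_gram(-1, 1), "non-negative")
})

test_that("the published case series reproduces its one-decimal L/D ratios", {
  ref <- reference_cases()
  ld <- ld_ratio(ref$lung_per_gram, ref$medium_per_ml)
  expect_equal(round(ld, 1), ref$ld_ratio)
  expect_error(ld_ratio(100, 0), "reference")
})

test_that("classification thresholds and boundary behaviour are as published", {
  expect_equal(as.character(classify_ld(10.9)), "strong_drowning")
  expect_equal(as.character(classify_ld(0.1)), "immersion_compatible")
  expect_equal(as.character(classify_ld(1)), "immersion_compatible")  # equality is not excess
  expect_equal(as.character(classify_ld(1.0001)), "drowning_supportive")
  expect_equal(as.character(classify_ld(2)), "drowning_supportive")
  expect_equal(as.character(classify_ld(2.0001)), "strong_drowning")
  expect_error(classify_ld(-0.1), "non-negative")
})

test_that("classification is monotone in the ratio", {
  lds <- sort(withr::with_seed(1, c(runif(200, 0, 5), 1, 2)))
  cls <- classify_ld(lds)
  expect_true(all(diff(as.integer(cls)) >= 0L))
})

test_that("peripheral categories partition the counts with no gaps or overlaps", {
  expect_equal(as.character(categorize_peripheral(c(0, 1, 4, 5, 9, 10, 250))),
               c("-", "+", "+", "++", "++", "+++", "+++"))
  counts <- 0:60
  cls <- categorize_peripheral(counts)
  expect_false(anyNA(cls))                       # no gaps
  expect_true(all(diff(as.integer(cls)) >= 0L))  # ordered, no overlaps
  expect_error(categorize_peripheral(-1), "non-negative")
  expect_error(categorize_peripheral(2.5), "integers")
})

test_that("replicability reports spread and rank correlation on control data", {
  same <- replicability(data.frame(mass_g = c(0.5, 1, 2), diatom_count = c(50, 100, 200)))
  expect_equal(same$max_rel_deviation_pct, 0)
  expect_equal(same$spearman_r, 1)

  a <- replicability(data.frame(mass_g = c(0.5, 1.1, 1.5),
                                diatom_count = c(57, 108, 155)))
  expect_equal(a$per_gram_values, c(114, 98.1818181818, 103.3333333), tolerance = 1e-9)
  pg <- c(57 / 0.5, 108 / 1.1, 155 / 1.5)
  expect_equal(a$max_rel_deviation_pct, 100 * (max(pg) - min(pg)) / mean(pg))
  expect_equal(a$spearman_r, 1)  # counts increase with mass

  expect_error(replicability(data.frame(mass_g = 1, diatom_count = 5)), "two samples")
})

test_that("replicability runs the Kruskal-Wallis stage on per-field counts", {
  pf <- withr::with_seed(3, list(rpois(20, 5), rpois(20, 5), rpois(20, 5)))
  rep3 <- replicability(control_case_counts()[1:3, c("mass_g", "diatom_count")],
                        per_field_counts = pf)
  expect_true(rep3$kruskal_p > 0 && rep3$kruskal_p <= 1)
  expect_identical(rep3$kruskal_p,
                   kruskal.test(unlist(pf), factor(rep(1:3, each = 20)))$p.value)
})

test_that("digestion volumes follow the validated 4:1 batches with disintegration warnings", {
  r5 <- recommend_digestion(0.5)
  expect_equal(c(r5$hno3_ml, r5$h2o2_ml), c(4, 1))
  expect_length(r5$warnings, 0)
  r10 <- recommend_digestion(1.0)
  expect_equal(c(r10$hno3_ml, r10$h2o2_ml), c(8, 2))
  r15 <- recommend_digestion(1.5)
  expect_equal(c(r15$hno3_ml, r15$h2o2_ml), c(12, 3))
  # 4:1 ratio and additivity hold for every batch
  for (r in list(r5, r10, r15)) {
    expect_equal(r$hno3_ml / r$h2o2_ml, 4)
    expect_equal(r$hno3_ml + r$h2o2_ml, r$total_volume_ml)
  }
  # oversized volume on a small sample risks frustule damage
  expect_match(recommend_digestion(0.5, total_volume_ml = 10)$warnings, "disintegration")
  expect_match(recommend_digestion(1.0, total_volume_ml = 15)$warnings, "disintegration")
  expect_error(recommend_digestion(2.5), "adjust the tissue mass")
  expect_error(recommend_digestion(0))
})

test_that("analyze_case composes concentrations, ratio, class and flags", {
  rec <- analyze_case("case_4", lung_count = 4521, lung_mass_g = 1,
                      medium_count = 6750, medium_volume_ml = 10,
                      peripheral_counts = c(liver = 2, kidney = 12))
  expect_equal(rec$ld_ratio_reported, 6.7)
  expect_equal(as.character(rec$diagnostic_class), "strong_drowning")
  expect_equal(as.character(rec$peripheral[["liver"]]), "+")
  expect_equal(as.character(rec$peripheral[["kidney"]]), "+++")

  rec2 <- analyze_case("case_2", 410, 1, 1750, 10)
  expect_equal(rec2$ld_ratio_reported, 2.3)

  none <- analyze_case("x", 0, 1, 500, 10)
  expect_equal(none$ld_ratio, 0)
  expect_equal(as.character(none$diagnostic_class), "immersion_compatible")
})

test_that("synthetic cases with clear true ratios are recovered reliably", {
  # true L/D 2.5 with expected counts of 500 (lung) and 200 (medium)
  hits_high <- vapply(1:300, function(s) {
    sc <- simulate_case(500, 200, tissue_masses = 1, medium_volumes = 1, seed = s)
    case_ld_estimate(sc) > 2
  }, TRUE)
  expect_gte(mean(hits_high), 0.95)

  hits_low <- vapply(1:300, function(s) {
    sc <- simulate_case(100, 200, tissue_masses = 2, medium_volumes = 10, seed = s)
    case_ld_estimate(sc) <= 1  # true L/D 0.5
  }, TRUE)
  expect_gte(mean(hits_low), 0.95)
})
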