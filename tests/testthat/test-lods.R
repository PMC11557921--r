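# Organ-system scoring against the point table, its boundaries, and the
# brute-force transcription oracle.

test_that("every point-table boundary scores correctly on both sides", {
  # neurologic: GCS 3-5 / 6-8 / 9-13 / 14-15
  expect_equal(score_neurologic(c(3, 5, 6, 8, 9, 13, 14, 15)),
               c(5, 5, 3, 3, 1, 1, 0, 0))
  # heart rate: < 30 -> 5, >= 140 -> 1
  expect_equal(score_cardiovascular(c(29, 30, 80, 80), c(80, 80, 139, 140),
                                    rep(120, 4), rep(120, 4)),
               c(5, 0, 0, 1))
  # SBP minimum bands: < 40 / 40-69 / 70-89 / >= 90
  expect_equal(score_cardiovascular(rep(80, 5), rep(80, 5),
                                    c(39, 40, 69, 70, 90),
                                    rep(120, 5)),
               c(5, 3, 3, 1, 0))
  expect_equal(score_cardiovascular(80, 80, 89, 120), 1)
  # SBP maximum bands: 240-269 -> 1, >= 270 -> 3
  expect_equal(score_cardiovascular(rep(80, 4), rep(80, 4), rep(120, 4),
                                    c(239, 240, 269, 270)),
               c(0, 1, 1, 3))
  # urea: 6 / 10 / 20 thresholds
  expect_equal(score_renal(c(5.9, 6, 9.9, 10, 19.9, 20), rep(0.9, 6),
                           rep(1.5, 6)),
               c(0, 1, 1, 3, 3, 5))
  # creatinine: 1.20 / 1.60
  expect_equal(score_renal(rep(4, 4), c(1.19, 1.20, 1.59, 1.60), rep(1.5, 4)),
               c(0, 1, 1, 3))
  # urine output: 0.5 / 0.75 / 10
  expect_equal(score_renal(rep(4, 6), rep(0.9, 6),
                           c(0.49, 0.5, 0.74, 0.75, 9.99, 10)),
               c(5, 3, 3, 0, 0, 3))
  # PaO2/FiO2: 150 mmHg and 19.9 kPa
  expect_equal(score_pulmonary(c(TRUE, TRUE), c(149.9, 150)), c(3, 1))
  expect_equal(score_pulmonary(c(TRUE, TRUE), c(19.8, 19.9),
                               unit = "kPa"), c(3, 1))
  expect_equal(score_pulmonary(FALSE), 0)
  # leucocytes: 1.0 / 2.5 / 50; platelets: 50
  expect_equal(score_hematologic(c(0.9, 1.0, 2.4, 2.5), c(8, 8, 8, 8),
                                 rep(250, 4)),
               c(3, 1, 1, 0))
  expect_equal(score_hematologic(c(8, 8), c(49.9, 50), c(250, 250)), c(0, 1))
  expect_equal(score_hematologic(c(8, 8), c(8, 8), c(49, 50)), c(1, 0))
  # bilirubin 2.0; PT 3 s above control (strict)
  expect_equal(score_hepatic(c(1.9, 2.0), c(0, 0)), c(0, 1))
  expect_equal(score_hepatic(c(0.5, 0.5), c(3, 3.01)), c(0, 1))
})

test_that("out-of-range and inconsistent inputs raise named errors", {
  expect_error(score_neurologic(2), "gcs_min")
  expect_error(score_neurologic(16), "gcs_min")
  expect_error(score_cardiovascular(-1, 80, 120, 120), "non-negative")
  expect_error(score_cardiovascular(90, 80, 120, 120), "hr_min")
  expect_error(score_renal(-1, 0.9, 1.5), "non-negative")
  expect_error(score_pulmonary(TRUE, NA_real_), "pao2_fio2")
  expect_error(score_pulmonary(TRUE, 100, unit = "atm"), "unit")
})

test_that("compute_lods sums systems, excludes GCS, and tracks missing fields", {
  all_normal <- as.data.frame(witness_observations(0))
  b <- compute_lods(all_normal)
  expect_equal(b$lods_total, 0L)
  expect_equal(b$lods_without_gcs, 0L)

  b <- compute_lods(list(gcs_min = 4, hr_min = 80, hr_max = 80,
                         sbp_min = 120, sbp_max = 120))
  expect_equal(b$lods_total, 5L)
  expect_equal(b$lods_without_gcs, 0L)

  b <- compute_lods(list(gcs_min = 7, urea_max = 25,
                         ventilated_or_cpap = TRUE, pao2_fio2 = 100))
  expect_equal(b$lods_total, 11L)
  expect_equal(b$lods_without_gcs, 8L)
  expect_true(grepl("platelets_min", b$lods_missing))

  # headline score respects include_gcs
  expect_equal(compute_lods(list(gcs_min = 4, hr_min = 80, hr_max = 80),
                            include_gcs = FALSE)$lods, 0L)

  # nothing to score
  expect_error(compute_lods(data.frame(gcs_min = NA_integer_)), "missing")
})

test_that("modular scorer agrees with the rule-table oracle on random observations", {
  set.seed(71)
  n <- 10000
  obs <- random_observation_frame(n)
  got <- compute_lods(obs)
  for (i in seq_len(n)) {
    want <- oracle_lods(as.list(obs[i, ]))
    expect_identical(got$lods_total[i], as.integer(want$total))
  }
  # spot-check per-system agreement on a subsample
  for (i in sample(n, 200)) {
    want <- oracle_lods(as.list(obs[i, ]))$per_system
    expect_identical(got$neurologic[i], as.integer(want[["neurologic"]]))
    expect_identical(got$cardiovascular[i], as.integer(want[["cardiovascular"]]))
    expect_identical(got$renal[i], as.integer(want[["renal"]]))
    expect_identical(got$pulmonary[i], as.integer(want[["pulmonary"]]))
    expect_identical(got$hematologic[i], as.integer(want[["hematologic"]]))
    expect_identical(got$hepatic[i], as.integer(want[["hepatic"]]))
  }
})

test_that("totals stay in bounds, are additive, and GCS exclusion is exact", {
  set.seed(72)
  obs <- random_observation_frame(2000)
  b <- compute_lods(obs)
  expect_true(all(b$lods_total >= 0 & b$lods_total <= 22))
  expect_true(all(b$lods_without_gcs >= 0 & b$lods_without_gcs <= 17))
  expect_true(all(b$neurologic %in% c(0, 1, 3, 5)))
  expect_true(all(b$cardiovascular %in% c(0, 1, 3, 5)))
  expect_true(all(b$renal %in% c(0, 1, 3, 5)))
  expect_true(all(b$pulmonary %in% c(0, 1, 3)))
  expect_true(all(b$hematologic %in% c(0, 1, 3)))
  expect_true(all(b$hepatic %in% c(0, 1)))
  expect_equal(b$lods_total,
               b$neurologic + b$cardiovascular + b$renal + b$pulmonary +
                 b$hematologic + b$hepatic)
  expect_equal(b$lods_total - b$lods_without_gcs,
               score_neurologic(obs$gcs_min))
})

test_that("worsening a single variable never decreases the total", {
  set.seed(73)
  worsen <- list(
    gcs_min = function(o) { o$gcs_min <- max(3, o$gcs_min - sample(1:4, 1)); o },
    sbp_min = function(o) { o$sbp_min <- o$sbp_min * 0.6; o },
    sbp_max = function(o) { o$sbp_max <- max(o$sbp_max, o$sbp_max + 60); o },
    hr_min = function(o) { o$hr_min <- o$hr_min * 0.5; o },
    hr_max = function(o) { o$hr_max <- o$hr_max + 50; o },
    urea_max = function(o) { o$urea_max <- o$urea_max + 8; o },
    creatinine_max = function(o) { o$creatinine_max <- o$creatinine_max + 0.5; o },
    platelets_min = function(o) { o$platelets_min <- o$platelets_min * 0.3; o },
    bilirubin_max = function(o) { o$bilirubin_max <- o$bilirubin_max + 1.5; o },
    pt_excess_sec = function(o) { o$pt_excess_sec <- o$pt_excess_sec + 3; o },
    wbc_min = function(o) { o$wbc_min <- min(o$wbc_min, 2.4) * 0.4; o },
    pao2_fio2 = function(o) {
      if (isTRUE(o$ventilated_or_cpap)) o$pao2_fio2 <- o$pao2_fio2 * 0.5
      o
    },
    urine_24h = function(o) { o$urine_24h <- min(o$urine_24h, 9) * 0.4; o }
  )
  for (rep_i in 1:200) {
    o <- random_observation()
    base <- compute_lods(as.data.frame(o))$lods_total
    f <- worsen[[sample(length(worsen), 1)]]
    worse <- compute_lods(as.data.frame(f(o)))$lods_total
    expect_gte(worse, base)
  }
})
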