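test_that("generated EEG round-trips its target relative powers", {
  rec <- gen_eeg(eeg_gen_spec(seed = 11))
  bp <- band_powers(eeg_spectrum(rec))
  expect_true(all(abs(bp$global - 0.25) < 0.02))

  tgt <- table2_fractions()
  bp2 <- band_powers(eeg_spectrum(gen_eeg(eeg_gen_spec(tgt, seed = 12))))
  expect_true(all(abs(bp2$global - tgt) < 0.02))
})

test_that("generated EEG reproduces the target DAR through the full analyser", {
  tgt <- table2_fractions()
  qs <- qeeg_summary(gen_eeg(eeg_gen_spec(tgt, seed = 7)))
  expect_lt(abs(qs$dar / (0.744 / 0.095) - 1), 0.05)
})

test_that("hemispheric asymmetry maps to the BSI closed form", {
  qs <- qeeg_summary(gen_eeg(eeg_gen_spec(asymmetry = 3, seed = 2)))
  expect_lt(abs(qs$bsi - 0.5), 0.05)   # |(3-1)/(3+1)|
  qs0 <- qeeg_summary(gen_eeg(eeg_gen_spec(seed = 3)))
  expect_lt(qs0$bsi, 0.1)
})

test_that("EEG generation is deterministic in the seed", {
  a <- gen_eeg(eeg_gen_spec(seed = 9, duration = 10))
  b <- gen_eeg(eeg_gen_spec(seed = 9, duration = 10))
  c <- gen_eeg(eeg_gen_spec(seed = 10, duration = 10))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("EEG spec validation rejects bad fractions and sampling rates", {
  expect_error(eeg_gen_spec(c(delta = 0.5, theta = 0.5, alpha = 0.5,
                              beta = 0.5)), "sum to 1")
  expect_error(eeg_gen_spec(fs = 50), "twice")
  expect_error(eeg_gen_spec(duration = 0), "duration")
  expect_error(eeg_gen_spec(asymmetry = -1), "asymmetry")
})

test_that("noiseless Doppler envelope round-trips (vs, vd) exactly", {
  env <- gen_tcd(tcd_gen_spec(vs = 60, vd = 30))
  bs <- detect_beats(env)
  expect_true(all(bs$beats$vs == 60))
  expect_true(all(bs$beats$vd == 30))
  # 72 bpm over 30 s: 36 cycles, boundary trimming allows one fewer
  expect_true(abs(nrow(bs$beats) - 36) <= 1)
})

test_that("recovered PI matches the printed formula on group-mean inputs", {
  env <- gen_tcd(tcd_gen_spec(vs = 91.2, vd = 26.6))
  bs <- detect_beats(env)
  pis <- pulsatility_index(bs$beats$vs, bs$beats$vd)
  expect_true(all(abs(pis - 1.342105) < 1e-6))
})

test_that("zero-pulsatility limit drives PI to zero", {
  env <- gen_tcd(tcd_gen_spec(vs = 50 + 1e-6, vd = 50))
  bs <- detect_beats(env)
  expect_lt(max(pulsatility_index(bs$beats$vs, bs$beats$vd)), 1e-6)
})

test_that("Doppler generator validates and is seed-deterministic", {
  expect_error(tcd_gen_spec(vs = 30, vd = 30), "vs > vd")
  expect_error(tcd_gen_spec(vs = 60, vd = 30, heart_rate = 0), "heart rate")
  a <- gen_tcd(tcd_gen_spec(60, 30, velocity_noise_sd = 2, seed = 4))
  b <- gen_tcd(tcd_gen_spec(60, 30, velocity_noise_sd = 2, seed = 4))
  expect_identical(a$velocity, b$velocity)
})

test_that("cohort generator hits its calibrated group means", {
  co <- gen_cohort(cohort_gen_spec(seed = 21))
  upi_s <- co$upi[!co$died90]; upi_n <- co$upi[co$died90]
  expect_lt(abs(mean(upi_s) - 1.1), 3 * 0.2 / sqrt(21))
  expect_lt(abs(mean(upi_n) - 1.4), 3 * 0.2 / sqrt(26))
  expect_identical(co$died90, rep(c(FALSE, TRUE), c(21, 26)))
})

test_that("a two-normal feature attains its closed-form AUROC", {
  co <- gen_cohort(cohort_gen_spec(1000, 1000, seed = 22))
  expect_lt(abs(auc_mw(co$upi, co$died90) - pnorm(0.3 / sqrt(0.08))), 0.02)
})

test_that("null cohorts pass the type-I screen untouched", {
  par <- default_cohort_params()
  for (nm in names(par)) par[[nm]]$nonsurvivor <- par[[nm]]$survivor
  co <- gen_cohort(cohort_gen_spec(21, 26, params = par, seed = 23))
  sc <- suppressWarnings(univariate_screen(co))
  expect_false(any(sc$selected))
})

test_that("skewed variables reproduce their median and IQR calibration", {
  co <- gen_cohort(cohort_gen_spec(4000, 4000, seed = 24))
  vol_n <- co$hematoma_volume[co$died90]
  q <- quantile(vol_n, c(0.25, 0.5, 0.75))
  expect_equal(unname(q[2]), 62.8, tolerance = 0.05)
  expect_equal(unname(q[3] / q[1]), 90.1 / 44.1, tolerance = 0.1)
})

test_that("cohort generation is deterministic in the seed", {
  expect_identical(gen_cohort(cohort_gen_spec(seed = 5)),
                   gen_cohort(cohort_gen_spec(seed = 5)))
  expect_false(identical(gen_cohort(cohort_gen_spec(seed = 5)),
                         gen_cohort(cohort_gen_spec(seed = 6))))
})

test_that("screening roster reproduces the requested funnel", {
  roster <- gen_screening_roster()
  expect_equal(nrow(roster), 76)
  flags <- as.matrix(as.data.frame(roster)[, exclusion_criteria()])
  expect_true(all(rowSums(flags) <= 1))
  expect_equal(sum(rowSums(flags)), 29)

  empty <- gen_screening_roster(setNames(rep(0L, 7), exclusion_criteria()),
                                n_enrolled = 10)
  expect_equal(nrow(empty), 10)
  expect_equal(apply_eligibility(empty)$n_enrolled, 10)

  one <- gen_screening_roster(setNames(c(1L, rep(0L, 6)), exclusion_criteria()),
                              n_enrolled = 0)
  expect_equal(nrow(one), 1)
  expect_equal(apply_eligibility(one)$n_enrolled, 0)

  expect_error(gen_screening_roster(c(bogus = 1)), "named after")
})
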