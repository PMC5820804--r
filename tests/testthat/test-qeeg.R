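fs <- 128
tt <- seq(0, 20 - 1 / fs, by = 1 / fs)

two_ch <- function(x) eeg_recording(rbind(x, x), fs, c("C3", "C4"))

test_that("band-pass filter passes in-band, rejects out-of-band and DC", {
  s50 <- sin(2 * pi * 50 * tt)
  out <- eeg_bandpass(two_ch(s50))
  expect_lt(sd(out$data[1, ]), 0.10 * sd(s50))

  s10 <- sin(2 * pi * 10 * tt)
  out <- eeg_bandpass(two_ch(s10))
  expect_lt(abs(sd(out$data[1, ]) / sd(s10) - 1), 0.05)

  out <- eeg_bandpass(two_ch(s10 + 100))
  expect_lt(abs(mean(out$data[1, ])), 0.5)

  expect_error(eeg_bandpass(two_ch(s10), low = 0.3, high = fs / 2),
               "Nyquist")
  expect_error(eeg_bandpass(two_ch(s10), low = 30, high = 0.3), "low < high")
})

test_that("zero-phase contract: no group delay between channels", {
  set.seed(3)
  x <- rnorm(length(tt))
  rec <- eeg_recording(rbind(x, x), fs, c("C3", "C4"))
  out <- eeg_bandpass(rec)
  expect_identical(out$data[1, ], out$data[2, ])
  # peak cross-correlation with the input at zero lag
  cc <- ccf(out$data[1, ], x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("artifact rejection masks exactly the offending epochs", {
  set.seed(1)
  clean <- matrix(rnorm(2 * 10 * 2 * fs, sd = 20), nrow = 2)  # 10 epochs of 2 s
  rec <- eeg_recording(clean, fs, c("C3", "C4"))
  out <- reject_artifacts(rec, amplitude_limit = 200, epoch_len = 2)
  expect_false(any(out$artifact_mask))

  spiked <- clean
  spiked[1, 2 * fs * 2 + 10] <- 500   # inside epoch 3
  out <- reject_artifacts(eeg_recording(spiked, fs, c("C3", "C4")), 200, 2)
  ep3 <- (2 * fs * 2 + 1):(3 * fs * 2)
  expect_true(all(out$artifact_mask[ep3]))
  expect_false(any(out$artifact_mask[-ep3]))

  expect_error(reject_artifacts(rec, amplitude_limit = 0),
               "no analyzable data")
})

test_that("masked epochs are excluded from the spectrum", {
  set.seed(2)
  x <- matrix(rnorm(2 * 10 * 2 * fs, sd = 20), nrow = 2)
  x[, (2 * fs * 2 + 1):(3 * fs * 2)] <- 1e4  # corrupt epoch 3 massively
  rec <- reject_artifacts(eeg_recording(x, fs, c("C3", "C4")), 200, 2)
  sp <- eeg_spectrum(rec)
  clean <- eeg_spectrum(eeg_recording(x[, -((2 * fs * 2 + 1):(3 * fs * 2))],
                                      fs, c("C3", "C4")))
  # corrupted epoch contributes nothing: power stays at the noise scale
  expect_lt(max(sp$power), 10 * max(clean$power))
})

test_that("Welch spectrum: flat for white noise, Parseval for a sinusoid", {
  set.seed(42)
  recw <- eeg_recording(matrix(rnorm(fs * 300), 1), fs, "C3")
  spw <- eeg_spectrum(recw)
  expect_lt(max(abs(spw$power[1, ] / mean(spw$power[1, ]) - 1)), 0.15)

  A <- 20
  t2 <- seq(0, 120 - 1 / fs, by = 1 / fs)
  rec <- two_ch(A * sin(2 * pi * 10 * t2))
  sp <- eeg_spectrum(rec)
  expect_equal(sum(sp$power[1, ]) * sp$resolution, A^2 / 2, tolerance = 1e-6)
  # spectral mass concentrated at the 10 Hz bin
  expect_equal(sp$freqs[which.max(sp$power[1, ])], 10)
  expect_identical(sp$power[1, ], sp$power[2, ])

  expect_error(eeg_spectrum(eeg_recording(matrix(rnorm(fs), 1), fs, "C3"),
                            epoch_len = 2), "shorter")
})

test_that("relative band powers follow the bin-center band convention", {
  # pure alpha
  t2 <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sp <- eeg_spectrum(two_ch(10 * sin(2 * pi * 10 * t2)))
  bp <- band_powers(sp)
  expect_gt(bp$global[["alpha"]], 0.99)

  # flat spectrum on 1 Hz bins centered 1..30: delta 3, theta 4, alpha 6, beta 17
  spf <- make_spectrum(1, freqs = 1:30, labels = c("C3", "C4"))
  bpf <- band_powers(spf)
  expect_equal(unname(bpf$global),
               c(3, 4, 6, 17) / 30, tolerance = 1e-12)

  # normalization and gain invariance
  set.seed(7)
  spr <- make_spectrum(runif(2 * 59, 0.1, 2), freqs = seq(1, 30, 0.5),
                       labels = c("C3", "C4"))
  bpr <- band_powers(spr)
  expect_equal(sum(bpr$global), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(bpr$per_channel) - 1) < 1e-9))
  spr10 <- spr; spr10$power <- spr$power * 10
  expect_equal(band_powers(spr10)$global, bpr$global, tolerance = 1e-12)

  spz <- make_spectrum(0, freqs = 1:30, labels = "C3")
  expect_error(band_powers(spz), "zero total")
})

test_that("DAR and DTABR are exact ratio arithmetic", {
  r <- dar_dtabr(c(delta = 0.744, theta = 0.084, alpha = 0.095, beta = 0.064))
  expect_equal(unname(r["dar"]), 0.744 / 0.095, tolerance = 1e-12)   # 7.83
  r2 <- dar_dtabr(c(delta = 0.70, theta = 0.095, alpha = 0.119, beta = 0.071))
  expect_equal(unname(r2["dtabr"]), (0.70 + 0.095) / (0.119 + 0.071),
               tolerance = 1e-12)                                    # 4.18
  r3 <- dar_dtabr(c(delta = 0.25, theta = 0.25, alpha = 0.25, beta = 0.25))
  expect_equal(unname(r3), c(1, 1))
  expect_error(dar_dtabr(c(delta = 1, theta = 0, alpha = 0, beta = 0.5)),
               "alpha")
})

test_that("DAR is gain-invariant and increasing in delta share", {
  f <- c(delta = 0.5, theta = 0.2, alpha = 0.2, beta = 0.1)
  expect_equal(dar_dtabr(f * 7), dar_dtabr(f))
  f2 <- c(delta = 0.6, theta = 0.2, alpha = 0.2, beta = 0.1)
  expect_gt(dar_dtabr(f2)["dar"], dar_dtabr(f)["dar"])
})

test_that("BSI matches the hand-computed double sum on a toy spectrum", {
  labs <- c("R1", "L1", "R2", "L2")
  pow <- rbind(R1 = c(1, 2, 3, 4), L1 = c(1, 1, 1, 1),
               R2 = c(2, 2, 2, 2), L2 = c(1, 2, 3, 4))
  sp <- make_spectrum(pow, freqs = c(2, 6, 10, 20), labels = labs)
  pairs <- data.frame(right = c("R1", "R2"), left = c("L1", "L2"))
  # hand computation of (1/M) sum_j |(1/N) sum_i (R-L)/(R+L)|
  dj <- sapply(1:4, function(j) {
    mean(c((pow[1, j] - pow[2, j]) / (pow[1, j] + pow[2, j]),
           (pow[3, j] - pow[4, j]) / (pow[3, j] + pow[4, j])))
  })
  expect_equal(bsi(sp, pairs), mean(abs(dj)), tolerance = 1e-15)
})

test_that("BSI closed forms: symmetry 0, 3:1 ratio 0.5, one-sided silence 1", {
  labs <- c("R1", "L1", "R2", "L2")
  pairs <- data.frame(right = c("R1", "R2"), left = c("L1", "L2"))
  freqs <- seq(1, 30, 0.5)
  base <- matrix(rep(c(1, 1, 2, 2), length(freqs)), nrow = 4)
  expect_equal(bsi(make_spectrum(base, freqs, labs), pairs), 0)
  asym <- base * c(3, 1, 3, 1)
  expect_equal(bsi(make_spectrum(asym, freqs, labs), pairs), 0.5)
  silent <- base * c(1, 0, 1, 0)
  expect_equal(bsi(make_spectrum(silent, freqs, labs), pairs), 1)
})

test_that("BSI is invariant to common gain and to the sign flip of sides", {
  set.seed(11)
  labs <- c("R1", "L1", "R2", "L2")
  pairs <- data.frame(right = c("R1", "R2"), left = c("L1", "L2"))
  freqs <- seq(1, 30, 0.5)
  pow <- matrix(runif(4 * length(freqs), 0.5, 3), nrow = 4)
  sp <- make_spectrum(pow, freqs, labs)
  b <- bsi(sp, pairs)
  expect_true(b >= 0 && b <= 1)
  sp2 <- sp; sp2$power <- sp$power * 5
  expect_equal(bsi(sp2, pairs), b, tolerance = 1e-12)
  swapped <- data.frame(right = pairs$left, left = pairs$right)
  expect_equal(bsi(sp, swapped), b, tolerance = 1e-12)
  expect_error(bsi(sp, data.frame(right = "R9", left = "L1")), "missing")
})

test_that("injected delta power raises RDP and DAR monotonically", {
  set.seed(5)
  rec <- gen_eeg(eeg_gen_spec(seed = 5, duration = 30))
  qs1 <- qeeg_summary(rec)
  t2 <- seq(0, 30 - 1 / fs, by = 1 / fs)
  extra <- 25 * sin(2 * pi * 2 * t2)
  rec2 <- eeg_recording(sweep(rec$data, 2, extra, "+"), rec$fs,
                        rec$channel_labels)
  qs2 <- qeeg_summary(rec2)
  expect_gt(qs2$rdp, qs1$rdp)
  expect_gt(qs2$dar, qs1$dar)
})
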