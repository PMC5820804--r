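#' Specification for a synthetic EEG recording
#'
#' Describes a multichannel EEG whose per-channel relative band powers hit
#' prescribed targets, with optional per-band right/left power asymmetry.
#'
#' @param target_relative_powers named fractions (`delta`, `theta`, `alpha`,
#'   `beta`), non-negative and summing to 1.
#' @param n_channels number of channels (default 16).
#' @param channel_labels 10-20 labels, one per channel.
#' @param fs sampling rate, Hz; must be at least twice the 30 Hz band top.
#' @param duration recording length, seconds.
#' @param asymmetry right/left power ratio per band, a single non-negative
#'   number or a length-4 vector in band order; 1 = symmetric hemispheres.
#' @param total_sd overall per-channel signal SD, microvolts.
#' @param analysis_epoch_len Welch epoch length (seconds) the output is
#'   meant to be re-analysed with; component variances are pre-compensated
#'   for that window's spectral leakage so the measured relative powers
#'   match the targets in expectation. Set to `NULL` to disable.
#' @param seed integer RNG seed; same seed gives a bit-identical recording.
#' @return validated list of class `eeg_gen_spec`.
#' @export
eeg_gen_spec <- function(target_relative_powers = c(delta = 0.25, theta = 0.25,
                                                    alpha = 0.25, beta = 0.25),
                         n_channels = 16, channel_labels = ten_twenty_16(),
                         fs = 128, duration = 60, asymmetry = 1,
                         total_sd = 30, analysis_epoch_len = 2, seed = 1) {
  p <- target_relative_powers[c("delta", "theta", "alpha", "beta")]
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_nm("target fractions must name the four bands, be non-negative and sum to 1")
  if (fs < 60) stop_nm("fs below twice the 30 Hz band top")
  if (duration <= 0) stop_nm("duration must be positive")
  if (length(channel_labels) != n_channels || anyDuplicated(channel_labels))
    stop_nm("need n_channels unique labels")
  if (length(asymmetry) == 1) asymmetry <- rep(asymmetry, 4)
  if (length(asymmetry) != 4 || any(asymmetry < 0))
    stop_nm("asymmetry must be a non-negative scalar or length-4 vector")
  names(asymmetry) <- c("delta", "theta", "alpha", "beta")
  structure(list(target_relative_powers = p, n_channels = n_channels,
                 channel_labels = channel_labels, fs = fs, duration = duration,
                 asymmetry = asymmetry, total_sd = total_sd,
                 analysis_epoch_len = analysis_epoch_len, seed = seed),
            class = "eeg_gen_spec")
}

is_right_channel <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  !is.na(num) & num %% 2 == 0
}

# |DTFT of the length-N Hann window|^2 at a frequency offset of d Hz,
# evaluated in closed form via Dirichlet kernels.
hann_kernel2 <- function(d, N, fs) {
  om <- 2 * pi * as.vector(d) / fs
  dirichlet <- function(om) {
    out <- complex(real = rep(N, length(om)))
    nz <- abs(sin(om / 2)) > 1e-12
    out[nz] <- exp(-1i * om[nz] * (N + 1) / 2) *
      sin(N * om[nz] / 2) / sin(om[nz] / 2)
    out
  }
  a <- 2 * pi / (N + 1)
  k2 <- Mod(0.5 * dirichlet(om) -
              0.25 * (dirichlet(om - a) + dirichlet(om + a)))^2
  if (is.matrix(d)) matrix(k2, nrow(d)) else k2
}

.leakage_cache <- new.env(parent = emptyenv())

# Expected band-to-band power transfer of the Welch analysis (Hann window,
# epoch nper samples) applied to unit-variance brick-wall band noise on the
# length-n synthesis grid. M0[b, k] = expected power measured in band b per
# unit variance of a component confined to band k (out-of-band loss below
# 1 Hz is retained, so columns need not sum to 1).
leakage_matrix <- function(n, fs, nper, fmin = 1, fmax = 30,
                           bands = qeeg_bands()) {
  key <- paste(n, fs, nper, fmin, fmax, sep = "|")
  if (!is.null(.leakage_cache[[key]])) return(.leakage_cache[[key]])
  half <- floor(n / 2)
  fgen <- (0:half) * fs / n
  bgen <- band_of(fgen, bands)
  fa <- (1:floor(nper / 2)) * fs / nper
  fa <- fa[fa >= fmin & fa <= fmax]
  ba <- band_of(fa, bands)
  M0 <- matrix(0, nrow(bands), nrow(bands),
               dimnames = list(bands$band, bands$band))
  for (k in seq_len(nrow(bands))) {
    ik <- which(!is.na(bgen) & bgen == bands$band[k])
    if (!length(ik)) next
    Kmat <- hann_kernel2(outer(fgen[ik], fa, "-"), nper, fs)
    for (b in seq_len(nrow(bands)))
      M0[b, k] <- mean(rowSums(Kmat[, !is.na(ba) & ba == bands$band[b],
                                    drop = FALSE]))
  }
  .leakage_cache[[key]] <- M0
  M0
}

# Gaussian noise whose spectrum is confined to the FFT bins flagged in
# `mask` (frequency-sampling synthesis: random phase, flat in-band gain).
band_noise <- function(n, mask) {
  half <- floor(n / 2)
  coef <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) *
    mask[2:(half + 1)]
  spec <- complex(length.out = n)
  spec[2:(half + 1)] <- coef
  spec[n:(n - half + 2)] <- Conj(coef[1:(half - 1)])
  if (n %% 2 == 0) spec[half + 1] <- complex(real = Re(spec[half + 1]) * sqrt(2))
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate a synthetic EEG recording
#'
#' Each channel is a sum of four independent band-limited Gaussian noise
#' processes (frequency-domain synthesis with an ideal brick-wall band
#' mask per clinical band). Component variances are not the raw target
#' fractions: they are pre-compensated through the analysis window's
#' band-to-band leakage matrix (see `analysis_epoch_len` in
#' [eeg_gen_spec()]), so that re-analysing the output with
#' [eeg_spectrum()] and [band_powers()] at matched settings recovers the
#' target fractions in expectation, not merely up to leakage bias.
#' Right-hemisphere channels are scaled per band by the square root of the
#' requested right/left power ratio.
#'
#' @param spec an [eeg_gen_spec].
#' @return an [eeg_recording]; generator settings recorded in `meta`.
#' @export
gen_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_gen_spec"))
  n <- round(spec$duration * spec$fs)
  half <- floor(n / 2)
  freqs <- (0:half) * spec$fs / n
  bandlab <- band_of(freqs)
  right <- is_right_channel(spec$channel_labels)
  p <- spec$target_relative_powers
  cvar <- if (is.null(spec$analysis_epoch_len)) p
  else {
    M0 <- leakage_matrix(n, spec$fs, round(spec$analysis_epoch_len * spec$fs))
    v <- pmax(solve(M0, p), 0)
    stats::setNames(v / sum(v), names(p))
  }
  total_var <- spec$total_sd^2
  with_seed(spec$seed, {
    data <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      x <- numeric(n)
      for (b in names(p)) {
        if (p[[b]] <= 0 || cvar[[b]] <= 0) next
        mask <- as.numeric(!is.na(bandlab) & bandlab == b)
        if (sum(mask) == 0) next
        comp <- band_noise(n, mask)
        v <- cvar[[b]] * total_var
        if (right[ch]) v <- v * spec$asymmetry[[b]]
        x <- x + comp * sqrt(v / stats::var(comp))
      }
      data[ch, ] <- x
    }
    eeg_recording(data, spec$fs, spec$channel_labels, meta = list(
      generator = "band-limited Gaussian noise, frequency-domain brick-wall bands",
      leakage_compensation = !is.null(spec$analysis_epoch_len),
      target_relative_powers = p, component_variances = cvar,
      asymmetry = spec$asymmetry, seed = spec$seed))
  })
}

#' Specification for a synthetic Doppler envelope
#'
#' @param vs,vd peak systolic and end-diastolic velocity, cm/s (`vs > vd >= 0`).
#' @param heart_rate beats per minute (> 0).
#' @param fs envelope sampling rate, Hz.
#' @param duration seconds.
#' @param velocity_noise_sd additive Gaussian noise SD, cm/s.
#' @param seed integer RNG seed (used only when noise is added).
#' @return validated list of class `tcd_gen_spec`.
#' @export
tcd_gen_spec <- function(vs, vd, heart_rate = 72, fs = 100, duration = 30,
                         velocity_noise_sd = 0, seed = 1) {
  if (!(vs > vd && vd >= 0)) stop_nm("need vs > vd >= 0")
  if (heart_rate <= 0) stop_nm("heart rate must be positive")
  if (velocity_noise_sd < 0) stop_nm("noise SD must be non-negative")
  structure(list(vs = vs, vd = vd, heart_rate = heart_rate, fs = fs,
                 duration = duration, velocity_noise_sd = velocity_noise_sd,
                 seed = seed),
            class = "tcd_gen_spec")
}

#' Generate a synthetic Doppler velocity envelope
#'
#' Periodic cardiac waveform built beat by beat: a sinusoidal systolic
#' upstroke over the first 15% of the cycle from Vd to Vs, a brief
#' systolic plateau (3 samples, the rounded peak), a shifted-exponential
#' diastolic decay reaching exactly Vd, and a late-diastolic rest at Vd
#' over the last ~8% of the cycle before the next upstroke. The plateaus
#' make the per-beat extremes well defined: noiseless output round-trips
#' through [detect_beats()] with (Vs, Vd) recovered exactly.
#'
#' @param spec a [tcd_gen_spec].
#' @param side `"left"` or `"right"`.
#' @param insonation_depth probe depth, mm.
#' @return a [tcd_envelope]; the beat template is recorded in `meta`.
#' @export
gen_tcd <- function(spec, side = "left", insonation_depth = 55) {
  stopifnot(inherits(spec, "tcd_gen_spec"))
  n <- round(spec$duration * spec$fs)
  period <- 60 / spec$heart_rate
  n_beats <- ceiling(spec$duration / period) + 1
  bounds <- round((0:n_beats) * period * spec$fs)
  v <- numeric(bounds[length(bounds)])
  amp <- spec$vs - spec$vd
  a <- 3  # decay rate constant (dimensionless, per beat)
  for (k in seq_len(n_beats)) {
    len <- bounds[k + 1] - bounds[k]
    if (len < 12) stop_nm("heart rate too fast for the envelope sampling rate")
    n_up <- max(3, round(0.15 * len))
    n_rest <- max(3, round(0.08 * len))
    n_dec <- len - n_up - 2 - n_rest
    up <- spec$vd + amp * sin(pi / 2 * (0:(n_up - 1)) / (n_up - 1))
    s <- (1:n_dec) / n_dec
    dec <- spec$vd + amp * (exp(-a * s) - exp(-a)) / (1 - exp(-a))
    v[(bounds[k] + 1):bounds[k + 1]] <-
      c(up, rep(spec$vs, 2), dec, rep(spec$vd, n_rest))
  }
  v <- v[seq_len(n)]
  if (spec$velocity_noise_sd > 0)
    v <- with_seed(spec$seed, v + stats::rnorm(n, 0, spec$velocity_noise_sd))
  tcd_envelope(v, spec$fs, side, insonation_depth, meta = list(
    generator = paste("sinusoidal upstroke (15% of cycle), 3-sample systolic",
                      "plateau, shifted-exponential decay (rate 3),",
                      "late-diastolic rest (8% of cycle)"),
    vs = spec$vs, vd = spec$vd, heart_rate = spec$heart_rate, seed = spec$seed))
}

#' Default cohort calibration
#'
#' Per-group marginal distributions for each clinical, Doppler and EEG
#' variable of the two outcome groups (survivors vs nonsurvivors at 90
#' days): `normal` variables as (mean, sd), right-skewed variables as
#' log-normals matched to (median, q25, q75), binary variables as
#' (events, group size), and bounded integer scores as quantile-matched
#' rounded normals. Variables are sampled independently within group.
#'
#' @return named list of variable descriptors understood by [gen_cohort()].
#' @export
default_cohort_params <- function() {
  nrm <- function(s, ns) list(dist = "normal", survivor = s, nonsurvivor = ns)
  lnm <- function(s, ns) list(dist = "lognormal", survivor = s, nonsurvivor = ns)
  bin <- function(s, ns) list(dist = "binary", survivor = s, nonsurvivor = ns)
  ord <- function(s, ns, lo, hi) list(dist = "ordinal", survivor = s,
                                      nonsurvivor = ns, lo = lo, hi = hi)
  list(
    age = nrm(c(68.8, 12.5), c(64.1, 12.4)),
    male = bin(c(9, 21), c(14, 26)),
    hypertension = bin(c(18, 21), c(23, 26)),
    diabetes = bin(c(3, 21), c(4, 26)),
    hyperlipidemia = bin(c(8, 21), c(5, 26)),
    coronary_disease = bin(c(6, 21), c(7, 26)),
    smoking = bin(c(5, 21), c(10, 26)),
    excessive_drinking = bin(c(4, 21), c(7, 26)),
    onset_to_monitor = lnm(c(39, 19, 65), c(26, 18.8, 46)),
    gcs = ord(c(7, 7, 8), c(6, 4, 7), lo = 3, hi = 8),
    sbp = nrm(c(175.3, 25.9), c(162.7, 32.4)),
    dbp = nrm(c(90.5, 18.1), c(80.9, 23.0)),
    wbc = nrm(c(12.5, 4.2), c(13.3, 2.8)),
    platelet = nrm(c(205.4, 74.5), c(192.5, 83.2)),
    aptt = nrm(c(29.1, 3.7), c(29.0, 3.1)),
    inr = nrm(c(0.98, 0.09), c(1.01, 0.10)),
    glucose = lnm(c(7.2, 6.8, 9.6), c(7.7, 6.7, 9.2)),
    potassium = nrm(c(3.6, 0.4), c(3.7, 0.4)),
    calcium = nrm(c(141.6, 6.2), c(141.0, 4.9)),
    sodium = lnm(c(2.2, 2.1, 2.3), c(2.2, 2.1, 2.3)),
    hematoma_side_left = bin(c(13, 21), c(17, 26)),
    location_deep = bin(c(18, 21), c(21, 26)),
    hematoma_volume = lnm(c(25.0, 19.6, 39.6), c(62.8, 44.1, 90.1)),
    ivh = bin(c(17, 21), c(20, 26)),
    avs = nrm(c(84.9, 18.4), c(85.6, 23.9)),
    uvs = nrm(c(89.5, 21.8), c(91.2, 23.0)),
    avm = nrm(c(46.3, 10.5), c(43.8, 13.6)),
    uvm = nrm(c(51.7, 12.7), c(48.0, 12.9)),
    avd = nrm(c(27.6, 7.0), c(23.6, 9.9)),
    uvd = nrm(c(33.0, 8.9), c(26.6, 8.7)),
    api = nrm(c(1.2, 0.2), c(1.5, 0.2)),
    upi = nrm(c(1.1, 0.2), c(1.4, 0.2)),
    rdp = lnm(c(70.0, 67.7, 73.1), c(74.4, 72.5, 78.2)),
    rtp = lnm(c(9.5, 8.2, 12.0), c(8.4, 7.2, 10.1)),
    rap = lnm(c(11.9, 10.2, 13.2), c(9.5, 8.4, 10.8)),
    rbp = lnm(c(7.1, 4.2, 8.7), c(6.4, 5.0, 7.5)),
    dar = lnm(c(6.1, 5.4, 6.9), c(7.8, 6.8, 9.4)),
    dtabr = lnm(c(4.3, 3.7, 4.8), c(5.1, 4.6, 6.0)),
    bsi = lnm(c(0.36, 0.31, 0.40), c(0.38, 0.33, 0.40))
  )
}

#' Specification for a synthetic patient cohort
#'
#' @param n_survivors,n_nonsurvivors group sizes (> 0).
#' @param params per-variable descriptor list, see [default_cohort_params()].
#' @param seed integer RNG seed.
#' @return validated list of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_survivors = 21, n_nonsurvivors = 26,
                            params = default_cohort_params(), seed = 1) {
  if (n_survivors <= 0 || n_nonsurvivors <= 0)
    stop_nm("group sizes must be positive")
  for (nm in names(params)) {
    p <- params[[nm]]
    for (g in c("survivor", "nonsurvivor")) {
      v <- p[[g]]
      if (p$dist == "normal" && v[2] <= 0)
        stop_nm(nm, ": SD must be positive")
      if (p$dist == "binary" && (v[1] < 0 || v[1] > v[2]))
        stop_nm(nm, ": proportion outside [0,1]")
      if (p$dist %in% c("lognormal", "ordinal") &&
          !(v[2] <= v[1] && v[1] <= v[3]))
        stop_nm(nm, ": need q25 <= median <= q75")
    }
  }
  structure(list(n_survivors = n_survivors, n_nonsurvivors = n_nonsurvivors,
                 params = params, seed = seed),
            class = "cohort_gen_spec")
}

sample_var <- function(p, n, group) {
  v <- p[[group]]
  switch(p$dist,
    normal = stats::rnorm(n, v[1], v[2]),
    lognormal = {
      lp <- lnorm_from_quartiles(v[1], v[2], v[3])
      stats::rlnorm(n, lp$meanlog, lp$sdlog)
    },
    binary = stats::rbinom(n, 1, v[1] / v[2]) == 1,
    ordinal = {
      sd <- max((v[3] - v[2]) / (2 * qnorm(0.75)), 0.5)
      pmin(pmax(round(stats::rnorm(n, v[1], sd)), p$lo), p$hi)
    },
    stop_nm("unknown distribution: ", p$dist))
}

#' Generate a synthetic patient cohort
#'
#' Samples every variable independently within outcome group from the
#' calibrated marginals; the 90-day outcome is fixed by group membership.
#'
#' @param spec a [cohort_gen_spec].
#' @return data.frame with `id`, `died90`, and one column per variable.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_survivors; nn <- spec$n_nonsurvivors
    out <- data.frame(id = seq_len(ns + nn),
                      died90 = rep(c(FALSE, TRUE), c(ns, nn)))
    for (nm in names(spec$params)) {
      p <- spec$params[[nm]]
      out[[nm]] <- c(sample_var(p, ns, "survivor"),
                     sample_var(p, nn, "nonsurvivor"))
    }
    out
  })
}

#' Eligibility screening criteria
#'
#' Exclusion criteria applied at enrollment, in protocol order.
#'
#' @return character vector of flag names.
#' @export
exclusion_criteria <- function() {
  c("late_admission", "surgical", "macrovascular_stenosis",
    "prior_cerebrovascular", "no_temporal_window", "signal_artifacts",
    "lost_followup")
}

#' Printed screening-funnel exclusion tallies
#'
#' The per-criterion exclusion counts of the study funnel (76 screened,
#' 29 excluded, 47 enrolled).
#'
#' @return named integer vector in protocol order.
#' @export
funnel_tallies <- function() {
  stats::setNames(c(4L, 2L, 7L, 5L, 6L, 3L, 2L), exclusion_criteria())
}

#' Generate a screening roster
#'
#' Builds a roster of pseudo-patients reproducing a screening funnel:
#' `sum(tallies)` excluded records carrying exactly one exclusion flag
#' each, plus `n_enrolled` flag-free records.
#'
#' @param tallies named non-negative counts per criterion (names must match
#'   [exclusion_criteria()]); default is the printed study funnel.
#' @param n_enrolled number of eligible records (default 47).
#' @param seed optional seed to shuffle record order.
#' @return data.frame of class `screening_roster`: `id` plus one logical
#'   column per criterion.
#' @export
gen_screening_roster <- function(tallies = funnel_tallies(), n_enrolled = 47,
                                 seed = NULL) {
  crits <- exclusion_criteria()
  if (is.null(names(tallies))) names(tallies) <- crits[seq_along(tallies)]
  if (!setequal(names(tallies), crits))
    stop_nm("tallies must be named after exclusion_criteria()")
  tallies <- tallies[crits]
  if (any(tallies < 0) || n_enrolled < 0) stop_nm("counts must be non-negative")
  n <- sum(tallies) + n_enrolled
  roster <- data.frame(id = seq_len(n))
  for (cr in crits) roster[[cr]] <- FALSE
  at <- 1L
  for (cr in crits) {
    k <- tallies[[cr]]
    if (k > 0) { roster[at:(at + k - 1), cr] <- TRUE; at <- at + k }
  }
  if (!is.null(seed))
    roster <- with_seed(seed, roster[sample.int(n), , drop = FALSE])
  roster$id <- seq_len(n)
  rownames(roster) <- NULL
  class(roster) <- c("screening_roster", "data.frame")
  roster
}
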