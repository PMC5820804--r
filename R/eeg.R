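#' Multichannel EEG recording
#'
#' Container for a scalp EEG segment: a channels-by-samples matrix in
#' microvolts with 10-20 channel labels, sampling rate, and an optional
#' per-sample artifact mask (TRUE = contaminated, excluded from spectra).
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz; must exceed 60 Hz so the 1-30 Hz
#'   analysis band is well below Nyquist.
#' @param channel_labels unique channel names, one per row of `data`.
#' @param artifact_mask optional logical vector, one entry per sample.
#' @param meta named list of free-form provenance metadata.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`, `artifact_mask`, `meta`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          artifact_mask = NULL, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_nm("EEG data must be a finite numeric matrix")
  if (length(channel_labels) != nrow(data))
    stop_nm("one channel label per data row required")
  if (anyDuplicated(channel_labels))
    stop_nm("duplicate channel labels: ",
            paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.numeric(fs) || fs <= 60)
    stop_nm("sampling rate must exceed 60 Hz")
  if (!is.null(artifact_mask)) {
    if (length(artifact_mask) != ncol(data))
      stop_nm("artifact mask length must equal the number of samples")
    artifact_mask <- as.logical(artifact_mask)
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 artifact_mask = artifact_mask, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (!is.null(x$artifact_mask))
    cat(sprintf("  masked samples: %d (%.1f%%)\n", sum(x$artifact_mask),
                100 * mean(x$artifact_mask)))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Butterworth high-pass and low-pass applied forward-backward
#' (`signal::filtfilt`), so no group delay is introduced between channels.
#' Each channel is demeaned before filtering to suppress the edge transient
#' a large DC offset would otherwise excite in the very-low-frequency
#' high-pass stage.
#'
#' @param rec an [eeg_recording].
#' @param low high-pass edge, Hz (default 0.3).
#' @param high low-pass edge, Hz (default 30).
#' @param hp_order,lp_order Butterworth orders (before the forward-backward
#'   doubling); the defaults attenuate by more than 20 dB one octave past
#'   each edge.
#' @return Filtered [eeg_recording], same length, filter recorded in `meta`.
#' @export
eeg_bandpass <- function(rec, low = 0.3, high = 30, hp_order = 2, lp_order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high)) stop_nm("need 0 < low < high")
  if (high >= nyq) stop_nm("cutoff at or above Nyquist (", nyq, " Hz)")
  hp <- signal::butter(hp_order, low / nyq, type = "high")
  lp <- signal::butter(lp_order, high / nyq, type = "low")
  out <- t(apply(rec$data, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x - mean(x)))
  }))
  eeg_recording(out, rec$fs, rec$channel_labels, rec$artifact_mask,
                meta = c(rec$meta, list(filter = sprintf(
                  "butterworth zero-phase: HP order %d @ %g Hz, LP order %d @ %g Hz",
                  hp_order, low, lp_order, high))))
}

#' Amplitude-based artifact rejection
#'
#' Splits the recording into consecutive non-overlapping epochs and masks
#' every epoch in which any channel exceeds `amplitude_limit` in absolute
#' value. Downstream spectral estimation uses unmasked epochs only.
#'
#' @param rec an [eeg_recording].
#' @param amplitude_limit rejection threshold, microvolts (default 200).
#' @param epoch_len epoch length in seconds (default 2).
#' @return The recording with an updated `artifact_mask`.
#' @export
reject_artifacts <- function(rec, amplitude_limit = 200, epoch_len = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_len <= 0) stop_nm("epoch_len must be positive")
  n <- ncol(rec$data)
  step <- floor(epoch_len * rec$fs)
  if (step < 1 || step > n) stop_nm("recording shorter than one epoch")
  mask <- rec$artifact_mask %||% rep(FALSE, n)
  starts <- seq(1, n - step + 1, by = step)
  for (s in starts) {
    idx <- s:(s + step - 1)
    if (max(abs(rec$data[, idx])) > amplitude_limit) mask[idx] <- TRUE
  }
  # trailing partial epoch, if any, judged by the same criterion
  tail_start <- max(starts) + step
  if (tail_start <= n && max(abs(rec$data[, tail_start:n])) > amplitude_limit)
    mask[tail_start:n] <- TRUE
  if (all(mask)) stop_nm("no analyzable data: every epoch exceeds the amplitude limit")
  eeg_recording(rec$data, rec$fs, rec$channel_labels, mask, rec$meta)
}

#' Averaged-periodogram power spectrum (Welch estimate)
#'
#' Per-channel power spectral density by averaging Hann-windowed
#' modified periodograms over overlapping epochs, restricted to the
#' analysis band. Epochs containing any masked sample are excluded.
#' Scaling is such that the band-integrated power (sum of density times
#' bin width) equals the in-band signal variance up to windowing loss.
#'
#' @param rec an [eeg_recording].
#' @param epoch_len epoch length in seconds; spectral resolution is
#'   `1/epoch_len` (default 2 s, i.e. 0.5 Hz).
#' @param overlap fractional epoch overlap in `[0, 1)` (default 0.5).
#' @param fmin,fmax analysis band, Hz (default 1-30).
#' @return An object of class `power_spectrum`: `freqs` (bin centers, Hz),
#'   `power` (channels x bins, uV^2/Hz), `resolution`, `n_epochs`, `meta`.
#' @export
eeg_spectrum <- function(rec, epoch_len = 2, overlap = 0.5, fmin = 1, fmax = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(overlap >= 0 && overlap < 1)) stop_nm("overlap must be in [0, 1)")
  nper <- floor(epoch_len * rec$fs)
  n <- ncol(rec$data)
  if (nper < 4 || nper > n) stop_nm("recording shorter than one epoch")
  step <- max(1, floor(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  if (!is.null(rec$artifact_mask)) {
    keep <- vapply(starts, function(s) !any(rec$artifact_mask[s:(s + nper - 1)]),
                   logical(1))
    starts <- starts[keep]
  }
  if (!length(starts)) stop_nm("no artifact-free epochs available")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- 2 / (rec$fs * sum(w^2))
  nfreq <- floor(nper / 2)
  freqs <- (1:nfreq) * rec$fs / nper
  acc <- matrix(0, nrow(rec$data), nfreq)
  for (s in starts) {
    seg <- rec$data[, s:(s + nper - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- t(mvfft(t(seg * rep(w, each = nrow(seg)))))
    acc <- acc + Mod(X[, 2:(nfreq + 1), drop = FALSE])^2 * scale
  }
  pow <- acc / length(starts)
  rownames(pow) <- rec$channel_labels
  sel <- freqs >= fmin & freqs <= fmax
  if (!any(sel)) stop_nm("no frequency bins inside the analysis band")
  structure(list(freqs = freqs[sel],
                 power = pow[, sel, drop = FALSE],
                 resolution = rec$fs / nper,
                 n_epochs = length(starts),
                 channel_labels = rec$channel_labels,
                 meta = c(rec$meta, list(
                   window = "hann", epoch_len = epoch_len, overlap = overlap,
                   band = c(fmin, fmax)))),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels x %d bins, %g-%g Hz @ %g Hz, %d epochs\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              x$resolution, x$n_epochs))
  invisible(x)
}

#' Frequency band definitions
#'
#' Clinical band edges on the continuous frequency axis. The conventional
#' integer labels (delta 1-3, theta 4-7, alpha 8-13, beta 14-30 Hz) leave
#' the gap frequencies unassigned; gaps are closed upward, giving half-open
#' intervals `[1,4) [4,8) [8,14) [14,30]`. A spectral bin belongs to the
#' band containing its center frequency.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
qeeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             lo = c(1, 4, 8, 14), hi = c(4, 8, 14, 30),
             stringsAsFactors = FALSE)
}

band_of <- function(freqs, bands = qeeg_bands()) {
  out <- rep(NA_character_, length(freqs))
  for (k in seq_len(nrow(bands))) {
    inb <- if (k == nrow(bands)) freqs >= bands$lo[k] & freqs <= bands$hi[k]
           else freqs >= bands$lo[k] & freqs < bands$hi[k]
    out[inb] <- bands$band[k]
  }
  out
}

#' Relative band powers
#'
#' Integrates the spectrum over each frequency band per channel and
#' normalizes by the total in-band power, yielding the relative delta,
#' theta, alpha and beta powers (RDP, RTP, RAP, RBP). The global fraction
#' is the unweighted mean of per-channel fractions (`global = "mean"`), or
#' the ratio of channel-pooled powers (`global = "pooled"`).
#'
#' @param spec a [power_spectrum][eeg_spectrum].
#' @param bands band table, see [qeeg_bands()].
#' @param global `"mean"` (default) or `"pooled"`.
#' @return list with `global` (named fractions summing to 1) and
#'   `per_channel` (data.frame of per-channel fractions).
#' @export
band_powers <- function(spec, bands = qeeg_bands(), global = c("mean", "pooled")) {
  stopifnot(inherits(spec, "power_spectrum"))
  global <- match.arg(global)
  bb <- band_of(spec$freqs, bands)
  keep <- !is.na(bb)
  pow <- spec$power[, keep, drop = FALSE]
  bb <- bb[keep]
  abs_band <- vapply(bands$band, function(b)
    rowSums(pow[, bb == b, drop = FALSE]), numeric(nrow(pow)))
  abs_band <- matrix(abs_band, nrow = nrow(pow),
                     dimnames = list(spec$channel_labels, bands$band))
  tot <- rowSums(abs_band)
  if (any(tot <= 0)) stop_nm("zero total in-band power in channel(s): ",
                             paste(spec$channel_labels[tot <= 0], collapse = ", "))
  per_channel <- abs_band / tot
  g <- if (global == "mean") colMeans(per_channel)
       else colSums(abs_band) / sum(abs_band)
  list(global = g,
       per_channel = as.data.frame(per_channel))
}

#' Slow/fast spectral ratios
#'
#' The delta/alpha ratio DAR = RDP/RAP and the slowing ratio
#' DTABR = (RDP+RTP)/(RAP+RBP), computed from relative band powers.
#'
#' @param fractions named numeric vector with elements `delta`, `theta`,
#'   `alpha`, `beta` (any common scale; ratios are scale-free).
#' @return named numeric vector `c(dar, dtabr)`.
#' @export
dar_dtabr <- function(fractions) {
  f <- fractions[c("delta", "theta", "alpha", "beta")]
  if (any(is.na(f))) stop_nm("fractions must name delta, theta, alpha, beta")
  if (f["alpha"] <= 0) stop_nm("zero alpha power: DAR undefined")
  if (f["alpha"] + f["beta"] <= 0) stop_nm("zero alpha+beta power: DTABR undefined")
  c(dar = unname(f["delta"] / f["alpha"]),
    dtabr = unname((f["delta"] + f["theta"]) / (f["alpha"] + f["beta"])))
}

#' Brain symmetry index
#'
#' Frequency-averaged absolute left/right spectral asymmetry over N
#' homologous bipolar channel pairs and M in-band frequency bins:
#' \deqn{BSI = \frac{1}{M} \sum_{j=1}^{M} \left| \frac{1}{N} \sum_{i=1}^{N}
#'   \frac{R_{ij} - L_{ij}}{R_{ij} + L_{ij}} \right|}
#' 0 means perfect hemispheric symmetry, 1 one-sided spectral silence.
#' Bins where any pair's summed power falls below a floor (1e-12 of the
#' median pairwise power sum) are skipped and M reduced, avoiding 0/0
#' without biasing toward extreme asymmetry.
#'
#' @param spec a [power_spectrum][eeg_spectrum] containing all paired channels
#'   (normally of a bipolar-derived recording, see [derive_bipolar()]).
#' @param pairs data.frame with character columns `right` and `left`.
#' @return single numeric value in `[0, 1]`.
#' @export
bsi <- function(spec, pairs = bsi_pairs_16()) {
  stopifnot(inherits(spec, "power_spectrum"))
  miss <- setdiff(c(pairs$right, pairs$left), spec$channel_labels)
  if (length(miss)) stop_nm("channels missing from spectrum: ",
                            paste(miss, collapse = ", "))
  R <- spec$power[pairs$right, , drop = FALSE]
  L <- spec$power[pairs$left, , drop = FALSE]
  tot <- R + L
  floor_ <- 1e-12 * stats::median(tot)
  ok_bin <- apply(tot > floor_, 2, all)
  if (!any(ok_bin)) stop_nm("no usable frequency bins for BSI")
  d <- (R[, ok_bin, drop = FALSE] - L[, ok_bin, drop = FALSE]) /
    tot[, ok_bin, drop = FALSE]
  mean(abs(colMeans(d)))
}

#' Quantitative EEG summary for one recording
#'
#' End-to-end convenience wrapper: band-pass filter, amplitude-based
#' artifact rejection, Welch spectrum of the referential channels for
#' relative band powers / DAR / DTABR, and Welch spectrum of the bipolar
#' derivations for the brain symmetry index.
#'
#' @param rec an [eeg_recording] (referential 10-20 channels).
#' @param low,high band-pass edges, Hz.
#' @param amplitude_limit artifact threshold, microvolts.
#' @param epoch_len,overlap Welch parameters (seconds, fraction).
#' @param chains bipolar chain table ([bipolar_chains_16()]).
#' @param global global averaging convention, see [band_powers()].
#' @return Object of class `qeeg_summary`: fractions `rdp`, `rtp`, `rap`,
#'   `rbp`, ratios `dar`, `dtabr`, symmetry `bsi`, per-channel fraction
#'   table, and provenance metadata.
#' @export
qeeg_summary <- function(rec, low = 0.3, high = 30, amplitude_limit = 200,
                         epoch_len = 2, overlap = 0.5,
                         chains = bipolar_chains_16(),
                         global = c("mean", "pooled")) {
  global <- match.arg(global)
  filt <- eeg_bandpass(rec, low, high)
  filt <- reject_artifacts(filt, amplitude_limit, epoch_len)
  sp <- eeg_spectrum(filt, epoch_len, overlap)
  bp <- band_powers(sp, global = global)
  ratios <- dar_dtabr(bp$global)
  sp_bip <- eeg_spectrum(derive_bipolar(filt, chains), epoch_len, overlap)
  b <- bsi(sp_bip, bsi_pairs_16(chains))
  structure(list(
    rdp = unname(bp$global["delta"]), rtp = unname(bp$global["theta"]),
    rap = unname(bp$global["alpha"]), rbp = unname(bp$global["beta"]),
    dar = unname(ratios["dar"]), dtabr = unname(ratios["dtabr"]), bsi = b,
    per_channel = bp$per_channel,
    meta = c(sp$meta, list(amplitude_limit = amplitude_limit,
                           global_convention = global,
                           n_epochs = sp$n_epochs))),
    class = "qeeg_summary")
}

#' @export
print.qeeg_summary <- function(x, digits = 3, ...) {
  cat("<qeeg_summary>\n")
  cat(sprintf("  RDP %.3f  RTP %.3f  RAP %.3f  RBP %.3f\n",
              x$rdp, x$rtp, x$rap, x$rbp))
  cat(sprintf("  DAR %.*f  DTABR %.*f  BSI %.*f\n",
              digits, x$dar, digits, x$dtabr, digits, x$bsi))
  invisible(x)
}

#' @export
as.data.frame.qeeg_summary <- function(x, ...) {
  data.frame(rdp = x$rdp, rtp = x$rtp, rap = x$rap, rbp = x$rbp,
             dar = x$dar, dtabr = x$dtabr, bsi = x$bsi)
}
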