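#' Transcranial Doppler velocity envelope
#'
#' One side's middle-cerebral-artery velocity envelope: the per-sample
#' maximum-velocity trace exported by the Doppler device, in cm/s.
#'
#' @param velocity numeric vector, cm/s.
#' @param fs sampling rate of the envelope, Hz (> 20).
#' @param side `"left"` or `"right"`.
#' @param insonation_depth optional probe depth in mm; the optimal MCA
#'   window lies at 50-60 mm, values outside that range warn.
#' @param meta named list of provenance metadata.
#' @return Object of class `tcd_envelope`.
#' @export
tcd_envelope <- function(velocity, fs, side = c("left", "right"),
                         insonation_depth = NULL, meta = list()) {
  side <- match.arg(side)
  if (!is.numeric(velocity) || any(!is.finite(velocity)))
    stop_nm("velocity must be finite numeric")
  if (!is.numeric(fs) || fs <= 20) stop_nm("envelope sampling rate must exceed 20 Hz")
  if (!is.null(insonation_depth) &&
      (insonation_depth < 50 || insonation_depth > 60))
    warning("insonation depth outside the optimal 50-60 mm MCA window")
  structure(list(velocity = as.numeric(velocity), fs = fs, side = side,
                 insonation_depth = insonation_depth, meta = meta),
            class = "tcd_envelope")
}

#' @export
print.tcd_envelope <- function(x, ...) {
  cat(sprintf("<tcd_envelope> %s side, %d samples @ %g Hz (%.1f s)\n",
              x$side, length(x$velocity), x$fs, length(x$velocity) / x$fs))
  invisible(x)
}

# local maxima exceeding a mid-range threshold, pruned to a minimum
# inter-peak distance keeping the taller peak
find_systolic_peaks <- function(v, min_dist, frac = 0.5) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  thr <- min(v) + frac * (max(v) - min(v))
  cand <- cand[v[cand] >= thr]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand)
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  sort(kept)
}

#' Beat detection on a velocity envelope
#'
#' Finds systolic peaks on a running-median-smoothed copy of the envelope
#' (local maxima above the mid-range with a minimum inter-peak distance of
#' `60/max_rate` seconds), then delimits beats by the diastolic minima
#' between successive peaks, including the leading and trailing partial
#' segments. Per beat, Vs is the median of the raw envelope over 3 samples
#' around the smoothed systolic peak and Vd the median over 5 samples
#' around the smoothed end-diastolic minimum: localization on the smoothed
#' trace with value read-out from short raw medians is exact on clean
#' waveforms and, unlike a plain min/max, carries no extreme-value bias
#' under measurement noise. Beats violating Vs > Vd or falling outside the
#' admissible rate window are dropped and counted.
#'
#' @param env a [tcd_envelope].
#' @param min_rate,max_rate admissible heart-rate window, beats/min
#'   (defaults 40-150, the physiologic range that also excludes
#'   double-peak miscounts).
#' @return Object of class `beat_set`: `boundaries` (sample indices of
#'   diastolic minima), data.frame `beats` with per-beat `vs`, `vd`,
#'   `duration` (s), and `n_dropped`.
#' @export
detect_beats <- function(env, min_rate = 40, max_rate = 150) {
  stopifnot(inherits(env, "tcd_envelope"))
  v <- env$velocity
  n <- length(v)
  sm <- stats::runmed(v, 5)
  min_dist <- floor(env$fs * 60 / max_rate)
  peaks <- find_systolic_peaks(sm, min_dist)
  if (length(peaks) < 3)
    stop_nm("unreadable waveform: fewer than 3 cardiac cycles detected")
  seg_min <- function(idx) idx[which.min(sm[idx])]
  mins <- vapply(seq_len(length(peaks) - 1), function(k)
    seg_min(peaks[k]:peaks[k + 1]), integer(1))
  if (peaks[1] > 1) mins <- c(seg_min(1:peaks[1]), mins)
  if (peaks[length(peaks)] < n) mins <- c(mins, seg_min(peaks[length(peaks)]:n))
  med_at <- function(center, halfwidth) {
    idx <- max(1, center - halfwidth):min(n, center + halfwidth)
    stats::median(v[idx])
  }
  nb <- length(mins) - 1
  if (nb < 3) stop_nm("unreadable waveform: fewer than 3 valid beats")
  vs <- vd <- dur <- numeric(nb)
  for (k in seq_len(nb)) {
    seg <- mins[k]:mins[k + 1]
    p <- seg[which.max(sm[seg])]
    vs[k] <- med_at(p, 1)
    vd[k] <- med_at(mins[k + 1], 2)
    dur[k] <- (mins[k + 1] - mins[k]) / env$fs
  }
  ok <- vs > vd & dur >= 60 / max_rate & dur <= 60 / min_rate
  if (sum(ok) < 3) stop_nm("unreadable waveform: fewer than 3 valid beats")
  structure(list(boundaries = mins,
                 beats = data.frame(vs = vs[ok], vd = vd[ok], duration = dur[ok]),
                 n_dropped = sum(!ok), side = env$side),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d valid beats (%d dropped), %s side\n",
              nrow(x$beats), x$n_dropped, x$side %||% "?"))
  invisible(x)
}

#' Mean flow velocity
#'
#' Time-weighted mean velocity from the systolic and diastolic extremes:
#' `Vm = (Vs - Vd)/3 + Vd`.
#'
#' @param vs,vd systolic and end-diastolic velocity, cm/s (vectorized).
#' @return mean velocity, cm/s.
#' @export
mean_velocity <- function(vs, vd) {
  if (any(vd < 0)) stop_nm("velocities must be non-negative")
  if (any(vs < vd)) stop_nm("Vs must be >= Vd")
  (vs - vd) / 3 + vd
}

#' Gosling pulsatility index
#'
#' `PI = (Vs - Vd)/Vm`; rises with downstream vascular resistance and
#' intracranial pressure.
#'
#' @param vs,vd systolic and end-diastolic velocity, cm/s (vectorized).
#' @param vm mean velocity; computed via [mean_velocity()] when omitted.
#' @return dimensionless pulsatility index.
#' @export
pulsatility_index <- function(vs, vd, vm = mean_velocity(vs, vd)) {
  if (any(vm <= 0)) stop_nm("PI undefined for non-positive mean velocity")
  (vs - vd) / vm
}

summarize_beats <- function(bs, convention) {
  b <- bs$beats
  vm_i <- mean_velocity(b$vs, b$vd)
  pi_i <- pulsatility_index(b$vs, b$vd, vm_i)
  if (convention == "per_beat")
    data.frame(vs = mean(b$vs), vd = mean(b$vd), vm = mean(vm_i),
               pi = mean(pi_i), n_beats = nrow(b))
  else {
    vs <- mean(b$vs); vd <- mean(b$vd); vm <- mean_velocity(vs, vd)
    data.frame(vs = vs, vd = vd, vm = vm,
               pi = pulsatility_index(vs, vd, vm), n_beats = nrow(b))
  }
}

#' Bilateral hemisphere TCD summary
#'
#' Averages per-beat indices per side and labels the sides by the hematoma
#' location: the affected hemisphere carries the clot (indices AVs, AVd,
#' AVm, API), the contralateral one is unaffected (UVs, UVd, UVm, UPI).
#' By default Vm and PI are computed per beat and then averaged (the
#' clinical convention; a ratio of averaged Vs/Vd is available via
#' `convention = "ratio_of_means"` — mean-of-ratios and ratio-of-means
#' differ whenever beats vary).
#'
#' @param beats_left,beats_right [beat_set][detect_beats] per side; either
#'   may be `NULL`, giving a flagged unilateral result.
#' @param hematoma_side `"left"` or `"right"`.
#' @param convention `"per_beat"` (default) or `"ratio_of_means"`.
#' @return Object of class `tcd_indices`: data.frame `sides` (one row per
#'   available side with vs, vd, vm, pi, role), `affected_side`, named
#'   vector `indices` with the AVs/AVd/AVm/API/UVs/UVd/UVm/UPI labels that
#'   are available, and `unilateral` flag.
#' @export
hemisphere_summary <- function(beats_left, beats_right,
                               hematoma_side = c("left", "right"),
                               convention = c("per_beat", "ratio_of_means")) {
  hematoma_side <- match.arg(hematoma_side)
  convention <- match.arg(convention)
  if (is.null(beats_left) && is.null(beats_right))
    stop_nm("at least one side's beats required")
  rows <- list()
  for (side in c("left", "right")) {
    bs <- if (side == "left") beats_left else beats_right
    if (is.null(bs)) next
    stopifnot(inherits(bs, "beat_set"))
    r <- summarize_beats(bs, convention)
    r$side <- side
    r$role <- if (side == hematoma_side) "affected" else "unaffected"
    rows[[side]] <- r
  }
  sides <- do.call(rbind, rows)
  idx <- c()
  for (k in seq_len(nrow(sides))) {
    pre <- if (sides$role[k] == "affected") "A" else "U"
    v <- c(sides$vs[k], sides$vd[k], sides$vm[k], sides$pi[k])
    names(v) <- paste0(pre, c("Vs", "Vd", "Vm", "PI"))
    idx <- c(idx, v)
  }
  structure(list(sides = sides, affected_side = hematoma_side,
                 indices = idx, convention = convention,
                 unilateral = nrow(sides) < 2),
            class = "tcd_indices")
}

#' @export
print.tcd_indices <- function(x, ...) {
  cat(sprintf("<tcd_indices> affected side: %s%s\n", x$affected_side,
              if (x$unilateral) " [UNILATERAL]" else ""))
  print(round(x$indices, 3))
  invisible(x)
}
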