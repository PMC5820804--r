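#' Write / read an EEG recording as annotated text
#'
#' Plain-text multichannel signal format: `#`-prefixed `key: value` header
#' lines (sampling rate, channel labels, units, free metadata) followed by
#' a tab-separated samples-by-channels matrix. Human-readable, loss limited
#' to the printed precision (15 significant digits).
#'
#' @param rec an [eeg_recording].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eeg_txt <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# format: neuromon-eeg-text v1",
               paste0("# fs_hz: ", format(rec$fs, digits = 15)),
               paste0("# channels: ", paste(rec$channel_labels, collapse = ",")),
               "# units: uV"), con)
  for (nm in names(rec$meta)) {
    v <- rec$meta[[nm]]
    if (is.atomic(v) && length(v) < 10)
      writeLines(paste0("# meta.", nm, ": ", paste(format(v, digits = 15),
                                                   collapse = ",")), con)
  }
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_txt
#' @param must_exist unused, reserved.
#' @export
read_eeg_txt <- function(path, must_exist = TRUE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  fs <- get("fs_hz")
  if (is.null(fs)) stop_nm("missing sampling rate (fs_hz) in header")
  labels <- strsplit(get("channels") %||%
                       stop_nm("missing channel labels in header"), ",")[[1]]
  if (anyDuplicated(labels)) stop_nm("duplicate channel labels in file")
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  if (ncol(dat) != length(labels))
    stop_nm("column count does not match channel labels")
  known <- labels %in% ten_twenty_16()
  meta <- list(source = path)
  if (!all(known)) meta$unknown_channels <- labels[!known]
  eeg_recording(t(as.matrix(dat)), as.numeric(fs), labels, meta = meta)
}

#' Write / read a Doppler velocity envelope as CSV
#'
#' Two-column CSV `time,velocity` (seconds, cm/s). On reading, the
#' sampling rate is inferred from the median timestamp increment.
#'
#' @param env a [tcd_envelope].
#' @param path CSV file.
#' @return `path` invisibly (write); a [tcd_envelope] (read).
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "tcd_envelope"))
  df <- data.frame(time = (seq_along(env$velocity) - 1) / env$fs,
                   velocity = env$velocity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @param side envelope side, `"left"` or `"right"`.
#' @param insonation_depth optional probe depth, mm.
#' @export
read_envelope_csv <- function(path, side = "left", insonation_depth = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time", "velocity") %in% names(df)))
    stop_nm("envelope CSV needs 'time' and 'velocity' columns")
  dt <- stats::median(diff(df$time))
  if (!is.finite(dt) || dt <= 0) stop_nm("cannot infer sampling rate from timestamps")
  tcd_envelope(df$velocity, fs = 1 / dt, side = side,
               insonation_depth = insonation_depth,
               meta = list(source = path))
}

#' Cohort CSV column dictionary
#'
#' Single source of truth for the cohort table layout: one row per column
#' with its unit and meaning. [write_cohort_csv()] stores exactly these
#' columns; unknown columns on read raise an error.
#'
#' @return data.frame with `column`, `unit`, `description`.
#' @export
cohort_column_dictionary <- function() {
  d <- function(column, unit, description)
    data.frame(column = column, unit = unit, description = description)
  rbind(
    d("id", "-", "1-based patient identifier"),
    d("died90", "logical", "dead at 90-day follow-up"),
    d("age", "years", "age at admission"),
    d("male", "logical", "male sex"),
    d("hypertension", "logical", "history of hypertension"),
    d("diabetes", "logical", "diabetes mellitus"),
    d("hyperlipidemia", "logical", "hyperlipidemia"),
    d("coronary_disease", "logical", "coronary heart disease"),
    d("smoking", "logical", "current smoking"),
    d("excessive_drinking", "logical", "excessive alcohol use"),
    d("onset_to_monitor", "h", "ictus to start of monitoring"),
    d("gcs", "points", "admission Glasgow Coma Scale (3-15)"),
    d("sbp", "mmHg", "systolic blood pressure"),
    d("dbp", "mmHg", "diastolic blood pressure"),
    d("wbc", "1e9/L", "white blood cell count"),
    d("platelet", "1e9/L", "platelet count"),
    d("aptt", "s", "activated partial thromboplastin time"),
    d("inr", "-", "international normalized ratio"),
    d("glucose", "mmol/L", "serum glucose"),
    d("potassium", "mmol/L", "serum potassium"),
    d("calcium", "mmol/L", "serum calcium (as printed in the source table)"),
    d("sodium", "mmol/L", "serum sodium (as printed in the source table)"),
    d("hematoma_side_left", "logical", "hematoma in left hemisphere"),
    d("location_deep", "logical", "deep (vs lobar) hematoma"),
    d("hematoma_volume", "cm3", "clot volume, length x width x depth / 2 or 3"),
    d("ivh", "logical", "intraventricular extension"),
    d("avs", "cm/s", "affected-side systolic velocity"),
    d("uvs", "cm/s", "unaffected-side systolic velocity"),
    d("avm", "cm/s", "affected-side mean velocity"),
    d("uvm", "cm/s", "unaffected-side mean velocity"),
    d("avd", "cm/s", "affected-side diastolic velocity"),
    d("uvd", "cm/s", "unaffected-side diastolic velocity"),
    d("api", "-", "affected-side pulsatility index"),
    d("upi", "-", "unaffected-side pulsatility index"),
    d("rdp", "%", "relative delta power"),
    d("rtp", "%", "relative theta power"),
    d("rap", "%", "relative alpha power"),
    d("rbp", "%", "relative beta power"),
    d("dar", "-", "delta/alpha power ratio"),
    d("dtabr", "-", "(delta+theta)/(alpha+beta) power ratio"),
    d("bsi", "-", "brain symmetry index")
  )
}

#' Write / read a cohort table as CSV
#'
#' RFC-4180 CSV restricted to the columns of [cohort_column_dictionary()];
#' unknown columns raise an error on read rather than passing silently.
#'
#' @param records cohort data.frame.
#' @param path CSV file.
#' @return `path` invisibly (write); the cohort data.frame (read).
#' @export
write_cohort_csv <- function(records, path) {
  unknown <- setdiff(names(records), cohort_column_dictionary()$column)
  if (length(unknown)) stop_nm("columns not in the dictionary: ",
                               paste(unknown, collapse = ", "))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  dict <- cohort_column_dictionary()
  unknown <- setdiff(names(df), dict$column)
  if (length(unknown)) stop_nm("unknown cohort column(s): ",
                               paste(unknown, collapse = ", "))
  logicals <- dict$column[dict$unit == "logical"]
  for (nm in intersect(logicals, names(df))) df[[nm]] <- as.logical(df[[nm]])
  if (anyNA(df)) stop_nm("missing values in cohort table; imputation is not supported")
  df
}

#' Pipeline run configuration
#'
#' Validated bag of every tunable pipeline parameter, each with a recorded
#' default. Unknown arguments are errors, never silently ignored. The
#' configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param n_survivors,n_nonsurvivors synthetic cohort group sizes.
#' @param funnel named exclusion tallies for the screening stage.
#' @param n_enrolled_funnel eligible records in the screening roster.
#' @param eeg_fs,eeg_duration synthetic EEG sampling rate (Hz) and length (s).
#' @param epoch_len,overlap Welch parameters (s, fraction).
#' @param bandpass_low,bandpass_high filter edges, Hz.
#' @param amplitude_limit artifact rejection threshold, uV.
#' @param tcd_fs,tcd_duration,heart_rate synthetic envelope parameters.
#' @param min_rate,max_rate admissible beat-rate window, bpm.
#' @param tcd_convention `"per_beat"` or `"ratio_of_means"`.
#' @param selection_alpha univariate selection threshold.
#' @param removal_alpha backward-elimination retention threshold.
#' @param n_signal_patients how many enrolled patients get full synthetic
#'   signals regenerated and re-measured (0 = use tabulated indices only).
#' @param seed master RNG seed.
#' @param outdir output directory, or `NULL` for in-memory results only.
#' @return named list of class `run_config`.
#' @export
run_config <- function(n_survivors = 21, n_nonsurvivors = 26,
                       funnel = funnel_tallies(), n_enrolled_funnel = 47,
                       eeg_fs = 128, eeg_duration = 60,
                       epoch_len = 2, overlap = 0.5,
                       bandpass_low = 0.3, bandpass_high = 30,
                       amplitude_limit = 200,
                       tcd_fs = 100, tcd_duration = 30, heart_rate = 72,
                       min_rate = 40, max_rate = 150,
                       tcd_convention = "per_beat",
                       selection_alpha = 0.001, removal_alpha = 0.10,
                       n_signal_patients = 4, seed = 1, outdir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$funnel <- as.list(out$funnel)  # keep tally names through JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop_nm("unknown config key(s): ",
                               paste(unknown, collapse = ", "))
  if (!is.null(raw$funnel)) raw$funnel <- unlist(raw$funnel)
  do.call(run_config, raw)
}

# Hash of the analysis-relevant configuration (where outputs are written
# does not change what is computed).
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg$outdir <- NULL
  class(cfg) <- "run_config"
  write_run_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full monitoring-and-prognosis pipeline
#'
#' End-to-end orchestration on synthetic data: build the screening roster
#' and apply eligibility; generate the enrolled cohort; for a configurable
#' number of patients synthesize raw EEG and bilateral Doppler envelopes
#' from their tabulated indices and re-measure them through the QEEG and
#' TCD analysers (a generator-analyser consistency loop); run the
#' univariate screen; fit the backward stepwise logistic model on the
#' selected variables; and compare the five candidate prognostic models.
#' Deterministic given `cfg$seed`; when `cfg$outdir` is set, every CSV is
#' stamped with the configuration hash and a provenance JSON is written.
#'
#' @param cfg a [run_config].
#' @return list of class `pipeline_report`: `screening`, `cohort`,
#'   `signal_check` (measured vs tabulated indices, or NULL), `screen`
#'   (univariate table), `model` ([backward_logistic] result),
#'   `comparison` ([compare_five_models] result), `mortality_pct`,
#'   `provenance`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  seeds <- with_seed(cfg$seed, sample.int(2^31 - 1, 8))

  roster <- gen_screening_roster(cfg$funnel, cfg$n_enrolled_funnel)
  screening <- apply_eligibility(roster)

  cohort <- gen_cohort(cohort_gen_spec(cfg$n_survivors, cfg$n_nonsurvivors,
                                       seed = seeds[1]))
  mortality_pct <- 100 * mean(cohort$died90)

  signal_check <- NULL
  n_sig <- min(cfg$n_signal_patients, nrow(cohort))
  if (n_sig > 0) {
    rows <- lapply(seq_len(n_sig), function(i) {
      pt <- cohort[i, ]
      fr <- c(delta = pt$rdp, theta = pt$rtp, alpha = pt$rap, beta = pt$rbp)
      fr <- fr / sum(fr)
      eeg <- gen_eeg(eeg_gen_spec(fr, fs = cfg$eeg_fs,
                                  duration = cfg$eeg_duration,
                                  seed = seeds[2] %% 2^20 + i))
      qs <- qeeg_summary(eeg, low = cfg$bandpass_low, high = cfg$bandpass_high,
                         amplitude_limit = cfg$amplitude_limit,
                         epoch_len = cfg$epoch_len, overlap = cfg$overlap)
      mk_env <- function(vs, vd, side) {
        gen_tcd(tcd_gen_spec(vs, vd, heart_rate = cfg$heart_rate,
                             fs = cfg$tcd_fs, duration = cfg$tcd_duration,
                             seed = seeds[3] %% 2^20 + i), side = side)
      }
      aff <- if (isTRUE(pt$hematoma_side_left)) "left" else "right"
      una <- setdiff(c("left", "right"), aff)
      env_a <- mk_env(pt$avs, pt$avd, aff)
      env_u <- mk_env(pt$uvs, pt$uvd, una)
      beats <- list()
      beats[[aff]] <- detect_beats(env_a, cfg$min_rate, cfg$max_rate)
      beats[[una]] <- detect_beats(env_u, cfg$min_rate, cfg$max_rate)
      ti <- hemisphere_summary(beats$left, beats$right, hematoma_side = aff,
                               convention = cfg$tcd_convention)
      data.frame(id = pt$id,
                 dar_tgt = unname(fr["delta"] / fr["alpha"]), dar_meas = qs$dar,
                 rdp_tgt = unname(fr["delta"]), rdp_meas = qs$rdp,
                 upi_tgt = pulsatility_index(pt$uvs, pt$uvd),
                 upi_meas = unname(ti$indices["UPI"]),
                 bsi_meas = qs$bsi)
    })
    signal_check <- do.call(rbind, rows)
  }

  screen <- univariate_screen(cohort, outcome = "died90",
                              selection_alpha = cfg$selection_alpha)
  # Backward elimination can hit (quasi-)separation at enrollment-scale n
  # with several strong, correlated predictors; drop the offending variable
  # and refit rather than abort the whole run.
  selected <- screen$variable[screen$selected]
  model <- NULL
  while (length(selected)) {
    model <- tryCatch(
      backward_logistic(cohort, selected, outcome = "died90",
                        removal_alpha = cfg$removal_alpha),
      error = function(e) e)
    if (!inherits(model, "error")) break
    bad <- sub(".*offending variable: ", "", conditionMessage(model))
    if (!bad %in% selected)
      stop_nm("prognosis stage: ", conditionMessage(model))
    warning("prognosis stage: dropped '", bad, "' (", conditionMessage(model),
            ") and refitted")
    selected <- setdiff(selected, bad)
    model <- NULL
  }
  comparison <- compare_five_models(cohort)

  provenance <- list(config = unclass(cfg), config_hash = hash,
                     package_version = as.character(utils::packageVersion("neuromon")),
                     n_screened = screening$n_screened,
                     n_enrolled = screening$n_enrolled,
                     n_excluded = screening$n_excluded)

  report <- structure(list(screening = screening, cohort = cohort,
                           signal_check = signal_check, screen = screen,
                           model = model, comparison = comparison,
                           mortality_pct = mortality_pct,
                           provenance = provenance),
                      class = "pipeline_report")
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(cfg$outdir, f)
    write_stamped_csv(cohort, fp("cohort.csv"), hash)
    write_stamped_csv(screen, fp("univariate_screen.csv"), hash)
    write_stamped_csv(comparison$aucs, fp("model_aucs.csv"), hash)
    write_stamped_csv(comparison$comparisons, fp("delong_tests.csv"), hash)
    if (!is.null(model))
      write_stamped_csv(model$coefficients, fp("logistic_model.csv"), hash)
    if (!is.null(signal_check))
      write_stamped_csv(signal_check, fp("signal_check.csv"), hash)
    jsonlite::write_json(provenance, fp("provenance.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  screened %d, excluded %d, enrolled %d; 90-day mortality %.1f%%\n",
              x$screening$n_screened, x$screening$n_excluded,
              x$screening$n_enrolled, x$mortality_pct))
  cat(sprintf("  univariate screen: %d of %d variables selected (p <= %g)\n",
              sum(x$screen$selected), nrow(x$screen),
              x$provenance$config$selection_alpha))
  if (!is.null(x$model))
    cat("  logistic model retained:",
        paste(x$model$retained, collapse = ", "), "\n")
  print(x$comparison)
  invisible(x)
}
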