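# Fiducial-point detection and the pulse-morphology feature registry.
# Each quality-passing pulse yields one fixed-order named feature vector,
# computed on both the raw pulse and its MODWT-enhanced version.

#' Detect the five characteristic points of a PPG pulse
#'
#' Landmarks: max-slope point (argmax of the first derivative before the
#' systolic peak), systolic peak (global maximum), dicrotic notch (first
#' local minimum after the peak, falling back to the second-derivative
#' maximum when no distinct notch exists), inflection point (zero crossing
#' of the second derivative between notch and diastolic peak, falling back
#' to the notch), and diastolic peak (first local maximum after the notch,
#' falling back to the inflection point). Also extracts the a-e waves of
#' the second-derivative PPG (SDPPG). Derivatives are central differences
#' after light Savitzky-Golay smoothing.
#'
#' @param pulse Numeric pulse samples (one beat, foot to foot).
#' @param fs Sampling rate in Hz.
#' @return Object of class `fiducial_points`: list of 1-based indices and
#'   amplitudes per landmark, plus `sdppg` (a-e indices/amplitudes).
#' @export
detect_fiducials <- function(pulse, fs) {
  n <- length(pulse)
  if (n < 16) stop("fiducials not found: pulse too short")
  sm <- if (n >= 11) as.numeric(signal::sgolayfilt(pulse, p = 3, n = 9)) else pulse
  d1 <- c(0, diff(sm))
  d2 <- c(0, diff(d1))

  sys_peak <- which.max(pulse)
  if (sys_peak <= 2 || sys_peak >= n - 2) {
    stop("fiducials not found: systolic peak at pulse border")
  }
  if (sys_peak > 0.6 * n) {
    stop("fiducials not found: systolic peak too late (systole precedes diastole)")
  }
  max_slope <- which.max(d1[seq_len(sys_peak - 1)])

  is_min <- function(i) pulse[i] <= pulse[i - 1] && pulse[i] < pulse[i + 1]
  is_max <- function(i) pulse[i] >= pulse[i - 1] && pulse[i] > pulse[i + 1]
  notch <- NA_integer_
  if (sys_peak + 1 <= n - 1) {
    for (i in (sys_peak + 1):(n - 1)) if (is_min(i)) { notch <- i; break }
  }
  if (is.na(notch)) {                   # fallback: max curvature after peak
    win <- (sys_peak + 2):(n - 1)
    if (length(win) < 1) stop("fiducials not found: no post-peak region")
    notch <- win[which.max(d2[win])]
  }
  dias <- NA_integer_
  if (notch + 1 <= n - 1) {
    for (i in (notch + 1):(n - 1)) if (is_max(i)) { dias <- i; break }
  }
  infl <- notch
  hi <- if (is.na(dias)) n - 1 else dias
  if (hi - 1 >= notch) {
    for (i in notch:(hi - 1)) {
      if (d2[i] > 0 && d2[i + 1] <= 0) { infl <- i + 1; break }
    }
  }
  if (is.na(dias)) dias <- infl         # fallback: no distinct diastolic peak
  if (!(max_slope < sys_peak && sys_peak < notch && notch <= infl &&
        infl <= dias)) {
    stop("fiducials not found: landmark ordering violated")
  }

  # SDPPG a-e waves: alternating extrema of the second derivative
  sd_idx <- rep(NA_integer_, 5)
  names(sd_idx) <- c("a", "b", "c", "d", "e")
  seek <- function(from, to, maximum) {
    if (from > to) return(NA_integer_)
    w <- from:to
    w[if (maximum) which.max(d2[w]) else which.min(d2[w])]
  }
  sd_idx["a"] <- seek(2L, sys_peak, TRUE)
  sd_idx["b"] <- seek(sd_idx["a"] + 1L, min(notch, n - 1L), FALSE)
  prev <- sd_idx["b"]
  for (wn in c("c", "d", "e")) {
    if (is.na(prev)) break
    sd_idx[wn] <- seek(prev + 1L, n - 1L, wn %in% c("c", "e"))
    prev <- sd_idx[wn]
  }
  for (wn in names(sd_idx)) if (is.na(sd_idx[wn])) sd_idx[wn] <- notch

  idx <- c(max_slope = max_slope, systolic_peak = sys_peak,
           dicrotic_notch = notch, inflection_point = infl,
           diastolic_peak = dias)
  structure(
    list(index = idx, amplitude = stats::setNames(pulse[idx], names(idx)),
         sdppg = list(index = sd_idx,
                      amplitude = stats::setNames(d2[sd_idx], names(sd_idx))),
         fs = fs, n = n),
    class = "fiducial_points"
  )
}

.moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  list(mean = m, sd = sqrt(v),
       skewness = if (v > 0) mean((x - m)^3) / v^1.5 else 0,
       kurtosis = if (v > 0) mean((x - m)^4) / v^2 else 0)
}

.trapz <- function(y, dt) if (length(y) < 2) 0 else dt * (sum(y) - (y[1] + y[length(y)]) / 2)

# Pulse width (s) at a relative height of the normalized pulse.
.width_at <- function(pulse, frac, fs) {
  rng <- range(pulse)
  if (diff(rng) == 0) return(0)
  rel <- (pulse - rng[1]) / diff(rng)
  sum(rel >= frac) / fs
}

# The per-pulse half of the registry; `prefix` is "raw_" or "enh_".
.pulse_feature_block <- function(pulse, fid, fs, prefix) {
  n <- length(pulse)
  dt <- 1 / fs
  idx <- fid$index
  amp <- fid$amplitude
  base <- min(pulse)
  height <- max(pulse) - base
  tsec <- (idx - 1) / fs

  sm <- if (n >= 11) as.numeric(signal::sgolayfilt(pulse, p = 3, n = 9)) else pulse
  d1 <- c(0, diff(sm)) * fs
  d2 <- c(0, diff(c(0, diff(sm)))) * fs^2
  sd_amp <- unname(fid$sdppg$amplitude) * fs^2
  sd_t <- unname(fid$sdppg$index - 1) / fs
  a_amp <- sd_amp[1]

  notch <- idx[["dicrotic_notch"]]
  area_sys <- .trapz(pulse[1:notch], dt)
  area_dia <- .trapz(pulse[notch:n], dt)
  area_tot <- .trapz(pulse, dt)

  mom <- .moments(pulse)
  qs <- stats::quantile(pulse, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  spec <- stats::fft(pulse - mean(pulse))
  nh <- 5L
  harm <- if (n >= 2 * (nh + 1)) spec[2:(nh + 1)] else rep(0+0i, nh)
  mags <- Mod(harm) / n
  phases <- Arg(harm)
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  pw <- Mod(spec[seq_len(floor(n / 2))])^2
  centroid <- if (sum(pw) > 0) sum(freqs * pw) / sum(pw) else 0

  v <- c(
    # amplitudes at the fiducials
    amp_max_slope = amp[["max_slope"]],
    amp_systolic_peak = amp[["systolic_peak"]],
    amp_dicrotic_notch = amp[["dicrotic_notch"]],
    amp_inflection = amp[["inflection_point"]],
    amp_diastolic_peak = amp[["diastolic_peak"]],
    pulse_height = height,
    ratio_diastolic_systolic = if (height > 0)
      (amp[["diastolic_peak"]] - base) / height else 0,
    ratio_notch_systolic = if (height > 0)
      (amp[["dicrotic_notch"]] - base) / height else 0,
    # times and durations (s)
    t_max_slope = tsec[["max_slope"]],
    t_systolic_peak = tsec[["systolic_peak"]],
    t_dicrotic_notch = tsec[["dicrotic_notch"]],
    t_inflection = tsec[["inflection_point"]],
    t_diastolic_peak = tsec[["diastolic_peak"]],
    duration = n / fs,
    dt_systolic_diastolic = tsec[["diastolic_peak"]] - tsec[["systolic_peak"]],
    t_peak_to_end = (n - idx[["systolic_peak"]]) / fs,
    frac_systolic_time = idx[["systolic_peak"]] / n,
    width_25 = .width_at(pulse, 0.25, fs),
    width_50 = .width_at(pulse, 0.50, fs),
    width_75 = .width_at(pulse, 0.75, fs),
    upstroke_slope = if (tsec[["systolic_peak"]] > 0)
      (amp[["systolic_peak"]] - pulse[1]) / tsec[["systolic_peak"]] else 0,
    downstroke_slope = (pulse[n] - amp[["systolic_peak"]]) /
      max((n - idx[["systolic_peak"]]) / fs, dt),
    # areas (trapezoidal, split at the dicrotic notch)
    area_total = area_tot,
    area_systolic = area_sys,
    area_diastolic = area_dia,
    ratio_area_sys_total = if (area_tot != 0) area_sys / area_tot else 0,
    ratio_area_dia_total = if (area_tot != 0) area_dia / area_tot else 0,
    ratio_area_sys_dia = if (area_dia != 0) area_sys / area_dia else 0,
    # non-linear: natural log of the 0-based landmark positions, ln(1 + i)
    log_notch_position = log1p(idx[["dicrotic_notch"]] - 1),
    log_inflection_position = log1p(idx[["inflection_point"]] - 1),
    # sample statistics
    stat_mean = mom$mean,
    stat_sd = mom$sd,
    stat_skewness = mom$skewness,
    stat_kurtosis = mom$kurtosis,
    stat_rms = sqrt(mean(pulse^2)),
    stat_iqr = qs[4] - qs[2],
    stat_p10 = qs[1], stat_p25 = qs[2], stat_p50 = qs[3],
    stat_p75 = qs[4], stat_p90 = qs[5],
    # first derivative
    d1_max = max(d1), d1_min = min(d1),
    d1_mean_abs = mean(abs(d1)), d1_sd = stats::sd(d1),
    t_d1_max = (which.max(d1) - 1) / fs,
    t_d1_min = (which.min(d1) - 1) / fs,
    d1_ratio = if (min(d1) != 0) max(d1) / abs(min(d1)) else 0,
    # second derivative and SDPPG a-e waves
    d2_max = max(d2), d2_min = min(d2), d2_sd = stats::sd(d2),
    sdppg_a = sd_amp[1], sdppg_b = sd_amp[2], sdppg_c = sd_amp[3],
    sdppg_d = sd_amp[4], sdppg_e = sd_amp[5],
    t_sdppg_a = sd_t[1], t_sdppg_b = sd_t[2], t_sdppg_c = sd_t[3],
    t_sdppg_d = sd_t[4], t_sdppg_e = sd_t[5],
    sdppg_b_a = if (a_amp != 0) sd_amp[2] / a_amp else 0,
    sdppg_c_a = if (a_amp != 0) sd_amp[3] / a_amp else 0,
    sdppg_d_a = if (a_amp != 0) sd_amp[4] / a_amp else 0,
    sdppg_e_a = if (a_amp != 0) sd_amp[5] / a_amp else 0,
    # frequency domain: first five DFT harmonics of the single pulse
    fft_mag1 = mags[1], fft_mag2 = mags[2], fft_mag3 = mags[3],
    fft_mag4 = mags[4], fft_mag5 = mags[5],
    fft_phase1 = phases[1], fft_phase2 = phases[2], fft_phase3 = phases[3],
    fft_phase4 = phases[4], fft_phase5 = phases[5],
    fft_centroid = centroid
  )
  names(v) <- paste0(prefix, names(v))
  v
}

#' Extract the full feature vector for one pulse
#'
#' Computes the registry block on the raw pulse and again on its
#' MODWT-enhanced version, plus the shared beat-rate features. The
#' registry is fixed-order; see [feature_registry()].
#'
#' @param raw_pulse Preprocessed pulse samples.
#' @param enhanced_pulse Output of [enhance_pulse()] on the same pulse
#'   (computed when `NULL`).
#' @param fid Optional [detect_fiducials()] result for the raw pulse.
#' @param fs Sampling rate in Hz.
#' @param modwt_config List with `wavelet`, `levels`, `drop_levels` for the
#'   enhancement when `enhanced_pulse` is `NULL`.
#' @return Named numeric vector (the feature registry).
#' @export
extract_features <- function(raw_pulse, enhanced_pulse = NULL, fid = NULL,
                             fs = 125,
                             modwt_config = list(wavelet = "sym4",
                                                 levels = 4,
                                                 drop_levels = 1L)) {
  if (is.null(enhanced_pulse)) {
    enhanced_pulse <- enhance_pulse(raw_pulse,
                                    wavelet = modwt_config$wavelet,
                                    levels = modwt_config$levels,
                                    drop_levels = modwt_config$drop_levels)
  }
  if (is.null(fid)) fid <- detect_fiducials(raw_pulse, fs)
  fid_enh <- detect_fiducials(as.numeric(enhanced_pulse), fs)
  c(.pulse_feature_block(raw_pulse, fid, fs, "raw_"),
    .pulse_feature_block(as.numeric(enhanced_pulse), fid_enh, fs, "enh_"),
    beat_period_s = length(raw_pulse) / fs,
    beat_rate_bpm = 60 * fs / length(raw_pulse))
}

#' The feature registry manifest
#'
#' Names, families and units of every feature, in registry order.
#' @return Data frame with columns `name`, `family`, `units`.
#' @export
feature_registry <- function() {
  block <- function(prefix) {
    nm <- names(.pulse_feature_block(.registry_probe_pulse,
                                     detect_fiducials(.registry_probe_pulse, 125),
                                     125, prefix))
    fam <- vapply(nm, function(x) {
      x <- sub("^(raw|enh)_", "", x)
      if (grepl("^amp_|^pulse_height|^ratio_diastolic|^ratio_notch", x)) "amplitude"
      else if (grepl("^t_sdppg|^sdppg|^d2_", x)) "second_derivative"
      else if (grepl("^t_|^duration|^dt_|^frac|^width", x)) "time"
      else if (grepl("^upstroke|^downstroke|^d1_", x)) "first_derivative"
      else if (grepl("^area|^ratio_area", x)) "area"
      else if (grepl("^log_", x)) "nonlinear"
      else if (grepl("^stat_", x)) "statistics"
      else if (grepl("^fft_", x)) "frequency"
      else "other"
    }, character(1))
    unit <- vapply(nm, function(x) {
      x <- sub("^(raw|enh)_", "", x)
      if (grepl("^t_|^duration|^dt_|^width", x)) "s"
      else if (grepl("^area", x)) "a.u.*s"
      else if (grepl("^fft_phase", x)) "rad"
      else if (grepl("^fft_centroid", x)) "Hz"
      else if (grepl("^frac|^ratio|^log|^sdppg_[bcde]_a", x)) "dimensionless"
      else "a.u."
    }, character(1))
    data.frame(name = nm, family = unname(fam), units = unname(unit))
  }
  rbind(block("raw_"), block("enh_"),
        data.frame(name = c("beat_period_s", "beat_rate_bpm"),
                   family = "time", units = c("s", "1/min")))
}

# deterministic probe pulse used to enumerate registry names
.registry_probe_pulse <- local({
  t <- (0:99) / 100
  exp(-0.5 * ((t - 0.28) / 0.095)^2) + 0.42 * exp(-0.5 * ((t - 0.60) / 0.12)^2) +
    0.25 * exp(-0.5 * ((t - 0.45) / 0.28)^2)
})

#' Build the feature table from labeled pulses
#'
#' One row per pulse: identifiers, targets (`sbp`, `dbp`) and the full
#' feature registry. Pulses whose fiducial cascade fails or that produce
#' any non-finite feature are dropped and counted in attribute `n_dropped`.
#'
#' @param pulses Data frame from [process_record()] (needs list-column
#'   `ppg_samples` plus `sbp`, `dbp`).
#' @param fs Sampling rate in Hz.
#' @param subject_id Identifier copied into each row.
#' @param modwt_config Enhancement configuration, see [extract_features()].
#' @return Data frame; attribute `n_dropped` counts excluded pulses.
#' @export
build_feature_table <- function(pulses, fs = 125, subject_id = "synthetic",
                                modwt_config = list(wavelet = "sym4",
                                                    levels = 4,
                                                    drop_levels = 1L)) {
  empty <- function() {
    out <- data.frame(subject_id = character(0), pulse_index = integer(0),
                      sbp = numeric(0), dbp = numeric(0))
    attr(out, "n_dropped") <- 0L
    out
  }
  if (nrow(pulses) == 0) return(empty())
  rows <- vector("list", nrow(pulses))
  dropped <- 0L
  for (i in seq_len(nrow(pulses))) {
    fv <- tryCatch(
      extract_features(pulses$ppg_samples[[i]], fs = fs,
                       modwt_config = modwt_config),
      error = function(e) NULL
    )
    if (is.null(fv) || !all(is.finite(fv))) { dropped <- dropped + 1L; next }
    rows[[i]] <- c(sbp = pulses$sbp[i], dbp = pulses$dbp[i], fv)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(empty())
  mat <- do.call(rbind, rows[keep])
  out <- data.frame(subject_id = subject_id,
                    pulse_index = pulses$pulse_index[keep], mat,
                    check.names = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Names of the feature columns of a feature table
#'
#' @param table A feature table.
#' @return Character vector: every numeric column except identifiers and
#'   targets.
#' @export
feature_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("sbp", "dbp", "pulse_index"))
}
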