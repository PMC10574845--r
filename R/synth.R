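# Synthetic paired PPG/ABP waveform generator with analytic ground truth.
# One beat is a train of positive Gaussian bumps (systolic wave, diastolic
# wave, optional extra bump); the ABP beat is a skewed copy of the bump
# train mapped affinely onto [DBP, SBP] with an explicit dicrotic notch.
# Every downstream stage (alignment, segmentation, fiducials, labels) can
# therefore be tested against known truth without any data download.

#' Pulse-shape parameters for one synthetic beat
#'
#' @param period_s Beat period in seconds.
#' @param ppg_components List of `c(amplitude, center, width)` triples, the
#'   Gaussian bumps making up the PPG beat. Centers and widths are
#'   fractions of the period. At least two components (systolic and
#'   diastolic waves) are required for a non-degenerate morphology.
#' @param abp_sbp,abp_dbp Target systolic/diastolic pressure in mmHg. The
#'   generated ABP beat spans exactly `[abp_dbp, abp_sbp]`. Defaults to the
#'   physiologic study ranges SBP 80-180, DBP 60-110.
#' @param notch_depth Depth of the carved ABP dicrotic notch as a fraction
#'   of pulse amplitude.
#' @param notch_time Notch center as a fraction of the period.
#' @param range_check When `TRUE` (default) enforce 80 <= SBP <= 180 and
#'   60 <= DBP <= 110.
#' @return Object of class `pulse_shape_params`.
#' @export
pulse_shape_params <- function(period_s = 0.8,
                               ppg_components = list(c(1.00, 0.28, 0.095),
                                                     c(0.42, 0.60, 0.120),
                                                     c(0.25, 0.45, 0.280)),
                               abp_sbp = 120, abp_dbp = 80,
                               notch_depth = 0.12, notch_time = 0.45,
                               range_check = TRUE) {
  vals <- c(period_s, abp_sbp, abp_dbp, notch_depth, notch_time,
            unlist(ppg_components))
  if (any(!is.finite(vals))) stop("non-finite pulse parameter")
  if (period_s <= 0) stop("period_s must be positive")
  if (length(ppg_components) < 2) {
    stop("degenerate morphology: need at least systolic and diastolic components")
  }
  for (cmp in ppg_components) {
    if (length(cmp) != 3 || cmp[1] <= 0 || cmp[3] <= 0) {
      stop("each PPG component must be c(amplitude > 0, center, width > 0)")
    }
  }
  if (abp_sbp <= abp_dbp) stop("abp_sbp must exceed abp_dbp")
  if (range_check && (abp_sbp < 80 || abp_sbp > 180)) {
    stop("abp_sbp outside [80, 180] mmHg (set range_check = FALSE to override)")
  }
  if (range_check && (abp_dbp < 60 || abp_dbp > 110)) {
    stop("abp_dbp outside [60, 110] mmHg (set range_check = FALSE to override)")
  }
  structure(list(period_s = period_s, ppg_components = ppg_components,
                 abp_sbp = abp_sbp, abp_dbp = abp_dbp,
                 notch_depth = notch_depth, notch_time = notch_time),
            class = "pulse_shape_params")
}

.bump_train <- function(t, components, center_shift = 0, width_scale = 1) {
  out <- numeric(length(t))
  for (cmp in components) {
    out <- out + cmp[1] * exp(-0.5 * ((t - (cmp[2] + center_shift)) /
                                        (cmp[3] * width_scale))^2)
  }
  out
}

# One ABP beat over fractional time t in [0, 1): a broadened, skewed copy
# of the PPG bump train plus a linear diastolic runoff (so the pressure
# minimum sits at end-diastole, just before the next upstroke), with the
# dicrotic notch carved at notch_time, mapped affinely onto [DBP, SBP].
.abp_beat <- function(t, params, runoff = 0.15) {
  shape <- .bump_train(t, params$ppg_components, width_scale = 1.15) +
    runoff * (1 - t)
  shape <- shape - params$notch_depth * max(shape) *
    exp(-0.5 * ((t - params$notch_time) / 0.02)^2)
  rng <- range(shape)
  params$abp_dbp + (params$abp_sbp - params$abp_dbp) *
    (shape - rng[1]) / (rng[2] - rng[1])
}

# Landmark scan on a noiseless beat: max-slope, systolic peak, dicrotic
# notch, inflection point, diastolic peak (1-based sample indices).
.scan_landmarks <- function(x) {
  n <- length(x)
  sys_peak <- which.max(x)
  d1 <- diff(x)
  max_slope <- which.max(d1[seq_len(max(sys_peak - 1, 1))])
  # first local minimum after the systolic peak
  notch <- NA_integer_
  for (i in (sys_peak + 1):(n - 1)) {
    if (i < 2) break
    if (x[i] <= x[i - 1] && x[i] < x[i + 1]) { notch <- i; break }
  }
  if (is.na(notch)) stop("degenerate morphology: no dicrotic notch found")
  dias <- NA_integer_
  if (notch + 1 <= n - 1) {
    for (i in (notch + 1):(n - 1)) {
      if (x[i] >= x[i - 1] && x[i] > x[i + 1]) { dias <- i; break }
    }
  }
  if (is.na(dias)) stop("degenerate morphology: no diastolic peak found")
  # inflection: sign change of the second derivative between notch and peak
  d2 <- diff(x, differences = 2)         # d2[i] ~ x''(i + 1)
  infl <- notch
  if (dias - 1 >= notch) {
    for (i in notch:(dias - 1)) {
      j <- i - 1                          # index into d2 for sample i
      if (j >= 1 && j + 1 <= length(d2) && d2[j] > 0 && d2[j + 1] <= 0) {
        infl <- i + 1
        break
      }
    }
  }
  list(max_slope = max_slope, systolic_peak = sys_peak,
       dicrotic_notch = notch, inflection_point = infl,
       diastolic_peak = dias)
}

#' Generate one synthetic PPG/ABP beat
#'
#' @param params A [pulse_shape_params()] object.
#' @param fs Sampling rate in Hz.
#' @return List with `ppg`, `abp` (each `round(period_s * fs)` samples; ABP
#'   spans exactly `[abp_dbp, abp_sbp]` mmHg) and `fiducials`, the 1-based
#'   indices of the five PPG landmarks found by exhaustive scan of the
#'   noiseless waveform.
#' @export
generate_pulse <- function(params, fs = 125) {
  stopifnot(inherits(params, "pulse_shape_params"))
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  n <- round(params$period_s * fs)
  if (n < 8) stop("period too short for the sampling rate")
  t <- (seq_len(n) - 1) / n             # fraction of period
  ppg <- .bump_train(t, params$ppg_components)
  list(ppg = ppg, abp = .abp_beat(t, params), fiducials = .scan_landmarks(ppg))
}

#' Record-level specification for the synthetic generator
#'
#' Defaults emulate a resting adult at 75 bpm sampled at 125 Hz with a
#' slow sinusoidal blood-pressure trend plus per-beat jitter (so the
#' regression targets vary), respiratory-like baseline drift on the PPG
#' channel, and additive white Gaussian noise on both channels.
#'
#' @param n_beats Number of beats (>= 1).
#' @param fs Sampling rate in Hz (study default 125).
#' @param base_params [pulse_shape_params()] supplying the base morphology
#'   and the mean SBP/DBP.
#' @param sbp_trend_amp,dbp_trend_amp Amplitude (mmHg) of the slow
#'   sinusoidal SBP/DBP trend across beats.
#' @param trend_period_beats Period of that trend in beats.
#' @param bp_jitter_sd Per-beat SBP/DBP jitter SD in mmHg.
#' @param noise_sd Additive white-noise SD (a.u. on PPG; mmHg on ABP).
#' @param drift_amplitude,drift_period_s Sinusoidal PPG baseline drift.
#' @param ppg_abp_lag_s Deliberate delay of the PPG stream relative to ABP
#'   in seconds (bounded by one beat period); exercises the aligner.
#' @param seed Integer RNG seed; fixed seed gives bitwise-identical records.
#' @return Object of class `record_spec`.
#' @export
record_spec <- function(n_beats = 50, fs = 125,
                        base_params = pulse_shape_params(),
                        sbp_trend_amp = 15, dbp_trend_amp = 8,
                        trend_period_beats = 40, bp_jitter_sd = 2,
                        noise_sd = 0, drift_amplitude = 0,
                        drift_period_s = 10, ppg_abp_lag_s = 0,
                        seed = 1L) {
  if (!is.finite(n_beats) || n_beats < 1) stop("n_beats must be >= 1")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(ppg_abp_lag_s) >= base_params$period_s) {
    stop("ppg_abp_lag_s must be smaller than one beat period")
  }
  structure(list(n_beats = as.integer(n_beats), fs = fs,
                 base_params = base_params, sbp_trend_amp = sbp_trend_amp,
                 dbp_trend_amp = dbp_trend_amp,
                 trend_period_beats = trend_period_beats,
                 bp_jitter_sd = bp_jitter_sd, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 ppg_abp_lag_s = ppg_abp_lag_s, seed = as.integer(seed)),
            class = "record_spec")
}

# Evaluate a function with a locally-seeded RNG, restoring global state.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic paired PPG/ABP record
#'
#' Concatenates per-beat waveforms (with slowly varying SBP/DBP and mild
#' BP-coupled PPG morphology), adds sinusoidal baseline drift to the PPG,
#' white Gaussian noise to both channels, and finally delays the PPG
#' stream by `ppg_abp_lag_s` (circular shift). Ground-truth onsets,
#' fiducials and per-beat SBP/DBP refer to the ABP timeline.
#'
#' @param spec A [record_spec()] object.
#' @return Object of class `synthetic_record`: list with `record` (a
#'   [waveform_record()]), `truth_onsets` (1-based beat start indices),
#'   `truth_fiducials` (per-beat landmark indices, record coordinates),
#'   `truth_sbp`, `truth_dbp` (mmHg), and `spec`.
#' @export
generate_record <- function(spec) {
  stopifnot(inherits(spec, "record_spec"))
  .with_seed(spec$seed, function() {
    bp <- spec$base_params
    nb <- spec$n_beats
    phase <- 2 * pi * (seq_len(nb) - 1) / spec$trend_period_beats
    sbp <- bp$abp_sbp + spec$sbp_trend_amp * sin(phase) +
      stats::rnorm(nb, 0, spec$bp_jitter_sd)
    dbp <- bp$abp_dbp + spec$dbp_trend_amp * sin(phase) +
      stats::rnorm(nb, 0, spec$bp_jitter_sd)
    sbp <- pmin(pmax(sbp, 80), 180)
    dbp <- pmin(pmax(dbp, 60), 110)
    dbp <- pmin(dbp, sbp - 10)           # generator never emits SBP <= DBP

    n_beat <- round(bp$period_s * spec$fs)
    n <- n_beat * nb
    buf <- 16L                          # slack for the zero-lag calibration
    ppg_full <- numeric(n + 2L * buf)
    abp <- numeric(n)
    t1 <- (seq_len(n_beat) - 1) / n_beat
    half <- floor(n_beat / 2)
    # beat waveform with its left tail and decaying right tail, so that
    # overlap-adding neighboring beats yields smooth feet
    t2 <- ((seq_len(2 * n_beat + half) - 1) - half) / n_beat
    for (i in seq_len(nb)) {
      # couple PPG morphology to the beat's pressures: overall amplitude
      # tracks pulse pressure, the diastolic wave tracks SBP/DBP
      comps <- bp$ppg_components
      amp_scale <- 0.75 + 0.5 * ((sbp[i] - dbp[i]) - 40) / 40
      comps <- lapply(comps, function(cmp) { cmp[1] <- cmp[1] * amp_scale; cmp })
      comps[[2]][1] <- comps[[2]][1] * (0.7 + 0.6 * (sbp[i] - 80) / 100)
      comps[[2]][3] <- comps[[2]][3] * (0.85 + 0.3 * (dbp[i] - 60) / 50)
      prm <- pulse_shape_params(period_s = bp$period_s, ppg_components = comps,
                                abp_sbp = sbp[i], abp_dbp = dbp[i],
                                notch_depth = bp$notch_depth,
                                notch_time = bp$notch_time)
      # PPG: overlap-add the beat with its tails, giving smooth feet
      pos <- (i - 1L) * n_beat + buf
      wf <- .bump_train(t2, prm$ppg_components)
      lo <- pos + 1L - half
      idx <- max(1L, lo):min(pos + 2L * n_beat, n + 2L * buf)
      ppg_full[idx] <- ppg_full[idx] + wf[idx - lo + 1L]
      abp[((i - 1L) * n_beat + 1L):((i - 1L) * n_beat + n_beat)] <-
        .abp_beat(t1, prm)
    }
    # calibrate the record's zero-lag convention: "aligned" means the
    # normalized cross-correlation between the channels peaks at lag 0, so
    # any residual morphological offset between the PPG and ABP beat
    # shapes is measured and removed before the requested lag is injected
    shift <- 0L
    for (it in 1:3) {
      ppg <- ppg_full[(buf + 1L + shift):(buf + n + shift)]
      eps <- .best_lag(abp, ppg, -(buf - 2L):(buf - 2L))
      if (eps == 0L) break
      shift <- max(-buf, min(buf, shift + eps))
    }
    ppg <- ppg_full[(buf + 1L + shift):(buf + n + shift)]
    # ground truth by exhaustive scan of the noiseless streams: the foot
    # (onset) is the local minimum near each nominal beat boundary, and the
    # five fiducials are the landmarks of each foot-to-foot PPG segment
    onsets <- integer(nb)
    onsets[1] <- 1L
    w <- max(2L, round(0.1 * n_beat))
    for (i in 2:nb) {
      b <- (i - 1L) * n_beat + 1L
      win <- max(1L, b - w):min(n, b + w)
      onsets[i] <- win[which.min(ppg[win])]
    }
    fids <- vector("list", nb)
    for (i in seq_len(nb)) {
      s <- onsets[i]
      e <- if (i < nb) onsets[i + 1] - 1L else n
      fids[[i]] <- lapply(.scan_landmarks(ppg[s:e]), function(k) k + s - 1L)
    }
    truth_sbp <- vapply(seq_len(nb), function(i) {
      s <- onsets[i]; e <- if (i < nb) onsets[i + 1] - 1L else n
      max(abp[s:e])
    }, numeric(1))
    truth_dbp <- vapply(seq_len(nb), function(i) {
      s <- onsets[i]; e <- if (i < nb) onsets[i + 1] - 1L else n
      min(abp[s:e])
    }, numeric(1))
    tt <- (seq_len(n) - 1) / spec$fs
    if (spec$drift_amplitude > 0) {
      ppg <- ppg + spec$drift_amplitude * sin(2 * pi * tt / spec$drift_period_s)
    }
    if (spec$noise_sd > 0) {
      ppg <- ppg + stats::rnorm(n, 0, spec$noise_sd)
      abp <- abp + stats::rnorm(n, 0, spec$noise_sd)
    }
    k <- round(spec$ppg_abp_lag_s * spec$fs)
    if (k != 0) {
      k <- k %% n
      ppg <- c(ppg[(n - k + 1):n], ppg[seq_len(n - k)])
    }
    structure(
      list(record = waveform_record(ppg, abp, spec$fs, subject_id = "synthetic"),
           truth_onsets = onsets, truth_fiducials = fids,
           truth_sbp = truth_sbp, truth_dbp = truth_dbp, spec = spec),
      class = "synthetic_record"
    )
  })
}

#' Synthetic feature table with a known pressure-generating model
#'
#' Desk-scale stand-in for a large labeled pulse corpus: draws morphology
#' feature columns and sets the targets to smooth functions of a few of
#' them plus Gaussian noise, `SBP = g(f1..f4) + N(0, sigma)` centered in
#' the 80-180 mmHg study range (DBP analogously in 60-110). Used for
#' parameter-recovery benchmarks of the model-fitting path: the achievable
#' test RMSE approaches `sigma` from above as rows increase.
#'
#' @param n Number of rows.
#' @param sigma Target noise SD in mmHg.
#' @param n_noise_features Additional uninformative feature columns.
#' @param seed Integer seed.
#' @return Data frame with columns `f1..f4`, noise features, `sbp`, `dbp`.
#' @export
simulate_bp_features <- function(n, sigma = 3, n_noise_features = 6,
                                 seed = 1L) {
  .with_seed(seed, function() {
    f1 <- stats::runif(n); f2 <- stats::runif(n)
    f3 <- stats::runif(n); f4 <- stats::runif(n)
    g_sbp <- 130 + 30 * (f1 - 0.5) + 18 * sin(pi * f2) - 9 +
      14 * (f3 - 0.5)^2 * 4 - 7 + 8 * f1 * f4 - 4
    g_dbp <- 85 + 18 * (f2 - 0.5) + 10 * sin(pi * f3) - 5 + 6 * f4 - 3
    out <- data.frame(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
    for (j in seq_len(n_noise_features)) {
      out[[paste0("noise", j)]] <- stats::runif(n)
    }
    out$sbp <- g_sbp + stats::rnorm(n, 0, sigma)
    out$dbp <- g_dbp + stats::rnorm(n, 0, sigma)
    out
  })
}
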