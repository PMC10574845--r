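# Signal-conditioning chain from raw paired waveforms to labeled pulses:
# align ABP and PPG, band-pass denoise, Z-score, baseline-correct, segment
# foot-to-foot, gate on quality and PPG/ABP shape similarity, label each
# pulse with SBP/DBP read off the ABP channel, and apply the physiologic
# range filter. Sample indices are 1-based; a pulse occupies the inclusive
# index range [start, end].

#' Paired PPG/ABP waveform record
#'
#' @param ppg PPG samples (arbitrary units).
#' @param abp ABP samples (mmHg); must match `ppg` in length.
#' @param fs Sampling rate in Hz.
#' @param subject_id Opaque identifier.
#' @return Object of class `waveform_record`.
#' @export
waveform_record <- function(ppg, abp, fs, subject_id = "unknown") {
  if (length(ppg) != length(abp)) stop("ppg and abp must have equal length")
  if (!all(is.finite(ppg)) || !all(is.finite(abp))) stop("samples must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(ppg = as.numeric(ppg), abp = as.numeric(abp), fs = fs,
                 subject_id = subject_id),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("waveform_record '%s': %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$ppg), x$fs, length(x$ppg) / x$fs))
  invisible(x)
}

# Normalized cross-correlation of abp[t] with ppg[t + k] over a lag set;
# returns the maximizing lag.
.best_lag <- function(abp, ppg, lags) {
  n <- length(ppg)
  best <- -Inf
  best_lag <- 0L
  for (k in lags) {
    if (k >= 0) {
      a <- abp[seq_len(n - k)]
      p <- ppg[(1 + k):n]
    } else {
      a <- abp[(1 - k):n]
      p <- ppg[seq_len(n + k)]
    }
    if (stats::sd(a) == 0 || stats::sd(p) == 0) next
    r <- stats::cor(a, p)
    if (r > best) { best <- r; best_lag <- k }
  }
  best_lag
}

# Dominant beat period (samples) from the autocorrelation, searched over
# the physiologic 25-240 bpm window.
.beat_period <- function(x, fs) {
  ac <- stats::acf(x, lag.max = min(round(2.4 * fs), length(x) - 1),
                   plot = FALSE)$acf[-1]
  lo <- max(2L, round(0.25 * fs))
  lo + which.max(ac[lo:length(ac)]) - 1L
}

# Coarse channel lag from matched systolic-peak trains. Cardiac signals
# are quasi-periodic, so raw cross-correlation is ambiguous at multiples
# of the beat period; the beat-to-beat amplitude variation is not. The
# beat offset m is chosen by correlating the per-beat peak-height
# sequences of the two channels, then the positional lag is the median
# offset between matched peaks.
.coarse_lag_beats <- function(abp, ppg, period, L) {
  detrend <- function(x) {            # remove sub-beat-rate baseline drift
    w <- 2L * period + 1L
    m <- stats::filter(x, rep(1 / w, w), sides = 2)
    m[is.na(m)] <- mean(x)
    x - as.numeric(m)
  }
  abp <- detrend(abp)
  ppg <- detrend(ppg)
  pk <- function(x) .find_peaks(x, min_dist = round(0.6 * period),
                                height = mean(x))
  pa <- pk(abp)
  pp <- pk(ppg)
  if (length(pa) < 3 || length(pp) < 3) return(0L)
  ha <- abp[pa]
  hp <- ppg[pp]
  m_max <- min(ceiling(L / period) + 1, length(pa) - 3, length(pp) - 3)
  best_m <- 0L
  best_r <- -Inf
  for (m in -m_max:m_max) {
    ia <- seq_along(pa)
    ip <- ia + m
    ok <- ip >= 1 & ip <= length(pp)
    if (sum(ok) < 3) next
    a <- ha[ia[ok]]
    p <- hp[ip[ok]]
    if (stats::sd(a) == 0 || stats::sd(p) == 0) next
    r <- stats::cor(a, p)
    if (r > best_r) { best_r <- r; best_m <- m }
  }
  ia <- seq_along(pa)
  ip <- ia + best_m
  ok <- ip >= 1 & ip <= length(pp)
  as.integer(round(stats::median(pp[ip[ok]] - pa[ia[ok]])))
}

#' Align the PPG stream to the ABP stream
#'
#' Recovers the lag `k` maximizing the normalized cross-correlation between
#' `abp[t]` and `ppg[t + k]` within `+/- max_lag_s` (k > 0 means the PPG
#' stream is delayed relative to ABP). Because cardiac signals are
#' quasi-periodic, a plain correlation scan is ambiguous at multiples of
#' the beat period; the search therefore first resolves the beat
#' correspondence by matching the per-beat peak-amplitude sequences of the
#' two channels (the beat-to-beat amplitude variation acts as a
#' fingerprint), then refines the lag by raw cross-correlation within less
#' than half a beat period of that coarse estimate. The PPG stream is
#' shifted back by the recovered lag and both streams truncated to common
#' support.
#'
#' @param record A [waveform_record()].
#' @param max_lag_s Lag search bound in seconds (default 2, covering pulse
#'   transit-time offsets).
#' @return Aligned `waveform_record` with attribute `lag` (samples).
#' @export
align_record <- function(record, max_lag_s = 2) {
  stopifnot(inherits(record, "waveform_record"))
  n <- length(record$ppg)
  fs <- record$fs
  L <- round(max_lag_s * fs)
  if (n < 2 * L) stop("record too short for the requested lag search")
  if (stats::sd(record$ppg) == 0 || stats::sd(record$abp) == 0) {
    stop("uninformative signal: zero variance")
  }
  period <- .beat_period(record$ppg, fs)
  coarse <- .coarse_lag_beats(record$abp, record$ppg, period, L)
  coarse <- max(-L, min(L, coarse))
  half <- max(3L, floor(period / 2) - 1L)
  k <- .best_lag(record$abp, record$ppg,
                 max(-L, coarse - half):min(L, coarse + half))
  if (k >= 0) {
    abp <- record$abp[seq_len(n - k)]
    ppg <- record$ppg[(1 + k):n]
  } else {
    abp <- record$abp[(1 - k):n]
    ppg <- record$ppg[seq_len(n + k)]
  }
  out <- waveform_record(ppg, abp, record$fs, record$subject_id)
  attr(out, "lag") <- k
  out
}

#' Band-pass denoise a PPG signal
#'
#' Zero-phase Butterworth band-pass (default 0.5-10 Hz, the standard PPG
#' band), applied forward and backward so fiducial timing is preserved.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band Pass band in Hz.
#' @param order Butterworth design order per band edge.
#' @return Filtered signal, same length.
#' @export
denoise <- function(x, fs, band = c(0.5, 10), order = 4) {
  if (!all(is.finite(x))) stop("samples must be finite")
  if (band[2] >= fs / 2) stop("pass band violates the Nyquist limit")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Z-score standardization
#'
#' @param x Numeric signal with positive variance.
#' @return `(x - mean) / sd`, sample SD (n-1).
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance signal cannot be standardized")
  (x - mean(x)) / s
}

#' Remove slow baseline drift
#'
#' Zero-phase Butterworth high-pass at `cutoff` (default 0.5 Hz) removing
#' respiratory and motion drift while preserving the pulse band.
#'
#' @param x Numeric signal, at least 2 s long.
#' @param fs Sampling rate in Hz.
#' @param cutoff High-pass corner in Hz.
#' @param order Design order.
#' @return Filtered signal, same length.
#' @export
baseline_correct <- function(x, fs, cutoff = 0.5, order = 4) {
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# Local maxima above `height` separated by at least `min_dist` samples,
# keeping the taller peak when two compete.
.find_peaks <- function(x, min_dist, height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= height]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Segment a PPG signal into foot-to-foot pulses
#'
#' Detects systolic peaks (local maxima with a plausibility spacing of
#' `min_period_s`), locates each beat's maximum-upstroke point, and places
#' the onset at the local minimum preceding it. Segments run from one
#' onset to the sample before the next onset (the final beat runs to the
#' end of the signal) and are dropped when their duration falls outside
#' `[min_period_s, max_period_s]`.
#'
#' @param ppg Preprocessed PPG signal.
#' @param fs Sampling rate in Hz.
#' @param min_period_s,max_period_s Plausible beat-duration bounds in
#'   seconds (defaults 0.25 and 2.4, i.e. 25-240 bpm).
#' @return Data frame with columns `start`, `end` (1-based inclusive) and a
#'   list-column `samples`; zero rows when no beats are detectable.
#' @export
segment_pulses <- function(ppg, fs, min_period_s = 0.25, max_period_s = 2.4) {
  n <- length(ppg)
  thr <- mean(ppg) + 0.5 * stats::sd(ppg)
  peaks <- .find_peaks(ppg, min_dist = round(min_period_s * fs), height = thr)
  if (length(peaks) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      samples = I(list())))
  }
  d1 <- c(diff(ppg), 0)
  onsets <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1) 1L else peaks[i - 1]
    win <- lo:(peaks[i] - 1)
    if (length(win) < 2) { onsets[i] <- lo; next }
    ms <- win[which.max(d1[win])]        # max upstroke before the peak
    # last local minimum before the max-slope point
    seg <- ppg[lo:ms]
    mins <- which(diff(sign(diff(seg))) > 0) + 1L
    onsets[i] <- if (length(mins) > 0) lo + mins[length(mins)] - 1L
                 else lo + which.min(seg) - 1L
  }
  starts <- onsets
  ends <- c(onsets[-1] - 1L, n)
  keep <- (ends - starts + 1) >= round(min_period_s * fs) &
          (ends - starts + 1) <= round(max_period_s * fs)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    start = starts, end = ends,
    samples = I(lapply(seq_along(starts),
                       function(i) ppg[starts[i]:ends[i]]))
  )
}

#' Pulse quality gate
#'
#' A pulse passes when (a) its duration lies within the physiologic
#' bounds, (b) it has exactly one dominant maximum (unimodality), and
#' (c) its correlation with the running beat template (resampled to the
#' pulse length) reaches `cor_threshold`.
#'
#' @param pulse Numeric pulse samples.
#' @param fs Sampling rate in Hz.
#' @param template Optional reference beat shape; skipped when `NULL`.
#' @param cor_threshold Template-correlation threshold (default 0.9).
#' @param min_period_s,max_period_s Duration bounds in seconds.
#' @param dominance Relative height (of the min-max range) above which a
#'   local maximum counts as dominant.
#' @return Logical flag with attribute `reasons` naming any failures.
#' @export
quality_check <- function(pulse, fs, template = NULL, cor_threshold = 0.9,
                          min_period_s = 0.25, max_period_s = 2.4,
                          dominance = 0.7) {
  reasons <- character(0)
  dur <- length(pulse) / fs
  if (dur < min_period_s || dur > max_period_s) reasons <- c(reasons, "duration")
  rng <- diff(range(pulse))
  if (rng == 0) {
    reasons <- c(reasons, "flat")
  } else {
    rel <- (pulse - min(pulse)) / rng
    n_dom <- length(.find_peaks(rel, min_dist = 1, height = dominance))
    if (n_dom != 1) reasons <- c(reasons, "multimodal")
  }
  if (!is.null(template) && rng > 0) {
    tmpl <- stats::approx(seq_along(template), template,
                          xout = seq(1, length(template),
                                     length.out = length(pulse)))$y
    if (stats::sd(tmpl) == 0 || stats::cor(pulse, tmpl) < cor_threshold) {
      reasons <- c(reasons, "template")
    }
  }
  structure(length(reasons) == 0, reasons = reasons)
}

#' Shape similarity between a paired PPG and ABP pulse
#'
#' Both pulses are resampled to a common length and compared by Pearson
#' correlation of their normalized shapes (affine-invariant).
#'
#' @param ppg_pulse,abp_pulse Numeric pulse samples.
#' @param n_points Common resampling length.
#' @return Correlation in `[-1, 1]`.
#' @export
similarity_check <- function(ppg_pulse, abp_pulse, n_points = 100) {
  rs <- function(x) stats::approx(seq_along(x), x,
                                  xout = seq(1, length(x),
                                             length.out = n_points))$y
  a <- rs(ppg_pulse); b <- rs(abp_pulse)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance pulse in similarity check")
  }
  stats::cor(a, b)
}

#' Label a pulse from its ABP segment
#'
#' @param abp_pulse ABP samples in mmHg for one beat.
#' @return `c(sbp, dbp)` = max and min of the segment.
#' @export
label_pulse <- function(abp_pulse) {
  sbp <- max(abp_pulse); dbp <- min(abp_pulse)
  if (sbp <= dbp) stop("rejected pulse: SBP <= DBP (flat segment)")
  c(sbp = sbp, dbp = dbp)
}

#' Physiologic range filter for labeled pulses
#'
#' Keeps rows with `80 <= sbp <= 180` and `60 <= dbp <= 110` (bounds
#' inclusive). Idempotent.
#'
#' @param pulses Data frame with `sbp` and `dbp` columns.
#' @param sbp_range,dbp_range Inclusive bounds in mmHg.
#' @return Filtered data frame.
#' @export
filter_range <- function(pulses, sbp_range = c(80, 180),
                         dbp_range = c(60, 110)) {
  keep <- pulses$sbp >= sbp_range[1] & pulses$sbp <= sbp_range[2] &
          pulses$dbp >= dbp_range[1] & pulses$dbp <= dbp_range[2]
  pulses[keep, , drop = FALSE]
}

#' Full preprocessing pipeline: record to labeled pulses
#'
#' Composes alignment, denoising, Z-score standardization, baseline
#' correction, foot-to-foot segmentation, quality and similarity gating,
#' ABP labeling and the physiologic range filter. Labels are read from the
#' raw (aligned but unfiltered) ABP channel so they stay in mmHg.
#'
#' @param record A [waveform_record()].
#' @param max_lag_s Alignment search bound in seconds.
#' @param quality_threshold Template-correlation gate (default 0.9).
#' @param similarity_threshold PPG/ABP shape-correlation gate (default 0.8).
#' @param apply_range_filter Apply [filter_range()] at the end.
#' @param onset_guard Samples trimmed from the start of each ABP segment
#'   before reading the labels, so that onset-detection jitter cannot pull
#'   the previous beat's end-diastolic minimum into this beat's DBP.
#' @return Data frame, one row per surviving pulse: `pulse_index`, `start`,
#'   `end` (indices into the aligned record), `sbp`, `dbp`, `quality_pass`,
#'   `similarity`, and list-columns `ppg_samples` (preprocessed) and
#'   `abp_samples` (raw mmHg). Attribute `n_segmented` records the count
#'   before gating.
#' @export
process_record <- function(record, max_lag_s = 2, quality_threshold = 0.9,
                           similarity_threshold = 0.8,
                           apply_range_filter = TRUE, onset_guard = 3L) {
  rec <- align_record(record, max_lag_s)
  ppg <- baseline_correct(zscore(denoise(rec$ppg, rec$fs)), rec$fs)
  segs <- segment_pulses(ppg, rec$fs)
  n_seg <- nrow(segs)
  if (n_seg == 0) {
    out <- data.frame(pulse_index = integer(0), start = integer(0),
                      end = integer(0), sbp = numeric(0), dbp = numeric(0),
                      quality_pass = logical(0), similarity = numeric(0))
    attr(out, "n_segmented") <- 0L
    return(out)
  }
  template <- segs$samples[[which.max(vapply(segs$samples, length, 1L))]]
  rows <- lapply(seq_len(n_seg), function(i) {
    p <- segs$samples[[i]]
    a <- rec$abp[segs$start[i]:segs$end[i]]
    q <- isTRUE(quality_check(p, rec$fs, template,
                              cor_threshold = quality_threshold))
    sim <- tryCatch(similarity_check(p, a), error = function(e) NA_real_)
    a_lab <- if (length(a) > onset_guard) a[-seq_len(onset_guard)] else a
    lab <- tryCatch(label_pulse(a_lab), error = function(e) c(sbp = NA, dbp = NA))
    data.frame(pulse_index = i, start = segs$start[i], end = segs$end[i],
               sbp = lab[["sbp"]], dbp = lab[["dbp"]], quality_pass = q,
               similarity = sim)
  })
  out <- do.call(rbind, rows)
  out$ppg_samples <- I(segs$samples)
  out$abp_samples <- I(lapply(seq_len(n_seg),
                              function(i) rec$abp[segs$start[i]:segs$end[i]]))
  keep <- out$quality_pass & !is.na(out$similarity) &
    out$similarity >= similarity_threshold & !is.na(out$sbp)
  out <- out[keep, , drop = FALSE]
  if (apply_range_filter) out <- filter_range(out)
  attr(out, "n_segmented") <- n_seg
  attr(out, "lag") <- attr(rec, "lag")
  out
}
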