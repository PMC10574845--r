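test_that("alignment recovers injected lags and handles edge cases", {
  rec <- generate_record(record_spec(n_beats = 50, noise_sd = 0,
                                     ppg_abp_lag_s = 0.2, seed = 4))
  al <- align_record(rec$record)
  expect_identical(attr(al, "lag"), 25L)
  expect_length(al$ppg, length(al$abp))

  same <- waveform_record(rec$record$abp, rec$record$abp, 125)
  expect_identical(attr(align_record(same), "lag"), 0L)

  flat <- waveform_record(rep(1, 1000), rnorm(1000) + 10, 125)
  expect_error(align_record(flat), "uninformative")
})

test_that("band-pass denoising passes the pulse band and kills mains-range noise", {
  fs <- 125
  t <- seq(0, 40, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  hum <- sin(2 * pi * 50 * t)
  out <- denoise(hum, fs)
  expect_lt(sqrt(mean(out[mid]^2)), 0.05 * sqrt(mean(hum[mid]^2)))
  pulse <- sin(2 * pi * 1 * t)
  out2 <- denoise(pulse, fs)
  expect_lt(abs(sqrt(mean(out2[mid]^2)) / sqrt(mean(pulse[mid]^2)) - 1), 0.05)
  expect_equal(denoise(rep(0, 1000), fs), rep(0, 1000), tolerance = 1e-12)
  expect_error(denoise(rnorm(100), fs = 15), "Nyquist")
})

test_that("z-score standardization is exact and affine invariant", {
  z <- zscore(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  x <- rnorm(500)
  expect_equal(zscore(3.2 * x - 17), zscore(x), tolerance = 1e-9)
  expect_error(zscore(rep(2, 10)), "variance")
})

test_that("baseline correction removes drift and preserves the pulse", {
  fs <- 125
  t <- seq(0, 60, by = 1 / fs)
  pulse <- sin(2 * pi * 1 * t)
  drift <- 5 * sin(2 * pi * 0.05 * t)
  out <- baseline_correct(pulse + drift, fs)
  # project the output onto the unit-normalized drift waveform
  resid_amp <- abs(sum(out * drift) / sum(drift * drift)) * 5
  expect_lt(resid_amp, 0.25)
  out2 <- baseline_correct(pulse, fs)
  expect_lt(sqrt(mean((out2 - pulse)^2)) / sqrt(mean(pulse^2)), 0.05)
  out3 <- baseline_correct(drift, fs)
  expect_lt(sqrt(mean(out3^2)), 0.05 * sqrt(mean(drift^2)))
})

test_that("segmentation partitions clean records foot to foot", {
  rec <- clean_record(seed = 5)
  ppg <- baseline_correct(zscore(denoise(rec$record$ppg, 125)), 125)
  segs <- segment_pulses(ppg, 125)
  expect_gte(nrow(segs), 48)
  # disjoint, ordered, plausible durations
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
  durs <- segs$end - segs$start + 1
  expect_true(all(durs >= 0.25 * 125 & durs <= 2.4 * 125))

  # two concatenated identical beats give two equal segments
  beat <- generate_pulse(pulse_shape_params(), 125)$ppg
  two <- segment_pulses(zscore(c(beat, beat, beat)), 125)
  if (nrow(two) >= 2) {
    d <- two$end - two$start + 1
    expect_lte(abs(d[1] - d[2]), 1)
  }
})

test_that("pure noise yields no quality-passing pulses", {
  set.seed(42)
  noise <- rnorm(2000)
  segs <- segment_pulses(noise, 125)
  if (nrow(segs) > 0) {
    tmpl <- generate_pulse(pulse_shape_params(), 125)$ppg
    pass <- vapply(segs$samples, function(p)
      isTRUE(quality_check(p, 125, template = tmpl)), logical(1))
    expect_lte(mean(pass), 0.2)
  } else {
    expect_identical(nrow(segs), 0L)
  }
})

test_that("the quality gate enforces duration, unimodality and template shape", {
  p <- clean_pulse()
  expect_true(quality_check(p$pulse, 125, template = p$pulse))
  corrupted <- p$pulse
  k <- round(0.4 * length(corrupted))
  corrupted[seq_len(k)] <- corrupted[1]
  q <- quality_check(corrupted, 125, template = p$pulse)
  expect_false(q)
  expect_true("template" %in% attr(q, "reasons") ||
                "multimodal" %in% attr(q, "reasons"))
  short <- p$pulse[1:12]
  expect_false(quality_check(short, 125))
})

test_that("shape similarity is an affine-invariant correlation", {
  p <- clean_pulse()
  expect_equal(similarity_check(p$pulse, 3 * p$pulse + 7), 1.0,
               tolerance = 1e-9)
  expect_equal(similarity_check(p$pulse, -p$pulse), -1.0, tolerance = 1e-9)
  expect_gte(similarity_check(p$pulse, p$abp), 0.8)
  expect_error(similarity_check(p$pulse, rep(1, 80)), "zero-variance")
})

test_that("labels are the per-pulse ABP extrema", {
  beat <- generate_pulse(pulse_shape_params(abp_sbp = 120, abp_dbp = 80), 125)
  lab <- label_pulse(beat$abp)
  expect_equal(unname(lab), c(120, 80), tolerance = 0.1)
  lab2 <- label_pulse(beat$abp + 10)
  expect_equal(unname(lab2 - lab), c(10, 10), tolerance = 1e-12)
  expect_error(label_pulse(rep(100, 50)), "rejected")
})

test_that("the physiologic range filter keeps exactly the in-range labels", {
  d <- data.frame(sbp = c(79, 80, 180, 181, 120), dbp = c(70, 60, 110, 90, 59))
  kept <- filter_range(d)
  expect_equal(kept$sbp, c(80, 180))
  expect_identical(nrow(filter_range(d[0, ])), 0L)
  expect_identical(filter_range(kept), kept)   # idempotent
  set.seed(9)
  big <- data.frame(sbp = runif(1000, 70, 190), dbp = runif(1000, 50, 120))
  brute <- big[big$sbp >= 80 & big$sbp <= 180 &
                 big$dbp >= 60 & big$dbp <= 110, ]
  expect_equal(nrow(filter_range(big)), nrow(brute))
})
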