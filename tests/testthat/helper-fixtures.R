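# Shared fixtures, generated in code (no stored data).

clean_record <- function(n_beats = 50, seed = 3, ...) {
  generate_record(record_spec(n_beats = n_beats, noise_sd = 0,
                              drift_amplitude = 0, seed = seed, ...))
}

# one clean preprocessed pulse plus its beat-local ground-truth fiducials
clean_pulse <- function(seed = 3, beat = 5) {
  rec <- clean_record(seed = seed)
  res <- process_record(rec$record)
  i <- which.min(abs(res$start - rec$truth_onsets[beat]))
  j <- which.min(abs(rec$truth_onsets - res$start[i]))
  truth <- vapply(rec$truth_fiducials[[j]], function(k) k - res$start[i] + 1,
                  numeric(1))
  list(pulse = res$ppg_samples[[i]], abp = res$abp_samples[[i]],
       truth = truth, sbp = res$sbp[i], dbp = res$dbp[i])
}
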