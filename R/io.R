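# Readers and writers: two-column CSV records with a JSON ground-truth
# sidecar, a minimal WFDB format-16 reader/writer (header + int16 .dat,
# signal names PLETH/ABP, mirroring MIMIC-III waveform layout), and the
# labeled-pulse / feature-table CSV (or optional Parquet) round trip.

#' Write a waveform record as two-column CSV
#'
#' Columns `ppg, abp`; for a [generate_record()] result a JSON sidecar
#' `<path>.truth.json` stores the ground truth (onsets, fiducials, per-beat
#' SBP/DBP, sampling rate).
#'
#' @param record A `waveform_record` or `synthetic_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  truth <- NULL
  if (inherits(record, "synthetic_record")) {
    truth <- list(fs = record$record$fs,
                  truth_onsets = record$truth_onsets,
                  truth_fiducials = record$truth_fiducials,
                  truth_sbp = record$truth_sbp, truth_dbp = record$truth_dbp)
    record <- record$record
  }
  stopifnot(inherits(record, "waveform_record"))
  utils::write.csv(data.frame(ppg = record$ppg, abp = record$abp), path,
                   row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a two-column CSV record
#'
#' @param path CSV with `ppg` and `abp` columns.
#' @param fs Sampling rate in Hz (125 for the study data).
#' @param subject_id Identifier for the record.
#' @return A [waveform_record()].
#' @export
read_record_csv <- function(path, fs = 125, subject_id = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("ppg", "abp") %in% names(d))) stop("CSV needs ppg and abp columns")
  waveform_record(d$ppg, d$abp, fs, subject_id)
}

#' Write a record in WFDB format (format 16)
#'
#' Minimal single-segment writer: `<name>.hea` header plus interleaved
#' 16-bit `<name>.dat`, signals `PLETH` (a.u.) and `ABP` (mmHg), matching
#' the layout of MIMIC-III waveform records.
#'
#' @param record A `waveform_record`.
#' @param name Record name (file stem).
#' @param dir Output directory.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, name, dir = ".") {
  stopifnot(inherits(record, "waveform_record"))
  n <- length(record$ppg)
  scale_gain <- function(x) {
    rng <- max(abs(x), 1e-9)
    gain <- 30000 / rng
    list(gain = gain, dig = as.integer(round(x * gain)))
  }
  p <- scale_gain(record$ppg)
  a <- scale_gain(record$abp)
  hea <- c(
    sprintf("%s 2 %g %d", name, record$fs, n),
    sprintf("%s.dat 16 %.6f(0)/NU 16 0 %d 0 0 PLETH", name, p$gain, p$dig[1]),
    sprintf("%s.dat 16 %.6f(0)/mmHg 16 0 %d 0 0 ABP", name, a$gain, a$dig[1])
  )
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  inter <- as.vector(rbind(p$dig, a$dig))
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}

#' Read a WFDB record (format 16)
#'
#' Reads the subset of the WFDB specification used by [write_wfdb()] and
#' by MIMIC-III-style paired PLETH/ABP records: a single-segment header
#' and one interleaved 16-bit `.dat` file, applying each signal's
#' gain/baseline.
#'
#' @param name Record name (file stem) or path to the `.hea` file.
#' @param dir Directory containing the record.
#' @return A [waveform_record()] (PLETH mapped to `ppg`, ABP to `abp`).
#' @export
read_wfdb <- function(name, dir = ".") {
  name <- sub("\\.hea$", "", name)
  hea <- readLines(file.path(dir, paste0(name, ".hea")))
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  if (n_sig != 2) stop("expected a 2-signal record")
  sig <- lapply(hea[2:3], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (f[2] != "16") stop("only WFDB format 16 is supported")
    gain_spec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- 0
    if (grepl("\\(", gain_spec)) {
      baseline <- as.numeric(sub(".*\\(([^)]*)\\).*", "\\1", gain_spec))
    }
    list(file = f[1], gain = gain, baseline = baseline,
         name = f[length(f)])
  })
  con <- file(file.path(dir, sig[[1]]$file), "rb")
  on.exit(close(con))
  raw_v <- readBin(con, "integer", n = 2 * n, size = 2, endian = "little",
                   signed = TRUE)
  ch <- lapply(seq_len(2), function(j) {
    s <- sig[[j]]
    (raw_v[seq(j, by = 2, length.out = n)] - s$baseline) / s$gain
  })
  names(ch) <- vapply(sig, `[[`, "", "name")
  ppg <- ch[[grep("PLETH", names(ch))[1]]]
  abp <- ch[[grep("ABP", names(ch))[1]]]
  waveform_record(ppg, abp, fs, subject_id = name)
}

#' Write a labeled-pulse or feature table
#'
#' CSV by default; Parquet when `path` ends in `.parquet` (requires the
#' `arrow` package). List-columns of samples are expanded to
#' `sample_1..sample_k` padded with `NA`.
#'
#' @param table Data frame (list-columns allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pulse_table <- function(table, path) {
  for (col in names(table)) {
    if (is.list(table[[col]])) {
      k <- max(vapply(table[[col]], length, 1L), 0L)
      mat <- t(vapply(table[[col]],
                      function(x) c(x, rep(NA_real_, k - length(x))),
                      numeric(k)))
      colnames(mat) <- paste0(col, "_", seq_len(k))
      table[[col]] <- NULL
      table <- cbind(table, mat)
    }
  }
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the 'arrow' package")
    }
    arrow::write_parquet(table, path)
  } else {
    utils::write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a table written by [write_pulse_table()]
#'
#' @param path CSV or Parquet path.
#' @return Data frame.
#' @export
read_pulse_table <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet input requires the 'arrow' package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
}
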