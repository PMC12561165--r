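# ECG record and beat-dataset containers plus WFDB-format I/O.
#
# WFDB support is a minimal in-package reader/writer for the header +
# format-16 (little-endian int16) signal layout used by the PhysioNet ECG
# databases: enough to round-trip multi-lead records with sampling rate,
# per-record patient ID and diagnosis label (carried as header comments).

#' Construct an ECG record
#'
#' @param signal numeric matrix, \code{n_samples x n_leads}, in millivolts.
#' @param sampling_rate_hz positive sampling rate.
#' @param leads character vector of lead names, one per signal column.
#' @param record_id,patient_id identifiers carried through the pipeline.
#' @param label one of the 12 class codes (see [rtcn_classes()]) or
#'   \code{"unknown"}. Unknown labels are accepted on read and rejected at
#'   training time.
#' @return An object of class \code{ecg_record}.
#' @export
ecg_record <- function(signal, sampling_rate_hz, leads,
                       record_id = "rec", patient_id = "unknown",
                       label = "unknown") {
  signal <- as.matrix(signal)
  assert_that(nrow(signal) > 0, "signal must contain at least one sample")
  assert_that(is.numeric(sampling_rate_hz) && sampling_rate_hz > 0,
              "sampling_rate_hz must be positive")
  assert_that(length(leads) == ncol(signal),
              "one lead name per signal column required")
  check_class_code(label, allow_unknown = TRUE)
  structure(list(record_id = record_id, patient_id = patient_id,
                 sampling_rate_hz = sampling_rate_hz,
                 leads = as.character(leads), signal = signal, label = label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> patient %s, %d samples @ %g Hz, leads: %s, label: %s\n",
              x$record_id, x$patient_id, nrow(x$signal), x$sampling_rate_hz,
              paste(x$leads, collapse = ","), x$label))
  invisible(x)
}

record_lead <- function(record, lead) {
  idx <- match(tolower(lead), tolower(record$leads))
  if (is.na(idx)) {
    stop_rtcn("lead '", lead, "' not found; available leads: ",
              paste(record$leads, collapse = ", "))
  }
  record$signal[, idx]
}

#' Write an ECG record as a WFDB header/signal pair
#'
#' Signals are quantized with the stated gain (ADC counts) and stored in
#' format 16 (interleaved little-endian int16). Patient ID and label are kept
#' as header comment lines so they survive the round trip.
#'
#' @param record an [ecg_record()].
#' @param path path prefix (without extension); \code{<path>.hea} and
#'   \code{<path>.dat} are written.
#' @param gain ADC counts per millivolt.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, path, gain = 1000) {
  n <- nrow(record$signal); nsig <- ncol(record$signal)
  base <- basename(path)
  hea <- paste0(path, ".hea"); dat <- paste0(path, ".dat")
  lines <- sprintf("%s %d %g %d", base, nsig, record$sampling_rate_hz, n)
  for (j in seq_len(nsig)) {
    lines <- c(lines, sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
                              base, gain, record$leads[j]))
  }
  lines <- c(lines,
             sprintf("# patient_id: %s", record$patient_id),
             sprintf("# label: %s", record$label))
  writeLines(lines, hea)
  adc <- round(record$signal * gain)
  adc <- pmax(pmin(adc, 32767), -32768)
  con <- file(dat, "wb"); on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(hea)
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#")]
  rec <- strsplit(trimws(body[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(strsplit(rec[3], "/")[[1]][1]) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(body[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gg <- regmatches(gain_field, regexec("^([-0-9.eE+]+)(\\(([-0-9.]+)\\))?", gain_field))[[1]]
    gain <- as.numeric(gg[2]); if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (!is.na(gg[4]) && nzchar(gg[4])) as.numeric(gg[4]) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else f[length(f)]
    list(file = f[1], fmt = sub("x.*|:.*|\\+.*", "", f[2]), gain = gain,
         baseline = baseline, name = desc)
  })
  meta <- list(patient_id = "unknown", label = "unknown")
  for (cm in comments) {
    m <- regmatches(cm, regexec("#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", cm))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- trimws(m[3])
  }
  list(record = sub("/.*$", "", rec[1]), nsig = nsig, fs = fs, nsamp = nsamp,
       signals = sig, patient_id = meta$patient_id, label = meta$label)
}

#' Read one lead of a WFDB record
#'
#' Reads the header and format-16 signal file and returns the requested lead
#' converted to physical units (millivolts), with sampling rate, patient ID
#' and label taken from the header.
#'
#' @param path path to the record: either the \code{.hea} file or the prefix.
#' @param lead lead name (case-insensitive); default lead II.
#' @return A single-lead [ecg_record()].
#' @export
read_wfdb_record <- function(path, lead = "ii") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop_rtcn("WFDB header not found: ", hea)
  h <- parse_wfdb_header(hea)
  names_avail <- vapply(h$signals, `[[`, "", "name")
  idx <- match(tolower(lead), tolower(names_avail))
  if (is.na(idx)) {
    stop_rtcn("lead '", lead, "' not found; available leads: ",
              paste(names_avail, collapse = ", "))
  }
  fmt <- h$signals[[idx]]$fmt
  if (fmt != "16") stop_rtcn("unsupported WFDB signal format: ", fmt)
  dat <- file.path(dirname(hea), h$signals[[idx]]$file)
  if (!file.exists(dat)) stop_rtcn("WFDB signal file not found: ", dat)
  con <- file(dat, "rb"); on.exit(close(con))
  n_int <- file.size(dat) / 2
  raw <- readBin(con, "integer", n = n_int, size = 2, endian = "little", signed = TRUE)
  mat <- matrix(raw, ncol = h$nsig, byrow = TRUE)
  if (!is.na(h$nsamp) && nrow(mat) > h$nsamp) mat <- mat[seq_len(h$nsamp), , drop = FALSE]
  phys <- (mat[, idx] - h$signals[[idx]]$baseline) / h$signals[[idx]]$gain
  ecg_record(matrix(phys, ncol = 1), h$fs, leads = names_avail[idx],
             record_id = h$record, patient_id = h$patient_id, label = h$label)
}

# ---------------------------------------------------------------------------
# Beat datasets: a fixed-length sample matrix plus a metadata table.

#' Construct a beat dataset
#'
#' A beat dataset holds segmented heartbeats of a common length \code{L}
#' (651 samples at the default 250-before / 400-after R-peak window) as an
#' \code{L x n} matrix together with per-beat metadata: class label, patient
#' ID, the R-peak position inside the window, and whether the beat is real or
#' DDPM-synthesized.
#'
#' @param samples numeric matrix \code{L x n} (one column per beat, mV).
#' @param label character vector of class codes (length n).
#' @param patient_id character vector (length n).
#' @param r_index integer vector (length n), 1-based R-peak position in 1..L.
#' @param source \code{"real"} or \code{"synthetic"} per beat.
#' @return An object of class \code{beat_set}.
#' @export
beat_set <- function(samples, label, patient_id, r_index, source = "real") {
  samples <- as.matrix(samples)
  n <- ncol(samples); L <- nrow(samples)
  lab <- rep_len(as.character(label), n)
  pid <- rep_len(as.character(patient_id), n)
  ri <- rep_len(as.integer(r_index), n)
  src <- rep_len(as.character(source), n)
  if (n == 0) {
    return(structure(list(samples = samples,
                          meta = data.frame(label = character(0),
                                            patient_id = character(0),
                                            r_index = integer(0),
                                            source = character(0),
                                            stringsAsFactors = FALSE)),
                     class = "beat_set"))
  }
  check_class_code(lab, allow_unknown = TRUE)
  assert_that(all(src %in% c("real", "synthetic")),
              "source must be 'real' or 'synthetic'")
  assert_that(all(ri >= 1L & ri <= L), "r_index must lie inside the beat window")
  structure(list(samples = samples,
                 meta = data.frame(label = lab, patient_id = pid,
                                   r_index = ri, source = src,
                                   stringsAsFactors = FALSE)),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats x %d samples; classes: %s\n",
              ncol(x$samples), nrow(x$samples),
              paste(names(table(x$meta$label)), table(x$meta$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Number of beats in a beat set
#' @param x a [beat_set()].
#' @return Integer count.
#' @export
n_beats <- function(x) ncol(x$samples)

#' Subset a beat set by beat index
#' @param x a [beat_set()].
#' @param idx integer or logical index over beats.
#' @return A [beat_set()].
#' @export
beat_subset <- function(x, idx) {
  beat_set(x$samples[, idx, drop = FALSE], x$meta$label[idx],
           x$meta$patient_id[idx], x$meta$r_index[idx], x$meta$source[idx])
}

#' Concatenate beat sets
#' @param ... beat sets with a common beat length.
#' @return A [beat_set()].
#' @export
beat_bind <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, TRUE)]
  Ls <- vapply(sets, function(s) nrow(s$samples), 0L)
  assert_that(length(unique(Ls)) == 1, "beat sets differ in beat length")
  beat_set(do.call(cbind, lapply(sets, `[[`, "samples")),
           unlist(lapply(sets, function(s) s$meta$label)),
           unlist(lapply(sets, function(s) s$meta$patient_id)),
           unlist(lapply(sets, function(s) s$meta$r_index)),
           unlist(lapply(sets, function(s) s$meta$source)))
}

#' Save / load a beat dataset
#'
#' Beats are stored as two plain-text CSV tables under \code{path} (created if
#' needed): \code{samples.csv} with one row per beat, and \code{meta.csv} with
#' the label / patient / R-index / source columns. The round trip preserves
#' sample values to better than 1e-9 relative error.
#'
#' @param beats a [beat_set()].
#' @param path directory to write to / read from.
#' @return \code{save_beats}: the path, invisibly. \code{load_beats}: a
#'   [beat_set()].
#' @export
save_beats <- function(beats, path) {
  assert_that(inherits(beats, "beat_set"), "beats must be a beat_set")
  assert_that(n_beats(beats) > 0, "cannot save an empty beat set")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(t(beats$samples)),
                     file.path(path, "samples.csv"))
  data.table::fwrite(beats$meta, file.path(path, "meta.csv"))
  invisible(path)
}

#' @rdname save_beats
#' @export
load_beats <- function(path) {
  sp <- file.path(path, "samples.csv"); mp <- file.path(path, "meta.csv")
  if (!file.exists(sp) || !file.exists(mp)) {
    stop_rtcn("no beat dataset found at ", path)
  }
  samples <- t(as.matrix(data.table::fread(sp)))
  dimnames(samples) <- NULL
  meta <- data.table::fread(mp, colClasses = list(character = c("label", "patient_id", "source")))
  beat_set(samples, meta$label, meta$patient_id, meta$r_index, meta$source)
}
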