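#' Multichannel sensor recording
#'
#' Container for a multichannel MEG time series: a channels-by-samples matrix
#' together with the sampling rate, channel names, per-channel sensor type
#' (`"grad"`, `"mag"` or `"other"`) and a list of bad channels.
#'
#' @param data numeric matrix, `n_channels x n_samples`.
#' @param sfreq sampling frequency in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param sensor_type character vector of per-channel types; recycled if
#'   length 1.
#' @param bads character vector of excluded channel names.
#' @return An object of class `"sensor_recording"`.
#' @export
sensor_recording <- function(data, sfreq, channel_names = NULL,
                             sensor_type = "grad", bads = character(0)) {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- sprintf("CH%03d", seq_len(nrow(data)))
  }
  if (length(sensor_type) == 1L) {
    sensor_type <- rep(sensor_type, nrow(data))
  }
  if (nrow(data) != length(channel_names) ||
      nrow(data) != length(sensor_type)) {
    abort("channel_names and sensor_type must match the number of data rows")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    abort("sfreq must be a single positive number")
  }
  if (!all(sensor_type %in% c("grad", "mag", "other"))) {
    abort("sensor_type entries must be 'grad', 'mag' or 'other'")
  }
  structure(
    list(data = data, sfreq = as.numeric(sfreq),
         channel_names = as.character(channel_names),
         sensor_type = as.character(sensor_type),
         bads = as.character(bads)),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  tt <- table(x$sensor_type)
  cat("  sensor types:", paste(names(tt), tt, sep = "=", collapse = ", "))
  if (length(x$bads)) cat("; bads:", paste(x$bads, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Select channels of one sensor type
#'
#' Restricts a recording to channels of a given sensor type, dropping bad
#' channels. Gradiometer and magnetometer data are processed in entirely
#' separate pipeline passes and never mixed in one matrix.
#'
#' @param rec a [sensor_recording()].
#' @param type `"grad"`, `"mag"` or `"other"`; `NULL` keeps all types (bads
#'   are still dropped).
#' @return A [sensor_recording()] whose channels are all of the requested
#'   type.
#' @export
pick_sensors <- function(rec, type = NULL) {
  stopifnot(inherits(rec, "sensor_recording"))
  keep <- !(rec$channel_names %in% rec$bads)
  if (!is.null(type)) {
    type <- match.arg(type, c("grad", "mag", "other"))
    keep <- keep & rec$sensor_type == type
  }
  if (!any(keep)) abort("zero channels left after sensor-type filtering")
  sensor_recording(rec$data[keep, , drop = FALSE], rec$sfreq,
                   rec$channel_names[keep], rec$sensor_type[keep],
                   bads = character(0))
}

# Zero-phase FIR band-pass of a numeric vector. Hamming-window design
# (~53 dB stop-band); linear-phase delay is compensated exactly, so the
# filter is zero-phase for the symmetric taps used here.
fir_bandpass_vec <- function(x, lo, hi, sfreq, taps = NULL) {
  nyq <- sfreq / 2
  if (!(lo > 0 && hi > lo && hi < nyq)) {
    abort("band edges must satisfy 0 < lo < hi < sfreq/2")
  }
  if (is.null(taps)) taps <- fir_bandpass_taps(lo, hi, sfreq, length(x))
  n <- length(taps)
  delay <- (n - 1L) / 2L
  y <- signal::fftfilt(taps, c(x, numeric(delay)))
  y[(delay + 1L):(delay + length(x))]
}

fir_bandpass_taps <- function(lo, hi, sfreq, n_samples) {
  nyq <- sfreq / 2
  if (!(lo > 0 && hi > lo && hi < nyq)) {
    abort("band edges must satisfy 0 < lo < hi < sfreq/2")
  }
  # transition width: a fraction of the band edges, floored so the filter
  # stays much shorter than the signal
  trans <- min(lo / 2, (nyq - hi) / 2, 2)
  n <- ceiling(3.3 / (trans / sfreq))        # Hamming transition heuristic
  n <- min(n, max(8, floor(n_samples / 3)))
  if (n %% 2L == 1L) n <- n + 1L             # even order -> odd length
  signal::fir1(n, c(lo, hi) / nyq, type = "pass", window = signal::hamming(n + 1))
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase FIR band-pass (Hamming window design) to every
#' channel. Shape and sampling rate are preserved.
#'
#' @param rec a [sensor_recording()].
#' @param lo_hz,hi_hz band edges in Hz; must satisfy
#'   `0 < lo_hz < hi_hz < sfreq/2`.
#' @return The filtered [sensor_recording()].
#' @export
bandpass <- function(rec, lo_hz, hi_hz) {
  stopifnot(inherits(rec, "sensor_recording"))
  taps <- fir_bandpass_taps(lo_hz, hi_hz, rec$sfreq, ncol(rec$data))
  out <- rec
  out$data <- t(apply(rec$data, 1L, fir_bandpass_vec,
                      lo = lo_hz, hi = hi_hz, sfreq = rec$sfreq, taps = taps))
  out
}

#' Resample a recording to a lower rate
#'
#' Polyphase anti-aliased resampling of every channel. Only downsampling (or
#' the identity) is allowed; the duration is preserved within one sample.
#'
#' @param rec a [sensor_recording()].
#' @param new_sfreq target rate in Hz, `<= rec$sfreq`.
#' @return A [sensor_recording()] at `new_sfreq`.
#' @export
resample_recording <- function(rec, new_sfreq) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (new_sfreq > rec$sfreq) abort("upsampling is not supported")
  if (new_sfreq == rec$sfreq) return(rec)
  fr <- ratio_pq(new_sfreq / rec$sfreq)
  out <- rec
  resample1 <- if (fr[1] == 1L) {
    # integer decimation: anti-aliased and zero-phase
    function(x) as.numeric(signal::decimate(x, fr[2], ftype = "iir"))
  } else {
    function(x) as.numeric(signal::resample(x, fr[1], fr[2]))
  }
  out$data <- t(apply(rec$data, 1L, resample1))
  out$sfreq <- as.numeric(new_sfreq)
  n_expect <- ncol(rec$data) * new_sfreq / rec$sfreq
  if (abs(ncol(out$data) - n_expect) > 1) {
    abort("resampling failed to preserve duration")
  }
  out
}

# small-denominator rational approximation of a rate ratio
ratio_pq <- function(r, max_q = 1000L) {
  for (q in seq_len(max_q)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  abort("sampling-rate ratio is not a simple rational number")
}

#' Write / read a recording as a matrix file plus channel manifest
#'
#' The interchange format is a tab-separated channels-by-samples matrix
#' (`<path>_data.tsv`) and a JSON manifest (`<path>.json`) holding the
#' sampling rate, channel names, sensor types and bad channels.
#'
#' @param rec a [sensor_recording()].
#' @param path path prefix (no extension).
#' @return `write_recording()` returns `path` invisibly; `load_recording()`
#'   returns a [sensor_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  data.table::fwrite(data.table::as.data.table(rec$data),
                     paste0(path, "_data.tsv"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(data_file = paste0(basename(path), "_data.tsv"),
         sfreq = rec$sfreq, channel_names = rec$channel_names,
         sensor_type = rec$sensor_type, bads = rec$bads),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param sensor_type_filter optional sensor type passed to [pick_sensors()].
#' @rdname write_recording
#' @export
load_recording <- function(path, sensor_type_filter = NULL) {
  manifest <- sub("\\.json$", "", path)
  mpath <- paste0(manifest, ".json")
  if (!file.exists(mpath)) abort(paste0("unknown format: no manifest at ", mpath))
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  dfile <- file.path(dirname(mpath), m$data_file)
  dat <- as.matrix(data.table::fread(dfile, sep = "\t", header = FALSE))
  dimnames(dat) <- NULL
  rec <- sensor_recording(dat, m$sfreq, m$channel_names, m$sensor_type,
                          as.character(m$bads %||% character(0)))
  if (!is.null(sensor_type_filter)) rec <- pick_sensors(rec, sensor_type_filter)
  rec
}
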