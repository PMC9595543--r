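#' Event tables
#'
#' Candidate and assigned spike events are kept in a tibble with columns
#' `time_s` (seconds from recording start), `sample` (0-based index at the
#' table's sampling rate), `stage` (`"stage1"`, `"cluster:<k>"` or
#' `"visual"`), `gof` (dipole goodness of fit, 0-1, `NA` when not scored)
#' and `sensor_type`.
#'
#' @param time_s numeric vector of timestamps in seconds.
#' @param sfreq sampling rate used to derive `sample`.
#' @param stage,gof,sensor_type per-event metadata (recycled if length 1).
#' @return A tibble of class `"event_table"`, sorted by time.
#' @export
event_table <- function(time_s, sfreq, stage = "stage1", gof = NA_real_,
                        sensor_type = "grad") {
  tb <- tibble(
    time_s = as.numeric(time_s),
    sample = as.integer(round(time_s * sfreq)),
    stage = as.character(stage),
    gof = as.numeric(gof),
    sensor_type = as.character(sensor_type)
  )
  tb <- tb[order(tb$time_s), , drop = FALSE]
  for (st in unique(tb$stage)) {
    tt <- tb$time_s[tb$stage == st]
    if (anyDuplicated(tt)) abort("duplicate timestamps within one stage")
  }
  attr(tb, "sfreq") <- as.numeric(sfreq)
  class(tb) <- c("event_table", class(tb))
  tb
}

#' Write / read an event table as TSV
#'
#' Columns `time_s, sample, stage, gof, sensor_type`; the sampling rate is
#' stored in a `# sfreq=` header comment so the round trip is lossless.
#'
#' @param events an [event_table()].
#' @param path file path.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sfreq=%.10g", attr(events, "sfreq") %||% NA_real_), con)
  utils::write.table(as.data.frame(events), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1L)
  sfreq <- as.numeric(sub("# sfreq=", "", first, fixed = TRUE))
  df <- utils::read.delim(path, comment.char = "#", sep = "\t")
  event_table(df$time_s, sfreq, df$stage, df$gof, df$sensor_type)
}
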