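#' Pipeline configuration
#'
#' All numeric parameters of the two-stage spike-detection pipeline, with the
#' published defaults. Values can be overridden by name; unknown names are an
#' error. The configuration round-trips losslessly through YAML
#' ([read_config()] / [write_config()]).
#'
#' The main parameters are:
#' \describe{
#'   \item{n_ica}{number of ICA components extracted (20).}
#'   \item{n_ica_ranked}{components eligible for selection, taken from the top
#'     of the explained-variance ranking (10).}
#'   \item{kurtosis_range}{closed interval of acceptable excess kurtosis
#'     (`c(1, 10)`).}
#'   \item{gof_threshold_mag, gof_threshold_grad}{dipolarity (MUSIC goodness of
#'     fit, 0-1) thresholds for magnetometers (0.80) and gradiometers (0.60).}
#'   \item{gof_override}{a component with dipolarity above this value (0.95) is
#'     selected irrespective of kurtosis.}
#'   \item{peak_band}{band-pass applied to component time courses before peak
#'     detection, Hz (`c(20, 90)`).}
#'   \item{min_peaks}{adaptive peak detection lowers its threshold until at
#'     least this many peaks are found (300).}
#'   \item{peak_grid}{descending grid of peak thresholds in robust-scaled
#'     units; the last entry is the floor.}
#'   \item{music_window}{window around a candidate peak used for MUSIC dipole
#'     scanning, seconds (`c(-0.020, 0.030)`).}
#'   \item{refractory}{minimum interspike interval, seconds (0.5).}
#'   \item{csc_band}{band-pass of the data entering ICA and sparse coding, Hz
#'     (`c(2, 90)`).}
#'   \item{n_atoms_per_run}{atoms learned per sparse-coding run (3).}
#'   \item{atom_len}{temporal extent of an atom, seconds (0.5).}
#'   \item{lambda_reg}{l1 regularization weight of the activations (0.1).}
#'   \item{epoch_len}{length of candidate epochs, seconds (1).}
#'   \item{mad_start, mad_floor, mad_grid}{MAD-threshold schedule for event
#'     assignment (7 down to 1.5).}
#'   \item{min_events}{the MAD loop stops once this many events are assigned
#'     (15).}
#'   \item{events_cap}{event count at which the cluster-population score
#'     saturates (20).}
#'   \item{n_runs}{stage-1/stage-2 iterations building the library (4).}
#'   \item{binarize_frac}{activation maps are binarized at this fraction of
#'     their maximum (0.5).}
#'   \item{smooth_mm}{radius of the final binary smoothing, millimetres (10).}
#'   \item{resection_margin_mm}{margin added around the resection border when
#'     building its source-space mask, millimetres (3).}
#'   \item{lambda2}{minimum-norm regularization (1/9, the SNR = 3 convention).}
#'   \item{csc_n_iter}{maximum outer iterations of the sparse-coding solver.}
#'   \item{exclude_atoms}{character vector of atom ids to force out of the
#'     selected library, emulating visual review.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(min_peaks = 100)
#' cfg$lambda_reg
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_ica = 20,
    n_ica_ranked = 10,
    kurtosis_range = c(1, 10),
    gof_threshold_mag = 0.80,
    gof_threshold_grad = 0.60,
    gof_override = 0.95,
    peak_band = c(20, 90),
    min_peaks = 300,
    peak_grid = c(8, 7, 6, 5, 4, 3, 2.5, 2),
    music_window = c(-0.020, 0.030),
    refractory = 0.5,
    csc_band = c(2, 90),
    n_atoms_per_run = 3,
    atom_len = 0.5,
    lambda_reg = 0.1,
    epoch_len = 1.0,
    mad_start = 7,
    mad_floor = 1.5,
    mad_grid = c(7, 6, 5, 4, 3, 2.5, 2, 1.5),
    min_events = 15,
    events_cap = 20,
    n_runs = 4,
    binarize_frac = 0.5,
    smooth_mm = 10,
    resection_margin_mm = 3,
    lambda2 = 1 / 9,
    csc_n_iter = 40,
    csc_tol = 1e-5,
    exclude_atoms = character(0)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML field names mirror [pipeline_config()] exactly.
#'
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$exclude_atoms <- as.character(raw$exclude_atoms %||% character(0))
  do.call(pipeline_config, raw)
}

#' @param cfg a [pipeline_config()].
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> ", length(x), " parameters\n", sep = "")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
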