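#' ICA decomposition of a recording
#'
#' FastICA decomposition of the sensor data (expected resampled to 200 Hz and
#' band-passed 2-90 Hz), restricted to `n_components` components ordered by
#' explained variance. Component signs are fixed so that the largest-magnitude
#' topography loading is positive, making the result reproducible given the
#' seed.
#'
#' @param rec a [sensor_recording()].
#' @param n_components number of components (default 20).
#' @param seed integer seed for the FastICA initialization.
#' @return An object of class `"component_set"`: `topographies`
#'   (`n_channels x n_components`), `sources` (`n_components x n_samples`),
#'   `sfreq`, `sensor_type`, and empty scoring slots filled by
#'   [score_components()].
#' @export
ica_decompose <- function(rec, n_components = 20, seed = 1) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (nrow(rec$data) < n_components) {
    abort("fewer channels than requested components")
  }
  set.seed(seed)
  X <- t(rec$data)                       # samples x channels
  fit <- ica::icafast(X, nc = n_components, maxit = 200, tol = 1e-6)
  topo <- fit$M                          # channels x components (vaf-ordered)
  src <- t(fit$S)                        # components x samples
  if (qr(topo)$rank < n_components) {
    abort("rank deficiency below the requested number of components")
  }
  # fixed sign convention: dominant topography loading positive
  for (k in seq_len(n_components)) {
    s <- sign(topo[which.max(abs(topo[, k])), k])
    if (s < 0) { topo[, k] <- -topo[, k]; src[k, ] <- -src[k, ] }
  }
  structure(
    list(topographies = topo, sources = src, sfreq = rec$sfreq,
         sensor_type = rec$sensor_type[1], vaf = fit$vafs,
         kurtosis = NULL, gof = NULL, selected = NULL),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components (%s), %d samples @ %g Hz\n",
              ncol(x$topographies), x$sensor_type, ncol(x$sources), x$sfreq))
  if (!is.null(x$selected)) {
    cat("  selected:", paste(which(x$selected), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score and select peaky, dipolar ICA components
#'
#' Among the first `n_ica_ranked` components (explained-variance order), a
#' component is selected if its excess kurtosis lies in `kurtosis_range`
#' (closed interval) AND its topography's MUSIC dipolarity reaches the
#' sensor-type threshold (0.80 for magnetometers, 0.60 for gradiometers);
#' a dipolarity above `gof_override` (0.95) selects the component
#' irrespective of kurtosis.
#'
#' @param cs a `component_set` from [ica_decompose()].
#' @param fwd a [forward_model()] used for the dipolarity scan.
#' @param cfg a [pipeline_config()].
#' @return The `component_set` with `kurtosis`, `gof` and `selected` filled.
#'   If nothing is selected, `selected` is all-`FALSE` and a warning of class
#'   `megspike_no_candidates` is emitted.
#' @export
score_components <- function(cs, fwd, cfg = pipeline_config()) {
  stopifnot(inherits(cs, "component_set"))
  nc <- ncol(cs$topographies)
  if (nc < cfg$n_ica_ranked) abort("component set smaller than n_ica_ranked")
  kurt <- apply(cs$sources, 1L, e1071::kurtosis, type = 1)
  gof <- vapply(seq_len(nc), function(k) {
    music_scan(cs$topographies[, k], fwd)$gof
  }, numeric(1))
  if (!all(is.finite(kurt)) || !all(is.finite(gof))) {
    abort("non-finite component scores")
  }
  thr <- if (cs$sensor_type == "mag") cfg$gof_threshold_mag else cfg$gof_threshold_grad
  eligible <- seq_len(nc) <= cfg$n_ica_ranked
  pass <- (kurt >= cfg$kurtosis_range[1] & kurt <= cfg$kurtosis_range[2] &
             gof >= thr) | gof > cfg$gof_override
  cs$kurtosis <- kurt
  cs$gof <- gof
  cs$selected <- eligible & pass
  if (!any(cs$selected)) {
    warn("no ICA component passed the selection criteria",
         class = "megspike_no_candidates")
  }
  cs
}

# (x - median) / IQR with a degenerate-scale guard: a constant series maps
# to zero signal
robust_scale <- function(x) {
  s <- IQR(x)
  if (s < .Machine$double.eps) return(numeric(length(x)))
  (x - median(x)) / s
}

# strict-rise local maxima of x at or above thresh
local_peaks <- function(x, thresh) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] >= thresh) + 1L
  core
}

#' Adaptive peak detection on selected component time courses
#'
#' Each selected component's time course is band-passed 20-90 Hz, robustly
#' scaled (median/IQR) and rectified; peaks are local maxima above a
#' threshold taken from a fixed descending grid. The threshold decreases
#' until the total count across components reaches `min_peaks` (300) or the
#' grid floor is reached. Peaks are detected on the absolute scaled signal
#' because the ICA component sign is arbitrary.
#'
#' @param cs a scored `component_set` ([score_components()]).
#' @param cfg a [pipeline_config()].
#' @param components optional integer subset restricting which selected
#'   components are used (library runs 2-4 pass one topography cluster).
#' @return A list of class `"candidate_peaks"`: `peaks` (per-component tibble
#'   of `sample` (1-based), `amplitude` in scaled units), `theta` (final
#'   threshold), `component` indices and `sfreq`. Signals a condition of
#'   class `megspike_no_candidates` if the floor yields zero peaks.
#' @export
detect_component_peaks <- function(cs, cfg = pipeline_config(),
                                   components = NULL) {
  stopifnot(inherits(cs, "component_set"))
  if (is.null(cs$selected)) abort("run score_components() first")
  comp <- which(cs$selected)
  if (!is.null(components)) comp <- intersect(comp, components)
  if (!length(comp)) {
    abort("no selected components", class = "megspike_no_candidates")
  }
  scaled <- lapply(comp, function(k) {
    abs(robust_scale(fir_bandpass_vec(cs$sources[k, ], cfg$peak_band[1],
                                      cfg$peak_band[2], cs$sfreq)))
  })
  theta_used <- tail(cfg$peak_grid, 1)
  peaks <- NULL
  for (theta in cfg$peak_grid) {
    peaks <- lapply(scaled, function(x) {
      idx <- local_peaks(x, theta)
      tibble(sample = idx, amplitude = x[idx])
    })
    total <- sum(vapply(peaks, nrow, integer(1)))
    if (total >= cfg$min_peaks) { theta_used <- theta; break }
    theta_used <- theta
  }
  total <- sum(vapply(peaks, nrow, integer(1)))
  if (total == 0L) {
    abort("no peaks above the threshold floor",
          class = "megspike_no_candidates")
  }
  structure(list(peaks = peaks, component = comp, theta = theta_used,
                 sfreq = cs$sfreq, sensor_type = cs$sensor_type),
            class = "candidate_peaks")
}

#' @export
print.candidate_peaks <- function(x, ...) {
  cat(sprintf("<candidate_peaks> %d peaks on %d components (theta = %g)\n",
              sum(vapply(x$peaks, nrow, integer(1))), length(x$component),
              x$theta))
  invisible(x)
}

#' Refine candidate peaks by MUSIC scanning and refractory pruning
#'
#' Every candidate peak is scored by a MUSIC dipole scan of the sensor-space
#' window -20 to +30 ms around it; peaks whose window exceeds the recording
#' bounds are dropped with a warning. Within any 0.5 s span only the event
#' with the largest goodness of fit survives: events are processed in
#' descending gof order and any unselected event within the refractory
#' interval of a kept one is suppressed.
#'
#' @param peaks a `candidate_peaks` object.
#' @param rec the [sensor_recording()] the components came from.
#' @param fwd a [forward_model()].
#' @param cfg a [pipeline_config()].
#' @return An [event_table()] (stage `"stage1"`), sorted by time, whose
#'   pairwise separations all exceed `cfg$refractory`.
#' @export
refine_peaks <- function(peaks, rec, fwd, cfg = pipeline_config()) {
  stopifnot(inherits(peaks, "candidate_peaks"),
            inherits(rec, "sensor_recording"))
  sf <- rec$sfreq
  w0 <- round(cfg$music_window[1] * sf)
  w1 <- round(cfg$music_window[2] * sf)
  samp <- unlist(lapply(peaks$peaks, `[[`, "sample"))
  samp <- sort(unique(samp))
  n <- ncol(rec$data)
  ok <- samp + w0 >= 1L & samp + w1 <= n
  if (any(!ok)) {
    warn(sprintf("%d peak(s) dropped: MUSIC window exceeds recording bounds",
                 sum(!ok)))
    samp <- samp[ok]
  }
  if (!length(samp)) abort("no peaks left after bounds check",
                           class = "megspike_no_candidates")
  gain <- music_gain(fwd)
  gof <- vapply(samp, function(s) {
    win <- rec$data[, (s + w0):(s + w1), drop = FALSE]
    if (!any(win != 0)) return(0)
    sub <- svd(win, nu = 1L, nv = 0)$u
    max(music_gof(sub, gain))
  }, numeric(1))
  # greedy refractory pruning, largest gof first
  ord <- order(-gof, samp)
  kept <- integer(0)
  refr_samp <- cfg$refractory * sf
  for (i in ord) {
    if (!length(kept) || all(abs(samp[i] - samp[kept]) > refr_samp)) {
      kept <- c(kept, i)
    }
  }
  kept <- kept[order(samp[kept])]
  event_table((samp[kept] - 1L) / sf, sf, stage = "stage1",
              gof = gof[kept], sensor_type = peaks$sensor_type)
}
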