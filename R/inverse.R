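#' Minimum-norm inverse operator
#'
#' Tikhonov-regularized minimum-norm estimation with a diagonal noise
#' covariance: the leadfield is whitened per channel, and
#' `W = G' (G G' + lambda2 * mu * I)^-1` in whitened coordinates, with `mu`
#' the mean diagonal of the whitened Gram (so `lambda2` follows the usual
#' `1/SNR^2` convention). With free orientations the three orientation
#' components of a vertex are combined by Euclidean norm at map time.
#'
#' @param fwd a [forward_model()].
#' @param noise_diag per-channel noise variances (positive).
#' @param lambda2 regularization (default 1/9, SNR = 3).
#' @return An object of class `"inverse_operator"` with the kernel `W`
#'   (`(n_vertices * n_orient) x n_channels`), the whitener and the forward
#'   model geometry.
#' @export
make_inverse <- function(fwd, noise_diag, lambda2 = 1 / 9) {
  stopifnot(inherits(fwd, "forward_model"))
  noise_diag <- as.numeric(noise_diag)
  if (length(noise_diag) == 1L) noise_diag <- rep(noise_diag, nrow(fwd$leadfield))
  if (any(noise_diag <= 0)) abort("noise variances must be positive")
  wh <- 1 / sqrt(noise_diag)
  Gw <- fwd$leadfield * wh                 # row-wise whitening
  gram <- tcrossprod(Gw)
  mu <- mean(diag(gram))
  K <- gram + lambda2 * mu * diag(nrow(gram))
  W <- t(solve(K, Gw))                     # (V*orient) x n_channels
  if (!all(is.finite(W))) abort("singular system: increase lambda2")
  structure(list(W = W, whitener = wh, lambda2 = lambda2,
                 vertex_coords = fwd$vertex_coords,
                 n_orient = fwd$n_orient),
            class = "inverse_operator")
}

#' Apply an inverse operator
#'
#' @param inv an [make_inverse()] operator.
#' @param x sensor vector or `n_channels x n_samples` matrix.
#' @return Source estimate matrix `(n_vertices * n_orient) x n_samples`.
#' @export
apply_inverse <- function(inv, x) {
  x <- as.matrix(x)
  inv$W %*% (x * inv$whitener)
}

# per-vertex magnitude of a source column (norm over orientations)
source_magnitude <- function(inv, s) {
  if (inv$n_orient == 1) return(abs(as.numeric(s)))
  m <- matrix(as.numeric(s), nrow = inv$n_orient)
  sqrt(colSums(m^2))
}

# global field power: spatial RMS across channels per sample
gfp <- function(x) sqrt(colMeans(x^2))

#' Average the events assigned to an atom
#'
#' Re-cuts epochs of +/- 0.5 s around every assigned timestamp (events whose
#' window exceeds the recording are dropped), averages them, and finds the
#' map latencies on the global field power (GFP) of the average: `PEAK` is
#' the GFP argmax and `SLOPE` the first sample on the ascending branch at or
#' above 50% of the peak GFP. The per-channel variance over the averaged
#' window provides the diagonal noise covariance for the inverse.
#'
#' @param atom a `csc_atom` with assigned events.
#' @param rec the [sensor_recording()] (same sensor type).
#' @return An object of class `"cluster_average"`: `avg`
#'   (`n_channels x T`), `gfp`, `peak_latency`, `slope_latency` (1-based
#'   samples), `noise_diag`, `n_events`, `flagged` (TRUE when the peak sits
#'   at the window edge and the atom should be skipped in mapping).
#' @export
average_cluster <- function(atom, rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  ev <- if (inherits(atom, "csc_atom")) atom$assigned_events else atom
  if (is.null(ev) || !nrow(ev)) abort("atom has no assigned events")
  sf <- rec$sfreq
  half <- round(0.5 * sf)
  centre <- ev$sample + 1L
  ok <- centre - half >= 1L & centre + half <= ncol(rec$data)
  centre <- centre[ok]
  if (!length(centre)) abort("no event window inside the recording")
  avg <- matrix(0, nrow(rec$data), 2L * half + 1L)
  for (s in centre) avg <- avg + rec$data[, (s - half):(s + half)]
  avg <- avg / length(centre)
  g <- gfp(avg)
  pk <- which.max(g)
  flagged <- pk == 1L || pk == length(g)
  slope <- slope_latency(g, pk)
  structure(list(avg = avg, gfp = g, sfreq = sf,
                 peak_latency = pk, slope_latency = slope,
                 noise_diag = pmax(apply(avg, 1L, var), .Machine$double.eps),
                 n_events = length(centre), flagged = flagged),
            class = "cluster_average")
}

# first sample at >= 50% of peak GFP on the ascending branch: one past the
# latest pre-peak sample strictly below half maximum
slope_latency <- function(g, pk) {
  if (pk <= 1L) return(1L)
  below <- which(g[seq_len(pk - 1L)] < 0.5 * g[pk])
  if (!length(below)) return(1L)
  min(tail(below, 1L) + 1L, pk - 1L)
}

#' @export
print.cluster_average <- function(x, ...) {
  cat(sprintf(
    "<cluster_average> %d events, peak @ %d, slope @ %d%s\n",
    x$n_events, x$peak_latency, x$slope_latency,
    if (x$flagged) " [flagged: peak at window edge]" else ""))
  invisible(x)
}

#' Binary activation map of a cluster average at one latency
#'
#' Localizes the averaged cluster with the minimum-norm operator at the
#' `SLOPE` or `PEAK` latency and binarizes the per-vertex magnitude at 50%
#' of its maximum.
#'
#' @param ca a [average_cluster()] result.
#' @param inv an [make_inverse()] operator (built with the cluster's
#'   `noise_diag`).
#' @param latency `"slope"` or `"peak"`, or an explicit 1-based sample.
#' @param binarize_frac binarization fraction (default 0.5).
#' @return A binary [cortical_map()].
#' @export
atom_iz_map <- function(ca, inv, latency = c("peak", "slope"),
                        binarize_frac = 0.5) {
  stopifnot(inherits(ca, "cluster_average"), inherits(inv, "inverse_operator"))
  if (is.character(latency)) {
    latency <- match.arg(latency)
    lat <- if (latency == "peak") ca$peak_latency else ca$slope_latency
  } else {
    lat <- as.integer(latency)
  }
  if (lat < 1L || lat > ncol(ca$avg)) abort("latency sample outside the window")
  act <- source_magnitude(inv, apply_inverse(inv, ca$avg[, lat]))
  amap <- cortical_map(act, inv$vertex_coords, "activation")
  binarize_map(amap, binarize_frac)
}

#' Combine per-atom binary maps into the predicted irritative zone
#'
#' Majority vote across atom maps (gradiometer and magnetometer atoms count
#' as independent contributions): vertices pointed to by MORE than half of
#' the maps are kept (strict inequality), then every vertex within
#' `smooth_mm` of a kept vertex is included.
#'
#' @param maps list of binary [cortical_map()]s on the same source space.
#' @param smooth_mm smoothing radius, millimetres (default 10).
#' @return A binary [cortical_map()]; empty (with a warning) when the vote
#'   keeps nothing.
#' @export
combine_atom_maps <- function(maps, smooth_mm = 10) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "cortical_map")))
  votes <- Reduce(`+`, lapply(maps, `[[`, "values"))
  keep <- as.numeric(votes > length(maps) / 2)
  out <- cortical_map(keep, maps[[1]]$vertex_coords, "binary")
  if (!any(keep > 0)) {
    warn("majority vote kept no vertex: empty irritative zone")
    return(out)
  }
  smooth_binary_map(out, smooth_mm)
}

#' Irritative zone from visually marked spikes
#'
#' Each marked spike is localized individually at its GFP peak latency
#' (searched within +/- 50 ms of the mark inside a +/- 0.5 s window), the
#' activation is binarized at 50% of its maximum, vertices present in at
#' least half of the per-spike maps are kept (non-strict), and the result
#' is smoothed within `smooth_mm`.
#'
#' @param events an [event_table()] of visual marks (>= 2 events).
#' @param rec the [sensor_recording()].
#' @param inv an [make_inverse()] operator.
#' @param smooth_mm smoothing radius (default 10).
#' @param binarize_frac binarization fraction (default 0.5).
#' @return A binary [cortical_map()].
#' @export
visual_spike_map <- function(events, rec, inv, smooth_mm = 10,
                             binarize_frac = 0.5) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (nrow(events) < 2L) abort("need at least 2 visually marked events")
  sf <- rec$sfreq
  half <- round(0.5 * sf)
  search <- round(0.05 * sf)
  maps <- list()
  for (i in seq_len(nrow(events))) {
    s0 <- events$sample[i] + 1L
    if (s0 - half < 1L || s0 + half > ncol(rec$data)) next
    win <- rec$data[, (s0 - half):(s0 + half), drop = FALSE]
    g <- gfp(win)
    ctr <- half + 1L
    look <- max(1L, ctr - search):min(length(g), ctr + search)
    lat <- look[which.max(g[look])]
    act <- source_magnitude(inv, apply_inverse(inv, win[, lat]))
    if (max(act) <= 0) next
    maps <- c(maps, list(binarize_map(
      cortical_map(act, inv$vertex_coords, "activation"), binarize_frac)))
  }
  if (length(maps) < 2L) abort("fewer than 2 usable spike windows")
  counts <- Reduce(`+`, lapply(maps, `[[`, "values"))
  keep <- as.numeric(counts >= length(maps) / 2)
  out <- cortical_map(keep, inv$vertex_coords, "binary")
  if (!any(keep > 0)) {
    warn("no vertex survived the per-spike vote")
    return(out)
  }
  smooth_binary_map(out, smooth_mm)
}
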