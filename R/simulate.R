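#' Biphasic spike waveform template
#'
#' Skewed derivative-of-Gaussian transient used as the planted
#' interictal-spike morphology: a sharp dominant deflection followed by a
#' broader, smaller wave of opposite polarity (the width of the trailing
#' lobe is 1.6x the leading one, so the sharp peak is unambiguous). Peak
#' absolute amplitude is 1; total duration is parameterized in seconds.
#'
#' @param width_s total waveform duration in seconds (typically 0.07-0.2).
#' @param sfreq sampling rate in Hz.
#' @return Numeric vector of `round(width_s * sfreq)` samples.
#' @export
spike_waveform <- function(width_s = 0.12, sfreq = 200) {
  n <- max(7L, round(width_s * sfreq))
  t <- seq(-3, 4.8, length.out = n)
  s <- ifelse(t < 0, 1, 1.6)
  w <- -(t / s^2) * exp(-t^2 / (2 * s^2))
  w / max(abs(w))
}

# quasi-uniform points on a hemispherical shell (Fibonacci lattice)
fibonacci_hemisphere <- function(n, radius, z_min = 0.05) {
  i <- seq_len(n) - 0.5
  z <- z_min + (1 - z_min) * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}

#' Simulate a dipolar forward model
#'
#' Places source vertices on a hemispheric shell (default radius 80 mm) and
#' sensors on a concentric cap (radius 110 mm), and fills the leadfield with
#' smooth dipolar field patterns: each column is the radial component of the
#' field of a tangential current dipole at the vertex, computed from the
#' Biot-Savart leading term. Columns of nearby vertices are similar but
#' mutually distinguishable (normalized off-diagonal correlation < 0.99).
#'
#' @param n_channels number of sensors.
#' @param n_vertices number of source vertices (>= 10).
#' @param seed integer seed (used for a small deterministic jitter of the
#'   vertex shell that breaks lattice symmetries).
#' @param n_orient 1 for a fixed tangential orientation per vertex, 3 for
#'   free orientations (two tangential plus radial columns per vertex).
#' @param radius_mm source-shell radius in millimetres.
#' @param sensor_types per-channel sensor labels (recycled).
#' @return A [forward_model()].
#' @export
simulate_forward <- function(n_channels, n_vertices, seed = 1, n_orient = 1,
                             radius_mm = 80, sensor_types = "grad") {
  if (n_vertices < 10) abort("need at least 10 vertices")
  set.seed(seed)
  sens <- fibonacci_hemisphere(n_channels, 110, z_min = 0.1)
  vert <- fibonacci_hemisphere(n_vertices, radius_mm, z_min = 0.05)
  vert <- vert + matrix(rnorm(length(vert), sd = 0.5), ncol = 3)
  if (any(!is.finite(vert))) abort("degenerate geometry")
  sens_n <- sens / sqrt(rowSums(sens^2))          # radial sensing direction

  dipole_pattern <- function(r0, q) {
    d <- sweep(sens, 2L, r0)                       # sensor - source
    cx <- cbind(q[2] * d[, 3] - q[3] * d[, 2],
                q[3] * d[, 1] - q[1] * d[, 3],
                q[1] * d[, 2] - q[2] * d[, 1])     # q x d
    rowSums(cx * sens_n) / (rowSums(d^2))^1.5 * 1e5
  }

  cols <- vector("list", n_vertices)
  for (j in seq_len(n_vertices)) {
    r0 <- vert[j, ]
    rad <- r0 / sqrt(sum(r0^2))
    # tangential basis at the vertex
    a <- if (abs(rad[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- c(rad[2] * a[3] - rad[3] * a[2],
            rad[3] * a[1] - rad[1] * a[3],
            rad[1] * a[2] - rad[2] * a[1])
    t1 <- t1 / sqrt(sum(t1^2))
    if (n_orient == 1) {
      cols[[j]] <- dipole_pattern(r0, t1)
    } else {
      t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
              rad[3] * t1[1] - rad[1] * t1[3],
              rad[1] * t1[2] - rad[2] * t1[1])
      cols[[j]] <- cbind(dipole_pattern(r0, t1), dipole_pattern(r0, t2),
                         dipole_pattern(r0, rad))
    }
  }
  fwd <- forward_model(do.call(cbind, cols), vert, n_orient,
                       sprintf("%s%03d", "SIM", seq_len(n_channels)))
  attr(fwd, "sensor_types") <- rep_len(sensor_types, n_channels)
  fwd
}

# 1/f-shaped Gaussian noise, unit RMS, length n at rate sfreq
pink_noise <- function(n, sfreq) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f)                      # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a recording with planted rank-1 spike sources
#'
#' Plants `n_atoms` repeating dipolar spike sources in 1/f background noise.
#' Each source is the outer product of a unit-normalized leadfield column
#' (its true spatial pattern) and a biphasic spike waveform; events are
#' placed at Poisson times thinned to a minimum separation of 0.5 s across
#' all sources. `snr` is the ratio of the spike's peak absolute amplitude to
#' the background RMS at the source's best channel; `snr = 0` yields pure
#' noise with the ground-truth event times still listed.
#'
#' @param fwd a [forward_model()] (fixed orientation).
#' @param n_atoms number of planted sources.
#' @param rate_per_min total event rate (summed over sources),
#'   events/minute; events are dealt round-robin to the sources.
#' @param duration_s recording length in seconds (>= 60).
#' @param snr peak-amplitude-to-noise ratio at the best channel.
#' @param seed integer seed; all randomness flows from it.
#' @param sfreq sampling rate in Hz.
#' @param spike_width_s vector of waveform widths recycled over atoms.
#' @return A list with elements `recording` (a [sensor_recording()]) and
#'   `truth` (ground truth: per-atom `u_true`, `v_true`, `event_times`,
#'   `true_vertex`, a synthetic resection sphere and the seed).
#' @export
simulate_recording <- function(fwd, n_atoms = 2, rate_per_min = 3,
                               duration_s = 1200, snr = 4, seed = 1,
                               sfreq = 200,
                               spike_width_s = c(0.12, 0.09, 0.16, 0.07)) {
  stopifnot(inherits(fwd, "forward_model"))
  if (fwd$n_orient != 1) abort("simulation requires a fixed-orientation model")
  if (duration_s < 60) abort("duration must be at least 60 s")
  min_sep <- 0.5
  lambda <- rate_per_min / 60
  if (lambda * min_sep > 0.8) {
    abort("requested rate is incompatible with the 0.5 s separation constraint")
  }
  set.seed(seed)
  n_samp <- round(duration_s * sfreq)
  nchan <- nrow(fwd$leadfield)

  # pick well-separated true vertices
  verts <- integer(n_atoms)
  cand <- sample.int(n_vertices(fwd))
  verts[1] <- cand[1]
  k <- 1L
  for (j in cand[-1]) {
    if (k == n_atoms) break
    d <- sqrt(rowSums((fwd$vertex_coords[verts[seq_len(k)], , drop = FALSE] -
                       matrix(fwd$vertex_coords[j, ], k, 3, byrow = TRUE))^2))
    if (all(d > 30)) { k <- k + 1L; verts[k] <- j }
  }
  if (k < n_atoms) verts[(k + 1):n_atoms] <- cand[seq_len(n_atoms - k)]

  # global Poisson event stream thinned to >= 0.5 s separation,
  # then dealt round-robin to atoms
  times <- cumsum(rexp(ceiling(lambda * duration_s * 2) + 20, rate = lambda))
  times <- times[times < duration_s - 1]
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= min_sep && tt > 1) { keep <- c(keep, tt); last <- tt }
  }
  atom_of <- rep(seq_len(n_atoms), length.out = length(keep))

  noise <- t(vapply(seq_len(nchan), function(i) pink_noise(n_samp, sfreq),
                    numeric(n_samp)))
  dat <- noise
  truth_atoms <- vector("list", n_atoms)
  for (a in seq_len(n_atoms)) {
    u <- fwd$leadfield[, verts[a]]
    u <- u / sqrt(sum(u^2))
    v <- spike_waveform(spike_width_s[(a - 1) %% length(spike_width_s) + 1], sfreq)
    best <- which.max(abs(u))
    amp <- if (snr > 0) snr * sd(noise[best, ]) / abs(u[best]) else 0
    ev <- keep[atom_of == a]
    for (tt in ev) {
      s0 <- round(tt * sfreq) + 1L
      idx <- s0:(s0 + length(v) - 1L)
      ok <- idx >= 1L & idx <= n_samp
      dat[, idx[ok]] <- dat[, idx[ok]] + amp * outer(u, v[ok])
    }
    # ground-truth timestamps mark the sharp peak of the waveform
    pk_off <- (which.max(abs(v)) - 1L) / sfreq
    truth_atoms[[a]] <- list(u_true = u, v_true = v, event_times = ev + pk_off,
                             true_vertex = verts[a])
  }
  rec <- sensor_recording(dat, sfreq,
                          channel_names = fwd$channel_names,
                          sensor_type = attr(fwd, "sensor_types") %||% "grad")
  truth <- list(
    atoms = truth_atoms,
    resection_center = fwd$vertex_coords[verts[1], ],
    resection_radius = 15,
    seed = seed
  )
  list(recording = rec, truth = truth)
}

#' Source-space mask of a resection volume
#'
#' Marks every vertex inside the resection sphere or within `margin_mm` of
#' its border.
#'
#' @param fwd a [forward_model()].
#' @param center length-3 centre, millimetres.
#' @param radius_mm resection radius (> 0).
#' @param margin_mm extra margin beyond the border (default 3).
#' @return A binary [cortical_map()].
#' @export
make_resection_mask <- function(fwd, center, radius_mm, margin_mm = 3) {
  if (radius_mm <= 0) abort("radius must be positive")
  d <- sqrt(rowSums(sweep(fwd$vertex_coords, 2L, center)^2))
  vals <- as.numeric(d <= radius_mm + margin_mm)
  if (!any(vals > 0)) abort("no vertex inside the resection mask")
  cortical_map(vals, fwd$vertex_coords, "binary")
}
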