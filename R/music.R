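#' Single-dipole MUSIC scan
#'
#' Scans every source-space vertex for the best single equivalent current
#' dipole explaining a sensor-space pattern or short data window. The signal
#' subspace is spanned by the top `n_signal_dims` left singular vectors of
#' the window (a plain vector is treated as a one-column window); the
#' goodness of fit at a vertex is the squared cosine of the principal angle
#' between the vertex's leadfield span (one column with fixed orientation,
#' three with free orientations) and the signal subspace. The result is
#' invariant to rescaling and sign flips of the input.
#'
#' @param x numeric vector (a topography) or matrix `n_channels x n_samples`
#'   (a data window).
#' @param fwd a [forward_model()].
#' @param n_signal_dims dimension of the signal subspace (default 1: one
#'   dipolar source per scanned window).
#' @return A list of class `"dipole_fit"`: `vertex_index` (argmax vertex),
#'   `gof` in `[0, 1]`, `gof_all` (per-vertex values) and `n_signal_dims`.
#' @export
music_scan <- function(x, fwd, n_signal_dims = 1) {
  stopifnot(inherits(fwd, "forward_model"))
  x <- as.matrix(x)
  if (!any(x != 0)) abort("zero-norm window")
  if (ncol(x) < n_signal_dims) abort("window has fewer samples than n_signal_dims")
  sub <- svd(x, nu = n_signal_dims, nv = 0)$u
  gof <- music_gof(sub, music_gain(fwd))
  j <- which.max(gof)
  structure(list(vertex_index = j, gof = gof[j], gof_all = gof,
                 n_signal_dims = n_signal_dims),
            class = "dipole_fit")
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("<dipole_fit> vertex %d, gof %.3f\n", x$vertex_index, x$gof))
  invisible(x)
}

# Precompute per-vertex orthonormalized gain spans; cached on the forward
# model via an environment so repeated scans over the same model are cheap.
music_gain <- function(fwd) {
  cache <- attr(fwd, "music_cache")
  if (!is.null(cache) && !is.null(cache$gain)) return(cache$gain)
  nv <- n_vertices(fwd)
  if (fwd$n_orient == 1) {
    nrm <- sqrt(colSums(fwd$leadfield^2))
    nrm[nrm == 0] <- 1
    gain <- list(type = "fixed", Q = sweep(fwd$leadfield, 2L, nrm, "/"))
  } else {
    Qs <- vector("list", nv)
    for (j in seq_len(nv)) {
      Qs[[j]] <- qr.Q(qr(vertex_leadfield(fwd, j)))
    }
    gain <- list(type = "free", Qs = Qs)
  }
  gain
}

# squared subspace correlation between signal subspace `sub` (orthonormal
# columns) and each vertex's gain span
music_gof <- function(sub, gain) {
  if (gain$type == "fixed") {
    p <- crossprod(gain$Q, sub)                  # n_vertices x d
    # 1-D gain span vs d-dim subspace: cos^2 of the principal angle is the
    # squared norm of the projection of the unit gain onto the subspace
    gof <- rowSums(p^2)
  } else {
    gof <- vapply(gain$Qs, function(Q) {
      s <- svd(crossprod(Q, sub), nu = 0, nv = 0)$d
      s[1]^2
    }, numeric(1))
  }
  pmin(pmax(gof, 0), 1)
}
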