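#' 3-D convex hull (incremental)
#'
#' Incremental convex hull of a 3-D point cloud: starting from a
#' non-degenerate tetrahedron, each remaining point outside the current hull
#' removes its visible faces and is reconnected along the horizon edges.
#' Face normals are unit length and point outward.
#'
#' @param points numeric matrix `m x 3`.
#' @return A list of class `"hull3d"`: `faces` (`f x 3` vertex indices into
#'   `points`), `normals` (`f x 3`, outward unit), `offsets` (`n . x = d`
#'   plane constants) and `points`.
#' @export
convex_hull_3d <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L || nrow(pts) < 4L) {
    abort("need at least 4 points in 3-D")
  }
  scale <- max(1, max(abs(pts)))
  tol <- 1e-9 * scale

  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }

  ## initial simplex: extreme point, farthest point, farthest from the line,
  ## farthest from the plane
  i1 <- which.min(pts[, 1])
  d <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d)
  e1 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- t(apply(rel, 1L, cross3, b = e1))
  i3 <- which.max(rowSums(cr^2))
  nrm <- cross3(e1, pts[i3, ] - pts[i1, ])
  if (sqrt(sum(nrm^2)) <= tol) abort("degenerate hull: points are collinear")
  h <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= tol) abort("degenerate hull: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))

  face_geom <- function(f) {
    a <- pts[f[1], ]
    n <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    nn <- sqrt(sum(n^2))
    if (nn <= tol^2) return(NULL)
    n <- n / nn
    if (sum(n * (interior - a)) > 0) { n <- -n; f <- f[c(1, 3, 2)] }
    list(f = f, n = n, d = sum(n * a))
  }
  geo <- lapply(seq_len(nrow(faces)), function(i) face_geom(faces[i, ]))
  geo <- geo[!vapply(geo, is.null, logical(1))]

  rest <- setdiff(seq_len(nrow(pts)), c(i1, i2, i3, i4))
  for (p in rest) {
    q <- pts[p, ]
    vis <- vapply(geo, function(g) sum(g$n * q) - g$d > tol, logical(1))
    if (!any(vis)) next
    vis_faces <- geo[vis]
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(vis_faces, function(g) {
      rbind(g$f[c(1, 2)], g$f[c(2, 3)], g$f[c(3, 1)])
    }))
    key <- paste(edges[, 1], edges[, 2])
    rkey <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(key %in% rkey), , drop = FALSE]
    geo <- geo[!vis]
    for (e in seq_len(nrow(horizon))) {
      g <- face_geom(c(horizon[e, 1], horizon[e, 2], p))
      if (!is.null(g)) geo <- c(geo, list(g))
    }
  }
  structure(
    list(faces = do.call(rbind, lapply(geo, `[[`, "f")),
         normals = do.call(rbind, lapply(geo, `[[`, "n")),
         offsets = vapply(geo, `[[`, numeric(1), "d"),
         points = pts),
    class = "hull3d")
}

#' @export
print.hull3d <- function(x, ...) {
  cat(sprintf("<hull3d> %d facets over %d points\n",
              nrow(x$faces), nrow(x$points)))
  invisible(x)
}

# Euclidean distance from point q to triangle (a, b, c): project onto the
# plane; if the projection's barycentric coordinates are all non-negative
# the plane distance is the answer, otherwise the minimum over the three
# clamped edge segments.
point_triangle_distance <- function(q, a, b, c) {
  seg_dist <- function(p0, p1) {
    v <- p1 - p0
    tt <- sum((q - p0) * v) / max(sum(v^2), .Machine$double.eps)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((q - (p0 + tt * v))^2))
  }
  e0 <- b - a; e1 <- c - a
  n <- c(e0[2] * e1[3] - e0[3] * e1[2], e0[3] * e1[1] - e0[1] * e1[3],
         e0[1] * e1[2] - e0[2] * e1[1])
  n2 <- sum(n^2)
  if (n2 > 0) {
    w <- q - a
    dist_plane <- sum(w * n) / sqrt(n2)
    proj <- q - dist_plane * n / sqrt(n2)
    # barycentric coordinates of the projection
    d00 <- sum(e0 * e0); d01 <- sum(e0 * e1); d11 <- sum(e1 * e1)
    pv <- proj - a
    d20 <- sum(pv * e0); d21 <- sum(pv * e1)
    den <- d00 * d11 - d01 * d01
    if (den > 0) {
      v <- (d11 * d20 - d01 * d21) / den
      w2 <- (d00 * d21 - d01 * d20) / den
      if (v >= 0 && w2 >= 0 && v + w2 <= 1) return(abs(dist_plane))
    }
  }
  min(seg_dist(a, b), seg_dist(b, c), seg_dist(c, a))
}

# signed distance of one point to the hull surface (negative inside)
hull_signed_distance <- function(hull, q) {
  tolv <- 1e-9 * max(1, max(abs(hull$points)))
  inside <- all(hull$normals %*% q - hull$offsets <= tolv)
  d <- min(vapply(seq_len(nrow(hull$faces)), function(i) {
    f <- hull$faces[i, ]
    point_triangle_distance(q, hull$points[f[1], ], hull$points[f[2], ],
                            hull$points[f[3], ])
  }, numeric(1)))
  if (inside) -d else d
}

#' Signed distance of an irritative zone from a resection hull
#'
#' The resected area is converted to its convex hull and every active
#' vertex of the estimated irritative zone is given its Euclidean distance
#' to the hull surface, negated when the vertex lies inside the hull (so
#' the more negative the mean, the larger the overlap of the estimate with
#' the resection).
#'
#' @param iz a binary [cortical_map()] (the estimated irritative zone),
#'   non-empty.
#' @param ra the resected area: an `m x 3` point matrix or a binary
#'   [cortical_map()] whose active vertices are used.
#' @return A list of class `"distance_report"`: `mean_signed_distance_mm`,
#'   `distances` (per active IZ vertex), `n_iz_vertices`, `n_ra_points`,
#'   `size_ratio` (IZ size over RA size), `concordant` (any IZ vertex inside
#'   or on the hull).
#' @export
hull_distance <- function(iz, ra) {
  stopifnot(inherits(iz, "cortical_map"))
  act <- which(iz$values > 0)
  if (!length(act)) abort("empty irritative zone")
  ra_pts <- if (inherits(ra, "cortical_map")) {
    ra$vertex_coords[ra$values > 0, , drop = FALSE]
  } else {
    as.matrix(ra)
  }
  hull <- convex_hull_3d(ra_pts)
  qs <- iz$vertex_coords[act, , drop = FALSE]
  d <- vapply(seq_len(nrow(qs)), function(i) {
    hull_signed_distance(hull, qs[i, ])
  }, numeric(1))
  structure(
    list(mean_signed_distance_mm = mean(d), distances = d,
         n_iz_vertices = length(act), n_ra_points = nrow(ra_pts),
         size_ratio = length(act) / nrow(ra_pts),
         concordant = any(d <= 0)),
    class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(
    "<distance_report> mean signed distance %.2f mm (SD %.2f) over %d IZ vertices; %sconcordant\n",
    x$mean_signed_distance_mm, sd(x$distances), x$n_iz_vertices,
    if (x$concordant) "" else "not "))
  invisible(x)
}

#' @export
tidy.distance_report <- function(x, ...) {
  tibble(vertex = seq_along(x$distances), signed_distance_mm = x$distances)
}

#' @export
glance.distance_report <- function(x, ...) {
  tibble(mean_signed_distance_mm = x$mean_signed_distance_mm,
         sd_distance_mm = sd(x$distances),
         n_iz_vertices = x$n_iz_vertices,
         size_ratio = x$size_ratio,
         concordant = x$concordant)
}

#' Compare irritative-zone estimates across subjects
#'
#' Takes per-subject mean distances for several estimate types (visual,
#' slope, peak) and compares every pair of types with a paired two-sided
#' Wilcoxon signed-rank test. Zero differences are dropped first and the
#' exact distribution is used for up to 25 informative pairs (identical
#' vectors give p = 1 by convention); with a single subject the test is
#' skipped and only distances are reported.
#'
#' @param distances a data frame with columns `subject`, `estimate` and
#'   `distance_mm` (optionally `size_ratio`).
#' @return A list of class `"iz_comparison"`: `summary` (per-estimate mean,
#'   SD, n) and `tests` (pairwise tibble with n informative pairs and
#'   p-values, `NA` when skipped).
#' @export
compare_iz_estimates <- function(distances) {
  df <- as.data.frame(distances)
  stopifnot(all(c("subject", "estimate", "distance_mm") %in% names(df)))
  ests <- unique(df$estimate)
  summary <- do.call(rbind, lapply(ests, function(e) {
    d <- df$distance_mm[df$estimate == e]
    data.frame(estimate = e, n = length(d), mean_mm = mean(d),
               sd_mm = sd(d), stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(ests) >= 2) {
    prs <- utils::combn(ests, 2)
    for (i in seq_len(ncol(prs))) {
      a <- df[df$estimate == prs[1, i], c("subject", "distance_mm")]
      b <- df[df$estimate == prs[2, i], c("subject", "distance_mm")]
      m <- merge(a, b, by = "subject")
      if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) abort("unpaired inputs")
      p <- wilcoxon_paired_p(m$distance_mm.x, m$distance_mm.y)
      tests <- rbind(tests, data.frame(
        estimate_a = prs[1, i], estimate_b = prs[2, i],
        n = nrow(m), p_value = p, stringsAsFactors = FALSE))
    }
  }
  structure(list(summary = as_tibble(summary),
                 tests = if (is.null(tests)) NULL else as_tibble(tests),
                 data = as_tibble(df)),
            class = "iz_comparison")
}

# exact paired two-sided Wilcoxon signed-rank p; zeros dropped, p = 1 when
# nothing differs, NA for a single subject. For small n the exact null is
# enumerated over all sign assignments (average ranks handle ties, which
# stats::wilcox.test's exact path refuses); beyond that the standard exact
# or normal approximation is used.
wilcoxon_paired_p <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(1)
  n <- length(d)
  if (n <= 15L) {
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
    return(min(p, 1))
  }
  suppressWarnings(
    wilcox.test(d, exact = !any(duplicated(abs(d))), correct = FALSE)$p.value)
}

#' @export
print.iz_comparison <- function(x, ...) {
  cat("<iz_comparison>\n")
  print(x$summary)
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' @export
tidy.iz_comparison <- function(x, ...) x$summary

#' @export
glance.iz_comparison <- function(x, ...) {
  if (is.null(x$tests)) return(tibble(n_estimates = nrow(x$summary)))
  out <- x$tests
  out$comparison <- paste(out$estimate_a, "vs", out$estimate_b)
  tibble(n_estimates = nrow(x$summary),
         min_p = min(out$p_value, na.rm = TRUE))
}
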