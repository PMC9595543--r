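# Independent oracles used by the correctness tests.

# Dense convolutional design matrix for one epoch: columns are shifted
# copies of the rank-1 atom u v' flattened channel-major, so the z-step
# becomes an ordinary non-negative lasso in explicit form.
conv_design_matrix <- function(u, v, T_ep) {
  C <- length(u); L <- length(v); P <- T_ep - L + 1L
  D <- matrix(0, C * T_ep, P)
  for (t in seq_len(P)) {
    block <- matrix(0, C, T_ep)
    block[, t:(t + L - 1L)] <- outer(u, v)
    D[, t] <- as.numeric(block)
  }
  D
}

# Projected (proximal) gradient solver for
#   min_z 0.5 ||x - D z||^2 + lambda sum(z),  z >= 0
# -- an algorithm independent of the package's coordinate descent.
ista_nnlasso <- function(D, x, lambda, n_iter = 20000) {
  Lip <- max(eigen(crossprod(D), symmetric = TRUE, only.values = TRUE)$values)
  z <- numeric(ncol(D))
  Dtx <- crossprod(D, x)
  G <- crossprod(D)
  for (i in seq_len(n_iter)) {
    grad <- G %*% z - Dtx
    z_new <- pmax(0, z - (as.numeric(grad) + lambda) / Lip)
    if (max(abs(z_new - z)) < 1e-12) { z <- z_new; break }
    z <- z_new
  }
  z
}

nnlasso_objective <- function(D, x, z, lambda) {
  0.5 * sum((x - D %*% z)^2) + lambda * sum(z)
}

# Point-to-triangle distance by explicit KKT case enumeration (interior,
# three edges, three vertices) -- independent of the package's
# projection-plus-barycentric routine.
point_tri_dist_oracle <- function(q, a, b, c) {
  cand <- list(a, b, c)
  # edges: minimize over clamped parameter
  for (ed in list(list(a, b), list(b, c), list(c, a))) {
    v <- ed[[2]] - ed[[1]]
    tt <- sum((q - ed[[1]]) * v) / sum(v^2)
    tt <- min(max(tt, 0), 1)
    cand <- c(cand, list(ed[[1]] + tt * v))
  }
  # interior: solve the unconstrained 2x2 system in (s, t)
  e0 <- b - a; e1 <- c - a
  M <- rbind(c(sum(e0 * e0), sum(e0 * e1)), c(sum(e0 * e1), sum(e1 * e1)))
  rhs <- c(sum((q - a) * e0), sum((q - a) * e1))
  st <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (!is.null(st) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
    cand <- c(cand, list(a + st[1] * e0 + st[2] * e1))
  }
  min(vapply(cand, function(p) sqrt(sum((q - p)^2)), numeric(1)))
}

# brute-force signed hull distance: KKT point-triangle oracle over every
# facet plus the half-space inside test
hull_distance_oracle <- function(hull, q) {
  d <- min(vapply(seq_len(nrow(hull$faces)), function(i) {
    f <- hull$faces[i, ]
    point_tri_dist_oracle(q, hull$points[f[1], ], hull$points[f[2], ],
                          hull$points[f[3], ])
  }, numeric(1)))
  inside <- all(hull$normals %*% q - hull$offsets <= 1e-9 * max(1, max(abs(hull$points))))
  if (inside) -d else d
}
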