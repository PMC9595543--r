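#' Build an epoch tensor around stage-I timestamps
#'
#' Cuts 1 s windows centred on each candidate event. Epochs that would
#' exceed the recording bounds are dropped; every remaining epoch maps to
#' exactly one stage-I timestamp.
#'
#' @param rec a [sensor_recording()] (band-passed 2-90 Hz for sparse coding).
#' @param events an [event_table()].
#' @param epoch_len epoch length in seconds (default 1).
#' @return An object of class `"epoch_tensor"`: array `X`
#'   (`N x n_channels x T`), `sfreq`, `events` (the retained rows),
#'   `start_sample` (0-based start of each epoch).
#' @export
extract_epochs <- function(rec, events, epoch_len = 1) {
  stopifnot(inherits(rec, "sensor_recording"))
  sf <- rec$sfreq
  T_ep <- round(epoch_len * sf)
  half <- floor(T_ep / 2)
  n <- ncol(rec$data)
  centre <- events$sample + 1L              # to 1-based
  start <- centre - half
  ok <- start >= 1L & start + T_ep - 1L <= n
  events <- events[ok, , drop = FALSE]
  start <- start[ok]
  if (!length(start)) abort("no epochs inside the recording bounds")
  X <- array(0, dim = c(length(start), nrow(rec$data), T_ep))
  for (i in seq_along(start)) {
    X[i, , ] <- rec$data[, start[i]:(start[i] + T_ep - 1L)]
  }
  structure(list(X = X, sfreq = sf, events = events,
                 start_sample = start - 1L,
                 sensor_type = rec$sensor_type[1]),
            class = "epoch_tensor")
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<epoch_tensor> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

# full convolution of activation z (length P) with waveform v (length L):
# s[t] = sum_l v[l] z[t - l + 1], length P + L - 1
conv_full <- function(z, v) {
  n <- length(z) + length(v) - 1L
  if (all(z == 0)) return(numeric(n))
  Re(fft(fft(c(z, numeric(length(v) - 1L))) *
           fft(c(v, numeric(length(z) - 1L))), inverse = TRUE)) / n
}

# valid correlation: out[t] = sum_l a[l] x[t + l - 1], t = 1..(len(x)-len(a)+1)
valid_corr <- function(x, a) {
  E <- stats::embed(x, length(a))     # rows: x[t+L-1], ..., x[t]
  as.numeric(E %*% rev(a))
}

csc_objective <- function(X, atoms, lambda) {
  N <- dim(X)[1]
  obj <- 0
  for (n in seq_len(N)) {
    R <- X[n, , ]
    for (a in atoms) {
      s <- conv_full(a$z[n, ], a$v)
      R <- R - outer(a$u, s)
      obj <- obj + lambda * sum(a$z[n, ])
    }
    obj <- obj + 0.5 * sum(R^2)
  }
  obj
}

# Seeded initialization from random epochs' best-channel windows. A pool of
# candidate epochs is drawn and atoms take greedily spatially-diverse
# members of the pool (smallest max |correlation| of the peak-time snapshot
# with the snapshots already chosen), so K atoms do not all start on the
# same dominant source.
init_atoms <- function(X, K, L, seed) {
  set.seed(seed)
  N <- dim(X)[1]; C <- dim(X)[2]; T_ep <- dim(X)[3]
  P <- T_ep - L + 1L
  pool <- sample.int(N, min(N, max(5L * K, 10L)))
  snaps <- vapply(pool, function(n) {
    ep <- X[n, , ]
    X[n, , arrayInd(which.max(abs(ep)), dim(ep))[2]]
  }, numeric(C))                                   # C x pool
  amp <- vapply(pool, function(n) max(abs(X[n, , ])), numeric(1))
  chosen <- which.max(amp)
  while (length(chosen) < K) {
    cand <- setdiff(seq_along(pool), chosen)
    if (!length(cand)) { chosen <- c(chosen, chosen[1]); next }
    sim <- vapply(cand, function(i) {
      cc <- abs(suppressWarnings(cor(snaps[, i], snaps[, chosen, drop = FALSE])))
      cc <- cc[is.finite(cc)]
      if (!length(cc)) 1 else max(cc)
    }, numeric(1))
    chosen <- c(chosen, cand[which.min(sim)])
  }
  picks <- pool[chosen]
  atoms <- vector("list", K)
  for (k in seq_len(K)) {
    ep <- X[picks[k], , ]
    ij <- arrayInd(which.max(abs(ep)), dim(ep))
    c0 <- ij[1]; t0 <- ij[2]
    # place the dominant sample at the canonical atom position so early
    # activation latencies stay representable
    t_start <- min(max(1L, t0 - max(2L, L %/% 5) + 1L), T_ep - L + 1L)
    v <- ep[c0, t_start:(t_start + L - 1L)]
    u <- ep[, t0]
    u <- u / max(sqrt(sum(u^2)), .Machine$double.eps)
    v <- v / max(sqrt(sum(v^2)), .Machine$double.eps)
    atoms[[k]] <- list(u = u, v = v, z = matrix(0, N, P))
  }
  atoms
}

# Shift an atom's waveform so its dominant sample sits at a canonical
# position, compensating the activations; entries shifted out of range are
# dropped, so the caller must guard with an objective check.
shift_atom <- function(a, target) {
  s <- target - which.max(abs(a$v))
  if (s == 0L) return(NULL)
  L <- length(a$v); P <- ncol(a$z)
  v <- numeric(L)
  if (s > 0) v[(1 + s):L] <- a$v[1:(L - s)] else v[1:(L + s)] <- a$v[(1 - s):L]
  z <- matrix(0, nrow(a$z), P)
  if (s > 0) {
    keep <- seq_len(P - s)
    z[, keep] <- a$z[, keep + s]
  } else {
    keep <- (1 - s):P
    z[, keep] <- a$z[, keep + s]
  }
  list(u = a$u, v = v, z = z)
}

# exact minimizer of ||w - Z v||^2 (+ scale) over the unit ball via
# trust-region bisection on the Tikhonov multiplier
ball_ls <- function(A, b) {
  v <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(v) && sqrt(sum(v^2)) <= 1) return(v)
  lo <- 0
  hi <- max(sqrt(sum(b^2)), 1)
  for (i in 1:200) {
    hi_v <- tryCatch(solve(A + hi * diag(nrow(A)), b), error = function(e) NULL)
    if (!is.null(hi_v) && sqrt(sum(hi_v^2)) < 1) break
    hi <- hi * 2
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    v <- solve(A + mid * diag(nrow(A)), b)
    if (sqrt(sum(v^2)) > 1) lo <- mid else hi <- mid
  }
  v <- solve(A + hi * diag(nrow(A)), b)
  v
}

#' Rank-1 multivariate convolutional sparse coding
#'
#' Learns `K` rank-1 spatiotemporal atoms (spatial pattern `u`, temporal
#' waveform `v`, both constrained to the unit l2 ball) and non-negative
#' sparse activations `z` from an epoch tensor, by minimizing
#' `sum_n 0.5 * ||X_n - sum_k z_k^n * (u_k v_k')||^2 + lambda * sum_k ||z_k^n||_1`.
#' Alternating minimization: the z-step solves a non-negative convolutional
#' lasso per epoch by coordinate descent (compiled); the (u,v)-step solves
#' each atom's ball-constrained least-squares problem exactly, so the
#' objective is non-increasing across outer iterations. Atoms are initialized
#' from random epochs' best-channel windows (seeded) and sign-fixed so the
#' largest-magnitude sample of `v` is positive.
#'
#' @param epochs an `epoch_tensor` from [extract_epochs()].
#' @param K number of atoms (default 3).
#' @param lambda activation l1 weight as a fraction of `lambda_max`, the
#'   smallest weight that zeroes every activation (default 0.1) -- the
#'   scale-free convention of convolutional dictionary learning; the
#'   effective weight is fixed at the first iteration.
#' @param n_iter maximum outer iterations (default 40).
#' @param seed integer seed for the initialization.
#' @param atom_len_s temporal extent of an atom in seconds (default 0.5).
#' @param tol relative objective-change stopping tolerance (default 1e-5).
#' @param cd_sweeps,cd_tol sweep cap and relative move tolerance of the
#'   per-epoch coordinate descent; looser values trade z-step exactness for
#'   speed without breaking the monotone-objective guarantee.
#' @return A list of class `"atom_fit"`: `atoms` (each with `u`, `v`, `z`
#'   `[N x P]`, `sensor_type`), `objective` (per-iteration trace), `epochs`
#'   metadata.
#' @export
fit_rank1_csc <- function(epochs, K = 3, lambda = 0.1, n_iter = 40, seed = 1,
                          atom_len_s = 0.5, tol = 1e-5, cd_sweeps = 30,
                          cd_tol = 1e-5) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  if (K < 1) abort("K must be at least 1")
  X <- epochs$X
  N <- dim(X)[1]; C <- dim(X)[2]; T_ep <- dim(X)[3]
  L <- round(atom_len_s * epochs$sfreq)
  if (L > T_ep) abort("atom length exceeds the epoch length")
  P <- T_ep - L + 1L
  # standardize so the l1 weight acts on a unit-variance scale; u, v and the
  # event assignment (MAD-relative) are invariant, z is in standardized units
  x_scale <- sd(X)
  if (is.finite(x_scale) && x_scale > 0) X <- X / x_scale
  atoms <- init_atoms(X, K, L, seed)
  obj_trace <- numeric(0)
  lambda_eff <- lambda

  if (all(X == 0)) {
    # degenerate input: zero activations are optimal
    for (k in seq_len(K)) atoms[[k]]$z <- matrix(0, N, P)
    return(structure(list(atoms = finalize_atoms(atoms, epochs),
                          objective = 0, epochs = epochs),
                     class = "atom_fit"))
  }

  # channels x (epochs*time) view of the tensor, column index (n, t) with n
  # fastest -- aligns with column-major flattening of N x T matrices
  Xmat <- matrix(aperm(X, c(2, 1, 3)), C, N * T_ep)

  conv_rows <- function(z, v) {                        # N x T reconstructions
    t(vapply(seq_len(N), function(n) conv_full(z[n, ], v), numeric(T_ep)))
  }

  for (it in seq_len(n_iter)) {
    ## ---- z-step: non-negative convolutional lasso per epoch ----
    U <- vapply(atoms, `[[`, numeric(C), "u")          # C x K
    V <- vapply(atoms, `[[`, numeric(L), "v")          # L x K
    udot <- crossprod(U)
    vcc <- array(0, dim = c(K, K, 2L * L - 1L))
    for (k in seq_len(K)) for (k2 in seq_len(K)) {
      # index d+L holds sum_l v_k[l] v_k2[l+d]
      vcc[k, k2, ] <- conv_full(rev(V[, k]), V[, k2])
    }
    Rall <- crossprod(U, Xmat)                         # K x (N*T)
    b_all <- array(0, dim = c(K, P, N))
    for (n in seq_len(N)) {
      r <- matrix(Rall[, n + N * (seq_len(T_ep) - 1L)], K, T_ep)
      b_all[, , n] <- t(vapply(seq_len(K), function(k) {
        valid_corr(r[k, ], V[, k])
      }, numeric(P)))
    }
    if (it == 1L) {
      # lambda is a fraction of lambda_max, the smallest weight that zeroes
      # every activation -- the scale-free convention of convolutional
      # dictionary learning
      lambda_eff <- lambda * max(abs(b_all))
    }
    for (n in seq_len(N)) {
      zmat <- t(vapply(seq_len(K), function(k) atoms[[k]]$z[n, ], numeric(P)))
      res <- csc_cd_epoch(matrix(b_all[, , n], K, P), udot, as.numeric(vcc),
                          L, matrix(zmat, K, P), lambda_eff, cd_sweeps, cd_tol)
      for (k in seq_len(K)) atoms[[k]]$z[n, ] <- res$z[k, ]
    }

    ## ---- (u,v)-step: per-atom ball-constrained least squares ----
    S <- lapply(seq_len(K), function(k) {
      conv_rows(atoms[[k]]$z, atoms[[k]]$v)            # N x T
    })
    for (k in seq_len(K)) {
      cross <- vapply(seq_len(K), function(j) sum(S[[j]] * S[[k]]), numeric(1))
      # u_k: Hessian proportional to identity -> LS solution projected
      if (cross[k] > 0) {
        num <- as.numeric(Xmat %*% as.numeric(S[[k]]))
        for (j in seq_len(K)) if (j != k) {
          num <- num - atoms[[j]]$u * cross[j]
        }
        u <- num / cross[k]
        nu <- sqrt(sum(u^2))
        if (nu > 1) u <- u / nu
        atoms[[k]]$u <- u
      }
      # v_k: Toeplitz normal equations, exact ball constraint
      u <- atoms[[k]]$u
      uu <- sum(u^2)
      W <- matrix(as.numeric(u %*% Xmat), N, T_ep)     # w_n = X_n' u, rows
      for (j in seq_len(K)) if (j != k) {
        W <- W - sum(atoms[[j]]$u * u) * S[[j]]
      }
      bv <- numeric(L)
      acf_sum <- numeric(L)
      for (n in seq_len(N)) {
        z <- atoms[[k]]$z[n, ]
        if (all(z == 0)) next
        bv <- bv + valid_corr(W[n, ], z)               # length T-P+1 = L
        cc <- conv_full(rev(z), z)                     # autocorrelation
        acf_sum <- acf_sum + cc[P:(P + L - 1L)]        # lags 0..L-1
      }
      if (any(acf_sum != 0) && uu > 0) {
        A <- uu * stats::toeplitz(acf_sum)
        atoms[[k]]$v <- ball_ls(A, bv)
        # refresh this atom's reconstruction for subsequent atoms
        S[[k]] <- conv_rows(atoms[[k]]$z, atoms[[k]]$v)
      }
    }
    Smat <- vapply(S, as.numeric, numeric(N * T_ep))   # (N*T) x K
    U <- vapply(atoms, `[[`, numeric(C), "u")
    obj <- 0.5 * sum((Xmat - U %*% t(Smat))^2) +
      lambda_eff * sum(vapply(atoms, function(a) sum(a$z), numeric(1)))

    # recenter atoms (canonical peak position) when it does not hurt the
    # objective; removes the waveform/activation shift ambiguity
    target <- max(2L, L %/% 5)
    shifted <- lapply(atoms, shift_atom, target = target)
    if (any(!vapply(shifted, is.null, logical(1)))) {
      cand <- atoms
      for (k in seq_len(K)) {
        if (!is.null(shifted[[k]])) {
          cand[[k]]$u <- shifted[[k]]$u
          cand[[k]]$v <- shifted[[k]]$v
          cand[[k]]$z <- shifted[[k]]$z
        }
      }
      S2 <- lapply(cand, function(a) conv_rows(a$z, a$v))
      Smat2 <- vapply(S2, as.numeric, numeric(N * T_ep))
      obj2 <- 0.5 * sum((Xmat - U %*% t(Smat2))^2) +
        lambda_eff * sum(vapply(cand, function(a) sum(a$z), numeric(1)))
      if (obj2 <= obj + 1e-12 * max(1, abs(obj))) {
        atoms <- cand
        obj <- obj2
      }
    }
    obj_trace <- c(obj_trace, obj)
    if (it > 1) {
      rel <- (obj_trace[it - 1] - obj) / max(abs(obj_trace[it - 1]), 1e-12)
      if (rel < tol) break
    }
  }
  structure(list(atoms = finalize_atoms(atoms, epochs),
                 objective = obj_trace, epochs = epochs),
            class = "atom_fit")
}

# sign convention + bundle per-atom metadata
finalize_atoms <- function(atoms, epochs) {
  lapply(seq_along(atoms), function(k) {
    a <- atoms[[k]]
    if (length(a$v) && a$v[which.max(abs(a$v))] < 0) {
      a$u <- -a$u; a$v <- -a$v
    }
    a$k <- k
    a$sfreq <- epochs$sfreq
    a$sensor_type <- epochs$sensor_type
    a$epoch_events <- epochs$events
    a$epoch_start <- epochs$start_sample
    a$assigned_events <- NULL
    a$score <- NA_real_
    structure(a, class = "csc_atom")
  })
}

#' @export
print.csc_atom <- function(x, ...) {
  cat(sprintf("<csc_atom %d> ||u||=%.3f ||v||=%.3f, %d assigned events, score %.3f\n",
              x$k, sqrt(sum(x$u^2)), sqrt(sum(x$v^2)),
              NROW(x$assigned_events), x$score))
  invisible(x)
}

# robust activation scale; see methods vignette for the degenerate-sparse
# fallbacks
activation_scale <- function(zpos) {
  if (!length(zpos)) return(0)
  s <- mad(zpos, constant = 1)
  if (s == 0) s <- mean(abs(zpos - median(zpos)))
  s
}

#' Assign events to an atom by an iterative MAD threshold
#'
#' Each epoch contributes its maximal activation value and latency. Epochs
#' whose maximum reaches `theta * MAD` (MAD of the pooled non-zero
#' activations) are assigned to the atom; `theta` starts at 7 and decreases
#' on a fixed grid until at least `min_events` (15) epochs are assigned or
#' the floor of 1.5 is reached. Assigned timestamps are shifted to the
#' activation latency plus the atom's sharp-peak offset (`argmax |v|`), so
#' events align at the spike peak.
#'
#' @param atom a `csc_atom` from [fit_rank1_csc()].
#' @param cfg a [pipeline_config()].
#' @return The atom with `assigned_events` (an [event_table()], stage
#'   `"cluster:<k>"`), `theta_used` and per-event `latency` filled. An
#'   all-zero activation yields an empty assignment.
#' @export
assign_events <- function(atom, cfg = pipeline_config()) {
  stopifnot(inherits(atom, "csc_atom"))
  z <- atom$z
  N <- nrow(z)
  mx <- apply(z, 1L, max)
  lat <- apply(z, 1L, which.max)          # 1-based within epoch
  zpos <- z[z > 0]
  sf <- atom$sfreq
  if (!length(zpos)) {
    atom$assigned_events <- empty_assignment(atom)
    atom$theta_used <- NA_real_
    return(atom)
  }
  s <- activation_scale(zpos)
  grid <- cfg$mad_grid
  sel <- logical(N)
  theta_used <- tail(grid, 1)
  for (theta in grid) {
    sel <- if (s > 0) mx >= theta * s else mx > 0
    theta_used <- theta
    if (sum(sel) >= cfg$min_events) break
  }
  idx <- which(sel)
  pk_off <- which.max(abs(atom$v)) - 1L
  time_s <- (atom$epoch_start[idx] + (lat[idx] - 1L) + pk_off) / sf
  dup <- duplicated(time_s)
  idx <- idx[!dup]; time_s <- time_s[!dup]
  ev <- event_table(time_s, sf, stage = paste0("cluster:", atom$k),
                    gof = NA_real_, sensor_type = atom$sensor_type)
  atom$assigned_events <- ev
  atom$assigned_epochs <- idx[order(time_s)]
  atom$latency <- lat[idx][order(time_s)]
  atom$theta_used <- theta_used
  atom
}

empty_assignment <- function(atom) {
  ev <- event_table(numeric(0), atom$sfreq, stage = character(0),
                    gof = numeric(0), sensor_type = character(0))
  ev
}

# three 0-1 features averaged into the atom score
combine_atom_score <- function(f1, f2, n_events, cap = 20) {
  f3 <- min(n_events / cap, 1)
  (f1 + max(0, f2) + f3) / 3
}

#' Score an atom's cluster quality
#'
#' Three features, each in `[0, 1]`, averaged: the MUSIC dipolarity of the
#' spatial pattern `u`; the mean Pearson correlation between `v` and the
#' assigned epochs' time course at the channel with maximum `|u|`, aligned
#' at the activation latency (clamped at 0, and 0 when nothing is
#' assigned); and the cluster population `min(n_events / 20, 1)`.
#'
#' @param atom a `csc_atom` with events assigned ([assign_events()]).
#' @param epochs the `epoch_tensor` the atom was fitted on.
#' @param fwd a [forward_model()].
#' @param cfg a [pipeline_config()].
#' @return The atom with `features` and `score` filled.
#' @export
score_atom <- function(atom, epochs, fwd, cfg = pipeline_config()) {
  stopifnot(inherits(atom, "csc_atom"), inherits(epochs, "epoch_tensor"))
  f1 <- music_scan(atom$u, fwd)$gof
  idx <- atom$assigned_epochs
  L <- length(atom$v)
  T_ep <- dim(epochs$X)[3]
  if (length(idx)) {
    best <- which.max(abs(atom$u))
    rr <- vapply(seq_along(idx), function(i) {
      t0 <- min(atom$latency[i], T_ep - L + 1L)
      seg <- epochs$X[idx[i], best, t0:(t0 + L - 1L)]
      if (sd(seg) == 0 || sd(atom$v) == 0) return(0)
      cor(atom$v, seg)
    }, numeric(1))
    f2 <- mean(rr)
  } else {
    f2 <- 0
  }
  n_ev <- length(idx)
  atom$features <- c(dipolarity = f1, waveform_corr = max(0, f2),
                     population = min(n_ev / cfg$events_cap, 1))
  atom$score <- combine_atom_score(f1, f2, n_ev, cfg$events_cap)
  atom
}
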