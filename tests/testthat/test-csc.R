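make_toy_epochs <- function(X, sfreq = 200) {
  N <- dim(X)[1]
  ev <- event_table(seq_len(N), sfreq, stage = "stage1",
                    sensor_type = "grad")
  structure(list(X = X, sfreq = sfreq, events = ev,
                 start_sample = as.integer(seq_len(N)) * 0L,
                 sensor_type = "grad"),
            class = "epoch_tensor")
}

test_that("a noiseless planted atom is recovered nearly exactly", {
  set.seed(4)
  C <- 12; T_ep <- 200; L <- 100; N <- 20
  u <- rnorm(C); u <- u / sqrt(sum(u^2))
  v <- spike_waveform(0.12, 200)
  v <- c(v, numeric(L - length(v))); v <- v / sqrt(sum(v^2))
  X <- array(0, dim = c(N, C, T_ep))
  lat <- sample(15:(T_ep - L), N, replace = TRUE)
  for (n in seq_len(N)) {
    amp <- runif(1, 5, 10)
    X[n, , lat[n]:(lat[n] + L - 1)] <- X[n, , lat[n]:(lat[n] + L - 1)] +
      amp * outer(u, v)
  }
  ep <- make_toy_epochs(X)
  fit <- fit_rank1_csc(ep, K = 1, lambda = 1e-4, n_iter = 60, seed = 2,
                       atom_len_s = 0.5, cd_sweeps = 200, cd_tol = 1e-9)
  a <- fit$atoms[[1]]
  expect_gt(abs(cor(a$u, u)), 0.99)
  # the waveform is identified up to a time shift absorbed by z
  lag_corr <- vapply(0:40, function(s) {
    vv <- c(numeric(s), v)[seq_along(v)]
    abs(cor(a$v, vv))
  }, numeric(1))
  expect_gt(max(lag_corr), 0.99)
  # reconstruction residual below 1% of signal energy
  Xs <- X / sd(X)
  resid <- 0
  for (n in seq_len(N)) {
    s <- megspike:::conv_full(a$z[n, ], a$v)
    resid <- resid + sum((Xs[n, , ] - outer(a$u, s))^2)
  }
  expect_lt(resid / sum(Xs^2), 0.01)
})

test_that("an all-zero epoch tensor yields zero activations and zero objective", {
  X <- array(0, dim = c(4, 3, 60))
  ep <- make_toy_epochs(X, sfreq = 100)
  fit <- fit_rank1_csc(ep, K = 2, lambda = 0.1, n_iter = 5, seed = 1,
                       atom_len_s = 0.2)
  expect_true(all(vapply(fit$atoms, function(a) all(a$z == 0), logical(1))))
  expect_equal(sum(fit$objective), 0)
})

test_that("the objective is monotone non-increasing on a noisy fixture", {
  set.seed(9)
  X <- array(rnorm(15 * 6 * 120), dim = c(15, 6, 120))
  ep <- make_toy_epochs(X)
  fit <- fit_rank1_csc(ep, K = 2, lambda = 0.1, n_iter = 20, seed = 3,
                       atom_len_s = 0.3)
  o <- fit$objective
  expect_true(all(diff(o) <= 1e-9 * pmax(abs(o[-length(o)]), 1)))
})

test_that("the z-step matches a generic non-negative lasso oracle", {
  # small instance: N = 5 epochs, 4 channels, T = 40, L = 8, K = 1
  set.seed(7)
  C <- 4; T_ep <- 40; L <- 8; N <- 5
  u <- rnorm(C); u <- u / sqrt(sum(u^2))
  v <- rnorm(L); v <- v / sqrt(sum(v^2))
  lambda <- 0.1
  X <- array(rnorm(N * C * T_ep, sd = 0.3), dim = c(N, C, T_ep))
  for (n in 1:3) X[n, , 10:(10 + L - 1)] <- X[n, , 10:(10 + L - 1)] + 2 * outer(u, v)
  P <- T_ep - L + 1L
  D <- conv_design_matrix(u, v, T_ep)
  udot <- matrix(sum(u * u), 1, 1)
  vcc <- megspike:::conv_full(rev(v), v)
  for (n in seq_len(N)) {
    x <- as.numeric(X[n, , ])
    r <- as.numeric(u %*% X[n, , ])
    b <- matrix(megspike:::valid_corr(r, v), 1, P)
    z0 <- matrix(0, 1, P)
    res <- megspike:::csc_cd_epoch(b, udot, vcc, L, z0, lambda,
                                   max_sweeps = 5000, tol = 1e-12)
    z_cd <- as.numeric(res$z)
    z_or <- ista_nnlasso(D, x, lambda)
    f_cd <- nnlasso_objective(D, x, z_cd, lambda)
    f_or <- nnlasso_objective(D, x, z_or, lambda)
    expect_lt(abs(f_cd - f_or), 1e-6)
    expect_true(all(z_cd >= 0))
  }
})

test_that("unit-ball and non-negativity constraints hold after fitting", {
  sf <- small_fit()
  for (a in sf$fit$atoms) {
    expect_lte(sum(a$u^2), 1 + 1e-9)
    expect_lte(sum(a$v^2), 1 + 1e-9)
    expect_true(all(a$z >= 0))
    # sign convention: dominant sample of v is positive
    expect_gt(a$v[which.max(abs(a$v))], 0)
  }
})

test_that("two planted atoms are recovered at snr 4 with assigned-event recall >= 0.8", {
  pr <- planted_recovery()
  for (m in pr$metrics) {
    expect_gt(m$u_corr, 0.95)
    expect_gt(m$v_corr, 0.9)
    expect_gte(m$recall, 0.8)
  }
})

test_that("MAD-threshold event assignment follows the documented schedule", {
  mk_atom <- function(z) {
    structure(list(u = c(1, 0), v = c(0.2, 1, 0.3), z = z, k = 1L,
                   sfreq = 200, sensor_type = "grad",
                   epoch_start = seq_len(nrow(z)) * 400L,
                   epoch_events = NULL),
              class = "csc_atom")
  }
  # 30 epochs with a clear activation, 70 at zero: all 30 taken at theta = 7
  z <- matrix(0, 100, 5)
  z[1:30, 3] <- 5
  a <- assign_events(mk_atom(z))
  expect_equal(nrow(a$assigned_events), 30)
  expect_equal(a$theta_used, 7)

  # 5 large and 20 moderate activations: the threshold must drop until
  # at least 15 events are captured
  z2 <- matrix(0, 100, 5)
  z2[1:5, 2] <- 10
  z2[6:25, 4] <- 3
  a2 <- assign_events(mk_atom(z2))
  expect_gte(nrow(a2$assigned_events), 15)
  expect_lt(a2$theta_used, 7)

  # all-zero activations: no events
  a3 <- assign_events(mk_atom(matrix(0, 10, 5)))
  expect_equal(nrow(a3$assigned_events), 0)
})

test_that("atom scoring combines dipolarity, waveform correlation and population", {
  expect_equal(megspike:::combine_atom_score(1, 1, 20), 1)
  expect_equal(megspike:::combine_atom_score(0.8, 0.5, 10), 0.6)
  expect_equal(megspike:::combine_atom_score(0.9, -0.4, 40), (0.9 + 0 + 1) / 3)

  # a true-pattern atom outscores a noise atom on the fitted fixture
  sf <- small_fit()
  fwd <- small_fwd()
  scored <- lapply(sf$fit$atoms, function(a) {
    score_atom(assign_events(a), sf$ep, fwd)
  })
  scores <- vapply(scored, `[[`, numeric(1), "score")
  noise_atom <- sf$fit$atoms[[1]]
  set.seed(77)
  noise_atom$u <- rnorm(length(noise_atom$u))
  noise_atom$u <- noise_atom$u / sqrt(sum(noise_atom$u^2))
  noise_atom$v <- rnorm(length(noise_atom$v))
  noise_atom$v <- noise_atom$v / sqrt(sum(noise_atom$v^2))
  noise_score <- score_atom(assign_events(noise_atom), sf$ep, fwd)$score
  expect_gt(max(scores), noise_score)
})

test_that("fitting is deterministic given the seed", {
  sf <- small_fit()
  fit2 <- fit_rank1_csc(sf$ep, K = 3, lambda = 0.1, n_iter = 30, seed = 11)
  expect_equal(fit2$objective, sf$fit$objective, tolerance = 1e-12)
  expect_equal(fit2$atoms[[1]]$u, sf$fit$atoms[[1]]$u, tolerance = 1e-12)
})
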