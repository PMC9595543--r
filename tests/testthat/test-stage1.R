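test_that("ICA recovers the planted topography and is deterministic", {
  st <- small_stage1()
  cs <- st$cs
  expect_equal(ncol(cs$topographies), 20)
  expect_equal(nrow(cs$sources), 20)
  u1 <- st$sim$truth$atoms[[1]]$u_true
  expect_gt(max(abs(cor(u1, cs$topographies))), 0.9)
  cs2 <- ica_decompose(st$rec, 20, seed = 11)
  expect_equal(cs2$topographies, cs$topographies, tolerance = 1e-8)
  expect_error(ica_decompose(sensor_recording(matrix(rnorm(50), 5, 10), 200), 20),
               "fewer channels")
})

test_that("component selection applies kurtosis band, sensor thresholds and gof override", {
  fwd <- small_fwd()
  # synthetic component set with controlled kurtosis and topographies
  n <- 20000
  set.seed(1)
  spiky <- rnorm(n); spiky[seq(500, n, by = 500)] <- 25      # high kurtosis
  gauss <- rnorm(n)                                          # kurtosis ~ 0
  g1 <- fwd$leadfield[, 10] / sqrt(sum(fwd$leadfield[, 10]^2))
  mk_cs <- function(topo, src, type) {
    structure(list(topographies = topo, sources = src, sfreq = 200,
                   sensor_type = type, vaf = rev(seq_len(ncol(topo))) / 100,
                   kurtosis = NULL, gof = NULL, selected = NULL),
              class = "component_set")
  }
  topo <- cbind(g1, matrix(rnorm(64 * 9), 64, 9))
  src <- rbind(spiky, matrix(rnorm(9 * n), 9, n))
  cs <- score_components(mk_cs(topo, src, "grad"), fwd)
  expect_true(cs$selected[1])             # dipolar + kurtosis in band
  expect_gt(cs$kurtosis[1], 1)
  expect_gt(cs$gof[1], 0.6)

  # dipolar but Gaussian time course: selected only via the gof override
  topo2 <- cbind(g1, matrix(rnorm(64 * 9), 64, 9))
  src2 <- rbind(gauss, matrix(rnorm(9 * n), 9, n))
  cs2 <- score_components(mk_cs(topo2, src2, "grad"), fwd)
  expect_lt(abs(cs2$kurtosis[1]), 0.2)
  if (cs2$gof[1] > 0.95) expect_true(cs2$selected[1]) else expect_false(cs2$selected[1])

  # gradiometer component below the 0.60 dipolarity threshold is rejected
  set.seed(2)
  junk <- rnorm(64)
  expect_lt(music_scan(junk, fwd)$gof, 0.6)  # white vector is non-dipolar
  topo3 <- cbind(junk, matrix(rnorm(64 * 9), 64, 9))
  cs3 <- suppressWarnings(score_components(mk_cs(topo3, src, "grad"), fwd))
  expect_false(cs3$selected[1])

  # magnetometer threshold is stricter (0.80): a 0.6-0.8 component flips
  expect_equal(pipeline_config()$gof_threshold_mag, 0.80)
})

test_that("white Gaussian noise is rejected by kurtosis while sparse transients pass", {
  set.seed(42)
  x <- rnorm(1e5)
  expect_lt(abs(e1071::kurtosis(x, type = 1)), 0.2)
  y <- rnorm(1e5); y[seq(1000, 1e5, by = 1000)] <- 30
  expect_gt(e1071::kurtosis(y, type = 1), 1)
})

test_that("adaptive peak detection lowers the threshold to the floor on sparse input", {
  fwd <- small_fwd()
  n <- 60000
  set.seed(8)
  src <- matrix(rnorm(20 * n, sd = 1e-3), 20, n)
  # component 1: an in-band sinusoidal background (bounded at ~0.7 robust
  # units) plus exactly 10 isolated impulses calibrated so their band-passed
  # main lobes reach ~3.2 units while impulse ringing plus background stays
  # below the floor of 2
  x <- 1e-3 * sin(2 * pi * 55 * (1:n) / 200)
  xf <- megspike:::fir_bandpass_vec(x, 20, 90, 200)
  imp <- numeric(n); imp[100] <- 1
  impf <- megspike:::fir_bandpass_vec(imp, 20, 90, 200)
  a_imp <- 3.2 * IQR(xf) / max(abs(impf))
  pos <- seq(3000, by = 5000, length.out = 10)
  x[pos] <- x[pos] + a_imp
  src[1, ] <- x
  g1 <- fwd$leadfield[, 3] / sqrt(sum(fwd$leadfield[, 3]^2))
  cs <- structure(list(topographies = cbind(g1, matrix(rnorm(64 * 19), 64, 19)),
                       sources = src, sfreq = 200, sensor_type = "grad",
                       vaf = rev(seq_len(20)) / 100,
                       kurtosis = NULL, gof = NULL,
                       selected = c(TRUE, rep(FALSE, 19))),
                  class = "component_set")
  pk <- detect_component_peaks(cs)
  expect_equal(pk$theta, 2)                       # floor reached
  expect_equal(nrow(pk$peaks[[1]]), 10)
  near <- vapply(pos, function(p) min(abs(pk$peaks[[1]]$sample - p)),
                 numeric(1))
  expect_true(all(near <= 3))                     # filtering may shift slightly

  # constant component: no candidates at all
  cs$sources[1, ] <- 1
  expect_error(detect_component_peaks(cs), class = "megspike_no_candidates")
})

test_that("peak refinement keeps the best event per refractory window", {
  st <- small_stage1()
  fwd <- small_fwd()
  # construct two close peaks (0.3 s apart) and two far ones (0.6 s)
  sim <- st$sim
  tr <- sim$truth$atoms[[1]]
  s1 <- round(tr$event_times[1] * 200)
  pk <- structure(list(
    peaks = list(tibble::tibble(sample = c(s1, s1 + 60, s1 + 500, s1 + 620),
                                amplitude = c(9, 5, 8, 8))),
    component = 1L, theta = 5, sfreq = 200, sensor_type = "grad"),
    class = "candidate_peaks")
  ev <- refine_peaks(pk, st$rec, fwd)
  # the two peaks 0.3 s apart collapse to one; the 0.6 s pair survives
  expect_true(nrow(ev) >= 2 && nrow(ev) <= 3)
  expect_gt(min(diff(ev$time_s)), 0.5)
})

test_that("refinement recovers planted events with high recall and valid separations", {
  st <- small_stage1()
  fwd <- small_fwd()
  pk <- detect_component_peaks(st$cs)
  ev <- refine_peaks(pk, st$rec, fwd)
  expect_gt(min(diff(ev$time_s)), 0.5)
  expect_true(all(ev$gof >= 0 & ev$gof <= 1))
  truth_times <- sort(unlist(lapply(st$sim$truth$atoms, `[[`, "event_times")))
  recall <- mean(vapply(truth_times, function(tt) {
    any(abs(ev$time_s - tt) <= 0.025)
  }, logical(1)))
  expect_gte(recall, 0.9)
})

test_that("refractory pruning holds for arbitrary peak configurations (fuzz)", {
  st <- small_stage1()
  fwd <- small_fwd()
  for (seed in 1:5) {
    set.seed(seed)
    samp <- sort(sample(2000:30000, 60))
    pk <- structure(list(
      peaks = list(tibble::tibble(sample = samp, amplitude = runif(60, 2, 10))),
      component = 1L, theta = 2, sfreq = 200, sensor_type = "grad"),
      class = "candidate_peaks")
    ev <- suppressWarnings(refine_peaks(pk, st$rec, fwd))
    if (nrow(ev) > 1) expect_gt(min(diff(ev$time_s)), 0.5)
  }
})

test_that("stage 1 is deterministic end to end given the seed", {
  st <- small_stage1()
  fwd <- small_fwd()
  ev1 <- refine_peaks(detect_component_peaks(st$cs), st$rec, fwd)
  cs2 <- score_components(ica_decompose(st$rec, 20, seed = 11), fwd)
  ev2 <- refine_peaks(detect_component_peaks(cs2), st$rec, fwd)
  expect_equal(ev1$time_s, ev2$time_s)
  expect_equal(ev1$gof, ev2$gof, tolerance = 1e-10)
})
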