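test_that("identity leadfield with vanishing regularization reproduces the input", {
  fwd <- toy_identity_fwd()
  inv <- make_inverse(fwd, rep(1, 8), lambda2 = 1e-10)
  x <- rnorm(8)
  expect_equal(as.numeric(apply_inverse(inv, x)), x, tolerance = 1e-6)
  expect_equal(as.numeric(apply_inverse(inv, numeric(8))), numeric(8))
})

test_that("a noiseless leadfield column localizes to its own vertex", {
  fwd <- small_fwd()
  inv <- make_inverse(fwd, rep(1, 64), lambda2 = 1e-8)
  j <- 123
  s <- megspike:::source_magnitude(inv, apply_inverse(inv, fwd$leadfield[, j]))
  expect_equal(which.max(s), j)
  expect_error(make_inverse(fwd, rep(0, 64)), "positive")
})

test_that("cluster averaging reproduces identical epochs and locates peak/slope", {
  # averaging identical noiseless epochs returns the single epoch
  fwd <- small_fwd()
  sim <- simulate_recording(fwd, 1, 6, 120, snr = 0, seed = 13)
  v <- spike_waveform(0.12, 200)
  u <- sim$truth$atoms[[1]]$u_true
  rec <- sim$recording
  rec$data[] <- 0
  for (tt in c(20, 40, 60)) {
    s0 <- tt * 200 + 1L
    rec$data[, s0:(s0 + length(v) - 1L)] <- rec$data[, s0:(s0 + length(v) - 1L)] +
      outer(u, v)
  }
  pk_off <- (which.max(abs(v)) - 1) / 200
  ev <- event_table(c(20, 40, 60) + pk_off, 200, stage = "visual",
                    sensor_type = "grad")
  ca <- average_cluster(structure(list(assigned_events = ev),
                                  class = "csc_atom"), rec)
  s0 <- 20 * 200 + 1L
  single <- rec$data[, (s0 + round(pk_off * 200) - 100):(s0 + round(pk_off * 200) + 100)]
  expect_equal(ca$avg, single, tolerance = 1e-12)
  expect_equal(ca$peak_latency, 101)
  expect_false(ca$flagged)
  expect_lt(ca$slope_latency, ca$peak_latency)
})

test_that("slope latency lands on the 50% point of a triangular GFP ramp", {
  # single channel: GFP equals |x|; ramp 0 -> 1 over 20 samples
  g <- c(seq(0, 1, length.out = 21), rev(seq(0, 0.95, length.out = 20)))
  expect_equal(megspike:::slope_latency(g, which.max(g)), 11)
  expect_equal(g[11], 0.5)
})

test_that("planted cluster averages peak within 15 ms of the waveform peak", {
  st <- small_stage1()
  tr <- st$sim$truth$atoms[[1]]
  ev <- event_table(tr$event_times, 200, stage = "visual", sensor_type = "grad")
  ca <- average_cluster(structure(list(assigned_events = ev),
                                  class = "csc_atom"), st$rec)
  expect_lte(abs(ca$peak_latency - 101) / 200, 0.015)
})

test_that("activation maps binarize scale-invariantly at 50% of maximum", {
  coords <- matrix(rnorm(60), 20, 3)
  act <- c(10, 6, 5, 4.999, runif(16, 0, 4))
  m <- cortical_map(act, coords, "activation")
  b1 <- binarize_map(m, 0.5)
  expect_equal(b1$values[1:4], c(1, 1, 1, 0))
  for (c_ in c(0.01, 3, 1e4)) {
    b2 <- binarize_map(cortical_map(act * c_, coords, "activation"), 0.5)
    expect_identical(b2$values, b1$values)
  }
  expect_error(binarize_map(cortical_map(numeric(20), coords, "activation")),
               "all-zero")
})

test_that("atom map voting uses a strict majority and 10 mm smoothing", {
  fwd <- small_fwd()
  coords <- fwd$vertex_coords
  mk <- function(idx) {
    v <- numeric(nrow(coords)); v[idx] <- 1
    cortical_map(v, coords, "binary")
  }
  # three identical maps -> smoothed original
  m <- mk(c(5, 9))
  comb <- combine_atom_maps(list(m, m, m), smooth_mm = 10)
  expect_true(all(comb$values[c(5, 9)] == 1))
  expect_identical(comb$values,
                   megspike:::smooth_binary_map(m, 10)$values)
  # voting is permutation-invariant
  m2 <- mk(c(5, 17))
  maps <- list(m, m2, mk(5))
  expect_identical(combine_atom_maps(maps, 10)$values,
                   combine_atom_maps(rev(maps), 10)$values)
  # two disjoint maps: no strict majority anywhere -> empty map
  expect_warning(comb2 <- combine_atom_maps(list(mk(1), mk(12)), 10),
                 "empty")
  expect_equal(sum(comb2$values), 0)
  # three maps sharing one vertex -> that vertex plus its 10 mm ball
  maps3 <- list(mk(c(5, 1)), mk(c(5, 12)), mk(c(5, 30)))
  comb3 <- combine_atom_maps(maps3, 10)
  d <- sqrt(rowSums(sweep(coords, 2, coords[5, ])^2))
  expect_identical(which(comb3$values == 1), which(d <= 10))
})

test_that("visual spike maps follow the at-least-half rule and need 2+ events", {
  fwd <- small_fwd()
  sim <- simulate_recording(fwd, 1, 8, 180, snr = 6, seed = 17)
  rec <- bandpass(sim$recording, 2, 90)
  tr <- sim$truth$atoms[[1]]
  ev <- event_table(tr$event_times, 200, stage = "visual", sensor_type = "grad")
  nd <- pmax(apply(rec$data, 1, var), 1e-12)
  inv <- make_inverse(fwd, nd)
  vm <- visual_spike_map(ev, rec, inv)
  expect_identical(vm$kind, "binary")
  expect_lte(min_dist_to_map(vm, fwd$vertex_coords, tr$true_vertex), 10)
  expect_error(visual_spike_map(ev[1, ], rec, inv), "at least 2")
})

test_that("the predicted irritative zone covers the planted source end to end", {
  ee <- end_to_end_iz()
  expect_gte(length(ee$maps), 2)
  expect_gt(sum(ee$iz$values), 0)
  expect_lte(ee$min_dist, 10)
})
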