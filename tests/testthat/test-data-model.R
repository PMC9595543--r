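test_that("band-pass preserves in-band sinusoids and rejects out-of-band ones", {
  sf <- 200
  t <- seq(0, 20, by = 1 / sf)[-1]
  rec50 <- sensor_recording(rbind(sin(2 * pi * 50 * t)), sf)
  rec01 <- sensor_recording(rbind(sin(2 * pi * 1 * t)), sf)
  out50 <- bandpass(rec50, 20, 90)
  out01 <- bandpass(rec01, 20, 90)
  # compare RMS over the central region (away from filter edge transients)
  core <- seq(2 * sf, length(t) - 2 * sf)
  gain50 <- sqrt(mean(out50$data[1, core]^2)) / sqrt(mean(rec50$data[1, core]^2))
  gain01 <- sqrt(mean(out01$data[1, core]^2)) / sqrt(mean(rec01$data[1, core]^2))
  expect_gt(gain50, 0.95)
  expect_lt(gain50, 1.05)
  expect_lt(gain01, 0.10)
})

test_that("band-pass of all-zero input is all-zero and shape-preserving", {
  rec <- sensor_recording(matrix(0, 3, 1000), 200)
  out <- bandpass(rec, 20, 90)
  expect_identical(dim(out$data), dim(rec$data))
  expect_true(all(out$data == 0))
  expect_error(bandpass(rec, 50, 150), "Nyquist|band edges")
})

test_that("resampling preserves duration and waveform, and refuses upsampling", {
  sf <- 1000
  t <- seq(0, 60 - 1 / sf, by = 1 / sf)
  rec <- sensor_recording(rbind(sin(2 * pi * 5 * t)), sf)
  out <- resample_recording(rec, 200)
  expect_equal(out$sfreq, 200)
  expect_equal(ncol(out$data), 12000)
  # compare against the analytic 5 Hz sinusoid on the new grid
  t2 <- seq(0, by = 1 / 200, length.out = ncol(out$data))
  core <- seq(200, ncol(out$data) - 200)
  expect_gt(cor(out$data[1, core], sin(2 * pi * 5 * t2[core])), 0.999)
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(out, 500), "upsampling")
})

test_that("sensor-type split is a partition of the MEG channels", {
  dat <- matrix(rnorm(306 * 100), 306, 100)
  types <- rep(c("grad", "grad", "mag"), 102)
  rec <- sensor_recording(dat, 200, sprintf("MEG%04d", 1:306), types)
  g <- pick_sensors(rec, "grad")
  m <- pick_sensors(rec, "mag")
  expect_equal(nrow(g$data), 204)
  expect_equal(nrow(m$data), 102)
  expect_length(intersect(g$channel_names, m$channel_names), 0)
  expect_setequal(c(g$channel_names, m$channel_names), rec$channel_names)
  expect_true(all(g$sensor_type == "grad"))
})

test_that("recording round-trips through the matrix + manifest format", {
  dir <- withr::local_tempdir()
  dat <- matrix(rnorm(306 * 50), 306, 50)
  types <- rep(c("grad", "grad", "mag"), 102)
  rec <- sensor_recording(dat, 200, sprintf("MEG%04d", 1:306), types,
                          bads = "MEG0001")
  write_recording(rec, file.path(dir, "rec"))
  back <- load_recording(file.path(dir, "rec"))
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_identical(back$channel_names, rec$channel_names)
  grad <- load_recording(file.path(dir, "rec"), sensor_type_filter = "grad")
  expect_equal(nrow(grad$data), 203)   # one grad channel is marked bad
  mag <- load_recording(file.path(dir, "rec"), sensor_type_filter = "mag")
  expect_equal(nrow(mag$data), 102)
  expect_error(load_recording(file.path(dir, "nope")), "unknown format")
})

test_that("10-channel matrix recording loads unchanged without a filter", {
  dir <- withr::local_tempdir()
  rec <- sensor_recording(matrix(rnorm(10 * 40), 10, 40), 200)
  write_recording(rec, file.path(dir, "small"))
  back <- load_recording(file.path(dir, "small"))
  expect_equal(nrow(back$data), 10)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
})

test_that("event tables and cortical maps round-trip losslessly", {
  dir <- withr::local_tempdir()
  ev <- event_table(c(1.25, 3.5, 7.005), 200, stage = "stage1",
                    gof = c(0.9, 0.7, NA), sensor_type = "grad")
  f <- file.path(dir, "ev.tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$sample, ev$sample)
  expect_equal(back$gof, ev$gof)
  expect_equal(attr(back, "sfreq"), 200)
  # sample index consistency invariant
  expect_identical(back$sample, as.integer(round(back$time_s * 200)))

  coords <- matrix(rnorm(30), 10, 3)
  cm <- cortical_map(runif(10), coords, "activation")
  g <- file.path(dir, "map.json")
  write_cortical_map(cm, g)
  back2 <- read_cortical_map(g)
  expect_equal(back2$values, cm$values)
  expect_equal(back2$vertex_coords, cm$vertex_coords)
  expect_identical(back2$kind, "activation")
})

test_that("cortical map kind constraints are enforced", {
  coords <- matrix(rnorm(15), 5, 3)
  expect_error(cortical_map(c(0, 1, 2, 0, 1), coords, "binary"), "0/1")
  expect_error(cortical_map(c(-1, 0, 1, 0, 0), coords, "activation"),
               "non-negative")
})

test_that("pipeline config holds the published defaults and survives YAML", {
  cfg <- pipeline_config()
  expect_equal(cfg$n_ica, 20)
  expect_equal(cfg$n_ica_ranked, 10)
  expect_equal(cfg$kurtosis_range, c(1, 10))
  expect_equal(cfg$gof_threshold_mag, 0.80)
  expect_equal(cfg$gof_threshold_grad, 0.60)
  expect_equal(cfg$gof_override, 0.95)
  expect_equal(cfg$peak_band, c(20, 90))
  expect_equal(cfg$min_peaks, 300)
  expect_equal(cfg$music_window, c(-0.020, 0.030))
  expect_equal(cfg$refractory, 0.5)
  expect_equal(cfg$csc_band, c(2, 90))
  expect_equal(cfg$n_atoms_per_run, 3)
  expect_equal(cfg$atom_len, 0.5)
  expect_equal(cfg$lambda_reg, 0.1)
  expect_equal(cfg$epoch_len, 1.0)
  expect_equal(cfg$mad_start, 7)
  expect_equal(cfg$mad_floor, 1.5)
  expect_equal(cfg$min_events, 15)
  expect_equal(cfg$events_cap, 20)
  expect_equal(cfg$n_runs, 4)
  expect_equal(cfg$binarize_frac, 0.5)
  expect_equal(cfg$smooth_mm, 10)
  expect_equal(cfg$resection_margin_mm, 3)
  expect_error(pipeline_config(nonsense = 1), "unknown config field")

  dir <- withr::local_tempdir()
  f <- file.path(dir, "cfg.yaml")
  write_config(pipeline_config(min_peaks = 123), f)
  back <- read_config(f)
  expect_equal(back$min_peaks, 123)
  expect_equal(unclass(back)[names(back) != "min_peaks"],
               unclass(cfg)[names(cfg) != "min_peaks"])
})
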