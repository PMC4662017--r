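test_that("ROI bias statistics are exact on constructed maps", {
  ph <- make_phantom("grid", cardiac_tissues(), n = 30)
  rois <- phantom_rois(ph, half_width = 2)
  ref <- stats::setNames(ph$regions$t1_ms, ph$regions$name)
  # map identical to the reference
  t1 <- ph$t1_ms; t1[ph$region_labels == 0] <- NA
  pm <- parameter_map(t1_ms = t1, mask = ph$region_labels > 0)
  ev <- evaluate_bias(pm, ref, rois)
  expect_equal(ev$stats$bias, rep(0, 6))
  expect_equal(unname(ev$summary), c(0, 0))
  # constant +10 offset
  pm10 <- parameter_map(t1_ms = t1 + 10, mask = ph$region_labels > 0)
  ev10 <- evaluate_bias(pm10, ref, rois)
  expect_equal(ev10$stats$bias, rep(10, 6))
  expect_equal(unname(ev10$summary), c(10, 0))
  # empty ROI is named in the error
  rois$blood[] <- FALSE
  expect_error(evaluate_bias(pm, ref, rois), "blood")
})

test_that("modified Bland-Altman summaries are exact arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$limits, c(0, 0))
  bac <- bland_altman(c(4, 5, 6) + 2.5, c(4, 5, 6))
  expect_equal(bac$mean_diff, 2.5)
  expect_equal(bac$limits, c(2.5, 2.5))
  bapm <- bland_altman(c(11, 9), c(10, 10))
  expect_equal(bapm$mean_diff, 0)
  expect_equal(bapm$sd_diff, sqrt(2))
  expect_error(bland_altman(1, 1), "2 pairs")
  f <- tempfile(fileext = ".png")
  bland_altman(c(1, 2, 3), c(1.1, 1.9, 3.2), plot_file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
})

test_that("series round-trip through NIfTI plus sidecar", {
  tl <- toy_timeline()
  s <- simulate_entry(1048, 50, tl, slice_positions_default())
  img <- array(rep(s, each = 4), dim = c(2, 2, length(s)))
  ser <- molli_series(img, tl$effective_tis_ms, scheme = "5(3p)3",
                      rr_intervals_ms = rep(1000, 11), noise_sigma = 0,
                      seed = 1, config_digest = config_digest(phantom_params()))
  f <- file.path(tempdir(), "series.nii.gz")
  write_series(ser, f)
  back <- read_series(f)
  expect_equal(back$images, img, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$tis_ms, ser$tis_ms, tolerance = 1e-9)
  expect_equal(back$scheme, "5(3p)3")
  # missing sidecar
  f2 <- file.path(tempdir(), "orphan.nii.gz")
  RNifti::writeNifti(img, f2)
  expect_error(read_series(f2), "sidecar")
  # TI count mismatch
  bad <- ser; bad$tis_ms <- bad$tis_ms[-1]
  expect_error(molli_series(img, bad$tis_ms), "equal")
  jsonlite::write_json(list(tis_ms = 1:3), sub("nii.gz", "json", f2, fixed = TRUE),
                       auto_unbox = TRUE)
  expect_error(read_series(f2), "does not match image count")
})

test_that("configuration files round-trip in YAML and JSON", {
  p <- phantom_params()
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_config(p, f, scheme = "5(0p)3", rr_intervals_ms = rep(1000, 8))
    cfg <- read_config(f)
    expect_equal(cfg$params$tr_ms, p$tr_ms)
    expect_equal(cfg$params$initial_tis_ms, p$initial_tis_ms)
    expect_equal(cfg$scheme, "5(0p)3")
    expect_equal(cfg$timing$rr_intervals_ms, rep(1000, 8))
    expect_identical(config_digest(cfg$params), config_digest(p))
  }
})

test_that("the shipped protocol configuration reproduces the phantom setup", {
  f <- system.file("extdata", "phantom_protocol.yaml", package = "squaremr")
  expect_true(nzchar(f))
  cfg <- read_config(f)
  expect_equal(cfg$params$tr_ms, 2.54)
  expect_equal(cfg$params$te_ms, 1.27)
  expect_equal(cfg$params$flip_deg, 35)
  expect_equal(cfg$params$n_phase_encodes, 65)
  expect_equal(cfg$params$initial_tis_ms, c(114, 350))
  expect_equal(cfg$scheme, "5(3p)3")
})

test_that("run logs carry the digest needed to trace an output", {
  f <- tempfile(fileext = ".jsonl")
  d <- config_digest(phantom_params())
  log_run(f, "fit-squaremr", digest = d, seed = 7, n_pixels = 12)
  rec <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rec$action, "fit-squaremr")
  expect_equal(rec$digest, d)
  expect_equal(rec$seed, 7)
})

test_that("parameter maps are written as NIfTI volumes with provenance", {
  pm <- parameter_map(t1_ms = matrix(c(NA, 1000, 1200, NA), 2, 2),
                      mask = matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2),
                      provenance = list(method = "test"))
  d <- file.path(tempdir(), "maps")
  write_maps(pm, d)
  expect_true(file.exists(file.path(d, "t1.nii.gz")))
  expect_true(file.exists(file.path(d, "provenance.json")))
  back <- as.array(RNifti::readNifti(file.path(d, "t1.nii.gz")))
  expect_equal(back[2, 1], 1000, tolerance = 1e-6)
})
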