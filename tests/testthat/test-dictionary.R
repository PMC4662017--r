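test_that("grid enumeration respects the T2 <= T1 exclusion", {
  g <- enumerate_grid(grid_spec(200, 201, 1, 199, 201, 1))
  expect_equal(nrow(g), 5L)   # (200: 199,200), (201: 199,200,201)
  expect_true(all(g$t2_ms <= g$t1_ms))
  # sorted by (T1, T2)
  expect_false(is.unsorted(g$t1_ms))
  expect_false(is.unsorted(g$t2_ms[g$t1_ms == 201]))
})

test_that("physiological-range grid counts match a brute-force double loop", {
  g <- enumerate_grid(grid_spec(200, 1900, 1, 20, 400, 1))
  brute <- 0L
  for (t1 in 200:1900) brute <- brute + sum(20:400 <= t1)
  expect_identical(nrow(g), brute)
  expect_identical(brute, 627981L)
})

test_that("rectangular grids have closed-form counts", {
  set.seed(31)
  for (r in 1:10) {
    st1 <- sample(1:20, 1); st2 <- sample(1:20, 1)
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    sp <- grid_spec(500, 500 + st1 * (n1 - 1), st1,
                    20, 20 + st2 * (n2 - 1), st2, exclude_t2_gt_t1 = FALSE)
    expect_equal(nrow(enumerate_grid(sp)), n1 * n2)
  }
})

test_that("slice spin positions are symmetric and uniformly spaced", {
  expect_equal(slice_spin_positions(3, 6, 1), c(-3e-3, 0, 3e-3))
  p <- slice_spin_positions(21, 6, 2)
  expect_length(p, 21)
  expect_equal(range(p), c(-6e-3, 6e-3))
  expect_equal(unique(round(diff(p), 12)), 0.6e-3)
  expect_true(0 %in% p)
  expect_error(slice_spin_positions(20, 6, 2), "odd")
})

test_that("dictionary entries are deterministic and positive", {
  tl <- toy_timeline()
  pos <- slice_positions_default()
  a <- simulate_entry(1048, 50, tl, pos)
  b <- simulate_entry(1048, 50, tl, pos)
  expect_identical(a, b)
  expect_true(all(a > 0))
  expect_true(all(a <= length(pos)))
})

test_that("without relaxation the samples carry no inversion-time contrast", {
  # evolution between pulses is the identity, so stretching every TI (RR
  # 1000 -> 1600 ms) must leave all samples unchanged
  isos <- lapply(slice_positions_default(), function(z)
    isochromat(1048, 50, z_m = z))
  a <- ensemble_signal(isos, build_timeline(phantom_params(), "5(3p)3",
                                            fixed_rr(11, 1000)), relax = FALSE)
  b <- ensemble_signal(isos, build_timeline(phantom_params(), "5(3p)3",
                                            fixed_rr(11, 1600)), relax = FALSE)
  expect_equal(Mod(a), Mod(b), tolerance = 1e-9)
  expect_gt(max(Mod(a)), 0)
})

test_that("the signed first-group recovery is monotone from the first image", {
  # complex signal; consecutive shots carry opposite bSSFP phase parity
  # (odd pulse count per shot), corrected before reading the recovery
  tl <- toy_timeline()
  pos <- slice_positions_default()
  sig <- ensemble_signal(lapply(pos, function(z) isochromat(1048, 50, z_m = z)), tl)
  p <- acquisition_params()
  pulses_per_shot <- p$ramp_pulses + p$n_phase_encodes
  parity <- (-1)^((seq_along(sig) - 1) * pulses_per_shot)
  ref <- Arg(sig[5])   # last image of group 1: fully recovered, positive pole
  signed <- Re(sig * exp(-1i * ref)) * parity / parity[5]
  g1 <- signed[1:5]
  expect_true(all(diff(g1) > 0))
  expect_equal(which.min(g1), 1L)
})

test_that("dictionaries are sorted, reproducible and composable", {
  d <- toy_dict()
  expect_equal(length(d$t1_ms), 6L)
  expect_false(is.unsorted(d$t1_ms))
  # entry equals a standalone simulation
  tl <- toy_timeline()
  k <- which(d$t1_ms == 1000 & d$t2_ms == 40)
  expect_equal(d$signals[k, ],
               simulate_entry(1000, 40, tl, slice_positions_default()),
               tolerance = 1e-12)
  # worker count does not change the result
  spec <- grid_spec(800, 1200, 200, 40, 80, 40)
  d2 <- build_dictionary(spec, phantom_params(), "5(3p)3", fixed_rr(11),
                         n_workers = 2L)
  expect_equal(d2$signals, d$signals, tolerance = 1e-15)
  expect_identical(d2$t1_ms, d$t1_ms)
})

test_that("adjacent entries vary continuously and are distinct", {
  d <- coarse_dict()
  norm_rows <- d$signals / sqrt(rowSums(d$signals^2))
  sel <- which(d$t2_ms == 60)
  sel <- sel[order(d$t1_ms[sel])]
  dif <- sqrt(rowSums((norm_rows[sel[-1], ] - norm_rows[sel[-length(sel)], ])^2))
  expect_lt(max(dif), 0.2)   # one 20 ms step moves the normalized signal a little
  expect_gt(min(dif), 0)     # but never zero: distinct (T1,T2) -> distinct signals
  # no duplicate vectors on a subsample
  sub <- d$signals[seq(1, nrow(d$signals), by = 37), ]
  expect_equal(nrow(unique(round(sub, 12))), nrow(sub))
})

test_that("the slice-profile ensemble is self-converged at high spin counts", {
  tl <- build_timeline(phantom_params(dt_us = 10, initial_tis_ms = 114), "3",
                       fixed_rr(3))
  a <- simulate_entry(1048, 50, tl, slice_spin_positions(101, 6, 2)) / 101
  b <- simulate_entry(1048, 50, tl, slice_spin_positions(201, 6, 2)) / 201
  expect_lt(max(abs(a - b)) / max(b), 0.01)
})

test_that("dictionary persistence round-trips and verifies its digest", {
  d <- toy_dict()
  f <- tempfile(fileext = ".rds")
  save_dictionary(d, f)
  d2 <- load_dictionary(f, params = phantom_params())
  expect_equal(d2$signals, d$signals)
  expect_identical(d2$meta$config_digest, d$meta$config_digest)
  # a different session configuration is refused, naming both digests
  other <- phantom_params(tr_ms = 3, te_ms = 1.5)
  expect_error(load_dictionary(f, params = other), "digest mismatch")
  expect_error(load_dictionary(f, params = other, force = FALSE), d$meta$config_digest)
  expect_s3_class(load_dictionary(f, params = other, force = TRUE),
                  "signal_dictionary")
  # truncated file
  raw <- readBin(f, "raw", file.info(f)$size)
  f2 <- tempfile(fileext = ".rds")
  writeBin(raw[1:200], f2)
  expect_error(load_dictionary(f2), "corrupt")
})
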