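test_that("free relaxation matches the closed-form solutions", {
  cases <- list(c(t1 = 1000, t2 = 100, t_ms = 1000),
                c(t1 = 300, t2 = 40, t_ms = 120),
                c(t1 = 1570, t2 = 196, t_ms = 2500))
  for (cs in cases) {
    iso <- isochromat(cs["t1"], cs["t2"])
    # start from an inverted, partially transverse state
    m0 <- c(0.6, 0, -0.8)
    # many small steps
    n <- 200
    ev <- timeline_events(rep(cs["t_ms"] * 1e-3 / n, n))
    m <- m0
    for (i in seq_len(n)) m <- bloch_step(m, iso, ev[i, , drop = FALSE])
    mxy <- sqrt(sum(m[1:2]^2))
    expect_equal(mxy, 0.6 * exp(-cs["t_ms"] / cs["t2"]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(m[3], 1 + (-0.8 - 1) * exp(-cs["t_ms"] / cs["t1"]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    # a single long event is exact for field-free evolution
    m1 <- bloch_step(m0, iso, timeline_events(cs["t_ms"] * 1e-3))
    expect_equal(m1, m, tolerance = 1e-9)
  }
})

test_that("inversion recovery reaches the closed-form value after one T1", {
  iso <- isochromat(1000, 100)
  # 10000 steps of 0.1 ms from mz = -1 (relaxation is exact per event)
  m <- c(0, 0, -1)
  m <- bloch_step(m, iso, timeline_events(1.0))
  expect_equal(m[3], 1 - 2 * exp(-1), tolerance = 1e-9)
})

test_that("a 90 degree hard pulse tips equilibrium into the transverse plane", {
  iso <- isochromat(1e12, 1e12)
  m <- bloch_step(c(0, 0, 1), iso, hard_pulse_event(90))
  expect_lt(abs(m[3]), 1e-6)
  expect_equal(sqrt(sum(m[1:2]^2)), 1, tolerance = 1e-9)
})

test_that("stepwise propagation agrees with the matrix-exponential oracle", {
  skip_if_not_installed("pracma")
  set.seed(20)
  maxerr <- 0
  for (r in 1:100) {
    z <- runif(1, -3e-3, 3e-3); off <- runif(1, -200, 200)
    iso <- isochromat(300, 40, z_m = z, off_hz = off)
    m <- mo <- c(0, 0, 1)
    for (s in 1:20) {
      ev <- timeline_events(1e-6, rf_uT = runif(1, 0, 20),
                            phase_rad = runif(1, 0, 2 * pi),
                            grad_mTm = runif(1, -30, 30))
      m <- bloch_step(m, iso, ev)
      mo <- expm_oracle_step(mo, 0.3, 0.04, ev[1, ], z_m = z, off_hz = off)
      maxerr <- max(maxerr, max(abs(m - mo)))
    }
  }
  expect_lt(maxerr, 1e-6)
})

test_that("rotation-only propagation preserves the magnetization norm", {
  set.seed(4)
  iso <- isochromat(1000, 80)
  m <- c(0, 0, 1)
  for (s in 1:50) {
    ev <- timeline_events(1e-5, rf_uT = runif(1, 0, 30),
                          phase_rad = runif(1, 0, 2 * pi),
                          grad_mTm = runif(1, -40, 40))
    m2 <- bloch_step(m, iso, ev, relax = FALSE)
    expect_lt(abs(sqrt(sum(m2^2)) - sqrt(sum(m^2))), 1e-9)
    m <- m2
  }
})

test_that("crushers zero the transverse components and are idempotent", {
  iso <- isochromat(1e12, 1e12)
  ev <- timeline_events(1e-5, crusher = TRUE)
  m0 <- c(0.5, -0.4, 0.3)
  m1 <- bloch_step(m0, iso, ev)
  expect_identical(m1[1:2], c(0, 0))
  expect_equal(m1[3], 0.3)
  expect_equal(bloch_step(m1, iso, ev), m1, tolerance = 1e-12)
  # crusher events refuse RF
  expect_error(timeline_events(1e-5, rf_uT = 1, crusher = TRUE), "zero RF")
})

test_that("simulate_isochromat samples the transverse state at ADC markers", {
  iso <- isochromat(1e12, 1e12)
  tl <- rbind(hard_pulse_event(90), timeline_events(1e-6, adc = 1L))
  s <- simulate_isochromat(iso, tl)
  expect_equal(Mod(s), 1, tolerance = 1e-9)
  # free T2 decay after excitation (pulse duration counts toward the decay)
  iso2 <- isochromat(1e12, 100)
  tl2 <- rbind(hard_pulse_event(90), timeline_events(100e-3 - 1e-6, adc = 1L))
  expect_equal(Mod(simulate_isochromat(iso2, tl2)), exp(-1), tolerance = 1e-4)
  # no ADC markers -> empty result, not an error
  expect_length(simulate_isochromat(iso, hard_pulse_event(90)), 0)
})

test_that("numerical failure reports the offending step index", {
  iso <- isochromat(1000, 80)
  tl <- rbind(timeline_events(1e-5), timeline_events(1e-5, rf_uT = NaN),
              timeline_events(1e-5))
  expect_error(simulate_isochromat(iso, tl), "step 2")
})

test_that("ensemble signal is linear in the isochromats", {
  tl <- rbind(hard_pulse_event(35), timeline_events(5e-3, adc = 1L),
              timeline_events(20e-3), hard_pulse_event(35, phase_rad = pi),
              timeline_events(5e-3, adc = 2L))
  one <- isochromat(500, 60, z_m = 1e-3)
  other <- isochromat(900, 45, z_m = -2e-3)
  s1 <- ensemble_signal(list(one), tl)
  expect_identical(s1, simulate_isochromat(one, tl))
  expect_equal(ensemble_signal(list(one, one), tl), 2 * s1, tolerance = 1e-12)
  sAB <- ensemble_signal(list(one, other), tl)
  expect_equal(sAB, s1 + simulate_isochromat(other, tl), tolerance = 1e-12)
  expect_error(ensemble_signal(list(), tl), "empty ensemble")
})

test_that("invalid relaxation parameters are rejected", {
  expect_error(isochromat(-5, 50), "t1_ms")
  expect_error(isochromat(500, 0), "t2_ms")
  expect_error(timeline_events(0), "positive")
})

test_that("refining the simulation step leaves MOLLI samples unchanged", {
  # discretization convergence at the 10 us / 5 us resolutions
  pos <- slice_positions_default()
  t5 <- fixed_rr(8)
  a <- simulate_entry(1048, 50, build_timeline(phantom_params(dt_us = 10), "5(0p)3", t5), pos)
  b <- simulate_entry(1048, 50, build_timeline(phantom_params(dt_us = 5), "5(0p)3", t5), pos)
  expect_lt(max(abs(a - b)) / max(abs(b)), 0.005)
})
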