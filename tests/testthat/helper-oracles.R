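# Independent oracles and shared fixtures for the test suite.

# Exact per-step Bloch solution: exponentiate the 4x4 affine generator
# (rotation + relaxation + recovery toward equilibrium, simultaneously).
# Units: t1_s/t2_s in seconds; ev_row is one row of an event matrix.
expm_oracle_step <- function(m, t1_s, t2_s, ev_row, z_m = 0, off_hz = 0, eq = 1) {
  gam <- 2 * pi * gyromagnetic_ratio_hz_per_t()
  wx <- gam * ev_row[2] * 1e-6 * cos(ev_row[3])
  wy <- gam * ev_row[2] * 1e-6 * sin(ev_row[3])
  wz <- gam * ev_row[4] * 1e-3 * z_m + 2 * pi * off_hz
  G <- rbind(c(-1 / t2_s,  wz,  -wy, 0),
             c(-wz,  -1 / t2_s,  wx, 0),
             c( wy,  -wx, -1 / t1_s, eq / t1_s),
             c(0, 0, 0, 0))
  (pracma::expm(G * ev_row[1]) %*% c(m, 1))[1:3]
}

# Small-tip-angle oracle: the transverse slice profile of a weak RF pulse is
# the Fourier transform of its B1 envelope evaluated at gamma_bar * G * z.
sinc_fourier_profile <- function(sinc, z_m) {
  rf <- sinc$rf_events
  dt <- rf[1, 1]
  tt <- (seq_len(nrow(rf)) - 0.5) * dt
  fz <- gyromagnetic_ratio_hz_per_t() * sinc$grad_mTm * 1e-3 * z_m
  vapply(fz, function(f) Mod(sum(rf[, 2] * exp(2i * pi * f * tt)) * dt), numeric(1))
}

# Closed-form on-resonance bSSFP steady-state magnitude sampled at TE.
bssfp_steady_state <- function(t1_s, t2_s, tr_s, te_s, alpha_rad) {
  E1 <- exp(-tr_s / t1_s); E2 <- exp(-tr_s / t2_s)
  sin(alpha_rad) * (1 - E1) / (1 - (E1 - E2) * cos(alpha_rad) - E1 * E2) *
    exp(-te_s / t2_s)
}

# Hard pulse: single short event whose B1 area gives the requested flip.
hard_pulse_event <- function(flip_deg, phase_rad = 0, dur_s = 1e-6) {
  gam <- 2 * pi * gyromagnetic_ratio_hz_per_t()
  timeline_events(dur_s, rf_uT = flip_deg * pi / 180 / (gam * dur_s) * 1e6,
                  phase_rad = phase_rad)
}

# Desk-scale study conditions: the phantom protocol with the simulation step
# relaxed to 50 us.
phantom_params <- function(dt_us = 50, ...) acquisition_params(dt_us = dt_us, ...)

fixed_rr <- function(n_beats, rr_ms = 1000) cardiac_timing(rep(rr_ms, n_beats))

slice_positions_default <- function(n = 21) slice_spin_positions(n, 6, 2)

# Shared lazily built fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Tiny dictionary for matcher unit tests: 3 x 2 grid on the 5(3p)3 timeline.
toy_dict <- function() fixture("toy_dict", function() {
  build_dictionary(grid_spec(800, 1200, 200, 40, 80, 40),
                   phantom_params(), "5(3p)3", fixed_rr(11))
})

toy_timeline <- function() fixture("toy_timeline", function() {
  build_timeline(phantom_params(), "5(3p)3", fixed_rr(11))
})

# Coarse 20 ms / 20 ms dictionary over the physiological range (the
# parameter-recovery harness).
coarse_dict <- function() fixture("coarse_dict", function() {
  build_dictionary(grid_spec(200, 1900, 20, 20, 400, 20),
                   phantom_params(), "5(3p)3", fixed_rr(11))
})
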