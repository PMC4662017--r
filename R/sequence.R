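# MOLLI sequence expansion: acquisition parameters, scheme grammar, cardiac
# timing, and the fully expanded event timeline with per-image effective TIs.

#' MOLLI acquisition parameters
#'
#' Defaults reproduce the phantom protocol used throughout: bSSFP readout
#' with TR 2.54 ms / TE 1.27 ms, 35 degree flip, 10-pulse linear ramp-up,
#' 65 acquired phase-encode lines with a linear trajectory (k-space center
#' on line 33), 490 us sinc excitation over a 6 mm slice, 4.74 ms adiabatic
#' sech inversion, initial TIs 114 and 350 ms, and a 10 us simulation step.
#'
#' @param tr_ms,te_ms repetition and echo time, ms (TE is expected to be
#'   close to TR/2 for a balanced readout; a warning is issued otherwise).
#' @param flip_deg readout flip angle alpha, degrees.
#' @param ramp_pulses number of linear ramp-up startup pulses.
#' @param n_phase_encodes acquired k-space lines per single-shot readout.
#' @param center_line_index 1-based line at k-space center
#'   (default \code{ceiling(n_phase_encodes / 2)}).
#' @param slice_thickness_mm slice thickness, mm.
#' @param ir_pulse list describing the inversion pulse (shape "sech",
#'   \code{duration_ms}, \code{mu}, \code{beta_per_s}, \code{b1max_uT}).
#' @param excitation_pulse list describing the excitation (shape "sinc",
#'   \code{duration_us}, \code{lobes}, \code{apodization}).
#' @param dt_us simulation temporal step, microseconds.
#' @param initial_tis_ms initial TI per modified-Look-Locker experiment, ms.
#' @param n_slice_spins odd number of isochromats across the slice.
#' @param slice_fov_factor spin placement extent relative to slice thickness.
#' @return object of class \code{acq_params}.
#' @export
acquisition_params <- function(tr_ms = 2.54, te_ms = 1.27, flip_deg = 35,
                               ramp_pulses = 10, n_phase_encodes = 65,
                               center_line_index = NULL,
                               slice_thickness_mm = 6,
                               ir_pulse = list(shape = "sech", duration_ms = 4.74,
                                               mu = 5, beta_per_s = NULL,
                                               b1max_uT = NULL),
                               excitation_pulse = list(shape = "sinc",
                                                       duration_us = 490,
                                                       lobes = 3,
                                                       apodization = "hann"),
                               dt_us = 10, initial_tis_ms = c(114, 350),
                               n_slice_spins = 21, slice_fov_factor = 2) {
  if (is.null(center_line_index)) center_line_index <- ceiling(n_phase_encodes / 2)
  if (dt_us <= 0) stop("dt_us must be positive")
  if (ramp_pulses < 0) stop("ramp_pulses must be >= 0")
  if (center_line_index < 1 || center_line_index > n_phase_encodes)
    stop("center_line_index must lie in [1, n_phase_encodes]")
  if (abs(te_ms - tr_ms / 2) > 0.05 * tr_ms)
    warning("TE is not close to TR/2; the readout is not a centered bSSFP echo")
  structure(list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 ramp_pulses = ramp_pulses, n_phase_encodes = n_phase_encodes,
                 center_line_index = center_line_index,
                 slice_thickness_mm = slice_thickness_mm,
                 ir_pulse = ir_pulse, excitation_pulse = excitation_pulse,
                 dt_us = dt_us, initial_tis_ms = initial_tis_ms,
                 n_slice_spins = n_slice_spins,
                 slice_fov_factor = slice_fov_factor),
            class = "acq_params")
}

#' Parse a MOLLI scheme string
#'
#' Schemes are written n(pP)n(pP)...n, e.g. "5(3p)3": groups of single-shot
#' readouts on consecutive heartbeats with pause heartbeats between the
#' modified-Look-Locker experiments.
#'
#' @param text scheme string.
#' @return object of class \code{molli_scheme}: data frame with columns
#'   \code{n_readouts} and \code{pause_beats} (NA after the final group).
#' @export
parse_scheme <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub(" ", "", text)
  n_read <- integer(0); pauses <- integer(0)
  pos <- 1L; nc <- nchar(s)
  repeat {
    m <- regexpr("^[0-9]+", substring(s, pos))
    if (m == -1L) stop(sprintf("malformed scheme '%s': expected readout count at position %d", text, pos))
    len <- attr(m, "match.length")
    n <- as.integer(substring(s, pos, pos + len - 1L)); pos <- pos + len
    if (n < 1L) stop(sprintf("malformed scheme '%s': zero readouts at position %d", text, pos - len))
    n_read <- c(n_read, n)
    if (pos > nc) break
    pm <- regexpr("^\\(([0-9]+)p\\)", substring(s, pos))
    if (pm == -1L) stop(sprintf("malformed scheme '%s': expected '(<n>p)' at position %d", text, pos))
    plen <- attr(pm, "match.length")
    p <- as.integer(gsub("[^0-9]", "", substring(s, pos, pos + plen - 1L)))
    pauses <- c(pauses, p); pos <- pos + plen
    if (pos > nc) stop(sprintf("malformed scheme '%s': trailing pause at position %d", text, pos))
  }
  if (length(pauses) != length(n_read) - 1L)
    stop(sprintf("malformed scheme '%s'", text))
  structure(data.frame(n_readouts = n_read,
                       pause_beats = c(pauses, NA_integer_)),
            class = c("molli_scheme", "data.frame"), scheme_text = s)
}

#' Cardiac timing record
#'
#' @param rr_intervals_ms RR interval series, one per heartbeat, ms.
#' @param trigger_delay_ms delay from R-wave to single-shot start, ms.
#' @return object of class \code{cardiac_timing}.
#' @export
cardiac_timing <- function(rr_intervals_ms, trigger_delay_ms = 0) {
  if (any(rr_intervals_ms <= 0)) stop("all RR intervals must be positive")
  structure(list(rr_intervals_ms = as.numeric(rr_intervals_ms),
                 trigger_delay_ms = trigger_delay_ms),
            class = "cardiac_timing")
}

beats_required <- function(scheme) {
  sum(scheme$n_readouts) + sum(scheme$pause_beats, na.rm = TRUE)
}

#' Minimum feasible initial TI
#'
#' Time from the start of a single-shot block to the k-space-center echo:
#' ramp_pulses*TR + (center_line_index - 1)*TR + TE, plus any
#' inversion-to-trigger overhead the caller wants included (e.g. the offset
#' between block start and the excitation RF center).
#'
#' @param params an \code{\link{acquisition_params}} object.
#' @param overhead_ms extra overhead, ms.
#' @return minimum initial TI, ms.
#' @export
min_feasible_ti <- function(params, overhead_ms = 0) {
  params$ramp_pulses * params$tr_ms +
    (params$center_line_index - 1) * params$tr_ms + params$te_ms + overhead_ms
}

# One bSSFP TR block starting at relative time 0:
#   prewinder (-A/2) | sinc RF (+A, dur T_rf) | rephaser (-A/2) | idle | [ADC at
#   RF-center + TE] | idle to TR. Net slice-gradient area per TR is zero and
#   the spin phase of off-center spins refocuses at the echo.
make_tr_block <- function(sinc, tr_ms, te_ms, flip_scale, phase, adc = 0L) {
  tr_s <- tr_ms * 1e-3; te_s <- te_ms * 1e-3
  T_rf <- sinc$rf_dur_s
  pre <- timeline_events(duration_s = T_rf / 2, grad_mTm = -sinc$grad_mTm)
  rf <- sinc$rf_events
  rf[, "rf_uT"] <- rf[, "rf_uT"] * flip_scale
  rf[, "phase_rad"] <- phase
  reph <- timeline_events(duration_s = T_rf / 2, grad_mTm = -sinc$grad_mTm)
  t_echo <- T_rf + te_s                # from block start (RF center at T_rf)
  t_after_reph <- 2 * T_rf
  if (t_echo <= t_after_reph)
    stop("TE too short: echo falls inside the slice rephaser")
  idle1 <- timeline_events(duration_s = t_echo - t_after_reph, adc = adc)
  ev <- rbind(pre, rf, reph, idle1)
  if (tr_s > t_echo)
    ev <- rbind(ev, timeline_events(duration_s = tr_s - t_echo))
  attr(ev, "echo_offset_s") <- t_echo
  ev
}

#' Expand a MOLLI experiment into a concrete event timeline
#'
#' For each modified-Look-Locker experiment: crusher, sech inversion,
#' crusher, then a wait placing the k-space center of the first readout
#' exactly the initial TI after the end of the inversion pulse. Each
#' single-shot readout is a ramp-up of linearly increasing flip angles
#' (k*alpha/N, no ADC) followed by n_phase_encodes full-alpha bSSFP TRs with
#' one ADC marker at the echo of the center line. The bSSFP 0/pi phase
#' alternation runs continuously across ramp, acquisition, heartbeats and
#' groups. Pause beats contain free relaxation only.
#'
#' @param params an \code{\link{acquisition_params}} object.
#' @param scheme a \code{\link{parse_scheme}} result (or scheme string).
#' @param timing a \code{\link{cardiac_timing}} record.
#' @return object of class \code{molli_timeline}: list with the event matrix
#'   (\code{events}), \code{effective_tis_ms}, \code{image_group},
#'   \code{n_images} and \code{duration_s}.
#' @export
build_timeline <- function(params, scheme, timing) {
  stopifnot(inherits(params, "acq_params"))
  if (is.character(scheme)) scheme <- parse_scheme(scheme)
  stopifnot(inherits(scheme, "molli_scheme"), inherits(timing, "cardiac_timing"))
  nb <- beats_required(scheme)
  rr <- timing$rr_intervals_ms
  if (length(rr) < nb)
    stop(sprintf("cardiac timing supplies %d beats but the scheme needs %d",
                 length(rr), nb))
  if (length(params$initial_tis_ms) < nrow(scheme))
    stop("need one initial TI per modified-Look-Locker experiment")

  dt_s <- params$dt_us * 1e-6
  sinc <- make_sinc_pulse(duration_us = params$excitation_pulse$duration_us,
                          flip_deg = params$flip_deg,
                          lobes = params$excitation_pulse$lobes,
                          slice_thickness_mm = params$slice_thickness_mm,
                          dt_us = params$dt_us,
                          apodization = params$excitation_pulse$apodization)
  ir <- make_sech_pulse(duration_ms = params$ir_pulse$duration_ms,
                        mu = params$ir_pulse$mu,
                        beta_per_s = params$ir_pulse$beta_per_s,
                        b1max_uT = params$ir_pulse$b1max_uT,
                        dt_us = params$dt_us)
  ir_dur_s <- sum(ir[, "dur_s"])
  crush_s <- dt_s

  # absolute beat start times (s)
  beat_t <- (c(0, cumsum(rr))[seq_len(nb)] + timing$trigger_delay_ms) * 1e-3
  # offset from single-shot block start to the center-line echo
  shot_tr_n <- params$ramp_pulses + params$n_phase_encodes
  echo_off_s <- (params$ramp_pulses + params$center_line_index - 1) *
    params$tr_ms * 1e-3 + sinc$rf_dur_s + params$te_ms * 1e-3
  shot_dur_s <- shot_tr_n * params$tr_ms * 1e-3
  # shift the time origin so the first inversion (which precedes the first
  # triggered beat) starts at t >= 0
  lead_s <- (ir_dur_s + 2 * crush_s) -
    (beat_t[1] + echo_off_s - params$initial_tis_ms[1] * 1e-3)
  if (lead_s > 0) beat_t <- beat_t + lead_s

  pieces <- list(); np <- 0L
  add <- function(ev) { np <<- np + 1L; pieces[[np]] <<- ev }
  cursor <- 0      # absolute end time of the last emitted event
  idle_to <- function(t_abs) {
    if (t_abs > cursor + 1e-12) {
      add(timeline_events(duration_s = t_abs - cursor))
      cursor <<- t_abs
    } else if (t_abs < cursor - 1e-9) {
      stop("infeasible timing: overlapping sequence blocks")
    }
  }

  img <- 0L
  phase_idx <- 0L   # global bSSFP 0/pi alternation counter
  tis_ms <- numeric(0); img_group <- integer(0)
  adc_abs <- numeric(0)
  beat0 <- 1L
  for (g in seq_len(nrow(scheme))) {
    n_read <- scheme$n_readouts[g]
    ti0_ms <- params$initial_tis_ms[g]
    first_shot_t <- beat_t[beat0]
    inv_end_t <- first_shot_t + echo_off_s - ti0_ms * 1e-3
    inv_start_t <- inv_end_t - ir_dur_s - crush_s
    min_ti <- min_feasible_ti(params, overhead_ms = sinc$rf_dur_s * 1e3)
    if (inv_end_t > first_shot_t + 1e-12)
      stop(sprintf("infeasible timing: initial TI %.3f ms is shorter than the minimum feasible TI %.3f ms",
                   ti0_ms, min_ti))
    if (inv_start_t < cursor - 1e-9)
      stop(sprintf("infeasible timing: inversion of group %d would start before the preceding readout ends", g))
    idle_to(inv_start_t)
    add(timeline_events(duration_s = crush_s, crusher = TRUE)); cursor <- cursor + crush_s
    add(ir); cursor <- cursor + ir_dur_s
    add(timeline_events(duration_s = crush_s, crusher = TRUE)); cursor <- cursor + crush_s
    for (r in seq_len(n_read)) {
      shot_t <- beat_t[beat0 + r - 1L]
      idle_to(shot_t)
      for (k in seq_len(params$ramp_pulses)) {
        blk <- make_tr_block(sinc, params$tr_ms, params$te_ms,
                             flip_scale = k / params$ramp_pulses,
                             phase = (phase_idx %% 2) * pi)
        phase_idx <- phase_idx + 1L
        add(blk); cursor <- cursor + sum(blk[, "dur_s"])
      }
      for (l in seq_len(params$n_phase_encodes)) {
        is_center <- l == params$center_line_index
        if (is_center) {
          img <- img + 1L
          adc_id <- img
        } else adc_id <- 0L
        blk <- make_tr_block(sinc, params$tr_ms, params$te_ms, flip_scale = 1,
                             phase = (phase_idx %% 2) * pi, adc = adc_id)
        phase_idx <- phase_idx + 1L
        if (is_center) {
          adc_abs <- c(adc_abs, cursor + attr(blk, "echo_offset_s"))
          tis_ms <- c(tis_ms, (cursor + attr(blk, "echo_offset_s") - inv_end_t) * 1e3)
          img_group <- c(img_group, g)
        }
        add(blk); cursor <- cursor + sum(blk[, "dur_s"])
      }
    }
    beat0 <- beat0 + n_read + ifelse(is.na(scheme$pause_beats[g]), 0L, scheme$pause_beats[g])
  }
  events <- do.call(rbind, pieces)
  structure(list(events = events,
                 effective_tis_ms = tis_ms,
                 image_group = img_group,
                 n_images = img,
                 adc_times_s = adc_abs,
                 duration_s = cursor,
                 params = params,
                 scheme_text = attr(scheme, "scheme_text"),
                 rr_intervals_ms = rr[seq_len(nb)]),
            class = "molli_timeline")
}

#' @export
print.molli_timeline <- function(x, ...) {
  cat(sprintf("MOLLI timeline: scheme %s, %d images, %d events, %.2f s\n",
              x$scheme_text, x$n_images, nrow(x$events), x$duration_s))
  cat("effective TIs (ms):", paste(sprintf("%.1f", x$effective_tis_ms), collapse = ", "), "\n")
  invisible(x)
}
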