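#' @useDynLib squaremr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Gyromagnetic ratio of 1H
#'
#' @return gamma-bar in Hz per tesla (42.577478518 MHz/T).
#' @export
gyromagnetic_ratio_hz_per_t <- function() 42.577478518e6

#' Create a magnetization vector
#'
#' Magnetization is expressed in units of the equilibrium magnetization
#' (M0 = 1 per isochromat unless scaled), so a spin at rest is (0, 0, 1).
#'
#' @param mx,my,mz components of the magnetization vector.
#' @return numeric vector of length 3 with class \code{magnetization}.
#' @export
magnetization <- function(mx = 0, my = 0, mz = 1) {
  m <- c(mx = mx, my = my, mz = mz)
  if (!all(is.finite(m))) stop("magnetization components must be finite")
  structure(m, class = "magnetization")
}

#' Create an isochromat
#'
#' An isochromat is an idealized spin packet with a single T1, T2, position
#' along the slice-select axis and off-resonance frequency.
#'
#' @param t1_ms longitudinal relaxation time, ms. Must be > 0 (may be \code{Inf}).
#' @param t2_ms transverse relaxation time, ms. Must be > 0 (may be \code{Inf}).
#' @param z_m position along the slice-select axis, meters.
#' @param off_hz off-resonance frequency, Hz.
#' @param equilibrium equilibrium magnetization (dimensionless scale).
#' @return an object of class \code{isochromat}.
#' @export
isochromat <- function(t1_ms, t2_ms, z_m = 0, off_hz = 0, equilibrium = 1) {
  if (!is.numeric(t1_ms) || length(t1_ms) != 1L || is.na(t1_ms) || t1_ms <= 0)
    stop("invalid parameter: t1_ms must be a single positive number")
  if (!is.numeric(t2_ms) || length(t2_ms) != 1L || is.na(t2_ms) || t2_ms <= 0)
    stop("invalid parameter: t2_ms must be a single positive number")
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, z_m = z_m,
                 off_hz = off_hz, equilibrium = equilibrium),
            class = "isochromat")
}

#' Create a timeline event table
#'
#' Events are the discrete steps of the expanded pulse sequence. RF-bearing
#' events are sampled at the simulation step dt; pure-relaxation gaps may be
#' single events of arbitrary duration (rotation about z and relaxation are
#' exact for piecewise-constant fields).
#'
#' @param duration_s event durations in seconds (recycled).
#' @param rf_uT RF amplitude, microtesla.
#' @param phase_rad RF phase, rad.
#' @param grad_mTm slice-axis gradient, mT/m.
#' @param crusher logical; ideal crusher (transverse zeroed, no rotation).
#' @param adc integer; 0 for no sample, k > 0 to sample image k at the end
#'   of the event.
#' @return numeric matrix with one row per event and the canonical six
#'   columns (\code{dur_s}, \code{rf_uT}, \code{phase_rad}, \code{grad_mTm},
#'   \code{crusher}, \code{adc}).
#' @export
timeline_events <- function(duration_s, rf_uT = 0, phase_rad = 0, grad_mTm = 0,
                            crusher = FALSE, adc = 0L) {
  n <- max(length(duration_s), length(rf_uT), length(phase_rad),
           length(grad_mTm), length(crusher), length(adc))
  ev <- cbind(dur_s = rep_len(duration_s, n),
              rf_uT = rep_len(rf_uT, n),
              phase_rad = rep_len(phase_rad, n),
              grad_mTm = rep_len(grad_mTm, n),
              crusher = as.numeric(rep_len(crusher, n)),
              adc = as.numeric(rep_len(adc, n)))
  if (any(ev[, "dur_s"] <= 0)) stop("event durations must be positive")
  if (any(ev[, "crusher"] != 0 & ev[, "rf_uT"] != 0))
    stop("crusher events must carry zero RF")
  ev
}

event_matrix <- function(timeline) {
  if (inherits(timeline, "molli_timeline")) timeline$events else timeline
}

n_adc_images <- function(ev) as.integer(max(0, ev[, "adc"]))

#' Propagate a magnetization through a single timeline event
#'
#' One step of the discrete-event Bloch solver: rotation about the effective
#' field (RF transverse components plus gradient/off-resonance longitudinal
#' component) through angle gamma*|B_eff|*dt, followed by relaxation
#' (operator splitting). Crusher events zero the transverse components with
#' no rotation.
#'
#' @param mag magnetization vector (length 3 or \code{magnetization}).
#' @param iso an \code{\link{isochromat}}.
#' @param event a single-row event matrix (see \code{\link{timeline_events}}).
#' @param relax logical; set \code{FALSE} to disable relaxation (tests only).
#' @return the magnetization after the event, as a plain length-3 vector.
#' @export
bloch_step <- function(mag, iso, event, relax = TRUE) {
  stopifnot(inherits(iso, "isochromat"))
  ev <- rbind(event)
  res <- bloch_propagate_cpp(ev, iso$z_m, iso$t1_ms, iso$t2_ms, iso$off_hz,
                             iso$equilibrium, as.numeric(mag)[1:3], relax, 0L)
  res$final
}

#' Simulate one isochromat over a timeline
#'
#' Starts at equilibrium (0, 0, equilibrium) and returns the complex
#' transverse magnetization mx + i*my at every ADC marker.
#'
#' @param iso an \code{\link{isochromat}}.
#' @param timeline an event matrix or a \code{molli_timeline}.
#' @param relax logical; disable relaxation for validation runs only.
#' @return complex vector with one sample per ADC image index (possibly
#'   length 0 when the timeline carries no ADC markers).
#' @export
simulate_isochromat <- function(iso, timeline, relax = TRUE) {
  stopifnot(inherits(iso, "isochromat"))
  ev <- event_matrix(timeline)
  if (nrow(ev) == 0L) stop("timeline must be non-empty")
  n_img <- n_adc_images(ev)
  res <- bloch_propagate_cpp(ev, iso$z_m, iso$t1_ms, iso$t2_ms, iso$off_hz,
                             iso$equilibrium, c(0, 0, iso$equilibrium),
                             relax, n_img)
  res$samples
}

#' Complex ensemble signal over a timeline
#'
#' Sum of \code{\link{simulate_isochromat}} outputs over the ensemble; the
#' signal is linear in the isochromats.
#'
#' @param isochromats list of \code{\link{isochromat}} objects.
#' @param timeline an event matrix or a \code{molli_timeline}.
#' @param relax logical; disable relaxation for validation runs only.
#' @return complex vector, one ensemble sample per ADC image.
#' @export
ensemble_signal <- function(isochromats, timeline, relax = TRUE) {
  if (length(isochromats) == 0L) stop("invalid parameter: empty ensemble")
  ev <- event_matrix(timeline)
  n_img <- n_adc_images(ev)
  t1 <- vapply(isochromats, `[[`, numeric(1), "t1_ms")
  t2 <- vapply(isochromats, `[[`, numeric(1), "t2_ms")
  off <- vapply(isochromats, `[[`, numeric(1), "off_hz")
  eqv <- vapply(isochromats, `[[`, numeric(1), "equilibrium")
  z <- vapply(isochromats, `[[`, numeric(1), "z_m")
  if (length(unique(t1)) == 1L && length(unique(t2)) == 1L &&
      all(off == off[1]) && all(eqv == 1)) {
    return(bloch_ensemble_cpp(ev, z, t1[1], t2[1], off[1], relax, n_img))
  }
  out <- complex(n_img)
  for (iso in isochromats)
    out <- out + simulate_isochromat(iso, ev, relax = relax)
  out
}
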