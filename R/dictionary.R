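# Signal-dictionary construction: (T1,T2) grid enumeration, slice-profile
# ensemble simulation per pair on the exact timeline, persistence.

#' Specify a (T1, T2) simulation grid
#'
#' Grid values are generated by integer-step arithmetic in ms (no
#' floating-point accumulation). The physiological default range is
#' 200-1900 ms for T1 and 20-400 ms for T2 with combinations where
#' T2 > T1 excluded.
#'
#' @param t1_start_ms,t1_stop_ms,t1_step_ms T1 axis, ms.
#' @param t2_start_ms,t2_stop_ms,t2_step_ms T2 axis, ms.
#' @param exclude_t2_gt_t1 drop pairs with T2 > T1.
#' @param t1_stop_inclusive,t2_stop_inclusive whether the stop value itself
#'   is part of the axis (half-open axes are used by the performance
#'   fixtures, e.g. 600 <= T1 < 2000).
#' @return object of class \code{grid_spec}.
#' @export
grid_spec <- function(t1_start_ms = 200, t1_stop_ms = 1900, t1_step_ms = 1,
                      t2_start_ms = 20, t2_stop_ms = 400, t2_step_ms = 1,
                      exclude_t2_gt_t1 = TRUE,
                      t1_stop_inclusive = TRUE, t2_stop_inclusive = TRUE) {
  if (t1_step_ms <= 0 || t2_step_ms <= 0) stop("grid steps must be positive")
  if (t1_start_ms > t1_stop_ms || t2_start_ms > t2_stop_ms)
    stop("grid start must not exceed stop")
  structure(list(t1_start_ms = t1_start_ms, t1_stop_ms = t1_stop_ms,
                 t1_step_ms = t1_step_ms, t2_start_ms = t2_start_ms,
                 t2_stop_ms = t2_stop_ms, t2_step_ms = t2_step_ms,
                 exclude_t2_gt_t1 = exclude_t2_gt_t1,
                 t1_stop_inclusive = t1_stop_inclusive,
                 t2_stop_inclusive = t2_stop_inclusive),
            class = "grid_spec")
}

axis_values <- function(start, stop, step, inclusive) {
  n <- floor((stop - start) / step + 1e-9)
  v <- start + step * 0:n
  if (!inclusive) v <- v[v < stop - 1e-12]
  v
}

#' Enumerate the (T1, T2) pairs of a grid
#'
#' @param spec a \code{\link{grid_spec}}.
#' @return data frame with columns \code{t1_ms}, \code{t2_ms}, ordered by
#'   (T1, T2).
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  t1 <- axis_values(spec$t1_start_ms, spec$t1_stop_ms, spec$t1_step_ms,
                    spec$t1_stop_inclusive)
  t2 <- axis_values(spec$t2_start_ms, spec$t2_stop_ms, spec$t2_step_ms,
                    spec$t2_stop_inclusive)
  g <- expand.grid(t2_ms = t2, t1_ms = t1)[, c("t1_ms", "t2_ms")]
  if (spec$exclude_t2_gt_t1) g <- g[g$t2_ms <= g$t1_ms, , drop = FALSE]
  if (nrow(g) == 0L) stop("empty grid")
  rownames(g) <- NULL
  g
}

#' Isochromat positions across the slice
#'
#' Uniformly spaced, symmetric about slice center, spanning
#' \code{slice_fov_factor} times the slice thickness. An odd count is
#' required so one spin sits exactly at z = 0.
#'
#' @param n_spins odd number of spins, >= 3.
#' @param slice_thickness_mm slice thickness, mm.
#' @param slice_fov_factor extent relative to the slice thickness.
#' @return numeric vector of z positions in meters.
#' @export
slice_spin_positions <- function(n_spins, slice_thickness_mm, slice_fov_factor = 2) {
  if (n_spins < 3 || n_spins %% 2 == 0)
    stop("n_spins must be an odd count >= 3 (so one spin sits at slice center)")
  half <- slice_fov_factor * slice_thickness_mm * 1e-3 / 2
  seq(-half, half, length.out = n_spins)
}

#' Simulate one dictionary entry
#'
#' Magnitude of the complex slice-profile ensemble signal, one value per
#' image, for a single (T1, T2) pair on the given timeline. Noise-free and
#' deterministic.
#'
#' @param t1_ms,t2_ms relaxation times, ms.
#' @param timeline a \code{molli_timeline} (or raw event matrix).
#' @param positions slice positions from \code{\link{slice_spin_positions}}.
#' @return numeric magnitude vector, one entry per image.
#' @export
simulate_entry <- function(t1_ms, t2_ms, timeline, positions) {
  ev <- event_matrix(timeline)
  n_img <- n_adc_images(ev)
  sig <- tryCatch(
    bloch_ensemble_cpp(ev, positions, t1_ms, t2_ms, 0, TRUE, n_img),
    error = function(e) stop(sprintf("simulation failed for (T1=%g, T2=%g): %s",
                                     t1_ms, t2_ms, conditionMessage(e))))
  Mod(sig)
}

#' Build a signal dictionary
#'
#' Expands the timeline once, then simulates the slice-profile ensemble for
#' every (T1, T2) grid pair. Entries are independent, sorted by (T1, T2) and
#' order-deterministic regardless of the worker count (ordered parallel map).
#'
#' @param spec a \code{\link{grid_spec}}.
#' @param params an \code{\link{acquisition_params}} object.
#' @param scheme scheme string or \code{\link{parse_scheme}} result.
#' @param timing a \code{\link{cardiac_timing}} record.
#' @param n_workers parallel workers (forked; 1 = serial).
#' @param store_complex keep the signed complex sums as well (for
#'   phase-sensitive use); magnitudes are always stored.
#' @return object of class \code{signal_dictionary} with fields
#'   \code{t1_ms}, \code{t2_ms}, \code{signals} (entries x images magnitude
#'   matrix), \code{tis_ms} and \code{meta}.
#' @export
build_dictionary <- function(spec, params, scheme, timing, n_workers = 1L,
                             store_complex = FALSE) {
  if (is.character(scheme)) scheme <- parse_scheme(scheme)
  tl <- build_timeline(params, scheme, timing)
  grid <- enumerate_grid(spec)
  pos <- slice_spin_positions(params$n_slice_spins, params$slice_thickness_mm,
                              params$slice_fov_factor)
  run_chunk <- function(idx) {
    bloch_dictionary_cpp(tl$events, pos, grid$t1_ms[idx], grid$t2_ms[idx],
                         tl$n_images)
  }
  if (n_workers > 1L) {
    chunks <- split(seq_len(nrow(grid)),
                    cut(seq_len(nrow(grid)), n_workers, labels = FALSE))
    res <- parallel::mclapply(chunks, run_chunk, mc.cores = n_workers)
    bad <- vapply(res, inherits, logical(1), "try-error")
    if (any(bad)) stop("dictionary worker failed: ", res[[which(bad)[1]]])
    cplx <- do.call(rbind, res)
  } else {
    cplx <- run_chunk(seq_len(nrow(grid)))
  }
  dict <- structure(list(t1_ms = grid$t1_ms, t2_ms = grid$t2_ms,
                         signals = Mod(cplx),
                         complex_signals = if (store_complex) cplx else NULL,
                         tis_ms = tl$effective_tis_ms,
                         meta = list(config_digest = config_digest(params),
                                     grid_spec = unclass(spec),
                                     scheme = tl$scheme_text,
                                     rr_intervals_ms = tl$rr_intervals_ms,
                                     n_slice_spins = params$n_slice_spins,
                                     dt_us = params$dt_us,
                                     created = format(Sys.time(), tz = "UTC"),
                                     package_version = as.character(utils::packageVersion("squaremr")))),
                    class = "signal_dictionary")
  dict
}

#' @export
print.signal_dictionary <- function(x, ...) {
  cat(sprintf("Signal dictionary: %d entries x %d images (scheme %s, %d spins, dt %g us)\n",
              length(x$t1_ms), ncol(x$signals), x$meta$scheme,
              x$meta$n_slice_spins, x$meta$dt_us))
  invisible(x)
}

#' Save a signal dictionary
#'
#' Single-file container (RDS serialization) holding the entry arrays, the
#' effective TIs and the provenance metadata including the acquisition-config
#' digest that \code{\link{load_dictionary}} verifies.
#'
#' @param dict a \code{signal_dictionary}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "signal_dictionary"))
  saveRDS(dict, path)
  invisible(path)
}

#' Load a signal dictionary
#'
#' Refuses to load a dictionary whose stored acquisition-config digest does
#' not match the digest of the session configuration, unless \code{force}.
#'
#' @param path file written by \code{\link{save_dictionary}}.
#' @param params session \code{\link{acquisition_params}} to verify against
#'   (\code{NULL} skips verification).
#' @param force load despite a digest mismatch.
#' @return the \code{signal_dictionary}.
#' @export
load_dictionary <- function(path, params = NULL, force = FALSE) {
  dict <- tryCatch(readRDS(path),
                   error = function(e) stop(sprintf("corrupt dictionary file '%s': %s",
                                                    path, conditionMessage(e))))
  if (!inherits(dict, "signal_dictionary"))
    stop(sprintf("corrupt dictionary file '%s': not a signal dictionary", path))
  if (!is.null(params) && !force) {
    d <- config_digest(params)
    if (!identical(d, dict$meta$config_digest))
      stop(sprintf(paste0("dictionary/config digest mismatch: session %s vs stored %s; ",
                          "rebuild the dictionary or pass force = TRUE"),
                   d, dict$meta$config_digest))
  }
  dict
}
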