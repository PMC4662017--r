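# Digital-phantom generator: known T1/T2/M0 maps, simulated ECG, and
# Bloch-simulated MOLLI acquisition with Rician noise.

#' Cardiac tissue relaxation values (myocardial phantom)
#'
#' Reference T1/T2 pairs of the six-tissue myocardial phantom: pre-contrast
#' normal myocardium, blood, edema and infarct, plus normal myocardium at
#' 2-3 min and 13-15 min after gadolinium contrast.
#'
#' @return data frame with columns \code{name}, \code{t1_ms}, \code{t2_ms}.
#' @export
cardiac_tissues <- function() {
  data.frame(
    name = c("myocardium", "blood", "edema", "infarct",
             "post_gd_2_3min", "post_gd_13_15min"),
    t1_ms = c(1048, 1570, 1249, 1361, 344, 413),
    t2_ms = c(50, 196, 62, 64, 52, 50),
    stringsAsFactors = FALSE)
}

#' Eurospin-like T1 ladder (synthetic fixture)
#'
#' Six tubes with near-myocardial T2 (52 ms) and T1 spanning 212-1522 ms.
#' Only the endpoints are reference values; the intermediate rungs are
#' synthetic, evenly spaced choices.
#'
#' @return data frame with columns \code{name}, \code{t1_ms}, \code{t2_ms}.
#' @export
eurospin_tissues <- function() {
  t1 <- round(seq(212, 1522, length.out = 6))
  data.frame(name = paste0("tube", seq_along(t1)),
             t1_ms = t1, t2_ms = rep(52, length(t1)),
             stringsAsFactors = FALSE)
}

#' Build a digital phantom
#'
#' Non-overlapping disks (or rectangular tiles) on a square canvas, one
#' region per tissue; background has M0 = 0.
#'
#' @param layout "disks" or "grid".
#' @param tissue_table data frame with \code{name}, \code{t1_ms},
#'   \code{t2_ms} (defaults to \code{\link{cardiac_tissues}}).
#' @param n canvas side length in pixels.
#' @param m0 proton-density scale of the labeled regions.
#' @return object of class \code{phantom_maps}: \code{t1_ms}, \code{t2_ms},
#'   \code{m0}, \code{region_labels} matrices and the \code{regions} table.
#' @export
make_phantom <- function(layout = c("disks", "grid"),
                         tissue_table = cardiac_tissues(), n = 124, m0 = 1) {
  layout <- match.arg(layout)
  stopifnot(all(c("name", "t1_ms", "t2_ms") %in% names(tissue_table)))
  if (any(tissue_table$t2_ms > tissue_table$t1_ms) ||
      any(tissue_table$t2_ms <= 0))
    stop("tissue table must satisfy T1 >= T2 > 0")
  k <- nrow(tissue_table)
  lab <- matrix(0L, n, n)
  if (layout == "disks") {
    ncol_ <- ceiling(sqrt(k)); nrow_ <- ceiling(k / ncol_)
    cw <- n / ncol_; ch <- n / nrow_
    r <- 0.35 * min(cw, ch)
    xs <- row(lab); ys <- col(lab)
    for (i in seq_len(k)) {
      cx <- ((i - 1) %% ncol_ + 0.5) * cw
      cy <- (floor((i - 1) / ncol_) + 0.5) * ch
      inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      if (any(lab[inside] != 0L)) stop("layout error: overlapping regions")
      lab[inside] <- i
    }
  } else {
    ncol_ <- ceiling(sqrt(k)); nrow_ <- ceiling(k / ncol_)
    cw <- n %/% ncol_; ch <- n %/% nrow_
    for (i in seq_len(k)) {
      x0 <- ((i - 1) %% ncol_) * cw + 2
      y0 <- (floor((i - 1) / ncol_)) * ch + 2
      sel <- seq(x0, min(x0 + cw - 4, n))
      sely <- seq(y0, min(y0 + ch - 4, n))
      if (any(lab[sel, sely] != 0L)) stop("layout error: overlapping regions")
      lab[sel, sely] <- i
    }
  }
  t1 <- t2 <- m0m <- matrix(0, n, n)
  for (i in seq_len(k)) {
    sel <- lab == i
    t1[sel] <- tissue_table$t1_ms[i]
    t2[sel] <- tissue_table$t2_ms[i]
    m0m[sel] <- m0
  }
  structure(list(t1_ms = t1, t2_ms = t2, m0 = m0m, region_labels = lab,
                 regions = tissue_table),
            class = "phantom_maps")
}

#' Simulated ECG RR-interval series
#'
#' RR = 60000/mean_bpm plus Gaussian jitter (sd_ms) truncated at +/- 3 sd;
#' reproducible under the seed.
#'
#' @param mean_bpm mean heart rate, beats per minute.
#' @param sd_ms RR jitter standard deviation, ms.
#' @param n_beats number of heartbeats.
#' @param seed RNG seed (\code{NULL} leaves the RNG state alone).
#' @return a \code{\link{cardiac_timing}} record.
#' @export
make_rr_series <- function(mean_bpm = 60, sd_ms = 0, n_beats, seed = NULL) {
  stopifnot(mean_bpm > 0, sd_ms >= 0)
  rr0 <- 60000 / mean_bpm
  if (sd_ms > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    j <- pmin(pmax(stats::rnorm(n_beats, 0, sd_ms), -3 * sd_ms), 3 * sd_ms)
  } else j <- rep(0, n_beats)
  cardiac_timing(rr_intervals_ms = rr0 + j)
}

#' Bloch-simulate a MOLLI acquisition of a phantom
#'
#' Every distinct (T1, T2) pair in the phantom is simulated once through the
#' full timeline (slice-profile ensemble) and broadcast to its pixels scaled
#' by M0. Noise is added in the complex domain (independent Gaussian per
#' channel, sd \code{noise_sigma}) before taking magnitudes, giving Rician
#' magnitude statistics; \code{noise_sigma = 0} returns the exact noise-free
#' magnitudes.
#'
#' @param phantom a \code{\link{make_phantom}} result.
#' @param params an \code{\link{acquisition_params}} object.
#' @param scheme scheme string or parsed scheme.
#' @param timing a \code{\link{cardiac_timing}} record.
#' @param noise_sigma complex-channel noise sd, in units of the noise-free
#'   ensemble signal (which is bounded by n_slice_spins).
#' @param seed RNG seed for the noise (\code{NULL} leaves the RNG alone).
#' @return object of class \code{molli_series}: \code{images} (n x n x
#'   n_images magnitude array), \code{tis_ms}, \code{scheme},
#'   \code{rr_intervals_ms}, \code{noise_sigma}, \code{seed},
#'   \code{config_digest}.
#' @export
simulate_acquisition <- function(phantom, params, scheme, timing,
                                 noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_maps"))
  if (any(phantom$t2_ms > phantom$t1_ms))
    stop("phantom contains pixels with T2 > T1")
  tl <- build_timeline(params, scheme, timing)
  pos <- slice_spin_positions(params$n_slice_spins, params$slice_thickness_mm,
                              params$slice_fov_factor)
  lab <- phantom$region_labels
  dims <- dim(lab)
  n_img <- tl$n_images
  # one Bloch run per distinct (T1,T2) pair, cached
  pairs <- unique(data.frame(t1 = phantom$t1_ms[lab > 0],
                             t2 = phantom$t2_ms[lab > 0]))
  sig_complex <- vector("list", nrow(pairs))
  for (q in seq_len(nrow(pairs)))
    sig_complex[[q]] <- bloch_ensemble_cpp(tl$events, pos, pairs$t1[q],
                                           pairs$t2[q], 0, TRUE, n_img)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  imgs <- array(0, dim = c(dims, n_img))
  re <- im <- matrix(0, dims[1], dims[2])
  for (k in seq_len(n_img)) {
    for (q in seq_len(nrow(pairs))) {
      sel <- phantom$t1_ms == pairs$t1[q] & phantom$t2_ms == pairs$t2[q] & lab > 0
      re[sel] <- Re(sig_complex[[q]][k]) * phantom$m0[sel]
      im[sel] <- Im(sig_complex[[q]][k]) * phantom$m0[sel]
    }
    re[lab == 0] <- 0; im[lab == 0] <- 0
    if (noise_sigma > 0) {
      re_n <- re + stats::rnorm(length(re), 0, noise_sigma)
      im_n <- im + stats::rnorm(length(im), 0, noise_sigma)
      imgs[, , k] <- sqrt(re_n^2 + im_n^2)
    } else {
      imgs[, , k] <- sqrt(re^2 + im^2)
    }
  }
  structure(list(images = imgs, tis_ms = tl$effective_tis_ms,
                 scheme = tl$scheme_text,
                 rr_intervals_ms = tl$rr_intervals_ms,
                 noise_sigma = noise_sigma, seed = seed,
                 config_digest = config_digest(params)),
            class = "molli_series")
}

#' Construct a MOLLI series object
#'
#' @param images magnitude array (rows x cols x images).
#' @param tis_ms effective TI per image, ms.
#' @param ... further metadata fields (scheme, rr_intervals_ms, ...).
#' @return object of class \code{molli_series}.
#' @export
molli_series <- function(images, tis_ms, ...) {
  if (dim(images)[3] != length(tis_ms))
    stop("image count must equal the number of effective TIs")
  if (any(images < 0)) stop("magnitude images must be non-negative")
  structure(c(list(images = images, tis_ms = tis_ms), list(...)),
            class = "molli_series")
}

#' @export
print.molli_series <- function(x, ...) {
  cat(sprintf("MOLLI series: %d x %d pixels, %d images (scheme %s)\n",
              dim(x$images)[1], dim(x$images)[2], dim(x$images)[3],
              if (is.null(x$scheme)) "?" else x$scheme))
  invisible(x)
}
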