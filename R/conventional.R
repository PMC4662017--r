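# Conventional MOLLI post-processing: 3-parameter magnitude IR fit with
# exhaustive polarity restoration and the FLASH-based Look-Locker correction.

# Residual sum of squares of S(TI) = A - B*exp(-TI/T1*) with (A, B) solved
# linearly (variable projection) for a fixed T1*.
ir3_rss <- function(t1_star, tis, s) {
  e <- exp(-tis / t1_star)
  X <- cbind(1, -e)
  fit <- tryCatch(stats::lm.fit(X, s), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf, A = NA, B = NA))
  r <- fit$residuals
  list(rss = sum(r * r), A = fit$coefficients[1], B = fit$coefficients[2])
}

#' Three-parameter inversion-recovery fit of a magnitude series
#'
#' Fits S(TI) = A - B*exp(-TI/T1*) to a magnitude MOLLI series. Polarity is
#' restored by exhaustive search: for every candidate index k in 0..n the
#' first k samples (in sorted-TI order) are negated and the model is fitted;
#' the global residual minimum over k wins. For each polarity the nonlinear
#' T1* search combines a dense log-spaced profile scan with local refinement
#' (variable projection: A and B are solved linearly at each T1*), which
#' covers the conventional multi-start initializations.
#'
#' @param tis_ms inversion times, ms (sorted ascending; the samples are
#'   reordered alongside if not).
#' @param s magnitude samples, same length as \code{tis_ms}, >= 4 points.
#' @param t1_star_range search range for T1*, ms.
#' @return object of class \code{ir_fit}: \code{A}, \code{B},
#'   \code{t1_star_ms}, \code{t1_ms} (Look-Locker corrected),
#'   \code{inversion_index}, \code{residual}, \code{valid}.
#' @export
fit_ir3 <- function(tis_ms, s, t1_star_range = c(30, 12000)) {
  if (length(tis_ms) != length(s)) stop("tis_ms and s must have equal length")
  if (length(s) < 4) stop("at least 4 samples are required for a 3-parameter fit")
  o <- order(tis_ms)
  tis <- as.numeric(tis_ms)[o]; sm <- as.numeric(s)[o]
  grid <- exp(seq(log(t1_star_range[1]), log(t1_star_range[2]), length.out = 120))
  best <- list(rss = Inf)
  for (k in 0:length(sm)) {
    sk <- sm
    if (k > 0) sk[seq_len(k)] <- -sk[seq_len(k)]
    prof <- vapply(grid, function(t1s) ir3_rss(t1s, tis, sk)$rss, numeric(1))
    i <- which.min(prof)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(t1s) ir3_rss(t1s, tis, sk)$rss,
                           interval = c(lo, hi), tol = 1e-10)
    if (opt$objective < best$rss) {
      ab <- ir3_rss(opt$minimum, tis, sk)
      best <- list(rss = opt$objective, t1_star = opt$minimum,
                   A = unname(ab$A), B = unname(ab$B), k = k)
    }
  }
  if (!is.finite(best$rss)) {
    return(structure(list(A = NA_real_, B = NA_real_, t1_star_ms = NA_real_,
                          t1_ms = NA_real_, inversion_index = NA_integer_,
                          residual = Inf, valid = FALSE), class = "ir_fit"))
  }
  t1 <- if (is.finite(best$A) && best$A > 0)
    ll_correct(best$A, best$B, best$t1_star) else NA_real_
  structure(list(A = best$A, B = best$B, t1_star_ms = best$t1_star,
                 t1_ms = t1, inversion_index = best$k,
                 residual = best$rss, valid = TRUE),
            class = "ir_fit")
}

#' Look-Locker correction
#'
#' Converts the apparent relaxation time of the readout-perturbed recovery
#' to a T1 estimate via T1 = T1* (B/A - 1), the correction derived for FLASH
#' readouts and applied to MOLLI by convention.
#'
#' @param A,B parameters of the 3-parameter model S = A - B exp(-TI/T1*).
#' @param t1_star_ms apparent relaxation time, ms.
#' @return corrected T1, ms (NA with a warning when A <= 0).
#' @export
ll_correct <- function(A, B, t1_star_ms) {
  if (any(A <= 0)) {
    warning("Look-Locker correction undefined for A <= 0; flagging pixel invalid")
    return(ifelse(A > 0, t1_star_ms * (B / A - 1), NA_real_))
  }
  t1_star_ms * (B / A - 1)
}

#' Conventional MOLLI parameter map
#'
#' Per-pixel \code{\link{fit_ir3}} plus \code{\link{ll_correct}} over the
#' mask; pixels whose fit fails are flagged invalid (NA).
#'
#' @param series a \code{molli_series}.
#' @param mask logical matrix; \code{NULL} uses all pixels with any signal.
#' @return a \code{parameter_map} with \code{t1_ms} and \code{residual};
#'   \code{t2_ms} is not estimated by the conventional path.
#' @export
conventional_map <- function(series, mask = NULL) {
  stopifnot(inherits(series, "molli_series"))
  dims <- dim(series$images)[1:2]
  if (is.null(mask)) mask <- apply(series$images, c(1, 2), function(v) any(v > 0))
  if (!any(mask)) warning("empty mask: returning an empty parameter map")
  t1 <- res <- matrix(NA_real_, dims[1], dims[2])
  idx <- which(mask, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    s <- series$images[i, j, ]
    if (all(s == 0)) next
    f <- fit_ir3(series$tis_ms, s)
    if (isTRUE(f$valid)) { t1[i, j] <- f$t1_ms; res[i, j] <- f$residual }
  }
  parameter_map(t1_ms = t1, residual = res, mask = mask,
                provenance = list(method = "conventional-molli",
                                  fit = "ir3+look-locker"))
}
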