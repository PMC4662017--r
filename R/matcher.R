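# Dictionary matching: per-pixel (T1,T2) by least squared difference with an
# analytically optimal non-negative amplitude per entry (full linear search).

#' Match one measured signal against a dictionary
#'
#' For every entry d_k the optimal amplitude is
#' a_k = max(0, <s, d_k> / <d_k, d_k>) and the residual
#' r_k = ||s - a_k d_k||^2; the entry minimizing r_k wins. Ties are broken
#' by smaller T1, then smaller T2 (entries are sorted that way).
#'
#' @param s measured non-negative magnitude vector, one value per image.
#' @param dict a \code{signal_dictionary}.
#' @return list of class \code{match_result}: \code{t1_ms}, \code{t2_ms},
#'   \code{amplitude}, \code{residual}, \code{entry_index}.
#' @export
match_signal <- function(s, dict) {
  stopifnot(inherits(dict, "signal_dictionary"))
  s <- as.numeric(s)
  if (length(s) != ncol(dict$signals))
    stop(sprintf("signal length %d does not match dictionary image count %d",
                 length(s), ncol(dict$signals)))
  if (any(s < 0)) stop("measured magnitudes must be non-negative")
  if (all(s == 0)) stop("degenerate input: all-zero signal (masked pixel)")
  D <- dict$signals
  dd <- rowSums(D * D)
  sd_ <- as.numeric(D %*% s)
  a <- pmax(0, sd_ / dd)
  r <- sum(s * s) - 2 * a * sd_ + a * a * dd
  k <- which.min(r)      # first minimum = smallest (T1, T2) among ties
  res_k <- sum((s - a[k] * D[k, ])^2)   # direct form avoids cancellation
  structure(list(t1_ms = dict$t1_ms[k], t2_ms = dict$t2_ms[k],
                 amplitude = a[k], residual = res_k,
                 entry_index = k),
            class = "match_result")
}

#' Match a MOLLI image series pixel by pixel
#'
#' Requires the series TIs to equal the dictionary TIs within 1 ms per
#' image; otherwise the dictionary must be rebuilt for the session's actual
#' TIs and an explicit error lists both TI sets. The result is independent
#' of pixel processing order.
#'
#' @param series a \code{molli_series} (see
#'   \code{\link{simulate_acquisition}} or \code{\link{read_series}}).
#' @param dict a \code{signal_dictionary}.
#' @param mask logical matrix; \code{NULL} uses all pixels with any signal.
#' @return a \code{parameter_map} with \code{t1_ms}, \code{t2_ms},
#'   \code{amplitude} and \code{residual} matrices (NA outside the mask).
#' @export
match_series <- function(series, dict, mask = NULL) {
  stopifnot(inherits(series, "molli_series"), inherits(dict, "signal_dictionary"))
  if (length(series$tis_ms) != ncol(dict$signals) ||
      any(abs(series$tis_ms - dict$tis_ms) > 1)) {
    stop(sprintf(paste0("series/dictionary TI mismatch; rebuild the dictionary ",
                        "for the actual TIs.\n  series TIs (ms): %s\n  dictionary TIs (ms): %s"),
                 paste(round(series$tis_ms, 2), collapse = ", "),
                 paste(round(dict$tis_ms, 2), collapse = ", ")))
  }
  dims <- dim(series$images)[1:2]
  if (is.null(mask)) mask <- apply(series$images, c(1, 2), function(v) any(v > 0))
  if (!any(mask)) {
    warning("empty mask: returning an empty parameter map")
  }
  t1 <- t2 <- amp <- res <- matrix(NA_real_, dims[1], dims[2])
  idx <- which(mask, arr.ind = TRUE)
  D <- dict$signals
  dd <- rowSums(D * D)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    s <- series$images[i, j, ]
    if (all(s == 0)) next
    sd_ <- as.numeric(D %*% s)
    a <- pmax(0, sd_ / dd)
    r <- sum(s * s) - 2 * a * sd_ + a * a * dd
    k <- which.min(r)
    t1[i, j] <- dict$t1_ms[k]; t2[i, j] <- dict$t2_ms[k]
    amp[i, j] <- a[k]; res[i, j] <- sum((s - a[k] * D[k, ])^2)
  }
  parameter_map(t1_ms = t1, t2_ms = t2, amplitude = amp, residual = res,
                mask = mask,
                provenance = list(method = "dictionary-match",
                                  dict_digest = dict$meta$config_digest,
                                  scheme = dict$meta$scheme))
}

#' Construct a parameter map
#'
#' @param t1_ms T1 matrix, ms (NA outside the mask).
#' @param t2_ms,amplitude,residual optional companion matrices.
#' @param mask logical matrix of fitted pixels.
#' @param provenance list recording the method and its settings/digest.
#' @return object of class \code{parameter_map}.
#' @export
parameter_map <- function(t1_ms, t2_ms = NULL, amplitude = NULL,
                          residual = NULL, mask, provenance = list()) {
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, amplitude = amplitude,
                 residual = residual, mask = mask, provenance = provenance),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("Parameter map (%s): %d x %d pixels, %d fitted\n",
              if (is.null(x$provenance$method)) "?" else x$provenance$method,
              nrow(x$t1_ms), ncol(x$t1_ms), sum(x$mask)))
  invisible(x)
}
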