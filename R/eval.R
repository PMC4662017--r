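# Evaluation statistics for phantom analysis: per-ROI bias against reference
# values and the modified Bland-Altman summary.

#' Rectangular ROIs at the region centers of a phantom
#'
#' Convenience for phantom studies: one square ROI centered in each labeled
#' region (mirroring a rectangular ROI placed in the center of each tube).
#'
#' @param phantom a \code{phantom_maps} object.
#' @param half_width half side length of the square ROI, pixels.
#' @return named list of logical matrices, one per region.
#' @export
phantom_rois <- function(phantom, half_width = 3) {
  lab <- phantom$region_labels
  out <- list()
  for (i in seq_len(nrow(phantom$regions))) {
    idx <- which(lab == i, arr.ind = TRUE)
    cx <- round(mean(idx[, 1])); cy <- round(mean(idx[, 2]))
    roi <- matrix(FALSE, nrow(lab), ncol(lab))
    xr <- max(1, cx - half_width):min(nrow(lab), cx + half_width)
    yr <- max(1, cy - half_width):min(ncol(lab), cy + half_width)
    roi[xr, yr] <- TRUE
    roi <- roi & lab == i
    out[[phantom$regions$name[i]]] <- roi
  }
  out
}

#' Per-ROI bias of a parameter map against reference values
#'
#' bias_i = mean(map over ROI_i) - reference_i; the summary is the mean and
#' SD of the per-ROI biases.
#'
#' @param map a \code{parameter_map} (the \code{t1_ms} plane is evaluated).
#' @param reference named numeric vector of reference values, one per ROI.
#' @param rois named list of logical ROI matrices (same names as
#'   \code{reference}).
#' @return list with \code{stats} (data frame: roi, n, mean, sd, reference,
#'   bias) and \code{summary} (mean and sd of the biases).
#' @export
evaluate_bias <- function(map, reference, rois) {
  stopifnot(inherits(map, "parameter_map"))
  if (is.null(names(rois)) || !all(names(rois) %in% names(reference)))
    stop("rois and reference must share names")
  rows <- lapply(names(rois), function(nm) {
    v <- map$t1_ms[rois[[nm]] & map$mask]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop(sprintf("empty ROI '%s'", nm))
    data.frame(roi = nm, n = length(v), mean = mean(v), sd = stats::sd(v),
               reference = reference[[nm]],
               bias = mean(v) - reference[[nm]],
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  list(stats = stats,
       summary = c(mean_bias = mean(stats$bias), sd_bias = stats::sd(stats$bias)))
}

#' Modified Bland-Altman analysis
#'
#' Differences (estimate - reference) summarized as mean, SD and 95% limits
#' of agreement (mean +/- 1.96 SD). In the modified form the differences are
#' plotted against the reference value rather than the pair mean.
#'
#' @param estimates,references paired numeric vectors (n >= 2).
#' @param plot_file optional path; when given, the plot is written there
#'   (PNG or PDF by extension).
#' @return list with \code{mean_diff}, \code{sd_diff} and \code{limits}
#'   (length-2 vector).
#' @export
bland_altman <- function(estimates, references, plot_file = NULL) {
  if (length(estimates) != length(references)) stop("paired vectors required")
  if (length(estimates) < 2) stop("at least 2 pairs are required")
  d <- estimates - references
  m <- mean(d); s <- stats::sd(d)
  lim <- c(m - 1.96 * s, m + 1.96 * s)
  if (!is.null(plot_file)) {
    open_dev <- if (grepl("\\.pdf$", plot_file)) grDevices::pdf else grDevices::png
    open_dev(plot_file)
    on.exit(grDevices::dev.off())
    graphics::plot(references, d, xlab = "Reference value",
                   ylab = "Estimate - reference",
                   main = "Modified Bland-Altman (x = reference)")
    graphics::abline(h = m)
    graphics::abline(h = lim, lty = 2)
  }
  list(mean_diff = m, sd_diff = s, limits = lim)
}
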