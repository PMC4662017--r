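# I/O: NIfTI series/maps with JSON sidecars, YAML/JSON configuration,
# config digests and structured run logging.

#' Digest of an acquisition configuration
#'
#' MD5 of the canonicalized JSON serialization of the parameters; used to
#' tie dictionaries, series and maps to the configuration that produced
#' them.
#'
#' @param params an \code{\link{acquisition_params}} object (or any list).
#' @return hex digest string.
#' @export
config_digest <- function(params) {
  x <- unclass(params)
  x <- x[order(names(x))]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Write a MOLLI series as NIfTI plus JSON sidecar
#'
#' The sidecar is mandatory metadata: it carries the effective TIs, the
#' scheme string, the RR series, the noise level, the seed and the config
#' digest.
#'
#' @param series a \code{molli_series}.
#' @param path output NIfTI path (e.g. \code{series.nii.gz}); the sidecar
#'   is written alongside with extension \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "molli_series"))
  RNifti::writeNifti(series$images, path)
  sidecar <- list(tis_ms = series$tis_ms, scheme = series$scheme,
                  rr_intervals_ms = series$rr_intervals_ms,
                  noise_sigma = series$noise_sigma, seed = series$seed,
                  config_digest = series$config_digest)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a MOLLI series from NIfTI plus JSON sidecar
#'
#' @param path NIfTI path written by \code{\link{write_series}} (or any
#'   magnitude series with a matching sidecar).
#' @param sidecar explicit sidecar path; default replaces the extension.
#' @return a \code{molli_series}.
#' @export
read_series <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar '%s': effective TIs are mandatory metadata", sidecar))
  img <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$tis_ms)) stop("sidecar lacks tis_ms")
  if (dim(img)[3] != length(meta$tis_ms))
    stop(sprintf("sidecar TI count (%d) does not match image count (%d)",
                 length(meta$tis_ms), dim(img)[3]))
  structure(c(list(images = img), meta), class = "molli_series")
}

#' Write a parameter map set as NIfTI volumes
#'
#' Writes \code{t1.nii.gz} (and \code{t2/amplitude/residual} when present),
#' \code{mask.nii.gz} and a \code{provenance.json} into \code{dir}.
#'
#' @param map a \code{parameter_map}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_maps <- function(map, dir) {
  stopifnot(inherits(map, "parameter_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    m[is.na(m)] <- 0
    RNifti::writeNifti(m, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(map$t1_ms, "t1")
  if (!is.null(map$t2_ms)) wr(map$t2_ms, "t2")
  if (!is.null(map$amplitude)) wr(map$amplitude, "amplitude")
  if (!is.null(map$residual)) wr(map$residual, "residual")
  wr(map$mask * 1, "mask")
  jsonlite::write_json(map$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an acquisition configuration file
#'
#' YAML or JSON (by extension). Recognized keys mirror
#' \code{\link{acquisition_params}} plus \code{scheme} (literal scheme
#' string) and \code{rr_intervals_ms} / \code{mean_bpm} for the timing.
#'
#' @param path config file.
#' @return list with \code{params} (class \code{acq_params}), \code{scheme}
#'   (string or NULL) and \code{timing} (\code{cardiac_timing} or NULL).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(acquisition_params))
  pars <- cfg[intersect(names(cfg), known)]
  params <- do.call(acquisition_params, pars)
  timing <- NULL
  if (!is.null(cfg$rr_intervals_ms))
    timing <- cardiac_timing(unlist(cfg$rr_intervals_ms),
                             trigger_delay_ms = if (is.null(cfg$trigger_delay_ms)) 0 else cfg$trigger_delay_ms)
  list(params = params, scheme = cfg$scheme, timing = timing,
       mean_bpm = cfg$mean_bpm, n_beats = cfg$n_beats)
}

#' Write an acquisition configuration file
#'
#' @param params an \code{\link{acquisition_params}} object.
#' @param path output path (\code{.yaml} or \code{.json}).
#' @param scheme optional scheme string to embed.
#' @param rr_intervals_ms optional RR series to embed.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path, scheme = NULL, rr_intervals_ms = NULL) {
  cfg <- unclass(params)
  if (!is.null(scheme)) cfg$scheme <- scheme
  if (!is.null(rr_intervals_ms)) cfg$rr_intervals_ms <- rr_intervals_ms
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Append a structured log record for a processing run
#'
#' One JSON line per run: timestamp, action, config digest, seed and any
#' extra fields, so every output map can be traced to its dictionary digest
#' or fit settings from the logs alone.
#'
#' @param logfile path of the JSON-lines log.
#' @param action short action name.
#' @param digest config/dictionary digest string.
#' @param seed RNG seed used (or NULL).
#' @param ... further fields.
#' @return the record, invisibly.
#' @export
log_run <- function(logfile, action, digest = NULL, seed = NULL, ...) {
  rec <- list(time = format(Sys.time(), tz = "UTC"), action = action,
              digest = digest, seed = seed, ...)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  cat(as.character(line), "\n", file = logfile, append = TRUE, sep = "")
  invisible(rec)
}
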