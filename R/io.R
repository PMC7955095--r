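#' Read a multi-page 16-bit TIFF into an ImageStack
#'
#' Pages must be single-channel, identical size, 16-bit. Page order and bit
#' depth are preserved; intensities come back as integers in \[0, 65535\].
#'
#' @param path path to a TIFF file.
#' @param pitchUm in-plane pixel pitch (um/px); the field of a 500 x 500
#'   image at 0.28 um/px is 140 um x 140 um.
#' @param zStepUm axial step between slices (um); may be \code{NA}.
#' @param channel acquisition channel tag.
#' @return an \linkS4class{ImageStack}.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' s <- ImageStack(matrix(1234L, 16, 16), pitchUm = 0.28, channel = "SHG")
#' writeStack(s, f)
#' identical(pixels(readStack(f, 0.28, channel = "SHG"))[[1]], pixels(s)[[1]])
#' @export
readStack <- function(path, pitchUm, zStepUm = NA_real_,
                      channel = c("SHG", "CARS", "TPEF")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  bits <- as.integer(meta$bits.per.sample)
  if (any(bits != 16L))
    stop(sprintf("expected 16-bit TIFF pages, found %s bits per sample",
                 paste(unique(bits), collapse = "/")))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) stop("multi-channel pages are not supported")
      p <- p[, , 1L]
    }
    p
  })
  dims <- vapply(pages, function(p) dim(p), integer(2))
  if (ncol(dims) > 1L && any(dims != dims[, 1L]))
    stop("TIFF pages have mixed sizes")
  ImageStack(pages, pitchUm = pitchUm, zStepUm = zStepUm, channel = channel)
}

#' Write an ImageStack as a multi-page 16-bit TIFF
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  pages <- lapply(stack@pixels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a BinaryMask as an 8-bit {0, 255} TIFF (Fiji-compatible)
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  tiff::writeTIFF(ifelse(mask@mask, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit mask TIFF into a BinaryMask
#'
#' Nonzero pixels are TRUE.
#'
#' @param path path to a TIFF file.
#' @param pitchUm pixel pitch (um/px).
#' @return a \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, pitchUm = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  BinaryMask(p > 0, pitchUm)
}

#' Load a pipeline configuration from a YAML file
#'
#' Missing keys take the built-in defaults (the constants the
#' quantification was defined with: SHG threshold 20000, 0.4 % saturated
#' pixels, mean-filter radius 1 px, background radius 30 px, 2.255 um
#' isotropic OCT voxel, refractive index 1.33, 10-slice composite,
#' alpha 0.05). Keys use the slot names of
#' \linkS4class{PipelineConfig}. Invariant violations are rejected.
#'
#' @param path path to a YAML file, or \code{NULL} for all defaults.
#' @return a validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- loadConfig()
#' cfg@shgThreshold
#' @export
loadConfig <- function(path = NULL) {
  cfg <- new("PipelineConfig")
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- slotNames(cfg)
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(vals)) slot(cfg, k) <- as.numeric(vals[[k]])
  validObject(cfg)
  cfg
}

#' Log the fully resolved configuration of a pipeline run
#'
#' Every quantitative result depends on the pipeline constants, so runs
#' should record them; this emits one \code{message()} line per setting.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return \code{config}, invisibly.
#' @export
logConfig <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  for (s in slotNames(config))
    message(sprintf("config %s = %s", s, format(slot(config, s))))
  invisible(config)
}

#' Write per-animal region results to CSV
#'
#' One row per (animal, region, metric). Non-finite values (e.g. the
#' \code{NaN} standard deviation of a single observation) are serialized
#' as \code{NaN} with a warning, and survive a round trip through
#' [readResultsTable()].
#'
#' @param results data frame with at least columns \code{animal},
#'   \code{region}, \code{metric}, \code{value}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data frame")
  need <- c("animal", "region", "metric", "value")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results lack column(s): ", paste(miss, collapse = ", "))
  num <- vapply(results, is.numeric, logical(1))
  if (any(vapply(results[num], function(col) any(!is.finite(col)), logical(1))))
    warning("non-finite values serialized as-is (NaN/NA/Inf)")
  utils::write.csv(results, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' Read a results CSV written by [writeResultsTable()]
#'
#' @param path CSV path.
#' @return data frame.
#' @export
readResultsTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize per-animal results as mean +/- SD per (region, metric)
#'
#' With a single animal the SD is reported as \code{NaN} (the convention
#' used throughout: an SD of a singleton is undefined).
#'
#' @param results data frame as in [writeResultsTable()].
#' @return data frame with columns region, metric, n, mean, sd.
#' @export
summarizeResultsTable <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  sp <- split(results, list(results$region, results$metric), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    s <- if (nrow(d) > 1L) stats::sd(d$value) else NaN
    data.frame(region = d$region[1L], metric = d$metric[1L], n = nrow(d),
               mean = mean(d$value), sd = s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$region), , drop = FALSE]
}
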