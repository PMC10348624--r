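#' Read a single-channel intensity image from TIFF
#'
#' Images are stored as 16-bit unsigned TIFF, the common microscope export
#' format. Values are returned on the raw integer scale (0..65535), not
#' rescaled to \[0, 1\].
#'
#' @param path Path to a single-channel TIFF file.
#' @return A numeric matrix of pixel intensities (rows = image rows).
#' @seealso [write_channel_image()], [ingest_label_map()]
#' @export
read_channel_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L)
      stopf("expected a single-channel image, got %d channels: %s", dim(m)[3], path)
    m <- m[, , 1L]
  }
  storage.mode(m) <- "double"
  m
}

#' Write a single-channel intensity image as 16-bit TIFF
#'
#' Values are rounded to integers and clipped to \[0, 65535\]; the fraction
#' of clipped pixels is returned invisibly and attached as an attribute so
#' saturation never passes silently.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param path Output file path.
#' @return Invisibly, the fraction of pixels clipped at either end.
#' @export
write_channel_image <- function(image, path) {
  stopifnot(is.matrix(image), is.numeric(image))
  v <- round(image)
  clipped <- mean(v < 0 | v > 65535)
  v[v < 0] <- 0
  v[v > 65535] <- 65535
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(structure(clipped, names = "clipped_fraction"))
}

#' Read an instance-segmentation label map from TIFF
#'
#' The interchange format for externally produced segmentations (e.g.
#' Cellpose ROIs exported as a label raster): a single-channel integer TIFF
#' where 0 is background and each positive integer labels one cell
#' instance. Non-integer or negative rasters are rejected.
#'
#' @param path Path to an integer-valued single-channel TIFF.
#' @param companion_shape Optional `c(height, width)`; the label map must
#'   match it (guards against mixing masks and images from different
#'   acquisitions).
#' @return An integer matrix of instance labels.
#' @export
ingest_label_map <- function(path, companion_shape = NULL) {
  if (!file.exists(path)) stopf("label map file not found: %s", path)
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE), error = function(e) {
    if (grepl("floating point", conditionMessage(e)))
      stopf("%s: raster is not integer-valued (floating-point TIFF)", path)
    stop(e)
  })
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stopf("label map must be single-channel: %s", path)
    m <- m[, , 1L]
  }
  as_label_map(m, companion_shape = companion_shape, context = path)
}

#' Validate an integer raster as a label map
#'
#' @param labels Matrix of instance labels (0 = background).
#' @param companion_shape Optional `c(height, width)` to check against.
#' @param context Label used in error messages.
#' @return The validated label map as an integer matrix.
#' @export
as_label_map <- function(labels, companion_shape = NULL, context = "label map") {
  stopifnot(is.matrix(labels))
  if (any(!is.finite(labels)) || any(labels != floor(labels)))
    stopf("%s: raster is not integer-valued (is this a float image?)", context)
  if (any(labels < 0))
    stopf("%s: negative labels are not allowed", context)
  if (!is.null(companion_shape) && !identical(dim(labels), as.integer(companion_shape)))
    stopf("%s: shape (%s) does not match companion images (%s)", context,
          paste(dim(labels), collapse = "x"), paste(companion_shape, collapse = "x"))
  storage.mode(labels) <- "integer"
  labels
}

#' Write a label map as 16-bit integer TIFF
#'
#' @param labels Integer label matrix (values must fit in 16 bits).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(labels, path) {
  labels <- as_label_map(labels)
  if (max(labels) > 65535L)
    stopf("label map has %d objects; 16-bit TIFF supports at most 65535", max(labels))
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
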