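#' Parameters for the baseline cell segmenter
#'
#' The study pipeline identifies cells with an external deep-learning
#' segmenter (Cellpose) and imports its ROIs; this package accepts any
#' such label map via [ingest_label_map()]. For self-contained synthetic
#' work it also ships this deterministic classical baseline: Gaussian
#' smoothing, global threshold (Otsu or mean + k*SD), connected
#' components, optional distance-transform watershed to split touching
#' cells, and a minimum-area filter.
#'
#' @param smoothing_sigma Gaussian pre-smoothing SD in pixels (0 = none).
#' @param threshold_method `"otsu"` or `"mean_plus_k_sd"`.
#' @param k Multiplier for `mean_plus_k_sd`.
#' @param min_cell_area Minimum object area in pixels (>= 1).
#' @param split_touching Split touching cells by watershed on the distance
#'   transform.
#' @param exclude_border Drop objects touching the image border (off by
#'   default; the emulated workflow keeps them).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "mean_plus_k_sd"),
                                k = 3,
                                min_cell_area = 9L,
                                split_touching = TRUE,
                                exclude_border = FALSE) {
  structure(list(
    smoothing_sigma = check_pos(smoothing_sigma, "smoothing_sigma", strict = FALSE),
    threshold_method = match.arg(threshold_method),
    k = check_pos(k, "k", strict = FALSE),
    min_cell_area = check_count(min_cell_area, "min_cell_area", min = 1L),
    split_touching = isTRUE(split_touching),
    exclude_border = isTRUE(exclude_border)
  ), class = "segmentation_params")
}

#' Canonically renumber a label map
#'
#' Objects are renumbered 1..K by the row-major position of their
#' centroids (row first, then column), so repeated runs and different
#' label sources produce bit-comparable downstream tables.
#'
#' @param labels Integer label matrix.
#' @return Relabeled integer matrix.
#' @export
canonical_relabel <- function(labels) {
  labels <- as_label_map(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ys <- (idx - 1L) %% nrow(labels) + 1L
  xs <- (idx - 1L) %/% nrow(labels) + 1L
  cy <- rowsum(as.numeric(ys), lab) / as.vector(table(lab))
  cx <- rowsum(as.numeric(xs), lab) / as.vector(table(lab))
  ord <- order(cy, cx)
  new_id <- integer(max(ids))
  new_id[ids[ord]] <- seq_along(ids)
  out <- labels
  out[idx] <- new_id[lab]
  out
}

#' Segment cells in a marker-channel image
#'
#' Deterministic for fixed inputs; the marker channel (not the IgG
#' channel) is segmented, and IgG is later measured inside the resulting
#' masks. A constant (all-background) image yields an empty label map,
#' not an error.
#'
#' @param marker_image Numeric matrix of marker-channel intensities.
#' @param params A [segmentation_params()].
#' @return An integer label map in canonical (centroid row-major) order.
#' @export
segment_baseline <- function(marker_image, params = segmentation_params()) {
  stopifnot(is.matrix(marker_image), inherits(params, "segmentation_params"))
  if (any(!is.finite(marker_image))) stopf("marker image contains non-finite values")
  img <- marker_image
  if (params$smoothing_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), params$smoothing_sigma))
  rng <- range(img)
  if (rng[1] == rng[2])
    return(matrix(0L, nrow(img), ncol(img)))
  thr <- switch(params$threshold_method,
    otsu = {
      scaled <- (img - rng[1]) / (rng[2] - rng[1])
      rng[1] + (rng[2] - rng[1]) * EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    },
    mean_plus_k_sd = mean(img) + params$k * stats::sd(img))
  mask <- img > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  if (params$split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  }
  storage.mode(lab) <- "integer"
  # minimum-area filter
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < params$min_cell_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (params$exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0L]
    if (length(border)) lab[lab %in% border] <- 0L
  }
  canonical_relabel(lab)
}

#' Match segmented objects to ground-truth cell centers
#'
#' A truth center is recovered if it falls inside exactly one object's
#' mask; recall and precision are computed from the center-in-object
#' containment relation (an object containing no center is a false
#' positive, a center in no object a false negative).
#'
#' @param labels Label map.
#' @param centers Data frame or matrix with columns `y`, `x`.
#' @return List with `recall`, `precision`, `n_objects`, `n_centers`, and
#'   the per-center object id (`0` = unmatched).
#' @export
match_to_truth <- function(labels, centers) {
  labels <- as_label_map(labels)
  centers <- as.data.frame(centers)
  ids <- sort(unique(labels[labels > 0L]))
  hit <- integer(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    y <- round(centers$y[i]); x <- round(centers$x[i])
    if (y >= 1 && y <= nrow(labels) && x >= 1 && x <= ncol(labels))
      hit[i] <- labels[y, x]
  }
  matched_objects <- unique(hit[hit > 0L])
  list(recall = if (nrow(centers)) mean(hit > 0L) else NA_real_,
       precision = if (length(ids)) length(matched_objects) / length(ids) else NA_real_,
       n_objects = length(ids), n_centers = nrow(centers),
       center_object = hit)
}
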