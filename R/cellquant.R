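#' Experiment-wide intensity threshold
#'
#' The minimum pixel-intensity threshold for a channel is set from the
#' pooled pixel population of *all* images of one experiment: with pooled
#' mean `mu` and standard deviation `sigma`, the default rule is
#' `T = mu + k * sigma` with `k = 8`. The underlying wording ("8 x SD of
#' the mean pixel intensity of all the images") admits a literal reading
#' `T = k * sigma`; both rules are supported and the choice is recorded in
#' the returned object. For near-zero fluorescence background the two
#' nearly coincide.
#'
#' Pooling is over pixels, not per-image means, so images of different
#' shapes may be mixed. Statistics are accumulated from per-image sums
#' (single pass), which keeps memory flat over large experiments.
#'
#' @param images List of numeric matrices: every image of the experiment
#'   for one channel.
#' @param channel Channel role label (e.g. `"marker"`, `"igg"`), recorded
#'   in the result.
#' @param k Threshold multiplier (default 8).
#' @param rule `"mu_plus_k_sd"` (default) or `"k_sd_only"`.
#' @return An object of class `experiment_threshold`: list with `channel`,
#'   `mu`, `sigma`, `k`, `rule`, `threshold`, `n_pixels`.
#' @export
compute_experiment_threshold <- function(images, channel = "channel", k = 8,
                                         rule = c("mu_plus_k_sd", "k_sd_only")) {
  rule <- match.arg(rule)
  if (!is.list(images) || length(images) == 0L)
    stopf("`images` must be a non-empty list of image matrices")
  k <- check_pos(k, "k", strict = FALSE)
  n <- 0; s1 <- 0; s2 <- 0
  for (img in images) {
    stopifnot(is.matrix(img), is.numeric(img))
    if (any(!is.finite(img))) stopf("image contains non-finite pixel values")
    n <- n + length(img)
    s1 <- s1 + sum(img)
    s2 <- s2 + sum(img^2)
  }
  mu <- s1 / n
  # sample SD of the pooled pixel population
  sigma <- if (n > 1) sqrt(max(0, (s2 - n * mu^2) / (n - 1))) else 0
  threshold <- switch(rule, mu_plus_k_sd = mu + k * sigma, k_sd_only = k * sigma)
  structure(list(channel = channel, mu = mu, sigma = sigma, k = k,
                 rule = rule, threshold = threshold, n_pixels = n),
            class = "experiment_threshold")
}

#' @export
print.experiment_threshold <- function(x, ...) {
  cat(sprintf("experiment threshold [%s]: T = %.3f (rule %s, mu = %.3f, sigma = %.3f, k = %g, %d px)\n",
              x$channel, x$threshold, x$rule, x$mu, x$sigma, x$k, x$n_pixels))
  invisible(x)
}

#' Per-cell suprathreshold area, integrated density, and positivity
#'
#' For every labeled object and every channel, counts the in-mask pixels
#' with intensity *strictly above* the channel's experiment threshold
#' (`area_above`), sums the raw intensities of those pixels
#' (`intden_above`, the ImageJ "integrated density" convention), and calls
#' the cell positive for the channel when `area_above >= min_area`. The
#' strict inequality makes a constant image yield zero positives under the
#' degenerate `sigma = 0` threshold.
#'
#' @param label_map Integer label map (same shape as the images).
#' @param images Named list of channel images, e.g.
#'   `list(marker =, igg =)`.
#' @param thresholds Named list of [compute_experiment_threshold()] results,
#'   one per channel in `images` (same names).
#' @param min_area Minimum suprathreshold pixel area for positivity
#'   (default 5, configurable; always echoed into the output attributes).
#' @param sample_id Sample label copied into every row.
#' @param image_index Optional field-of-view index copied into every row.
#' @return A data frame with one row per labeled cell: `sample_id`,
#'   `image_index`, `cell_id`, `n_pixels`, and per channel `c`:
#'   `area_above_<c>`, `intden_<c>`, `is_positive_<c>`. Attributes
#'   `min_area` and `thresholds` record the scoring configuration.
#' @export
measure_cells <- function(label_map, images, thresholds, min_area = 5L,
                          sample_id = "sample", image_index = NA_integer_) {
  label_map <- as_label_map(label_map)
  stopifnot(is.list(images), !is.null(names(images)))
  for (ch in names(images)) {
    if (is.null(thresholds[[ch]]))
      stopf("missing threshold for channel '%s'", ch)
    if (!inherits(thresholds[[ch]], "experiment_threshold"))
      stopf("thresholds[['%s']] must come from compute_experiment_threshold()", ch)
    if (!identical(dim(images[[ch]]), dim(label_map)))
      stopf("channel '%s' shape does not match the label map", ch)
  }
  min_area <- check_count(min_area, "min_area", min = 1L)
  idx <- which(label_map > 0L)
  lab <- label_map[idx]
  ids <- sort(unique(lab))
  out <- data.frame(sample_id = rep(sample_id, length(ids)),
                    image_index = rep(image_index, length(ids)),
                    cell_id = ids,
                    n_pixels = as.vector(table(factor(lab, levels = ids))))
  for (ch in names(images)) {
    thr <- thresholds[[ch]]$threshold
    v <- images[[ch]][idx]
    above <- v > thr
    f <- factor(lab, levels = ids)
    area <- as.vector(rowsum(as.numeric(above), f))
    intden <- as.vector(rowsum(v * above, f))
    out[[paste0("area_above_", ch)]] <- area
    out[[paste0("intden_", ch)]] <- intden
    out[[paste0("is_positive_", ch)]] <- area >= min_area
  }
  attr(out, "min_area") <- min_area
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-sample summary of IgG binding
#'
#' The anti-SGC (or anti-neuron) readout for one serum/plasma sample: the
#' percentage of marker-positive cells that are also IgG-positive, and the
#' mean IgG integrated density across *all* marker-positive cells
#' (IgG-negative cells contribute zero). A sample with no marker-positive
#' cell is flagged unevaluable (`evaluable = FALSE`, `NA` readouts) rather
#' than scored zero or dropped.
#'
#' @param measurements Data frame from [measure_cells()] (rows may span
#'   several fields of view of one sample); must contain
#'   `is_positive_marker`, `is_positive_igg`, `intden_igg`.
#' @return One-row data frame: `sample_id`, `n_cells_imaged`,
#'   `n_marker_pos`, `n_igg_pos`, `pct_igg_pos`, `mean_intden`,
#'   `evaluable`.
#' @export
summarize_sample <- function(measurements) {
  req <- c("sample_id", "is_positive_marker", "is_positive_igg", "intden_igg")
  if (!all(req %in% names(measurements)))
    stopf("measurements must contain columns: %s", paste(req, collapse = ", "))
  sid <- unique(measurements$sample_id)
  if (length(sid) > 1L)
    stopf("measurements span multiple samples (%s); summarize one sample at a time",
          paste(sid, collapse = ", "))
  if (length(sid) == 0L) sid <- NA_character_
  mpos <- measurements$is_positive_marker
  n_marker <- sum(mpos)
  n_igg <- sum(mpos & measurements$is_positive_igg)
  data.frame(
    sample_id = sid,
    n_cells_imaged = nrow(measurements),
    n_marker_pos = n_marker,
    n_igg_pos = n_igg,
    pct_igg_pos = if (n_marker > 0) 100 * n_igg / n_marker else NA_real_,
    mean_intden = if (n_marker > 0) mean(measurements$intden_igg[mpos]) else NA_real_,
    evaluable = n_marker > 0
  )
}

#' Summarize several samples at once
#'
#' @param measurements Data frame of [measure_cells()] rows spanning
#'   multiple samples.
#' @return Data frame with one [summarize_sample()] row per sample.
#' @export
summarize_samples <- function(measurements) {
  parts <- split(measurements, measurements$sample_id)
  out <- do.call(rbind, lapply(parts, summarize_sample))
  rownames(out) <- NULL
  out
}

#' Quantify one sample's images end to end
#'
#' Convenience wrapper: segments (or ingests) per-field label maps,
#' measures every cell against the experiment thresholds, and returns the
#' cell table.
#'
#' @param images List over fields of view, each `list(marker =, igg =)`.
#' @param thresholds Named list of per-channel experiment thresholds.
#' @param sample_id Sample label.
#' @param label_maps Optional list of externally produced label maps (one
#'   per field); when `NULL`, [segment_baseline()] runs on each marker
#'   image.
#' @param params [segmentation_params()] for the baseline segmenter.
#' @param min_area Positivity area rule, pixels.
#' @return Cell-measurement data frame over all fields of the sample.
#' @export
quantify_sample <- function(images, thresholds, sample_id = "sample",
                            label_maps = NULL,
                            params = segmentation_params(),
                            min_area = 5L) {
  cells <- lapply(seq_along(images), function(im) {
    lm <- if (is.null(label_maps)) segment_baseline(images[[im]]$marker, params)
          else as_label_map(label_maps[[im]], companion_shape = dim(images[[im]]$marker))
    m <- measure_cells(lm, images[[im]], thresholds, min_area = min_area,
                       sample_id = sample_id, image_index = im)
    m
  })
  out <- do.call(rbind, cells)
  # cell ids unique within the sample, not just within a field
  if (nrow(out)) out$cell_id <- seq_len(nrow(out))
  attr(out, "min_area") <- min_area
  attr(out, "thresholds") <- thresholds
  out
}
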