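#' Parameters for DRG tissue object classification
#'
#' @param k Background-threshold multiplier for the structural channels
#'   and the IgG background threshold (tissue default 2; the culture
#'   scoring uses 8).
#' @param soma_min_area Minimum pixel area for a neuronal soma.
#' @param circ_min Minimum circularity (`4*pi*A / P^2`) for a soma.
#' @param adjacency_radius Dilation radius (pixels) defining
#'   "perineuronal": a GFAP-positive object within this distance of a soma
#'   is a satellite glia cell.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(k = 2, soma_min_area = 200L, circ_min = 0.6,
                          adjacency_radius = 3L) {
  structure(list(
    k = check_pos(k, "k", strict = FALSE),
    soma_min_area = check_count(soma_min_area, "soma_min_area", min = 1L),
    circ_min = check_prob(circ_min, "circ_min"),
    adjacency_radius = check_count(adjacency_radius, "adjacency_radius", min = 1L)
  ), class = "tissue_params")
}

#' Background threshold for a tissue slide
#'
#' Same rule as the culture pipeline (`mu + k * sigma` over the slide's
#' pixel population) with a tissue default of `k = 2`; a deterministic,
#' self-consistent stand-in for the background threshold of the emulated
#' tissue-analysis pipeline, recorded in output metadata.
#'
#' @param image IgG-channel image of the slide.
#' @param k Multiplier.
#' @return An `experiment_threshold` object.
#' @export
tissue_background_threshold <- function(image, k = 2) {
  compute_experiment_threshold(list(image), channel = "igg", k = k)
}

#' Classify DRG tissue objects as SGC, soma, axon, or other
#'
#' Applies the rule-based class definitions: a neuronal *soma* is an
#' NF200-positive object with large area and roughly circular morphology;
#' an *axon* is NF200-positive but fails the soma test; a satellite glia
#' cell (*SGC*) is a GFAP-positive object adjacent to (within a dilation
#' radius of) a soma; everything else in the foreground is *other*. Every
#' object receives exactly one class.
#'
#' @param labels Instance label map of all foreground objects (from an
#'   external segmenter or the simulator's ground-truth map).
#' @param gfap,nf200 Structural channel images, co-registered with
#'   `labels`.
#' @param params A [tissue_params()].
#' @return Data frame: `object_id`, `class`, `pixel_count`, `circularity`,
#'   `mean_gfap`, `mean_nf200`. If no soma is found, the SGC class is
#'   empty and a warning is recorded in attribute `"warnings"` (and
#'   signalled).
#' @export
classify_tissue_objects <- function(labels, gfap, nf200, params = tissue_params()) {
  labels <- as_label_map(labels, companion_shape = dim(gfap))
  if (!identical(dim(nf200), dim(gfap))) stopf("gfap and nf200 shapes differ")
  ids <- sort(unique(labels[labels > 0L]))
  warn <- character(0)
  if (length(ids) == 0L) {
    out <- data.frame(object_id = integer(0), class = factor(character(0), levels = c("SGC", "soma", "axon", "other")),
                      pixel_count = integer(0), circularity = numeric(0),
                      mean_gfap = numeric(0), mean_nf200 = numeric(0))
    attr(out, "warnings") <- "no objects in label map"
    return(out)
  }
  # positivity thresholds for the structural channels: background rule on
  # each channel's whole-slide pixel population
  thr_gfap <- compute_experiment_threshold(list(gfap), "gfap", k = params$k)$threshold
  thr_nf200 <- compute_experiment_threshold(list(nf200), "nf200", k = params$k)$threshold

  idx <- which(labels > 0L)
  f <- factor(labels[idx], levels = ids)
  cnt <- as.vector(table(f))
  mean_gfap <- as.vector(rowsum(gfap[idx], f)) / cnt
  mean_nf200 <- as.vector(rowsum(nf200[idx], f)) / cnt

  # circularity 4*pi*A/P^2; perimeter from 4-neighbour boundary edge
  # counts with the pi/4 isotropy correction (exact for rasterized discs,
  # and robust for 1-px-thin tracts, unlike contour tracing)
  per <- perimeter_by_label(labels, ids)
  circ <- pmin(1, 4 * pi * cnt / pmax(per, 1)^2)

  gfap_pos <- mean_gfap > thr_gfap
  nf_pos <- mean_nf200 > thr_nf200
  is_soma <- nf_pos & cnt >= params$soma_min_area & circ >= params$circ_min
  is_axon <- nf_pos & !is_soma

  # adjacency: dilate the union soma mask and ask which objects touch it
  near_soma <- rep(FALSE, length(ids))
  if (any(is_soma)) {
    soma_mask <- matrix(0, nrow(labels), ncol(labels))
    soma_mask[labels %in% ids[is_soma]] <- 1
    kern <- EBImage::makeBrush(2L * params$adjacency_radius + 1L, shape = "disc")
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(soma_mask), kern)) > 0
    touching <- unique(labels[dil & labels > 0L])
    near_soma <- ids %in% touching
  } else {
    warn <- c(warn, "no soma found: SGC class is empty")
    warning("no soma found: SGC class is empty", call. = FALSE)
  }
  is_sgc <- gfap_pos & !is_soma & !is_axon & near_soma
  cls <- rep("other", length(ids))
  cls[is_axon] <- "axon"
  cls[is_soma] <- "soma"
  cls[is_sgc] <- "SGC"

  out <- data.frame(object_id = ids,
                    class = factor(cls, levels = c("SGC", "soma", "axon", "other")),
                    pixel_count = cnt, circularity = unname(circ),
                    mean_gfap = mean_gfap, mean_nf200 = mean_nf200)
  attr(out, "thresholds") <- c(gfap = thr_gfap, nf200 = thr_nf200)
  if (length(warn)) attr(out, "warnings") <- warn
  out
}

# boundary edge count per label (canvas edge counts as background),
# scaled by pi/4 so a rasterized disc of radius r scores ~2*pi*r
perimeter_by_label <- function(labels, ids = sort(unique(labels[labels > 0L]))) {
  h <- nrow(labels); w <- ncol(labels)
  edges <- numeric(max(ids))
  count_dir <- function(a, b) {
    # a, b: label matrices of adjacent pixels; edge where a > 0 and b != a
    d <- a > 0L & b != a
    t <- tabulate(a[d], nbins = max(ids))
    edges <<- edges + t
  }
  count_dir(labels[-1, , drop = FALSE], labels[-h, , drop = FALSE])
  count_dir(labels[-h, , drop = FALSE], labels[-1, , drop = FALSE])
  count_dir(labels[, -1, drop = FALSE], labels[, -w, drop = FALSE])
  count_dir(labels[, -w, drop = FALSE], labels[, -1, drop = FALSE])
  # canvas borders
  for (v in list(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
    edges <- edges + tabulate(v[v > 0L], nbins = max(ids))
  edges[ids] * pi / 4
}

#' Background-normalized IgG intensity of one object
#'
#' Mean in-mask IgG pixel intensity divided by the slide's background
#' threshold. The whole-object mean (not the suprathreshold-only mean) is
#' used; dividing by the threshold makes the readout unitless and
#' comparable across slides with different gain.
#'
#' @param object_mask Logical matrix (or 0/1) selecting the object's
#'   pixels.
#' @param igg_image IgG-channel image.
#' @param background_threshold Positive scalar (e.g. from
#'   [tissue_background_threshold()]).
#' @return Unitless normalized intensity.
#' @export
normalized_intensity <- function(object_mask, igg_image, background_threshold) {
  if (!is.numeric(background_threshold) || length(background_threshold) != 1L ||
      !is.finite(background_threshold) || background_threshold <= 0)
    stopf("`background_threshold` must be a single value > 0")
  stopifnot(identical(dim(object_mask), dim(igg_image)))
  mask <- object_mask > 0
  if (!any(mask)) stopf("object mask is empty")
  mean(igg_image[mask]) / background_threshold
}

#' Measure every classified object on a slide
#'
#' @param labels Instance label map.
#' @param classes Data frame from [classify_tissue_objects()].
#' @param igg_image IgG-channel image.
#' @param background_threshold Positive scalar background threshold for
#'   the slide.
#' @param slide_id,donor_id,serum_id Identifiers copied into every row.
#' @return Data frame of `TissueObjectMeasurement`s: `donor_id`,
#'   `serum_id`, `slide_id`, `object_id`, `object_class`, `pixel_count`,
#'   `norm_intensity`.
#' @export
measure_tissue_objects <- function(labels, classes, igg_image, background_threshold,
                                   slide_id = "slide", donor_id = "donor",
                                   serum_id = "serum") {
  labels <- as_label_map(labels, companion_shape = dim(igg_image))
  if (background_threshold <= 0) stopf("`background_threshold` must be > 0")
  idx <- which(labels > 0L)
  f <- factor(labels[idx], levels = classes$object_id)
  cnt <- as.vector(table(f))
  mean_igg <- as.vector(rowsum(igg_image[idx], f)) / cnt
  data.frame(donor_id = donor_id, serum_id = serum_id, slide_id = slide_id,
             object_id = classes$object_id,
             object_class = classes$class,
             pixel_count = cnt,
             norm_intensity = mean_igg / background_threshold)
}

#' Slide-weighted per-donor, per-serum summary
#'
#' For each donor x serum x object class, averages the per-slide mean
#' normalized intensities with *slides weighted equally* (a slide with ten
#' times more objects does not dominate), matching the emulated workflow's
#' averaging over 5 separate slides per donor. Classes absent from a slide
#' simply do not contribute a slide mean.
#'
#' @param objects Data frame of [measure_tissue_objects()] rows across
#'   slides (and possibly donors/sera).
#' @return Data frame: `donor_id`, `serum_id`, `object_class`,
#'   `mean_norm_intensity`, `n_slides`.
#' @export
summarize_donor <- function(objects) {
  req <- c("donor_id", "serum_id", "slide_id", "object_class", "norm_intensity")
  if (!all(req %in% names(objects)))
    stopf("objects must contain columns: %s", paste(req, collapse = ", "))
  if (nrow(objects) == 0L) stopf("no tissue objects to summarize (donor with zero slides?)")
  slide_means <- stats::aggregate(norm_intensity ~ donor_id + serum_id + slide_id + object_class,
                                  data = objects, FUN = mean)
  out <- stats::aggregate(norm_intensity ~ donor_id + serum_id + object_class,
                          data = slide_means, FUN = mean)
  names(out)[names(out) == "norm_intensity"] <- "mean_norm_intensity"
  nsl <- stats::aggregate(slide_id ~ donor_id + serum_id + object_class,
                          data = slide_means, FUN = function(s) length(unique(s)))
  names(nsl)[names(nsl) == "slide_id"] <- "n_slides"
  merge(out, nsl, by = c("donor_id", "serum_id", "object_class"), sort = TRUE)
}
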