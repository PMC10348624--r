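#' Configuration for synthetic SGC/neuron culture samples
#'
#' Describes one serum or plasma sample's imaging session: a set of
#' two-channel fields of view (marker channel -- glutamine synthase for SGC
#' cultures or PGP 9.5 for neuron cultures -- plus a human-IgG channel)
#' containing randomly placed cultured cells. Defaults emulate the study
#' conditions the pipeline targets: on the order of 73 cells imaged per
#' sample of which roughly 80--85\% are marker-positive, with a
#' sample-specific fraction of the marker-positive cells bound by serum
#' IgG.
#'
#' @param image_shape `c(height, width)` in pixels; at least 64 x 64.
#' @param n_images Number of fields of view for the sample.
#' @param cells_per_image Mean number of cells per field (Poisson draw per
#'   field, so a 5-field sample at the default ~15 cells/field images ~73
#'   cells).
#' @param marker_pos_frac Probability that a cell is marker-positive.
#' @param igg_pos_frac Probability that a *marker-positive* cell is bound
#'   by human IgG.
#' @param cell_radius `(mean, sd)` cell radius in pixels.
#' @param marker_intensity `(mean, sd)` peak amplitude (arbitrary units, on
#'   the 16-bit scale) of the marker signal in positive cells.
#' @param igg_intensity `(mean, sd)` peak amplitude of the IgG signal in
#'   bound cells.
#' @param background_level Constant background offset (arbitrary units).
#' @param noise List with `gaussian_sd` (additive read-noise SD) and
#'   `poisson` (logical; add shot noise on the signal).
#' @param psf_sigma Gaussian point-spread-function SD in pixels.
#' @param nonspecific_marker_frac Peak amplitude of residual marker signal
#'   in marker-negative cells, as a fraction of the marker mean (keeps
#'   negative cells faintly visible, as in real cultures).
#' @param min_center_factor Dart-throwing placement: minimum center-to-center
#'   distance as a multiple of the mean radius.
#' @param max_attempts Placement attempts per cell before the sample is
#'   reported as unplaceable.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   images and truth.
#' @return An object of class `culture_sim_config`.
#' @seealso [simulate_culture_sample()]
#' @export
culture_sim_config <- function(image_shape = c(256L, 256L),
                               n_images = 5L,
                               cells_per_image = 15,
                               marker_pos_frac = 0.82,
                               igg_pos_frac = 0.35,
                               cell_radius = c(mean = 4, sd = 0.5),
                               marker_intensity = c(mean = 14000, sd = 1500),
                               igg_intensity = c(mean = 12000, sd = 1400),
                               background_level = 800,
                               noise = list(gaussian_sd = 120, poisson = FALSE),
                               psf_sigma = 1,
                               nonspecific_marker_frac = 0.04,
                               min_center_factor = 2.5,
                               max_attempts = 1000L,
                               seed = 1L) {
  if (!is.numeric(image_shape) || length(image_shape) != 2L || any(image_shape < 64))
    stopf("`image_shape` must be c(height, width) with both >= 64")
  cfg <- list(
    image_shape = as.integer(image_shape),
    n_images = check_count(n_images, "n_images", min = 1L),
    cells_per_image = check_pos(cells_per_image, "cells_per_image"),
    marker_pos_frac = check_prob(marker_pos_frac, "marker_pos_frac"),
    igg_pos_frac = check_prob(igg_pos_frac, "igg_pos_frac"),
    cell_radius = check_mean_sd(cell_radius, "cell_radius"),
    marker_intensity = check_mean_sd(marker_intensity, "marker_intensity"),
    igg_intensity = check_mean_sd(igg_intensity, "igg_intensity"),
    background_level = check_pos(background_level, "background_level", strict = FALSE),
    noise = list(gaussian_sd = check_pos(noise$gaussian_sd %||% 0, "noise$gaussian_sd", strict = FALSE),
                 poisson = isTRUE(noise$poisson)),
    psf_sigma = check_pos(psf_sigma, "psf_sigma", strict = FALSE),
    nonspecific_marker_frac = check_prob(nonspecific_marker_frac, "nonspecific_marker_frac"),
    min_center_factor = check_pos(min_center_factor, "min_center_factor"),
    max_attempts = check_count(max_attempts, "max_attempts", min = 1L),
    seed = check_count(seed, "seed")
  )
  structure(cfg, class = "culture_sim_config")
}

# dart-throwing placement with a minimum center distance; errors (never
# silently drops cells) when the canvas cannot host the requested count
place_centers <- function(n, shape, min_dist, margin, max_attempts) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("y", "x"))))
  ys <- numeric(n); xs <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      y <- stats::runif(1, 1 + margin, shape[1] - margin)
      x <- stats::runif(1, 1 + margin, shape[2] - margin)
      if (i == 1L || all((ys[seq_len(i - 1L)] - y)^2 + (xs[seq_len(i - 1L)] - x)^2 >= min_dist^2)) {
        ys[i] <- y; xs[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed)
      stopf(paste0("cell placement failed: could not place cell %d of %d on a %dx%d canvas ",
                   "(min center distance %.1f px, %d attempts); reduce cell count or density"),
            i, n, shape[1], shape[2], min_dist, max_attempts)
  }
  cbind(y = ys, x = xs)
}

# add one PSF-blurred Gaussian radial profile, truncated at 3*radius.
# sigma_eff folds the PSF into the cell profile (convolution of Gaussians).
render_spot <- function(img, cy, cx, radius, amplitude, psf_sigma) {
  sigma <- sqrt((radius / 2)^2 + psf_sigma^2)
  tr <- 3 * radius
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, floor(cy - tr)); r1 <- min(h, ceiling(cy + tr))
  c0 <- max(1L, floor(cx - tr)); c1 <- min(w, ceiling(cx + tr))
  yy <- r0:r1; xx <- c0:c1
  d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
  prof <- amplitude * exp(-d2 / (2 * sigma^2))
  prof[d2 > tr^2] <- 0
  img[yy, xx] <- img[yy, xx] + prof
  img
}

add_noise <- function(img, noise) {
  if (isTRUE(noise$poisson)) {
    pos <- img > 0
    img[pos] <- stats::rpois(sum(pos), lambda = img[pos])
  }
  if (noise$gaussian_sd > 0)
    img <- img + stats::rnorm(length(img), 0, noise$gaussian_sd)
  img[img < 0] <- 0
  img
}

#' Simulate one culture sample: two-channel images plus ground truth
#'
#' Renders each field of view as PSF-blurred Gaussian cell profiles on a
#' noisy background. The marker channel carries signal for marker-positive
#' cells (marker-negative cells get only a faint nonspecific residual);
#' the IgG channel carries signal only for the IgG-bound subset of
#' marker-positive cells. The returned truth table describes exactly what
#' was rendered.
#'
#' @param config A [culture_sim_config()].
#' @return A list with elements:
#' \describe{
#'   \item{images}{List of length `n_images`; each element is
#'     `list(marker =, igg =)` numeric matrices.}
#'   \item{truth}{Data frame with one row per rendered cell: `cell_id`,
#'     `image_index`, `y`, `x`, `radius`, `is_marker_pos`, `is_igg_pos`,
#'     `true_marker_amplitude`, `true_igg_amplitude`.}
#' }
#' @export
simulate_culture_sample <- function(config) {
  stopifnot(inherits(config, "culture_sim_config"))
  with_seed(config$seed, {
    images <- vector("list", config$n_images)
    truth <- vector("list", config$n_images)
    next_id <- 1L
    for (im in seq_len(config$n_images)) {
      n_cells <- stats::rpois(1L, config$cells_per_image)
      min_dist <- config$min_center_factor * config$cell_radius["mean"]
      centers <- place_centers(n_cells, config$image_shape, min_dist,
                               margin = config$cell_radius["mean"],
                               max_attempts = config$max_attempts)
      radius <- pmax(1, stats::rnorm(n_cells, config$cell_radius["mean"], config$cell_radius["sd"]))
      is_marker <- stats::runif(n_cells) < config$marker_pos_frac
      is_igg <- is_marker & (stats::runif(n_cells) < config$igg_pos_frac)
      # truncated-normal amplitudes: bright-cell variability without a
      # dim tail that would make positivity calls threshold-marginal
      amp_marker <- ifelse(is_marker,
                           pmax(0, rnorm_trunc(n_cells, config$marker_intensity["mean"],
                                               config$marker_intensity["sd"])),
                           config$nonspecific_marker_frac * config$marker_intensity["mean"])
      amp_igg <- ifelse(is_igg,
                        pmax(0, rnorm_trunc(n_cells, config$igg_intensity["mean"],
                                            config$igg_intensity["sd"])),
                        0)
      marker_img <- matrix(config$background_level, config$image_shape[1], config$image_shape[2])
      igg_img <- matrix(config$background_level, config$image_shape[1], config$image_shape[2])
      for (i in seq_len(n_cells)) {
        marker_img <- render_spot(marker_img, centers[i, "y"], centers[i, "x"],
                                  radius[i], amp_marker[i], config$psf_sigma)
        if (amp_igg[i] > 0)
          igg_img <- render_spot(igg_img, centers[i, "y"], centers[i, "x"],
                                 radius[i], amp_igg[i], config$psf_sigma)
      }
      images[[im]] <- list(marker = add_noise(marker_img, config$noise),
                           igg = add_noise(igg_img, config$noise))
      truth[[im]] <- data.frame(
        cell_id = if (n_cells > 0) seq.int(next_id, next_id + n_cells - 1L) else integer(0),
        image_index = rep(im, n_cells),
        y = unname(centers[, "y"]), x = unname(centers[, "x"]),
        radius = radius,
        is_marker_pos = is_marker,
        is_igg_pos = is_igg,
        true_marker_amplitude = amp_marker,
        true_igg_amplitude = amp_igg
      )
      next_id <- next_id + n_cells
    }
    list(images = images, truth = do.call(rbind, truth), config = config)
  })
}

#' Write a simulated culture sample to disk
#'
#' One 16-bit TIFF per channel per field, named
#' `{sample}_{image:03d}_{channel}.tif`, plus `{sample}_truth.csv`.
#'
#' @param sim Result of [simulate_culture_sample()].
#' @param dir Output directory (created if needed).
#' @param sample_id Sample label used in filenames.
#' @return Invisibly, a data frame of written image paths with the maximum
#'   clipped-pixel fraction as attribute `"clipped_fraction"`.
#' @export
write_culture_sample <- function(sim, dir, sample_id = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); clipped <- 0
  for (im in seq_along(sim$images)) {
    for (ch in names(sim$images[[im]])) {
      path <- file.path(dir, sprintf("%s_%03d_%s.tif", sample_id, im, ch))
      cl <- write_channel_image(sim$images[[im]][[ch]], path)
      clipped <- max(clipped, cl)
      rows[[length(rows) + 1L]] <- data.frame(sample_id = sample_id, image_index = im,
                                              channel = ch, path = path)
    }
  }
  utils::write.csv(sim$truth, file.path(dir, sprintf("%s_truth.csv", sample_id)),
                   row.names = FALSE)
  invisible(structure(do.call(rbind, rows), clipped_fraction = clipped))
}
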