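#' Configuration for synthetic DRG tissue sections
#'
#' A section contains large round neuronal soma (NF200 channel), a
#' perineuronal glia ring around a configurable fraction of soma (GFAP
#' channel; these are the satellite glia cells), curvilinear axons (NF200),
#' and GFAP-/NF200- "other" blobs (macrophages, fibroblasts, matrix). The
#' human-IgG channel draws each object's intensity from a per-class
#' distribution, which is how a serum's class-specific binding is injected.
#'
#' @param image_shape `c(height, width)` pixels.
#' @param n_soma Number of neuronal soma.
#' @param ring_fraction Fraction of soma wearing a perineuronal glia ring.
#' @param n_axons Number of axon tracts.
#' @param n_other Number of non-neuronal, non-glial blobs.
#' @param soma_radius `(mean, sd)` soma radius, pixels.
#' @param ring_thickness Glia ring thickness, pixels; must be < soma radius.
#' @param axon_width Half-width of axon tracts, pixels.
#' @param other_radius `(mean, sd)` radius of "other" blobs, pixels.
#' @param gfap_intensity,nf200_intensity Peak structural-channel amplitudes.
#' @param igg_intensity_by_class Named list `SGC`, `soma`, `axon`, `other`
#'   of `(mean, sd)` IgG amplitudes per object class.
#' @param background_level,noise,psf_sigma,seed As in [culture_sim_config()].
#' @return An object of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(image_shape = c(256L, 256L),
                              n_soma = 6L,
                              ring_fraction = 1,
                              n_axons = 4L,
                              n_other = 6L,
                              soma_radius = c(mean = 16, sd = 2),
                              ring_thickness = 4,
                              axon_width = 2,
                              other_radius = c(mean = 5, sd = 1),
                              gfap_intensity = 12000,
                              nf200_intensity = 12000,
                              igg_intensity_by_class = list(
                                SGC = c(mean = 3000, sd = 400),
                                soma = c(mean = 1400, sd = 300),
                                axon = c(mean = 1400, sd = 300),
                                other = c(mean = 1200, sd = 300)),
                              background_level = 600,
                              noise = list(gaussian_sd = 100, poisson = FALSE),
                              psf_sigma = 1,
                              seed = 1L) {
  if (!is.numeric(image_shape) || length(image_shape) != 2L || any(image_shape < 64))
    stopf("`image_shape` must be c(height, width) with both >= 64")
  stopifnot(setequal(names(igg_intensity_by_class), c("SGC", "soma", "axon", "other")))
  igg <- lapply(igg_intensity_by_class, function(x) {
    x <- unname(x)
    if (x[1] < 0 || x[2] < 0) stopf("igg_intensity_by_class means and sds must be >= 0")
    c(mean = x[1], sd = x[2])
  })
  sr <- check_mean_sd(soma_radius, "soma_radius")
  if (ring_thickness <= 0 || ring_thickness >= sr["mean"])
    stopf("`ring_thickness` must satisfy 0 < ring_thickness < mean soma radius")
  structure(list(
    image_shape = as.integer(image_shape),
    n_soma = check_count(n_soma, "n_soma"),
    ring_fraction = check_prob(ring_fraction, "ring_fraction"),
    n_axons = check_count(n_axons, "n_axons"),
    n_other = check_count(n_other, "n_other"),
    soma_radius = sr,
    ring_thickness = check_pos(ring_thickness, "ring_thickness"),
    axon_width = check_pos(axon_width, "axon_width"),
    other_radius = check_mean_sd(other_radius, "other_radius"),
    gfap_intensity = check_pos(gfap_intensity, "gfap_intensity"),
    nf200_intensity = check_pos(nf200_intensity, "nf200_intensity"),
    igg_intensity_by_class = igg,
    background_level = check_pos(background_level, "background_level", strict = FALSE),
    noise = list(gaussian_sd = check_pos(noise$gaussian_sd %||% 0, "noise$gaussian_sd", strict = FALSE),
                 poisson = isTRUE(noise$poisson)),
    psf_sigma = check_pos(psf_sigma, "psf_sigma", strict = FALSE),
    seed = check_count(seed, "seed")
  ), class = "tissue_sim_config")
}

# paint `value` into `target[mask_idx]` only where labels are still 0,
# assigning `id` there; returns updated (labels, idx actually painted)
claim_pixels <- function(labels, idx, id) {
  idx <- idx[labels[idx] == 0L]
  labels[idx] <- id
  list(labels = labels, idx = idx)
}

disc_idx <- function(shape, cy, cx, r_in, r_out) {
  tr <- ceiling(r_out)
  yy <- max(1L, floor(cy - tr)):min(shape[1], ceiling(cy + tr))
  xx <- max(1L, floor(cx - tr)):min(shape[2], ceiling(cx + tr))
  d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
  keep <- which(d2 <= r_out^2 & d2 >= r_in^2, arr.ind = TRUE)
  (xx[keep[, 2]] - 1L) * shape[1] + yy[keep[, 1]]
}

# a gently curving tract rasterized with a given half-width; low angular
# diffusion keeps tracts elongated (never compact blobs), and short walks
# that exit the canvas early are redrawn
axon_idx <- function(shape, width, steps = 200L, min_steps = 80L, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    y <- stats::runif(1, shape[1] * 0.15, shape[1] * 0.85)
    x <- stats::runif(1, shape[2] * 0.15, shape[2] * 0.85)
    theta <- stats::runif(1, 0, 2 * pi)
    idx <- integer(0)
    taken <- 0L
    for (s in seq_len(steps)) {
      theta <- theta + stats::rnorm(1, 0, 0.04)
      y <- y + sin(theta); x <- x + cos(theta)
      if (y < 2 || y > shape[1] - 1 || x < 2 || x > shape[2] - 1) break
      idx <- c(idx, disc_idx(shape, y, x, 0, width))
      taken <- s
    }
    if (taken >= min_steps) return(unique(idx))
  }
  unique(idx)
}

#' Simulate a DRG tissue section with per-object ground truth
#'
#' @param config A [tissue_sim_config()].
#' @return A list with:
#' \describe{
#'   \item{images}{`list(gfap =, nf200 =, igg =)` numeric matrices.}
#'   \item{labels}{Integer instance label map covering every object.}
#'   \item{truth}{Data frame: `object_id`, `class` (`SGC`, `soma`, `axon`,
#'     `other`), `pixel_count`, `true_igg_amplitude`, and for soma/SGC the
#'     id of the partner object (`partner_id`).}
#' }
#' @export
simulate_tissue_section <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  with_seed(config$seed, {
    shape <- config$image_shape
    gfap <- matrix(config$background_level, shape[1], shape[2])
    nf200 <- matrix(config$background_level, shape[1], shape[2])
    igg <- matrix(config$background_level, shape[1], shape[2])
    labels <- matrix(0L, shape[1], shape[2])

    soma_r <- pmax(4, stats::rnorm(config$n_soma, config$soma_radius["mean"],
                                   config$soma_radius["sd"]))
    margin <- max(c(soma_r, 4)) + config$ring_thickness + 2
    if (config$n_soma > 0L && 2 * margin >= min(shape))
      stopf("geometric infeasibility: soma radius %.1f px does not fit a %dx%d canvas",
            max(soma_r), shape[1], shape[2])
    centers <- tryCatch(
      place_centers(config$n_soma, shape,
                    min_dist = 2 * (config$soma_radius["mean"] + config$ring_thickness) + 4,
                    margin = margin, max_attempts = 2000L),
      error = function(e) stopf("geometric infeasibility: %s", conditionMessage(e)))

    truth <- list(); next_id <- 1L
    has_ring <- stats::runif(config$n_soma) < config$ring_fraction
    amp <- function(cls) max(0, stats::rnorm(1, config$igg_intensity_by_class[[cls]]["mean"],
                                             config$igg_intensity_by_class[[cls]]["sd"]))
    add_object <- function(idx, cls, channel_vals, igg_amp, partner = NA_integer_) {
      cl <- claim_pixels(labels, idx, next_id)
      labels <<- cl$labels
      for (ch in names(channel_vals)) {
        img <- get(ch, inherits = TRUE)
        img[cl$idx] <- img[cl$idx] + channel_vals[[ch]]
        assign(ch, img, inherits = TRUE)
      }
      igg[cl$idx] <<- igg[cl$idx] + igg_amp
      truth[[length(truth) + 1L]] <<- data.frame(
        object_id = next_id, class = cls, pixel_count = length(cl$idx),
        true_igg_amplitude = igg_amp, partner_id = partner)
      next_id <<- next_id + 1L
    }

    for (i in seq_len(config$n_soma)) {
      soma_id <- next_id
      add_object(disc_idx(shape, centers[i, 1], centers[i, 2], 0, soma_r[i]),
                 "soma", list(nf200 = config$nf200_intensity), amp("soma"))
      if (has_ring[i]) {
        # perineuronal glia ring: annulus hugging the soma boundary
        add_object(disc_idx(shape, centers[i, 1], centers[i, 2],
                            soma_r[i] + 0.5, soma_r[i] + 0.5 + config$ring_thickness),
                   "SGC", list(gfap = config$gfap_intensity), amp("SGC"),
                   partner = soma_id)
      }
    }
    for (i in seq_len(config$n_axons)) {
      # keep tracts with enough unclaimed length to stay recognisably
      # elongated after soma/ring pixels are excluded
      idx <- axon_idx(shape, config$axon_width)
      for (try in seq_len(20L)) {
        if (sum(labels[idx] == 0L) >= 150L) break
        idx <- axon_idx(shape, config$axon_width)
      }
      add_object(idx, "axon", list(nf200 = config$nf200_intensity), amp("axon"))
    }
    for (i in seq_len(config$n_other)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        r <- max(2, stats::rnorm(1, config$other_radius["mean"], config$other_radius["sd"]))
        cy <- stats::runif(1, r + 1, shape[1] - r)
        cx <- stats::runif(1, r + 1, shape[2] - r)
        idx <- disc_idx(shape, cy, cx, 0, r)
        # require clear space (2 px margin) so blobs never abut glia rings
        if (all(labels[disc_idx(shape, cy, cx, 0, r + 2)] == 0L)) {
          add_object(idx, "other", list(), amp("other"))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("geometric infeasibility: no free space for non-neuronal blob %d", i)
    }

    # PSF blur then noise, per channel; labels stay crisp (they are the
    # segmentation ground truth, not an optical image)
    blur <- function(img) {
      if (config$psf_sigma > 0)
        img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), config$psf_sigma))
      add_noise(img, config$noise)
    }
    truth <- do.call(rbind, truth)
    truth$class <- factor(truth$class, levels = c("SGC", "soma", "axon", "other"))
    # an object fully occluded during placement is not rendered content
    truth <- truth[truth$pixel_count > 0L, , drop = FALSE]
    list(images = list(gfap = blur(gfap), nf200 = blur(nf200), igg = blur(igg)),
         labels = labels, truth = truth, config = config)
  })
}
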