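# Independent oracles and hand-built fixtures. Nothing here calls the
# package's internal rendering or measurement paths: rendering uses a
# plain closed-form Gaussian sum, measurement a naive per-cell pixel loop,
# pooled statistics a two-pass computation over the concatenated vector.

# two-pass pooled mean / sample SD over raw pixel vectors
pooled_stats_oracle <- function(images) {
  v <- unlist(lapply(images, as.vector))
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / (length(v) - 1))
  list(mu = mu, sigma = sigma, n = length(v))
}

# naive double loop: per-cell suprathreshold area and integrated density
naive_measure_oracle <- function(label_map, image, threshold) {
  ids <- sort(unique(label_map[label_map > 0]))
  area <- intden <- numeric(length(ids))
  for (k in seq_along(ids)) {
    for (i in seq_len(nrow(label_map))) for (j in seq_len(ncol(label_map))) {
      if (label_map[i, j] == ids[k] && image[i, j] > threshold) {
        area[k] <- area[k] + 1
        intden[k] <- intden[k] + image[i, j]
      }
    }
  }
  data.frame(cell_id = ids, area_above = area, intden_above = intden)
}

# closed-form rendering of Gaussian cells, independent of the package
draw_cells_image <- function(shape, centers, radius = 4, amplitude = 14000,
                             background = 800, psf_sigma = 1) {
  img <- matrix(background, shape[1], shape[2])
  sigma <- sqrt((radius / 2)^2 + psf_sigma^2)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(shape[1]) - centers[i, 1])^2,
                (seq_len(shape[2]) - centers[i, 2])^2, `+`)
    a <- if (length(amplitude) > 1) amplitude[i] else amplitude
    img <- img + ifelse(d2 <= (3 * radius)^2, a * exp(-d2 / (2 * sigma^2)), 0)
  }
  img
}

# random blob label map + intensity image for oracle-equivalence checks
random_measure_fixture <- function(seed, shape = c(48L, 48L), n_cells = 5L) {
  set.seed(seed)
  labels <- matrix(0L, shape[1], shape[2])
  for (k in seq_len(n_cells)) {
    cy <- sample(5:(shape[1] - 5), 1); cx <- sample(5:(shape[2] - 5), 1)
    r <- runif(1, 2, 4)
    d2 <- outer((seq_len(shape[1]) - cy)^2, (seq_len(shape[2]) - cx)^2, `+`)
    labels[d2 <= r^2 & labels == 0L] <- k
  }
  image <- matrix(runif(prod(shape), 0, 2000), shape[1], shape[2])
  list(labels = labels, image = image)
}

# a threshold object with a known value T: constant images give mu = T,
# sigma = 0, so the mu + k*sigma rule returns exactly T
constant_threshold <- function(T, channel = "igg") {
  compute_experiment_threshold(list(matrix(T, 4L, 4L)), channel = channel)
}

# minimal single-strip little-endian TIFF with 32-bit IEEE float samples
# (the tiff package cannot write one; needed to exercise float rejection)
write_float_tiff <- function(values, path) {
  stopifnot(is.matrix(values))
  h <- nrow(values); w <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  n_bytes <- 4L * h * w
  ifd_offset <- data_offset + n_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  entries <- list(
    c(256L, 3L, 1L, w),            # ImageWidth
    c(257L, 3L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, 32L),          # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression: none
    c(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_offset),  # StripOffsets
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 3L, 1L, h),            # RowsPerStrip
    c(279L, 4L, 1L, n_bytes),      # StripByteCounts
    c(339L, 3L, 1L, 3L))           # SampleFormat: IEEE float
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L) {
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

# measurement-level qualitative-pattern check for one simulated cohort
# replicate; returns named logicals for each element of the study pattern
pattern_check <- function(seed_triplet, cohort_config = cohort_sim_config(),
                          cells_per_subject = 200) {
  co <- simulate_cohort(modifyList_config(cohort_config, seed = seed_triplet[1]))
  ss <- simulate_sample_summaries(co, cells_per_subject = cells_per_subject,
                                  seed = seed_triplet[2])
  nn <- simulate_sample_summaries(co, cells_per_subject = cells_per_subject,
                                  binding = "neuron", seed = seed_triplet[3])
  j <- merge(as.data.frame(co), ss, by.x = "subject_id", by.y = "sample_id")
  fm <- j[j$group == "FM", ]
  fm_gt_hc <- suppressWarnings(stats::wilcox.test(pct_igg_pos ~ group, j)$p.value) < 0.05 &&
    stats::median(j$pct_igg_pos[j$group == "FM"]) > stats::median(j$pct_igg_pos[j$group == "HC"])
  r1 <- suppressWarnings(stats::cor.test(fm$pct_igg_pos, fm$vas_avg,
                                         method = "spearman", exact = FALSE)$estimate)
  r2 <- suppressWarnings(stats::cor.test(fm$pct_igg_pos, fm$vas_max,
                                         method = "spearman", exact = FALSE)$estimate)
  cl <- cluster_severity(fm, seed = 1)
  grp3 <- factor(ifelse(j$group == "HC", "HC",
                        as.character(cl$assignments[match(j$subject_id, fm$subject_id)])),
                 levels = c("HC", "FM-mild", "FM-severe"))
  cg <- compare_groups(j$pct_igg_pos, grp3, "proportion_like")
  ph <- cg$posthoc
  rownames(ph) <- ph$comparison
  jn <- merge(as.data.frame(co), nn, by.x = "subject_id", by.y = "sample_id")
  c(fm_gt_hc = fm_gt_hc,
    rho_positive = unname(r1 > 0 && r2 > 0),
    severe_gt_mild = ph["FM-mild-FM-severe", "p_value"] < 0.05 &&
      mean(j$pct_igg_pos[grp3 == "FM-severe"]) > mean(j$pct_igg_pos[grp3 == "FM-mild"]),
    severe_gt_hc = ph["HC-FM-severe", "p_value"] < 0.05,
    mild_eq_hc = ph["HC-FM-mild", "p_value"] >= 0.05,
    neuron_null = suppressWarnings(stats::wilcox.test(pct_igg_pos ~ group, jn)$p.value) >= 0.05)
}

# rebuild a config list with one field changed, keeping its class
modifyList_config <- function(config, ...) {
  cls <- class(config)
  out <- utils::modifyList(unclass(config), list(...))
  class(out) <- cls
  out
}
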