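test_that("a constant pixel pool gives sigma 0 and zero suprathreshold pixels", {
  th <- compute_experiment_threshold(list(matrix(42, 10, 10), matrix(42, 5, 5)))
  expect_equal(th$sigma, 0)
  expect_equal(th$threshold, 42)
  # strictly-greater rule: nothing in a constant image is above threshold
  labels <- matrix(1L, 10, 10)
  m <- measure_cells(labels, list(igg = matrix(42, 10, 10)), list(igg = th))
  expect_equal(m$area_above_igg, 0)
  expect_equal(m$intden_igg, 0)
  expect_false(any(m$is_positive_igg))
})

test_that("pooled mean/SD match a two-pass brute-force oracle", {
  # the constructed pool: 999,000 zeros and 1,000 pixels at 1000
  images <- list(matrix(0, 999, 1000), matrix(1000, 10, 100))
  th <- compute_experiment_threshold(images, k = 8)
  oracle <- pooled_stats_oracle(images)
  expect_equal(th$mu, 1.0)
  expect_equal(th$mu, oracle$mu)
  expect_equal(th$sigma, oracle$sigma)
  expect_equal(th$threshold, oracle$mu + 8 * oracle$sigma)
  expect_equal(th$n_pixels, oracle$n)
  # random pools, both rules
  set.seed(3)
  imgs <- replicate(4, matrix(runif(300, 0, 4000), 15, 20), simplify = FALSE)
  o <- pooled_stats_oracle(imgs)
  expect_equal(compute_experiment_threshold(imgs)$threshold, o$mu + 8 * o$sigma)
  expect_equal(compute_experiment_threshold(imgs, rule = "k_sd_only")$threshold, 8 * o$sigma)
})

test_that("the threshold transforms exactly under affine intensity maps", {
  set.seed(4)
  imgs <- replicate(3, matrix(runif(400, 0, 3000), 20, 20), simplify = FALSE)
  th <- compute_experiment_threshold(imgs)
  a <- 1.7; b <- 250
  th2 <- compute_experiment_threshold(lapply(imgs, function(m) a * m + b))
  expect_equal(th2$threshold, a * th$threshold + b)
})

test_that("a hand-built cell reproduces the arithmetic of the positivity rule", {
  T0 <- 100
  th <- constant_threshold(T0)
  img <- matrix(0, 8, 8)
  img[1, 1:5] <- T0 + 10
  labels <- matrix(1L, 8, 8)
  m5 <- measure_cells(labels, list(igg = img), list(igg = th), min_area = 5L)
  expect_equal(m5$area_above_igg, 5)
  expect_equal(m5$intden_igg, 5 * (T0 + 10))
  expect_true(m5$is_positive_igg)
  m6 <- measure_cells(labels, list(igg = img), list(igg = th), min_area = 6L)
  expect_false(m6$is_positive_igg)
})

test_that("measurements equal the naive pixel-loop oracle on random fixtures", {
  th <- constant_threshold(1000)
  for (s in 1:6) {
    fx <- random_measure_fixture(s)
    m <- measure_cells(fx$labels, list(igg = fx$image), list(igg = th), min_area = 3L)
    o <- naive_measure_oracle(fx$labels, fx$image, 1000)
    expect_equal(m$cell_id, o$cell_id)
    expect_equal(m$area_above_igg, o$area_above)
    expect_equal(m$intden_igg, o$intden_above)
    expect_equal(m$is_positive_igg, o$area_above >= 3)
  }
})

test_that("missing channels are reported by name", {
  th <- constant_threshold(10)
  expect_error(measure_cells(matrix(1L, 4, 4), list(igg = matrix(0, 4, 4)),
                             list(marker = th)),
               "missing threshold for channel 'igg'")
})

test_that("sample summaries follow the percentage and averaging conventions", {
  mk <- function(n, marker, igg, intden) {
    data.frame(sample_id = "s", cell_id = seq_len(n),
               is_positive_marker = marker, is_positive_igg = igg,
               intden_igg = intden)
  }
  s <- summarize_sample(mk(12, rep(c(TRUE, FALSE), c(10, 2)),
                           rep(c(TRUE, FALSE), c(4, 8)),
                           c(rep(500, 4), rep(0, 8))))
  expect_equal(s$pct_igg_pos, 40)
  # mean over ALL marker-positive cells, zeros included
  expect_equal(s$mean_intden, 4 * 500 / 10)
  none <- summarize_sample(mk(5, rep(TRUE, 5), rep(FALSE, 5), rep(0, 5)))
  expect_equal(none$pct_igg_pos, 0)
  expect_equal(none$mean_intden, 0)
  # zero marker-positive cells: unevaluable, not zero and not an error
  empty <- summarize_sample(mk(4, rep(FALSE, 4), rep(FALSE, 4), rep(0, 4)))
  expect_false(empty$evaluable)
  expect_true(is.na(empty$pct_igg_pos))
  expect_error(summarize_sample(rbind(mk(2, TRUE, TRUE, 1),
                                      transform(mk(2, TRUE, TRUE, 1), sample_id = "t"))),
               "multiple samples")
})

test_that("affine intensity maps change no positivity call or area", {
  sim <- simulate_culture_sample(culture_sim_config(seed = 31L, n_images = 2L,
                                                    igg_pos_frac = 0.5))
  imgs <- sim$images
  th <- list(marker = compute_experiment_threshold(lapply(imgs, `[[`, "marker"), "marker"),
             igg = compute_experiment_threshold(lapply(imgs, `[[`, "igg"), "igg"))
  a <- 2.3; b <- 400
  imgs2 <- lapply(imgs, function(im) lapply(im, function(m) a * m + b))
  th2 <- list(marker = compute_experiment_threshold(lapply(imgs2, `[[`, "marker"), "marker"),
              igg = compute_experiment_threshold(lapply(imgs2, `[[`, "igg"), "igg"))
  for (im in 1:2) {
    lm <- segment_baseline(imgs[[im]]$marker)  # same masks for both scales
    m1 <- measure_cells(lm, imgs[[im]], th)
    m2 <- measure_cells(lm, imgs2[[im]], th2)
    expect_equal(m2$area_above_marker, m1$area_above_marker)
    expect_equal(m2$area_above_igg, m1$area_above_igg)
    expect_identical(m2$is_positive_marker, m1$is_positive_marker)
    expect_identical(m2$is_positive_igg, m1$is_positive_igg)
  }
})

test_that("recovered binding tracks the simulator truth and is monotone in igg_pos_frac", {
  pct <- sapply(c(0, 0.5, 1), function(frac) {
    sim <- simulate_culture_sample(culture_sim_config(seed = 41L, n_images = 3L,
                                                      igg_pos_frac = frac))
    th <- list(marker = compute_experiment_threshold(lapply(sim$images, `[[`, "marker"), "marker"),
               igg = compute_experiment_threshold(lapply(sim$images, `[[`, "igg"), "igg"))
    s <- summarize_sample(quantify_sample(sim$images, th, "s"))
    true_pct <- 100 * sum(sim$truth$is_igg_pos) / sum(sim$truth$is_marker_pos)
    expect_lt(abs(s$pct_igg_pos - true_pct), 8)
    s$pct_igg_pos
  })
  expect_true(all(diff(pct) >= 0))
  expect_equal(pct[1], 0)
  expect_equal(pct[3], 100)
})

test_that("marker-positive counts are conserved from cells to summaries", {
  sim <- simulate_culture_sample(culture_sim_config(seed = 51L, n_images = 3L))
  th <- list(marker = compute_experiment_threshold(lapply(sim$images, `[[`, "marker"), "marker"),
             igg = compute_experiment_threshold(lapply(sim$images, `[[`, "igg"), "igg"))
  cells <- quantify_sample(sim$images, th, "s")
  s <- summarize_sample(cells)
  per_image <- tapply(cells$is_positive_marker, cells$image_index, sum)
  expect_equal(sum(per_image), s$n_marker_pos)
  expect_equal(nrow(cells), s$n_cells_imaged)
})
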