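test_that("a constant image yields an empty label map, not an error", {
  lm <- segment_baseline(matrix(500, 64, 64))
  expect_identical(sum(lm), 0L)
  expect_identical(dim(lm), c(64L, 64L))
})

test_that("well-separated bright cells are each found exactly once", {
  centers <- as.matrix(expand.grid(y = c(30, 80, 130, 180, 230), x = c(60, 180)))
  img <- draw_cells_image(c(256L, 256L), centers)
  set.seed(2); img <- img + rnorm(length(img), 0, 80)  # SNR well above 10
  lm <- segment_baseline(img, segmentation_params())
  expect_identical(max(lm), 10L)
  mt <- match_to_truth(lm, data.frame(y = centers[, "y"], x = centers[, "x"]))
  expect_equal(mt$recall, 1)
  expect_equal(mt$precision, 1)
  expect_identical(sort(unique(mt$center_object)), 1:10)  # one center per object
})

test_that("touching cells at 1.6x radius separation are split by watershed", {
  r <- 6
  centers <- rbind(c(60, 60), c(60, 60 + 1.6 * r))
  img <- draw_cells_image(c(120L, 120L), centers, radius = r)
  # mean + 3 SD puts the mask boundary near the cells' nominal radius, so
  # the pair touches at this separation and only the watershed divides it
  split_on <- segment_baseline(img, segmentation_params(threshold_method = "mean_plus_k_sd",
                                                        k = 3, split_touching = TRUE))
  split_off <- segment_baseline(img, segmentation_params(threshold_method = "mean_plus_k_sd",
                                                         k = 3, split_touching = FALSE))
  expect_identical(max(split_on), 2L)
  expect_identical(max(split_off), 1L)
})

test_that("labels come out in canonical centroid row-major order", {
  centers <- rbind(c(100, 20), c(20, 100), c(60, 60))
  img <- draw_cells_image(c(120L, 120L), centers)
  lm <- segment_baseline(img)
  mt <- match_to_truth(lm, data.frame(y = centers[, 1], x = centers[, 2]))
  # topmost object must be label 1, bottom-most label 3
  expect_identical(mt$center_object, c(3L, 1L, 2L))
  # canonical_relabel is idempotent and permutation-invariant
  shuffled <- lm
  shuffled[lm == 1L] <- 9L
  shuffled[lm == 3L] <- 1L
  shuffled[lm == 2L] <- 5L
  expect_identical(canonical_relabel(shuffled)[shuffled > 0L], lm[lm > 0L])
})

test_that("segmentation is deterministic on repeated runs", {
  sim <- simulate_culture_sample(culture_sim_config(seed = 21L, n_images = 1L))
  a <- segment_baseline(sim$images[[1]]$marker)
  b <- segment_baseline(sim$images[[1]]$marker)
  expect_identical(a, b)
})

test_that("recall and precision reach 0.95 on the standard synthetic fixture", {
  for (s in c(1L, 2L, 3L)) {
    sim <- simulate_culture_sample(culture_sim_config(seed = s))
    stats <- lapply(seq_along(sim$images), function(im) {
      lm <- segment_baseline(sim$images[[im]]$marker)
      tr <- sim$truth[sim$truth$image_index == im & sim$truth$is_marker_pos, ]
      match_to_truth(lm, tr[c("y", "x")])
    })
    recall <- mean(unlist(lapply(stats, `[[`, "recall")))
    precision <- mean(unlist(lapply(stats, `[[`, "precision")))
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})

test_that("the minimum-area filter drops specks", {
  img <- matrix(0, 64, 64)
  img[30:38, 30:38] <- 5000   # 81 px
  img[10, 10] <- 5000         # single-pixel speck
  lm <- segment_baseline(img, segmentation_params(smoothing_sigma = 0, min_cell_area = 9L))
  expect_identical(max(lm), 1L)
  expect_identical(lm[10, 10], 0L)
})

test_that("exclude_border drops objects touching the image edge", {
  img <- draw_cells_image(c(96L, 96L), rbind(c(4, 48), c(48, 48)))
  keep <- segment_baseline(img, segmentation_params(exclude_border = FALSE))
  drop <- segment_baseline(img, segmentation_params(exclude_border = TRUE))
  expect_identical(max(keep), 2L)
  expect_identical(max(drop), 1L)
})
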