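test_that("normalized intensity follows the mean-over-threshold arithmetic", {
  mask <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  img <- matrix(c(10, 20, 30, 40, 99, 99), 2, 3)
  expect_equal(normalized_intensity(mask, img, 10), 2.5)
  # uniform in-mask intensity equal to the threshold gives exactly 1
  expect_equal(normalized_intensity(mask, matrix(7, 2, 3), 7), 1.0)
  # scale invariance: doubling image and threshold changes nothing
  expect_equal(normalized_intensity(mask, 2 * img, 20), 2.5)
  expect_error(normalized_intensity(mask, img, 0), "> 0")
  expect_error(normalized_intensity(mask * 0, img, 10), "empty")
})

test_that("object classes are recovered on standard synthetic sections", {
  for (s in c(2L, 5L, 8L)) {
    sec <- simulate_tissue_section(tissue_sim_config(seed = s))
    cls <- classify_tissue_objects(sec$labels, sec$images$gfap, sec$images$nf200)
    m <- merge(sec$truth, cls, by = "object_id")
    acc <- mean(as.character(m$class.x) == as.character(m$class.y))
    expect_gte(acc, 0.95)
    # partition: every foreground object got exactly one class
    expect_identical(nrow(cls), nrow(sec$truth))
    expect_false(anyNA(cls$class))
  }
})

test_that("with full rings, every SGC call is adjacent to a soma", {
  sec <- simulate_tissue_section(tissue_sim_config(ring_fraction = 1, seed = 3L))
  cls <- classify_tissue_objects(sec$labels, sec$images$gfap, sec$images$nf200)
  m <- merge(sec$truth, cls, by = "object_id")
  soma_pred <- m$object_id[m$class.y == "soma"]
  # every predicted SGC is a true ring, and each ring hugs a soma
  sgc_pred <- m[m$class.y == "SGC", ]
  expect_true(all(sgc_pred$class.x == "SGC"))
  expect_true(all(sgc_pred$partner_id %in% soma_pred))
})

test_that("sections without axons receive no axon calls", {
  sec <- simulate_tissue_section(tissue_sim_config(n_axons = 0L, seed = 6L))
  cls <- classify_tissue_objects(sec$labels, sec$images$gfap, sec$images$nf200)
  expect_identical(sum(cls$class == "axon"), 0L)
})

test_that("a soma-free section warns and leaves the SGC class empty", {
  sec <- simulate_tissue_section(tissue_sim_config(n_soma = 0L, ring_fraction = 0,
                                                   n_axons = 2L, n_other = 3L, seed = 2L))
  expect_warning(cls <- classify_tissue_objects(sec$labels, sec$images$gfap,
                                                sec$images$nf200),
                 "no soma")
  expect_identical(sum(cls$class == "SGC"), 0L)
})

test_that("donor averaging weights slides equally, not objects", {
  # slide 1: one SGC at 2.0; slide 2: ten SGCs at 4.0. Slide weighting
  # gives 3.0; object weighting would give 41/11.
  objects <- data.frame(
    donor_id = "d1", serum_id = "FM",
    slide_id = rep(c("sl1", "sl2"), c(1, 10)),
    object_id = 1:11, object_class = "SGC",
    norm_intensity = c(2.0, rep(4.0, 10)))
  ds <- summarize_donor(objects)
  expect_equal(ds$mean_norm_intensity, 3.0)
  expect_identical(ds$n_slides, 2L)
  object_weighted <- mean(objects$norm_intensity)
  expect_gt(abs(ds$mean_norm_intensity - object_weighted), 0.5)
  # a single slide's summary is that slide's mean
  one <- summarize_donor(objects[objects$slide_id == "sl1", ])
  expect_equal(one$mean_norm_intensity, 2.0)
  expect_error(summarize_donor(objects[0, ]), "zero slides")
})

test_that("a background-only IgG channel scores below 1 against its threshold", {
  zero <- list(SGC = c(0, 0), soma = c(0, 0), axon = c(0, 0), other = c(0, 0))
  sec <- simulate_tissue_section(tissue_sim_config(igg_intensity_by_class = zero, seed = 7L))
  thr <- tissue_background_threshold(sec$images$igg)
  cls <- classify_tissue_objects(sec$labels, sec$images$gfap, sec$images$nf200)
  obj <- measure_tissue_objects(sec$labels, cls, sec$images$igg, thr$threshold)
  # objects carry only background: mean/threshold = mu/(mu + 2 sigma) < 1
  expect_true(all(obj$norm_intensity < 1))
  expected <- thr$mu / thr$threshold
  expect_lt(abs(mean(obj$norm_intensity) - expected), 0.05)
})

test_that("class-specific IgG elevation shows up as an SGC-vs-soma contrast", {
  hits <- vapply(1:8, function(s) {
    cfg <- tissue_sim_config(seed = s, igg_intensity_by_class = list(
      SGC = c(3000, 400), soma = c(1400, 300), axon = c(1400, 300), other = c(1200, 300)))
    sec <- simulate_tissue_section(cfg)
    thr <- tissue_background_threshold(sec$images$igg)
    cls <- classify_tissue_objects(sec$labels, sec$images$gfap, sec$images$nf200)
    obj <- measure_tissue_objects(sec$labels, cls, sec$images$igg, thr$threshold)
    agg <- tapply(obj$norm_intensity, obj$object_class, mean)
    agg[["SGC"]] > agg[["soma"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
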