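test_that("identical groups give a null rank-test result", {
  x <- rep(c(10, 20, 30, 40, 50), 2)
  g <- rep(c("FM", "HC"), each = 5)
  res <- compare_groups(x, g, "proportion_like")
  expect_identical(res$test_name, "Mann-Whitney")
  expect_gt(res$p_value, 0.9)
})

test_that("constant data in all groups is a degenerate-input report", {
  res <- compare_groups(rep(5, 10), rep(c("a", "b"), 5), "proportion_like")
  expect_identical(res$test_name, "degenerate")
  expect_true(is.na(res$p_value))
})

test_that("three-group comparisons attach the right post hoc tables", {
  set.seed(10)
  x <- c(rnorm(12, 0), rnorm(12, 0.5), rnorm(12, 3))
  g <- rep(c("HC", "mild", "severe"), each = 12)
  pr <- compare_groups(x, g, "proportion_like")
  expect_identical(pr$test_name, "Kruskal-Wallis")
  expect_identical(nrow(pr$posthoc), 3L)
  it <- compare_groups(x, g, "intensity_like")
  expect_identical(it$test_name, "one-way ANOVA")
  expect_identical(nrow(it$posthoc), 3L)
  # the clearly separated pair is detected by both post hocs
  expect_lt(pr$posthoc$p_value[pr$posthoc$comparison == "HC-severe"], 0.01)
  expect_lt(it$posthoc$p_value[grepl("severe", it$posthoc$comparison) &
                               grepl("HC", it$posthoc$comparison)], 0.01)
})

test_that("Dunn z agrees with Kruskal-Wallis in the two-group case", {
  # dual route: for 2 groups, the KW chi-squared equals the squared Dunn z
  set.seed(11)
  x <- c(rnorm(9), rnorm(11, 1)); g <- rep(c("a", "b"), c(9, 11))
  d <- dunn_test(x, g)
  kw <- kruskal.test(x, factor(g))
  expect_equal(unname(d$z^2), unname(kw$statistic), tolerance = 1e-10)
})

test_that("Spearman rho is exactly 1 for monotone relations and rank invariant", {
  x <- c(-3, -1, 0.5, 2, 4, 7)
  cm <- correlation_matrix(data.frame(x = x, y = x^3))
  expect_equal(cm$rho["x", "y"], 1)
  set.seed(12)
  a <- rnorm(40); b <- a + rnorm(40)
  r1 <- correlation_matrix(data.frame(a, b))$rho["a", "b"]
  r2 <- correlation_matrix(data.frame(a = exp(a), b = rank(b)^3))$rho["a", "b"]
  expect_equal(r1, r2)
})

test_that("independent columns have near-zero rho and constant columns report NA", {
  set.seed(13)
  cm <- correlation_matrix(data.frame(u = rnorm(10000), v = rnorm(10000)))
  expect_lt(abs(cm$rho["u", "v"]), 0.03)
  cc <- correlation_matrix(data.frame(u = rnorm(10), k = rep(1, 10)))
  expect_true(is.na(cc$rho["u", "k"]))
  expect_false(cc$significant["u", "k"])
})

test_that("the significance mask is consistent with p and alpha", {
  set.seed(14)
  df <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  df$d <- df$a + rnorm(30, 0, 0.3)
  cm <- correlation_matrix(df, alpha = 0.05)
  off <- upper.tri(cm$p)
  expect_identical(cm$significant[off], !is.na(cm$p[off]) & cm$p[off] < 0.05)
  expect_true(cm$significant["a", "d"])
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))
  long <- as.data.frame(cm)
  expect_identical(nrow(long), 6L)
})

test_that("well-separated severity clusters are recovered exactly (ARI = 1)", {
  set.seed(15)
  truth <- rep(c("FM-mild", "FM-severe"), each = 15)
  feats <- data.frame(
    fiq = c(rnorm(15, 40, 5), rnorm(15, 55, 5) + 3 * 5),
    vas_avg = c(rnorm(15, 40, 6), rnorm(15, 40, 6) + 3 * 6),
    vas_max = c(rnorm(15, 60, 5), rnorm(15, 60, 5) + 3 * 5))
  cl <- cluster_severity(feats, seed = 2)
  expect_equal(mclust::adjustedRandIndex(cl$assignments, truth), 1)
  expect_identical(levels(cl$assignments), c("FM-mild", "FM-severe"))
  # severe = higher centroid, independent of row order
  perm <- sample(nrow(feats))
  cl2 <- cluster_severity(feats[perm, ], seed = 2)
  expect_identical(as.character(cl2$assignments), as.character(cl$assignments)[perm])
})

test_that("clustering rejects degenerate and undersized inputs", {
  same <- data.frame(fiq = rep(50, 8), vas_avg = rep(40, 8), vas_max = rep(70, 8))
  expect_error(cluster_severity(same), "degenerate")
  expect_error(cluster_severity(same[1:3, ]), ">= 4 subjects")
  expect_error(cluster_severity(same[-1]), "missing feature columns: fiq")
})

test_that("the paired donor test handles identity, effects, and antisymmetry", {
  ident <- paired_donor_test(fm = c(1, 2, 3, 4), hc = c(1, 2, 3, 4))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  set.seed(16)
  fm <- rnorm(6, 3, 0.3); hc <- rnorm(6, 2, 0.3)
  up <- paired_donor_test(fm = fm, hc = hc)
  down <- paired_donor_test(fm = hc, hc = fm)
  expect_equal(down$statistic, -up$statistic)
  expect_equal(down$p_value, up$p_value)
  expect_lt(up$p_value, 0.05)
  expect_gt(up$estimate, 0)
})

test_that("unmatched donors are listed by name", {
  dv <- data.frame(donor_id = c("d1", "d1", "d2", "d3", "d3"),
                   serum_group = c("FM", "HC", "FM", "FM", "HC"),
                   value = 1:5)
  expect_error(paired_donor_test(dv), "d2")
  expect_error(paired_donor_test(fm = c(1, 2), hc = c(2, 3)), ">= 3 matched")
})

test_that("a paired effect of twice the noise SD is detected reliably", {
  hits <- vapply(1:40, function(s) {
    set.seed(400 + s)
    base <- rnorm(6, 2, 0.4)          # donor-to-donor variation (paired out)
    hc <- base
    fm <- base + 0.5 + rnorm(6, 0, 0.25)  # shift = 2 x the pair-noise SD
    r <- paired_donor_test(fm = fm, hc = hc)
    r$p_value < 0.05 && r$estimate > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("single-plate data pass through plate correction unchanged", {
  el <- data.frame(sample_id = paste0("s", 1:10), plate_id = "p1",
                   value = rnorm(10, 1, 0.2))
  res <- correct_plate_effects(el)
  expect_equal(res$corrected$corrected, el$value)
  expect_equal(res$offsets$offset, 0)
})

test_that("an injected plate offset is recovered and the grand mean preserved", {
  set.seed(17)
  truth <- rnorm(40, 1.0, 0.3)
  bridge <- 1:8  # bridging controls measured on both plates
  el <- rbind(
    data.frame(sample_id = paste0("s", 1:40), plate_id = "p1",
               value = truth + rnorm(40, 0, 0.05)),
    data.frame(sample_id = paste0("s", bridge), plate_id = "p2",
               value = truth[bridge] + 0.3 + rnorm(8, 0, 0.05)),
    data.frame(sample_id = paste0("t", 1:32), plate_id = "p2",
               value = rnorm(32, 1.0, 0.3) + 0.3 + rnorm(32, 0, 0.05)))
  res <- correct_plate_effects(el)
  off <- res$offsets
  gap <- off$offset[off$plate_id == "p2"] - off$offset[off$plate_id == "p1"]
  expect_lt(abs(gap - 0.3), 0.05)
  expect_equal(mean(res$corrected$corrected), mean(el$value))
  # plate-2 bridging samples land near their plate-1 twins after correction
  w <- res$corrected
  d <- sapply(bridge, function(i) {
    diff(w$corrected[w$sample_id == paste0("s", i)])
  })
  expect_lt(mean(abs(d)), 0.15)
})

test_that("disconnected plate designs are refused", {
  el <- data.frame(sample_id = c("a", "b", "c", "d"),
                   plate_id = c("p1", "p1", "p2", "p2"),
                   value = 1:4)
  expect_error(correct_plate_effects(el), "disconnected")
})
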