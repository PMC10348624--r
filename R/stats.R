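#' Compare an outcome between subject groups
#'
#' Follows the analysis conventions of the emulated study: proportion-like
#' outcomes (percent of cells bound by IgG) use rank-based tests --
#' Mann-Whitney for 2 groups, Kruskal-Wallis plus Dunn post hoc for more;
#' intensity-like outcomes (integrated density, titres, phenotype scores)
#' use a two-tailed t-test or one-way ANOVA plus Tukey post hoc. All tests
#' are two-sided and no multiple-testing correction is applied by default
#' (Dunn adjustment is available behind `p_adjust`).
#'
#' @param values Numeric outcome vector.
#' @param groups Factor (or coercible) of group membership, same length.
#' @param value_kind `"proportion_like"` or `"intensity_like"`.
#' @param p_adjust P-adjustment method for the Dunn post hoc
#'   (`"none"` by default, matching the emulated analysis).
#' @return An object of class `group_comparison`: list with `variable
#'   kind`, `test_name`, `statistic`, `p_value`, `groups`, `n`, and
#'   `posthoc` (pairwise data frame when > 2 groups, else `NULL`). When
#'   the data are constant in every group the result is a degenerate-input
#'   report (`test_name = "degenerate"`, `p_value = NA`).
#' @export
compare_groups <- function(values, groups,
                           value_kind = c("proportion_like", "intensity_like"),
                           p_adjust = "none") {
  value_kind <- match.arg(value_kind)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) < 2L) stopf("need >= 2 groups")
  if (any(table(groups) < 2L)) stopf("every group needs n >= 2")
  res <- list(value_kind = value_kind, groups = levels(groups),
              n = as.vector(table(groups)), posthoc = NULL)
  if (stats::var(values) == 0) {
    res$test_name <- "degenerate"
    res$statistic <- NA_real_
    res$p_value <- NA_real_
    res$note <- "constant data in all groups; no test performed"
    class(res) <- "group_comparison"
    return(res)
  }
  two <- nlevels(groups) == 2L
  if (value_kind == "proportion_like") {
    if (two) {
      ht <- suppressWarnings(stats::wilcox.test(values ~ groups, exact = NULL, correct = TRUE))
      res$test_name <- "Mann-Whitney"
    } else {
      ht <- stats::kruskal.test(values, groups)
      res$test_name <- "Kruskal-Wallis"
      res$posthoc <- dunn_test(values, groups, p_adjust = p_adjust)
    }
  } else {
    if (two) {
      ht <- stats::t.test(values ~ groups)
      res$test_name <- "t-test"
    } else {
      fit <- stats::aov(values ~ groups)
      sm <- summary(fit)[[1]]
      ht <- list(statistic = sm[["F value"]][1], p.value = sm[["Pr(>F)"]][1])
      res$test_name <- "one-way ANOVA"
      tk <- stats::TukeyHSD(fit)$groups
      res$posthoc <- data.frame(comparison = rownames(tk),
                                estimate = tk[, "diff"], p_value = tk[, "p adj"],
                                row.names = NULL)
    }
  }
  res$statistic <- unname(if (is.list(ht)) ht$statistic else ht$statistic)
  res$p_value <- unname(if (is.list(ht)) ht$p.value else ht$p.value)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %s, p = %s [groups: %s; n = %s]\n",
              x$test_name, x$value_kind,
              format(x$statistic, digits = 4), format(x$p_value, digits = 4),
              paste(x$groups, collapse = "/"), paste(x$n, collapse = "/")))
  if (!is.null(x$posthoc)) { cat("post hoc:\n"); print(x$posthoc) }
  invisible(x)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z-statistics on pooled mid-ranks with the standard tie
#' correction; two-sided p-values, unadjusted by default.
#'
#' @param values Numeric outcome vector.
#' @param groups Factor of group membership.
#' @param p_adjust Method passed to [stats::p.adjust()] (`"none"` default).
#' @return Data frame: `comparison`, `z`, `p_value` (and `p_adjusted` when
#'   adjustment is requested).
#' @export
dunn_test <- function(values, groups, p_adjust = "none") {
  groups <- droplevels(as.factor(groups))
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  rows <- list()
  for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1L):length(lev)) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[i] + 1 / ng[j]))
    z <- (rbar[i] - rbar[j]) / se
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste(lev[i], lev[j], sep = "-"),
      z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))))
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Significance-masked Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations over the numeric columns of a
#' table, with pairwise-complete observations, two-sided p-values, and a
#' logical mask of significance at `alpha` (only significant entries are
#' shown coloured in the corresponding correlation-dot figures; the mask
#' reproduces that rule). Constant columns yield `NA` correlations for
#' their pairs, reported, not dropped. No multiple-testing correction is
#' applied.
#'
#' @param table Data frame; non-numeric columns are ignored.
#' @param alpha Significance level for the mask.
#' @param min_pairs Minimum complete pairs required per cell.
#' @return An object of class `correlation_matrix`: list of matrices
#'   `rho`, `p`, `n`, logical `significant`, plus `alpha`.
#' @export
correlation_matrix <- function(table, alpha = 0.05, min_pairs = 3L) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(num) < 2L) stopf("need >= 2 numeric columns")
  vars <- names(num)
  p <- rho <- nmat <- matrix(NA_real_, ncol(num), ncol(num), dimnames = list(vars, vars))
  for (i in seq_along(vars)) for (j in seq_len(i)) {
    x <- num[[i]]; y <- num[[j]]
    ok <- !is.na(x) & !is.na(y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < min_pairs) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next  # rho undefined
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(rho = rho, p = p, n = nmat,
                 significant = !is.na(p) & p < alpha, alpha = alpha),
            class = "correlation_matrix")
}

#' Long-format view of a correlation matrix
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Data frame `var1`, `var2`, `rho`, `p`, `n`, `significant`
#'   (lower triangle, no diagonal).
#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  vars <- rownames(x$rho)
  rows <- list()
  for (i in seq_along(vars)[-1]) for (j in seq_len(i - 1L)) {
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = vars[i], var2 = vars[j], rho = x$rho[i, j], p = x$p[i, j],
      n = x$n[i, j], significant = x$significant[i, j])
  }
  do.call(rbind, rows)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman correlation matrix (%d variables, mask at p < %g):\n",
              nrow(x$rho), x$alpha))
  print(round(x$rho, 3))
  invisible(x)
}

#' K-means severity clustering of FM subjects
#'
#' Splits FM subjects into FM-severe and FM-mild groups by k-means
#' (k = 2) on FIQ, average pain intensity, and maximum pain intensity.
#' Features are z-scored before clustering by default (the three scales
#' share a 0-100 range but not variance); the best of `n_restarts` random
#' starts by within-cluster sum of squares is kept. The *severe* label
#' goes to the cluster whose centroid has the higher mean standardized
#' feature value, so labels do not depend on input row order.
#'
#' @param features Data frame (FM subjects only) with columns `fiq`,
#'   `vas_avg`, `vas_max` (or pass any 3+ numeric columns via
#'   `feature_cols`).
#' @param feature_cols Character vector naming the feature columns.
#' @param scale Z-score features before clustering (default `TRUE`).
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of random starts.
#' @return An object of class `severity_clustering`: list with
#'   `assignments` (factor `FM-mild`/`FM-severe` in input row order),
#'   `centroids` (on the standardized scale when `scale = TRUE`),
#'   `features`, `seed`, `n_restarts`, `tot_withinss`.
#' @export
cluster_severity <- function(features,
                             feature_cols = c("fiq", "vas_avg", "vas_max"),
                             scale = TRUE, seed = 1L, n_restarts = 25L) {
  stopifnot(is.data.frame(features))
  if (!all(feature_cols %in% names(features)))
    stopf("missing feature columns: %s",
          paste(setdiff(feature_cols, names(features)), collapse = ", "))
  x <- as.matrix(features[feature_cols])
  if (anyNA(x)) stopf("clustering features contain missing values")
  if (nrow(x) < 4L) stopf("need >= 4 subjects to cluster")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0))
    stopf("degenerate input: all features identical across subjects")
  if (scale) {
    keep_sd <- ifelse(sds > 0, sds, 1)
    x <- sweep(sweep(x, 2, colMeans(x)), 2, keep_sd, "/")
  }
  if (nrow(unique(x)) < 2L)
    stopf("degenerate input: fewer than 2 distinct feature vectors")
  km <- with_seed(seed, stats::kmeans(x, centers = 2L, nstart = n_restarts))
  severe_cluster <- which.max(rowMeans(km$centers))
  assignments <- factor(ifelse(km$cluster == severe_cluster, "FM-severe", "FM-mild"),
                        levels = c("FM-mild", "FM-severe"))
  if (nlevels(droplevels(assignments)) < 2L)
    stopf("clustering degenerate: one cluster is empty")
  structure(list(assignments = assignments,
                 centroids = km$centers[order(rowMeans(km$centers)), , drop = FALSE],
                 features = feature_cols, scaled = scale,
                 seed = seed, n_restarts = n_restarts,
                 tot_withinss = km$tot.withinss),
            class = "severity_clustering")
}

#' @export
print.severity_clustering <- function(x, ...) {
  cat(sprintf("severity clustering on %s (k = 2, %d restarts, seed %d): %d mild / %d severe\n",
              paste(x$features, collapse = " + "), x$n_restarts, x$seed,
              sum(x$assignments == "FM-mild"), sum(x$assignments == "FM-severe")))
  invisible(x)
}

#' Paired t-test across matched donors
#'
#' Compares FM-serum vs HC-serum readouts measured on tissue from the same
#' donors (each donor contributes one matched pair), with a two-sided
#' paired t-test.
#'
#' @param donor_values Data frame with columns `donor_id`, `serum_group`
#'   (two levels, e.g. FM/HC), and `value`; or supply `fm` and `hc`
#'   numeric vectors plus `donor_id`.
#' @param fm,hc Optional paired numeric vectors (used when
#'   `donor_values` is missing).
#' @param donor_id Donor identifiers for the vector interface.
#' @return `htest`-like list with `statistic`, `p_value`, `estimate`
#'   (mean FM - HC difference), `n_pairs`, `donors`.
#' @export
paired_donor_test <- function(donor_values = NULL, fm = NULL, hc = NULL,
                              donor_id = NULL) {
  if (!is.null(donor_values)) {
    req <- c("donor_id", "serum_group", "value")
    if (!all(req %in% names(donor_values)))
      stopf("donor_values must contain columns: %s", paste(req, collapse = ", "))
    g <- as.factor(donor_values$serum_group)
    if (nlevels(g) != 2L) stopf("`serum_group` must have exactly 2 levels")
    wide <- stats::reshape(donor_values[c("donor_id", "serum_group", "value")],
                           idvar = "donor_id", timevar = "serum_group",
                           direction = "wide")
    miss <- wide$donor_id[!stats::complete.cases(wide)]
    if (length(miss))
      stopf("unmatched donors (missing one serum group): %s", paste(miss, collapse = ", "))
    fm <- wide[[paste0("value.", levels(g)[1])]]
    hc <- wide[[paste0("value.", levels(g)[2])]]
    donor_id <- wide$donor_id
  }
  stopifnot(is.numeric(fm), is.numeric(hc), length(fm) == length(hc))
  if (length(fm) < 3L) stopf("need >= 3 matched donor pairs")
  d <- fm - hc
  if (stats::sd(d) == 0 && all(d == 0)) {
    # identical pairs: t = 0, p = 1 by convention (t.test would error)
    return(list(statistic = 0, p_value = 1, estimate = 0,
                n_pairs = length(fm), donors = donor_id,
                test_name = "paired t-test"))
  }
  ht <- stats::t.test(fm, hc, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       estimate = unname(ht$estimate), n_pairs = length(fm),
       donors = donor_id, test_name = "paired t-test")
}

#' Correct ELISA plate effects
#'
#' Removes additive per-plate offsets from a sample x plate absorbance
#' table. Offsets are estimated from a linear model with fixed sample
#' effects and sum-to-zero plate effects; samples appearing on more than
#' one plate (bridging controls or replicates) identify the offsets. The
#' design must be connected: every plate must share at least one sample
#' with the rest of the design, otherwise offsets are not identifiable and
#' an error lists the disconnected components. The grand mean of the
#' corrected values equals the grand mean of the inputs exactly.
#'
#' @param elisa Data frame with columns `sample_id`, `plate_id`, `value`.
#' @return List with `corrected` (the input data frame plus a `corrected`
#'   column) and `offsets` (data frame `plate_id`, `offset`).
#' @export
correct_plate_effects <- function(elisa) {
  req <- c("sample_id", "plate_id", "value")
  if (!all(req %in% names(elisa)))
    stopf("elisa must contain columns: %s", paste(req, collapse = ", "))
  if (anyNA(elisa$value)) stopf("absorbance values contain NA")
  elisa$sample_id <- as.factor(elisa$sample_id)
  elisa$plate_id <- as.factor(elisa$plate_id)
  plates <- levels(elisa$plate_id)
  if (length(plates) == 1L) {
    elisa$corrected <- elisa$value
    return(list(corrected = elisa,
                offsets = data.frame(plate_id = plates, offset = 0)))
  }
  # connectivity: plates joined when they share a sample
  comp <- plate_components(elisa$sample_id, elisa$plate_id)
  if (max(comp) > 1L) {
    parts <- split(plates, comp)
    stopf("disconnected plate design (no bridging samples between): %s",
          paste(vapply(parts, paste, "", collapse = "+"), collapse = " | "))
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(value ~ sample_id + plate_id, data = elisa)
  cf <- stats::coef(fit)
  pc <- cf[grep("^plate_id", names(cf))]
  if (anyNA(pc)) stopf("plate offsets not estimable (confounded design)")
  offsets <- c(pc, -sum(pc))
  names(offsets) <- plates
  corrected <- elisa$value - offsets[as.character(elisa$plate_id)]
  # identifiability: restore the observed grand mean exactly
  corrected <- corrected + mean(offsets[as.character(elisa$plate_id)])
  elisa$corrected <- unname(corrected)
  list(corrected = elisa,
       offsets = data.frame(plate_id = plates, offset = unname(offsets)))
}

# connected components of the plate graph (plates share an edge when a
# sample appears on both); simple BFS, returns a component id per plate
plate_components <- function(sample_id, plate_id) {
  plates <- levels(plate_id)
  adj <- lapply(split(as.integer(plate_id), sample_id), unique)
  comp <- integer(length(plates))
  cur <- 0L
  for (p in seq_along(plates)) {
    if (comp[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    comp[p] <- cur
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      for (nb in adj) if (q %in% nb) {
        new <- nb[comp[nb] == 0L]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  comp
}
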