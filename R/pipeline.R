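#' Configuration of a full synthetic pipeline run
#'
#' Bundles every knob of a simulate -> segment -> quantify -> summarize ->
#' analyze run. Unknown keys are rejected, and every parameter is echoed
#' verbatim into the run's `run_meta.json` so the threshold rule, `k`, and
#' `min_area` choices are always auditable.
#'
#' @param out_dir Output directory for the run.
#' @param cohort A [cohort_sim_config()].
#' @param culture Culture imaging template: a [culture_sim_config()];
#'   per-subject seeds and IgG fractions are filled in by the pipeline.
#' @param k Threshold multiplier (default 8).
#' @param threshold_rule `"mu_plus_k_sd"` or `"k_sd_only"`.
#' @param min_area Positivity minimum suprathreshold area, pixels.
#' @param segmentation A [segmentation_params()].
#' @param alpha Significance level for masks and post hocs.
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_restarts K-means restarts for severity clustering.
#' @param blind Replace sample identities by opaque codes during
#'   quantification, re-joining only at the stats stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_sim_config(),
                       culture = culture_sim_config(),
                       k = 8,
                       threshold_rule = c("mu_plus_k_sd", "k_sd_only"),
                       min_area = 5L,
                       segmentation = segmentation_params(),
                       alpha = 0.05,
                       seed = 1L,
                       n_restarts = 25L,
                       blind = TRUE) {
  structure(list(
    out_dir = out_dir,
    cohort = cohort, culture = culture,
    k = check_pos(k, "k", strict = FALSE),
    threshold_rule = match.arg(threshold_rule),
    min_area = check_count(min_area, "min_area", min = 1L),
    segmentation = segmentation,
    alpha = check_prob(alpha, "alpha"),
    seed = check_count(seed, "seed"),
    n_restarts = check_count(n_restarts, "n_restarts", min = 1L),
    blind = isTRUE(blind)
  ), class = "run_config")
}

#' Read a run configuration from YAML/JSON
#'
#' Keys mirror the [run_config()] arguments (nested simulation configs use
#' their constructors' argument names). Unknown keys raise a validation
#' error naming the key.
#'
#' @param path YAML or JSON file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stopf("unknown configuration key%s in %s: %s",
            if (length(unknown) > 1) "s" else "", where, paste(unknown, collapse = ", "))
  }
  check_keys(raw, names(formals(run_config)), "run config")
  build <- function(field, ctor) {
    if (is.null(raw[[field]])) return(NULL)
    check_keys(raw[[field]], names(formals(ctor)), field)
    args <- raw[[field]]
    # (mean, sd) pairs may arrive as length-2 lists from YAML
    args <- lapply(args, function(a) if (is.list(a) && !is.null(names(a)) &&
                                         all(c("gaussian_sd", "poisson") %in% names(a))) a
                   else if (is.list(a)) unlist(a) else a)
    do.call(ctor, args)
  }
  args <- raw[setdiff(names(raw), c("cohort", "culture", "segmentation"))]
  if (!is.null(out_dir)) args$out_dir <- out_dir
  for (nm in c("cohort", "culture", "segmentation")) {
    val <- build(nm, switch(nm, cohort = cohort_sim_config,
                            culture = culture_sim_config,
                            segmentation = segmentation_params))
    if (!is.null(val)) args[[nm]] <- val
  }
  do.call(run_config, args)
}

#' Opaque blinding codes for a set of samples
#'
#' The quantification stages see only the codes; the mapping is written
#' once and re-read only by the analysis stage, supporting the blinded
#' single-pass design of the emulated study.
#'
#' @param sample_ids Character vector of true sample identities.
#' @param seed Seed for the permutation.
#' @return Data frame `sample_id`, `code`.
#' @export
blind_samples <- function(sample_ids, seed = 1L) {
  stopifnot(!anyDuplicated(sample_ids))
  codes <- sprintf("B%04d", with_seed(seed, sample(length(sample_ids))))
  data.frame(sample_id = sample_ids, code = codes)
}

#' Run the full synthetic pipeline
#'
#' Simulates a phenotyped cohort, renders each subject's culture images
#' with the subject's true binding fraction, segments the marker channel,
#' computes experiment-wide thresholds over *all* images of the run (the
#' run is the experiment), measures and summarizes every sample, then
#' performs the group comparisons, the significance-masked Spearman
#' correlation matrix (FM subjects), severity clustering, and the
#' severe/mild/HC comparisons. All tables and a `run_meta.json` are
#' written under `config$out_dir`; the run is deterministic given the
#' config.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory tables (`cohort`,
#'   `samples`, `cells`, `thresholds`, `comparisons`, `correlations`,
#'   `clusters`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 3L)

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seeds[1]
  cohort <- simulate_cohort(cohort_cfg)

  # render each subject's sample with its true binding fraction
  subj_seeds <- derive_seeds(seeds[2], nrow(cohort))
  sims <- lapply(seq_len(nrow(cohort)), function(i) {
    cc <- config$culture
    cc$igg_pos_frac <- cohort$igg_frac_true[i]
    cc$seed <- subj_seeds[i]
    simulate_culture_sample(cc)
  })
  names(sims) <- cohort$subject_id

  code_map <- blind_samples(cohort$subject_id, seed = seeds[3])
  quant_ids <- if (config$blind) code_map$code[match(cohort$subject_id, code_map$sample_id)]
               else cohort$subject_id

  # experiment = every image declared in this run; per-channel thresholds
  all_marker <- unlist(lapply(sims, function(s) lapply(s$images, `[[`, "marker")), recursive = FALSE)
  all_igg <- unlist(lapply(sims, function(s) lapply(s$images, `[[`, "igg")), recursive = FALSE)
  thresholds <- list(
    marker = compute_experiment_threshold(all_marker, "marker", k = config$k, rule = config$threshold_rule),
    igg = compute_experiment_threshold(all_igg, "igg", k = config$k, rule = config$threshold_rule))

  cells <- do.call(rbind, lapply(seq_along(sims), function(i)
    quantify_sample(sims[[i]]$images, thresholds, sample_id = quant_ids[i],
                    params = config$segmentation, min_area = config$min_area)))
  samples <- summarize_samples(cells)

  # unblind for analysis
  samples$subject_id <- if (config$blind)
    code_map$sample_id[match(samples$sample_id, code_map$code)] else samples$sample_id
  joined <- merge(as.data.frame(cohort), samples, by = "subject_id")

  analysis <- analyze_cohort(joined, alpha = config$alpha, seed = config$seed,
                             n_restarts = config$n_restarts)

  paths <- write_run_outputs(config, cohort, cells, samples, thresholds, code_map, analysis)
  invisible(c(list(cohort = cohort, cells = cells, samples = samples,
                   thresholds = thresholds, code_map = code_map, paths = paths),
              analysis))
}

#' Statistical analysis of a joined samples + phenotype table
#'
#' The analysis layer on its own: FM-vs-HC comparisons of the binding
#' readouts (rank test for the percentage, t-test for the intensity), the
#' FM-only Spearman correlation matrix of binding vs phenotype,
#' severity clustering of the FM group, and severe/mild/HC comparisons
#' (Kruskal-Wallis + Dunn for the percentage, ANOVA + Tukey for the
#' intensity). No multiple-testing correction is applied; every output
#' table records this in a comment attribute.
#'
#' @param joined Data frame joining sample summaries and phenotypes
#'   (columns `group`, `pct_igg_pos`, `mean_intden`, plus phenotype
#'   columns).
#' @param alpha Significance level.
#' @param seed,n_restarts Passed to [cluster_severity()].
#' @param pheno_vars Phenotype columns to correlate with the binding
#'   readouts (defaults to those present).
#' @return List: `comparisons` (data frame), `correlations`
#'   (`correlation_matrix`), `clusters` (`severity_clustering` or `NULL`),
#'   `cluster_comparisons` (data frame or `NULL`), `cluster_table`.
#' @export
analyze_cohort <- function(joined, alpha = 0.05, seed = 1L, n_restarts = 25L,
                           pheno_vars = c("vas_avg", "vas_max", "vas_min", "vas_current",
                                          "fiq", "bdi", "ppt_mean", "cpm_score",
                                          "age", "bmi", "fm_duration", "pain_duration")) {
  joined <- joined[!is.na(joined$pct_igg_pos), , drop = FALSE]
  cmp_pct <- compare_groups(joined$pct_igg_pos, joined$group, "proportion_like")
  cmp_int <- compare_groups(joined$mean_intden, joined$group, "intensity_like")
  comparisons <- data.frame(
    variable = c("pct_igg_pos", "mean_intden"),
    test = c(cmp_pct$test_name, cmp_int$test_name),
    statistic = c(cmp_pct$statistic, cmp_int$statistic),
    p_value = c(cmp_pct$p_value, cmp_int$p_value))

  fm <- joined[joined$group == "FM", , drop = FALSE]
  vars <- intersect(c("pct_igg_pos", "mean_intden", pheno_vars), names(fm))
  correlations <- correlation_matrix(fm[vars], alpha = alpha)

  clusters <- NULL; cluster_comparisons <- NULL; cluster_table <- NULL
  if (nrow(fm) >= 4L && all(c("fiq", "vas_avg", "vas_max") %in% names(fm))) {
    clusters <- cluster_severity(fm, seed = seed, n_restarts = n_restarts)
    cluster_table <- data.frame(subject_id = fm$subject_id,
                                severity = clusters$assignments)
    grp3 <- factor(ifelse(joined$group == "HC", "HC",
                          as.character(clusters$assignments[match(joined$subject_id, fm$subject_id)])),
                   levels = c("HC", "FM-mild", "FM-severe"))
    c3_pct <- compare_groups(joined$pct_igg_pos, grp3, "proportion_like")
    c3_int <- compare_groups(joined$mean_intden, grp3, "intensity_like")
    cluster_comparisons <- rbind(
      cbind(variable = "pct_igg_pos", c3_pct$posthoc[c("comparison", "p_value")],
            omnibus_p = c3_pct$p_value, test = c3_pct$test_name),
      cbind(variable = "mean_intden", c3_int$posthoc[c("comparison", "p_value")],
            omnibus_p = c3_int$p_value, test = c3_int$test_name))
  }
  list(comparisons = comparisons, correlations = correlations,
       clusters = clusters, cluster_comparisons = cluster_comparisons,
       cluster_table = cluster_table)
}

#' Quantify samples listed in an image manifest
#'
#' The file-based front door of the scoring pipeline. The manifest CSV
#' maps each image file to a sample, channel, and experiment; thresholds
#' are computed per experiment x channel over every listed image (the
#' experiment is exactly the set of images declared together), then every
#' sample is measured and summarized. Results are written as `cells.csv`,
#' `samples.csv`, and `thresholds.json` under `out_dir`.
#'
#' @param manifest Path to a CSV with columns `sample_id`, `image_index`,
#'   `channel` (`marker`/`igg`), `path`, and optionally `experiment_id`
#'   (defaults to a single experiment).
#' @param out_dir Output directory.
#' @param labels_dir Optional directory of label-map TIFFs named
#'   `{sample_id}_{image_index:03d}_labels.tif`; when absent the baseline
#'   segmenter runs on each marker image.
#' @param k,threshold_rule,min_area,params Scoring configuration (see
#'   [compute_experiment_threshold()], [measure_cells()],
#'   [segmentation_params()]).
#' @return Invisibly, list with `cells`, `samples`, `thresholds`, `paths`.
#' @export
quantify_manifest <- function(manifest, out_dir, labels_dir = NULL,
                              k = 8, threshold_rule = "mu_plus_k_sd",
                              min_area = 5L, params = segmentation_params()) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  req <- c("sample_id", "image_index", "channel", "path")
  if (!all(req %in% names(mf)))
    stopf("manifest must contain columns: %s", paste(req, collapse = ", "))
  if (is.null(mf$experiment_id)) mf$experiment_id <- "experiment1"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_cells <- list(); all_thresholds <- list()
  for (exp_id in unique(mf$experiment_id)) {
    sub <- mf[mf$experiment_id == exp_id, , drop = FALSE]
    imgs <- lapply(sub$path, read_channel_image)
    names(imgs) <- NULL
    thresholds <- lapply(split(seq_len(nrow(sub)), sub$channel), function(ix)
      compute_experiment_threshold(imgs[ix], channel = sub$channel[ix[1]],
                                   k = k, rule = threshold_rule))
    all_thresholds[[exp_id]] <- thresholds
    for (sid in unique(sub$sample_id)) {
      ssub <- sub[sub$sample_id == sid, , drop = FALSE]
      fields <- sort(unique(ssub$image_index))
      sample_images <- lapply(fields, function(fi) {
        rows <- ssub[ssub$image_index == fi, , drop = FALSE]
        stats::setNames(lapply(match(rows$path, sub$path), function(j) imgs[[j]]), rows$channel)
      })
      label_maps <- NULL
      if (!is.null(labels_dir)) {
        label_maps <- lapply(fields, function(fi)
          ingest_label_map(file.path(labels_dir, sprintf("%s_%03d_labels.tif", sid, fi))))
      }
      all_cells[[paste(exp_id, sid)]] <- quantify_sample(
        sample_images, thresholds, sample_id = sid, label_maps = label_maps,
        params = params, min_area = min_area)
    }
  }
  cells <- do.call(rbind, all_cells)
  rownames(cells) <- NULL
  samples <- summarize_samples(cells)
  paths <- c(cells = file.path(out_dir, "cells.csv"),
             samples = file.path(out_dir, "samples.csv"),
             thresholds = file.path(out_dir, "thresholds.json"))
  utils::write.csv(cells, paths["cells"], row.names = FALSE)
  utils::write.csv(samples, paths["samples"], row.names = FALSE)
  jsonlite::write_json(
    list(rule = threshold_rule, k = k, min_area = min_area,
         experiments = lapply(all_thresholds, function(th) lapply(th, unclass))),
    paths["thresholds"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cells = cells, samples = samples, thresholds = all_thresholds,
                 paths = paths))
}

write_run_outputs <- function(config, cohort, cells, samples, thresholds, code_map, analysis) {
  od <- config$out_dir
  w <- function(df, name) {
    p <- file.path(od, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    cohort = w(as.data.frame(cohort), "cohort.csv"),
    cells = w(cells, "cells.csv"),
    samples = w(samples, "samples.csv"),
    code_map = w(code_map, "code_map.csv"),
    comparisons = w(analysis$comparisons, "comparisons.csv"),
    correlations = w(as.data.frame(analysis$correlations), "correlations.csv"))
  if (!is.null(analysis$cluster_table)) {
    paths["clusters"] <- w(analysis$cluster_table, "clusters.csv")
    paths["cluster_comparisons"] <- w(analysis$cluster_comparisons, "cluster_comparisons.csv")
  }
  meta <- list(
    package = "sgcquant",
    version = as.character(utils::packageVersion("sgcquant")),
    seed = config$seed,
    threshold_rule = config$threshold_rule,
    k = config$k,
    min_area = config$min_area,
    alpha = config$alpha,
    blind = config$blind,
    multiple_testing_correction = "none",
    thresholds = lapply(thresholds, function(t) t[c("channel", "mu", "sigma", "k", "rule", "threshold", "n_pixels")]),
    cohort_config = unclass(config$cohort),
    culture_config = unclass(config$culture),
    segmentation = unclass(config$segmentation))
  mp <- file.path(od, "run_meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(paths, run_meta = mp)
}
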