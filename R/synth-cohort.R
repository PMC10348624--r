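#' Configuration for synthetic FM/HC cohorts
#'
#' Each subject carries a latent anti-SGC level `z` (standard normal,
#' shifted by `latent_effect` in the FM group). Every severity variable is
#' a scale-affine transform of `severity_coupling * (z - group mean) +
#' sqrt(1 - coupling^2) * noise`, so one knob controls every correlation
#' the statistics layer must recover. The latent level maps to a
#' per-subject IgG-binding fraction through a floored sigmoid
#' (`igg_link`), so that binding is near a common floor for most subjects
#' and elevated mainly in the high-latent tail -- mimicking cohorts where
#' only a subset of patients is seropositive and occasional controls show
#' high nonspecific binding.
#'
#' @param n_fm,n_hc Group sizes (>= 2 each).
#' @param latent_effect Standardized shift of the FM group's latent level.
#' @param severity_coupling Correlation in \[-1, 1\] between the latent
#'   level and each severity variable (pain VAS, FIQ; PPT couples with the
#'   opposite sign).
#' @param noise_sd Multiplier on each phenotype variable's residual SD.
#' @param igg_link Named numeric `c(base, span, center, width)`: binding
#'   fraction = `base + span * plogis((z - center) / width)`.
#' @param intden_base,intden_zslope Per-cell IgG integrated-density scale
#'   for bound cells: mean `intden_base * exp(intden_zslope * z)`.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @seealso [simulate_cohort()], [simulate_sample_summaries()]
#' @export
cohort_sim_config <- function(n_fm = 30L, n_hc = 29L,
                              latent_effect = 1.0,
                              severity_coupling = 0.5,
                              noise_sd = 1,
                              igg_link = c(base = 0.12, span = 0.7,
                                           center = 1.4, width = 0.35),
                              intden_base = 15000,
                              intden_zslope = 0.25,
                              seed = 1L) {
  if (abs(severity_coupling) > 1)
    stopf("`severity_coupling` must lie in [-1, 1]")
  structure(list(
    n_fm = check_count(n_fm, "n_fm", min = 2L),
    n_hc = check_count(n_hc, "n_hc", min = 2L),
    latent_effect = check_pos(abs(latent_effect), "latent_effect", strict = FALSE) * sign(latent_effect + (latent_effect == 0)),
    severity_coupling = severity_coupling,
    noise_sd = check_pos(noise_sd, "noise_sd", strict = FALSE),
    igg_link = {
      stopifnot(all(c("base", "span", "center", "width") %in% names(igg_link)))
      check_prob(igg_link[["base"]], "igg_link base")
      check_prob(igg_link[["base"]] + igg_link[["span"]], "igg_link base + span")
      igg_link
    },
    intden_base = check_pos(intden_base, "intden_base"),
    intden_zslope = intden_zslope,
    seed = check_count(seed, "seed")
  ), class = "cohort_sim_config")
}

igg_link_fraction <- function(z, link) {
  link[["base"]] + link[["span"]] * stats::plogis((z - link[["center"]]) / link[["width"]])
}

clip_scale <- function(x, lo, hi) {
  clipped <- x < lo | x > hi
  list(x = pmin(hi, pmax(lo, x)), clipped = clipped)
}

#' Simulate a phenotyped FM/HC cohort with a latent anti-SGC level
#'
#' Generates one row per subject with pain VAS values (0--100), FIQ (FM
#' only, 0--100), BDI, eight PPT site readings and their mean (kPa), CPM
#' baseline/end pressures and score, demographics, the latent anti-SGC
#' level `latent_sgc`, and the implied true binding fraction
#' `igg_frac_true`. Values pushed outside their scale bounds are clipped
#' and flagged in the logical `clipped` column.
#'
#' @param config A [cohort_sim_config()].
#' @return A data frame, one row per subject, of class
#'   `c("cohort", "data.frame")`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_fm + config$n_hc
    group <- factor(rep(c("FM", "HC"), c(config$n_fm, config$n_hc)), levels = c("FM", "HC", "OA"))
    fm <- group == "FM"
    z <- stats::rnorm(n) + ifelse(fm, config$latent_effect, 0)
    cc <- config$severity_coupling
    ns <- config$noise_sd
    # centered latent, so coupling is a within-group correlation
    zc <- z - ifelse(fm, config$latent_effect, 0)
    sev <- function() cc * zc + sqrt(1 - cc^2) * stats::rnorm(n)

    clipped <- rep(FALSE, n)
    take <- function(cs) { clipped <<- clipped | cs$clipped; cs$x }

    # each severity variable draws its own residual, so the latent level is
    # the only source of correlation among them
    vas_avg <- take(clip_scale(ifelse(fm, 55 + 15 * ns * sev(), 6 + 4 * abs(stats::rnorm(n)) * ns), 0, 100))
    vas_max <- take(clip_scale(ifelse(fm, 73 + 12 * ns * sev(), 10 + 5 * abs(stats::rnorm(n)) * ns), 0, 100))
    vas_max <- pmax(vas_max, vas_avg)
    vas_min <- pmax(0, vas_avg - ifelse(fm, 25 + 8 * abs(stats::rnorm(n)), 3 + 2 * abs(stats::rnorm(n))))
    vas_current <- take(clip_scale(vas_avg + 10 * stats::rnorm(n) * ns, 0, 100))
    fiq <- ifelse(fm, take(clip_scale(55 + 18 * ns * sev(), 0, 100)), NA_real_)
    bdi <- pmax(0, ifelse(fm, 12 + 6 * stats::rnorm(n), 3 + 2 * abs(stats::rnorm(n))))
    # pressure pain thresholds: severity lowers the threshold
    ppt_subj <- pmax(60, ifelse(fm, 250 - 40 * ns * sev(), 420 + 50 * stats::rnorm(n) * ns))
    ppt_sites <- matrix(pmax(30, rep(ppt_subj, each = 8L) + stats::rnorm(8L * n, 0, 25 * ns)),
                        nrow = n, ncol = 8L, byrow = TRUE)
    colnames(ppt_sites) <- paste0("ppt_s", 1:8)
    cpm_baseline <- pmax(60, ppt_subj + stats::rnorm(n, 0, 30))
    cpm <- stats::rnorm(n, 0.15, 0.25)   # uncoupled: CPM is unrelated to the latent level
    cpm_end <- cpm_baseline * (1 + cpm)
    age <- take(clip_scale(stats::rnorm(n, 45, 10), 20, 60))
    bmi <- pmax(17, stats::rnorm(n, 25, 3))
    fm_duration <- ifelse(fm, pmax(0.5, stats::rnorm(n, 8, 5)), 0)
    pain_duration <- ifelse(fm, fm_duration + abs(stats::rnorm(n, 2, 2)), 0)

    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, cohort = "synthetic",
      vas_avg = vas_avg, vas_max = vas_max, vas_min = vas_min, vas_current = vas_current,
      fiq = fiq, bdi = bdi, ppt_sites,
      ppt_mean = rowMeans(ppt_sites),
      cpm_baseline = cpm_baseline, cpm_end = cpm_end,
      cpm_score = (cpm_end - cpm_baseline) / cpm_baseline,
      age = age, bmi = bmi,
      fm_duration = fm_duration, pain_duration = pain_duration,
      latent_sgc = z,
      igg_frac_true = igg_link_fraction(z, config$igg_link),
      clipped = clipped
    )
    class(out) <- c("cohort", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' Measurement-level sample summaries for a simulated cohort
#'
#' Draws each subject's per-cell binding outcomes directly (binomial
#' positivity among marker-positive cells, per-cell integrated density for
#' bound cells) without rendering pixels. This is the same statistical
#' model the image-level path samples from, and is the generator mode used
#' for replicate-heavy calibration studies; [simulate_culture_sample()]
#' plus segmentation and thresholding is the image-level counterpart.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param cells_per_subject Mean number of cells imaged per subject
#'   (Poisson; the emulated sessions average ~73).
#' @param marker_pos_frac Fraction of imaged cells that are marker-positive.
#' @param intden_cv Coefficient of variation of per-cell integrated density.
#' @param binding `"sgc"` uses each subject's latent-linked
#'   `igg_frac_true`; `"neuron"` models the anti-neuron assay, where
#'   binding is unrelated to the latent level (a common fraction for all
#'   subjects).
#' @param seed Integer seed.
#' @return A data frame with columns `sample_id`, `n_cells_imaged`,
#'   `n_marker_pos`, `n_igg_pos`, `pct_igg_pos`, `mean_intden`,
#'   `evaluable`.
#' @export
simulate_sample_summaries <- function(cohort, cells_per_subject = 73,
                                      marker_pos_frac = 0.8,
                                      intden_cv = 0.25,
                                      binding = c("sgc", "neuron"),
                                      seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  binding <- match.arg(binding)
  cfg <- attr(cohort, "config")
  with_seed(seed, {
    n <- nrow(cohort)
    frac <- if (binding == "sgc") cohort$igg_frac_true
            else rep(cfg$igg_link[["base"]], n)
    n_cells <- stats::rpois(n, cells_per_subject)
    n_marker <- stats::rbinom(n, n_cells, marker_pos_frac)
    n_igg <- stats::rbinom(n, n_marker, frac)
    m <- if (binding == "sgc") cfg$intden_base * exp(cfg$intden_zslope * cohort$latent_sgc)
         else rep(cfg$intden_base, n)
    # per-cell suprathreshold integrated density ~ area x amplitude; the
    # per-sample mean averages over all marker-positive cells (zeros for
    # unbound cells), matching the scoring convention downstream
    total_intden <- vapply(seq_len(n), function(i) {
      if (n_igg[i] == 0L) return(0)
      sum(pmax(0, stats::rnorm(n_igg[i], m[i], intden_cv * m[i])) * 30)
    }, numeric(1))
    data.frame(
      sample_id = cohort$subject_id,
      n_cells_imaged = n_cells,
      n_marker_pos = n_marker,
      n_igg_pos = n_igg,
      pct_igg_pos = ifelse(n_marker > 0, 100 * n_igg / n_marker, NA_real_),
      mean_intden = ifelse(n_marker > 0, total_intden / n_marker, NA_real_),
      evaluable = n_marker > 0
    )
  })
}

#' Write a cohort table to CSV
#' @param cohort Result of [simulate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
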