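#' Mixed-model slope recovery study
#'
#' Generates many independent synthetic SSPT cohorts with a known planted
#' slope of the focal-minus-other combined score on sucrose
#' concentration, runs each cohort through the scoring pipeline
#' (rasterization, tabulation, occupancy normalization, delta scores)
#' and the random-intercept mixed model, and reports the estimated
#' slopes and the coverage of their confidence intervals.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param seed Master seed; each replicate derives its own substream.
#' @param n_animals Animals per cohort.
#' @param dcvs_slope Planted slope (frames/s per sucrose %).
#' @param trial_duration Trial length (s).
#' @param conf_level CI level passed to [fit_mixed_model()].
#' @return List: `fits` (tibble with one row per replicate: `slope`,
#'   `ci_lo`, `ci_hi`, `covered`, `singular`), `mean_slope`,
#'   `coverage`, `true_slope`.
#' @export
slope_recovery_study <- function(n_replicates = 500, seed = 1,
                                 n_animals = 8, dcvs_slope = 0.034,
                                 trial_duration = 600,
                                 conf_level = 0.95) {
  sspt_grid <- tibble::tibble(task = "SSPT",
                              condition = c("Jv2", "Jv5", "Jv10"),
                              day = 1:3)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_animals = n_animals, trials = sspt_grid,
                      trial_duration = trial_duration,
                      seed = trial_seed(seed, "replicate", r))
    cohort <- generate_cohort(cfg, dcvs_slope = dcvs_slope,
                              positions = FALSE)
    scored <- score_cohort(cohort, zone_source = "truth")
    d <- cohort_delta_scores(scored, "SSPT")
    fit <- withCallingHandlers(
      fit_mixed_model(d$dcvs, "dcvs", conf_level = conf_level),
      warning = function(w) invokeRestart("muffleWarning"))
    rows[[r]] <- tibble::tibble(
      slope = fit$slope, ci_lo = fit$ci[1], ci_hi = fit$ci[2],
      covered = fit$ci[1] <= dcvs_slope & dcvs_slope <= fit$ci[2],
      singular = fit$singular)
  }
  fits <- do.call(rbind, rows)
  list(fits = fits,
       mean_slope = mean(fits$slope),
       coverage = mean(fits$covered),
       true_slope = dcvs_slope)
}
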