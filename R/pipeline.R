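#' Pipeline run configuration
#'
#' @param input_mode `"synthetic"` (generate a cohort) or `"files"`
#'   (read a cohort directory written by [write_cohort()] or assembled
#'   from annotation/tracking exports in the same layout).
#' @param data_dir Cohort directory (file mode).
#' @param outdir Output directory for the report bundle.
#' @param threshold Subtype inclusion threshold in percent of call
#'   frames.
#' @param seed Master seed (synthetic mode).
#' @param n_animals Animals in the synthetic cohort.
#' @param trial_duration,frame_rate Trial parameters (synthetic mode).
#' @return A `run_config`.
#' @export
run_config <- function(input_mode = c("synthetic", "files"),
                       data_dir = NULL, outdir = tempfile("usvrun"),
                       threshold = 2, seed = 1, n_animals = 8,
                       trial_duration = 600, frame_rate = 25) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "files") {
    if (is.null(data_dir) || !dir.exists(data_dir))
      stop("file mode requires an existing data_dir")
  }
  structure(list(input_mode = input_mode, data_dir = data_dir,
                 outdir = outdir, threshold = threshold, seed = seed,
                 n_animals = n_animals, trial_duration = trial_duration,
                 frame_rate = frame_rate),
            class = "run_config")
}

#' Vocal statistics battery on a scored cohort
#'
#' Subtype prevalence filter, log-CVS repeated-measures ANOVAs
#' (condition x reward zone, per task), between-subtype Kruskal-Wallis
#' on dSVS per condition, within-subtype Wilcoxon (SDT) and Friedman
#' (SSPT) tests over the included subtypes, and random-intercept mixed
#' models of dCVS and per-subtype dSVS on sucrose concentration.
#'
#' @param scored Result of [score_cohort()].
#' @param threshold Subtype inclusion threshold (%).
#' @return List: `filter`, `anova` (tibble), `between_subtype` (tibble),
#'   `within_subtype` (tibble), `mixed` (tibble), `notes` (character).
#' @export
run_vocal_stats <- function(scored, threshold = 2) {
  filt <- subtype_filter(scored$pooled_counts, threshold)
  notes <- character(0)
  tasks <- unique(scored$zone_scores$task)

  anova_rows <- list()
  for (task in intersect(c("SDT", "SSPT"), tasks)) {
    zs <- scored$zone_scores
    zs <- zs[zs$task == task & zs$role %in% c("focal", "other") &
               !is.na(zs$cvs), ]
    n_cells <- length(unique(zs$condition)) * 2
    per_animal <- table(zs$animal)
    keep <- names(per_animal)[per_animal == n_cells]
    if (length(keep) < length(per_animal))
      notes <- c(notes, sprintf(
        "%s CVS ANOVA: dropped %d animal(s) with unvisited zones",
        task, length(per_animal) - length(keep)))
    zs <- zs[zs$animal %in% keep, ]
    if (length(keep) < 2 || length(unique(zs$condition)) < 2) {
      notes <- c(notes, sprintf(
        "%s CVS ANOVA skipped: design incomplete", task))
      next
    }
    zs$log_cvs_dv <- log_cvs(zs$cvs)
    an <- rm_anova_within(zs, dv = "log_cvs_dv",
                          within = c("condition", "role"),
                          subject = "animal")
    an$task <- task
    anova_rows[[task]] <- an
  }

  deltas <- list()
  for (task in intersect(c("SDT", "SSPT"), tasks))
    deltas[[task]] <- cohort_delta_scores(scored, task)

  between <- list(); within <- list(); mixed_rows <- list()
  if (length(filt$included) == 0) {
    notes <- c(notes, "no subtypes included at threshold; subtype stats skipped")
  } else {
    for (task in names(deltas)) {
      dsv <- deltas[[task]]$dsvs
      dsv <- dsv[dsv$subtype %in% filt$included & !is.na(dsv$dsvs), ]
      for (cond in unique(dsv$condition)) {
        sub <- dsv[dsv$condition == cond, ]
        if (length(unique(sub$subtype)) < 2) next
        kt <- rank_test("kruskal_wallis", sub$dsvs, sub$subtype)
        kt$task <- task; kt$condition <- cond
        between[[paste(task, cond)]] <- kt
      }
      conds <- sort(unique(dsv$condition))
      for (st in unique(dsv$subtype)) {
        sub <- dsv[dsv$subtype == st, ]
        wtab <- stats::reshape(
          as.data.frame(sub[, c("animal", "condition", "dsvs")]),
          idvar = "animal", timevar = "condition", direction = "wide")
        mat <- as.matrix(wtab[, -1, drop = FALSE])
        mat <- mat[stats::complete.cases(mat), , drop = FALSE]
        if (nrow(mat) < 2) next
        res <- if (task == "SDT" && ncol(mat) == 2) {
          rank_test("wilcoxon_signed_rank", mat[, 1], mat[, 2])
        } else if (ncol(mat) >= 3) {
          rank_test("friedman", mat)
        } else NULL
        if (!is.null(res)) {
          res$task <- task; res$subtype <- st
          within[[paste(task, st)]] <- res
        }
      }
    }
    if ("SSPT" %in% names(deltas)) {
      fit_one <- function(data, dv, label) {
        data <- data[!is.na(data[[dv]]), ]
        n_per <- tapply(data$condition, data$animal,
                        function(v) length(unique(v)))
        data <- data[data$animal %in%
                       names(n_per)[!is.na(n_per) & n_per >= 2], ]
        if (nrow(data) < 4 || length(unique(data$animal)) < 2)
          return(NULL)
        fit <- withCallingHandlers(
          fit_mixed_model(data, dv = dv),
          warning = function(w) invokeRestart("muffleWarning"))
        tibble::tibble(
          dv = label, slope = fit$slope, ci_lo = fit$ci[1],
          ci_hi = fit$ci[2], t = fit$t, df = fit$df, p = fit$p,
          r2_marginal = fit$r2_marginal, method = fit$method)
      }
      mixed_rows[["dCVS"]] <- fit_one(deltas$SSPT$dcvs, "dcvs", "dCVS")
      dsv <- deltas$SSPT$dsvs
      for (st in filt$included) {
        mixed_rows[[st]] <- fit_one(dsv[dsv$subtype == st, ], "dsvs",
                                    paste0("dSVS_", st))
      }
    }
  }
  list(filter = filt,
       anova = if (length(anova_rows)) do.call(rbind, anova_rows),
       between_subtype = if (length(between)) do.call(rbind, between),
       within_subtype = if (length(within)) do.call(rbind, within),
       mixed = if (length(mixed_rows)) do.call(rbind, mixed_rows),
       notes = notes)
}

#' Behavioral statistics battery on a scored cohort
#'
#' Preference scores per trial (focal vs other reward-zone time), the
#' one-way repeated-measures ANOVA on SSPT juvenile preference with
#' Bonferroni post hocs, one-sample t tests vs indifference (50%) per
#' SSPT condition, and paired t tests on absolute zone times.
#'
#' @param scored Result of [score_cohort()].
#' @return List: `preference` (tibble per animal x condition), `anova`,
#'   `posthoc`, `vs_indifference` (tibble), `paired_zone_time` (tibble).
#' @export
run_behavior_stats <- function(scored) {
  zs <- scored$zone_scores[scored$zone_scores$role != "neutral", ]
  wide <- merge(
    zs[zs$role == "focal",
       c("animal", "task", "condition", "occupancy_seconds")],
    zs[zs$role == "other",
       c("animal", "task", "condition", "occupancy_seconds")],
    by = c("animal", "task", "condition"), suffixes = c("_focal", "_other"))
  wide$preference <- preference_score(wide$occupancy_seconds_focal,
                                      wide$occupancy_seconds_other)
  pref <- tibble::as_tibble(wide)

  sspt <- pref[pref$task == "SSPT" & !is.na(pref$preference), ]
  anova <- NULL; posthoc <- NULL; vs50 <- NULL; paired <- NULL
  if (nrow(sspt) > 0 && length(unique(sspt$condition)) >= 2) {
    n_cond <- length(unique(sspt$condition))
    per_animal <- table(sspt$animal)
    complete <- sspt[sspt$animal %in%
                       names(per_animal)[per_animal == n_cond], ]
    if (length(unique(complete$animal)) >= 2) {
      anova <- rm_anova_within(complete, dv = "preference",
                               within = "condition",
                               subject = "animal")
      posthoc <- posthoc_pairwise(complete, dv = "preference",
                                  factor_col = "condition",
                                  subject = "animal")
    }
    rows <- list(); prows <- list()
    for (cond in sort(unique(sspt$condition))) {
      sub <- sspt[sspt$condition == cond, ]
      if (nrow(sub) < 2) next
      tt <- usv_t_test("one_sample", sub$preference, mu = 50)
      tt$condition <- cond
      rows[[cond]] <- tt
      pt <- usv_t_test("paired", sub$occupancy_seconds_focal,
                       sub$occupancy_seconds_other)
      pt$condition <- cond
      prows[[cond]] <- pt
    }
    vs50 <- if (length(rows)) do.call(rbind, rows)
    paired <- if (length(prows)) do.call(rbind, prows)
  }
  list(preference = pref, anova = anova, posthoc = posthoc,
       vs_indifference = vs50, paired_zone_time = paired)
}

#' Run the full pipeline
#'
#' simulate/ingest -> synchronize -> score -> analyze -> report. All
#' outputs land in `config$outdir`: score tables, statistics tables, a
#' filter report, a plain-text run log with exclusion accounting, and an
#' echo of the configuration. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Report bundle (list with `scored`, `vocal`, `behavior`,
#'   `outdir`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("usvscore pipeline run, seed %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("ingest", {
    if (config$input_mode == "synthetic") {
      sc <- sim_config(n_animals = config$n_animals,
                       trial_duration = config$trial_duration,
                       frame_rate = config$frame_rate,
                       seed = config$seed)
      generate_cohort(sc)
    } else {
      read_cohort(config$data_dir)
    }
  })
  log_lines <- c(log_lines,
                 sprintf("ingest: %d trials", nrow(cohort$manifest)))

  scored <- stage("score", score_cohort(cohort))
  ex <- scored$exclusions
  log_lines <- c(log_lines,
    sprintf("score: excluded %d 22-kHz frames", ex[["frames_22k"]]),
    sprintf("score: %d Unclear frames (in CVS, out of subtype stats)",
            ex[["frames_unclear"]]),
    sprintf("score: excluded %d neutral/sandpaper-zone call frames",
            ex[["frames_neutral"]]),
    sprintf("score: excluded %d tracking-gap frames",
            ex[["frames_gap"]]))

  # the score CSVs are the interface between stages: write them first and
  # analyze from the written tables, so re-running the analyze stage on a
  # saved score bundle reproduces the stats tables bit-exactly
  stage("score", {
    write_scores_table(scored$zone_scores,
                       file.path(config$outdir, "zone_scores.csv"))
    write_scores_table(scored$svs, file.path(config$outdir, "svs.csv"))
  })
  scored_io <- stage("analyze", {
    sv <- read_scores_table(file.path(config$outdir, "svs.csv"))
    pooled <- tapply(sv$frames, sv$subtype, sum)
    list(zone_scores = read_scores_table(file.path(config$outdir,
                                                   "zone_scores.csv")),
         svs = sv,
         pooled_counts = stats::setNames(as.numeric(pooled),
                                         names(pooled)),
         exclusions = scored$exclusions)
  })
  vocal <- stage("analyze", run_vocal_stats(scored_io, config$threshold))
  nf <- vocal$filter
  log_lines <- c(log_lines,
    sprintf("analyze: %d subtypes included at %.3g%% threshold (%s)",
            length(nf$included), nf$threshold_percent,
            if (length(nf$included)) paste(nf$included, collapse = ", ")
            else "none"),
    sprintf("analyze: excluded subtype frames below threshold: %d",
            sum(nf$prevalence$frames[!nf$prevalence$included &
                                       nf$prevalence$subtype != "Unclear"])),
    vocal$notes)
  behavior <- stage("analyze", run_behavior_stats(scored_io))

  stage("report", {
    write_scores_table(nf$prevalence,
                       file.path(config$outdir, "filter_report.csv"))
    write_scores_table(behavior$preference,
                       file.path(config$outdir, "preference.csv"))
    for (nmx in c("anova", "between_subtype", "within_subtype", "mixed")) {
      tab <- vocal[[nmx]]
      if (!is.null(tab))
        write_scores_table(tab, file.path(config$outdir,
                                          paste0("stats_", nmx, ".csv")))
    }
    for (nmx in c("anova", "posthoc", "vs_indifference",
                  "paired_zone_time")) {
      tab <- behavior[[nmx]]
      if (!is.null(tab))
        write_scores_table(tab, file.path(config$outdir,
                                          paste0("behavior_", nmx,
                                                 ".csv")))
    }
    writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
    yaml::write_yaml(unclass(config),
                     file.path(config$outdir, "config_echo.yaml"))
  })
  invisible(list(cohort = cohort, scored = scored, vocal = vocal,
                 behavior = behavior, outdir = config$outdir,
                 log = log_lines))
}

#' Re-run the statistics stage from saved score tables
#'
#' Reads `zone_scores.csv` and `svs.csv` from a previous run's output
#' directory and recomputes the statistics tables; with the same
#' threshold this reproduces the saved stats bit-exactly.
#'
#' @param outdir Directory holding `zone_scores.csv` and `svs.csv`.
#' @param threshold Subtype inclusion threshold (%).
#' @return As [run_vocal_stats()].
#' @export
reanalyze_scores <- function(outdir, threshold = 2) {
  zs <- read_scores_table(file.path(outdir, "zone_scores.csv"))
  sv <- read_scores_table(file.path(outdir, "svs.csv"))
  pooled <- tapply(sv$frames, sv$subtype, sum)
  pooled_v <- stats::setNames(as.numeric(pooled), names(pooled))
  scored <- list(zone_scores = zs, svs = sv, pooled_counts = pooled_v,
                 exclusions = c(frames_22k = NA, frames_unclear = NA,
                                frames_neutral = NA, frames_gap = NA))
  run_vocal_stats(scored, threshold)
}
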