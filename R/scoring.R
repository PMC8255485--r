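#' Behavioral preference score
#'
#' Percentage of reward-zone time spent in the focal zone: the higher
#' sucrose zone for the sucrose discrimination test, the juvenile zone for
#' the social-sucrose preference test. Neutral-platform time never enters.
#'
#' @param t_focal,t_other Zone times in seconds (vectorized, >= 0).
#' @return Percentage in `[0, 100]`; `NA` where both times are zero
#'   (undefined preference, flagged missing rather than scored 0).
#' @export
preference_score <- function(t_focal, t_other) {
  stopifnot(all(t_focal >= 0, na.rm = TRUE),
            all(t_other >= 0, na.rm = TRUE))
  tot <- t_focal + t_other
  ifelse(tot > 0, 100 * t_focal / tot, NA_real_)
}

#' Combined vocalization score (CVS)
#'
#' Call frames per second of zone occupancy, over the 15-subtype universe
#' (the fourteen 50-kHz subtypes plus Unclear; 22-kHz calls excluded).
#'
#' @param total_call_frames Call-frame count (non-22-kHz).
#' @param occupancy_seconds Zone occupancy (s).
#' @return Rate in frames/s; `NA` where occupancy is zero (undefined).
#' @export
cvs <- function(total_call_frames, occupancy_seconds) {
  stopifnot(all(total_call_frames >= 0, na.rm = TRUE))
  ifelse(occupancy_seconds > 0, total_call_frames / occupancy_seconds,
         NA_real_)
}

#' Log-transformed CVS
#'
#' Natural log with a small offset so zero rates stay finite:
#' `ln(cvs + eps)`. The default offset, 0.001 frames/s, is a floor of one
#' call frame per 1000 s of occupancy.
#'
#' @param x CVS value(s), >= 0.
#' @param eps Offset in frames/s.
#' @return `ln(x + eps)`.
#' @export
log_cvs <- function(x, eps = 0.001) {
  if (any(x < 0, na.rm = TRUE)) stop("negative vocalization score")
  log(x + eps)
}

#' Per-subtype vocalization scores (SVS) from tabulated counts
#'
#' `SVS[zone, subtype] = call frames / occupancy seconds`. Summing SVS
#' over the 15-subtype universe recovers the zone's CVS.
#'
#' @param counts A [tabulate_zone_subtypes()] result.
#' @return Tibble `zone`, `subtype`, `frames`, `occupancy_seconds`,
#'   `svs`; zones with zero occupancy get `NA` scores.
#' @export
svs_table <- function(counts) {
  stopifnot(inherits(counts, "zone_subtype_counts"))
  occ <- counts$occupancy
  grid <- expand.grid(zone = occ$zone, subtype = usv_vocabulary(),
                      stringsAsFactors = FALSE)
  key <- paste(counts$counts$zone, counts$counts$subtype)
  m <- match(paste(grid$zone, grid$subtype), key)
  grid$frames <- ifelse(is.na(m), 0L, counts$counts$frames[m])
  grid$occupancy_seconds <-
    occ$occupancy_seconds[match(grid$zone, occ$zone)]
  grid$svs <- cvs(grid$frames, grid$occupancy_seconds)
  tibble::as_tibble(grid)
}

#' Zone-level score summary for one trial
#'
#' @param counts A [tabulate_zone_subtypes()] result.
#' @return Tibble per zone: occupancy seconds, non-22-kHz call frames,
#'   `cvs`, `log_cvs`.
#' @export
trial_scores <- function(counts) {
  sv <- svs_table(counts)
  sv50 <- sv[sv$subtype %in% cvs_subtypes(), ]
  agg <- stats::aggregate(frames ~ zone, data = sv50, FUN = sum)
  occ <- counts$occupancy
  out <- tibble::tibble(
    zone = agg$zone,
    occupancy_seconds = occ$occupancy_seconds[match(agg$zone, occ$zone)],
    call_frames = agg$frames
  )
  out$cvs <- cvs(out$call_frames, out$occupancy_seconds)
  out$log_cvs <- ifelse(is.na(out$cvs), NA_real_, log_cvs(out$cvs))
  out
}

#' Between-zone score differences (dCVS / dSVS)
#'
#' The within-subject contrast of a trial: focal-zone score minus
#' other-zone score, where focal is the higher sucrose zone (SDT) or the
#' social zone (SSPT). Antisymmetric under zone swap; missing if either
#' zone's score is undefined.
#'
#' @param focal,other Score values (CVS or SVS; vectorized).
#' @return `focal - other`, `NA` propagating.
#' @export
delta_score <- function(focal, other) {
  focal - other
}

#' Subtype prevalence filter
#'
#' Computes each subtype's share of pooled call frames and keeps those at
#' or above the threshold. The denominator is all non-22-kHz call frames
#' (Unclear included); Unclear itself is always excluded from the
#' included set because unclassifiable calls enter no subtype analysis.
#'
#' @param pooled_counts Named numeric vector: call frames per subtype,
#'   pooled over trials and tasks.
#' @param threshold_percent Inclusion cut-off (default 2).
#' @return A `subtype_filter` list: `prevalence` (tibble `subtype`,
#'   `frames`, `prevalence_pct`, `included`), `included`, `excluded`,
#'   `threshold_percent`.
#' @export
subtype_filter <- function(pooled_counts, threshold_percent = 2) {
  st <- names(pooled_counts)
  if (is.null(st) || !all(st %in% usv_vocabulary()))
    stop("pooled_counts must be named by vocabulary subtypes")
  stopifnot(all(pooled_counts >= 0))
  universe <- cvs_subtypes()
  frames <- stats::setNames(numeric(length(universe)), universe)
  frames[intersect(st, universe)] <-
    pooled_counts[intersect(st, universe)]
  denom <- sum(frames)
  if (denom == 0) stop("no call frames: prevalence undefined")
  prev <- 100 * frames / denom
  included <- names(prev)[prev >= threshold_percent & frames > 0 &
                            names(prev) != "Unclear"]
  structure(list(
    prevalence = tibble::tibble(subtype = universe,
                                frames = unname(frames),
                                prevalence_pct = unname(prev),
                                included = universe %in% included),
    included = included,
    excluded = setdiff(universe, included),
    threshold_percent = threshold_percent
  ), class = "subtype_filter")
}

#' Score a cohort of synchronized trials
#'
#' Runs rasterization, zone assignment and tabulation for every trial of
#' a cohort (in-memory or read from disk) and assembles the per
#' animal x condition x zone score table plus per-subtype SVS rows.
#'
#' @param cohort A `usv_cohort` or the list returned by [read_cohort()].
#' @param maps Named list of zone maps per group (defaults to groups A
#'   and B with default geometry).
#' @param frame_rate,duration Raster parameters; taken from the cohort
#'   when present.
#' @param zone_source `"tracks"` (default: assign zones from the
#'   tracking table via [assign_zones()]) or `"truth"` (use the
#'   generator's stored zone timeline; only available for in-memory
#'   synthetic cohorts, used in large simulation studies).
#' @return List: `zone_scores` (tibble with one row per trial x reward
#'   zone/neutral: occupancy, call frames, cvs, log_cvs, role),
#'   `svs` (tibble per trial x zone x subtype), `pooled_counts` (named
#'   vector of call frames per subtype over both reward zones),
#'   `exclusions` (audit counts: 22-kHz frames, unclear frames, neutral
#'   frames, gap frames).
#' @export
score_cohort <- function(cohort, maps = NULL, frame_rate = NULL,
                         duration = NULL,
                         zone_source = c("tracks", "truth")) {
  zone_source <- match.arg(zone_source)
  manifest <- cohort$manifest
  fr <- frame_rate %||% cohort$params$frame_rate %||% cohort$frame_rate
  dur <- duration %||% cohort$params$trial_duration %||%
    cohort$trial_duration
  if (is.null(maps))
    maps <- list(A = make_zone_map("A"), B = make_zone_map("B"))

  zone_rows <- list(); svs_rows <- list()
  pooled <- stats::setNames(numeric(length(usv_vocabulary())),
                            usv_vocabulary())
  excl <- c(frames_22k = 0, frames_unclear = 0, frames_neutral = 0,
            frames_gap = 0)

  for (i in seq_len(nrow(manifest))) {
    key <- manifest$key[i]
    trial <- cohort$trials[[key]]
    map <- maps[[manifest$group[i]]]
    zones_cond <- condition_zones(manifest$condition[i], map)

    frames <- rasterize_labels(trial$labels, fr, dur)
    ztl <- if (zone_source == "truth") {
      if (is.null(trial$zone_frames))
        stop("cohort carries no ground-truth zone timeline for ", key)
      trial$zone_frames
    } else {
      assign_zones(trial$tracks, map, fr, dur)
    }
    tab <- tabulate_zone_subtypes(frames, ztl, fr)

    excl["frames_gap"] <- excl["frames_gap"] + tab$n_gap_frames
    lab_n <- tab$counts
    excl["frames_22k"] <- excl["frames_22k"] +
      sum(lab_n$frames[lab_n$subtype == "22kHz"])
    excl["frames_unclear"] <- excl["frames_unclear"] +
      sum(lab_n$frames[lab_n$subtype == "Unclear"])
    excl["frames_neutral"] <- excl["frames_neutral"] +
      sum(lab_n$frames[!(lab_n$zone %in% zones_cond)])

    ts <- trial_scores(tab)
    role <- ifelse(ts$zone == zones_cond[["focal"]], "focal",
                   ifelse(ts$zone == zones_cond[["other"]], "other",
                          "neutral"))
    meta <- manifest[i, c("animal", "task", "condition", "day", "group")]
    zr <- cbind(meta[rep(1, nrow(ts)), ], ts, role = role)
    zone_rows[[key]] <- zr

    sv <- svs_table(tab)
    sv <- sv[sv$zone %in% zones_cond, ]
    sv$role <- ifelse(sv$zone == zones_cond[["focal"]], "focal", "other")
    svs_rows[[key]] <- cbind(meta[rep(1, nrow(sv)), ], sv)

    in_reward <- lab_n$zone %in% zones_cond
    if (any(in_reward)) {
      agg <- tapply(lab_n$frames[in_reward], lab_n$subtype[in_reward],
                    sum)
      pooled[names(agg)] <- pooled[names(agg)] + agg
    }
  }
  list(zone_scores = tibble::as_tibble(do.call(rbind, zone_rows)),
       svs = tibble::as_tibble(do.call(rbind, svs_rows)),
       pooled_counts = pooled,
       exclusions = excl)
}

#' Per animal x condition delta scores from a scored cohort
#'
#' @param scored Result of [score_cohort()].
#' @param task `"SDT"` or `"SSPT"`.
#' @return List: `dcvs` (tibble `animal`, `condition`, `sucrose`,
#'   `cvs_focal`, `cvs_other`, `dcvs`), `dsvs` (tibble `animal`,
#'   `condition`, `subtype`, `dsvs`).
#' @export
cohort_delta_scores <- function(scored, task = "SSPT") {
  zs <- scored$zone_scores[scored$zone_scores$task == task &
                             scored$zone_scores$role != "neutral", ]
  wide <- merge(
    zs[zs$role == "focal", c("animal", "condition", "cvs")],
    zs[zs$role == "other", c("animal", "condition", "cvs")],
    by = c("animal", "condition"), suffixes = c("_focal", "_other"),
    all = TRUE)
  wide$dcvs <- delta_score(wide$cvs_focal, wide$cvs_other)
  if (task == "SSPT") wide$sucrose <- sspt_sucrose_level(wide$condition)

  sv <- scored$svs[scored$svs$task == task, ]
  svw <- merge(
    sv[sv$role == "focal", c("animal", "condition", "subtype", "svs")],
    sv[sv$role == "other", c("animal", "condition", "subtype", "svs")],
    by = c("animal", "condition", "subtype"),
    suffixes = c("_focal", "_other"), all = TRUE)
  svw$dsvs <- delta_score(svw$svs_focal, svw$svs_other)
  if (task == "SSPT") svw$sucrose <- sspt_sucrose_level(svw$condition)
  list(dcvs = tibble::as_tibble(wide), dsvs = tibble::as_tibble(svw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
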