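#' Simulation configuration for a synthetic cohort
#'
#' Describes the trial grid of a synthetic study: which animals run which
#' task/condition/day, trial duration and raster rate. The default grid
#' mirrors the labeled portion of the study design: per animal, two
#' sucrose-discrimination (SDT) conditions and three social-sucrose
#' preference (SSPT) conditions.
#'
#' @param n_animals Number of experimental animals.
#' @param trials Data frame with columns `task`, `condition`, `day`; one
#'   row per trial every animal performs. Conditions must be legal for
#'   their task (see [task_conditions()]).
#' @param trial_duration Trial length in seconds (default 600).
#' @param frame_rate Raster rate in Hz (default 25).
#' @param seed Master seed; per-trial substreams are derived from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_animals = 8,
                       trials = default_trial_grid(),
                       trial_duration = 600, frame_rate = 25, seed = 1) {
  stopifnot(n_animals >= 1, trial_duration > 0, frame_rate > 0)
  stopifnot(all(c("task", "condition", "day") %in% names(trials)))
  for (i in seq_len(nrow(trials))) {
    ok <- trials$condition[i] %in% task_conditions(trials$task[i])
    if (!ok) stop("condition ", trials$condition[i],
                  " not legal for task ", trials$task[i])
  }
  key <- paste(trials$task, trials$condition, trials$day)
  if (anyDuplicated(key))
    stop("duplicate (task, condition, day) keys in trial grid")
  structure(list(n_animals = as.integer(n_animals), trials = trials,
                 trial_duration = trial_duration, frame_rate = frame_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_trial_grid <- function() {
  tibble::tibble(
    task = c("SDT", "SDT", "SSPT", "SSPT", "SSPT"),
    condition = c("2v10", "5v10", "Jv2", "Jv5", "Jv10"),
    day = c(2L, 3L, 1L, 2L, 3L)
  )
}

#' Zone-dwell occupancy model
#'
#' A semi-Markov shuttle process over \{focal reward zone, other reward
#' zone, neutral platform\}: exponential dwell in the current zone, then a
#' transition. Reward-to-reward moves always pass through the neutral
#' platform, so from neutral the animal picks the focal zone with a
#' probability chosen such that the long-run fraction of reward-zone time
#' spent in the focal zone equals `target_preference`.
#'
#' @param target_preference Long-run fraction of reward-zone time in the
#'   focal zone, in `[0, 1]`.
#' @param mean_dwell_focal,mean_dwell_other,mean_dwell_neutral Mean dwell
#'   times (s) per visit.
#' @return An `occupancy_model` with the derived transition matrix.
#' @export
occupancy_model <- function(target_preference,
                            mean_dwell_focal = 20, mean_dwell_other = 20,
                            mean_dwell_neutral = 5) {
  stopifnot(target_preference >= 0, target_preference <= 1,
            mean_dwell_focal > 0, mean_dwell_other > 0,
            mean_dwell_neutral > 0)
  p <- target_preference
  mf <- mean_dwell_focal; mo <- mean_dwell_other
  # choose focal with probability q so that q*mf / (q*mf + (1-q)*mo) = p
  q <- if (p == 0) 0 else if (p == 1) 1 else p * mo / (p * mo + (1 - p) * mf)
  trans <- rbind(focal = c(0, 0, 1),
                 other = c(0, 0, 1),
                 neutral = c(q, 1 - q, 0))
  colnames(trans) <- c("focal", "other", "neutral")
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-12))
  structure(list(target_preference = p,
                 mean_dwell = c(focal = mf, other = mo,
                                neutral = mean_dwell_neutral),
                 transition = trans),
            class = "occupancy_model")
}

#' Default occupancy models per condition
#'
#' Focal-zone preferences and neutral dwell calibrated to the group-mean
#' zone times of the study conditions (e.g. Juvenile-vs-10%: about 98 s
#' juvenile vs 408 s sucrose, hence a focal preference near 0.19 and about
#' 16% of the trial on the neutral platform). The focal zone is the
#' higher sucrose for SDT and the juvenile for SSPT.
#'
#' @return Named list of [occupancy_model()]s keyed by condition.
#' @export
default_occupancy_models <- function() {
  list(
    "2v5"  = occupancy_model(0.65, mean_dwell_neutral = 5),
    "2v10" = occupancy_model(0.70, mean_dwell_neutral = 5),
    "5v10" = occupancy_model(0.70, mean_dwell_neutral = 5),
    "Jv2"  = occupancy_model(0.62, mean_dwell_neutral = 8.7),
    "Jv5"  = occupancy_model(0.55, mean_dwell_neutral = 6.4),
    "Jv10" = occupancy_model(0.19, mean_dwell_neutral = 3.7)
  )
}

#' Call emission model
#'
#' Calls are emitted as a Poisson process whose rate depends on the zone
#' role the animal currently occupies (focal reward, other reward,
#' neutral), with the subtype drawn from the zone's rate mix and the call
#' duration from a per-subtype truncated normal. Generated calls are
#' thinned so that no two calls overlap or share a raster frame (the
#' one-hot constraint of the label raster).
#'
#' @param rates Numeric matrix, rows = subtypes (full 16-symbol
#'   vocabulary), columns = `focal`, `other`, `neutral`; calls per second
#'   of occupancy. All entries must be finite and >= 0.
#' @param durations Data frame with columns `subtype`, `mean`, `sd`,
#'   `min` (seconds).
#' @return An `emission_model`.
#' @export
emission_model <- function(rates, durations) {
  stopifnot(is.matrix(rates), all(is.finite(rates)), all(rates >= 0),
            all(colnames(rates) == c("focal", "other", "neutral")),
            setequal(rownames(rates), usv_vocabulary()))
  stopifnot(all(c("subtype", "mean", "sd", "min") %in% names(durations)),
            all(durations$mean > 0), all(durations$min > 0))
  structure(list(rates = rates[usv_vocabulary(), , drop = FALSE],
                 durations = durations),
            class = "emission_model")
}

#' @rdname emission_model
#' @details `default_call_durations()` gives 50-kHz calls a 30-40 ms
#'   duration scale and 22-kHz calls a 1-3 s scale.
#' @export
default_call_durations <- function() {
  st <- usv_vocabulary()
  tibble::tibble(
    subtype = st,
    mean = ifelse(st == "22kHz", 2.0, 0.035),
    sd = ifelse(st == "22kHz", 0.5, 0.005),
    min = ifelse(st == "22kHz", 0.5, 0.02)
  )
}

#' Default subtype mix of the 50-kHz repertoire
#'
#' Relative frame-count weights over the 15 non-22-kHz subtypes,
#' calibrated to the pooled subtype prevalences of the study (Trill and
#' Flat most prevalent; six rare subtypes each near 1%). Weights are
#' normalized to sum to 1.
#'
#' @param trill_shift Amount of weight moved from Flat to Trill (used for
#'   zone-asymmetric mixes: the social zone tilts toward Trill).
#' @return Named numeric vector over [cvs_subtypes()].
#' @export
default_subtype_mix <- function(trill_shift = 0) {
  w <- c("Trill" = 27.2, "Flat" = 24.4, "Complex" = 11.5,
         "Composite" = 11.3, "Short" = 5.5,
         "Flat-Trill-combination" = 4.0, "Split" = 3.4,
         "Trill-with-Jump" = 2.2, "Unclear" = 3.9,
         "Step-Down" = 1.1, "Inverted-U" = 1.1, "Step-Up" = 1.1,
         "Multi-Step" = 1.1, "Downward-Ramp" = 1.1, "Upward-Ramp" = 1.1)
  w <- w / sum(w)
  shift <- min(trill_shift, w[["Flat"]] * 0.9)
  w[["Trill"]] <- w[["Trill"]] + shift
  w[["Flat"]] <- w[["Flat"]] - shift
  w[cvs_subtypes()]
}

#' Expected raster frames occupied by a call of a given duration
#'
#' A call of duration `d` with uniform phase relative to the frame grid
#' overlaps `d * frame_rate + 1` frames in expectation (any positive
#' overlap labels a frame).
#'
#' @param mean_dur Mean call duration (s).
#' @param frame_rate Raster rate (Hz).
#' @return Expected frames per call.
#' @keywords internal
expected_frames_per_call <- function(mean_dur, frame_rate = 25) {
  mean_dur * frame_rate + 1
}

#' Convert a target occupancy-normalized frame rate into call rates
#'
#' Distributes a target combined vocalization score `F` (call frames per
#' second of occupancy) over subtypes according to a mix, converting to
#' call rates via the expected frames per call.
#'
#' @param frame_score Target frames/s over the 15-subtype universe.
#' @param mix Named weights over [cvs_subtypes()] summing to 1.
#' @param durations Duration table (see [emission_model()]).
#' @param frame_rate Raster rate (Hz).
#' @return Named call-rate vector (calls/s) over [cvs_subtypes()].
#' @export
call_rates_for_frame_score <- function(frame_score, mix,
                                       durations = default_call_durations(),
                                       frame_rate = 25) {
  stopifnot(frame_score >= 0, abs(sum(mix) - 1) < 1e-8)
  st <- cvs_subtypes()
  md <- durations$mean[match(st, durations$subtype)]
  frame_score * mix[st] / expected_frames_per_call(md, frame_rate)
}

#' Default emission model for a condition
#'
#' The zone-specific combined scores are calibrated to the study's group
#' means: in SSPT the focal (juvenile) zone score exceeds the sucrose-zone
#' score by an amount that grows linearly with the competing sucrose
#' concentration (`dcvs_intercept + dcvs_slope * sucrose%`); in SDT the
#' lower-sucrose zone carries the higher score. 22-kHz calls are emitted
#' at a low rate everywhere such that their (long) calls contribute
#' roughly a fifth of all call frames.
#'
#' @param condition Condition code.
#' @param dcvs_slope SSPT focal-minus-other score slope per sucrose
#'   percentage point (frames/s per %; default 0.034).
#' @param dcvs_intercept SSPT score difference at 0% sucrose (frames/s).
#' @param base_score Sucrose-zone combined score in SSPT (frames/s).
#' @param trill_shift Extra Trill weight (taken from Flat) in the SSPT
#'   social zone.
#' @param frame_rate Raster rate (Hz).
#' @return An [emission_model()].
#' @export
default_emission_model <- function(condition, dcvs_slope = 0.034,
                                   dcvs_intercept = 0.048,
                                   base_score = 0.31,
                                   trill_shift = 0.10,
                                   frame_rate = 25) {
  task <- if (startsWith(condition, "J")) "SSPT" else "SDT"
  if (task == "SSPT") {
    s <- sspt_sucrose_level(condition)
    f_other <- base_score
    f_focal <- base_score + dcvs_intercept + dcvs_slope * s
    mix_focal <- default_subtype_mix(trill_shift)
    mix_other <- default_subtype_mix(0)
  } else {
    zone_scores <- list("2v5" = c(0.30, 0.15), "2v10" = c(0.407, 0.213),
                        "5v10" = c(0.129, 0.127))[[condition]]
    f_other <- zone_scores[1]  # lower sucrose: higher score in the study
    f_focal <- zone_scores[2]
    mix_focal <- mix_other <- default_subtype_mix(0)
  }
  f_neutral <- 0.15
  dur <- default_call_durations()
  rates <- matrix(0, nrow = length(usv_vocabulary()), ncol = 3,
                  dimnames = list(usv_vocabulary(),
                                  c("focal", "other", "neutral")))
  rates[cvs_subtypes(), "focal"] <-
    call_rates_for_frame_score(f_focal, mix_focal, dur, frame_rate)
  rates[cvs_subtypes(), "other"] <-
    call_rates_for_frame_score(f_other, mix_other, dur, frame_rate)
  rates[cvs_subtypes(), "neutral"] <-
    call_rates_for_frame_score(f_neutral, default_subtype_mix(0), dur,
                               frame_rate)
  # 22-kHz: long calls; rate set so their frames are ~23% of call frames
  f22_share <- 0.233
  mean22 <- dur$mean[dur$subtype == "22kHz"]
  for (z in colnames(rates)) {
    fz <- c(focal = f_focal, other = f_other, neutral = f_neutral)[[z]]
    rates["22kHz", z] <- (f22_share / (1 - f22_share)) * fz /
      expected_frames_per_call(mean22, frame_rate)
  }
  emission_model(rates, dur)
}

#' Microphone array model
#'
#' Four ultrasonic microphones at fixed maze positions; the recorded
#' amplitude of a call falls off monotonically with the distance between
#' the calling position and the microphone:
#' `amp = A0 - 20 * log10(1 + d / d0) + noise`.
#'
#' @param positions 4 x 2 numeric matrix of microphone (x, y) in cm.
#'   Defaults to one microphone near the end of each arm.
#' @param A0 Source level at zero distance (dB).
#' @param d0 Attenuation scale distance (cm).
#' @param noise_sd Additive Gaussian noise sd (dB).
#' @return A `mic_array` object.
#' @export
mic_array <- function(positions = rbind(c(0, 75), c(75, 0),
                                        c(0, -75), c(-75, 0)),
                      A0 = -20, d0 = 10, noise_sd = 2) {
  stopifnot(is.matrix(positions), nrow(positions) == 4,
            ncol(positions) == 2, d0 > 0, noise_sd >= 0)
  structure(list(positions = positions, A0 = A0, d0 = d0,
                 noise_sd = noise_sd),
            class = "mic_array")
}

#' @rdname mic_array
#' @param d Distance(s) in cm.
#' @param mics A `mic_array`.
#' @return `mic_amplitude()`: expected amplitude (dB) at distance `d`.
#' @export
mic_amplitude <- function(d, mics) {
  mics$A0 - 20 * log10(1 + d / mics$d0)
}

#' Derive a reproducible per-trial seed from the master seed
#'
#' Hashes the trial key so cohorts can be generated trial-by-trial, in
#' any order, with identical output.
#'
#' @param master Master seed.
#' @param ... Key components (animal, task, condition, day, stream name).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
trial_seed <- function(master, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master)) %% 2147483647)
}

#' Simulate a zone-dwell trajectory
#'
#' Runs the semi-Markov shuttle process of an [occupancy_model()] for one
#' trial, then renders it as 25 Hz tracking records whose positions are
#' sampled uniformly inside the occupied zone's polygon (or the neutral
#' disc). The realized zone of each frame is returned alongside as ground
#' truth.
#'
#' @param model An [occupancy_model()].
#' @param duration Trial duration (s), > 0.
#' @param frame_rate Raster rate (Hz).
#' @param seed Integer seed.
#' @param map A [make_zone_map()].
#' @param zones Named character vector (`focal`, `other`) of reward-zone
#'   polygon names, e.g. from [condition_zones()].
#' @param positions If `FALSE`, skip rendering x/y positions (`tracks` is
#'   `NULL`); the zone timeline is still returned. Useful for large
#'   simulation studies that score from the zone timeline directly.
#' @return List: `tracks` (tibble `t`, `x`, `y`, `gap`), `zone_frames`
#'   (character, per-frame polygon name or `"neutral"`), `role_frames`
#'   (per-frame `"focal"`/`"other"`/`"neutral"`).
#' @export
generate_trajectory <- function(model, duration, frame_rate, seed,
                                map, zones, positions = TRUE) {
  stopifnot(inherits(model, "occupancy_model"))
  if (duration <= 0) stop("duration must be positive")
  stopifnot(all(c("focal", "other") %in% names(zones)))
  set.seed(seed)
  n_frames <- as.integer(round(duration * frame_rate))

  # bout sequence
  states <- character(0); dwells <- numeric(0)
  state <- "neutral"; total <- 0
  q <- model$transition["neutral", "focal"]
  while (total < duration) {
    d <- stats::rexp(1, rate = 1 / model$mean_dwell[[state]])
    states <- c(states, state); dwells <- c(dwells, d)
    total <- total + d
    state <- if (state == "neutral") {
      if (stats::runif(1) < q) "focal" else "other"
    } else "neutral"
  }

  frame_mid <- (seq_len(n_frames) - 0.5) / frame_rate
  idx <- findInterval(frame_mid, cumsum(c(0, dwells)),
                      rightmost.closed = TRUE)
  idx[idx > length(states)] <- length(states)
  role_frames <- states[idx]
  zmap <- c(focal = unname(zones[["focal"]]),
            other = unname(zones[["other"]]), neutral = "neutral")
  zone_frames <- unname(zmap[role_frames])

  if (!positions) {
    return(list(tracks = NULL, zone_frames = zone_frames,
                role_frames = role_frames))
  }
  x <- numeric(n_frames); y <- numeric(n_frames)
  for (zn in unique(zone_frames)) {
    sel <- zone_frames == zn
    k <- sum(sel)
    if (zn == "neutral") {
      r <- map$neutral$radius * sqrt(stats::runif(k)) * 0.98
      th <- stats::runif(k, 0, 2 * pi)
      x[sel] <- map$neutral$center[1] + r * cos(th)
      y[sel] <- map$neutral$center[2] + r * sin(th)
    } else {
      pt <- sample_in_polygon(k, map$polygons[[zn]])
      x[sel] <- pt$x; y[sel] <- pt$y
    }
  }
  tracks <- tibble::tibble(t = (seq_len(n_frames) - 1) / frame_rate,
                           x = x, y = y, gap = FALSE)
  list(tracks = tracks, zone_frames = zone_frames,
       role_frames = role_frames)
}

# uniform points inside a polygon by rejection from the bounding box
sample_in_polygon <- function(n, poly) {
  xr <- range(poly$x); yr <- range(poly$y)
  # shrink slightly toward the centroid so points are strictly interior
  cx <- mean(poly$x); cy <- mean(poly$y)
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2 * (n - length(out_x)), 16)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, poly)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
  }
  list(x = cx + (out_x[seq_len(n)] - cx) * 0.98,
       y = cy + (out_y[seq_len(n)] - cy) * 0.98)
}

#' Simulate call labels along a zone timeline
#'
#' Emits calls as a piecewise-homogeneous Poisson process over the runs of
#' the per-frame role timeline, draws subtypes from the zone's rate mix
#' and durations from the per-subtype distribution, thins the result so
#' no two calls overlap or share a frame, and (if a microphone array and
#' positions are supplied) attaches four per-channel amplitudes with the
#' nearest microphone loudest in expectation.
#'
#' @param model An [emission_model()].
#' @param role_frames Per-frame roles (`"focal"`, `"other"`, `"neutral"`).
#' @param frame_rate Raster rate (Hz).
#' @param seed Integer seed.
#' @param mics Optional [mic_array()].
#' @param tracks Optional tracking tibble (needed for amplitudes).
#' @return Label tibble (`start`, `end`, `subtype`, `amp_ch1..4`,
#'   `channel`) sorted by start time, with attribute `call_frames`: a
#'   list of integer frame ranges (`f0`, `f1`, 0-based) per call.
#' @export
generate_calls <- function(model, role_frames, frame_rate, seed,
                           mics = NULL, tracks = NULL) {
  stopifnot(inherits(model, "emission_model"))
  set.seed(seed)
  runs <- rle(role_frames)
  ends <- cumsum(runs$lengths)
  starts_f <- ends - runs$lengths       # 0-based first frame of run
  st_names <- rownames(model$rates)
  dur_mean <- model$durations$mean[match(st_names,
                                         model$durations$subtype)]
  dur_sd <- model$durations$sd[match(st_names, model$durations$subtype)]
  dur_min <- model$durations$min[match(st_names, model$durations$subtype)]

  # call times are quantized to 1 microsecond so that serializing them
  # at 6 decimals round-trips bit-exactly; calls keep a small margin
  # inside their zone run so quantization can never push a frame across
  # a run boundary
  quant <- function(x) as.numeric(sprintf("%.6f", x))
  margin <- 1e-5

  call_start <- numeric(0); call_end <- numeric(0)
  call_sub <- character(0)
  for (i in seq_along(runs$values)) {
    role <- runs$values[i]
    rz <- model$rates[, role]
    total <- sum(rz)
    t0 <- starts_f[i] / frame_rate
    t1 <- ends[i] / frame_rate
    len <- t1 - t0
    if (total <= 0 || len <= 0) next
    n <- stats::rpois(1, total * len)
    if (n == 0) next
    sub_i <- sample(st_names, n, replace = TRUE, prob = rz / total)
    j <- match(sub_i, st_names)
    d <- pmax(stats::rnorm(n, dur_mean[j], dur_sd[j]), dur_min[j])
    d <- pmin(d, len - 10 * margin)
    s <- quant(t0 + margin + stats::runif(n) * (len - d - 2 * margin))
    call_start <- c(call_start, s)
    call_end <- c(call_end, quant(s + d))
    call_sub <- c(call_sub, sub_i)
  }

  ord <- order(call_start)
  call_start <- call_start[ord]; call_end <- call_end[ord]
  call_sub <- call_sub[ord]

  # thin to enforce non-overlap with a one-frame guard (plus the
  # quantization step) so no two calls ever share a raster frame
  keep <- logical(length(call_start))
  last_end <- -Inf
  guard <- 1 / frame_rate + margin
  for (i in seq_along(call_start)) {
    if (call_start[i] >= last_end + guard) {
      keep[i] <- TRUE
      last_end <- call_end[i]
    }
  }
  call_start <- call_start[keep]; call_end <- call_end[keep]
  call_sub <- call_sub[keep]

  n <- length(call_start)
  amp <- matrix(NA_real_, n, 4)
  if (!is.null(mics) && !is.null(tracks) && n > 0) {
    fi <- pmin(floor(call_start * frame_rate) + 1, nrow(tracks))
    px <- tracks$x[fi]; py <- tracks$y[fi]
    for (k in 1:4) {
      d <- sqrt((px - mics$positions[k, 1])^2 +
                (py - mics$positions[k, 2])^2)
      amp[, k] <- mic_amplitude(d, mics) +
        stats::rnorm(n, 0, mics$noise_sd)
    }
  }
  out <- tibble::tibble(start = call_start, end = call_end,
                        subtype = call_sub,
                        amp_ch1 = amp[, 1], amp_ch2 = amp[, 2],
                        amp_ch3 = amp[, 3], amp_ch4 = amp[, 4],
                        channel = NA_integer_)
  attr(out, "call_frames") <- list(
    f0 = floor(call_start * frame_rate),
    f1 = ceiling(call_end * frame_rate) - 1
  )
  out
}

#' Offered Poisson rate needed for a target accepted rate under thinning
#'
#' The non-overlap thinning keeps a call only if it starts at least one
#' guard interval after the previous kept call ends, which makes the kept
#' calls a renewal process with cycle `E[dur] + guard + 1/r`. Inverting
#' the accepted rate `r / (1 + r * (E[dur] + guard))` gives the offered
#' rate to request.
#'
#' @param rates Named accepted-rate vector (calls/s) over subtypes.
#' @param durations Duration table (see [emission_model()]).
#' @param guard Guard interval (s), normally one frame.
#' @return Scaled rate vector (offered calls/s), same mix.
#' @keywords internal
offered_rates_for_accepted <- function(rates, durations, guard) {
  a_tot <- sum(rates)
  if (a_tot <= 0) return(rates)
  md <- durations$mean[match(names(rates), durations$subtype)]
  dead <- sum(rates * md) / a_tot + guard
  if (a_tot * dead >= 0.9)
    stop("requested call rate too high for non-overlapping calls")
  rates * 1 / (1 - a_tot * dead)
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Runs the trajectory and emission generators for every animal x trial of
#' a [sim_config()], applying per-animal effects: a lognormal "chattiness"
#' multiplier on all call rates (inter-individual variation in overall
#' call output) and, in SSPT trials, a Gaussian random intercept on the
#' focal-zone combined score (between-animal variation in the
#' social-vs-sucrose score difference). Output is deterministic given the
#' master seed; per-trial substreams are derived with [trial_seed()].
#'
#' @param config A [sim_config()].
#' @param occupancy Named list of [occupancy_model()]s by condition.
#' @param emission Function `(condition) -> emission_model`, or `NULL`
#'   for [default_emission_model()] with `dcvs_slope`.
#' @param mics A [mic_array()].
#' @param dcvs_slope Planted SSPT focal-minus-other score slope per
#'   sucrose % (frames/s per %).
#' @param dcvs_intercept Planted SSPT score difference at 0% sucrose.
#' @param animal_sd SD of the per-animal SSPT focal-zone score offset
#'   (frames/s).
#' @param chattiness_sd SD (log scale) of the per-animal rate multiplier
#'   (drawn with mean 1).
#' @param positions If `FALSE`, skip position rendering and microphone
#'   amplitudes (tracks are `NULL`); ground-truth zone timelines are kept
#'   so the cohort can still be scored with
#'   `score_cohort(zone_source = "truth")`.
#' @return A `usv_cohort`: `manifest` (tibble), `trials` (named list of
#'   `labels`/`tracks` tibbles), `truth` (per-trial zone x subtype frame
#'   counts), `truth_occupancy` (per-trial zone occupancy frames), and
#'   `params` (the generating parameters).
#' @export
generate_cohort <- function(config,
                            occupancy = default_occupancy_models(),
                            emission = NULL,
                            mics = mic_array(),
                            dcvs_slope = 0.034,
                            dcvs_intercept = 0.048,
                            animal_sd = 0.08,
                            chattiness_sd = 0.25,
                            positions = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  # with the default emission model the SSPT focal-vs-other score
  # difference is pinned per animal to intercept + slope * sucrose% +
  # random offset; a user-supplied emission model is used as-is
  plant <- is.null(emission)
  if (is.null(emission)) {
    emission <- function(condition)
      default_emission_model(condition, dcvs_slope = dcvs_slope,
                             dcvs_intercept = dcvs_intercept,
                             frame_rate = config$frame_rate)
  }
  fr <- config$frame_rate
  dur <- config$trial_duration
  guard <- 1 / fr

  set.seed(trial_seed(config$seed, "animal-effects"))
  chatt <- stats::rlnorm(config$n_animals, -chattiness_sd^2 / 2,
                         chattiness_sd)
  a_off <- stats::rnorm(config$n_animals, 0, animal_sd)

  manifest <- list(); trials <- list()
  truth <- list(); truth_occ <- list()
  maps <- list(A = make_zone_map("A"), B = make_zone_map("B"))

  for (an in seq_len(config$n_animals)) {
    group <- if (an %% 2 == 1) "A" else "B"
    map <- maps[[group]]
    for (i in seq_len(nrow(config$trials))) {
      task <- config$trials$task[i]
      condition <- config$trials$condition[i]
      day <- config$trials$day[i]
      key <- sprintf("a%02d_%s_%s_d%d", an, task, condition, day)
      zones <- condition_zones(condition, map)

      seed_t <- trial_seed(config$seed, an, task, condition, day, "traj")
      traj <- generate_trajectory(occupancy[[condition]], dur, fr,
                                  seed_t, map, zones,
                                  positions = positions)

      em <- emission(condition)
      rates <- em$rates * chatt[an]
      if (plant && task == "SSPT") {
        # pin the focal-minus-other combined score of this animal to
        # intercept + slope * sucrose% + animal offset, regardless of the
        # chattiness multiplier (which scales both zones alike)
        epc <- expected_frames_per_call(
          em$durations$mean[match(cvs_subtypes(),
                                  em$durations$subtype)], fr)
        f_other <- sum(rates[cvs_subtypes(), "other"] * epc)
        f_focal <- sum(rates[cvs_subtypes(), "focal"] * epc)
        s_lv <- sspt_sucrose_level(condition)
        target <- max(f_other + dcvs_intercept + dcvs_slope * s_lv +
                        a_off[an], 0.01)
        rates[, "focal"] <- rates[, "focal"] * target / f_focal
      }
      # compensate for thinning so realized rates match the targets
      for (z in colnames(rates)) {
        rates[, z] <- offered_rates_for_accepted(rates[, z],
                                                 em$durations, guard)
      }
      em_an <- emission_model(rates, em$durations)

      seed_c <- trial_seed(config$seed, an, task, condition, day, "calls")
      labels <- generate_calls(em_an, traj$role_frames, fr, seed_c,
                               mics = if (positions) mics,
                               tracks = traj$tracks)

      cf <- attr(labels, "call_frames")
      if (length(cf$f0)) {
        zc <- traj$zone_frames[cf$f0 + 1]
        nfr <- cf$f1 - cf$f0 + 1
        tr <- stats::aggregate(nfr,
                               by = list(zone = zc, subtype = labels$subtype),
                               FUN = sum)
        names(tr)[3] <- "frames"
      } else {
        tr <- data.frame(zone = character(0), subtype = character(0),
                         frames = integer(0))
      }
      occ <- as.data.frame(table(zone = traj$zone_frames),
                           stringsAsFactors = FALSE)
      names(occ)[2] <- "occupancy_frames"

      meta <- tibble::tibble(animal = an, task = task,
                             condition = condition, day = day,
                             group = group, key = key)
      manifest[[key]] <- meta
      trials[[key]] <- list(labels = labels, tracks = traj$tracks,
                            zone_frames = traj$zone_frames)
      truth[[key]] <- cbind(meta[rep(1, nrow(tr)), ], tr)
      truth_occ[[key]] <- cbind(meta[rep(1, nrow(occ)), ], occ)
    }
  }
  structure(list(
    manifest = do.call(rbind, manifest),
    trials = trials,
    truth = do.call(rbind, truth),
    truth_occupancy = do.call(rbind, truth_occ),
    params = list(seed = config$seed, frame_rate = fr,
                  trial_duration = dur, dcvs_slope = dcvs_slope,
                  animal_sd = animal_sd, chattiness_sd = chattiness_sd,
                  chattiness = chatt, animal_offset = a_off)
  ), class = "usv_cohort")
}

#' Write / read a synthetic cohort as plain-text files
#'
#' One tab-delimited label table and one track table per trial, a YAML
#' manifest, and the generator's ground-truth frame counts as a sidecar
#' CSV. Reading the directory back yields the tables in the package's
#' in-memory layout.
#'
#' @param cohort A `usv_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "usv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$trials)) {
    tr <- cohort$trials[[key]]
    lab <- as.data.frame(tr$labels)
    lab$start <- sprintf("%.6f", lab$start)
    lab$end <- sprintf("%.6f", lab$end)
    names(lab)[names(lab) == "subtype"] <- "label"
    utils::write.table(lab, file.path(dir, paste0("labels_", key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "")
    trk <- as.data.frame(tr$tracks)
    trk$x[trk$gap] <- NA; trk$y[trk$gap] <- NA
    trk$gap <- NULL
    utils::write.table(trk, file.path(dir, paste0("tracks_", key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "")
  }
  man <- as.data.frame(cohort$manifest)
  yaml::write_yaml(list(
    frame_rate = cohort$params$frame_rate,
    trial_duration = cohort$params$trial_duration,
    seed = cohort$params$seed,
    trials = lapply(seq_len(nrow(man)), function(i) as.list(man[i, ]))
  ), file.path(dir, "manifest.yaml"))
  readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$truth_occupancy,
                   file.path(dir, "ground_truth_occupancy.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort()`: list with `manifest`, `trials`, `truth`,
#'   `truth_occupancy`, `frame_rate`, `trial_duration`.
#' @export
read_cohort <- function(dir) {
  man_y <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  manifest <- do.call(rbind, lapply(man_y$trials, function(x)
    tibble::as_tibble(x)))
  ld <- label_dialect(col_label = "label")
  td <- track_dialect()
  trials <- list()
  for (key in manifest$key) {
    trials[[key]] <- list(
      labels = read_label_table(file.path(dir, paste0("labels_", key,
                                                      ".tsv")), ld),
      tracks = read_track_table(file.path(dir, paste0("tracks_", key,
                                                      ".tsv")), td)
    )
  }
  truth_path <- file.path(dir, "ground_truth.csv")
  list(manifest = manifest, trials = trials,
       truth = if (file.exists(truth_path))
         readr::read_csv(truth_path, show_col_types = FALSE,
                         progress = FALSE) else NULL,
       truth_occupancy = if (file.exists(file.path(dir,
         "ground_truth_occupancy.csv")))
         readr::read_csv(file.path(dir, "ground_truth_occupancy.csv"),
                         show_col_types = FALSE, progress = FALSE)
       else NULL,
       frame_rate = man_y$frame_rate,
       trial_duration = man_y$trial_duration)
}
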