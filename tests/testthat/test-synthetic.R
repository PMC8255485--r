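test_that("simulation config validates conditions and trial keys", {
  expect_error(sim_config(trials = tibble::tibble(
    task = "SDT", condition = "Jv5", day = 1)), "not legal")
  expect_error(sim_config(trials = tibble::tibble(
    task = c("SDT", "SDT"), condition = c("2v10", "2v10"),
    day = c(1, 1))), "duplicate")
  expect_error(sim_config(trial_duration = -5), "trial_duration")
})

test_that("trajectories have one record per frame inside the right zone", {
  m <- make_zone_map("A")
  zones <- condition_zones("Jv10", m)
  om <- occupancy_model(0.5)
  tr <- generate_trajectory(om, 600, 25, seed = 1, m, zones)
  expect_equal(nrow(tr$tracks), 15000)
  expect_equal(length(tr$zone_frames), 15000)
  # every rendered position lies in the zone the frame is assigned to
  z_check <- zone_at(tr$tracks$x, tr$tracks$y, m)
  expect_identical(z_check, tr$zone_frames)

  expect_error(generate_trajectory(om, 0, 25, 1, m, zones),
               "duration")
})

test_that("degenerate preference puts every reward frame in the focal zone", {
  m <- make_zone_map("A")
  zones <- condition_zones("Jv5", m)
  tr <- generate_trajectory(occupancy_model(1), 300, 25, 2, m, zones,
                            positions = FALSE)
  reward <- tr$role_frames != "neutral"
  expect_true(any(reward))
  expect_true(all(tr$role_frames[reward] == "focal"))
})

test_that("realized preference converges to the target", {
  m <- make_zone_map("A")
  zones <- condition_zones("Jv5", m)
  tr <- generate_trajectory(occupancy_model(0.5), 10000, 25, 3, m,
                            zones, positions = FALSE)
  reward <- tr$role_frames != "neutral"
  frac <- mean(tr$role_frames[reward] == "focal")
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("call counts follow the Poisson expectation", {
  base <- default_emission_model("Jv5")
  rates <- base$rates * 0
  rates["Flat", ] <- 0.5
  em <- emission_model(rates, base$durations)
  calls <- generate_calls(em, rep("focal", 1000 * 25), 25, seed = 4)
  expect_lt(abs(nrow(calls) - 500), 3 * sqrt(500))
  expect_true(all(calls$subtype == "Flat"))

  silent <- emission_model(rates * 0, base$durations)
  none <- generate_calls(silent, rep("focal", 1000), 25, seed = 4)
  expect_equal(nrow(none), 0)
})

test_that("generated calls never share a raster frame (one-hot)", {
  em <- default_emission_model("Jv10")
  calls <- generate_calls(em, rep("focal", 600 * 25), 25, seed = 5)
  cf <- attr(calls, "call_frames")
  expect_true(all(cf$f0[-1] > cf$f1[-length(cf$f1)]))
  # and the rasterizer accepts them without one-hot violations
  expect_silent(rasterize_labels(calls, 25, 600))
})

test_that("the nearest microphone is loudest for a noiseless source", {
  mics <- mic_array(noise_sd = 0)
  em <- default_emission_model("Jv5")
  n <- 60 * 25
  at_mic1 <- tibble::tibble(t = (seq_len(n) - 1) / 25,
                            x = mics$positions[1, 1],
                            y = mics$positions[1, 2], gap = FALSE)
  calls <- generate_calls(em, rep("focal", n), 25, seed = 6,
                          mics = mics, tracks = at_mic1)
  expect_gt(nrow(calls), 0)
  amp <- as.matrix(calls[paste0("amp_ch", 1:4)])
  expect_true(all(apply(amp, 1, which.max) == 1))
  # attenuation is strictly monotone in distance
  d <- c(0, 5, 20, 80)
  expect_true(all(diff(mic_amplitude(d, mics)) < 0))
})

test_that("cohort generation is deterministic and complete", {
  c1 <- small_cohort(seed = 11)
  c2 <- small_cohort(seed = 11)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$truth, c2$truth)
  expect_equal(nrow(c1$manifest), 2 * 5)

  full <- sim_config(n_animals = 8)
  expect_equal(nrow(full$trials) * full$n_animals, 40)
})

test_that("written cohorts are byte-identical across runs and round-trip", {
  co <- small_cohort(seed = 12)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(co, d1)
  write_cohort(co, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  back <- read_cohort(d1)
  expect_equal(nrow(back$manifest), nrow(co$manifest))
  expect_equal(back$frame_rate, 25)
})

test_that("the pipeline recovers ground-truth counts exactly from files", {
  co <- small_cohort(seed = 13, n_animals = 2, duration = 120)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  scored_counts <- list()
  maps <- list(A = make_zone_map("A"), B = make_zone_map("B"))
  for (i in seq_len(nrow(back$manifest))) {
    key <- back$manifest$key[i]
    trial <- back$trials[[key]]
    frames <- rasterize_labels(trial$labels, 25, 120)
    zones <- assign_zones(trial$tracks, maps[[back$manifest$group[i]]],
                          25, 120)
    tab <- tabulate_zone_subtypes(frames, zones, 25)
    cts <- tab$counts
    cts$key <- key
    scored_counts[[key]] <- cts
  }
  got <- do.call(rbind, scored_counts)
  truth <- co$truth
  truth_key <- paste(truth$key, truth$zone, truth$subtype)
  got_key <- paste(got$key, got$zone, got$subtype)
  expect_setequal(got_key, truth_key)
  expect_equal(got$frames[match(truth_key, got_key)], truth$frames)
})

test_that("occupancy and emission rates are recovered within 5%", {
  m <- make_zone_map("A")
  zones <- condition_zones("Jv5", m)
  om <- occupancy_model(0.7)
  # the focal fraction has ~4% sampling sd at 10,000 s (bout-level
  # binomial noise); average a few independent trajectories
  fracs <- sapply(1:5, function(sd) {
    tr <- generate_trajectory(om, 10000, 25, sd, m, zones,
                              positions = FALSE)
    reward <- tr$role_frames != "neutral"
    mean(tr$role_frames[reward] == "focal")
  })
  expect_lt(abs(mean(fracs) / 0.7 - 1), 0.05)

  base <- default_emission_model("Jv5")
  target <- 0.4  # frames per occupancy second, single zone
  rates <- base$rates * 0
  rates[cvs_subtypes(), "focal"] <- call_rates_for_frame_score(
    target, default_subtype_mix(), base$durations)
  offered <- usvscore:::offered_rates_for_accepted(
    rates[, "focal"], base$durations, 1 / 25)
  rates[, "focal"] <- offered
  em <- emission_model(rates, base$durations)
  calls <- generate_calls(em, rep("focal", 10000 * 25), 25, seed = 8)
  frames <- rasterize_labels(calls, 25, 10000)
  est <- sum(!is.na(frames)) / 10000
  expect_lt(abs(est / target - 1), 0.05)
})
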