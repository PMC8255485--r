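test_that("preference score is the focal share of reward-zone time", {
  expect_equal(preference_score(300, 100), 75)
  expect_equal(preference_score(200, 200), 50)
  expect_true(is.na(preference_score(0, 0)))
  # group-mean juvenile vs 10% zone times round to the printed 19%
  expect_equal(round(preference_score(97.7, 408)), 19)
})

test_that("focal and other preference scores are complementary", {
  set.seed(21)
  tf <- runif(50, 0, 600); to <- runif(50, 0, 600)
  expect_equal(preference_score(tf, to) + preference_score(to, tf),
               rep(100, 50))
})

test_that("CVS is frames per occupancy second and scale invariant", {
  expect_equal(cvs(50, 100), 0.5)
  expect_equal(cvs(0, 100), 0)
  expect_true(is.na(cvs(10, 0)))
  set.seed(22)
  f <- rpois(20, 40); occ <- runif(20, 10, 500); k <- 7.3
  expect_equal(cvs(f * k, occ * k), cvs(f, occ))
})

test_that("log CVS uses a 0.001 frames/s floor and is monotone", {
  expect_equal(log_cvs(0), log(0.001))
  expect_equal(log_cvs(0), -6.9078, tolerance = 1e-4)
  expect_equal(log_cvs(1 - 0.001), 0)
  expect_error(log_cvs(-0.1), "negative")
  x <- sort(runif(20))
  expect_true(all(diff(log_cvs(x)) > 0))
})

test_that("SVS normalizes per subtype and sums to the zone CVS", {
  frames <- c(rep("Trill", 10), rep("Flat", 5), rep(NA, 35))
  zones <- rep("arm_N_reward", 50)
  tab <- tabulate_zone_subtypes(frames, zones, 25)  # occupancy 2 s
  sv <- svs_table(tab)
  expect_equal(sv$svs[sv$subtype == "Trill"], 10 / 2)
  expect_equal(sv$svs[sv$subtype == "Flat"], 5 / 2)
  ts <- trial_scores(tab)
  expect_equal(sum(sv$svs[sv$subtype %in% cvs_subtypes()]), ts$cvs)
})

test_that("delta scores are antisymmetric and zero at equality", {
  expect_equal(delta_score(0.3, 0.1), 0.2)
  expect_equal(delta_score(0.2, 0.2), 0)
  set.seed(23)
  a <- runif(10); b <- runif(10)
  expect_equal(delta_score(a, b), -delta_score(b, a))
  expect_true(is.na(delta_score(NA_real_, 0.1)))
})

test_that("prevalence filter keeps subtypes at or above the threshold", {
  counts <- c(Trill = 98, Flat = 1, Complex = 1)
  res <- subtype_filter(counts, 2)
  expect_equal(res$included, "Trill")
  expect_true(all(c("Flat", "Complex") %in% res$excluded))
  expect_equal(sum(res$prevalence$prevalence_pct), 100)
  expect_error(subtype_filter(c(Trill = 0, Flat = 0)), "no call frames")
})

test_that("the study's printed prevalences select eight subtypes at 2%", {
  counts <- c("Trill" = 27.2, "Flat" = 24.4, "Complex" = 11.5,
              "Composite" = 11.3, "Short" = 5.5,
              "Flat-Trill-combination" = 4.0, "Split" = 3.4,
              "Trill-with-Jump" = 2.2, "Unclear" = 3.9,
              "Step-Down" = 1.1, "Inverted-U" = 1.1, "Step-Up" = 1.1,
              "Multi-Step" = 1.1, "Downward-Ramp" = 1.1,
              "Upward-Ramp" = 1.1)
  res <- subtype_filter(counts, 2)
  expect_equal(length(res$included), 8)
  expect_setequal(res$included,
                  c("Trill", "Flat", "Complex", "Composite", "Short",
                    "Flat-Trill-combination", "Split", "Trill-with-Jump"))
  # Unclear stays out of subtype analyses even above threshold
  expect_false("Unclear" %in% res$included)
  # threshold 0 admits every observed subtype except Unclear
  expect_setequal(subtype_filter(counts, 0)$included, usv_subtypes_50k())
})

test_that("the included set shrinks monotonically with the threshold", {
  set.seed(24)
  counts <- stats::setNames(rpois(15, 30), cvs_subtypes())
  prev_set <- NULL
  for (th in c(0, 1, 2, 5, 10, 50, 100)) {
    inc <- subtype_filter(counts, th)$included
    if (!is.null(prev_set)) expect_true(all(inc %in% prev_set))
    prev_set <- inc
  }
})

test_that("planted Trill asymmetry is recovered in sign; Flat stays centered", {
  # emission model with Trill three times as frequent in the focal zone,
  # everything else symmetric
  base <- default_emission_model("Jv5")
  rates <- base$rates
  rates[, "focal"] <- rates[, "other"]
  rates["Trill", "focal"] <- 3 * rates["Trill", "other"]
  em <- emission_model(rates, base$durations)
  grid <- tibble::tibble(task = "SSPT",
                         condition = c("Jv2", "Jv5", "Jv10"), day = 1:3)
  n_rep <- 20
  trill_mean <- numeric(n_rep); flat_mean <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_animals = 8, trials = grid,
                      seed = trial_seed(31, "rep", r))
    co <- generate_cohort(cfg, emission = function(cond) em,
                          positions = FALSE)
    sc <- score_cohort(co, zone_source = "truth")
    d <- cohort_delta_scores(sc, "SSPT")$dsvs
    trill_mean[r] <- mean(d$dsvs[d$subtype == "Trill"], na.rm = TRUE)
    flat_mean[r] <- mean(d$dsvs[d$subtype == "Flat"], na.rm = TRUE)
  }
  expect_gte(mean(trill_mean > 0), 0.95)
  expect_lt(abs(mean(flat_mean)), 0.02)
})
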