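test_that("channel selection takes the loudest microphone, ties low", {
  expect_equal(select_channel(c(-40, -35, -50, -60)), 2)
  expect_equal(select_channel(c(-40, -40, -40, -40)), 1)
  expect_equal(select_channel(NULL, channel = 3), 3)
  expect_error(select_channel(NULL, NA_integer_), "no amplitudes")
  expect_error(select_channel(c(-40, NA, -50, -60)), "4 amplitude")
})

test_that("rasterization labels every frame a call positively overlaps", {
  calls <- tibble::tibble(start = 1.00, end = 1.10, subtype = "Trill")
  fr <- rasterize_labels(calls, 25, 2)
  expect_equal(which(!is.na(fr)) - 1, c(25, 26, 27))  # 0-based frames
  expect_equal(unique(fr[!is.na(fr)]), "Trill")

  expect_true(all(is.na(rasterize_labels(calls[0, ], 25, 2))))

  long <- tibble::tibble(start = 0, end = 2.0, subtype = "22kHz")
  expect_equal(sum(!is.na(rasterize_labels(long, 25, 600))), 50)
})

test_that("rasterization rejects ill-formed call sets", {
  overlap <- tibble::tibble(start = c(0.1, 0.15), end = c(0.2, 0.25),
                            subtype = c("Trill", "Flat"))
  expect_error(rasterize_labels(overlap, 25, 1), "overlapping calls")
  zero <- tibble::tibble(start = 0.1, end = 0.1, subtype = "Trill")
  expect_error(rasterize_labels(zero, 25, 1), "zero-length")
})

test_that("a call of duration d spans floor(25 d) to floor(25 d) + 2 frames", {
  set.seed(5)
  for (i in 1:200) {
    d <- runif(1, 0.01, 0.3)
    s <- runif(1, 0, 9)
    calls <- tibble::tibble(start = s, end = s + d, subtype = "Flat")
    n <- sum(!is.na(rasterize_labels(calls, 25, 10)))
    expect_gte(n, floor(d * 25))
    expect_lte(n, floor(d * 25) + 2)
  }
})

test_that("rasterization is invariant to call order", {
  set.seed(6)
  starts <- sort(runif(30, 0, 9.5))
  starts <- starts[c(TRUE, diff(starts) > 0.1)]
  calls <- tibble::tibble(start = starts, end = starts + 0.04,
                          subtype = sample(usv_subtypes_50k(),
                                           length(starts), TRUE))
  shuffled <- calls[sample(nrow(calls)), ]
  expect_identical(rasterize_labels(calls, 25, 10),
                   rasterize_labels(shuffled, 25, 10))
})

test_that("zone assignment follows the tracked position", {
  m <- make_zone_map("A")
  center <- tibble::tibble(t = (0:249) / 25, x = 0, y = 0, gap = FALSE)
  expect_true(all(assign_zones(center, m, 25, 10) == "neutral"))

  juv <- constant_track(m, "arm_N_reward", duration = 600)
  z <- assign_zones(juv, m, 25, 600)
  expect_true(all(z == "arm_N_reward"))
  expect_equal(sum(z == "arm_N_reward") / 25, 600)

  expect_error(assign_zones(juv[0, ], m, 25, 600), "empty track")
})

test_that("alternating occupancy splits time evenly between zones", {
  m <- make_zone_map("A")
  n <- 100 * 25
  sec <- floor((0:(n - 1)) / 25)
  in_n <- sec %% 2 == 0
  trk <- tibble::tibble(
    t = (0:(n - 1)) / 25,
    x = ifelse(in_n, 0, 70), y = ifelse(in_n, 70, 0), gap = FALSE)
  z <- assign_zones(trk, m, 25, 100)
  expect_lte(abs(sum(z == "arm_N_reward") - 50 * 25), 1)
  expect_lte(abs(sum(z == "arm_E_reward") - 50 * 25), 1)
})

test_that("gap frames are excluded from occupancy and counts", {
  m <- make_zone_map("A")
  trk <- constant_track(m, "arm_N_reward", duration = 10)
  trk$gap[1:50] <- TRUE
  trk$x[1:50] <- NA; trk$y[1:50] <- NA
  z <- assign_zones(trk, m, 25, 10)
  expect_equal(sum(z == "gap"), 50)
  calls <- tibble::tibble(start = c(0.5, 5.0), end = c(0.54, 5.04),
                          subtype = "Trill")
  tab <- tabulate_zone_subtypes(rasterize_labels(calls, 25, 10), z, 25)
  expect_equal(tab$n_gap_frames, 50)
  # the call at 0.5 s falls in the gap; only the 5.0 s call is counted,
  # and [5.0, 5.04) sits exactly on one frame
  expect_equal(sum(tab$counts$frames), 1)
  expect_equal(tab$occupancy$occupancy_seconds[
    tab$occupancy$zone == "arm_N_reward"], 8)
})

test_that("tabulation matches a hand count and conserves frames", {
  frames <- c("Trill", NA, "Trill", "Flat")
  zones <- c("A", "A", "B", "neutral")
  tab <- tabulate_zone_subtypes(frames, zones, 25)
  get <- function(z, s) {
    r <- tab$counts[tab$counts$zone == z & tab$counts$subtype == s, ]
    if (nrow(r)) r$frames else 0L
  }
  expect_equal(get("A", "Trill"), 1L)
  expect_equal(get("B", "Trill"), 1L)
  expect_equal(get("neutral", "Flat"), 1L)
  expect_equal(tab$occupancy$occupancy_frames[tab$occupancy$zone == "A"],
               2L)
  expect_equal(sum(tab$occupancy$occupancy_frames), 4L)
  expect_equal(sum(tab$counts$frames), sum(!is.na(frames)))

  silent <- tabulate_zone_subtypes(rep(NA_character_, 4), zones, 25)
  expect_equal(nrow(silent$counts), 0)
  expect_equal(sum(silent$occupancy$occupancy_frames), 4L)

  expect_error(tabulate_zone_subtypes(frames, zones[1:3], 25),
               "lengths differ")
})
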