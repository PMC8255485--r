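#' Select the recording channel of a call
#'
#' Each call was recorded on four microphones; the channel with the
#' largest amplitude is the one annotated. Ties break to the lowest
#' channel index. Calls carrying a pre-selected channel (and no
#' amplitudes) pass it through.
#'
#' @param amplitudes Numeric vector of 4 per-channel amplitudes (dB), or
#'   `NULL`/all-`NA`.
#' @param channel Pre-selected channel index, or `NA`.
#' @return Integer channel index in 1..4.
#' @export
select_channel <- function(amplitudes = NULL, channel = NA_integer_) {
  if (!is.null(amplitudes) && any(!is.na(amplitudes))) {
    if (length(amplitudes) != 4 || any(is.na(amplitudes)))
      stop("need 4 amplitude values")
    return(which.max(amplitudes))  # which.max: first maximum on ties
  }
  if (!is.na(channel)) {
    if (channel < 1 || channel > 4) stop("channel index out of range")
    return(as.integer(channel))
  }
  stop("no amplitudes and no pre-selected channel")
}

#' @rdname select_channel
#' @param labels Label tibble (from [read_label_table()]).
#' @return `select_channels()`: integer vector, one channel per call.
#' @export
select_channels <- function(labels) {
  amp <- as.matrix(labels[paste0("amp_ch", 1:4)])
  vapply(seq_len(nrow(labels)), function(i)
    select_channel(if (all(is.na(amp[i, ]))) NULL else amp[i, ],
                   labels$channel[i]),
    integer(1))
}

#' Rasterize call labels onto the 25 Hz frame grid
#'
#' Frame `k` (0-based) spans `[k/rate, (k+1)/rate)`; a frame carries a
#' subtype iff a call of that subtype overlaps the span by any positive
#' amount, which preserves 30-40 ms calls straddling a frame boundary.
#' If two non-overlapping calls touch the same frame, the earlier call
#' keeps it, so the result is independent of the input order.
#'
#' @param calls Label tibble with `start`, `end` (s) and `subtype`.
#' @param frame_rate Raster rate (Hz).
#' @param duration Trial duration (s).
#' @return Character vector of length `ceiling(duration * frame_rate)`;
#'   `NA` for silence, otherwise a subtype name.
#' @export
rasterize_labels <- function(calls, frame_rate = 25, duration = 600) {
  stopifnot(duration > 0, frame_rate > 0)
  n_frames <- as.integer(ceiling(duration * frame_rate))
  frames <- rep(NA_character_, n_frames)
  if (nrow(calls) == 0) return(frames)
  if (any(calls$end <= calls$start)) stop("zero-length call")
  if (any(calls$start < 0) || any(calls$end > duration))
    stop("call outside [0, duration)")
  ord <- order(calls$start)
  s <- calls$start[ord]; e <- calls$end[ord]; sub <- calls$subtype[ord]
  over <- which(s[-1] < e[-length(e)])
  if (length(over)) {
    bad <- over[sub[over] != sub[over + 1]]
    if (length(bad))
      stop("overlapping calls of different subtypes at t = ",
           format(s[bad[1] + 1]))
  }
  f0 <- pmax(floor(s * frame_rate), 0)
  f1 <- pmin(ceiling(e * frame_rate) - 1, n_frames - 1)
  for (i in seq_along(s)) {
    idx <- (f0[i]:f1[i]) + 1
    idx <- idx[is.na(frames[idx])]  # earlier call wins shared frames
    frames[idx] <- sub[i]
  }
  frames
}

#' Assign a maze zone to every raster frame
#'
#' Each frame takes the zone containing the tracking sample nearest in
#' time to the frame start, searched within one frame interval; frames
#' with no usable sample (none near enough, or the subject undetected)
#' become `"gap"`. Positions inside no reward/sandpaper polygon are
#' `"neutral"` (the central platform).
#'
#' @param tracks Tracking tibble (`t`, `x`, `y`, `gap`).
#' @param map A [make_zone_map()].
#' @param frame_rate Raster rate (Hz).
#' @param duration Trial duration (s).
#' @return Character vector of zone names per frame (`"gap"` included).
#' @export
assign_zones <- function(tracks, map, frame_rate = 25, duration = 600) {
  if (nrow(tracks) == 0) stop("empty track")
  n_frames <- as.integer(ceiling(duration * frame_rate))
  ft <- (seq_len(n_frames) - 1) / frame_rate
  # nearest sample: tracks$t sorted (checked at read)
  idx <- findInterval(ft, tracks$t)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, nrow(tracks))
  d_lo <- abs(ft - tracks$t[lo])
  d_hi <- abs(ft - tracks$t[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  usable <- dist <= 1 / frame_rate & !tracks$gap[nearest]
  zones <- rep("gap", n_frames)
  if (any(usable)) {
    zones[usable] <- zone_at(tracks$x[nearest[usable]],
                             tracks$y[nearest[usable]], map)
  }
  zones
}

#' Tabulate call frames and occupancy per zone and subtype
#'
#' Produces the numerators and denominators of the occupancy-normalized
#' scores: per zone x subtype call-frame counts, and per-zone occupancy in
#' frames and seconds. Gap frames are excluded from occupancy; labeled
#' frames falling on a gap are excluded from the counts (symmetry of
#' numerator and denominator).
#'
#' @param frames Character vector from [rasterize_labels()].
#' @param zones Character vector from [assign_zones()]; same length.
#' @param frame_rate Raster rate (Hz).
#' @return A `zone_subtype_counts` list: `counts` (tibble `zone`,
#'   `subtype`, `frames`), `occupancy` (tibble `zone`,
#'   `occupancy_frames`, `occupancy_seconds`), `frame_rate`,
#'   `n_gap_frames`.
#' @export
tabulate_zone_subtypes <- function(frames, zones, frame_rate = 25) {
  if (length(frames) != length(zones))
    stop("frame series and zone timeline lengths differ (",
         length(frames), " vs ", length(zones), ")")
  live <- zones != "gap"
  occ <- table(zone = zones[live])
  occupancy <- tibble::tibble(
    zone = names(occ),
    occupancy_frames = as.integer(occ),
    occupancy_seconds = as.integer(occ) / frame_rate
  )
  lab <- live & !is.na(frames)
  if (any(lab)) {
    ct <- table(zone = zones[lab], subtype = frames[lab])
    df <- as.data.frame(ct, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    counts <- tibble::tibble(zone = df$zone, subtype = df$subtype,
                             frames = as.integer(df$Freq))
  } else {
    counts <- tibble::tibble(zone = character(0), subtype = character(0),
                             frames = integer(0))
  }
  structure(list(counts = counts, occupancy = occupancy,
                 frame_rate = frame_rate,
                 n_gap_frames = sum(!live)),
            class = "zone_subtype_counts")
}
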