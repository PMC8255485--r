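#' Table dialects for annotation and tracking exports
#'
#' Manual spectrogram-annotation software and video-tracking software
#' export delimited tables whose delimiter, decimal mark and column names
#' vary by product and locale (European exports often use a decimal
#' comma). A dialect object states these explicitly; nothing is sniffed.
#'
#' @param delim Field delimiter.
#' @param decimal_mark `"."` or `","`.
#' @param col_start,col_end,col_label Column names in a label table.
#' @param col_amp Names of the four per-channel amplitude columns
#'   (in channel order), or `NULL` if the table carries a pre-selected
#'   channel instead.
#' @param col_channel Name of the pre-selected channel column (optional).
#' @return A `usv_dialect` list.
#' @export
label_dialect <- function(delim = "\t", decimal_mark = ".",
                          col_start = "start", col_end = "end",
                          col_label = "label",
                          col_amp = paste0("amp_ch", 1:4),
                          col_channel = "channel") {
  structure(list(delim = delim, decimal_mark = decimal_mark,
                 col_start = col_start, col_end = col_end,
                 col_label = col_label, col_amp = col_amp,
                 col_channel = col_channel),
            class = "usv_dialect")
}

#' @rdname label_dialect
#' @param col_t,col_x,col_y Column names in a tracking table.
#' @export
track_dialect <- function(delim = "\t", decimal_mark = ".",
                          col_t = "t", col_x = "x", col_y = "y") {
  structure(list(delim = delim, decimal_mark = decimal_mark,
                 col_t = col_t, col_x = col_x, col_y = col_y),
            class = "usv_dialect")
}

read_dialect_table <- function(path, dialect) {
  readr::read_delim(
    path, delim = dialect$delim,
    locale = readr::locale(decimal_mark = dialect$decimal_mark),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE)
}

num_col <- function(raw, dialect) {
  x <- raw
  if (dialect$decimal_mark == ",") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a call-label table
#'
#' One row per annotated call: start and end time (seconds from trial
#' start, half-open interval), subtype label from the closed vocabulary,
#' and either four per-channel amplitudes (dB) or a pre-selected channel
#' index. Row numbers in errors are 1-based data rows (header excluded).
#'
#' @param path File path.
#' @param dialect A [label_dialect()].
#' @return Tibble with columns `start`, `end`, `subtype`, amplitude
#'   columns `amp_ch1`..`amp_ch4` (NA when absent) and `channel`
#'   (NA when absent).
#' @export
read_label_table <- function(path, dialect = label_dialect()) {
  raw <- read_dialect_table(path, dialect)
  need <- c(dialect$col_start, dialect$col_end, dialect$col_label)
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("label table ", path, " missing columns: ",
         paste(missing, collapse = ", "))

  n <- nrow(raw)
  out <- tibble::tibble(
    start = num_col(raw[[dialect$col_start]], dialect),
    end = num_col(raw[[dialect$col_end]], dialect),
    subtype = raw[[dialect$col_label]]
  )
  for (k in 1:4) {
    cn <- dialect$col_amp[k]
    out[[paste0("amp_ch", k)]] <-
      if (!is.null(cn) && cn %in% names(raw)) num_col(raw[[cn]], dialect)
      else rep(NA_real_, n)
  }
  out$channel <-
    if (!is.null(dialect$col_channel) && dialect$col_channel %in% names(raw))
      suppressWarnings(as.integer(raw[[dialect$col_channel]]))
    else rep(NA_integer_, n)

  if (n == 0) return(out)
  bad <- which(!(out$subtype %in% usv_vocabulary()))
  if (length(bad))
    stop("unknown subtype, row ", bad[1], ": '", out$subtype[bad[1]], "'")
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) stop("unparseable time, row ", bad[1])
  bad <- which(out$start < 0)
  if (length(bad)) stop("negative start time, row ", bad[1])
  bad <- which(out$end <= out$start)
  if (length(bad)) stop("end <= start, row ", bad[1])
  out
}

#' Read a position-tracking table
#'
#' One row per video frame: time (s), x and y (cm, maze coordinates).
#' Rows where the subject was not detected have blank coordinates; they
#' are preserved as gap rows (`gap = TRUE`), never dropped.
#'
#' @param path File path.
#' @param dialect A [track_dialect()].
#' @return Tibble with columns `t`, `x`, `y`, `gap`.
#' @export
read_track_table <- function(path, dialect = track_dialect()) {
  raw <- read_dialect_table(path, dialect)
  need <- c(dialect$col_t, dialect$col_x, dialect$col_y)
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("track table ", path, " missing columns: ",
         paste(missing, collapse = ", "))
  out <- tibble::tibble(
    t = num_col(raw[[dialect$col_t]], dialect),
    x = num_col(raw[[dialect$col_x]], dialect),
    y = num_col(raw[[dialect$col_y]], dialect)
  )
  blank_x <- raw[[dialect$col_x]] == "" | is.na(out$x)
  blank_y <- raw[[dialect$col_y]] == "" | is.na(out$y)
  out$gap <- blank_x | blank_y
  out$x[out$gap] <- NA_real_
  out$y[out$gap] <- NA_real_
  bad <- which(is.na(out$t))
  if (length(bad)) stop("unparseable time, row ", bad[1])
  if (nrow(out) > 1 && any(diff(out$t) < 0)) {
    i <- which(diff(out$t) < 0)[1] + 1
    stop("non-monotone time, row ", i)
  }
  out
}

#' Write / read a score table as CSV
#'
#' Numeric values are rounded to 6 significant digits before writing;
#' re-reading the file reproduces the written values bit-exactly.
#' Undefined scores (e.g. preference with zero occupancy in both zones)
#' are serialized as empty cells.
#'
#' @param scores A data frame (one row per animal x condition x zone, or
#'   any of the package's score layouts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(scores, path) {
  out <- as.data.frame(scores)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- signif(out[[cn]], 6)
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_scores_table
#' @export
read_scores_table <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
}
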