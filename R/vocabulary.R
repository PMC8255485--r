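#' Call subtype vocabulary
#'
#' The closed label vocabulary used throughout the package: the fourteen
#' 50-kHz subtypes of the Wright et al. classification, plus `"Unclear"`
#' (a 50-kHz call not assignable to any named subtype) and `"22kHz"`
#' (long aversive calls).
#'
#' @return Character vector of subtype names.
#' @export
usv_subtypes_50k <- function() {
  c("Trill", "Flat", "Complex", "Composite", "Short",
    "Flat-Trill-combination", "Split", "Trill-with-Jump",
    "Step-Down", "Inverted-U", "Step-Up", "Multi-Step",
    "Downward-Ramp", "Upward-Ramp")
}

#' @rdname usv_subtypes_50k
#' @export
usv_vocabulary <- function() {
  c(usv_subtypes_50k(), "Unclear", "22kHz")
}

#' @rdname usv_subtypes_50k
#' @details `cvs_subtypes()` is the 15-subtype universe entering the
#'   combined vocalization score: all 50-kHz subtypes plus Unclear,
#'   excluding only 22-kHz calls.
#' @export
cvs_subtypes <- function() {
  c(usv_subtypes_50k(), "Unclear")
}

#' Two-letter display codes for frequent subtypes
#'
#' Conventional abbreviations (Tr, Fl, Cx, Ce, Sh, Ft, Sp, Tj, ...) used in
#' figures and reports.
#'
#' @return Named character vector mapping full subtype name to code.
#' @export
subtype_codes <- function() {
  c("Trill" = "Tr", "Flat" = "Fl", "Complex" = "Cx", "Composite" = "Ce",
    "Short" = "Sh", "Flat-Trill-combination" = "Ft", "Split" = "Sp",
    "Trill-with-Jump" = "Tj", "Step-Down" = "Sd", "Inverted-U" = "Iu",
    "Step-Up" = "Su", "Multi-Step" = "Ms", "Downward-Ramp" = "Dr",
    "Upward-Ramp" = "Ur", "Unclear" = "Un", "22kHz" = "22k")
}

#' Convert between call frames and seconds on the label raster
#'
#' One call frame is one bin of the 25 Hz synchronization raster
#' (40 ms by default).
#'
#' @param frames Number of frames.
#' @param seconds Number of seconds.
#' @param frame_rate Raster rate in Hz (default 25).
#' @return Numeric vector.
#' @export
frames_to_seconds <- function(frames, frame_rate = 25) {
  stopifnot(frame_rate > 0)
  frames / frame_rate
}

#' @rdname frames_to_seconds
#' @export
seconds_to_frames <- function(seconds, frame_rate = 25) {
  stopifnot(frame_rate > 0)
  seconds * frame_rate
}

#' Legal conditions per task
#'
#' SDT (sucrose discrimination) pits two sucrose concentrations head to
#' head; SSPT (social-sucrose preference) pits a caged juvenile against one
#' sucrose concentration.
#'
#' @param task `"SDT"`, `"SSPT"` or `"Habituation"`.
#' @return Character vector of condition codes.
#' @export
task_conditions <- function(task) {
  switch(task,
    SDT = c("2v5", "2v10", "5v10"),
    SSPT = c("Jv2", "Jv5", "Jv10"),
    Habituation = "open",
    stop("unknown task: ", task)
  )
}

#' Reward identities contrasted by a condition
#'
#' @param condition Condition code, e.g. `"2v10"` or `"Jv5"`.
#' @return List with elements `focal` and `other`: the focal reward (higher
#'   sucrose for SDT, Juvenile for SSPT) and the alternative.
#' @export
condition_rewards <- function(condition) {
  known <- list(
    "2v5"  = list(focal = "5",        other = "2"),
    "2v10" = list(focal = "10",       other = "2"),
    "5v10" = list(focal = "10",       other = "5"),
    "Jv2"  = list(focal = "Juvenile", other = "2"),
    "Jv5"  = list(focal = "Juvenile", other = "5"),
    "Jv10" = list(focal = "Juvenile", other = "10")
  )
  out <- known[[condition]]
  if (is.null(out)) stop("unknown condition: ", condition)
  out
}

#' Sucrose concentration (%) of the non-social reward in an SSPT condition
#'
#' @param condition SSPT condition code (`"Jv2"`, `"Jv5"`, `"Jv10"`).
#' @return Numeric percentage.
#' @export
sspt_sucrose_level <- function(condition) {
  lv <- c(Jv2 = 2, Jv5 = 5, Jv10 = 10)[condition]
  if (any(is.na(lv))) stop("not an SSPT condition: ",
                           paste(condition[is.na(lv)], collapse = ", "))
  unname(lv)
}
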