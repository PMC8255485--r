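# small programmatic fixtures shared across test files

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# two-call label fixture: a short Trill and a long 22-kHz call
label_fixture_path <- function() {
  write_tmp(c(
    "start\tend\tlabel\tamp_ch1\tamp_ch2\tamp_ch3\tamp_ch4",
    "0.50\t0.54\tTrill\t-40\t-35\t-50\t-60",
    "1.00\t2.20\t22kHz\t-42\t-48\t-39\t-55"
  ))
}

track_fixture_path <- function() {
  write_tmp(c(
    "t\tx\ty",
    "0.00\t1.0\t2.0",
    "0.04\t1.5\t2.5",
    "0.08\t2.0\t3.0"
  ))
}

# tiny cohort used by round-trip / pipeline tests
small_cohort <- function(seed = 11, n_animals = 2, duration = 120) {
  generate_cohort(sim_config(n_animals = n_animals,
                             trial_duration = duration, seed = seed))
}

# a constant-position track inside a given zone polygon
constant_track <- function(map, zone, duration = 600, frame_rate = 25) {
  poly <- map$polygons[[zone]]
  cx <- mean(poly$x); cy <- mean(poly$y)
  n <- duration * frame_rate
  tibble::tibble(t = (seq_len(n) - 1) / frame_rate, x = cx, y = cy,
                 gap = FALSE)
}

# independent sums-of-squares oracle for fully within-subject designs
# (one or two factors), returning F per effect
rm_anova_oracle <- function(data, dv, within, subject) {
  y <- data[[dv]]
  s <- factor(data[[subject]])
  A <- factor(data[[within[1]]])
  gm <- mean(y)
  if (length(within) == 1) {
    a <- nlevels(A); ns <- nlevels(s)
    ma <- tapply(y, A, mean); ms <- tapply(y, s, mean)
    mas <- tapply(y, list(A, s), mean)
    ss_a <- ns * sum((ma - gm)^2)
    # interaction residual: y_as - ma - ms + gm
    ss_as <- sum((t(t(mas) - ms) - ma + gm)^2)
    f <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (ns - 1)))
    return(c(A = f))
  }
  B <- factor(data[[within[2]]])
  a <- nlevels(A); b <- nlevels(B); ns <- nlevels(s)
  ma <- tapply(y, A, mean); mb <- tapply(y, B, mean)
  ms <- tapply(y, s, mean)
  mab <- tapply(y, list(A, B), mean)
  mas <- tapply(y, list(A, s), mean)
  mbs <- tapply(y, list(B, s), mean)
  mabs <- tapply(y, list(A, B, s), mean)
  ss_a <- b * ns * sum((ma - gm)^2)
  ss_b <- a * ns * sum((mb - gm)^2)
  ss_ab <- ns * sum((mab - outer(ma, mb, "+") + gm)^2)
  ss_as <- b * sum((mas - outer(ma, ms, "+") + gm)^2)
  ss_bs <- a * sum((mbs - outer(mb, ms, "+") + gm)^2)
  resid <- mabs
  for (i in 1:a) for (j in 1:b) for (k in 1:ns) {
    resid[i, j, k] <- mabs[i, j, k] - mab[i, j] - mas[i, k] -
      mbs[j, k] + ma[i] + mb[j] + ms[k] - gm
  }
  ss_abs <- sum(resid^2)
  c(A = (ss_a / (a - 1)) / (ss_as / ((a - 1) * (ns - 1))),
    B = (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (ns - 1))),
    AB = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_abs / ((a - 1) * (b - 1) * (ns - 1))))
}
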