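#' Construct the X-maze zone map
#'
#' The maze is a plus/X shape: a central neutral platform (disc) with four
#' arms extending north, east, south and west. Each arm carries a sandpaper
#' zone at its entrance and a reward zone at its far end. Which reward
#' identity (2%, 5%, 10% sucrose, or Juvenile) sits on which arm depends on
#' the counterbalancing group (A or B). Coordinates are cm, origin at the
#' maze center, y increasing toward group A's Juvenile arm.
#'
#' @param group Counterbalancing group, `"A"` or `"B"`.
#' @param arm_length Arm length in cm beyond the neutral platform.
#' @param arm_width Arm width in cm.
#' @param neutral_radius Radius of the central neutral platform in cm.
#' @param reward_depth Depth (cm) of the reward zone at the arm end.
#' @param sandpaper_depth Depth (cm) of the sandpaper zone at the arm
#'   entrance.
#' @return A `zone_map` object: named list of polygons (data frames with
#'   columns `x`, `y`), the neutral disc, and the reward-identity
#'   assignment for the group.
#' @export
make_zone_map <- function(group = "A", arm_length = 60, arm_width = 14,
                          neutral_radius = 18, reward_depth = 20,
                          sandpaper_depth = 17) {
  stopifnot(group %in% c("A", "B"), arm_length > 0, arm_width > 0,
            neutral_radius > 0, reward_depth > 0, sandpaper_depth > 0,
            reward_depth + sandpaper_depth <= arm_length)
  r0 <- neutral_radius
  r1 <- neutral_radius + arm_length
  hw <- arm_width / 2

  # rectangle along +y, then rotated per arm
  rect <- function(lo, hi) {
    data.frame(x = c(-hw, hw, hw, -hw), y = c(lo, lo, hi, hi))
  }
  rot <- function(poly, theta) {
    data.frame(x = cos(theta) * poly$x - sin(theta) * poly$y,
               y = sin(theta) * poly$x + cos(theta) * poly$y)
  }
  arms <- c(N = 0, E = -pi / 2, S = pi, W = pi / 2)
  polys <- list()
  for (a in names(arms)) {
    polys[[paste0("arm_", a, "_sandpaper")]] <-
      rot(rect(r0, r0 + sandpaper_depth), arms[[a]])
    polys[[paste0("arm_", a, "_reward")]] <-
      rot(rect(r1 - reward_depth, r1), arms[[a]])
  }

  assignment <- switch(group,
    A = c(N = "Juvenile", E = "10", S = "5", W = "2"),
    B = c(N = "5", E = "2", S = "Juvenile", W = "10")
  )

  map <- structure(
    list(polygons = polys,
         neutral = list(center = c(0, 0), radius = r0),
         group = group,
         assignment = assignment,
         geometry = list(arm_length = arm_length, arm_width = arm_width,
                         neutral_radius = r0, reward_depth = reward_depth,
                         sandpaper_depth = sandpaper_depth)),
    class = "zone_map")
  validate_zone_map(map)
  map
}

validate_zone_map <- function(map) {
  if (length(map$polygons) != 8)
    stop("zone map must define 8 arm polygons (4 reward + 4 sandpaper)")
  ids <- map$assignment
  if (anyDuplicated(ids))
    stop("reward identity mapped to two zones: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  if (!setequal(ids, c("2", "5", "10", "Juvenile")))
    stop("assignment must cover rewards 2, 5, 10, Juvenile exactly once")
  # pairwise disjointness: vertices of one polygon must not fall inside
  # another, and bounding boxes of distinct arms must not overlap interior
  nm <- names(map$polygons)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i == j) next
      p <- map$polygons[[nm[i]]]
      inside <- point_in_polygon(p$x, p$y, map$polygons[[nm[j]]])
      if (any(inside))
        stop("overlapping polygons: ", nm[i], " and ", nm[j])
    }
  }
  invisible(map)
}

#' Point-in-polygon test (ray casting)
#'
#' Vectorized over points; the polygon is a data frame of vertices in
#' order. Points exactly on an edge may fall on either side; the zone
#' polygons are separated by gaps so this never matters in practice.
#'
#' @param x,y Point coordinates.
#' @param poly Data frame with columns `x`, `y`.
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly$x; py <- poly$y
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Zone name at maze coordinates
#'
#' @param x,y Coordinates in cm (vectorized).
#' @param map A `zone_map`.
#' @return Character vector: a polygon name, `"neutral"` for points on the
#'   central platform or in no named polygon.
#' @export
zone_at <- function(x, y, map) {
  stopifnot(inherits(map, "zone_map"))
  out <- rep("neutral", length(x))
  for (nm in names(map$polygons)) {
    hit <- out == "neutral" & point_in_polygon(x, y, map$polygons[[nm]])
    out[hit] <- nm
  }
  out
}

#' Zone names holding the two rewards of a condition
#'
#' @param condition Condition code (see [condition_rewards()]).
#' @param map A `zone_map`.
#' @return Named character vector with entries `focal` and `other` giving
#'   reward-zone polygon names.
#' @export
condition_zones <- function(condition, map) {
  rw <- condition_rewards(condition)
  arm_of <- function(identity) {
    names(map$assignment)[map$assignment == identity]
  }
  c(focal = paste0("arm_", arm_of(rw$focal), "_reward"),
    other = paste0("arm_", arm_of(rw$other), "_reward"))
}

#' Read a zone map from a YAML config
#'
#' The config declares the maze geometry and the group; polygons are
#' rebuilt from the geometry so the invariants (disjointness, one zone per
#' reward identity) are checked at load.
#'
#' @param path Path to a YAML file with keys `group`, `arm_length`,
#'   `arm_width`, `neutral_radius`, `reward_depth`, `sandpaper_depth`.
#' @return A `zone_map`.
#' @export
load_zone_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("group", "arm_length", "arm_width", "neutral_radius",
            "reward_depth", "sandpaper_depth")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("zone map config missing keys: ", paste(missing, collapse = ", "))
  make_zone_map(group = cfg$group, arm_length = cfg$arm_length,
                arm_width = cfg$arm_width,
                neutral_radius = cfg$neutral_radius,
                reward_depth = cfg$reward_depth,
                sandpaper_depth = cfg$sandpaper_depth)
}

#' Write a zone map config to YAML
#'
#' @param map A `zone_map`.
#' @param path Output path.
#' @export
write_zone_map <- function(map, path) {
  yaml::write_yaml(c(list(group = map$group), map$geometry), path)
  invisible(path)
}
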