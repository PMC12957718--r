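# Roost detection: nightly median locations, five-night interval units,
# communal-attendance flags, roost-site clusters and study-area weights.

#' Detection configuration
#'
#' Parameters of the spatio-temporal communal-roost rule: a focal bird is at
#' a communal roost in an interval if at least `min_others` other tagged birds
#' had a night location within `radius` metres of one of its night locations
#' during the `window`-night interval.
#'
#' @param radius Buffer radius in metres (default 300).
#' @param window Interval length in nights (default 5).
#' @param min_others Minimum number of distinct other birds (default 2).
#' @param matching `"cross_night"` counts another bird if any of its night
#'   locations in the interval falls within the buffer of any focal night
#'   location (default); `"same_night"` requires the two birds on the same
#'   night.
#' @param twilight Solar elevation (degrees) defining dusk/dawn; default -6
#'   (civil twilight).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(radius = 300, window = 5, min_others = 2,
                             matching = c("cross_night", "same_night"),
                             twilight = -6) {
  matching <- match.arg(matching)
  stopifnot(radius > 0, window >= 1, min_others >= 1)
  structure(list(radius = radius, window = as.integer(window),
                 min_others = as.integer(min_others), matching = matching,
                 twilight = twilight),
            class = "detection_config")
}

#' Nightly median locations from projected fixes
#'
#' A fix belongs to night `d` if it falls after civil dusk of local date `d`,
#' or before civil dawn of local date `d + 1` (the tag duty cycle brackets
#' this window at 07:00--21:00 local). Per bird and night, the component-wise
#' median of the qualifying planar fixes is returned.
#'
#' @param fixes Data frame with columns `bird_id`, `timestamp` (POSIXct, UTC),
#'   `lon`, `lat`, and planar `x`, `y` (see [project_coordinates()]).
#' @param twilight Solar elevation threshold in degrees (default -6).
#' @param duty_window Local duty-cycle clock hours, default `c(7, 21)`.
#' @param tz Local timezone used for night dates; default `"Etc/GMT-1"` (CET
#'   without daylight saving, which does not apply in winter).
#' @return Data frame with `bird_id`, `night_date` (date of the evening),
#'   `x`, `y`, `n_fixes`.
#' @export
extract_night_locations <- function(fixes, twilight = -6,
                                    duty_window = c(7, 21), tz = "Etc/GMT-1") {
  if (nrow(fixes) == 0)
    return(data.frame(bird_id = character(), night_date = as.Date(character()),
                      x = numeric(), y = numeric(), n_fixes = integer()))
  lt <- as.POSIXlt(fixes$timestamp, tz = tz)
  local_date <- as.Date(lt)
  local_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  evening <- local_hour >= 12

  keep <- rep(FALSE, nrow(fixes))
  night <- local_date
  ev <- which(evening)
  if (length(ev)) {
    dusk <- civil_dusk(local_date[ev], fixes$lon[ev], fixes$lat[ev],
                       elevation = twilight)
    keep[ev] <- as.numeric(fixes$timestamp[ev]) >= as.numeric(dusk) &
      local_hour[ev] <= duty_window[2]
  }
  mo <- which(!evening)
  if (length(mo)) {
    dawn <- civil_dawn(local_date[mo], fixes$lon[mo], fixes$lat[mo],
                       elevation = twilight)
    keep[mo] <- as.numeric(fixes$timestamp[mo]) <= as.numeric(dawn) &
      local_hour[mo] >= duty_window[1]
    night[mo] <- local_date[mo] - 1
  }

  f <- fixes[keep, , drop = FALSE]
  night <- night[keep]
  if (nrow(f) == 0)
    return(data.frame(bird_id = character(), night_date = as.Date(character()),
                      x = numeric(), y = numeric(), n_fixes = integer()))
  key <- interaction(f$bird_id, night, drop = TRUE)
  out <- data.frame(
    bird_id = tapply(as.character(f$bird_id), key, `[`, 1),
    night_date = as.Date(as.numeric(tapply(as.numeric(night), key, `[`, 1))),
    x = as.numeric(tapply(f$x, key, stats::median)),
    y = as.numeric(tapply(f$y, key, stats::median)),
    n_fixes = as.integer(tapply(f$x, key, length)),
    row.names = NULL)
  out[order(out$bird_id, out$night_date), , drop = FALSE]
}

#' Assign winter and interval indices to night locations
#'
#' Winters run from 1 November to 31 January (92 nights) and are labelled by
#' the year of the 1 November. Intervals are consecutive non-overlapping
#' blocks of `window` nights anchored at 1 November; with the default
#' five-night window this gives 18 full blocks plus one 2-night block, i.e.
#' 19 intervals per winter. Nights outside November--January are dropped with
#' a message.
#'
#' @param nights Data frame from [extract_night_locations()].
#' @param window Block length in nights (default 5).
#' @return `nights` with `winter_id`, `interval_index` and `interval_t`
#'   (the interval index standardised over the winter sequence) appended.
#' @export
assign_intervals <- function(nights, window = 5) {
  mth <- as.integer(format(nights$night_date, "%m"))
  yr <- as.integer(format(nights$night_date, "%Y"))
  in_window <- mth >= 11 | mth == 1
  if (any(!in_window))
    message(sum(!in_window), " night(s) outside the Nov-Jan window dropped")
  nights <- nights[in_window, , drop = FALSE]
  mth <- mth[in_window]; yr <- yr[in_window]
  winter_id <- ifelse(mth >= 11, yr, yr - 1L)
  nov1 <- as.Date(paste0(winter_id, "-11-01"))
  day_index <- as.integer(nights$night_date - nov1)   # 0..91
  nights$winter_id <- as.integer(winter_id)
  nights$interval_index <- day_index %/% as.integer(window) + 1L
  n_int <- n_intervals_per_winter(window)
  idx <- seq_len(n_int)
  nights$interval_t <- (nights$interval_index - mean(idx)) / stats::sd(idx)
  nights
}

#' Number of interval blocks per winter
#'
#' @param window Block length in nights.
#' @return Integer count of blocks covering the 92-night winter.
#' @export
n_intervals_per_winter <- function(window = 5) {
  as.integer(ceiling(92 / window))
}

#' Detect communal-roost attendance
#'
#' For each bird and interval block, counts the distinct other birds whose
#' night locations fall within the buffer radius of the focal bird's night
#' locations (cross-night or same-night matching, see [detection_config()]),
#' and flags attendance when that count reaches `min_others`. Distances are
#' closed-ball: a pair exactly at the radius counts as inside.
#'
#' @param nights Night locations annotated by [assign_intervals()].
#' @param config A [detection_config()].
#' @return List with `units` (one row per bird x winter x interval:
#'   `n_nights_observed`, `n_neighbours`, `attendance`) and `nights` (the
#'   input with `n_neighbours_night`, the same-night distinct-other count,
#'   appended).
#' @export
detect_attendance <- function(nights, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  need <- c("bird_id", "night_date", "x", "y", "winter_id", "interval_index")
  if (!all(need %in% names(nights)))
    stop("nights must be annotated with assign_intervals()")
  nights$n_neighbours_night <- 0L
  blocks <- split(seq_len(nrow(nights)),
                  list(nights$winter_id, nights$interval_index), drop = TRUE)
  units <- vector("list", length(blocks))
  r <- config$radius
  for (k in seq_along(blocks)) {
    ii <- blocks[[k]]
    b <- nights[ii, , drop = FALSE]
    m <- nrow(b)
    dx <- outer(b$x, b$x, "-"); dy <- outer(b$y, b$y, "-")
    close <- (dx * dx + dy * dy) <= r * r
    diff_bird <- outer(b$bird_id, b$bird_id, "!=")
    same_night <- outer(as.numeric(b$night_date), as.numeric(b$night_date), "==")
    # per-night same-night neighbour counts (always same-night geometry)
    adj_sn <- close & diff_bird & same_night
    cnt <- integer(m)
    for (i in seq_len(m))
      cnt[i] <- length(unique(b$bird_id[adj_sn[i, ]]))
    nights$n_neighbours_night[ii] <- cnt
    adj <- if (config$matching == "same_night") adj_sn else close & diff_bird
    birds <- unique(b$bird_id)
    nn <- integer(length(birds))
    nobs <- integer(length(birds))
    for (j in seq_along(birds)) {
      rows <- b$bird_id == birds[j]
      nobs[j] <- sum(rows)
      nn[j] <- length(unique(b$bird_id[colSums(adj[rows, , drop = FALSE]) > 0]))
    }
    units[[k]] <- data.frame(
      bird_id = birds,
      winter_id = b$winter_id[1],
      interval_index = b$interval_index[1],
      n_nights_observed = nobs,
      n_neighbours = nn,
      attendance = as.integer(nn >= config$min_others))
  }
  units <- do.call(rbind, units)
  units <- units[order(units$bird_id, units$winter_id, units$interval_index), ,
                 drop = FALSE]
  rownames(units) <- NULL
  list(units = units, nights = nights)
}

#' Cluster nightly locations into roost sites
#'
#' Single-linkage connected components of one night's median locations under
#' the linkage radius; each component is a roost site with its mean-location
#' centroid and tagged-member count.
#'
#' @param nights Night locations (any annotation level).
#' @param linkage_radius Linkage distance in metres (default 300).
#' @return Data frame with `site_id`, `night_date`, `x`, `y` (centroid),
#'   `n_tagged`, `member_ids` (comma-separated bird ids).
#' @export
cluster_roost_sites <- function(nights, linkage_radius = 300) {
  out <- lapply(split(nights, nights$night_date), function(b) {
    m <- nrow(b)
    comp <- if (m == 1) 1L else {
      hc <- stats::hclust(stats::dist(cbind(b$x, b$y)), method = "single")
      stats::cutree(hc, h = linkage_radius)
    }
    data.frame(
      night_date = b$night_date[1],
      site_local = seq_len(max(comp)),
      x = as.numeric(tapply(b$x, comp, mean)),
      y = as.numeric(tapply(b$y, comp, mean)),
      n_tagged = as.integer(table(comp)),
      member_ids = vapply(split(as.character(b$bird_id), comp),
                          function(v) paste(sort(v), collapse = ","), ""))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$site_id <- sprintf("%s_%02d", format(res$night_date), res$site_local)
  res$site_local <- NULL
  res[, c("site_id", "night_date", "x", "y", "n_tagged", "member_ids")]
}

#' Study-area observation weights
#'
#' For each interval unit, the mean distance of its night locations to the
#' study-area polygon (zero inside) is scaled by the maximum mean distance
#' over all units and subtracted from one: units fully inside the study area
#' get weight 1, the farthest unit gets weight 0. These weights down-weight
#' intervals spent far from the study area, where absence from a communal
#' roost of tagged birds is least informative.
#'
#' @param units Interval units from [detect_attendance()].
#' @param nights Annotated night locations (same run).
#' @param study_area Two-column matrix of polygon vertices in planar metres.
#' @return `units` with a `weight` column and `mean_margin_dist` appended.
#' @export
compute_weights <- function(units, nights, study_area) {
  d <- distance_to_polygon(cbind(nights$x, nights$y), study_area)
  key_n <- paste(nights$bird_id, nights$winter_id, nights$interval_index)
  key_u <- paste(units$bird_id, units$winter_id, units$interval_index)
  md <- tapply(d, key_n, mean)
  units$mean_margin_dist <- as.numeric(md[key_u])
  dmax <- max(units$mean_margin_dist)
  units$weight <- if (dmax > 0) 1 - units$mean_margin_dist / dmax else 1
  units
}

#' Attach individual covariates to interval units
#'
#' Adds sex, tagging class, winter-count age (juvenile-tagged birds only; age
#' counts the winter season, so a bird born in spring of year y is age 1 in
#' the winter labelled y) and breeding status (1 from the first breeding
#' winter onwards) to detection units.
#'
#' @param units Interval units from [detect_attendance()].
#' @param individuals Individual table with `bird_id`, `sex`, `tag_class`,
#'   `birth_year`, `first_breeding_winter` (NA if never breeding).
#' @return `units` with `sex`, `tag_class`, `age`, `breeding_status`.
#' @export
build_interval_units <- function(units, individuals) {
  i <- match(units$bird_id, individuals$bird_id)
  if (anyNA(i)) stop("units contain birds missing from individuals")
  units$sex <- individuals$sex[i]
  units$tag_class <- individuals$tag_class[i]
  units$age <- ifelse(units$tag_class == "juvenile",
                      units$winter_id - individuals$birth_year[i] + 1L, NA_integer_)
  fbw <- individuals$first_breeding_winter[i]
  units$breeding_status <- as.integer(!is.na(fbw) & units$winter_id >= fbw)
  units
}

#' Sensitivity sweep over detection thresholds
#'
#' Re-runs the attendance rule over a grid of radii, window lengths and
#' minimum-other-bird counts and reports the attendance rate for each
#' combination. Attendance counts are non-decreasing in radius and window
#' and non-increasing in `min_others`.
#'
#' @param nights Night locations (un-annotated; intervals are re-assigned for
#'   each window value).
#' @param radii,windows,min_others_grid Numeric vectors defining the grid.
#' @param matching Matching rule, as in [detection_config()].
#' @return Data frame with one row per combination: `radius`, `window`,
#'   `min_others`, `n_units`, `attendance_rate`.
#' @export
sensitivity_sweep <- function(nights, radii = c(150, 300, 600),
                              windows = c(1, 3, 5), min_others_grid = c(1, 2, 3),
                              matching = "cross_night") {
  if (!length(radii) || !length(windows) || !length(min_others_grid))
    stop("empty sensitivity grid")
  grid <- expand.grid(radius = radii, window = windows,
                      min_others = min_others_grid)
  res <- vector("list", nrow(grid))
  for (w in unique(grid$window)) {
    ann <- assign_intervals(nights, window = w)
    for (r in unique(grid$radius)) {
      det <- detect_attendance(ann, detection_config(
        radius = r, window = w, min_others = 1, matching = matching))
      for (k in which(grid$window == w & grid$radius == r)) {
        att <- det$units$n_neighbours >= grid$min_others[k]
        res[[k]] <- data.frame(radius = r, window = w,
                               min_others = grid$min_others[k],
                               n_units = nrow(det$units),
                               attendance_rate = mean(att))
      }
    }
  }
  do.call(rbind, res)
}
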