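# CSV/GeoJSON interchange for synthetic fixtures and pipeline inputs.
#
# All files are comma-separated UTF-8 with ISO-8601 UTC timestamps and WGS84
# coordinates printed at fixed precision, so write -> read -> write
# round-trips byte-identically.

.fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- ""
  out
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic fixture to interchange files
#'
#' Writes `fixes.csv` (bird_id, timestamp, lon, lat), `individuals.csv`,
#' `broods.csv`, `pairs.csv`, `truth.csv` and `study_area.geojson` into a
#' directory. Planar coordinates are converted to WGS84 with the fixture's
#' declared projection.
#'
#' @param pop A [generate_population()] result.
#' @param sim A [simulate_winter_nights()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(pop, sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prj <- default_projection()
  fx <- sim$fixes
  .write_csv(data.frame(bird_id = fx$bird_id, timestamp = .fmt_ts(fx$timestamp),
                        lon = .fmt_num(fx$lon), lat = .fmt_num(fx$lat)),
             file.path(dir, "fixes.csv"))
  ind <- pop$individuals
  .write_csv(data.frame(bird_id = ind$bird_id, sex = ind$sex,
                        tag_class = ind$tag_class, birth_year = ind$birth_year,
                        natal_nest_id = ind$natal_nest_id,
                        first_breeding_winter = ind$first_breeding_winter,
                        death_date = format(ind$death_date),
                        tag_start_winter = ind$tag_start_winter),
             file.path(dir, "individuals.csv"))
  bll <- unproject_xy(cbind(pop$broods$x, pop$broods$y), prj)
  .write_csv(data.frame(nest_id = pop$broods$nest_id, year = pop$broods$year,
                        bird_id = pop$broods$bird_id,
                        lon = .fmt_num(bll[, 1]), lat = .fmt_num(bll[, 2])),
             file.path(dir, "broods.csv"))
  if (nrow(pop$pairs)) {
    pll <- unproject_xy(cbind(pop$pairs$x, pop$pairs$y), prj)
    pdf <- data.frame(year = pop$pairs$year, male_id = pop$pairs$male_id,
                      female_id = pop$pairs$female_id,
                      nest_id = pop$pairs$nest_id,
                      lon = .fmt_num(pll[, 1]), lat = .fmt_num(pll[, 2]))
  } else {
    pdf <- data.frame(year = integer(), male_id = character(),
                      female_id = character(), nest_id = character(),
                      lon = character(), lat = character())
  }
  .write_csv(pdf, file.path(dir, "pairs.csv"))
  tt <- sim$truth
  .write_csv(data.frame(bird_id = tt$bird_id, winter_id = tt$winter_id,
                        night_date = format(tt$night_date),
                        interval_index = tt$interval_index, age = tt$age,
                        breeding = tt$breeding, attendance = tt$attendance,
                        site_id = ifelse(is.na(tt$site_id), "", tt$site_id),
                        x = .fmt_num(tt$x, 2), y = .fmt_num(tt$y, 2),
                        co_mate = as.integer(tt$co_mate),
                        co_kin = as.integer(tt$co_kin)),
             file.path(dir, "truth.csv"))
  all_ll <- unproject_xy(pop$study_area, prj)
  write_geojson_polygon(all_ll, file.path(dir, "study_area.geojson"))
  invisible(dir)
}

#' Read fixture interchange files
#'
#' @param dir Directory written by [write_fixture()] (or hand-assembled in
#'   the same formats).
#' @return List with `fixes`, `individuals`, `broods`, `pairs`, `truth`
#'   (when present), `study_area_lonlat` and the default `projection`.
#' @export
read_fixture <- function(dir) {
  prj <- default_projection()
  out <- list(
    fixes = read_fixes(file.path(dir, "fixes.csv")),
    individuals = read_individuals(file.path(dir, "individuals.csv")),
    broods = .read_xy_csv(file.path(dir, "broods.csv"), prj),
    pairs = .read_xy_csv(file.path(dir, "pairs.csv"), prj),
    projection = prj)
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) {
    tt <- utils::read.csv(tp, stringsAsFactors = FALSE)
    tt$night_date <- as.Date(tt$night_date)
    tt$site_id[tt$site_id == ""] <- NA_character_
    out$truth <- tt
  }
  ap <- file.path(dir, "study_area.geojson")
  if (file.exists(ap)) out$study_area_lonlat <- read_geojson_polygon(ap)
  out
}

.read_xy_csv <- function(path, projection) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lon = "numeric", lat = "numeric"))
  if (nrow(df)) {
    xy <- project_lonlat(df[, c("lon", "lat")], projection)
    df$x <- xy[, 1]; df$y <- xy[, 2]
  } else {
    df$x <- numeric(); df$y <- numeric()
  }
  df
}

#' Read a GPS fix table
#'
#' Expects a CSV with header `bird_id,timestamp,lon,lat`, ISO-8601 UTC
#' timestamps and WGS84 decimal-degree coordinates. Rows with unparsable
#' timestamps or coordinates are dropped with a message naming their count
#' and row numbers; output is stably sorted by bird and time.
#'
#' @param path CSV path.
#' @return Data frame `bird_id`, `timestamp` (POSIXct UTC), `lon`, `lat`.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("bird_id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fixes file missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  alt <- is.na(ts)
  if (any(alt))  # tolerate a space separator
    ts[alt] <- as.POSIXct(df$timestamp[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- is.na(ts) | is.na(lon) | is.na(lat) | abs(lat) > 90
  if (any(bad))
    message(sum(bad), " malformed fix row(s) dropped (rows ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
  out <- data.frame(bird_id = df$bird_id[!bad], timestamp = ts[!bad],
                    lon = lon[!bad], lat = lat[!bad])
  out[order(out$bird_id, out$timestamp), , drop = FALSE]
}

#' Read an individual-metadata table
#'
#' @param path CSV path with columns `bird_id`, `sex`, `tag_class`,
#'   `birth_year`, `natal_nest_id`, `first_breeding_winter`, `death_date`.
#' @return Data frame with typed columns.
#' @export
read_individuals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$death_date <- as.Date(ifelse(df$death_date == "", NA, df$death_date))
  for (col in c("birth_year", "first_breeding_winter"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  df
}
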