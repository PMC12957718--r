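# Solar position and civil twilight.
#
# Low-precision NOAA solar equations (fractional-year Fourier expansions for
# declination and the equation of time). Accuracy of the resulting twilight
# times is a minute or two, which is ample for assigning hourly fixes to
# nights.

.frac_year <- function(date) {
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  2 * pi / 365 * (doy - 1 + 0.5)
}

.solar_params <- function(date) {
  g <- .frac_year(date)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)  # minutes, radians
}

#' Solar elevation angle
#'
#' @param time POSIXct (any timezone; converted to UTC).
#' @param lon,lat Observer position, WGS84 degrees.
#' @return Elevation of the sun above the horizon, degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  tu <- as.POSIXlt(time, tz = "UTC")
  sp <- .solar_params(as.Date(tu))
  tst <- (tu$hour * 60 + tu$min + tu$sec / 60 + sp$eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180  # solar hour angle
  phi <- lat * pi / 180
  cosz <- sin(phi) * sin(sp$decl) + cos(phi) * cos(sp$decl) * cos(ha)
  90 - acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

# Sun-crossing time (UTC, minutes after midnight) for a given zenith angle;
# morning = TRUE for the dawn-side crossing.
.crossing_utc_min <- function(date, lon, lat, zenith_deg, morning) {
  sp <- .solar_params(date)
  phi <- lat * pi / 180
  z <- zenith_deg * pi / 180
  cosha <- cos(z) / (cos(phi) * cos(sp$decl)) - tan(phi) * tan(sp$decl)
  if (any(abs(cosha) > 1))
    stop("sun does not cross the requested elevation on this date/latitude")
  ha <- acos(cosha) * 180 / pi
  if (morning) 720 - 4 * (lon + ha) - sp$eqtime else 720 - 4 * (lon - ha) - sp$eqtime
}

#' Civil twilight times
#'
#' Time at which the sun crosses the given elevation threshold (default -6
#' degrees, civil twilight) in the morning (`civil_dawn`) or evening
#' (`civil_dusk`) of a given date.
#'
#' @param date Date (local calendar date).
#' @param lon,lat Observer position, WGS84 degrees.
#' @param elevation Solar elevation threshold in degrees (default -6, civil).
#' @return POSIXct in UTC.
#' @export
civil_dawn <- function(date, lon, lat, elevation = -6) {
  date <- as.Date(date)
  mins <- .crossing_utc_min(date, lon, lat, 90 - elevation, morning = TRUE)
  as.POSIXct(date, tz = "UTC") + mins * 60
}

#' @rdname civil_dawn
#' @export
civil_dusk <- function(date, lon, lat, elevation = -6) {
  date <- as.Date(date)
  mins <- .crossing_utc_min(date, lon, lat, 90 - elevation, morning = FALSE)
  as.POSIXct(date, tz = "UTC") + mins * 60
}
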