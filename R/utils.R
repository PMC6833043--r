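# Shared helpers: distances, local metric frame, half-open interval algebra.

#' Haversine distance in metres
#'
#' Great-circle distance on a sphere of radius 6371.0088 km, the distance
#' metric used throughout the package (geofencing, stop detection, home
#' clustering). Arguments recycle a length-1 point against a vector.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  cpp_haversine(as.numeric(lat1), as.numeric(lon1),
                as.numeric(lat2), as.numeric(lon2))
}

# Metres east/north -> degrees, in a locally flat frame about (lat0, lon0).
# Adequate below a few kilometres, which is the scale of daily mobility here.
offset_latlon <- function(lat0, lon0, east_m, north_m) {
  m_per_deg <- pi / 180 * 6371008.8
  list(lat = lat0 + north_m / m_per_deg,
       lon = lon0 + east_m / (m_per_deg * cos(lat0 * pi / 180)))
}

# POSIXct (UTC, "civil clock time") helpers ---------------------------------

civil_time <- function(x, origin = "1970-01-01") {
  as.POSIXct(x, origin = origin, tz = "UTC")
}

parse_civil <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

civil_date <- function(x) as.Date(x, tz = "UTC")

fmt_civil <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

# Interval algebra ----------------------------------------------------------
# Events are half-open [start, end) at 1-s resolution. They are mapped to
# closed integer IRanges [start, end - 1] so that abutting events do not
# overlap and widths equal durations in seconds.

iv_ranges <- function(start, end) {
  s <- as.integer(round(as.numeric(start)))
  e <- as.integer(round(as.numeric(end)))
  keep <- e > s
  IRanges::IRanges(start = s[keep], end = e[keep] - 1L)
}

iv_seconds <- function(ir) sum(as.numeric(IRanges::width(ir)))

events_ranges <- function(events) iv_ranges(events$start, events$end)

# Total length (seconds) of the pairwise intersection of two event sets.
iv_intersect_seconds <- function(a, b) {
  iv_seconds(IRanges::intersect(IRanges::reduce(a), IRanges::reduce(b)))
}

empty_events <- function() {
  tibble::tibble(
    participant_id = character(), date = as.Date(character()),
    kind = character(), source = character(),
    start = civil_time(numeric()), end = civil_time(numeric()),
    duration_min = numeric()
  )
}

duration_min <- function(start, end) as.numeric(end) / 60 - as.numeric(start) / 60

stop_field <- function(..., field = NULL) {
  msg <- paste0(...)
  if (!is.null(field)) msg <- sprintf("%s (field '%s')", msg, field)
  stop(msg, call. = FALSE)
}
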