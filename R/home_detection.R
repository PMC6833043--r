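# Home-location validation: density clustering of first-morning and
# last-evening fixes, compared against the geocoded address.

#' First and last fixes of every valid day
#'
#' Anchor fixes for GPS-based home detection: the first morning and last
#' evening fix of each valid registration day (a single-fix day contributes
#' its fix once).
#'
#' @param days Flagged day table from [flag_valid_days()].
#' @return Tibble of anchor fixes `participant_id, timestamp, lat, lon`.
#' @export
anchor_fixes <- function(days) {
  valid <- days[days$is_valid, ]
  if (nrow(valid) == 0) {
    return(tibble::tibble(participant_id = character(),
                          timestamp = civil_time(numeric()),
                          lat = numeric(), lon = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(valid)), function(i) {
    f <- valid$fixes[[i]]
    f <- f[order(f$timestamp), ]
    idx <- unique(c(1L, nrow(f)))
    tibble::tibble(participant_id = valid$participant_id[i],
                   timestamp = f$timestamp[idx], lat = f$lat[idx],
                   lon = f$lon[idx])
  })
}

# Classic DBSCAN on a haversine distance matrix. Neighbourhoods include the
# point itself (min_pts = 3 means a core point has >= 2 other points within
# eps). Returns an integer cluster label per point, 0 = noise. Intended for
# the small anchor sets used in home detection.
dbscan_haversine <- function(lat, lon, eps_m, min_pts) {
  n <- length(lat)
  if (n == 0) return(integer(0))
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dm[i, ] <- haversine_m(lat[i], lon[i], lat, lon)
  }
  nb <- dm <= eps_m
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      if (!core[q]) next
      for (j in which(nb[q, ])) {
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Validate or replace the geocoded home with a GPS-derived home
#'
#' Clusters the anchor fixes with DBSCAN (haversine metric); the centre of
#' each cluster is the coordinate-wise median of its members. Among the
#' clusters, the one whose centre lies nearest the geocoded address is the
#' GPS home candidate. The home is valid when that centre lies within
#' `max_home_distance_m` of the address. The final coordinates are the GPS
#' candidate if it captures strictly more of `all_fixes` within a 60-m
#' buffer than the address does, else the address. Ties between two equally
#' near clusters go to the larger cluster, then to the lexicographically
#' smaller centre.
#'
#' @param anchors Anchor fixes of one participant ([anchor_fixes()]).
#' @param address_home Named list or one-row data frame with `lat`, `lon`.
#' @param eps_m,min_pts DBSCAN parameters (defaults 60 m, 3 points).
#' @param max_home_distance_m Maximum address-to-GPS-home distance for a
#'   valid home (default 150 m).
#' @param all_fixes All fixes of the participant, used for the buffer-count
#'   replacement rule.
#' @return One-row tibble `lat, lon, source ("address"/"gps"),
#'   distance_to_address_m, is_valid, note`.
#' @export
detect_home <- function(anchors, address_home, eps_m = 60, min_pts = 3,
                        max_home_distance_m = 150, all_fixes = NULL) {
  addr_lat <- address_home$lat[1]
  addr_lon <- address_home$lon[1]
  invalid <- function(note) {
    tibble::tibble(lat = addr_lat, lon = addr_lon, source = "address",
                   distance_to_address_m = NA_real_, is_valid = FALSE,
                   note = note)
  }
  if (is.null(anchors) || nrow(anchors) == 0) {
    return(invalid("no anchor fixes"))
  }
  labels <- dbscan_haversine(anchors$lat, anchors$lon, eps_m, min_pts)
  if (all(labels == 0L)) return(invalid("no cluster found (all noise)"))
  centres <- tibble::tibble(
    cluster = sort(unique(labels[labels > 0L]))
  )
  centres$lat <- vapply(centres$cluster,
                        function(k) median(anchors$lat[labels == k]),
                        numeric(1))
  centres$lon <- vapply(centres$cluster,
                        function(k) median(anchors$lon[labels == k]),
                        numeric(1))
  centres$size <- vapply(centres$cluster,
                         function(k) sum(labels == k), numeric(1))
  centres$dist <- haversine_m(centres$lat, centres$lon, addr_lat, addr_lon)
  centres <- centres[order(centres$dist, -centres$size, centres$lat,
                           centres$lon), ]
  gps_home <- centres[1, ]
  is_valid <- gps_home$dist < max_home_distance_m

  source <- "address"
  lat <- addr_lat; lon <- addr_lon
  if (is_valid && !is.null(all_fixes) && nrow(all_fixes) > 0) {
    n_gps <- sum(haversine_m(all_fixes$lat, all_fixes$lon,
                             gps_home$lat, gps_home$lon) <= 60)
    n_addr <- sum(haversine_m(all_fixes$lat, all_fixes$lon,
                              addr_lat, addr_lon) <= 60)
    if (n_gps > n_addr) {
      source <- "gps"; lat <- gps_home$lat; lon <- gps_home$lon
    }
  }
  tibble::tibble(lat = lat, lon = lon, source = source,
                 distance_to_address_m = gps_home$dist,
                 is_valid = is_valid, note = NA_character_)
}

#' Resolve home locations for a whole cohort
#'
#' Applies [detect_home()] per participant using their valid-day anchor
#' fixes and all their fixes for the replacement rule.
#'
#' @param days Flagged day table ([flag_valid_days()]).
#' @param homes Geocoded addresses, tibble `participant_id, lat, lon`.
#' @param eps_m,min_pts,max_home_distance_m See [detect_home()].
#' @return Tibble `participant_id, lat, lon, source, distance_to_address_m,
#'   is_valid, note`.
#' @export
resolve_homes <- function(days, homes, eps_m = 60, min_pts = 3,
                          max_home_distance_m = 150) {
  anchors <- anchor_fixes(days)
  purrr::map_dfr(seq_len(nrow(homes)), function(i) {
    pid <- homes$participant_id[i]
    a <- anchors[anchors$participant_id == pid, ]
    pf <- days[days$participant_id == pid, ]
    all_fixes <- if (nrow(pf) > 0) dplyr::bind_rows(pf$fixes) else NULL
    out <- detect_home(a, homes[i, ], eps_m = eps_m, min_pts = min_pts,
                       max_home_distance_m = max_home_distance_m,
                       all_fixes = all_fixes)
    dplyr::bind_cols(tibble::tibble(participant_id = pid), out)
  })
}
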