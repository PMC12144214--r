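#' Track-filter configuration
#'
#' Defaults follow standard Argos processing for slow-swimming marine
#' vertebrates: near-duplicates within 2 min are dropped, implied
#' swimming speeds above 5 km/h are implausible, and sharp out-and-back
#' spikes (turning angle < 15 deg with both adjacent segments > 2.5 km,
#' or < 25 deg with both > 5 km) are removed.
#'
#' @param duplicate_window Near-duplicate window (s).
#' @param vmax Maximum plausible speed (km/h).
#' @param spike_angles Ascending angle thresholds (degrees).
#' @param spike_lengths Ascending segment-length thresholds (km).
#' @param max_gap Trip-splitting gap (days).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(duplicate_window = 120, vmax = 5,
                          spike_angles = c(15, 25),
                          spike_lengths = c(2.5, 5),
                          max_gap = 7) {
  if (vmax <= 0) stop("filter_config: vmax must be > 0", call. = FALSE)
  if (is.unsorted(spike_angles) || is.unsorted(spike_lengths))
    stop("filter_config: angle and length thresholds must be ascending",
         call. = FALSE)
  structure(list(duplicate_window = duplicate_window, vmax = vmax,
                 spike_angles = spike_angles, spike_lengths = spike_lengths,
                 max_gap = max_gap), class = "filter_config")
}

# great-circle distance in km on a sphere of radius 6371 km
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Remove near-duplicate position fixes
#'
#' Drops any fix whose time is `window` seconds or less after the
#' previously retained fix of the same animal; the first fix is always
#' kept.  The pass is greedy in time order, so a chain of closely
#' spaced fixes collapses onto its first member.
#'
#' @param fixes Data frame with `time` (s) and optionally `id`;
#'   must be time-sorted within animal.
#' @param window Duplicate window (s), default 120.
#' @return The retained subset of `fixes`.
#' @export
remove_near_duplicates <- function(fixes, window = 120) {
  one <- function(g) {
    if (nrow(g) == 0) return(g)
    if (is.unsorted(g$time))
      stop("remove_near_duplicates: fixes must be time-sorted", call. = FALSE)
    keep <- logical(nrow(g))
    keep[1] <- TRUE
    last <- g$time[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$time[i] - last > window) {
        keep[i] <- TRUE
        last <- g$time[i]
      }
    }
    g[keep, , drop = FALSE]
  }
  if (!is.null(fixes$id) && length(unique(fixes$id)) > 1) {
    out <- do.call(rbind, lapply(split(fixes, fixes$id), one))
    out <- out[order(out$id, out$time), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    out <- one(fixes)
    rownames(out) <- NULL
    out
  }
}

#' Speed-distance-angle filter for Argos fixes
#'
#' Removes invalid class-Z fixes, then iterates two passes to a fixed
#' point: (i) a speed pass removing fixes that imply a great-circle
#' speed above `vmax` to the previously retained fix, and (ii) an angle
#' pass removing interior spike vertices whose turning angle is below
#' `spike_angles[1]` with both adjacent segments longer than
#' `spike_lengths[1]` km, or below `spike_angles[2]` with both longer
#' than `spike_lengths[2]` km.  The first and last fixes are never
#' removed except by class Z; the output is always a subsequence of the
#' input.
#'
#' @param fixes Deduplicated, time-sorted data frame with `time`,
#'   `lon`, `lat` and optionally `lc`.
#' @param cfg A [filter_config()].
#' @return The retained subset of `fixes`.
#' @export
sda_filter <- function(fixes, cfg = filter_config()) {
  if (!is.null(fixes$lc)) fixes <- fixes[fixes$lc != "Z", , drop = FALSE]
  if (nrow(fixes) < 3) {
    warning("sda_filter: fewer than 3 fixes after class-Z removal; ",
            "returned unfiltered")
    rownames(fixes) <- NULL
    return(fixes)
  }
  repeat {
    n0 <- nrow(fixes)
    fixes <- speed_pass(fixes, cfg$vmax)
    fixes <- angle_pass(fixes, cfg$spike_angles, cfg$spike_lengths)
    if (nrow(fixes) == n0) break
  }
  rownames(fixes) <- NULL
  fixes
}

speed_pass <- function(fixes, vmax) {
  repeat {
    n <- nrow(fixes)
    if (n < 2) return(fixes)
    d <- gc_dist_km(fixes$lon[-n], fixes$lat[-n], fixes$lon[-1], fixes$lat[-1])
    v <- d / (diff(fixes$time) / 3600)
    bad <- which(v > vmax)
    if (!length(bad)) return(fixes)
    i <- bad[1] + 1                      # later fix of the violating pair
    if (i == n) i <- n - 1               # endpoints are protected
    if (i == 1) return(fixes)
    fixes <- fixes[-i, , drop = FALSE]
  }
}

angle_pass <- function(fixes, angles, lengths) {
  repeat {
    n <- nrow(fixes)
    if (n < 3) return(fixes)
    a <- gc_dist_km(fixes$lon[1:(n - 2)], fixes$lat[1:(n - 2)],
                    fixes$lon[2:(n - 1)], fixes$lat[2:(n - 1)])
    b <- gc_dist_km(fixes$lon[2:(n - 1)], fixes$lat[2:(n - 1)],
                    fixes$lon[3:n], fixes$lat[3:n])
    cc <- gc_dist_km(fixes$lon[1:(n - 2)], fixes$lat[1:(n - 2)],
                     fixes$lon[3:n], fixes$lat[3:n])
    cosang <- (a^2 + b^2 - cc^2) / (2 * a * b)
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ang[a == 0 | b == 0] <- 180
    bad <- (ang < angles[1] & a > lengths[1] & b > lengths[1]) |
      (ang < angles[2] & a > lengths[2] & b > lengths[2])
    i <- which(bad)
    if (!length(i)) return(fixes)
    fixes <- fixes[-(i[1] + 1), , drop = FALSE]
  }
}

#' Split a track into trips at long data gaps
#'
#' Cuts between consecutive fixes separated by strictly more than
#' `max_gap` days; each portion is treated as an independent trip.
#'
#' @param fixes Time-sorted data frame with `time`.
#' @param max_gap Gap threshold in days (default 7).
#' @return List of data frames (trips), each with a `trip` column.
#' @export
split_trips <- function(fixes, max_gap = 7) {
  if (nrow(fixes) == 0) return(list())
  cut <- c(0, cumsum(diff(fixes$time) > max_gap * 86400))
  fixes$trip <- cut + 1L
  out <- split(fixes, fixes$trip)
  names(out) <- NULL
  lapply(out, function(g) { rownames(g) <- NULL; g })
}

#' Classify move persistence by per-individual median split
#'
#' For each individual, the median of its move-persistence index `g`
#' defines the threshold: fixes with `g` below the median are labelled
#' `"localised"`, fixes at or above it `"transiting"`.  With the
#' at-or-above convention, at least half of each individual's fixes are
#' transiting.
#'
#' @param fixes Data frame with `g` in `[0, 1]` and optionally `id`.
#' @return `fixes` with an added `mp_class` column.
#' @export
classify_move_persistence <- function(fixes) {
  if (is.null(fixes$g) || any(is.na(fixes$g)))
    stop("classify_move_persistence: g must be present on every fix",
         call. = FALSE)
  grp <- if (is.null(fixes$id)) rep(1L, nrow(fixes)) else fixes$id
  med <- stats::ave(fixes$g, grp, FUN = stats::median)
  fixes$mp_class <- ifelse(fixes$g < med, "localised", "transiting")
  fixes
}

#' Join dives to the nearest track position in time
#'
#' Each dive (by its start time) is joined to the nearest-in-time fix
#' within `tolerance` seconds; dives with no fix in tolerance get `NA`
#' attributes.  The default tolerance of 1 h is half a 2-h location
#' regularisation interval.
#'
#' @param dives Data frame with `start_time` (s).
#' @param fixes Time-sorted data frame with `time`, `lon`, `lat` and
#'   optionally `g`, `mp_class`.
#' @param tolerance Maximum time separation (s).
#' @return `dives` with added `lon`, `lat`, `g`, `mp_class` columns.
#' @export
link_dives_to_track <- function(dives, fixes, tolerance = 3600) {
  n <- nrow(dives)
  idx <- rep(NA_integer_, n)
  if (nrow(fixes) > 0 && n > 0) {
    lo <- findInterval(dives$start_time, fixes$time)
    lo[lo == 0] <- 1L
    hi <- pmin(lo + 1L, nrow(fixes))
    dlo <- abs(dives$start_time - fixes$time[lo])
    dhi <- abs(dives$start_time - fixes$time[hi])
    idx <- ifelse(dlo <= dhi, lo, hi)
    idx[pmin(dlo, dhi) > tolerance] <- NA_integer_
  }
  dives$lon <- fixes$lon[idx]
  dives$lat <- fixes$lat[idx]
  dives$g <- if (is.null(fixes$g)) NA_real_ else fixes$g[idx]
  dives$mp_class <- if (is.null(fixes$mp_class)) NA_character_ else
    fixes$mp_class[idx]
  dives
}
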