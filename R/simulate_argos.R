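#' Simulate an Argos-like surface track with known contaminants
#'
#' Generates a smooth base trajectory (a correlated random walk at
#' realistic swimming speed) sampled at roughly regular intervals, then
#' injects the three artefact types that Argos processing must remove:
#' near-duplicate fixes within 2 minutes of an existing fix, invalid
#' class-Z fixes, and spatial spikes implying swimming speeds above
#' 5 km/h.  Ground-truth labels are retained in the `truth` column so
#' filters can be scored exactly.
#'
#' @param n_fixes Number of base fixes (>= 2).
#' @param seed Integer seed.
#' @param start_lon,start_lat Starting position (decimal degrees WGS84).
#' @param fix_interval Mean time between fixes (s).
#' @param speed_kmh Mean swimming speed of the base trajectory (km/h).
#' @param duplicate_rate,z_rate,spike_rate Fraction of base fixes that
#'   spawn a duplicate, are degraded to class Z, or are displaced into a
#'   speed spike.
#' @param spike_km Displacement of spike fixes (km).
#' @param individual_id Identifier.
#' @return A `data.frame`: `id`, `time`, `lon`, `lat`, `lc` (location
#'   class), `truth` in `{"base","duplicate","z","spike"}`, plus an
#'   attribute `n_injected` with the per-type counts.
#' @export
simulate_argos_track <- function(n_fixes, seed = 1L,
                                 start_lon = 1.0, start_lat = 38.5,
                                 fix_interval = 7200, speed_kmh = 2,
                                 duplicate_rate = 0, z_rate = 0,
                                 spike_rate = 0, spike_km = 30,
                                 individual_id = "simtrack") {
  if (n_fixes < 2)
    stop("simulate_argos_track: n_fixes must be >= 2", call. = FALSE)
  set.seed(seed)
  dt <- fix_interval * stats::runif(n_fixes - 1, 0.8, 1.2)
  time <- cumsum(c(0, dt))
  heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n_fixes - 1, 0, 0.25)))
  step_km <- speed_kmh * c(dt, fix_interval)[seq_len(n_fixes)] / 3600
  # small-angle conversion; adequate away from the poles
  lat <- start_lat + cumsum(c(0, (step_km * cos(heading))[-n_fixes])) / 111.32
  lon <- start_lon + cumsum(c(0, (step_km * sin(heading))[-n_fixes])) /
    (111.32 * cos(start_lat * pi / 180))
  lc <- sample(c("3", "2", "1", "0", "A", "B"), n_fixes, replace = TRUE,
               prob = c(0.1, 0.15, 0.2, 0.2, 0.2, 0.15))
  fixes <- data.frame(id = individual_id, time = time, lon = lon, lat = lat,
                      lc = lc, truth = "base", stringsAsFactors = FALSE)

  n_z <- round(z_rate * n_fixes)
  if (n_z > 0) {
    iz <- sample(seq_len(n_fixes), n_z)
    fixes$lc[iz] <- "Z"
    fixes$truth[iz] <- "z"
  }
  n_spike <- round(spike_rate * n_fixes)
  if (n_spike > 0) {
    cand <- which(fixes$truth == "base")
    cand <- cand[cand > 1 & cand < n_fixes]
    is_ <- sample(cand, min(n_spike, length(cand)))
    ang <- stats::runif(length(is_), 0, 2 * pi)
    fixes$lat[is_] <- fixes$lat[is_] + spike_km * cos(ang) / 111.32
    fixes$lon[is_] <- fixes$lon[is_] + spike_km * sin(ang) /
      (111.32 * cos(start_lat * pi / 180))
    fixes$truth[is_] <- "spike"
    n_spike <- length(is_)
  }
  n_dup <- round(duplicate_rate * n_fixes)
  if (n_dup > 0) {
    id_ <- sample(which(fixes$truth == "base"), n_dup)
    dup <- fixes[id_, ]
    dup$time <- dup$time + stats::runif(n_dup, 10, 110)
    dup$truth <- "duplicate"
    fixes <- rbind(fixes, dup)
  }
  fixes <- fixes[order(fixes$time), ]
  rownames(fixes) <- NULL
  structure(fixes,
            n_injected = c(duplicate = n_dup, z = n_z, spike = n_spike))
}
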