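#' Simulate a labelled dive sequence
#'
#' Draws a first-order Markov chain of behavioural states and, for each
#' dive, lognormal dive metrics from the per-state parameters in `cfg`.
#' Dive start times accumulate as `dive_time + surface_interval`, so the
#' sequence can be rendered to a continuous depth trace with
#' [render_depth_series()].  When a state's `season_amplitude` is
#' non-zero, the probability of entering that state is modulated by a
#' cosine of the current calendar month peaking at
#' `season_peak_month`, which produces seasonal occupancy cycles while
#' leaving within-month dynamics Markovian.
#'
#' @param cfg A [sim_config()].
#' @param n_dives Number of dives to generate (>= 1).
#' @param start_time Epoch time (s) of the first dive's start.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A `data.frame` with one row per dive: `state`, `start_time`,
#'   `max_depth` (m), `dive_time` (s), `bottom_time` (s),
#'   `surface_interval` (s).
#' @export
simulate_dive_sequence <- function(cfg, n_dives, start_time = 0,
                                   seed = cfg$seed) {
  validate_sim_config(cfg)
  if (n_dives < 1) stop("simulate_dive_sequence: n_dives must be >= 1",
                        call. = FALSE)
  set.seed(seed)
  k <- cfg$n_states
  state <- integer(n_dives)
  max_depth <- dive_time <- bottom_time <- surface_interval <-
    start <- numeric(n_dives)
  t_now <- start_time
  seasonal <- any(cfg$season_amplitude != 0)
  for (i in seq_len(n_dives)) {
    p <- if (i == 1) cfg$pi else cfg$A[state[i - 1], ]
    if (seasonal) {
      m <- month_of(t_now)
      w <- 1 + cfg$season_amplitude *
        cos(2 * pi * (m - cfg$season_peak_month) / 12)
      w <- pmax(w, 0.05)
      p <- p * w
      p <- p / sum(p)
    }
    s <- sample.int(k, 1, prob = p)
    state[i] <- s
    sp <- cfg$state_params[[s]]
    draw <- stats::rlnorm(4, sp[, "meanlog"], sp[, "sdlog"])
    max_depth[i] <- draw[1]
    bf <- min(draw[2], 0.95)
    dive_time[i] <- draw[3]
    bottom_time[i] <- bf * dive_time[i]
    surface_interval[i] <- draw[4]
    start[i] <- t_now
    t_now <- t_now + dive_time[i] + surface_interval[i]
  }
  data.frame(state = state, start_time = start, max_depth = max_depth,
             dive_time = dive_time, bottom_time = bottom_time,
             surface_interval = surface_interval)
}

month_of <- function(t) as.POSIXlt(t, tz = "UTC", origin = "1970-01-01")$mon + 1L

#' Render labelled dives to a continuous depth trace
#'
#' Each dive is drawn as a piecewise-linear profile: descent from the
#' surface to 80% of the maximum depth over `(dive_time - bottom_time)/2`,
#' a symmetric excursion to the maximum depth occupying exactly
#' `bottom_time` at depths >= 0.8 * max_depth, and the mirror-image
#' ascent.  Depth is 0 during surface intervals.  The apex is snapped to
#' the sampling grid so that the sampled maximum equals the generated
#' maximum depth at the native resolution.
#'
#' @param dives Output of [simulate_dive_sequence()] (non-overlapping).
#' @param dt Sampling step of the rendered trace (s, > 0).
#' @param t_start,t_end Optional span of the output grid; default from
#'   the dives themselves (one `dt` of pad at each end).
#' @param individual_id Identifier stored on the result.
#' @return A [depth_series()] sampled at `dt`.
#' @export
render_depth_series <- function(dives, dt = 1, t_start = NULL, t_end = NULL,
                                individual_id = "sim") {
  if (dt <= 0) stop("render_depth_series: dt must be > 0", call. = FALSE)
  if (nrow(dives) == 0) {
    if (is.null(t_start) || is.null(t_end))
      stop("render_depth_series: empty dive list needs t_start and t_end",
           call. = FALSE)
    grid <- seq(t_start, t_end, by = dt)
    return(depth_series(grid, rep(0, length(grid)),
                        individual_id = individual_id, nominal_dt = dt))
  }
  dives <- dives[order(dives$start_time), , drop = FALSE]
  end <- dives$start_time + dives$dive_time
  if (nrow(dives) > 1 && any(dives$start_time[-1] < end[-nrow(dives)]))
    stop("render_depth_series: dives overlap in time", call. = FALSE)
  if (is.null(t_start)) t_start <- floor(dives$start_time[1]) - dt
  if (is.null(t_end)) t_end <- max(end) + dt
  grid <- seq(t_start, t_end, by = dt)

  bp_t <- t_start
  bp_d <- 0
  for (i in seq_len(nrow(dives))) {
    s <- dives$start_time[i]; D <- dives$dive_time[i]
    B <- min(dives$bottom_time[i], D * 0.999)
    m <- dives$max_depth[i]
    td <- (D - B) / 2
    apex <- s + td + B / 2
    apex <- t_start + round((apex - t_start) / dt) * dt  # grid-snapped apex
    apex <- min(max(apex, s + td + dt * 1e-6), s + td + B - dt * 1e-6)
    seg_t <- c(s, s + td, apex, s + td + B, s + D)
    seg_d <- c(0, 0.8 * m, m, 0.8 * m, 0)
    keep <- c(TRUE, diff(seg_t) > 0)
    bp_t <- c(bp_t, seg_t[keep])
    bp_d <- c(bp_d, seg_d[keep])
  }
  bp_t <- c(bp_t, t_end)
  bp_d <- c(bp_d, 0)
  ok <- c(TRUE, diff(bp_t) > 0)
  depth <- stats::approx(bp_t[ok], bp_d[ok], xout = grid, rule = 2)$y
  depth_series(grid, depth, individual_id = individual_id, nominal_dt = dt)
}

#' Add linear depth-sensor drift to a series
#'
#' Emulates the slow surface-offset drift of tag pressure sensors:
#' `depth(t) + rate * (t - t0) / 86400`.  Applied before any clamping,
#' so zero-offset correction can be tested as a round trip.
#'
#' @param series A [depth_series()].
#' @param rate Drift rate in metres per day.
#' @return The drifted `depth_series`.
#' @export
add_sensor_drift <- function(series, rate) {
  if (nrow(series) == 0)
    stop("add_sensor_drift: series must be non-empty", call. = FALSE)
  d <- series$depth + rate * (series$time - series$time[1]) / 86400
  depth_series(series$time, d, individual_id = attr(series, "individual_id"),
               nominal_dt = attr(series, "nominal_dt"))
}

#' Resample a depth series by point-sampling
#'
#' Emulates a tag reporting instantaneous depth once per interval: the
#' output takes, at each grid time `t0, t0+interval, ...`, the nearest
#' native reading at or before that time.  No averaging is performed, so
#' fast excursions between grid times vanish from the resampled trace.
#'
#' @param series A [depth_series()].
#' @param interval New sampling interval (s, >= native step).
#' @return A `depth_series` with `nominal_dt = interval`.
#' @export
resample_series <- function(series, interval) {
  dt0 <- attr(series, "nominal_dt")
  if (interval < dt0)
    stop("resample_series: interval must be >= the native sampling step",
         call. = FALSE)
  grid <- seq(series$time[1], series$time[nrow(series)], by = interval)
  idx <- findInterval(grid, series$time)
  depth_series(grid, series$depth[idx],
               individual_id = attr(series, "individual_id"),
               nominal_dt = interval)
}

#' Match detected dives to ground-truth dives one-to-one
#'
#' Greedy time-ordered assignment: each detected dive is matched to the
#' earliest unmatched true dive whose apex time (start + dive_time/2)
#' falls inside the detected interval.  Because the assignment is
#' one-to-one, a merged pair of true dives detected as a single record
#' counts as one match, not two, which makes recall sensitive to
#' merging.
#'
#' @param truth Data frame with `start_time` and `dive_time`.
#' @param detected Data frame with `start_time` and `end_time`.
#' @return Integer vector along `truth`: index of the matching detected
#'   dive or `NA`.
#' @export
match_dives <- function(truth, detected) {
  truth <- truth[order(truth$start_time), , drop = FALSE]
  apex <- truth$start_time + truth$dive_time / 2
  used <- rep(FALSE, nrow(detected))
  out <- rep(NA_integer_, nrow(truth))
  ord <- order(detected$start_time)
  for (i in seq_along(apex)) {
    j <- ord[!used[ord] &
               detected$start_time[ord] <= apex[i] &
               detected$end_time[ord] >= apex[i]]
    if (length(j)) {
      out[i] <- j[1]
      used[j[1]] <- TRUE
    }
  }
  out
}
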