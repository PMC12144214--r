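#' Dive-detection configuration
#'
#' @param threshold Dive threshold (m): readings deeper than this are
#'   dive readings.
#' @param interp_step Boundary interpolation grid step (s).
#' @param bottom_fraction Fraction of maximum depth defining the bottom
#'   phase (strictly deeper than `bottom_fraction * max_depth`).
#' @param min_depth_keep Dives with maximum depth at or below this (m)
#'   are excluded from analysis.
#' @param peak_prominence Minimum within-dive peak prominence (m) for
#'   dive splitting.
#' @param settle_exclusion Hours after deployment start excluded from
#'   analysis (tag-attachment recovery).
#' @param gap_factor A gap between consecutive readings longer than
#'   `gap_factor * nominal_dt` counts as missing data; dives spanning
#'   one are flagged `internal_gap`.
#' @return A list of class `dive_config`.
#' @export
dive_config <- function(threshold = 3, interp_step = 10,
                        bottom_fraction = 0.8, min_depth_keep = 10,
                        peak_prominence = 1, settle_exclusion = 24,
                        gap_factor = 1.5) {
  if (threshold <= 0) stop("dive_config: threshold must be > 0", call. = FALSE)
  if (bottom_fraction <= 0 || bottom_fraction >= 1)
    stop("dive_config: bottom_fraction must be in (0, 1)", call. = FALSE)
  structure(list(threshold = threshold, interp_step = interp_step,
                 bottom_fraction = bottom_fraction,
                 min_depth_keep = min_depth_keep,
                 peak_prominence = peak_prominence,
                 settle_exclusion = settle_exclusion,
                 gap_factor = gap_factor), class = "dive_config")
}

#' Zero-offset correction of a depth series
#'
#' Tag pressure sensors drift slowly, so surface readings wander away
#' from 0 m.  The surface offset is estimated as a low running quantile
#' of depth: the series is cut into windows of `window_h` hours, the
#' `quantile` (default 5th percentile) is taken per window, the window
#' offsets are smoothed by a running median, interpolated back to every
#' reading time, subtracted, and the result clamped at >= 0.  Windows
#' dominated by continuous diving (little surface time) inflate the
#' local quantile; the median smoothing limits, but does not remove,
#' the resulting overcorrection.
#'
#' @param series A [depth_series()].
#' @param window_h Window length in hours.
#' @param quantile Quantile taken as the surface estimate per window.
#' @return The corrected `depth_series`.
#' @export
zero_offset_correct <- function(series, window_h = 3, quantile = 0.05) {
  if (nrow(series) == 0)
    stop("zero_offset_correct: series must be non-empty", call. = FALSE)
  span <- series$time[nrow(series)] - series$time[1]
  w <- window_h * 3600
  if (span <= w) {
    warning("zero_offset_correct: window longer than deployment; ",
            "using a single global offset")
    off <- stats::quantile(series$depth, quantile, names = FALSE)
    d <- pmax(series$depth - off, 0)
    return(depth_series(series$time, d,
                        individual_id = attr(series, "individual_id"),
                        nominal_dt = attr(series, "nominal_dt")))
  }
  block <- floor((series$time - series$time[1]) / w)
  off_b <- as.numeric(tapply(series$depth, block, stats::quantile,
                             probs = quantile, names = FALSE))
  centers <- series$time[1] +
    (sort(unique(block)) + 0.5) * w
  # windows dominated by continuous diving inflate the local quantile;
  # a running minimum over +/-2 windows keeps the surface estimate
  # anchored to the nearest genuinely surfaced window
  nb <- length(off_b)
  off_s <- vapply(seq_len(nb), function(i)
    min(off_b[max(1, i - 2):min(nb, i + 2)]), 0)
  off <- stats::approx(centers, off_s, xout = series$time, rule = 2)$y
  depth_series(series$time, pmax(series$depth - off, 0),
               individual_id = attr(series, "individual_id"),
               nominal_dt = attr(series, "nominal_dt"))
}

# Earliest grid time (anchored at `anchor`, step `step`) in [t_lo, t_hi]
# at which the line through (t_lo, d_lo) -> (t_hi, d_hi) is at or
# beyond `thr`; direction = +1 for entry (depth rising past thr),
# -1 for exit (grid runs backwards from the anchor).
grid_crossing <- function(anchor, t_lo, d_lo, t_hi, d_hi, thr, step,
                          entry = TRUE) {
  if (d_hi == d_lo) return(if (entry) t_hi else t_lo)
  t_star <- t_lo + (thr - d_lo) / (d_hi - d_lo) * (t_hi - t_lo)
  if (entry) {
    k <- ceiling((t_star - anchor) / step - 1e-9)
    min(anchor + k * step, t_hi)
  } else {
    k <- floor((t_star - anchor) / step + 1e-9)
    max(anchor + k * step, t_lo)
  }
}

#' Detect dives in a zero-offset-corrected depth series
#'
#' Maximal runs of readings deeper than the threshold form candidate
#' dives.  Start and end times are refined by linear interpolation on a
#' grid of `interp_step` seconds anchored at the bracketing surface
#' reading: the start is the earliest grid time at which interpolated
#' depth reaches the threshold, the end the latest.  Dives whose
#' readings span a gap longer than `gap_factor * nominal_dt` are
#' flagged `internal_gap` (satellite transmission holes) and should be
#' excluded downstream.
#'
#' @param series A corrected [depth_series()].
#' @param cfg A [dive_config()].
#' @return A `data.frame`, one row per dive: `dive_id`,
#'   `individual_id`, `start_time`, `end_time`, `max_depth`,
#'   `n_readings`, `excluded_reason` (`NA` or `"internal_gap"`) and a
#'   list-column `readings` of in-dive `(time, depth)` samples.
#' @export
detect_dives <- function(series, cfg = dive_config()) {
  empty <- data.frame(dive_id = integer(), individual_id = character(),
                      start_time = numeric(), end_time = numeric(),
                      max_depth = numeric(), n_readings = integer(),
                      excluded_reason = character())
  empty$readings <- list()
  if (nrow(series) < 2) return(empty)
  thr <- cfg$threshold
  dt <- attr(series, "nominal_dt")
  below <- series$depth > thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  tt <- series$time
  dd <- series$depth
  out <- vector("list", length(runs))
  for (q in seq_along(runs)) {
    i <- starts[runs[q]]
    j <- ends[runs[q]]
    if (i > 1) {
      st <- grid_crossing(tt[i - 1], tt[i - 1], dd[i - 1], tt[i], dd[i],
                          thr, cfg$interp_step, entry = TRUE)
    } else st <- tt[i]
    if (j < length(tt)) {
      en <- grid_crossing(tt[j + 1], tt[j], dd[j], tt[j + 1], dd[j + 1],
                          thr, cfg$interp_step, entry = FALSE)
    } else en <- tt[j]
    lo <- max(i - 1, 1)
    hi <- min(j + 1, length(tt))
    gap <- any(diff(tt[lo:hi]) > cfg$gap_factor * dt)
    out[[q]] <- list(start_time = st, end_time = en,
                     max_depth = max(dd[i:j]), n = as.integer(j - i + 1),
                     gap = gap, idx = c(i, j))
  }
  res <- data.frame(
    dive_id = seq_along(out),
    individual_id = attr(series, "individual_id"),
    start_time = vapply(out, `[[`, 0, "start_time"),
    end_time = vapply(out, `[[`, 0, "end_time"),
    max_depth = vapply(out, `[[`, 0, "max_depth"),
    n_readings = vapply(out, function(x) x$n, 0L),
    excluded_reason = vapply(out, function(x)
      if (x$gap) "internal_gap" else NA_character_, ""),
    stringsAsFactors = FALSE)
  res$readings <- lapply(out, function(x)
    data.frame(time = tt[x$idx[1]:x$idx[2]], depth = dd[x$idx[1]:x$idx[2]]))
  res
}

#' Label descent, bottom and ascent phases of detected dives
#'
#' On a grid of `interp_step` seconds from dive start to end, depth is
#' linearly interpolated through the in-dive readings (with the
#' threshold crossings pinned at the boundaries).  The bottom phase is
#' the single contiguous span from the first to the last grid time at
#' which depth exceeds `bottom_fraction * max_depth` ("over 80% of the
#' maximum depth"); grid times before it are descent, after it ascent.
#' `bottom_time = bottom_exit - bottom_enter` and
#' `dive_time = end_time - start_time`.
#'
#' @param dives Output of [detect_dives()].
#' @param cfg A [dive_config()].
#' @param keep_profile If `TRUE`, attach the labelled grid as a
#'   list-column `phases`.
#' @return `dives` with added `bottom_enter`, `bottom_exit`,
#'   `bottom_time`, `dive_time` (and optionally `phases`).
#' @export
label_phases <- function(dives, cfg = dive_config(), keep_profile = FALSE) {
  n <- nrow(dives)
  be <- bx <- numeric(n)
  prof <- if (keep_profile) vector("list", n) else NULL
  for (i in seq_len(n)) {
    r <- dives$readings[[i]]
    st <- dives$start_time[i]
    en <- dives$end_time[i]
    x <- c(st, r$time, en)
    y <- c(cfg$threshold, r$depth, cfg$threshold)
    keep <- x >= st & x <= en
    x <- x[keep]; y <- y[keep]
    ok <- !duplicated(x)
    grid <- seq(st, en, by = cfg$interp_step)
    if (grid[length(grid)] < en) grid <- c(grid, en)
    gd <- stats::approx(x[ok], y[ok], xout = grid, rule = 2)$y
    bt <- cfg$bottom_fraction * dives$max_depth[i]
    inb <- which(gd > bt)
    if (!length(inb)) inb <- which.max(gd)
    be[i] <- grid[min(inb)]
    bx[i] <- grid[max(inb)]
    if (keep_profile) {
      phase <- ifelse(grid < be[i], "descent",
                      ifelse(grid > bx[i], "ascent", "bottom"))
      prof[[i]] <- data.frame(time = grid, depth = gd, phase = phase)
    }
  }
  dives$bottom_enter <- be
  dives$bottom_exit <- bx
  dives$bottom_time <- bx - be
  dives$dive_time <- dives$end_time - dives$start_time
  if (keep_profile) dives$phases <- prof
  dives
}
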