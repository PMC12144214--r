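#' Find within-dive peaks (near-surface excursions)
#'
#' At 5-minute sampling, two fast successive dives can be transmitted
#' as a single record whose interior contains a "peak": a local
#' minimum of depth where the animal approached (or reached) the
#' surface between readings.  Peaks are local minima of depth strictly
#' inside the dive whose prominence — the shallower of the two adjacent
#' readings minus the peak depth — exceeds `prominence_min`.  A run of
#' equal minimal depths bounded by deeper readings is reported once, at
#' the run's first reading, with `plateau = TRUE`.
#'
#' @param readings Data frame of in-dive `(time, depth)` samples
#'   (>= 3 rows).
#' @param prominence_min Minimum prominence (m), strict.
#' @return Data frame of peaks (possibly empty): `peak_idx`,
#'   `run_end_idx`, `peak_time`, `peak_depth`, `prev_time`,
#'   `prev_depth`, `next_time`, `next_depth`, `prominence`, `plateau`.
#' @export
find_dive_peaks <- function(readings, prominence_min = 1) {
  n <- nrow(readings)
  empty <- data.frame(peak_idx = integer(), run_end_idx = integer(),
                      peak_time = numeric(), peak_depth = numeric(),
                      prev_time = numeric(), prev_depth = numeric(),
                      next_time = numeric(), next_depth = numeric(),
                      prominence = numeric(), plateau = logical())
  if (n < 3) return(empty)
  d <- readings$depth
  r <- rle(d)
  m <- length(r$values)
  if (m < 3) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (q in 2:(m - 1)) {
    if (r$values[q] < r$values[q - 1] && r$values[q] < r$values[q + 1]) {
      i <- starts[q]; j <- ends[q]
      prev_i <- i - 1; next_i <- j + 1
      prom <- min(d[prev_i], d[next_i]) - r$values[q]
      if (prom > prominence_min) {
        out[[length(out) + 1]] <- data.frame(
          peak_idx = i, run_end_idx = j,
          peak_time = readings$time[i], peak_depth = d[i],
          prev_time = readings$time[prev_i], prev_depth = d[prev_i],
          next_time = readings$time[next_i], next_depth = d[next_i],
          prominence = prom, plateau = j > i)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Decide whether a peak splits a dive
#'
#' The peak could hide an unobserved surfacing only if the animal's
#' vertical speed around it was sufficient to cover the remaining
#' `peak_depth - threshold` metres within one sampling interval.  Two
#' candidate times are computed: one from the ascent rate into the peak
#' (`v_up`, from the previous reading) and one from the descent rate
#' out of it (`v_down`, to the next reading).  The dive is split if
#' either time is at most `nominal_dt`, or unconditionally if the peak
#' is a plateau (ascend-hold-descend without surfacing).  A peak at or
#' above the dive threshold means the boundary itself was mis-merged
#' and always splits via the speed rules (the time to surface is
#' non-positive).
#'
#' @param peak One row of [find_dive_peaks()] output.
#' @param threshold Dive threshold (m).
#' @param nominal_dt Sampling interval (s).
#' @return A one-row data frame: `v_up`, `v_down` (m/s),
#'   `t_surface_up`, `t_surface_down` (s), `split` (logical) and
#'   `rule` in `{"speed_up", "speed_down", "plateau", "none"}`.
#' @export
decide_split <- function(peak, threshold = 3, nominal_dt = 300) {
  if (peak$peak_time == peak$prev_time || peak$next_time == peak$peak_time)
    stop("decide_split: zero time spacing around peak", call. = FALSE)
  v_up <- (peak$prev_depth - peak$peak_depth) /
    (peak$peak_time - peak$prev_time)
  v_down <- (peak$next_depth - peak$peak_depth) /
    (peak$next_time - peak$peak_time)
  t_up <- if (v_up > 0) (peak$peak_depth - threshold) / v_up else Inf
  t_down <- if (v_down > 0) (peak$peak_depth - threshold) / v_down else Inf
  if (peak$plateau) {
    rule <- "plateau"
  } else if (min(t_up, t_down) <= nominal_dt) {
    rule <- if (t_up <= t_down) "speed_up" else "speed_down"
  } else {
    rule <- "none"
  }
  data.frame(v_up = v_up, v_down = v_down,
             t_surface_up = t_up, t_surface_down = t_down,
             split = rule != "none", rule = rule,
             stringsAsFactors = FALSE)
}

# Internal: split one labelled dive row at `peak` given a qualifying
# decision.  The first half ends where the projected ascent crossed the
# threshold (peak_time + t_surface_up); the second half starts where
# the projected descent re-crossed it (next_time - (next_depth -
# threshold)/v_down).  Plateau splits carry no imputed surfacing: both
# halves meet at the plateau's first reading.  Recorded samples are
# never altered; the peak reading closes the first half and plateau
# tails open the second.
split_one <- function(dive, peak, decision, cfg, nominal_dt) {
  r <- dive$readings[[1]]
  thr <- cfg$threshold
  if (peak$plateau) {
    p1 <- peak$peak_idx
    end1 <- start2 <- peak$peak_time
    idx1 <- seq_len(p1)
    idx2 <- p1:nrow(r)
  } else {
    p <- peak$peak_idx
    t_up <- decision$t_surface_up
    end1 <- if (is.finite(t_up)) peak$peak_time + max(t_up, 0) else
      peak$peak_time
    start2 <- if (decision$v_down > 0)
      peak$next_time - max((peak$next_depth - thr) / decision$v_down, 0) else
        end1
    end1 <- min(end1, peak$next_time)
    start2 <- min(max(start2, end1), peak$next_time)
    idx1 <- seq_len(p)
    idx2 <- (p + 1):nrow(r)
  }
  if (length(idx1) < 1 || length(idx2) < 1) return(NULL)
  halves <- dive[c(1, 1), , drop = FALSE]
  halves$end_time[1] <- end1
  halves$start_time[2] <- start2
  halves$readings <- list(r[idx1, , drop = FALSE], r[idx2, , drop = FALSE])
  halves$max_depth <- vapply(halves$readings, function(x) max(x$depth), 0)
  halves$n_readings <- vapply(halves$readings, nrow, 0L)
  halves
}

#' Split merged low-resolution dives at qualifying peaks
#'
#' Applies [find_dive_peaks()] and [decide_split()] to every dive and
#' recursively splits at the first qualifying peak, re-deriving each
#' half's boundary times, maximum depth and phase labels.  Recorded
#' samples are never modified: only boundaries and imputed surfacings
#' are introduced, so the number of dives is non-decreasing and total
#' in-dive time never grows.  Recursion depth is capped to guarantee
#' termination.
#'
#' @param dives Output of [detect_dives()] + [label_phases()].
#' @param cfg A [dive_config()].
#' @param nominal_dt Sampling interval of the series (s).
#' @param max_recursion Maximum splits per original dive (default 4).
#' @return A dive table sorted by start time with columns `was_split`,
#'   `parent_dive_id` and `split_rule` added, phases relabelled.
#' @export
split_merged_dives <- function(dives, cfg = dive_config(), nominal_dt = 300,
                               max_recursion = 4) {
  process <- function(dive, depth_left) {
    dive$was_split <- FALSE
    dive$split_rule <- NA_character_
    r <- dive$readings[[1]]
    if (depth_left <= 0 || nrow(r) < 3) return(dive)
    peaks <- find_dive_peaks(r, cfg$peak_prominence)
    # a sub-threshold interior reading would have ended the run in
    # detect_dives, so peaks here are always deeper than the threshold
    if (nrow(peaks) == 0) return(dive)
    for (q in seq_len(nrow(peaks))) {
      dec <- decide_split(peaks[q, ], cfg$threshold, nominal_dt)
      if (dec$split) {
        halves <- split_one(dive, peaks[q, ], dec, cfg, nominal_dt)
        if (is.null(halves)) next
        halves <- label_phases(halves, cfg)
        out <- rbind(process(halves[1, ], depth_left - 1),
                     process(halves[2, ], depth_left - 1))
        out$was_split <- TRUE
        out$split_rule[is.na(out$split_rule)] <- dec$rule
        return(out)
      }
    }
    dive
  }
  if (nrow(dives) == 0) {
    dives$was_split <- logical()
    dives$parent_dive_id <- integer()
    dives$split_rule <- character()
    return(dives)
  }
  pieces <- lapply(seq_len(nrow(dives)), function(i) {
    out <- process(dives[i, , drop = FALSE], max_recursion)
    out$parent_dive_id <- dives$dive_id[i]
    out
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$start_time), , drop = FALSE]
  res$dive_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
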