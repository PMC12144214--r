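#' Extract per-dive features for state modelling
#'
#' Computes the four descriptors fed to the hidden Markov model:
#' maximum depth (m), bottom time (s, time spent over 80% of maximum
#' depth), dive time (s) and post-dive surface interval (s, the time
#' between the end of this dive's ascent and the start of the next
#' dive).  The last dive of each deployment has no following dive and
#' is dropped.  The calendar month (UTC) of the dive start is attached
#' for seasonal analyses.
#'
#' @param dives Phase-labelled dive table (one deployment, or several
#'   distinguished by `individual_id`), sorted by `start_time` within
#'   deployment.
#' @return A `data.frame`: `dive_id`, `individual_id`, `start_time`,
#'   `month`, `max_depth`, `bottom_time`, `dive_time`,
#'   `surface_interval`, `excluded_reason`.
#' @export
extract_features <- function(dives) {
  one <- function(g) {
    g <- g[order(g$start_time), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) return(NULL)
    si <- g$start_time[-1] - g$end_time[-n]
    if (any(si < 0)) {
      i <- which(si < 0)[1]
      stop(sprintf(
        "extract_features: dives %s and %s of %s overlap in time",
        g$dive_id[i], g$dive_id[i + 1], g$individual_id[1]), call. = FALSE)
    }
    data.frame(dive_id = g$dive_id[-n],
               individual_id = g$individual_id[-n],
               start_time = g$start_time[-n],
               month = month_of(g$start_time[-n]),
               max_depth = g$max_depth[-n],
               bottom_time = g$bottom_time[-n],
               dive_time = g$dive_time[-n],
               surface_interval = si,
               excluded_reason = g$excluded_reason[-n],
               stringsAsFactors = FALSE)
  }
  parts <- lapply(split(dives, dives$individual_id), one)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Apply the standard dive exclusions
#'
#' Removes, with one reason per dive (precedence: transmission gap,
#' first day, shallow): dives containing missing readings
#' (`internal_gap`), dives starting within `settle_exclusion` hours of
#' deployment start (`first_day`, tag-attachment recovery), and dives
#' with maximum depth at or below `min_depth_keep` metres (`shallow`,
#' unreliable at 5-minute resolution).
#'
#' @param features Output of [extract_features()].
#' @param deployment_start Named numeric vector of deployment start
#'   times (s) by `individual_id`, or a single value.
#' @param cfg A [dive_config()].
#' @return A list: `features` (retained rows) and `counts`, the number
#'   of dives dropped per reason plus `retained`.
#' @export
apply_exclusions <- function(features, deployment_start,
                             cfg = dive_config()) {
  if (is.null(names(deployment_start)))
    dep <- rep(deployment_start[1], nrow(features))
  else
    dep <- deployment_start[features$individual_id]
  reason <- rep(NA_character_, nrow(features))
  reason[features$max_depth <= cfg$min_depth_keep] <- "shallow"
  reason[features$start_time - dep < cfg$settle_exclusion * 3600] <-
    "first_day"
  reason[!is.na(features$excluded_reason) &
           features$excluded_reason == "internal_gap"] <- "internal_gap"
  counts <- c(internal_gap = sum(reason == "internal_gap", na.rm = TRUE),
              first_day = sum(reason == "first_day", na.rm = TRUE),
              shallow = sum(reason == "shallow", na.rm = TRUE),
              retained = sum(is.na(reason)))
  list(features = features[is.na(reason), , drop = FALSE], counts = counts)
}

#' Fit the feature transform (log + range scaling)
#'
#' Surface interval, maximum depth and dive time are natural-log
#' transformed (their distributions are strongly right-skewed); bottom
#' time is left on the raw scale.  All four features are then min-max
#' scaled to `[0, 1]` with ranges pooled over the whole dataset, so one
#' model is fitted across individuals and held-out data can be
#' transformed identically.  An epsilon guard (default 1 s) protects
#' the log of zero-length intervals that splitting can produce.
#'
#' @param features Output of [extract_features()] (after exclusions).
#' @param epsilon Lower guard for logged features (s or m).
#' @return A list: `spec` (class `transform_spec`) and `X`, the n x 4
#'   transformed matrix with columns `max_depth`, `bottom_time`,
#'   `dive_time`, `surface_interval`.
#' @export
fit_transform <- function(features, epsilon = 1) {
  if (nrow(features) < 2)
    stop("fit_transform: need at least 2 dives", call. = FALSE)
  log_features <- c("max_depth", "dive_time", "surface_interval")
  feats <- c("max_depth", "bottom_time", "dive_time", "surface_interval")
  raw <- as.matrix(features[, feats])
  for (f in log_features) raw[, f] <- log(pmax(raw[, f], epsilon))
  rmin <- apply(raw, 2, min)
  rmax <- apply(raw, 2, max)
  if (any(rmax - rmin <= 0))
    stop("fit_transform: constant feature cannot be range-scaled: ",
         paste(feats[rmax - rmin <= 0], collapse = ", "), call. = FALSE)
  spec <- structure(list(log_features = log_features, range_min = rmin,
                         range_max = rmax, epsilon = epsilon,
                         features = feats), class = "transform_spec")
  list(spec = spec, X = apply_transform(spec, features))
}

#' @rdname fit_transform
#' @param spec A `transform_spec`.
#' @export
apply_transform <- function(spec, features) {
  raw <- as.matrix(features[, spec$features])
  for (f in spec$log_features) raw[, f] <- log(pmax(raw[, f], spec$epsilon))
  sweep(sweep(raw, 2, spec$range_min), 2, spec$range_max - spec$range_min,
        "/")
}

#' @rdname fit_transform
#' @param X Transformed matrix.
#' @export
invert_transform <- function(spec, X) {
  raw <- sweep(sweep(X, 2, spec$range_max - spec$range_min, "*"), 2,
               spec$range_min, "+")
  for (f in spec$log_features) raw[, f] <- exp(raw[, f])
  raw
}
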