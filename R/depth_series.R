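#' Construct a depth series
#'
#' A depth series is the raw vertical signal of one deployment: a
#' strictly increasing time vector (seconds since epoch) and matching
#' depths in metres, positive down, at a nominally fixed sampling
#' interval.
#'
#' @param time Numeric vector, seconds since epoch, strictly increasing.
#' @param depth Numeric vector of depths (m, positive down).
#' @param individual_id Deployment identifier.
#' @param nominal_dt Nominal sampling step in seconds (1 for archival
#'   records, 300 for satellite-relayed ones).
#' @return A `data.frame` of class `depth_series` with columns `time`
#'   and `depth` and attributes `individual_id` and `nominal_dt`.
#' @export
depth_series <- function(time, depth, individual_id = "sim", nominal_dt = NULL) {
  if (length(time) != length(depth))
    stop("depth_series: time and depth must have equal length", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("depth_series: time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(depth)))
    stop("depth_series: depths must be finite", call. = FALSE)
  if (is.null(nominal_dt))
    nominal_dt <- if (length(time) > 1) stats::median(diff(time)) else 1
  if (nominal_dt <= 0)
    stop("depth_series: nominal_dt must be > 0", call. = FALSE)
  structure(data.frame(time = as.numeric(time), depth = as.numeric(depth)),
            individual_id = individual_id,
            nominal_dt = as.numeric(nominal_dt),
            class = c("depth_series", "data.frame"))
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> id=%s  n=%d  dt=%gs  span=%.1f h  max depth=%.1f m\n",
              attr(x, "individual_id"), nrow(x), attr(x, "nominal_dt"),
              diff(range(x$time)) / 3600, max(x$depth)))
  invisible(x)
}

#' Read / write depth series as CSV
#'
#' CSV columns: `id`, `time` (seconds since epoch or ISO-8601 UTC) and
#' `depth` (m, positive down).
#'
#' @param path File path.
#' @param series A `depth_series`.
#' @return `read_depth_csv()` returns a list of `depth_series`, one per
#'   `id`; `write_depth_csv()` returns `path` invisibly.
#' @export
write_depth_csv <- function(series, path) {
  utils::write.csv(data.frame(id = attr(series, "individual_id"),
                              time = series$time, depth = series$depth),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_csv
#' @export
read_depth_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(d$time))
    d$time <- as.numeric(as.POSIXct(d$time, tz = "UTC"))
  lapply(split(d, d$id), function(g)
    depth_series(g$time, g$depth, individual_id = as.character(g$id[1])))
}
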