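#' Pool dive maximum depths into 10 m bins for two resolutions
#'
#' Dives with maximum depth at or below `min_depth` are excluded; the
#' rest are pooled into half-open bins `[10, 20), [20, 30), ...` up to
#' the deepest dive in either arm, with empty trailing bins trimmed.
#'
#' @param depths_high,depths_low Maximum depths (m) of dives detected
#'   at high and low resolution.
#' @param width Bin width (m).
#' @param min_depth Exclusion threshold (m, "at or below").
#' @return A list of class `depth_bin_table`: `edges` (bin lower
#'   edges), `counts` (2 x K matrix, rows = high/low resolution).
#' @export
bin_max_depths <- function(depths_high, depths_low, width = 10,
                           min_depth = 10) {
  dh <- depths_high[depths_high > min_depth]
  dl <- depths_low[depths_low > min_depth]
  if (!length(dh) && !length(dl))
    stop("bin_max_depths: no dives deeper than the exclusion threshold ",
         "in either arm", call. = FALSE)
  top <- max(dh, dl)
  nb <- floor((top - min_depth) / width) + 1
  edges <- min_depth + width * (0:nb)
  lo <- edges[-length(edges)]
  cnt <- function(d) tabulate(findInterval(d, edges), nbins = length(lo))
  counts <- rbind(highres = cnt(dh), lowres = cnt(dl))
  colnames(counts) <- sprintf("[%g,%g)", lo, lo + width)
  structure(list(edges = lo, counts = counts), class = "depth_bin_table")
}

#' Fisher's exact test for a 2 x K contingency table
#'
#' For 2 x 2 tables the exact two-sided p-value is computed by
#' hypergeometric enumeration (summing the probabilities of all tables
#' at most as probable as the observed one).  For 2 x K tables the
#' exact network algorithm is used when the total count is at most
#' `exact_max`; larger tables fall back to a seeded Monte-Carlo
#' p-value with its standard error reported.
#'
#' @param tab Non-negative integer matrix with 2 rows.
#' @param mc_reps Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo branch.
#' @param exact_max Largest total for which the exact branch is tried.
#' @return A list: `p_value`, `method` (`"exact"` or `"monte-carlo"`),
#'   `mc_se` (`NA` for exact), `reps`, `seed`.
#' @export
fisher_exact <- function(tab, mc_reps = 1e5, seed = 1L, exact_max = 200) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("fisher_exact: table must hold non-negative integers",
         call. = FALSE)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
    warning("fisher_exact: degenerate table (empty row or column); p = 1")
    return(list(p_value = 1, method = "degenerate", mc_se = NA_real_,
                reps = NA_integer_, seed = seed))
  }
  exact <- ncol(tab) == 2 || sum(tab) <= exact_max
  if (exact) {
    p <- tryCatch(
      stats::fisher.test(tab, workspace = 2e7)$p.value,
      error = function(e) NULL)
    if (!is.null(p))
      return(list(p_value = p, method = "exact", mc_se = NA_real_,
                  reps = NA_integer_, seed = seed))
  }
  set.seed(seed)
  p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_reps)$p.value
  list(p_value = p, method = "monte-carlo",
       mc_se = sqrt(p * (1 - p) / mc_reps), reps = as.integer(mc_reps),
       seed = seed)
}

#' Compare dive detection at native and resampled resolution
#'
#' The validation protocol for low-resolution processing: the 1 s
#' series is point-resampled to `interval` seconds, dives are detected
#' at both resolutions, maximum depths are pooled into 10 m bins, and
#' the two frequency distributions are compared with Fisher's exact
#' test.  Dive counts are reported both in total and above the 10 m
#' retention threshold.  Splitting is not applied: the comparison
#' isolates what point-sampling alone loses.
#'
#' @param series_1s A high-resolution (1 s) [depth_series()].
#' @param cfg A [dive_config()].
#' @param interval Resampling interval (s).
#' @param mc_reps,seed Passed to [fisher_exact()].
#' @return A list: `n_dives_high`, `n_dives_low`, `n_keep_high`,
#'   `n_keep_low` (counts above the retention threshold), `bins`,
#'   `p_value`, `method`, `mc_se`.
#' @export
compare_resolutions <- function(series_1s, cfg = dive_config(),
                                interval = 300, mc_reps = 1e5, seed = 1L) {
  low <- resample_series(series_1s, interval)
  dh <- detect_dives(series_1s, cfg)
  dl <- detect_dives(low, cfg)
  bins <- bin_max_depths(dh$max_depth, dl$max_depth,
                         min_depth = cfg$min_depth_keep)
  ft <- fisher_exact(bins$counts, mc_reps = mc_reps, seed = seed)
  list(n_dives_high = nrow(dh), n_dives_low = nrow(dl),
       n_keep_high = sum(dh$max_depth > cfg$min_depth_keep),
       n_keep_low = sum(dl$max_depth > cfg$min_depth_keep),
       bins = bins, p_value = ft$p_value, method = ft$method,
       mc_se = ft$mc_se)
}
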