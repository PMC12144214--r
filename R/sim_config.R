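#' Simulation configuration for synthetic dive sequences
#'
#' Bundles the generative model behind [simulate_dive_sequence()]: a
#' first-order Markov chain over behavioural states and, per state,
#' log-scale location/scale parameters for the four dive descriptors
#' (maximum depth, bottom fraction of dive time, dive time, post-dive
#' surface interval).  Dive metrics are drawn lognormal and independent
#' within state, which mirrors the log-transform applied to the skewed
#' features before model fitting.
#'
#' The default configuration encodes four states with the qualitative
#' structure typically reported for loggerhead turtle diving:
#' \describe{
#'   \item{State 1}{intermediate depth, longest bottom time and dive
#'     time, short surface interval (resting-type dives);}
#'   \item{State 2}{deepest dives, intermediate bottom and dive time,
#'     long surface interval;}
#'   \item{State 3}{intermediate depth, least bottom time, shortest
#'     dive time, longest surface interval;}
#'   \item{State 4}{shallowest dives, shortest surface interval.}
#' }
#' so that canonical state labelling (see [canonical_state_labels()])
#' is exercised by construction.
#'
#' @param n_states Number of behavioural states.
#' @param pi Initial state probability vector (length `n_states`).
#' @param A Row-stochastic transition matrix (`n_states` x `n_states`).
#' @param state_params List with one element per state; each element is
#'   a 2-column matrix (`meanlog`, `sdlog`) with rows
#'   `max_depth` (m), `bottom_fraction` (unitless, in (0, 1) after
#'   capping), `dive_time` (s) and `surface_interval` (s).
#' @param season_amplitude Per-state multiplicative amplitude of monthly
#'   occupancy modulation (0 disables; unitless).
#' @param season_peak_month Per-state month (1-12) at which occupancy
#'   modulation peaks.
#' @param drift_m_per_day Depth-sensor drift rate used when rendering
#'   drifting traces (m/day).
#' @param seed Integer seed used by the generator when none is given at
#'   call time.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_states = 4,
                       pi = NULL,
                       A = NULL,
                       state_params = NULL,
                       season_amplitude = rep(0, n_states),
                       season_peak_month = c(1, 10, 7, 1)[seq_len(n_states)],
                       drift_m_per_day = 0.5,
                       seed = 1L) {
  if (is.null(pi)) pi <- default_pi(n_states)
  if (is.null(A)) A <- default_transitions(n_states)
  if (is.null(state_params)) state_params <- default_state_params(n_states)
  cfg <- structure(list(
    n_states = as.integer(n_states),
    pi = pi, A = A, state_params = state_params,
    season_amplitude = season_amplitude,
    season_peak_month = season_peak_month,
    drift_m_per_day = drift_m_per_day,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

default_pi <- function(n_states) {
  if (n_states == 4) c(0.048, 0.081, 0.601, 0.270) else rep(1 / n_states, n_states)
}

# Diagonally dominant transitions: states are persistent, row-normalised.
default_transitions <- function(n_states) {
  if (n_states == 4) {
    A <- rbind(c(0.833, 0.042, 0.052, 0.072),
               c(0.025, 0.804, 0.104, 0.068),
               c(0.023, 0.108, 0.781, 0.088),
               c(0.072, 0.112, 0.163, 0.652))
  } else {
    A <- matrix(0.2 / (n_states - 1), n_states, n_states)
    diag(A) <- 0.8
  }
  sweep(A, 1, rowSums(A), "/")
}

default_state_params <- function(n_states) {
  stopifnot(n_states == 4)
  mk <- function(depth, bf, dive, surf, sd_depth = 0.3, sd_bf = 0.2,
                 sd_dive = 0.3, sd_surf = 0.3) {
    m <- cbind(meanlog = log(c(depth, bf, dive, surf)),
               sdlog = c(sd_depth, sd_bf, sd_dive, sd_surf))
    rownames(m) <- c("max_depth", "bottom_fraction", "dive_time",
                     "surface_interval")
    m
  }
  list(mk(30, 0.80, 3600, 120),
       mk(80, 0.35, 1800, 1800),
       mk(30, 0.15, 700, 3600),
       mk(15, 0.50, 1500, 60))
}

validate_sim_config <- function(cfg) {
  k <- cfg$n_states
  if (k < 1) stop("sim_config: n_states must be >= 1", call. = FALSE)
  if (length(cfg$pi) != k || abs(sum(cfg$pi) - 1) > 1e-12 || any(cfg$pi < 0))
    stop("sim_config: pi must be a probability vector summing to 1 within 1e-12",
         call. = FALSE)
  if (!is.matrix(cfg$A) || any(dim(cfg$A) != k) ||
      any(abs(rowSums(cfg$A) - 1) > 1e-12) || any(cfg$A < 0))
    stop("sim_config: every row of A must sum to 1 within 1e-12", call. = FALSE)
  if (length(cfg$state_params) != k)
    stop("sim_config: state_params must have one element per state",
         call. = FALSE)
  for (s in seq_len(k)) {
    p <- cfg$state_params[[s]]
    if (any(p[, "sdlog"] <= 0))
      stop("sim_config: all sdlog must be > 0 (state ", s, ")", call. = FALSE)
    if (exp(p["bottom_fraction", "meanlog"]) >= 1)
      stop("sim_config: median bottom fraction must be < 1 (state ", s, ")",
           call. = FALSE)
  }
  invisible(cfg)
}
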