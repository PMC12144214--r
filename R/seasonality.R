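#' Monthly state counts per individual
#'
#' For each individual and calendar month with any dives, counts the
#' dives in each focal state (`n_state`) against all dives that month
#' (`n_total`), giving the binomial responses for the seasonal models.
#' Months with no dives are absent, not zero-filled.
#'
#' @param decoded Data frame with `individual_id`, `month` (1-12) and
#'   `state`.
#' @param n_states Number of states (default: maximum observed).
#' @return A `data.frame`: `individual_id`, `month`, `state`,
#'   `n_state`, `n_total` (one row per individual x month x state).
#' @export
monthly_state_counts <- function(decoded, n_states = max(decoded$state)) {
  tot <- stats::aggregate(list(n_total = decoded$state),
                          by = list(individual_id = decoded$individual_id,
                                    month = decoded$month),
                          FUN = length)
  out <- do.call(rbind, lapply(seq_len(n_states), function(k) {
    cnt <- stats::aggregate(list(n_state = decoded$state == k),
                            by = list(individual_id = decoded$individual_id,
                                      month = decoded$month),
                            FUN = sum)
    m <- merge(cnt, tot, by = c("individual_id", "month"))
    m$state <- k
    m
  }))
  out <- out[order(out$state, out$individual_id, out$month),
             c("individual_id", "month", "state", "n_state", "n_total")]
  rownames(out) <- NULL
  out
}

#' Cyclic cubic regression spline basis over months
#'
#' Basis for periodic seasonal smooths: cyclic cubic regression spline
#' with `knots` knots equally spaced on the period `[1, 13)`, so that
#' the fitted curve and its first two derivatives match between
#' December and January.  After the periodicity constraint the basis
#' has `knots - 1` columns; together with an intercept it reproduces
#' constants exactly.
#'
#' @param month Numeric months (fractional allowed); values are wrapped
#'   into `[1, 13)`.
#' @param knots Number of knots (>= 4).
#' @return Matrix with `length(month)` rows and `knots - 1` columns.
#' @export
cyclic_spline_basis <- function(month, knots = 6) {
  if (knots < 4)
    stop("cyclic_spline_basis: need at least 4 knots", call. = FALSE)
  x <- ((month - 1) %% 12) + 1
  mgcv::cSplineDes(x, knots = seq(1, 13, length.out = knots))
}

#' Seasonal binomial model of state occupancy
#'
#' Fits the monthly proportion of dives in one focal state as a
#' binomial-logit regression on the cyclic spline basis of month plus
#' per-individual intercepts (a fixed-effect simplification of
#' individual random effects).  The fit is by the standard IRLS of
#' `glm`; on complete separation or non-convergence a ridge-penalised
#' IRLS (penalty 1e-6) is used instead and flagged.
#'
#' @param counts One focal state's rows of [monthly_state_counts()]
#'   (>= 2 individuals, >= 6 distinct months).
#' @param knots Spline knots (default 6).
#' @return A list of class `seasonal_fit`: `knots`, `coefficients`,
#'   `deviance`, `curve` (data frame on a 0.1-month grid with the
#'   reference-individual curve `p_ref` and population-average curve
#'   `p_avg`), `ridge` (logical).
#' @export
fit_seasonal_binomial <- function(counts, knots = 6) {
  if (length(unique(counts$individual_id)) < 2)
    stop("fit_seasonal_binomial: need >= 2 individuals", call. = FALSE)
  if (length(unique(counts$month)) < 6)
    stop("fit_seasonal_binomial: need >= 6 distinct months", call. = FALSE)
  # the cyclic basis is a partition of unity, so one column is dropped
  # for identifiability against the intercept (same function space)
  B <- cyclic_spline_basis(counts$month, knots)[, -1, drop = FALSE]
  ind <- factor(counts$individual_id)
  Zi <- stats::model.matrix(~ind)[, -1, drop = FALSE]  # ref = first level
  X <- cbind(`(Intercept)` = 1, B, Zi)
  colnames(X) <- c("(Intercept)", paste0("cc", seq_len(ncol(B))),
                   colnames(Zi))
  ridge <- FALSE
  fit <- suppressWarnings(
    stats::glm.fit(X, counts$n_state / counts$n_total,
                   weights = counts$n_total, family = stats::binomial()))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    ridge <- TRUE
    fit <- ridge_irls_binomial(X, counts$n_state, counts$n_total,
                               lambda = 1e-6)
  }
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  grid <- seq(1, 13, by = 0.1)
  Bg <- cyclic_spline_basis(grid, knots)[, -1, drop = FALSE]
  eta_spline <- beta[1] + Bg %*% beta[1 + seq_len(ncol(B))]
  ind_eff <- c(0, beta[-(1:(1 + ncol(B)))])
  p_ref <- stats::plogis(eta_spline)
  p_avg <- rowMeans(stats::plogis(outer(drop(eta_spline), ind_eff, "+")))
  structure(list(knots = knots, coefficients = beta,
                 deviance = fit$deviance,
                 curve = data.frame(month = grid, p_ref = drop(p_ref),
                                    p_avg = p_avg),
                 ridge = ridge),
            class = "seasonal_fit")
}

# IRLS for a binomial-logit GLM with a small ridge penalty; used as a
# fallback under complete separation.
ridge_irls_binomial <- function(X, succ, tot, lambda = 1e-6,
                                max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  P <- diag(lambda, ncol(X))
  P[1, 1] <- 0
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- tot * mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (succ - tot * mu) / w
    beta_new <- solve(crossprod(X, w * X) + P, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- stats::plogis(drop(X %*% beta))
  dev <- -2 * sum(stats::dbinom(succ, tot, mu, log = TRUE) -
                    stats::dbinom(succ, tot, pmax(succ, 1e-12) / tot,
                                  log = TRUE))
  list(coefficients = drop(beta), deviance = dev, converged = TRUE)
}

#' Association between move-persistence class and behavioural state
#'
#' Reports, per state, the proportion of dives classified as localised
#' movement, and tests all pairwise differences in that proportion
#' with two-proportion z-tests under Holm adjustment (a conservative,
#' dependency-free stand-in for Tukey contrasts on a binomial GLM).
#' States with fewer than 2 dives are excluded from the pairwise tests
#' and flagged.
#'
#' @param dives Data frame with `state` and `mp_class`
#'   (`"localised"`/`"transiting"`).
#' @return A list: `proportions` (per-state n and localised
#'   proportion), `pairs` (comparison, estimate, se, z, p, p_adj),
#'   `excluded_states`.
#' @export
mp_state_association <- function(dives) {
  ok <- !is.na(dives$mp_class) & !is.na(dives$state)
  dives <- dives[ok, , drop = FALSE]
  st <- sort(unique(dives$state))
  n <- vapply(st, function(k) sum(dives$state == k), 0)
  nloc <- vapply(st, function(k)
    sum(dives$state == k & dives$mp_class == "localised"), 0)
  prop <- data.frame(state = st, n = n, n_localised = nloc,
                     prop_localised = nloc / n)
  keep <- st[n >= 2]
  dropped <- setdiff(st, keep)
  prs <- utils::combn(keep, 2)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    na <- n[st == a]; nb <- n[st == b]
    pa <- nloc[st == a] / na; pb <- nloc[st == b] / nb
    pp <- (nloc[st == a] + nloc[st == b]) / (na + nb)
    se <- sqrt(pp * (1 - pp) * (1 / na + 1 / nb))
    z <- (pa - pb) / se
    data.frame(comparison = sprintf("state %d - state %d", a, b),
               estimate = pa - pb, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "holm")
  list(proportions = prop, pairs = pairs, excluded_states = dropped)
}
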