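sim_counts <- function(pfun, n_ids = 10, n_per_month = 100, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(individual_id = paste0("id", seq_len(n_ids)),
                      month = 1:12, stringsAsFactors = FALSE)
  rows$n_total <- n_per_month
  rows$n_state <- rbinom(nrow(rows), rows$n_total, pfun(rows$month))
  rows
}

test_that("monthly counts aggregate dives per individual and month", {
  dec <- data.frame(individual_id = rep("a", 40), month = 3,
                    state = rep(c(1, 2), c(10, 30)))
  mc <- monthly_state_counts(dec, n_states = 4)
  r1 <- mc[mc$state == 1, ]
  expect_equal(r1$n_state, 10)
  expect_equal(r1$n_total, 40)
  # focal-state views partition the total
  expect_equal(sum(mc$n_state), 40)
  # months without dives are absent, not zero-filled
  expect_equal(sort(unique(mc$month)), 3)
})

test_that("the cyclic basis is periodic and spans constants", {
  B1 <- cyclic_spline_basis(1, knots = 6)
  B13 <- cyclic_spline_basis(13 - 1e-12, knots = 6)
  expect_lt(max(abs(B1 - B13)), 1e-8)
  expect_equal(ncol(B1), 5)
  # constants lie in the span of the basis plus intercept
  x <- seq(1, 12.99, by = 0.01)
  B <- cyclic_spline_basis(x, knots = 6)
  fit <- lm.fit(cbind(1, B), rep(1, length(x)))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_error(cyclic_spline_basis(1:12, knots = 3), "4 knots")
})

test_that("the basis approximates an annual sinusoid closely", {
  x <- seq(1, 12.99, by = 0.01)
  y <- sin(2 * pi * x / 12)
  B <- cyclic_spline_basis(x, knots = 6)
  fit <- lm.fit(cbind(1, B), y)
  expect_lt(max(abs(fit$residuals)), 0.01)
})

test_that("flat occupancy fits a near-flat seasonal curve", {
  counts <- sim_counts(function(m) rep(0.3, length(m)), n_ids = 20,
                       seed = 2)
  fit <- fit_seasonal_binomial(counts, knots = 6)
  expect_lt(diff(range(fit$curve$p_avg)), 0.05)
  expect_true(all(fit$curve$p_avg > 0 & fit$curve$p_avg < 1))
})

test_that("sinusoidal occupancy peaking in July is recovered", {
  pfun <- function(m) plogis(qlogis(0.3) + 1.2 * cos(2 * pi * (m - 7) / 12))
  fit <- fit_seasonal_binomial(sim_counts(pfun, seed = 3), knots = 6)
  peak <- fit$curve$month[which.max(fit$curve$p_avg)]
  expect_lt(min(abs(peak - 7), 12 - abs(peak - 7)), 1)
  # fitted curve is periodic at the month 1 / month 13 seam
  expect_lt(abs(fit$curve$p_ref[1] -
                  fit$curve$p_ref[nrow(fit$curve)]), 1e-8)
})

test_that("rotating month labels rotates the curve, not the deviance", {
  pfun <- function(m) plogis(qlogis(0.3) + cos(2 * pi * (m - 7) / 12))
  counts <- sim_counts(pfun, seed = 4)
  fit <- fit_seasonal_binomial(counts, knots = 6)
  # rotate by one knot spacing (12/5 months with 6 knots) so the knot
  # lattice maps onto itself and the spline space is exactly invariant
  rot <- counts
  off <- 12 / 5
  rot$month <- ((counts$month - 1 + off) %% 12) + 1
  fit_rot <- fit_seasonal_binomial(rot, knots = 6)
  expect_equal(fit_rot$deviance, fit$deviance, tolerance = 1e-6)
  peak <- fit$curve$month[which.max(fit$curve$p_avg)]
  peak_rot <- fit_rot$curve$month[which.max(fit_rot$curve$p_avg)]
  shift <- (peak_rot - peak) %% 12
  expect_lt(min(abs(shift - off), 12 - abs(shift - off)), 0.5)
})

test_that("the GLM route matches a hand-rolled IRLS on the same design", {
  counts <- sim_counts(function(m) plogis(-1 + 0.8 * sin(2 * pi * m / 12)),
                       n_ids = 4, n_per_month = 50, seed = 5)
  fit <- fit_seasonal_binomial(counts, knots = 6)
  B <- cyclic_spline_basis(counts$month, 6)[, -1, drop = FALSE]
  ind <- factor(counts$individual_id)
  X <- cbind(1, B, model.matrix(~ind)[, -1, drop = FALSE])
  beta <- rep(0, ncol(X))
  for (i in 1:200) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- counts$n_total * mu * (1 - mu)
    z <- eta + (counts$n_state - counts$n_total * mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-12) break
    beta <- beta_new
  }
  expect_equal(unname(fit$coefficients), unname(drop(beta)),
               tolerance = 1e-8)
})

test_that("equal localised proportions rarely yield false positives", {
  set.seed(6)
  n_sig <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    d <- data.frame(state = rep(1:4, each = 2500),
                    mp_class = sample(c("localised", "transiting"),
                                      10000, replace = TRUE))
    res <- mp_state_association(d)
    if (any(res$pairs$p_adj < 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / reps, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("a genuinely different state is flagged in all its pairs", {
  set.seed(7)
  d <- data.frame(state = rep(1:4, each = 2000))
  p <- c(0.3, 0.5, 0.5, 0.5)[d$state]
  d$mp_class <- ifelse(runif(8000) < p, "localised", "transiting")
  res <- mp_state_association(d)
  s1 <- grepl("state 1", res$pairs$comparison)
  expect_true(all(res$pairs$p_adj[s1] < 0.001))
  expect_true(all(res$pairs$p_adj[!s1] > 0.05))
  expect_true(all(res$proportions$prop_localised >= 0 &
                    res$proportions$prop_localised <= 1))
  expect_equal(res$proportions$n_localised,
               as.vector(table(d$state[d$mp_class == "localised"])))
})

test_that("states with too few dives are excluded from pairwise tests", {
  d <- data.frame(state = c(rep(1, 50), rep(2, 50), 3),
                  mp_class = "localised")
  res <- mp_state_association(d)
  expect_equal(res$excluded_states, 3)
  expect_equal(nrow(res$pairs), 1)
})
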