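test_that("one-state fit reduces to the closed-form Gaussian MLE", {
  set.seed(1)
  X <- matrix(runif(200), 50, 4)
  f <- fit_em(X, 1, seed = 2)
  expect_equal(drop(f$mu), colMeans(X), tolerance = 1e-6)
  sd_mle <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  expect_equal(drop(f$sigma), sd_mle, tolerance = 1e-5)
  ll <- sum(dnorm(X, rep(colMeans(X), each = 50),
                  rep(sd_mle, each = 50), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$n_params, 8)
  expect_equal(f$aic, 2 * 8 - 2 * f$loglik)
})

test_that("EM log-likelihood is non-decreasing", {
  dv <- simulate_dive_sequence(sim_config(), 400, seed = 23)
  X <- fit_transform(truth_features(dv))$X
  f <- fit_em(X, 3, seed = 5)
  expect_true(all(diff(f$loglik_trace) > -1e-7))
  expect_true(f$converged)
})

test_that("forward log-likelihood matches exhaustive enumeration", {
  set.seed(31)
  for (i in 1:25) {
    K <- sample(2:3, 1)
    Tn <- sample(1:6, 1)
    par <- rand_hmm(K)
    X <- matrix(runif(Tn * 2), Tn)
    fit <- as_fit(par, K)
    expect_equal(forward_loglik(fit, X),
                 brute_force_loglik(par$pi, par$A, par$mu, par$sigma, X),
                 tolerance = 1e-8)
  }
})

test_that("single-observation likelihood is the mixture density", {
  par <- rand_hmm(3)
  X <- matrix(c(0.4, 0.6), 1)
  dens <- sum(par$pi * sapply(1:3, function(k)
    prod(dnorm(X, par$mu[k, ], par$sigma[k, ]))))
  expect_equal(forward_loglik(as_fit(par, 3), X), log(dens),
               tolerance = 1e-10)
})

test_that("an impossible observation flags -Inf without crashing", {
  # zero emission scale gives an exactly-zero density off the mean
  fit <- as_fit(list(pi = c(0.5, 0.5),
                     A = matrix(0.5, 2, 2),
                     mu = matrix(0, 2, 2),
                     sigma = matrix(0, 2, 2)), 2)
  X <- rbind(c(0, 0), c(1e6, 1e6))
  expect_warning(ll <- forward_loglik(fit, X), "impossible")
  expect_identical(ll, -Inf)
})

test_that("Viterbi matches the exhaustive argmax path", {
  set.seed(37)
  for (i in 1:25) {
    K <- sample(2:3, 1)
    Tn <- sample(2:6, 1)
    par <- rand_hmm(K)
    X <- matrix(runif(Tn * 2), Tn)
    v <- decode(as_fit(par, K), X)[[1]]$states
    expect_equal(v, unname(brute_force_viterbi(par$pi, par$A, par$mu,
                                               par$sigma, X)))
  }
})

test_that("posterior rows sum to one", {
  dv <- simulate_dive_sequence(sim_config(), 300, seed = 41)
  X <- fit_transform(truth_features(dv))$X
  f <- fit_em(X, 4, seed = 7)
  post <- decode(f, X)[[1]]$posterior
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
})

test_that("identical emissions decode by the prior alone, first index", {
  fit <- as_fit(list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                     mu = matrix(0.5, 2, 2),
                     sigma = matrix(0.3, 2, 2)), 2)
  X <- matrix(runif(10), 5, 2)
  v <- decode(fit, X)[[1]]$states
  expect_equal(v, rep(1L, 5))  # all paths tie; lowest index wins
})

test_that("label permutation leaves loglik and AIC unchanged", {
  dv <- simulate_dive_sequence(sim_config(), 300, seed = 43)
  X <- fit_transform(truth_features(dv))$X
  f <- fit_em(X, 4, seed = 3)
  perm <- c(3L, 1L, 4L, 2L)
  f2 <- relabel_fit(f, perm)
  expect_equal(forward_loglik(f2, X), f$loglik, tolerance = 1e-8)
  expect_equal(f2$aic, f$aic)
  # the permutation really moved the parameters
  expect_equal(f2$mu[perm[1], ], f$mu[1, ])
})

test_that("likelihood is invariant to sequence order", {
  dv <- simulate_dive_sequence(sim_config(), 200, seed = 47)
  X <- fit_transform(truth_features(dv))$X
  f <- fit_em(X, 2, seed = 9)
  s1 <- X[1:100, ]
  s2 <- X[101:200, ]
  ll_a <- forward_loglik(f, s1) + forward_loglik(f, s2)
  ll_b <- forward_loglik(f, s2) + forward_loglik(f, s1)
  expect_equal(ll_a, ll_b, tolerance = 1e-12)
})

test_that("model selection retains the best AIC over restarts", {
  dv <- simulate_dive_sequence(sim_config(), 400, seed = 53)
  X <- fit_transform(truth_features(dv))$X
  aics <- sapply(1:6, function(r) fit_em(X, 2, seed = 100 + r)$aic)
  sel <- select_model(X, states = 2, n_restarts = 6, base_seed = 100)
  expect_equal(sel$table$aic, min(aics))
  # a superset of restarts can only improve
  sel2 <- select_model(X, states = 2, n_restarts = 3, base_seed = 100)
  expect_lte(sel$table$aic, sel2$table$aic)
})

test_that("two simulated states beat one by AIC", {
  cfg2 <- sim_config()
  cfg2$pi <- c(0.5, 0.5, 0, 0)
  cfg2$A <- rbind(c(0.9, 0.1, 0, 0), c(0.1, 0.9, 0, 0),
                  c(0, 0, 1, 0), c(0, 0, 0, 1))
  dv <- simulate_dive_sequence(cfg2, 1000, seed = 59)
  expect_true(all(dv$state %in% 1:2))
  X <- fit_transform(truth_features(dv))$X
  f1 <- fit_em(X, 1, seed = 1)
  sel <- select_model(X, states = 2, n_restarts = 5, base_seed = 1)
  expect_lt(sel$table$aic, f1$aic)
})

test_that("canonical labelling matches the generator's states", {
  cfg <- sim_config()
  dv <- simulate_dive_sequence(cfg, 1500, seed = 61)
  feats <- truth_features(dv)
  X <- fit_transform(feats)$X
  sel <- select_model(X, states = 4, n_restarts = 5, base_seed = 7)
  fit <- sel$fits[["4"]]
  summ <- summarise_states(fit, decode(fit, X), feats)
  expect_gt(mean(summ$state == dv$state), 0.95)
  expect_equal(rowSums(summ$fit$A), rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(summ$fit$pi), 1, tolerance = 1e-9)
  # diagonally dominant truth: every self-transition dominates its row
  for (k in 1:4)
    expect_true(all(summ$fit$A[k, k] >= summ$fit$A[k, -k]))
  # per-individual proportions sum to one
  expect_equal(unname(rowSums(summ$proportions)), 1)
})

test_that("canonical labelling falls back to depth ordering on collision", {
  sm <- cbind(max_depth = c(80, 60, 40, 20),
              bottom_time = c(900, 500, 300, 100),
              dive_time = c(1, 1, 1, 1), surface_interval = c(1, 1, 1, 1))
  expect_warning(perm <- canonical_state_labels(sm), "collide")
  expect_equal(perm, c(2L, 1L, 3L, 4L))
})
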