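#' Fit a multivariate hidden Markov model by Baum-Welch EM
#'
#' Fits an HMM with diagonal-Gaussian emissions (independent Gaussians
#' per feature within each state) to one or more observation sequences
#' sharing the same parameters.  Sequences are trips: chains do not
#' bridge deployment boundaries or multi-day track gaps.  Random
#' initialisation draws emission means from the observations with
#' k-means++-style seeding, emission standard deviations from the
#' pooled per-feature standard deviation, and the initial distribution
#' and transition rows from Dirichlet(1).  The E-step runs the scaled
#' forward-backward recursions; convergence is declared when the
#' relative log-likelihood change drops below `tol`.
#'
#' The parameter count for AIC is
#' `(K - 1) + K (K - 1) + 2 K p` for `K` states and `p` features.
#'
#' @param sequences A matrix or list of matrices (one per sequence,
#'   rows = dives, columns = transformed features in `[0, 1]`).
#' @param n_states Number of latent states (`K >= 1`).
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param sigma_floor Lower bound applied to emission standard
#'   deviations; hitting it is flagged in `sigma_floored`.
#' @return An object of class `hmm_fit`: `n_states`, `pi`, `A`, `mu`
#'   (K x p), `sigma` (K x p), `loglik` (nats), `aic`, `n_params`,
#'   `seed`, `converged`, `n_iter`, `sigma_floored`, `loglik_trace`.
#' @export
fit_em <- function(sequences, n_states, seed = 1L, max_iter = 500,
                   tol = 1e-6, sigma_floor = 1e-4) {
  X_list <- as_seq_list(sequences)
  if (any(vapply(X_list, nrow, 0L) < 2) && n_states > 1)
    stop("fit_em: every sequence must have length >= 2", call. = FALSE)
  K <- as.integer(n_states)
  pool <- do.call(rbind, X_list)
  p <- ncol(pool)

  set.seed(seed)
  mu <- pool[kmeanspp_idx(pool, K), , drop = FALSE]
  sigma <- matrix(rep(pmax(apply(pool, 2, stats::sd), sigma_floor), each = K),
                  K, p)
  pi0 <- rdirichlet1(K)
  A <- t(replicate(K, rdirichlet1(K)))
  if (K == 1) A <- matrix(1, 1, 1)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  floored <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g1 <- numeric(K)
    xi_sum <- matrix(0, K, K)
    gsum <- numeric(K)
    gx <- matrix(0, K, p)
    gx2 <- matrix(0, K, p)
    bad <- FALSE
    for (X in X_list) {
      logB <- emission_logdens(X, mu, sigma)
      fb <- forward_backward(pi0, A, logB)
      if (!is.finite(fb$loglik)) { bad <- TRUE; break }
      ll <- ll + fb$loglik
      g1 <- g1 + fb$gamma[1, ]
      xi_sum <- xi_sum + fb$xi_sum
      gsum <- gsum + colSums(fb$gamma)
      gx <- gx + t(fb$gamma) %*% X
      gx2 <- gx2 + t(fb$gamma) %*% (X^2)
    }
    if (bad) {
      converged <- FALSE
      break
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    pi0 <- g1 / sum(g1)
    if (K > 1) A <- sweep(xi_sum, 1, pmax(rowSums(xi_sum), 1e-300), "/")
    mu <- gx / gsum
    v <- gx2 / gsum - mu^2
    sigma_new <- sqrt(pmax(v, 0))
    if (any(sigma_new < sigma_floor)) floored <- TRUE
    sigma <- pmax(sigma_new, sigma_floor)
  }
  n_params <- (K - 1) + K * (K - 1) + 2 * K * p
  ll_final <- if (length(ll_trace)) ll_trace[length(ll_trace)] else NaN
  structure(list(n_states = K, pi = pi0, A = A, mu = mu, sigma = sigma,
                 loglik = ll_final, aic = 2 * n_params - 2 * ll_final,
                 n_params = n_params, seed = as.integer(seed),
                 converged = converged, n_iter = length(ll_trace),
                 sigma_floored = floored, loglik_trace = ll_trace),
            class = "hmm_fit")
}

as_seq_list <- function(sequences) {
  if (is.matrix(sequences)) list(sequences) else sequences
}

rdirichlet1 <- function(K) {
  g <- stats::rgamma(K, 1)
  g / sum(g)
}

# k-means++-style seeding: indices of K observations, first uniform,
# the rest with probability proportional to squared distance to the
# nearest centre chosen so far.
kmeanspp_idx <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  if (K == 1) return(idx)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (k in 2:K) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[k] <- sample.int(n, 1, prob = pr)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[k], ])^2))
  }
  idx
}

emission_logdens <- function(X, mu, sigma) {
  K <- nrow(mu)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    out[, k] <- rowSums(matrix(
      stats::dnorm(X, rep(mu[k, ], each = nrow(X)),
                   rep(sigma[k, ], each = nrow(X)), log = TRUE),
      nrow(X), ncol(X)))
  out
}

# Scaled forward-backward.  Returns loglik, gamma (T x K) and the sum
# over t of the transition posteriors xi (K x K).
forward_backward <- function(pi0, A, logB) {
  Tn <- nrow(logB)
  K <- length(pi0)
  shift <- apply(logB, 1, max)
  if (any(!is.finite(shift))) return(list(loglik = -Inf))
  B <- exp(logB - shift)
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) return(list(loglik = -Inf))
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    if (cvec[t] <= 0) return(list(loglik = -Inf))
    alpha[t, ] <- a / cvec[t]
  }
  loglik <- sum(log(cvec)) + sum(shift)
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  xi_sum <- matrix(0, K, K)
  if (Tn > 1) for (t in (Tn - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    xi_sum <- xi_sum + (outer(alpha[t, ], bb) * A) / cvec[t + 1]
    beta[t, ] <- (A %*% bb) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = loglik, gamma = gamma, xi_sum = xi_sum)
}

#' Forward log-likelihood of a sequence under a fitted HMM
#'
#' Exact marginal log-likelihood via the scaled forward recursion.  An
#' observation with zero emission density under every state yields
#' `-Inf` with a warning rather than an error.
#'
#' @param fit An `hmm_fit`.
#' @param X Observation matrix (rows = time steps).
#' @return Log-likelihood in nats.
#' @export
forward_loglik <- function(fit, X) {
  logB <- emission_logdens(X, fit$mu, fit$sigma)
  ll <- forward_backward(fit$pi, fit$A, logB)$loglik
  if (!is.finite(ll))
    warning("forward_loglik: observation impossible under every state")
  ll
}

#' Decode latent states
#'
#' Viterbi most-probable path (ties broken towards the lowest state
#' index) and forward-backward posterior state probabilities for each
#' sequence.
#'
#' @param fit A converged `hmm_fit`.
#' @param sequences Matrix or list of matrices.
#' @return A list with one element per sequence, each containing
#'   `states` (integer vector) and `posterior` (T x K matrix, rows sum
#'   to 1).
#' @export
decode <- function(fit, sequences) {
  X_list <- as_seq_list(sequences)
  lapply(X_list, function(X) {
    logB <- emission_logdens(X, fit$mu, fit$sigma)
    fb <- forward_backward(fit$pi, fit$A, logB)
    list(states = viterbi_path(fit$pi, fit$A, logB),
         posterior = fb$gamma)
  })
}

viterbi_path <- function(pi0, A, logB) {
  Tn <- nrow(logB)
  K <- length(pi0)
  logA <- log(A)
  delta <- log(pi0) + logB[1, ]
  back <- matrix(0L, Tn, K)
  if (Tn > 1) for (t in 2:Tn) {
    m <- delta + logA                 # K x K: m[i, j] = delta_i + log A_ij
    back[t, ] <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(back[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Fit HMMs over a range of state counts with seeded restarts
#'
#' For each candidate state count, runs `n_restarts` independent EM
#' fits (restart `r` uses seed `base_seed + r`, so each is individually
#' reproducible) and retains the converged fit with the lowest AIC.
#' The AIC comparison across state counts informs — but does not
#' dictate — the final choice: distinguishing, say, four from five
#' states is a judgement about whether the extra state is biologically
#' distinct.
#'
#' @param sequences Matrix or list of matrices.
#' @param states Candidate state counts.
#' @param n_restarts Restarts per state count.
#' @param base_seed Base of the restart seed ladder.
#' @param ... Passed to [fit_em()].
#' @return A list: `table` (data frame with `n_states`, `loglik`,
#'   `aic`, `n_params`, `converged_restarts`, `best_seed`) and `fits`
#'   (best `hmm_fit` per state count, named by state count).
#' @export
select_model <- function(sequences, states = 2:5, n_restarts = 100,
                         base_seed = 1L, ...) {
  fits <- list()
  rows <- list()
  for (K in states) {
    best <- NULL
    n_conv <- 0L
    for (r in seq_len(n_restarts)) {
      f <- fit_em(sequences, K, seed = base_seed + r, ...)
      if (!f$converged || !is.finite(f$aic)) next
      n_conv <- n_conv + 1L
      if (is.null(best) || f$aic < best$aic) best <- f
    }
    if (is.null(best)) {
      warning("select_model: no converged restart for ", K, " states")
      rows[[as.character(K)]] <- data.frame(
        n_states = K, loglik = NA_real_, aic = NA_real_,
        n_params = NA_integer_, converged_restarts = n_conv,
        best_seed = NA_integer_)
    } else {
      fits[[as.character(K)]] <- best
      rows[[as.character(K)]] <- data.frame(
        n_states = K, loglik = best$loglik, aic = best$aic,
        n_params = best$n_params, converged_restarts = n_conv,
        best_seed = best$seed)
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits)
}

#' Canonical behavioural-state labelling
#'
#' Relabels fitted states by their raw-scale feature structure so that
#' labels are comparable across fits: State 1 is the state with the
#' largest mean bottom time, State 2 the deepest of the remaining
#' states, State 4 the shallowest, and State 3 the one left over.  If
#' two criteria select the same state (a collision), labelling falls
#' back to pure depth ordering (deepest = 2, shallowest = 4, and of the
#' middle two the larger bottom time = 1) with a warning.
#'
#' @param state_means K x p matrix of per-state mean features on the
#'   raw scale (columns include `bottom_time` and `max_depth`).
#' @return Integer vector `perm` with `perm[k]` = canonical label of
#'   fitted state `k`.
#' @export
canonical_state_labels <- function(state_means) {
  K <- nrow(state_means)
  stopifnot(K == 4)
  bt <- state_means[, "bottom_time"]
  md <- state_means[, "max_depth"]
  s1 <- which.max(bt)
  rest <- setdiff(1:4, s1)
  s2 <- rest[which.max(md[rest])]
  s4 <- rest[which.min(md[rest])]
  if (s2 == s4 || which.max(md) == s1 || which.min(md) == s1) {
    warning("canonical_state_labels: criteria collide; ",
            "falling back to depth ordering")
    ord <- order(md, decreasing = TRUE)     # deepest first
    mid <- ord[2:3]
    perm <- integer(4)
    perm[ord[1]] <- 2L
    perm[ord[4]] <- 4L
    perm[mid[which.max(bt[mid])]] <- 1L
    perm[perm == 0] <- 3L
    return(perm)
  }
  s3 <- setdiff(rest, c(s2, s4))
  perm <- integer(4)
  perm[c(s1, s2, s3, s4)] <- 1:4
  perm
}

#' Permute the state labels of a fitted HMM
#'
#' Label permutation is a symmetry of the likelihood: the returned fit
#' has identical `loglik` and `aic`.
#'
#' @param fit An `hmm_fit`.
#' @param perm Integer vector, `perm[k]` = new label of old state `k`.
#' @return The relabelled `hmm_fit`.
#' @export
relabel_fit <- function(fit, perm) {
  inv <- order(perm)      # inv[new] = old
  fit$pi <- fit$pi[inv]
  fit$A <- fit$A[inv, inv, drop = FALSE]
  fit$mu <- fit$mu[inv, , drop = FALSE]
  fit$sigma <- fit$sigma[inv, , drop = FALSE]
  fit
}

#' Summarise a decoded state model
#'
#' Reports the fitted initial and transition probabilities under
#' canonical labels, per-state raw-feature means and medians, and
#' per-individual state proportions.
#'
#' @param fit A fitted 4-state `hmm_fit`.
#' @param decoded Output of [decode()].
#' @param features Feature data frame (rows aligned with the
#'   concatenated decoded sequences) including `individual_id` and the
#'   raw feature columns.
#' @return A list: `perm` (canonical relabelling), `fit` (relabelled),
#'   `state` (canonical per-dive states), `state_means`,
#'   `state_medians`, `proportions` (individual x state).
#' @export
summarise_states <- function(fit, decoded, features) {
  state_raw <- unlist(lapply(decoded, `[[`, "states"))
  stopifnot(length(state_raw) == nrow(features))
  feats <- c("max_depth", "bottom_time", "dive_time", "surface_interval")
  means_raw <- t(vapply(seq_len(fit$n_states), function(k)
    colMeans(features[state_raw == k, feats, drop = FALSE]),
    numeric(length(feats))))
  colnames(means_raw) <- feats
  perm <- canonical_state_labels(means_raw)
  state <- perm[state_raw]
  fit2 <- relabel_fit(fit, perm)
  inv <- order(perm)
  medians <- t(vapply(seq_len(fit$n_states), function(k)
    apply(features[state == k, feats, drop = FALSE], 2, stats::median),
    numeric(length(feats))))
  props <- prop.table(table(features$individual_id, state), margin = 1)
  list(perm = perm, fit = fit2, state = state,
       state_means = means_raw[inv, , drop = FALSE],
       state_medians = medians,
       proportions = props)
}
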