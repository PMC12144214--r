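# Independent oracles used across the suite.  These deliberately avoid
# the package's own recursions: likelihoods and decodings are obtained
# by exhaustive path enumeration, distances by a hand-written
# haversine, and Fisher p-values by direct hypergeometric enumeration.

# log-sum-exp over all n_states^T paths
brute_force_loglik <- function(pi0, A, mu, sigma, X) {
  K <- length(pi0)
  Tn <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1, function(s) {
    v <- log(pi0[s[1]])
    if (Tn > 1) for (t in 2:Tn) v <- v + log(A[s[t - 1], s[t]])
    for (t in seq_len(Tn))
      v <- v + sum(dnorm(X[t, ], mu[s[t], ], sigma[s[t], ], log = TRUE))
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

brute_force_viterbi <- function(pi0, A, mu, sigma, X) {
  K <- length(pi0)
  Tn <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1, function(s) {
    v <- log(pi0[s[1]])
    if (Tn > 1) for (t in 2:Tn) v <- v + log(A[s[t - 1], s[t]])
    for (t in seq_len(Tn))
      v <- v + sum(dnorm(X[t, ], mu[s[t], ], sigma[s[t], ], log = TRUE))
    v
  })
  paths[which.max(lp), ]
}

rand_hmm <- function(K, p = 2) {
  pi0 <- rgamma(K, 1)
  pi0 <- pi0 / sum(pi0)
  A <- matrix(rgamma(K * K, 1), K)
  A <- sweep(A, 1, rowSums(A), "/")
  list(pi = pi0, A = A,
       mu = matrix(runif(K * p), K),
       sigma = matrix(runif(K * p, 0.2, 1), K))
}

as_fit <- function(par, K) {
  structure(list(n_states = K, pi = par$pi, A = par$A, mu = par$mu,
                 sigma = par$sigma), class = "hmm_fit")
}

# two-sided 2x2 Fisher p by probability-ordering over the
# hypergeometric support
fisher_2x2_enum <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  pr <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# features data frame straight from the generator's ground truth
truth_features <- function(dv, id = "sim") {
  data.frame(individual_id = id, max_depth = dv$max_depth,
             bottom_time = dv$bottom_time, dive_time = dv$dive_time,
             surface_interval = dv$surface_interval,
             month = tdrstates:::month_of(dv$start_time),
             stringsAsFactors = FALSE)
}
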