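# Brute-force latent-state enumeration oracles for the likelihoods.
# These sum explicitly over every latent (entry bin b, exit bin d) interval
# per genus -- independent of the forward/backward recursions used by the
# package -- and are only feasible for tiny matrices.

oracle_interval_weight <- function(h, b, d, phi, p, entry_mass, K) {
  js <- seq_len(K)
  if (any(h[js < b | js > d] == 1L)) return(0)
  pr <- entry_mass[b]
  if (d > b) pr <- pr * prod(phi[b:(d - 1L)])
  if (d < K) pr <- pr * (1 - phi[d])
  span <- b:d
  pr * prod(ifelse(h[span] == 1L, p[span], 1 - p[span]))
}

oracle_hist_weight <- function(h, phi, p, entry_mass) {
  K <- length(h)
  tot <- 0
  for (b in seq_len(K)) for (d in b:K)
    tot <- tot + oracle_interval_weight(h, b, d, phi, p, entry_mass, K)
  tot
}

popan_loglik_oracle <- function(params, data) {
  M <- data$matrix
  K <- ncol(M)
  D <- nrow(M)
  N <- params$n_super
  if (N < D) return(-Inf)
  w <- function(h) oracle_hist_weight(h, params$survival, params$detection,
                                      params$entry_probs)
  ll <- lgamma(N + 1) - lgamma(N - D + 1) - lgamma(D + 1) +
    sum(apply(M, 1L, function(h) log(w(h))))
  if (N - D > 1e-12) ll <- ll + (N - D) * log(w(rep(0L, K)))
  ll
}

pradel_loglik_oracle <- function(params, data) {
  M <- data$matrix
  K <- ncol(M)
  phi <- params$survival
  gam <- params$seniority           # gam[j-1] = seniority of bin j
  p <- params$detection
  relN <- c(1, cumprod(phi / gam))
  entry_mass <- relN * c(1, 1 - gam)  # relative entry cohort sizes B_b / N_1
  w <- function(h) oracle_hist_weight(h, phi, p, entry_mass)
  # normalizer: summed weight of every observable (nonzero) history
  all_h <- as.matrix(expand.grid(rep(list(0:1), K)))
  all_h <- all_h[rowSums(all_h) > 0L, , drop = FALSE]
  W <- sum(apply(all_h, 1L, w))
  sum(apply(M, 1L, function(h) log(w(h) / W)))
}

# random small incidence matrix: every genus detected at least once
random_incidence <- function(n_genera, K, p_cell = 0.45) {
  repeat {
    M <- matrix(rbinom(n_genera * K, 1L, p_cell), n_genera, K)
    if (all(rowSums(M) > 0L)) break
  }
  rownames(M) <- sprintf("g%02d", seq_len(n_genera))
  older <- seq(520, by = -2, length.out = K)
  incidence_matrix(M, time_bins(sprintf("b%d", seq_len(K)), older, older - 2))
}

random_popan_params <- function(K) {
  w <- runif(K, 0.2, 1)
  popan_params(n_super = runif(1, 1.2, 3) * 6,
               entry_probs = w / sum(w),
               survival = runif(K - 1, 0.3, 0.95),
               detection = runif(K, 0.2, 0.9))
}

random_pradel_params <- function(K) {
  pradel_params(survival = runif(K - 1, 0.3, 0.95),
                seniority = runif(K - 1, 0.3, 0.95),
                detection = runif(K, 0.2, 0.9))
}
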