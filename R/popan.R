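#' POPAN parameter set
#'
#' Parameters of the Jolly-Seber model in the POPAN (superpopulation)
#' formulation: a superpopulation size, per-bin entry probabilities summing
#' to 1, per-transition survival probabilities and per-bin detection
#' probabilities.
#'
#' @param n_super superpopulation size (real, >= number of observed genera).
#' @param entry_probs K-vector on the simplex.
#' @param survival (K-1)-vector of survival probabilities phi_i.
#' @param detection K-vector of detection probabilities p_i.
#' @return A `popan_params` list.
#' @export
popan_params <- function(n_super, entry_probs, survival, detection) {
  K <- length(entry_probs)
  if (length(survival) != K - 1L || length(detection) != K)
    stop("parameter vector lengths inconsistent with K = ", K, call. = FALSE)
  if (any(entry_probs < 0) || abs(sum(entry_probs) - 1) > 1e-8)
    stop("entry_probs must be a probability simplex", call. = FALSE)
  if (any(survival < 0 | survival > 1) || any(detection < 0 | detection > 1))
    stop("survival and detection must lie in [0, 1]", call. = FALSE)
  structure(list(n_super = n_super, entry_probs = as.numeric(entry_probs),
                 survival = as.numeric(survival),
                 detection = as.numeric(detection)),
            class = "popan_params")
}

# forward pass over the latent entry/alive/dead chain for a block of
# histories (rows of H); returns P(history) per row. Works multiplicatively
# (no logs) so boundary parameter values (p = 0/1) are exact.
popan_forward <- function(H, pent, phi, p) {
  U <- nrow(H)
  K <- ncol(H)
  cum <- cumsum(pent)
  h1 <- H[, 1L] == 1L
  a_pre <- ifelse(h1, 0, 1 - pent[1L])
  a_alive <- pent[1L] * ifelse(h1, p[1L], 1 - p[1L])
  a_dead <- numeric(U)
  for (i in seq_len(K - 1L)) {
    denom <- 1 - cum[i]
    q <- if (denom <= 1e-14) 0 else min(pent[i + 1L] / denom, 1)
    hi <- H[, i + 1L] == 1L
    em1 <- ifelse(hi, p[i + 1L], 1 - p[i + 1L])
    new_alive <- (a_alive * phi[i] + a_pre * q) * em1
    a_pre <- a_pre * (1 - q)
    a_dead <- a_dead + a_alive * (1 - phi[i])
    a_pre[hi] <- 0       # latent pre-entry/dead states cannot be detected
    a_dead[hi] <- 0
    a_alive <- new_alive
  }
  a_pre + a_alive + a_dead
}

#' POPAN log-likelihood of an incidence matrix
#'
#' Full (unconditional) POPAN likelihood: a multinomial over observable
#' capture histories driven by entry, survival and detection probabilities,
#' plus the binomial term for the `n_super - D` genera in the
#' superpopulation that were never detected (D = observed genus count).
#' Returns `-Inf` (not an error) when `n_super < D` or when a history has
#' probability zero under the parameters.
#'
#' @param params a [popan_params].
#' @param data an `incidence_matrix`.
#' @return The log-likelihood (scalar).
#' @export
popan_loglik <- function(params, data) {
  stopifnot(inherits(params, "popan_params"), inherits(data, "incidence_matrix"))
  ch <- compress_histories(data$matrix)
  popan_loglik_ch(ch, params$n_super, params$entry_probs, params$survival,
                  params$detection)
}

popan_loglik_ch <- function(ch, n_super, pent, phi, p) {
  if (length(pent) != ch$K)
    stop("parameter dimensions do not match the ", ch$K, " bins", call. = FALSE)
  D <- ch$n
  if (n_super < D) return(-Inf)
  Ph <- popan_forward(ch$H, pent, phi, p)
  if (any(Ph <= 0)) return(-Inf)
  P0 <- popan_forward(matrix(0L, 1L, ch$K), pent, phi, p)
  ll <- lgamma(n_super + 1) - lgamma(n_super - D + 1) - lgamma(D + 1) +
    sum(ch$counts * log(Ph))
  if (n_super - D > 1e-12) {
    if (P0 <= 0) return(-Inf)
    ll <- ll + (n_super - D) * log(P0)
  }
  ll
}

#' Fit the POPAN Jolly-Seber model to an incidence matrix
#'
#' Maximum-likelihood fit over link-transformed parameters: log link for the
#' superpopulation excess over the observed genus count, multinomial-logit
#' for the entry simplex, logit for survival and detection. Detection in the
#' first and last bins is tied to its neighbouring bin by default
#' (`tie_end_p`), the standard identifiability constraint for the fully
#' time-varying model (entry/detection at the first occasion, and
#' survival/detection at the last, are otherwise confounded). Returns the
#' derived per-bin richness series `N_1 = n_super * entry_1`,
#' `N_(i+1) = N_i * phi_i + n_super * entry_(i+1)` with delta-method 95%
#' confidence intervals (log scale for richness).
#'
#' @param data an `incidence_matrix` with >= 3 bins and >= 1 genus.
#' @param options list; recognized fields: `restarts` (max jittered restarts
#'   on failure, default 5), `reltol` (optimizer relative tolerance, default
#'   1e-10), `tie_end_p` (default `TRUE`), `constant` (character subset of
#'   `c("phi", "p")` forcing a time-constant parameter).
#' @return A `cr_fit` with `model = "POPAN"`, the estimate table (parameter,
#'   bin, estimate, link-scale SE, 95% CI), log-likelihood, convergence
#'   diagnostics and the `richness` data frame (bin, observed, estimate,
#'   lcl, ucl).
#' @export
fit_popan <- function(data, options = list()) {
  stopifnot(inherits(data, "incidence_matrix"))
  opt <- utils::modifyList(list(restarts = 5L, reltol = 1e-10,
                                tie_end_p = TRUE, constant = character(0)),
                           options)
  ch <- compress_histories(data$matrix)
  K <- ch$K
  if (K < 3L) stop("fit_popan needs at least 3 bins", call. = FALSE)
  D <- ch$n

  phi_map <- if ("phi" %in% opt$constant) rep(1L, K - 1L) else seq_len(K - 1L)
  p_map <- if ("p" %in% opt$constant) rep(1L, K)
           else if (isTRUE(opt$tie_end_p)) c(1L, seq_len(K - 2L), K - 2L)
           else seq_len(K)
  np <- max(phi_map); npd <- max(p_map)
  i_N <- 1L
  i_eta <- 1L + seq_len(K - 1L)
  i_phi <- 1L + (K - 1L) + seq_len(np)
  i_p <- 1L + (K - 1L) + np + seq_len(npd)

  unpack <- function(th) {
    w <- exp(c(0, th[i_eta]))
    list(n_super = D + exp(th[i_N]),
         pent = w / sum(w),
         phi = invlogit(th[i_phi])[phi_map],
         p = invlogit(th[i_p])[p_map])
  }
  fn <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 50)) return(-Inf)
    pr <- unpack(th)
    popan_loglik_ch(ch, pr$n_super, pr$pent, pr$phi, pr$p)
  }

  # data-driven starting values
  first_det <- apply(ch$H, 1L, function(h) which(h == 1L)[1L])
  f_counts <- vapply(seq_len(K), function(i)
    sum(ch$counts[first_det == i]), 0) + 0.5
  obs <- as.vector(ch$counts %*% ch$H)
  p0 <- pmin(pmax(obs / max(obs), 0.2), 0.9) * 0.7
  theta0 <- c(log(0.3 * D + 5),
              log(f_counts[-1L] / f_counts[1L]),
              rep(logit(0.85), np),
              logit(vapply(seq_len(npd), function(g)
                mean(p0[p_map == g]), 0)))

  res <- maximize_loglik(fn, theta0, restarts = opt$restarts,
                         reltol = opt$reltol)
  th <- res$par
  pr <- unpack(th)
  V <- link_vcov(fn, th)
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)

  if (any(abs(th[c(i_phi, i_p)]) > 9))
    warning("some survival/detection estimates lie at the boundary of (0,1)",
            call. = FALSE)

  # derived richness with log-scale delta-method CIs
  richness_of <- function(th) {
    pr <- unpack(th)
    N <- numeric(K)
    N[1L] <- pr$n_super * pr$pent[1L]
    for (i in seq_len(K - 1L))
      N[i + 1L] <- N[i] * pr$phi[i] + pr$n_super * pr$pent[i + 1L]
    N
  }
  Nhat <- richness_of(th)
  J <- num_jacobian(function(x) log(pmax(richness_of(x), 1e-12)), th)
  vr <- rowSums((J %*% V) * J)
  se_logN <- sqrt(pmax(vr, 0))
  richness <- data.frame(
    bin = seq_len(K), name = data$bins$name,
    observed = obs,
    estimate = Nhat,
    lcl = Nhat * exp(-z * se_logN),
    ucl = Nhat * exp(z * se_logN)
  )

  # entry-probability CIs by delta method on the log simplex coordinates
  Jp <- num_jacobian(function(x) log(unpack(x)$pent), th)
  se_lpent <- sqrt(pmax(rowSums((Jp %*% V) * Jp), 0))

  est <- rbind(
    data.frame(parameter = "n_super", bin = NA_integer_,
               estimate = pr$n_super, se_link = se[i_N],
               lcl = D + exp(th[i_N] - z * se[i_N]),
               ucl = D + exp(th[i_N] + z * se[i_N])),
    data.frame(parameter = "pent", bin = seq_len(K), estimate = pr$pent,
               se_link = se_lpent,
               lcl = pr$pent * exp(-z * se_lpent),
               ucl = pmin(pr$pent * exp(z * se_lpent), 1)),
    prob_estimate_rows("phi", seq_len(K - 1L), th[i_phi][phi_map],
                       se[i_phi][phi_map]),
    prob_estimate_rows("p", seq_len(K), th[i_p][p_map], se[i_p][p_map])
  )

  structure(list(
    model = "POPAN", estimates = est, loglik = -res$value,
    convergence = list(code = res$convergence, starts = res$tries,
                       message = res$message %||% ""),
    theta = th, vcov = V, K = K, n_genera = D,
    scheme = data$bins, richness = richness,
    options = opt[c("restarts", "tie_end_p")],
    params = popan_params(pr$n_super, pr$pent, pr$phi, pr$p)
  ), class = "cr_fit")
}
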