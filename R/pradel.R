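#' Pradel parameter set
#'
#' Parameters of the Pradel survival/seniority model: per-transition survival
#' probabilities phi_i (genus extant in bin i still extant in bin i+1),
#' per-bin seniority probabilities gamma_(i+1) (genus extant in bin i+1 was
#' already extant in bin i) and per-bin detection probabilities p_i.
#'
#' @param survival (K-1)-vector phi.
#' @param seniority (K-1)-vector; element i is gamma_(i+1).
#' @param detection K-vector p.
#' @return A `pradel_params` list.
#' @export
pradel_params <- function(survival, seniority, detection) {
  K <- length(detection)
  if (length(survival) != K - 1L || length(seniority) != K - 1L)
    stop("parameter vector lengths inconsistent with K = ", K, call. = FALSE)
  ok <- function(x) all(x >= 0 & x <= 1)
  if (!ok(survival) || !ok(seniority) || !ok(detection))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(survival = as.numeric(survival),
                 seniority = as.numeric(seniority),
                 detection = as.numeric(detection)),
            class = "pradel_params")
}

#' Pradel log-likelihood of an incidence matrix
#'
#' Full-history Pradel likelihood, conditional on each genus being detected
#' at least once. For a genus first detected in bin f and last detected in
#' bin l the unnormalized contribution is
#' `(N_f / N_1) * xi_f * prod(detection terms over [f, l]) *
#' prod(phi over [f, l-1]) * chi_l`, where `N_j / N_1 = prod(phi_(m-1) /
#' gamma_m, m = 2..j)` is the relative extant richness implied by survival
#' and seniority, the backward recursion
#' `xi_j = (1 - gamma_j) + gamma_j (1 - p_(j-1)) xi_(j-1)` (with `xi_1 = 1`)
#' sums over latent entry bins weighted by non-detection before f, and the
#' forward recursion
#' `chi_j = (1 - phi_j) + phi_j (1 - p_(j+1)) chi_(j+1)` (with `chi_K = 1`)
#' sums over latent exit bins after l. Each contribution is normalized by
#' the summed weight of all observable histories (the probability that a
#' genus in the population is detected at all), which is what makes
#' seniority estimable from the distribution of first detections. The model
#' is symmetric under time reversal with phi and gamma exchanged.
#'
#' @param params a [pradel_params].
#' @param data an `incidence_matrix`.
#' @return The log-likelihood (scalar); `-Inf` for histories impossible
#'   under the parameters.
#' @export
pradel_loglik <- function(params, data) {
  stopifnot(inherits(params, "pradel_params"), inherits(data, "incidence_matrix"))
  ch <- compress_histories(data$matrix)
  if (length(params$detection) != ch$K)
    stop("parameter dimensions do not match the ", ch$K, " bins", call. = FALSE)
  fl <- history_spans(ch$H)
  pradel_loglik_ch(ch, fl, params$survival, params$seniority, params$detection)
}

# first/last detection indices and the [f, l] mask, computed once per matrix
history_spans <- function(H) {
  U <- nrow(H)
  K <- ncol(H)
  f <- apply(H, 1L, function(h) which(h == 1L)[1L])
  l <- apply(H, 1L, function(h) max(which(h == 1L)))
  cols <- matrix(seq_len(K), U, K, byrow = TRUE)
  list(f = f, l = l, mask = (cols >= f) & (cols <= l))
}

pradel_loglik_ch <- function(ch, fl, phi, gamma, p) {
  K <- ch$K
  xi <- numeric(K)
  xi[1L] <- 1
  for (j in seq_len(K - 1L) + 1L)
    xi[j] <- (1 - gamma[j - 1L]) + gamma[j - 1L] * (1 - p[j - 1L]) * xi[j - 1L]
  chi <- numeric(K)
  chi[K] <- 1
  for (j in rev(seq_len(K - 1L)))
    chi[j] <- (1 - phi[j]) + phi[j] * (1 - p[j + 1L]) * chi[j + 1L]

  # log relative extant richness N_j / N_1 and relative entry masses
  # B_j / N_1 = (N_j / N_1) (1 - gamma_j), with gamma_1 taken as 0
  lrelN <- c(0, cumsum(log(phi) - log(gamma)))
  lentry <- lrelN + log(c(1, 1 - gamma))

  # eta_b: P(never detected | entered at b)
  eta <- numeric(K)
  eta[K] <- 1 - p[K]
  for (b in rev(seq_len(K - 1L)))
    eta[b] <- (1 - p[b]) * ((1 - phi[b]) + phi[b] * eta[b + 1L])
  terms <- lentry + log1p(-eta)
  m <- max(terms)
  if (!is.finite(m)) return(-Inf)
  logW <- m + log(sum(exp(terms - m)))

  U <- nrow(ch$H)
  Lp <- matrix(log(p), U, K, byrow = TRUE)
  Lq <- matrix(log1p(-p), U, K, byrow = TRUE)
  L <- ifelse(ch$H == 1L, Lp, Lq)
  L[!fl$mask] <- 0
  mid <- rowSums(L)
  cphi <- c(0, cumsum(log(phi)))
  mid <- mid + cphi[fl$l] - cphi[fl$f]
  contrib <- lrelN[fl$f] + log(xi[fl$f]) + mid + log(chi[fl$l]) - logW
  if (any(!is.finite(contrib))) return(-Inf)
  sum(ch$counts * contrib)
}

#' Fit the Pradel survival/seniority model
#'
#' Maximum-likelihood fit of [pradel_loglik()] with logit links on all
#' parameters. As in [fit_popan()], detection in the first and last bin is
#' tied to the neighbouring bin by default: gamma_2 is confounded with p_1,
#' and phi_(K-1) with p_K, under fully time-varying detection.
#'
#' @param data an `incidence_matrix` with >= 3 bins.
#' @param options list; fields `restarts` (default 5), `reltol` (default
#'   1e-10), `tie_end_p` (default `TRUE`), `constant` (subset of
#'   `c("phi", "gamma", "p")`).
#' @return A `cr_fit` with `model = "Pradel"`: estimate table with rows for
#'   `phi` (bin i = transition i -> i+1), `gamma` (bin i+1, seniority
#'   relative to bin i) and `p`, link-scale SEs and 95% CIs, log-likelihood
#'   and convergence diagnostics.
#' @export
fit_pradel <- function(data, options = list()) {
  stopifnot(inherits(data, "incidence_matrix"))
  opt <- utils::modifyList(list(restarts = 5L, reltol = 1e-10,
                                tie_end_p = TRUE, constant = character(0)),
                           options)
  ch <- compress_histories(data$matrix)
  K <- ch$K
  if (K < 3L) stop("fit_pradel needs at least 3 bins", call. = FALSE)
  fl <- history_spans(ch$H)

  phi_map <- if ("phi" %in% opt$constant) rep(1L, K - 1L) else seq_len(K - 1L)
  gam_map <- if ("gamma" %in% opt$constant) rep(1L, K - 1L) else seq_len(K - 1L)
  p_map <- if ("p" %in% opt$constant) rep(1L, K)
           else if (isTRUE(opt$tie_end_p)) c(1L, seq_len(K - 2L), K - 2L)
           else seq_len(K)
  np <- max(phi_map); ng <- max(gam_map); npd <- max(p_map)
  i_phi <- seq_len(np)
  i_gam <- np + seq_len(ng)
  i_p <- np + ng + seq_len(npd)

  unpack <- function(th) list(phi = invlogit(th[i_phi])[phi_map],
                              gamma = invlogit(th[i_gam])[gam_map],
                              p = invlogit(th[i_p])[p_map])
  fn <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 50)) return(-Inf)
    pr <- unpack(th)
    pradel_loglik_ch(ch, fl, pr$phi, pr$gamma, pr$p)
  }

  obs <- as.vector(ch$counts %*% ch$H)
  p0 <- pmin(pmax(obs / max(obs), 0.2), 0.9) * 0.7
  theta0 <- c(rep(logit(0.8), np), rep(logit(0.8), ng),
              logit(vapply(seq_len(npd), function(g)
                mean(p0[p_map == g]), 0)))

  res <- maximize_loglik(fn, theta0, restarts = opt$restarts,
                         reltol = opt$reltol)
  th <- res$par
  pr <- unpack(th)
  V <- link_vcov(fn, th)
  se <- sqrt(diag(V))

  if (any(abs(th) > 9))
    warning("some parameter estimates lie at the boundary of (0,1)",
            call. = FALSE)

  est <- rbind(
    prob_estimate_rows("phi", seq_len(K - 1L), th[i_phi][phi_map],
                       se[i_phi][phi_map]),
    prob_estimate_rows("gamma", seq_len(K - 1L) + 1L, th[i_gam][gam_map],
                       se[i_gam][gam_map]),
    prob_estimate_rows("p", seq_len(K), th[i_p][p_map], se[i_p][p_map])
  )

  structure(list(
    model = "Pradel", estimates = est, loglik = -res$value,
    convergence = list(code = res$convergence, starts = res$tries,
                       message = res$message %||% ""),
    theta = th, vcov = V, K = K, n_genera = ch$n,
    scheme = data$bins,
    options = opt[c("restarts", "tie_end_p")],
    params = pradel_params(pr$phi, pr$gamma, pr$p)
  ), class = "cr_fit")
}
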