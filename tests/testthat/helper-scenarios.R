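# shared fixture builders

uniform_scheme <- function(K, width = 2, oldest = 520) {
  older <- seq(oldest, by = -width, length.out = K)
  time_bins(sprintf("u%02d", seq_len(K)), older, older - width)
}

# a cr_fit-shaped object with prescribed Pradel parameters, for testing the
# deterministic downstream stages (rates, survivorship) in isolation
fake_pradel_fit <- function(phi, gamma, p, scheme) {
  K <- nrow(scheme)
  est <- rbind(
    data.frame(parameter = "phi", bin = seq_len(K - 1), estimate = phi,
               se_link = 0.1, lcl = pmax(phi - 0.05, 0),
               ucl = pmin(phi + 0.05, 1)),
    data.frame(parameter = "gamma", bin = 2:K, estimate = gamma,
               se_link = 0.1, lcl = pmax(gamma - 0.05, 0),
               ucl = pmin(gamma + 0.05, 1)),
    data.frame(parameter = "p", bin = seq_len(K), estimate = p,
               se_link = 0.1, lcl = pmax(p - 0.05, 0), ucl = pmin(p + 0.05, 1))
  )
  structure(list(model = "Pradel", estimates = est, loglik = NA_real_,
                 convergence = list(code = 0L, starts = 1L, message = ""),
                 K = K, n_genera = NA_integer_, scheme = scheme,
                 options = list(restarts = 0L, tie_end_p = TRUE),
                 params = pradel_params(phi, gamma, p)),
            class = "cr_fit")
}

fast_fit <- list(restarts = 2L)

write_temp_csv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
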