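# Shared machinery for the likelihood fitters: link functions, history
# compression, numeric derivatives, multi-start optimization.

logit <- stats::qlogis
invlogit <- stats::plogis

# collapse an incidence matrix to unique capture histories with counts
compress_histories <- function(M) {
  key <- apply(M, 1L, paste0, collapse = "")
  tab <- table(key)
  H <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  list(H = H, counts = as.vector(tab), n = nrow(M), K = ncol(M))
}

# central-difference jacobian of a vector-valued function
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + eps
    xm[j] <- xm[j] - eps
    J[, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

# multi-start BFGS maximization of a log-likelihood; jittered restarts on
# failure or non-finite results. fn takes the link-scale parameter vector and
# returns the log-likelihood.
maximize_loglik <- function(fn, theta0, restarts = 5L, reltol = 1e-10,
                            jitter_sd = 0.5) {
  neg <- function(th) {
    v <- fn(th)
    if (!is.finite(v)) 1e10 else -v
  }
  best <- NULL
  tries <- 0L
  th <- theta0
  repeat {
    tries <- tries + 1L
    res <- tryCatch(
      stats::optim(th, neg, method = "BFGS",
                   control = list(maxit = 1000L, reltol = reltol)),
      error = function(e) NULL
    )
    if (!is.null(res) && is.finite(res$value)) {
      if (is.null(best) || res$value < best$value - 1e-12) best <- res
    }
    converged <- !is.null(best) && !is.null(res) &&
      res$convergence == 0L && res$value <= best$value + 1e-8
    if (converged || tries > restarts) break
    th <- theta0 + stats::rnorm(length(theta0), sd = jitter_sd)
  }
  if (is.null(best))
    stop("optimization failed after ", tries, " starts", call. = FALSE)
  best$tries <- tries
  best
}

# observed-information standard errors on the link scale, with a ridge
# fallback for near-singular Hessians (boundary estimates)
link_vcov <- function(fn, theta) {
  H <- tryCatch(stats::optimHess(theta, function(th) -fn(th)),
                error = function(e) NULL)
  if (is.null(H)) return(matrix(NA_real_, length(theta), length(theta)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V))
    V <- tryCatch(solve(H + diag(1e-6, nrow(H))), error = function(e)
      matrix(NA_real_, length(theta), length(theta)))
  # negative variances signal a saddle/boundary; flag as NA
  d <- diag(V)
  d[d < 0] <- NA_real_
  diag(V) <- d
  V
}

# assemble the per-parameter estimate table on the probability scale
prob_estimate_rows <- function(parameter, bin, link_est, link_se) {
  z <- stats::qnorm(0.975)
  data.frame(
    parameter = parameter,
    bin = bin,
    estimate = invlogit(link_est),
    se_link = link_se,
    lcl = invlogit(link_est - z * link_se),
    ucl = invlogit(link_est + z * link_se),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d bins, %d genera, log-likelihood %.3f (%s)\n",
              x$model, x$K, x$n_genera, x$loglik,
              if (x$convergence$code == 0L) "converged" else "NOT converged"))
  print(utils::head(x$estimates, 12L), row.names = FALSE)
  if (nrow(x$estimates) > 12L) cat("...", nrow(x$estimates), "rows\n")
  invisible(x)
}

#' Serialize a capture-recapture fit as flat CSV plus metadata block
#'
#' Writes the estimate table (parameter, bin, estimate, SE on the link
#' scale, 95% CI) to `path` and a small run-metadata text block
#' (`<path>.meta.txt`: model, log-likelihood, convergence, options).
#'
#' @param fit a `cr_fit`.
#' @param path output CSV path.
#' @export
write_cr_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cr_fit"))
  utils::write.csv(fit$estimates, path, row.names = FALSE)
  meta <- c(
    paste("model:", fit$model),
    paste("log_likelihood:", format(fit$loglik, digits = 12)),
    paste("convergence_code:", fit$convergence$code),
    paste("starts_used:", fit$convergence$starts),
    paste("n_genera:", fit$n_genera),
    paste("n_bins:", fit$K),
    paste("options:", paste(names(fit$options), unlist(fit$options),
                            sep = "=", collapse = "; "))
  )
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}

#' Build a capture-recapture fit object from prescribed parameters
#'
#' Wraps a [pradel_params] or [popan_params] set into the `cr_fit` container
#' the downstream stages ([evolutionary_rates()], [longevity_series()])
#' consume, with the per-parameter table filled in and no uncertainty
#' information (SEs `NA`, CIs equal to the point estimates). Useful for
#' evaluating the deterministic stages at known or published parameter
#' values.
#'
#' @param params a [pradel_params] or [popan_params].
#' @param scheme the [time_bins] scheme the parameters refer to.
#' @return A `cr_fit` object.
#' @export
cr_fit_from_params <- function(params, scheme) {
  stopifnot(inherits(scheme, "time_bins"))
  K <- nrow(scheme)
  row <- function(parameter, bin, est)
    data.frame(parameter = parameter, bin = bin, estimate = est,
               se_link = NA_real_, lcl = est, ucl = est,
               stringsAsFactors = FALSE)
  if (inherits(params, "pradel_params")) {
    if (length(params$detection) != K)
      stop("parameters and scheme disagree on the number of bins", call. = FALSE)
    est <- rbind(row("phi", seq_len(K - 1L), params$survival),
                 row("gamma", seq_len(K - 1L) + 1L, params$seniority),
                 row("p", seq_len(K), params$detection))
    model <- "Pradel"
  } else if (inherits(params, "popan_params")) {
    if (length(params$detection) != K)
      stop("parameters and scheme disagree on the number of bins", call. = FALSE)
    est <- rbind(row("n_super", NA_integer_, params$n_super),
                 row("pent", seq_len(K), params$entry_probs),
                 row("phi", seq_len(K - 1L), params$survival),
                 row("p", seq_len(K), params$detection))
    model <- "POPAN"
  } else stop("params must be pradel_params or popan_params", call. = FALSE)
  structure(list(model = model, estimates = est, loglik = NA_real_,
                 convergence = list(code = 0L, starts = 0L,
                                    message = "prescribed parameters"),
                 theta = NULL, vcov = NULL, K = K, n_genera = NA_integer_,
                 scheme = scheme, options = list(), params = params),
            class = "cr_fit")
}
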