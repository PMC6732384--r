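#' Modelled richness curve of one bin's genus cohort
#'
#' For the cohort of genera extant in a focal bin `t_i`, the modelled
#' fraction of the cohort still (or already) extant at increasing distance
#' from `t_i`: 1 at `t_i`, `prod(phi_j, j = i .. i+k-1)` at posterior offset
#' `+k`, and `prod(gamma_m, m = i-k+1 .. i)` at antecedent offset `-k`
#' (gamma_m is the seniority of bin m relative to m-1). Fractions are
#' non-increasing away from the focal bin by construction. With
#' `method = "refit"` the chain uses survival/seniority re-estimated on the
#' focal cohort's own incidence submatrix (sensitivity mode) instead of the
#' globally fitted parameters.
#'
#' @param fit a converged Pradel `cr_fit`.
#' @param t_i focal bin index (1-based, oldest = 1).
#' @param method `"chain"` (default) or `"refit"`.
#' @param data the `incidence_matrix` the fit was computed on; required for
#'   `method = "refit"`.
#' @return A `cohort_curve` data frame: `bin`, `offset`, `fraction`, `side`
#'   (`"antecedent"`, `"focal"`, `"posterior"`).
#' @export
cohort_fraction_curve <- function(fit, t_i, method = c("chain", "refit"),
                                  data = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "cr_fit"))
  if (fit$model != "Pradel")
    stop("cohort curves need a Pradel fit", call. = FALSE)
  K <- fit$K
  if (t_i < 1L || t_i > K) stop("focal bin out of range", call. = FALSE)
  if (method == "refit") {
    if (is.null(data)) stop("method = 'refit' needs the incidence matrix",
                            call. = FALSE)
    cohort <- data$matrix[data$matrix[, t_i] == 1L, , drop = FALSE]
    sub <- incidence_matrix(cohort, data$bins)
    fit <- fit_pradel(sub, options = list(restarts = fit$options$restarts))
  }
  phi <- fit$params$survival     # phi[j]: transition j -> j+1
  gam <- fit$params$seniority    # gam[m-1]: seniority of bin m

  post_k <- seq_len(K - t_i)
  post <- if (length(post_k)) cumprod(phi[t_i + post_k - 1L]) else numeric(0)
  ante_k <- seq_len(t_i - 1L)
  # antecedent offset -k multiplies seniorities of bins t_i, t_i-1, ...:
  # gam[t_i - 1], gam[t_i - 2], ..., gam[t_i - k]
  ante <- if (length(ante_k)) cumprod(gam[(t_i - 1L):1L][ante_k]) else numeric(0)

  out <- data.frame(
    bin = c(rev(t_i - ante_k), t_i, t_i + post_k),
    offset = c(rev(-ante_k), 0L, post_k),
    fraction = c(rev(ante), 1, post),
    side = c(rep("antecedent", length(ante_k)), "focal",
             rep("posterior", length(post_k))),
    stringsAsFactors = FALSE
  )
  attr(out, "t_i") <- t_i
  class(out) <- c("cohort_curve", "data.frame")
  out
}

#' Survivorship spans of a cohort curve at fixed richness levels
#'
#' For each level q, finds the most distal posterior (antecedent) bin whose
#' modelled cohort fraction is still >= q (ties inclusive) and measures the
#' forward (backward) survivorship as the maximum elapsed time consistent
#' with bin-level resolution: from the midpoint of the focal bin to the
#' distal boundary of that threshold bin. If even the adjacent bin falls
#' below q the threshold bin is the focal bin itself and the span is half
#' its duration. If the level is still met at the edge of the analysis
#' window the span is flagged censored.
#'
#' @param curve a [cohort_fraction_curve()] result.
#' @param scheme the [time_bins] scheme.
#' @param levels richness levels in (0, 1); default `c(0.5, 0.7, 0.9)`.
#' @return Data frame: `level`, `l_bw`, `l_fw` (Myr), `censored_bw`,
#'   `censored_fw`.
#' @export
survivorship_levels <- function(curve, scheme,
                                levels = c(0.5, 0.7, 0.9)) {
  stopifnot(inherits(curve, "cohort_curve"), inherits(scheme, "time_bins"))
  if (any(levels <= 0 | levels >= 1))
    stop("levels must lie strictly inside (0, 1)", call. = FALSE)
  t_i <- attr(curve, "t_i")
  K <- nrow(scheme)
  mid <- scheme$midpoint[t_i]
  post <- curve[curve$side == "posterior", ]
  ante <- curve[curve$side == "antecedent", ]
  res <- lapply(levels, function(q) {
    kf <- post$offset[post$fraction >= q - 1e-12]
    kf <- if (length(kf)) max(kf) else 0L
    kb <- -ante$offset[ante$fraction >= q - 1e-12]
    kb <- if (length(kb)) max(kb) else 0L
    data.frame(
      level = q,
      l_bw = scheme$older[t_i - kb] - mid,
      l_fw = mid - scheme$younger[t_i + kf],
      censored_bw = (t_i - kb) == 1L,
      censored_fw = (t_i + kf) == K
    )
  })
  do.call(rbind, res)
}

#' Per-bin survivorship and longevity series
#'
#' Applies [cohort_fraction_curve()] and [survivorship_levels()] to every
#' bin: backward survivorship `l_bw` (genus age), forward survivorship
#' `l_fw` (life expectancy) and overall longevity `l_o = l_bw + l_fw`, in
#' Myr, at each richness level. Censoring at the window edges propagates to
#' `l_o`.
#'
#' @param fit a converged Pradel `cr_fit`.
#' @param scheme the [time_bins] scheme of the fit.
#' @param levels richness levels, default `c(0.5, 0.7, 0.9)`.
#' @return A `survivorship_series` data frame: `bin`, `name`, `level`,
#'   `l_bw`, `l_fw`, `l_o`, `censored_bw`, `censored_fw`, `censored`.
#' @export
longevity_series <- function(fit, scheme, levels = c(0.5, 0.7, 0.9)) {
  stopifnot(inherits(fit, "cr_fit"), inherits(scheme, "time_bins"))
  if (fit$K != nrow(scheme))
    stop("fit and scheme describe different bins", call. = FALSE)
  rows <- lapply(seq_len(nrow(scheme)), function(i) {
    lv <- survivorship_levels(cohort_fraction_curve(fit, i), scheme, levels)
    cbind(data.frame(bin = i, name = scheme$name[i],
                     stringsAsFactors = FALSE), lv)
  })
  out <- do.call(rbind, rows)
  out$l_o <- out$l_bw + out$l_fw
  out$censored <- out$censored_bw | out$censored_fw
  rownames(out) <- NULL
  class(out) <- c("survivorship_series", "data.frame")
  out
}

#' Export a survivorship series as long-format CSV
#'
#' @param x a `survivorship_series`.
#' @param path output path.
#' @export
write_survivorship <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
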