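test_that("cohort curves are chain products of survival and seniority", {
  s <- uniform_scheme(8, width = 2)
  fit <- fake_pradel_fit(rep(0.9, 7), rep(0.8, 7), rep(0.7, 8), s)
  cv <- cohort_fraction_curve(fit, 4)
  expect_equal(cv$fraction[cv$offset == 0], 1)
  post <- cv$fraction[cv$side == "posterior"]
  expect_equal(post, cumprod(rep(0.9, 4)))
  ante <- rev(cv$fraction[cv$side == "antecedent"])
  expect_equal(ante, cumprod(rep(0.8, 3)))
  # non-increasing away from the focal bin on both sides
  expect_true(all(diff(post) <= 0) && all(diff(ante) <= 0))
  expect_error(cohort_fraction_curve(fit, 9), "out of range")

  flat <- cohort_fraction_curve(fake_pradel_fit(rep(1, 7), rep(1, 7),
                                                rep(0.7, 8), s), 4)
  expect_true(all(flat$fraction == 1))
})

test_that("worked geometric example: levels picked with inclusive ties", {
  # uniform 2-Myr bins, phi = 0.9 per transition, focal bin in the interior
  K <- 12
  s <- uniform_scheme(K, width = 2)
  fit <- fake_pradel_fit(rep(0.9, K - 1), rep(0.9, K - 1), rep(0.7, K), s)
  cv <- cohort_fraction_curve(fit, 6)
  lv <- survivorship_levels(cv, s)
  # q = 0.7: most distal posterior bin with fraction >= 0.7 is +3 (0.729)
  expect_equal(lv$l_fw[lv$level == 0.7], 1 + 3 * 2)
  # q = 0.9: +1 qualifies exactly (0.9 >= 0.9, inclusive tie)
  expect_equal(lv$l_fw[lv$level == 0.9], 1 + 1 * 2)
  # q = 0.5: 0.9^6 = 0.53 >= 0.5 at +6 (window edge for bin 6) -> censored
  expect_equal(lv$l_fw[lv$level == 0.5], 1 + 6 * 2)
  expect_true(lv$censored_fw[lv$level == 0.5])
  expect_false(any(lv$censored_fw[lv$level > 0.5]))
  expect_error(survivorship_levels(cv, s, levels = 1.2), "inside")
})

test_that("immortal cohorts are censored at both window edges", {
  s <- uniform_scheme(8, width = 2)
  fit <- fake_pradel_fit(rep(1, 7), rep(1, 7), rep(0.7, 8), s)
  lv <- survivorship_levels(cohort_fraction_curve(fit, 4), s)
  expect_true(all(lv$censored_bw) && all(lv$censored_fw))
  expect_equal(lv$l_fw, rep(s$midpoint[4] - s$younger[8], 3))
  expect_equal(lv$l_bw, rep(s$older[1] - s$midpoint[4], 3))
})

test_that("sharp cohort decline bottoms out at half the focal bin", {
  s <- uniform_scheme(8, width = 2)
  fit <- fake_pradel_fit(rep(0.3, 7), rep(0.3, 7), rep(0.7, 8), s)
  lv <- survivorship_levels(cohort_fraction_curve(fit, 4), s)
  expect_equal(lv$l_fw, rep(1, 3))  # half of the 2-Myr focal bin
  expect_equal(lv$l_bw, rep(1, 3))
})

test_that("longevity series: l_o identity, level ordering, censor propagation", {
  cfg <- scenario_config("stable", seed = 42)
  sim <- simulate_occurrences(cfg)
  inc <- bin_occurrences(sim$occurrences, cfg$scheme)
  fit <- fit_pradel(inc, options = fast_fit)
  sv <- longevity_series(fit, cfg$scheme)
  expect_equal(sv$l_o, sv$l_bw + sv$l_fw)
  expect_true(all(sv$censored == (sv$censored_bw | sv$censored_fw)))
  for (b in unique(sv$bin)) {
    x <- sv[sv$bin == b, ]
    x <- x[order(x$level), ]  # 0.5, 0.7, 0.9
    nc_f <- !x$censored_fw
    expect_true(all(diff(x$l_fw[nc_f]) <= 1e-9))
    nc_b <- !x$censored_bw
    expect_true(all(diff(x$l_bw[nc_b]) <= 1e-9))
    expect_true(all(x$l_fw >= 0 & x$l_bw >= 0))
  }
})

test_that("time-reversing the pipeline swaps forward and backward survivorship", {
  cfg <- scenario_config("volatile", n_super = 1500, seed = 5)
  sim <- simulate_occurrences(cfg)
  inc <- bin_occurrences(sim$occurrences, cfg$scheme)
  fit <- fit_pradel(inc, options = fast_fit)
  sv <- longevity_series(fit, cfg$scheme)
  rinc <- reverse_incidence(inc)
  rfit <- fit_pradel(rinc, options = fast_fit)
  rsv <- longevity_series(rfit, rinc$bins)
  K <- nrow(cfg$scheme)
  for (lev in c(0.5, 0.7, 0.9)) {
    a <- sv[sv$level == lev, ]
    b <- rsv[rsv$level == lev, ]
    b <- b[match(K + 1 - a$bin, b$bin), ]
    expect_equal(a$l_fw, b$l_bw, tolerance = 1e-6)
    expect_equal(a$l_bw, b$l_fw, tolerance = 1e-6)
  }
})

test_that("per-cohort refit mode reproduces the chain-product curve shape", {
  cfg <- scenario_config("stable", n_super = 800, seed = 19)
  sim <- simulate_occurrences(cfg)
  inc <- bin_occurrences(sim$occurrences, cfg$scheme)
  fit <- fit_pradel(inc, options = fast_fit)
  cv <- cohort_fraction_curve(fit, 5)
  cvr <- suppressWarnings(cohort_fraction_curve(fit, 5, method = "refit",
                                                data = inc))
  expect_equal(cvr$offset, cv$offset)
  post <- cv$fraction[cv$side == "posterior"]
  postr <- cvr$fraction[cvr$side == "posterior"]
  expect_lt(mean(abs(post - postr)), 0.1)
  expect_error(cohort_fraction_curve(fit, 5, method = "refit"), "needs")
})

test_that("modelled cohort decline tracks the simulator's true cohort survival", {
  cfg <- scenario_config("stable", seed = 1)
  nrep <- 20L
  err <- numeric(0)
  for (r in seq_len(nrep)) {
    cfg_r <- sim_config(cfg$scheme, cfg$n_super, cfg$entry_probs,
                        cfg$survival, cfg$detection, seed = 300L + r)
    sim <- simulate_occurrences(cfg_r)
    inc <- bin_occurrences(sim$occurrences, cfg$scheme)
    fit <- fit_pradel(inc, options = list(restarts = 1L))
    t_i <- 5L
    cv <- cohort_fraction_curve(fit, t_i)
    post <- cv$fraction[cv$side == "posterior"]
    g <- sim$truth$genera
    cohort <- g$entry_bin <= t_i & g$exit_bin >= t_i
    truth_frac <- vapply(seq_len(nrow(cfg$scheme) - t_i), function(k)
      sum(cohort & g$exit_bin >= t_i + k) / sum(cohort), 0)
    err <- c(err, abs(post - truth_frac))
  }
  expect_lt(mean(err), 0.05)
})
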