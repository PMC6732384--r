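test_that("degenerate configurations behave deterministically", {
  s <- uniform_scheme(4)
  cfg <- sim_config(s, n_super = 25, entry_probs = c(1, 0, 0, 0),
                    survival = rep(1, 3), detection = rep(1, 4), seed = 7)
  sim <- simulate_occurrences(cfg)
  inc <- bin_occurrences(sim$occurrences, s)
  expect_equal(unname(observed_richness(inc)), rep(25L, 4))
  expect_equal(sim$truth$bins$extant, rep(25L, 4))

  cfg0 <- sim_config(s, n_super = 25, entry_probs = c(1, 0, 0, 0),
                     survival = rep(1, 3), detection = rep(0, 4), seed = 7)
  sim0 <- simulate_occurrences(cfg0)
  expect_equal(nrow(sim0$occurrences), 0L)
  expect_equal(nrow(sim0$truth$genera), 25L)
  expect_false(any(sim0$truth$genera$detected))
})

test_that("config validation rejects impossible settings", {
  s <- uniform_scheme(3)
  expect_error(sim_config(s, 0, c(1, 0, 0), c(1, 1), rep(1, 3)), "positive")
  expect_error(sim_config(s, 10, c(0.5, 0.2, 0.2), c(1, 1), rep(1, 3)),
               "sum to 1")
  expect_error(sim_config(s, 10, c(1, 0, 0), c(1.2, 1), rep(1, 3)), "0, 1")
  expect_error(sim_config(uniform_scheme(2)[1, ], 10, 1, numeric(0), 1),
               "2 bins")
})

test_that("fixed seed gives bit-identical output", {
  cfg <- scenario_config("stable", n_super = 300, seed = 11)
  a <- simulate_occurrences(cfg)
  b <- simulate_occurrences(cfg)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(a$truth$genera, b$truth$genera)
})

test_that("observed richness tracks the expectation recursion N_i * p_i", {
  s <- uniform_scheme(10)
  cfg <- sim_config(s, n_super = 2000, entry_probs = rep(0.1, 10),
                    survival = rep(0.8, 9), detection = rep(0.6, 10),
                    seed = 99)
  sim <- simulate_occurrences(cfg)
  inc <- bin_occurrences(sim$occurrences, s)
  obs <- observed_richness(inc)
  expN <- expected_richness(cfg)
  mu <- expN * 0.6
  sd3 <- 3 * sqrt(expN * 0.6 * 0.4)
  expect_true(all(abs(obs - mu) <= sd3))
})

test_that("mean observed richness converges to N_i * p_i over replicates", {
  cfg0 <- scenario_config("stable", n_super = 10000)
  expN <- expected_richness(cfg0)
  K <- nrow(cfg0$scheme)
  nrep <- 200L
  acc <- matrix(0, nrep, K)
  for (r in seq_len(nrep)) {
    cfg <- sim_config(cfg0$scheme, cfg0$n_super, cfg0$entry_probs,
                      cfg0$survival, cfg0$detection, seed = 1000L + r)
    sim <- simulate_occurrences(cfg)
    det <- sim$occurrences
    acc[r, ] <- vapply(seq_len(K), function(i) {
      b <- cfg$scheme
      length(unique(det$genus[det$older <= b$older[i] &
                                det$younger >= b$younger[i]]))
    }, 0L)
  }
  rel <- abs(colMeans(acc) - expN * cfg0$detection) / (expN * cfg0$detection)
  expect_true(all(rel < 0.01))
})

test_that("true seniority follows the expected-richness recursion", {
  s <- uniform_scheme(4)
  # no entries after the first bin: every extant genus is a survivor
  cfg1 <- sim_config(s, 100, c(1, 0, 0, 0), rep(0.7, 3), rep(0.5, 4))
  expect_equal(true_seniority(cfg1), c(NA, 1, 1, 1))
  # zero survival: every extant genus is new
  cfg2 <- sim_config(s, 100, rep(0.25, 4), rep(0, 3), rep(0.5, 4))
  expect_equal(true_seniority(cfg2), c(NA, 0, 0, 0))
  # N_i = 100, phi = 0.9, 10 expected entries -> gamma = 90 / 100 = 0.9
  cfg3 <- sim_config(s, 1000, c(0.1, 0.01, 0.01, 0.88), rep(0.9, 3),
                     rep(0.5, 4))
  expect_equal(true_seniority(cfg3)[2], 90 / 100)
  # per-Myr truth: extinction rate is -log(phi) / midpoint spacing
  expect_equal(true_rates(cfg3)$extinction[1], -log(0.9) / 2)
  # zero expected richness in a bin is an error
  cfg4 <- sim_config(s, 100, c(1, 0, 0, 0), c(0, 0, 1), rep(0.5, 4))
  expect_error(true_seniority(cfg4), "undefined")
})

test_that("scenario presets exist and configs round-trip through YAML", {
  st <- scenario_config("stable")
  vo <- scenario_config("volatile")
  pu <- scenario_config("pulse")
  # the volatile regime has markedly higher true per-Myr rates
  m_ext <- function(cfg) mean(true_rates(cfg)$extinction, na.rm = TRUE)
  expect_gt(m_ext(vo), 3 * m_ext(st))
  # the pulse preset contains one transition far below background survival
  expect_lt(min(pu$survival), 0.5)
  expect_gt(sort(pu$survival)[2], 0.9)

  f <- tempfile(fileext = ".yml")
  write_sim_config(st, f)
  back <- read_sim_config(f)
  expect_equal(back$entry_probs, st$entry_probs, tolerance = 1e-12)
  expect_equal(back$survival, st$survival)
  expect_equal(back$scheme$older, st$scheme$older)
})
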