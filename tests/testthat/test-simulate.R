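small_cfg <- function(seed = 5, n = 20, t_points = 80, ...) {
  simulation_config(seed = seed, n_subjects = n, parc = compact_parcellation(),
                    t_points = t_points, ...)
}

test_that("block correlation matrices have the stated structure", {
  parc <- compact_parcellation()
  m <- build_block_correlation(parc, 0.5, 0.1)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, nrow(parc)))
  same <- outer(parc$network, parc$network, "==")
  expect_true(all(m[same & upper.tri(m)] == 0.5))
  expect_true(all(m[!same] == 0.1))

  # r_between = 0 gives a block-diagonal matrix
  m0 <- build_block_correlation(parc, 0.4, 0)
  expect_true(all(m0[!same] == 0))

  # default configuration is positive definite
  base <- build_block_correlation(shirer_like_parcellation(), 0.5, 0.1)
  ev <- eigen(base, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("configuration validation rejects impossible regimes", {
  expect_error(simulation_config(r_within = 0.2, r_between = 0.3),
               class = "sysseg_validation_error")
  expect_error(simulation_config(r_within = 1.1),
               class = "sysseg_validation_error")
  expect_error(
    simulation_config(behavioral = list(sys = c(NOPE = 1))),
    class = "sysseg_validation_error")
})

test_that("simulated time series are deterministic and match the target", {
  corr <- build_block_correlation(compact_parcellation(), 0.5, 0.1)
  a <- simulate_timeseries(corr, 50, seed = 99)
  b <- simulate_timeseries(corr, 50, seed = 99)
  expect_identical(a, b)

  # non-positive-definite input is rejected
  bad <- matrix(0.99, 4, 4); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(simulate_timeseries(bad, 10),
               class = "sysseg_validation_error")

  # Monte-Carlo consistency at large T
  small <- build_block_correlation(
    parcellation(data.frame(roi = paste0("r", 1:4),
                            network = c("a", "a", "b", "b"))), 0.5, 0.1)
  ts <- simulate_timeseries(small, 10000, seed = 4)
  expect_lt(max(abs(cor(ts) - small)), 0.02)

  # independence limit: off-diagonal sample correlations are O(1/sqrt(T))
  id <- diag(6); dimnames(id) <- list(paste0("r", 1:6), paste0("r", 1:6))
  ts_id <- simulate_timeseries(id, 2000, seed = 5)
  cc <- cor(ts_id)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(2000))
})

test_that("population truth follows the closed atanh form", {
  s <- expected_network_summary(list(r_within = c(NET = 0.5),
                                     r_between = 0.1))
  expect_equal(s$w, atanh(0.5), tolerance = 1e-12)
  expect_equal(s$b, atanh(0.1), tolerance = 1e-12)
  expect_equal(s$sys, (atanh(0.5) - atanh(0.1)) / atanh(0.5),
               tolerance = 1e-12)
  expect_equal(s$sys, 0.8173417, tolerance = 1e-6)

  expect_equal(expected_network_summary(list(r_within = c(N = 0.4),
                                             r_between = 0))$sys, 1)
  expect_equal(expected_network_summary(list(r_within = c(N = 0.4),
                                             r_between = 0.4))$sys, 0)
  expect_error(expected_network_summary(list(r_within = c(N = 0),
                                             r_between = 0)),
               class = "sysseg_undefined_error")
})

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(small_cfg(n = 5))
  b <- simulate_cohort(small_cfg(n = 5))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$items, b$items)
  expect_identical(a$truth, b$truth)
})

test_that("cohort tables are complete and within instrument score ranges", {
  sim <- simulate_cohort(small_cfg(n = 25))
  co <- sim$cohort
  expect_equal(nrow(co), 25)
  expect_true(all(is.finite(as.matrix(co[sapply(co, is.numeric)]))))
  qs <- default_questionnaires()
  ranges <- list(ptq = c(0, 60), pswq = c(0, 32), rrs = c(0, 66),
                 dass = c(0, 63), cognitive_complaints = c(0, 48),
                 emotional_stability = c(10, 50))
  for (nm in names(ranges)) {
    expect_true(all(co[[nm]] >= ranges[[nm]][1] & co[[nm]] <= ranges[[nm]][2]),
                info = nm)
  }
  expect_true(all(co$age >= 43 & co$age <= 68))
  expect_true(all(co$sex %in% 0:1))
  # brooding is the configured RRS item subset
  brood <- rowSums(sim$items$rrs[, qs$rrs$subscales$brooding])
  expect_equal(co$brooding, brood)
})

test_that("generator item matrices rescore to the cohort totals", {
  sim <- simulate_cohort(small_cfg(seed = 6, n = 15))
  qs <- sim$config$questionnaires
  expect_equal(score_questionnaire(sim$items$ptq, qs$ptq)$total,
               sim$cohort$ptq)
  expect_equal(score_questionnaire(sim$items$promis, qs$promis)$total,
               sim$cohort$cognitive_complaints)
  expect_equal(score_questionnaire(sim$items$ipip_es, qs$ipip_es)$total,
               sim$cohort$emotional_stability)
})

test_that("questionnaire internal consistency lands in the reported range", {
  sim <- simulate_cohort(small_cfg(seed = 12, n = 100))
  # the three RNT instruments report alphas of 0.92-0.97 in adult cohorts
  for (nm in c("ptq", "pswq", "rrs")) {
    a <- cronbach_alpha(sim$items[[nm]])
    expect_gt(a, 0.8)
    expect_lt(a, 1)
  }
})

test_that("estimated segregation recovers the population truth", {
  cfg <- small_cfg(seed = 21, n = 15, t_points = 300)
  sim <- simulate_cohort(cfg)
  truth <- expected_network_summary(cfg)
  for (nm in c("lecn", "recn", "asn", "ddmn", "vdmn")) {
    est <- mean(sim$cohort[[paste0("sys_", nm)]])
    tru <- truth$sys[tolower(truth$network) == nm]
    expect_lt(abs(est - tru), 0.05)
  }
})

test_that("zeroing negative correlations biases segregation below one", {
  # with r_between = 0 the estimated B is biased upward by thresholding,
  # so estimated SyS sits just below its population value of 1
  cfg <- small_cfg(seed = 31, n = 8, t_points = 740, r_between = 0,
                   sd_r_between = 0)
  sim <- simulate_cohort(cfg)
  for (nm in c("sys_lecn", "sys_asn", "sys_ddmn")) {
    est <- mean(sim$cohort[[nm]])
    expect_gt(est, 0.85)
    expect_lt(est, 1)
  }
})

test_that("a null behavioural model leaves RNT unrelated to segregation", {
  cfg <- simulation_config(
    seed = 41, n_subjects = 341, parc = compact_parcellation(),
    t_points = 80,
    behavioral = list(dass = 0, emotional_stability = 0,
                      cognitive_complaints = 0, age = 0, sex = 0,
                      sys = c(LECN = 0, ASN = 0, dDMN = 0, vDMN = 0,
                              RECN = 0)))
  sim <- simulate_cohort(cfg)
  for (nm in grep("^sys_", names(sim$cohort), value = TRUE)) {
    expect_lt(abs(cor(sim$cohort$rnt, sim$cohort[[nm]])), 0.15)
  }
})

test_that("a planted positive LECN effect yields a positive estimate", {
  # full-model OLS coefficient sign across replicates at default effects
  signs <- vapply(1:100, function(rep) {
    cfg <- simulation_config(seed = 5000 + rep, n_subjects = 120,
                             parc = compact_parcellation(), t_points = 100)
    sim <- simulate_cohort(cfg)
    f <- ols_fit(sim$cohort, "rnt",
                 c("age", "sex", "dass", "emotional_stability",
                   "cognitive_complaints", "sys_asn", "sys_ddmn",
                   "sys_vdmn", "sys_lecn", "sys_recn"))
    td <- tidy(f)
    td$estimate[td$term == "sys_lecn"] > 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})
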