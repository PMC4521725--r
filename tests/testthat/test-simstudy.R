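# hand-built per-replicate records for scoring checks
fake_records <- function(medians, lowers, uppers, scenario = "s1",
                         model = "cr", converged = TRUE) {
  n <- length(medians$phi)
  data.frame(scenario = scenario, model = model, rep = seq_len(n),
             n_detected = 50, converged = converged, max_rhat = 1.0,
             phi_avg_median = medians$phi, phi_avg_lower = lowers$phi,
             phi_avg_upper = uppers$phi,
             R_avg_median = medians$R, R_avg_lower = lowers$R,
             R_avg_upper = uppers$R,
             lambda_avg_median = medians$lambda,
             lambda_avg_lower = lowers$lambda,
             lambda_avg_upper = uppers$lambda)
}

truth1 <- list(s1 = c(phi_avg = 0.8, R_avg = 0.1, lambda_avg = 0.9))

test_that("scoring reproduces hand-computed bias, coverage and power", {
  # an oracle estimator: medians equal truth, degenerate intervals
  rec <- fake_records(
    medians = list(phi = rep(0.8, 4), R = rep(0.1, 4), lambda = rep(0.9, 4)),
    lowers = list(phi = rep(0.8, 4), R = rep(0.1, 4), lambda = rep(0.9, 4)),
    uppers = list(phi = rep(0.8, 4), R = rep(0.1, 4), lambda = rep(0.9, 4)))
  sc <- score_results(rec, truth1)
  expect_equal(sc$mean_bias, rep(0, 3))
  expect_equal(sc$cic, rep(100, 3))
  expect_equal(sc$power[sc$parameter == "lambda"], 100)  # lambda = 0.9 < 1

  # constant offset: bias 0.05; intervals (0,1) always cover
  rec2 <- fake_records(
    medians = list(phi = rep(0.85, 4), R = rep(0.15, 4), lambda = rep(1, 4)),
    lowers = list(phi = rep(0, 4), R = rep(0, 4), lambda = rep(0, 4)),
    uppers = list(phi = rep(1, 4), R = rep(1, 4), lambda = rep(1, 4)))
  sc2 <- score_results(rec2, truth1)
  expect_equal(sc2$mean_bias[sc2$parameter == "phi"], 0.05)
  expect_equal(sc2$cic, rep(100, 3))

  # power counts upper limits strictly below one
  rec3 <- fake_records(
    medians = list(phi = rep(0.8, 2), R = rep(0.1, 2), lambda = rep(0.9, 2)),
    lowers = list(phi = rep(0.7, 2), R = rep(0, 2), lambda = rep(0.8, 2)),
    uppers = list(phi = rep(0.9, 2), R = rep(0.2, 2), lambda = c(0.99, 1.01)))
  sc3 <- score_results(rec3, truth1)
  expect_equal(sc3$power[sc3$parameter == "lambda"], 50)

  # mixed hand-computed set: known medians and coverage pattern
  rec4 <- fake_records(
    medians = list(phi = c(0.75, 0.85, 0.9), R = c(0.1, 0.2, 0.0),
                   lambda = c(0.85, 1.05, 0.9)),
    lowers = list(phi = c(0.7, 0.84, 0.6), R = c(0.05, 0.15, 0),
                  lambda = c(0.8, 1.0, 0.85)),
    uppers = list(phi = c(0.9, 0.95, 0.7), R = c(0.15, 0.3, 0.05),
                  lambda = c(0.9, 1.1, 0.95)))
  sc4 <- score_results(rec4, truth1)
  expect_equal(sc4$mean_bias[sc4$parameter == "phi"],
               mean(c(0.75, 0.85, 0.9)) - 0.8)
  expect_equal(sc4$cic[sc4$parameter == "phi"], 100 * 1 / 3)
  expect_equal(sc4$cic[sc4$parameter == "R"], 100 * 1 / 3)
  expect_equal(sc4$power[sc4$parameter == "lambda"], 100 * 2 / 3)

  # unconverged replicates are excluded and counted
  rec5 <- rbind(rec, transform(rec, converged = FALSE, phi_avg_median = 0))
  sc5 <- score_results(rec5, truth1)
  expect_equal(sc5$mean_bias[sc5$parameter == "phi"], 0)
  expect_equal(unique(sc5$n_used), 4)
  expect_equal(unique(sc5$n_excluded), 4)
})

test_that("a miniature study runs end to end and is seed-reproducible", {
  sc <- list(mini = scenario_config(density = 0.3, g0 = 0.4, nx = 5, ny = 5,
                                    occasions = 3))
  cfg <- mcmc_config(n_chains = 2, n_iter = 500, n_burnin = 150,
                     ft_thin = 0)
  out1 <- run_simulation_study(list(mini = sc$mini), n_reps = 2,
                               models = "cr", config = cfg, seed = 30)
  out2 <- run_simulation_study(list(mini = sc$mini), n_reps = 2,
                               models = "cr", config = cfg, seed = 30)
  expect_identical(out1$scores, out2$scores)
  expect_equal(nrow(out1$records), 2)
  expect_true(all(is.finite(out1$scores$mean_bias)))
  expect_true(all(out1$scores$cic >= 0 & out1$scores$cic <= 100))
  # re-scoring saved records reproduces the table without refitting
  truth <- list(mini = c(phi_avg = 0.8, R_avg = 0.1, lambda_avg = 0.9))
  expect_identical(score_results(out1$records, truth), out1$scores)
})
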