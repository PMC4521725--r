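test_that("effort scaling follows the proportional-hazard transform", {
  expect_equal(effort_scaled_p(0.3, 0, 42), 0)
  expect_equal(effort_scaled_p(0.3, 42, 42), 0.3)
  expect_equal(effort_scaled_p(0.5, 84, 42), 0.75)
  expect_error(effort_scaled_p(1.2, 10, 42), "p_base")
  expect_error(effort_scaled_p(0.3, -1, 42), "n_days")
  # monotone in effort and in the baseline; saturates towards 1
  set.seed(3)
  for (r in 1:20) {
    p <- runif(1); d <- sort(runif(2, 0, 300)); ref <- runif(1, 1, 200)
    expect_lte(effort_scaled_p(p, d[1], ref), effort_scaled_p(p, d[2], ref))
    ps <- sort(runif(2))
    expect_lte(effort_scaled_p(ps[1], d[1], ref),
               effort_scaled_p(ps[2], d[1], ref))
  }
  expect_gt(effort_scaled_p(0.3, 1e5, 42), 1 - 1e-9)
})

test_that("cumulative detection combines trap types independently", {
  expect_equal(cumulative_detection_p(c(0, 0, 0)), 0)
  expect_equal(cumulative_detection_p(c(0.2, 0.5, 0)), 0.6)
  expect_equal(cumulative_detection_p(c(0.3, 1, 0.7)), 1)
  expect_error(cumulative_detection_p(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("cell detection probability evaluates the logit model", {
  expect_equal(detection_p(0, 0, 0, 1, 1), 0.5)
  expect_equal(detection_p(-1, -0.1, 5, 42, 42), plogis(-1.5))
  # strictly decreasing in DEDGE for a negative slope
  p <- detection_p(-1, -0.1, seq(0, 18, by = 2), 42, 42)
  expect_true(all(diff(p) < 0))
})

test_that("DEDGE imputation draws a truncated gamma", {
  x <- impute_dedge(4, 1, 2000, upper = 18.5, seed = 9)
  expect_length(x, 2000)
  expect_true(all(x >= 0 & x <= 18.5))
  expect_identical(x, impute_dedge(4, 1, 2000, upper = 18.5, seed = 9))
  # truncated mean against a numeric-integration oracle
  tm <- integrate(function(v) v * dgamma(v, 4, 1), 0, 18.5)$value /
    pgamma(18.5, 4, 1)
  expect_lt(abs(mean(x) - tm), 4 * sd(x) / sqrt(length(x)))
  # severe truncation still yields draws inside the bound
  y <- impute_dedge(25, 0.9, 500, upper = 5, seed = 10)
  expect_true(all(y <= 5))
})

test_that("the CR likelihood matches scalar cases", {
  reg <- unit_registry(K = 1, years = 1)
  det <- data.frame(individual_id = "a", sex = "F", year = 1, occasion = 1,
                    trap_id = "t1")
  ds <- capture_data(det, reg, boundary = "buffer:2")
  params <- list(beta = array(qlogis(0.25), c(1, 1, 1)), beta_dedge = 0,
                 dedge = 0, sex_group = 1L)
  expect_equal(cr_log_likelihood(params, matrix(1L, 1, 1), ds, reg),
               log(0.25))
  # z = 0 everywhere with an all-zero augmented history contributes nothing
  z2 <- rbind(1L, 0L)
  params2 <- list(beta = array(qlogis(0.25), c(1, 1, 1)), beta_dedge = 0,
                  dedge = c(0, 0), sex_group = c(1L, 1L))
  expect_equal(cr_log_likelihood(params2, z2, ds, reg), log(0.25))
  expect_error(
    cr_log_likelihood(params, matrix(0L, 1, 1), ds, reg), "impossible")
})

test_that("the CR likelihood equals the brute-force cell product", {
  for (seed in 1:5) {
    fx <- random_tiny_fixture(seed)
    n_obs <- nrow(fx$dataset$individuals)
    n <- n_obs + 2                      # two augmented individuals
    set.seed(seed + 100)
    z <- matrix(0L, n, 2)
    z[seq_len(n_obs), ] <- (apply(fx$dataset$y_nonspatial, c(1, 4), max) > 0) * 1L
    z[z == 0] <- rbinom(sum(z == 0), 1, 0.5)
    params <- list(
      beta = array(rnorm(4 * 3 * 2, -1, 0.7), c(4, 3, 2)),
      beta_dedge = -0.08,
      dedge = runif(n, 0, 6),
      sex_group = c(ifelse(fx$dataset$individuals$sex == "M", 2L, 1L),
                    sample(1:2, 2, TRUE)))
    expect_equal(cr_log_likelihood(params, z, fx$dataset, fx$registry),
                 cr_ll_brute(params, z, fx$dataset, fx$registry),
                 tolerance = 1e-10)
  }
})

test_that("the likelihood separates across trap types", {
  fx <- random_tiny_fixture(8)
  n <- nrow(fx$dataset$individuals)
  z <- matrix(1L, n, 2)
  params <- list(beta = array(-0.5, c(4, 3, 1)), beta_dedge = 0,
                 dedge = rep(0, n), sex_group = rep(1L, n))
  total <- cr_log_likelihood(params, z, fx$dataset, fx$registry)
  # zero out the effort of all but one type at a time and re-sum
  parts <- vapply(fx$dataset$trap_types, function(m) {
    reg <- fx$registry
    off <- reg$traps$trap_type != m
    reg$effort[off, , ] <- 0
    ds <- fx$dataset
    ds$y_nonspatial[, , fx$dataset$trap_types != m, ] <- 0L
    cr_log_likelihood(params, z, ds, reg)
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-10)
})
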