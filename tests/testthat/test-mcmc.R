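test_that("Gelman-Rubin flags separated chains and passes identical ones", {
  set.seed(4)
  x <- matrix(rnorm(1000), ncol = 1)
  expect_lt(gelman_rubin(list(x, x, x))[1], 1.0 + 1e-8)
  y <- matrix(rnorm(1000, mean = 5), ncol = 1)
  expect_gt(gelman_rubin(list(x, y))[1], 3)
  const <- matrix(rep(2.5, 500), ncol = 1)
  expect_equal(unname(gelman_rubin(list(const, const))[1]), 1.0)
  expect_error(gelman_rubin(list(x)), "at least 2")
  expect_error(gelman_rubin(list(x, y[1:10, , drop = FALSE])), "equal length")
})

test_that("HPD intervals are the shortest covering window", {
  expect_equal(hpd_interval(rep(3.2, 50)), c(3.2, 3.2))
  set.seed(6)
  u <- runif(1e5)
  h <- hpd_interval(u, 0.95)
  expect_lt(abs(diff(h) - 0.95), 0.01)
  # brute-force oracle on small samples
  for (r in 1:10) {
    x <- sort(rgamma(40, 2, 1))
    m <- ceiling(0.95 * 40)
    widths <- vapply(seq_len(40 - m + 1),
                     function(i) x[i + m - 1] - x[i], numeric(1))
    i <- which.min(widths)
    expect_equal(hpd_interval(x, 0.95), c(x[i], x[i + m - 1]))
  }
  expect_error(hpd_interval(numeric(0)), "no samples")
})

test_that("alive-state updates respect data constraints and dynamics", {
  # detected years are pinned alive
  ll1 <- matrix(-1, 1, 3)
  det <- matrix(c(0L, 1L, 0L), 1)
  set.seed(10)
  for (r in 1:20) {
    upd <- update_alive_states(ll1, det, phi = c(0.5, 0.5),
                               gamma = c(0.5, 0.5, 0.5))
    expect_equal(upd$alive[1, 2], 1L)
  }
  # deterministic survival keeps detected animals alive in later years
  set.seed(11)
  det2 <- matrix(c(1L, 0L, 0L), 1)
  for (r in 1:20) {
    upd <- update_alive_states(matrix(0, 1, 3), det2, phi = c(1, 1),
                               gamma = c(0.5, 0.5, 0.5))
    expect_equal(upd$alive[1, ], c(1L, 1L, 1L))
  }
  # no re-entry: alive -> dead -> alive never occurs
  set.seed(12)
  for (r in 1:200) {
    upd <- update_alive_states(matrix(-0.5, 1, 3), matrix(0L, 1, 3),
                               phi = c(0.3, 0.3), gamma = c(0.6, 0.6, 0.6))
    s <- upd$state[1, ]
    expect_false(any(s[-1] == 1 & s[-3] == 2))
  }
})

test_that("single-sweep state updates match the conditional enumeration", {
  # one undetected individual, two years, fixed parameters: the exact
  # conditional of (z1, z2) is enumerable
  phi <- 0.7; gam <- c(0.4, 0.3); p_alive_year_ll <- log(0.6)
  prior <- c(`00` = (1 - gam[1]) * (1 - gam[2]),
             `01` = (1 - gam[1]) * gam[2],
             `10` = gam[1] * (1 - phi),
             `11` = gam[1] * phi)
  lik <- c(1, 0.6, 0.6, 0.36)
  expected <- prior * lik / sum(prior * lik)
  set.seed(13)
  draws <- replicate(12000, {
    upd <- update_alive_states(matrix(p_alive_year_ll, 1, 2),
                               matrix(0L, 1, 2), phi = phi, gamma = gam)
    paste0(upd$alive[1, 1], upd$alive[1, 2])
  })
  freq <- table(factor(draws, levels = names(expected))) / length(draws)
  expect_lt(max(abs(as.numeric(freq) - expected)), 0.02)
})

test_that("the full sampler reproduces the enumerable toy posterior", {
  # one augmented, never-detected individual over two years; the exact path
  # posterior marginalises phi/gamma analytically and the detection
  # baseline by quadrature
  K <- 5
  reg <- unit_registry(K = K, years = 2)
  cfg <- mcmc_config(n_chains = 3, n_iter = 6000, n_burnin = 1000,
                     augment = 1, seed = 14, sex_model = "none",
                     beta_structure = "constant", ft_thin = 0, z_thin = 1)
  fit <- run_mcmc(NULL, reg, model = "cr", config = cfg)
  expected <- toy_path_posterior(K)
  freq <- toy_path_frequencies(fit)
  expect_lt(max(abs(freq - expected)), 0.02)
})

test_that("chains are reproducible from the seed", {
  sim <- simulate_scenario(scenario_config(density = 0.3, g0 = 0.3, nx = 5,
                                           ny = 5), seed = 15)
  cfg <- mcmc_config(n_chains = 2, n_iter = 400, n_burnin = 100,
                     augment = 15, seed = 16, sex_model = "none",
                     beta_structure = "constant", ft_thin = 5)
  f1 <- run_mcmc(sim$dataset, sim$traps, "cr", cfg)
  f2 <- run_mcmc(sim$dataset, sim$traps, "cr", cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(sim$dataset, sim$traps, "scr", cfg)
  f4 <- run_mcmc(sim$dataset, sim$traps, "scr", cfg)
  expect_identical(f3$draws, f4$draws)
})

test_that("with no data the posteriors reproduce the uniform priors", {
  reg <- unit_registry(K = 3, years = 3)
  cfg <- mcmc_config(n_chains = 2, n_iter = 6000, n_burnin = 500,
                     augment = 25, seed = 17, sex_model = "none",
                     beta_structure = "constant", ft_thin = 0)
  fit <- run_mcmc(NULL, reg, model = "cr", config = cfg)
  d <- posterior_matrix(fit)
  for (par in c("phi[1]", "phi[2]", "gamma[2]")) {
    x <- d[seq(1, nrow(d), by = 10), par]
    ks <- suppressWarnings(ks.test(x, "punif"))
    expect_gt(ks$p.value, 1e-4)
    expect_lt(abs(mean(x) - 0.5), 0.05)
  }
})
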