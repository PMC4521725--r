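test_that("identical seeds reproduce identical datasets", {
  cfg <- scenario_config(density = 0.5, g0 = 0.2)
  a <- simulate_scenario(cfg, seed = 99)
  b <- simulate_scenario(cfg, seed = 99)
  expect_identical(a$dataset$detections, b$dataset$detections)
  expect_identical(a$truth$centres, b$truth$centres)
  c <- simulate_scenario(cfg, seed = 100)
  expect_false(identical(a$dataset$detections, c$dataset$detections))
})

test_that("population projection obeys the stated dynamics", {
  # deterministic survival, no recruitment: N constant
  cfg <- scenario_config(phi = 1, R = 0)
  tr <- simulate_open_population(cfg, seed = 1)
  expect_true(all(tr$N == tr$N[1]))
  expect_equal(tr$N[1], round(1.0 * 196))  # fixed initial size, 14x14 km

  # the alive matrix is a clean A -> L -> D trajectory per individual
  cfg2 <- scenario_config(phi = 0.8, R = 0.1)
  tr2 <- simulate_open_population(cfg2, seed = 2)
  for (i in sample(nrow(tr2$alive), 25)) {
    a <- tr2$alive[i, ]
    runs <- rle(a)$values
    expect_lte(length(runs[runs == 1]), 1)   # one contiguous alive streak
    expect_equal(which(a == 1)[1], tr2$entry_year[i])
  }
  expect_gte(nrow(tr2$alive), max(tr2$N))
  first_alive <- apply(tr2$alive, 1, function(a) which(a == 1)[1])
  expect_equal(unname(first_alive), tr2$entry_year)

  # E[N2] = N1 * (phi + R) = 196 * 0.9; check the replicate mean within 3 SE
  n2 <- vapply(1:400, function(s) {
    simulate_open_population(cfg2, seed = 1000 + s)$N[2]
  }, numeric(1))
  se <- sd(n2) / sqrt(length(n2))
  expect_lt(abs(mean(n2) - 176.4), 3 * se + 0.01)
})

test_that("capture simulation honours the half-normal detection model", {
  cfg <- scenario_config(g0 = 0)
  tr <- simulate_open_population(cfg, seed = 3)
  expect_null(simulate_captures(tr, scenario_traps(cfg), cfg, seed = 3))

  # single animal sitting on the only trap: P(ever detected) = 1 - (1-g0)^K
  cfg1 <- scenario_config(g0 = 0.5, occasions = 3, years = 1)
  reg1 <- unit_registry(K = 3, years = 1)
  truth1 <- structure(list(
    centres = matrix(c(0, 0), 1), alive = matrix(1L, 1, 1),
    entry_year = 1L, N = 1L, area = 196,
    boundary = rbind(c(-7, -7), c(7, -7), c(7, 7), c(-7, 7))),
    class = "population_truth")
  set.seed(42)
  hits <- vapply(1:800, function(s) {
    !is.null(simulate_captures(truth1, reg1, cfg1))
  }, logical(1))
  p_exp <- 1 - 0.5^3
  se <- sqrt(p_exp * (1 - p_exp) / 800)
  expect_lt(abs(mean(hits) - p_exp), 4 * se)

  # detection frequency decays with trap distance from the centre
  cfgd <- scenario_config(g0 = 0.4, occasions = 5, years = 1)
  traps <- data.frame(trap_id = paste0("t", 1:5), trap_type = "generic",
                      x_km = 0:4, y_km = 0)
  eff <- array(1, dim = c(5, 5, 1), dimnames = list(traps$trap_id, NULL, 1))
  regd <- trap_registry(traps, eff, years = 1,
                        reference_days = c(generic = 5))
  truthd <- truth1
  truthd$boundary <- rbind(c(-3, -3), c(7, -3), c(7, 3), c(-3, 3))
  set.seed(5)
  counts <- integer(5)
  for (r in 1:300) {
    ds <- simulate_captures(truthd, regd, cfgd)
    if (!is.null(ds)) {
      counts <- counts + vapply(seq_len(5), function(j)
        sum(ds$y_spatial[, j, , ]), numeric(1))
    }
  }
  expect_true(all(diff(counts) < 0))
})

test_that("the grizzly-like design produces the advertised structure", {
  out <- simulate_grizzly_design(grizzly_config(), seed = 21)
  reg <- out$traps
  expect_setequal(unique(reg$traps$trap_type),
                  c("hair_trap", "bear_rub", "highway_crossing"))
  hair <- reg$traps$trap_type == "hair_trap"
  cross <- reg$traps$trap_type == "highway_crossing"
  # ragged occasions: hair traps 5 occasions in years 1 and 3 only,
  # crossings all 8 occasions every year
  expect_true(all(reg$effort[hair, , 2] == 0))
  expect_true(all(reg$effort[hair, 6:8, ] == 0))
  expect_true(all(reg$effort[cross, , ] == 1))
  expect_false(is.null(out$dataset))

  # zero effort -> no detections at all
  none <- simulate_grizzly_design(grizzly_config(effort_multiplier = 0),
                                  seed = 21)
  expect_null(none$dataset)

  # sex-specific sigma: male detections span wider trap extents
  span_by_sex <- function(sim) {
    ds <- sim$dataset
    xy <- cbind(sim$traps$traps$x_km, sim$traps$traps$y_km)
    used <- apply(ds$y_spatial, c(1, 2), max) > 0
    span <- vapply(seq_len(nrow(used)), function(i) {
      js <- which(used[i, ])
      if (length(js) < 2) return(NA_real_)
      max(dist(xy[js, , drop = FALSE]))
    }, numeric(1))
    tapply(span, ds$individuals$sex, mean, na.rm = TRUE)
  }
  spans <- rowMeans(vapply(1:4, function(s) {
    span_by_sex(simulate_grizzly_design(grizzly_config(), seed = 30 + s))
  }, numeric(2)))
  expect_gt(spans["M"], spans["F"])
})

test_that("doubling effort increases expected detection counts", {
  n_events <- function(mult, seed) {
    sim <- simulate_grizzly_design(grizzly_config(effort_multiplier = mult),
                                   seed = seed)
    if (is.null(sim$dataset)) 0L else nrow(sim$dataset$detections)
  }
  base <- vapply(1:5, function(s) n_events(1, 50 + s), integer(1))
  doubled <- vapply(1:5, function(s) n_events(2, 50 + s), integer(1))
  expect_gt(mean(doubled), mean(base))
})
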