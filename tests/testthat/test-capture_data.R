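test_that("observed centres follow the MCP-centroid conventions", {
  expect_equal(observed_centre(matrix(c(3, 4), 1)), c(3, 4))
  expect_equal(observed_centre(rbind(c(0, 0), c(2, 2))), c(1, 1))
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(observed_centre(sq), c(0.5, 0.5))
  # area centroid, not vertex mean: a dense cluster of hull vertices on one
  # side must not drag the centroid (oracle: centroid of the same square)
  sq2 <- rbind(sq, c(0, 0.2), c(0, 0.4), c(0, 0.6), c(0, 0.8))
  expect_equal(observed_centre(sq2), c(0.5, 0.5))
  # permutation invariance
  set.seed(11)
  pts <- matrix(runif(20), 10, 2)
  for (r in 1:5) {
    expect_equal(observed_centre(pts[sample(10), ]), observed_centre(pts))
  }
  # collinear points fall back to the mean of unique points
  col <- rbind(c(0, 0), c(1, 1), c(3, 3), c(1, 1))
  expect_equal(observed_centre(col), colMeans(rbind(c(0, 0), c(1, 1), c(3, 3))))
  expect_error(observed_centre(matrix(numeric(0), 0, 2)), "no trap")
})

test_that("distance to the study-area edge is the nearest-segment distance", {
  sq <- rbind(c(0, 0), c(14, 0), c(14, 14), c(0, 14))
  expect_equal(distance_to_edge(c(7, 7), sq), 7)
  expect_equal(distance_to_edge(c(0, 5), sq), 0)
  expect_equal(distance_to_edge(c(1, 5), sq), 1)
  expect_error(distance_to_edge(c(20, 5), sq), "outside")
  # non-convex boundary: nearest segment may be an interior notch
  notch <- rbind(c(0, 0), c(10, 0), c(10, 10), c(6, 10), c(6, 4),
                 c(4, 4), c(4, 10), c(0, 10))
  expect_equal(distance_to_edge(c(5, 2), notch), 2)  # below the notch floor
  expect_equal(polygon_area(sq), 196)
})

test_that("a single detection event maps to a single array cell", {
  reg <- tiny_registry()
  det <- data.frame(individual_id = "a", sex = "F", year = 1, occasion = 2,
                    trap_id = "h1")
  ds <- capture_data(det, reg, boundary = "buffer:5")
  expect_equal(sum(ds$y_spatial), 1)
  expect_equal(ds$y_spatial["a", "h1", 2, "1"], 1L)
  expect_equal(sum(ds$y_nonspatial), 1)
  expect_equal(ds$y_nonspatial["a", 2, "hair_trap", "1"], 1L)
})

test_that("the per-type view is the OR of per-trap detections", {
  reg <- tiny_registry()
  det <- data.frame(individual_id = c("a", "a"), sex = "F", year = 1,
                    occasion = 1, trap_id = c("h1", "h2"))
  ds <- capture_data(det, reg, boundary = "buffer:5")
  expect_equal(sum(ds$y_spatial), 2)
  expect_equal(ds$y_nonspatial["a", 1, "hair_trap", "1"], 1L)
  expect_equal(sum(ds$y_nonspatial), 1)

  # property: collapse consistency on random fixtures
  for (seed in 1:4) {
    fx <- random_tiny_fixture(seed)
    types <- fx$dataset$trap_types
    for (m in seq_along(types)) {
      js <- which(fx$registry$traps$trap_type == types[m])
      manual <- apply(fx$dataset$y_spatial[, js, , , drop = FALSE],
                      c(1, 3, 4), max)
      expect_equal(unname(fx$dataset$y_nonspatial[, , m, ]),
                   unname(manual * 1L))
    }
  }
})

test_that("datasets survive a write/read round trip unchanged", {
  fx <- random_tiny_fixture(7)
  dir <- tempfile("rt")
  write_dataset(fx$dataset, fx$registry, dir)
  back <- read_dataset(file.path(dir, "detections.csv"),
                       file.path(dir, "traps.csv"),
                       file.path(dir, "effort.csv"),
                       boundary_spec = "buffer:5")
  expect_equal(back$dataset$y_spatial, fx$dataset$y_spatial)
  expect_equal(back$dataset$y_nonspatial, fx$dataset$y_nonspatial)
  expect_equal(back$dataset$individuals, fx$dataset$individuals)
  expect_equal(back$traps$effort, fx$registry$effort)
})

test_that("malformed inputs are rejected with informative errors", {
  reg <- tiny_registry()
  bad_trap <- data.frame(individual_id = "a", sex = "F", year = 1,
                         occasion = 1, trap_id = "nope")
  expect_error(capture_data(bad_trap, reg, "buffer:5"), "row 1.*unknown trap")
  # h1 is inactive at occasion 3 (hair traps run occasions 1-2)
  zero_eff <- data.frame(individual_id = "a", sex = "F", year = 1,
                         occasion = 3, trap_id = "h1")
  expect_error(capture_data(zero_eff, reg, "buffer:5"), "zero effort")
  inconsistent_sex <- data.frame(individual_id = c("a", "a"), sex = c("F", "M"),
                                 year = 1, occasion = 1,
                                 trap_id = c("h1", "h2"))
  expect_error(capture_data(inconsistent_sex, reg, "buffer:5"), "sex")
})

test_that("detection summaries match hand-computed values", {
  reg <- tiny_registry()
  # bear a: 3 events in year 1, 1 in year 2; bear b: 1 event in year 1
  det <- data.frame(
    individual_id = c("a", "a", "a", "a", "b"),
    sex = c("F", "F", "F", "F", "M"),
    year = c(1, 1, 1, 2, 1),
    occasion = c(1, 1, 2, 1, 1),
    trap_id = c("h1", "r1", "r2", "h2", "x1"))
  tab <- tabulate_detections(capture_data(det, reg, "buffer:5"))
  y1 <- tab[tab$stratum == "1", ]
  expect_equal(y1$n_individuals, 2)
  expect_equal(y1$n_female, 1)
  expect_equal(y1$n_male, 1)
  expect_equal(y1$mean_detections_per_year, 2.0)  # 4 events / 2 animal-years
  expect_equal(y1$pct_gt1_detection, 50.0)        # a yes, b no
  tot <- tab[tab$stratum == "Total", ]
  expect_equal(tot$n_individuals, 2)
  expect_equal(tot$mean_detections_per_year, round(5 / 3, 1))
  hair <- tab[tab$stratum == "hair_trap", ]
  expect_equal(hair$n_individuals, 1)
  expect_equal(hair$mean_detections_per_year, 1.0)

  # two bears detected once each: mean 1.0, nobody above one detection
  det2 <- det[c(4, 5), ]
  tab2 <- tabulate_detections(capture_data(det2, reg, "buffer:5"))
  tot2 <- tab2[tab2$stratum == "Total", ]
  expect_equal(tot2$mean_detections_per_year, 1.0)
  expect_equal(tot2$pct_gt1_detection, 0)
})
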