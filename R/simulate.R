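# Synthetic-data generators.
#
# Two designs are emulated:
#  * the square-grid scenario design: 10 x 10 traps with spacing s = sigma =
#    1 km, state space a 2.5 s buffer around the grid, fixed initial density,
#    annual survival phi = 0.8 and per-capita recruitment R = 0.1, five
#    occasions per year for three years, half-normal detection;
#  * a grizzly-like multi-detector design: bear rubs, hair traps and highway
#    crossings with ragged occasion structure, variable effort and
#    sex-specific detection scale.

#' Scenario configuration for the square-grid simulation design
#'
#' Defaults are the study conditions of the simulation experiment: a 10 x 10
#' trap grid with spacing `s = 1` km, `sigma = 1` km, a `2.5 s` state-space
#' buffer, three years with five occasions each, survival `phi = 0.8` and
#' per-capita recruitment `R = 0.1` (growth rate `phi + R = 0.9`). Density
#' (animals per `s^-2`, i.e. per km2 at the default spacing) and baseline
#' detection `g0` span the scenario grid `{0.5, 1.0} x {0.1, 0.5}`.
#'
#' @param density animals per km2 of state space.
#' @param g0 per-trap per-occasion detection probability at distance zero.
#' @param sigma half-normal detection scale, km.
#' @param spacing trap spacing, km.
#' @param nx,ny trap grid dimensions.
#' @param phi annual apparent survival.
#' @param R per-capita recruitment rate.
#' @param years number of years.
#' @param occasions sampling occasions per year.
#' @param buffer state-space buffer in multiples of `spacing`.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(density = 1.0, g0 = 0.5, sigma = 1.0,
                            spacing = 1.0, nx = 10, ny = 10, phi = 0.8,
                            R = 0.1, years = 3, occasions = 5,
                            buffer = 2.5) {
  stopifnot(density > 0, g0 >= 0, g0 <= 1, phi >= 0, phi <= 1,
            R >= 0, R <= 1, buffer > 0, sigma > 0, years >= 1)
  structure(list(density = density, g0 = g0, sigma = sigma,
                 spacing = spacing, nx = nx, ny = ny, phi = phi, R = R,
                 years = years, occasions = occasions, buffer = buffer),
            class = "scenario_config")
}

#' Trap registry for a scenario configuration
#'
#' Square grid of `generic` traps, one nominal trap-day per occasion in
#' every year; the per-type reference effort equals the total active
#' trap-days so the effort exponent is exactly one (unscaled detection).
#'
#' @param config a [scenario_config()].
#' @return a [trap_registry].
#' @export
scenario_traps <- function(config) {
  xy <- expand.grid(x = (seq_len(config$nx) - 1) * config$spacing,
                    y = (seq_len(config$ny) - 1) * config$spacing)
  J <- nrow(xy)
  traps <- data.frame(trap_id = sprintf("g%03d", seq_len(J)),
                      trap_type = "generic", x_km = xy$x, y_km = xy$y)
  eff <- array(1, dim = c(J, config$occasions, config$years),
               dimnames = list(traps$trap_id, NULL, seq_len(config$years)))
  trap_registry(traps, eff, years = seq_len(config$years),
                reference_days = c(generic = J))
}

#' State-space rectangle of a scenario configuration
#' @param config a [scenario_config()].
#' @return 4 x 2 vertex matrix (trap grid buffered by `buffer * spacing`).
#' @export
scenario_boundary <- function(config) {
  xy <- cbind((c(1, config$nx) - 1) * config$spacing,
              (c(1, config$ny) - 1) * config$spacing)
  buffer_rectangle(xy, config$buffer * config$spacing)
}

# population projection shared by both designs: fixed initial size, Bernoulli
# survival, each animal alive at t recruits one new animal at t+1 with
# probability R; recruits placed uniformly; centres never move.
project_population <- function(n1, phi, R, years, rect) {
  runif_rect <- function(n) cbind(runif(n, rect[1, 1], rect[2, 1]),
                                  runif(n, rect[1, 2], rect[3, 2]))
  centres <- runif_rect(n1)
  alive <- matrix(0L, n1, years)
  alive[, 1] <- 1L
  entry <- rep(1L, n1)
  for (t in seq_len(years - 1)) {
    cur <- which(alive[, t] == 1L)
    surv <- cur[runif(length(cur)) < phi]
    alive[surv, t + 1] <- 1L
    n_new <- sum(runif(length(cur)) < R)
    if (n_new > 0) {
      centres <- rbind(centres, runif_rect(n_new))
      newrows <- matrix(0L, n_new, years)
      newrows[, t + 1] <- 1L
      alive <- rbind(alive, newrows)
      entry <- c(entry, rep(t + 1L, n_new))
    }
  }
  list(centres = centres, alive = alive, entry_year = entry)
}

#' Simulate the open-population truth for a scenario
#'
#' The initial population size is fixed at `round(density * area)` with
#' centres uniform on the buffered state space. Each animal alive at year
#' `t` survives to `t + 1` with probability `phi` and, independently,
#' introduces one new animal (uniform centre) with probability `R`. Dead
#' animals never re-enter and centres do not move.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed.
#' @return object of class `population_truth`: list with `centres` (n x 2),
#'   `alive` (n x years, 0/1), `entry_year`, `N` (per-year totals), `area`
#'   (state-space area, km2), `boundary`.
#' @export
simulate_open_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rect <- scenario_boundary(config)
  area <- polygon_area(rect)
  n1 <- round(config$density * area)
  pop <- project_population(n1, config$phi, config$R, config$years, rect)
  structure(list(centres = pop$centres, alive = pop$alive,
                 entry_year = pop$entry_year, N = colSums(pop$alive),
                 area = area, boundary = rect),
            class = "population_truth")
}

# Bernoulli detections with half-normal probability; effort-aware: a cell
# with e active trap-days uses 1 - (1 - p)^e. Returns event data.frame.
draw_detections <- function(centres, alive, registry, g0_of_trap, sigma_of_ind) {
  xy <- cbind(registry$traps$x_km, registry$traps$y_km)
  J <- nrow(xy); K <- dim(registry$effort)[2]; Tn <- length(registry$years)
  d2 <- outer(centres[, 1], xy[, 1], "-")^2 +
        outer(centres[, 2], xy[, 2], "-")^2
  p0 <- exp(-d2 / (2 * rep(sigma_of_ind, J)^2)) *
        matrix(g0_of_trap, nrow(centres), J, byrow = TRUE)
  ev <- vector("list", Tn * K)
  for (t in seq_len(Tn)) {
    rows <- which(alive[, t] == 1L)
    if (!length(rows)) next
    for (k in seq_len(K)) {
      e <- registry$effort[, k, t]
      act <- which(e > 0)
      if (!length(act)) next
      pcell <- 1 - (1 - p0[rows, act, drop = FALSE])^
        matrix(e[act], length(rows), length(act), byrow = TRUE)
      hit <- which(matrix(runif(length(pcell)), nrow(pcell)) < pcell,
                   arr.ind = TRUE)
      if (nrow(hit)) {
        ev[[(t - 1) * K + k]] <- data.frame(
          ind = rows[hit[, 1]],
          trap_id = registry$traps$trap_id[act[hit[, 2]]],
          occasion = k, year = registry$years[t])
      }
    }
  }
  do.call(rbind, ev)
}

#' Simulate detection histories for a scenario population
#'
#' Each alive individual is detected independently at each trap and occasion
#' with probability `g0 * exp(-d^2 / (2 sigma^2))`, `d` the distance from its
#' activity centre to the trap. Individuals never detected are absent from
#' the returned dataset but remain countable via `truth`.
#'
#' @param truth a [simulate_open_population()] result.
#' @param registry a [scenario_traps()] registry (or compatible).
#' @param config the [scenario_config()] supplying `g0`, `sigma`.
#' @param seed optional integer seed.
#' @return a [capture_data] object (attribute `truth_index` maps its
#'   individuals back to rows of `truth$centres`), or `NULL` when no animal
#'   was detected.
#' @export
simulate_captures <- function(truth, registry, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(registry$traps)
  ev <- draw_detections(truth$centres, truth$alive, registry,
                        g0_of_trap = rep(config$g0, J),
                        sigma_of_ind = rep(config$sigma, nrow(truth$centres)))
  if (is.null(ev) || nrow(ev) == 0L) return(NULL)
  ids <- sprintf("i%04d", ev$ind)
  dets <- data.frame(individual_id = ids, sex = "F", year = ev$year,
                     occasion = ev$occasion, trap_id = ev$trap_id)
  ds <- capture_data(dets, registry, boundary = truth$boundary)
  attr(ds, "truth_index") <- as.integer(sub("^i", "", ds$individuals$id))
  ds
}

#' Simulate a full scenario dataset
#'
#' Convenience wrapper: population truth plus detection histories.
#'
#' @inheritParams simulate_captures
#' @param config a [scenario_config()].
#' @param seed optional integer seed.
#' @return list with `truth`, `traps` (registry) and `dataset`.
#' @export
simulate_scenario <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  registry <- scenario_traps(config)
  truth <- simulate_open_population(config)
  dataset <- simulate_captures(truth, registry, config)
  list(truth = truth, traps = registry, dataset = dataset)
}

#' Configuration for the grizzly-like multi-detector design
#'
#' Emulates a DNA hair-snag monitoring design: ~42 hair traps on a coarse
#' grid run in years 1 and 3 only (5 occasions), ~150 bear rubs (up to 7
#' occasions, starting mid-year in year 1), and 20 highway crossing
#' structures along a central transport corridor (8 occasions, all years).
#' Effort is recorded as active-trap indicators; reference effort per type
#' follows the monitoring convention (162 / 42 / 20). Detection scale is
#' sex-specific (about 5 km for females, 9 km for males, matching observed
#' grizzly home-range scale) and baseline detection differs by trap type.
#'
#' @param n1_female,n1_male initial population sizes.
#' @param phi,R survival and per-capita recruitment.
#' @param years number of years.
#' @param sigma_f,sigma_m half-normal scale by sex, km.
#' @param g0 named per-type baseline detection at distance zero.
#' @param n_rubs number of bear-rub detectors.
#' @param effort_multiplier scales all active-trap-day counts (default 1).
#' @return list of settings.
#' @export
grizzly_config <- function(n1_female = 28, n1_male = 35, phi = 0.8, R = 0.1,
                           years = 3, sigma_f = 5, sigma_m = 9,
                           g0 = c(bear_rub = 0.04, hair_trap = 0.06,
                                  highway_crossing = 0.015),
                           n_rubs = 150, effort_multiplier = 1) {
  list(n1_female = n1_female, n1_male = n1_male, phi = phi, R = R,
       years = years, sigma_f = sigma_f, sigma_m = sigma_m, g0 = g0,
       n_rubs = n_rubs, effort_multiplier = effort_multiplier)
}

#' Simulate a grizzly-like multi-detector dataset
#'
#' Generates a three-trap-type design with ragged occasion structures and
#' variable effort (see [grizzly_config()]), projects a two-sex open
#' population, and draws detections from a sex-specific half-normal model
#' with per-trap-day effort scaling.
#'
#' @param config a [grizzly_config()].
#' @param seed optional integer seed.
#' @return list with `truth` (includes `sex`), `traps` and `dataset`
#'   (`NULL` when nothing was detected).
#' @export
simulate_grizzly_design <- function(config = grizzly_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  years <- seq_len(config$years)

  hair <- expand.grid(x = seq(6, 54, length.out = 7),
                      y = seq(4, 36, length.out = 6))
  rubs <- cbind(runif(config$n_rubs, 0, 60), runif(config$n_rubs, 0, 40))
  cross <- cbind(seq(1.5, 58.5, length.out = 20), rep(20, 20))
  traps <- data.frame(
    trap_id = c(sprintf("H%02d", seq_len(nrow(hair))),
                sprintf("R%03d", seq_len(nrow(rubs))),
                sprintf("X%02d", seq_len(nrow(cross)))),
    trap_type = rep(c("hair_trap", "bear_rub", "highway_crossing"),
                    c(nrow(hair), nrow(rubs), nrow(cross))),
    x_km = c(hair$x, rubs[, 1], cross[, 1]),
    y_km = c(hair$y, rubs[, 2], cross[, 2]))

  K <- 8L
  J <- nrow(traps)
  eff <- array(0, dim = c(J, K, config$years),
               dimnames = list(traps$trap_id, NULL, years))
  is_hair <- traps$trap_type == "hair_trap"
  is_rub <- traps$trap_type == "bear_rub"
  is_cross <- traps$trap_type == "highway_crossing"
  for (t in years) {
    if (t %in% c(1, min(3, config$years))) eff[is_hair, 1:5, t] <- 1
    rub_occ <- if (t == 1) 4:7 else 1:7        # rubs start mid-year 1
    # variable effort: each rub active in a random ~85% of its occasions
    act <- matrix(runif(sum(is_rub) * length(rub_occ)) < 0.85,
                  sum(is_rub), length(rub_occ))
    eff[which(is_rub), rub_occ, t] <- act * 1
    eff[is_cross, 1:8, t] <- 1
  }
  eff <- eff * config$effort_multiplier
  registry <- trap_registry(traps, eff, years = years)

  rect <- buffer_rectangle(cbind(traps$x_km, traps$y_km), 10)
  popf <- project_population(config$n1_female, config$phi, config$R,
                             config$years, rect)
  popm <- project_population(config$n1_male, config$phi, config$R,
                             config$years, rect)
  centres <- rbind(popf$centres, popm$centres)
  alive <- rbind(popf$alive, popm$alive)
  sex <- rep(c("F", "M"), c(nrow(popf$centres), nrow(popm$centres)))
  truth <- structure(
    list(centres = centres, alive = alive,
         entry_year = c(popf$entry_year, popm$entry_year),
         sex = sex, N = colSums(alive), area = polygon_area(rect),
         boundary = rect),
    class = "population_truth")

  sigma_of_ind <- ifelse(sex == "M", config$sigma_m, config$sigma_f)
  g0_of_trap <- unname(config$g0[traps$trap_type])
  ev <- draw_detections(centres, alive, registry, g0_of_trap, sigma_of_ind)
  dataset <- NULL
  if (!is.null(ev) && nrow(ev) > 0L) {
    dets <- data.frame(individual_id = sprintf("b%04d", ev$ind),
                       sex = sex[ev$ind], year = ev$year,
                       occasion = ev$occasion, trap_id = ev$trap_id)
    dataset <- capture_data(dets, registry, boundary = rect)
    attr(dataset, "truth_index") <-
      as.integer(sub("^b", "", dataset$individuals$id))
  }
  list(truth = truth, traps = registry, dataset = dataset)
}
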