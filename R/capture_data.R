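# Data model: trap registry + multi-year detection dataset.
#
# Detections are kept in three mutually consistent views:
#   * an event table (one row per individual x trap x occasion x year),
#   * y_spatial[i, j, k, t]  -- binary, per trap (SCR view),
#   * y_nonspatial[i, k, m, t] -- binary, per trap *type* (CR view, the OR
#     over traps of that type within the occasion).
# Occasion structure may be ragged across trap types; a global occasion axis
# is used with zero-effort cells marking "trap not deployed".

TRAP_TYPES <- c("bear_rub", "hair_trap", "highway_crossing", "generic")

#' Default per-type reference effort (median active trap days)
#'
#' Reference trap-days used by the proportional-hazard effort scaling:
#' 162 for bear rubs, 42 for hair traps, 20 for highway crossings. The
#' `generic` type (simulated square-grid designs with uniform effort) uses 1,
#' so one nominal trap-day per occasion leaves detection unscaled.
#' @export
default_reference_days <- function() {
  c(bear_rub = 162, hair_trap = 42, highway_crossing = 20, generic = 1)
}

#' Build a trap registry
#'
#' @param traps data.frame with columns `trap_id`, `trap_type` (one of
#'   `r paste(TRAP_TYPES, collapse = ", ")`), `x_km`, `y_km`.
#' @param effort either a data.frame with columns `trap_id`, `year`,
#'   `occasion`, `days`, or a 3-d array `[trap, occasion, year]` of active
#'   trap-days. Missing rows / zero entries mean the trap was not deployed.
#' @param years ordered vector of study years (defaults to those in `effort`).
#' @param n_occasions number of global occasions (defaults to max in `effort`).
#' @param reference_days named vector of per-type reference trap-days;
#'   defaults to [default_reference_days()].
#' @return object of class `trap_registry`: list with elements `traps`
#'   (data.frame), `effort` (array `[J, K, T]` of days), `years`,
#'   `reference_days`.
#' @export
trap_registry <- function(traps, effort, years = NULL, n_occasions = NULL,
                          reference_days = default_reference_days()) {
  traps <- as.data.frame(traps)
  need <- c("trap_id", "trap_type", "x_km", "y_km")
  if (!all(need %in% names(traps))) {
    stop("traps must have columns ", paste(need, collapse = ", "))
  }
  traps$trap_id <- as.character(traps$trap_id)
  if (anyDuplicated(traps$trap_id)) stop("duplicate trap_id in traps table")
  if (!all(traps$trap_type %in% TRAP_TYPES)) {
    stop("unknown trap_type; allowed: ", paste(TRAP_TYPES, collapse = ", "))
  }
  if (!all(is.finite(traps$x_km)) || !all(is.finite(traps$y_km))) {
    stop("trap coordinates must be finite")
  }

  if (is.array(effort) && length(dim(effort)) == 3L) {
    eff <- effort
    if (is.null(years)) years <- as.integer(dimnames(eff)[[3]])
  } else {
    effort <- as.data.frame(effort)
    if (!all(c("trap_id", "year", "occasion", "days") %in% names(effort))) {
      stop("effort must have columns trap_id, year, occasion, days")
    }
    effort$trap_id <- as.character(effort$trap_id)
    bad <- which(!effort$trap_id %in% traps$trap_id)
    if (length(bad)) {
      stop("effort row ", bad[1], ": unknown trap_id '", effort$trap_id[bad[1]], "'")
    }
    if (any(effort$days < 0)) stop("effort days must be nonnegative")
    if (is.null(years)) years <- sort(unique(as.integer(effort$year)))
    if (is.null(n_occasions)) n_occasions <- max(as.integer(effort$occasion))
    eff <- array(0, dim = c(nrow(traps), n_occasions, length(years)),
                 dimnames = list(traps$trap_id, seq_len(n_occasions), years))
    ji <- match(effort$trap_id, traps$trap_id)
    ki <- as.integer(effort$occasion)
    ti <- match(as.integer(effort$year), years)
    if (anyNA(ti)) stop("effort references a year outside the study years")
    eff[cbind(ji, ki, ti)] <- effort$days
  }
  if (any(eff < 0)) stop("effort days must be nonnegative")
  dimnames(eff) <- list(traps$trap_id, seq_len(dim(eff)[2]), years)

  rd <- reference_days[unique(traps$trap_type)]
  if (anyNA(rd) || any(rd <= 0)) {
    stop("reference_days must be positive for every trap type in use")
  }
  structure(
    list(traps = traps, effort = eff, years = as.integer(years),
         reference_days = reference_days),
    class = "trap_registry")
}

#' @export
print.trap_registry <- function(x, ...) {
  cat("trap_registry:", nrow(x$traps), "traps,",
      dim(x$effort)[2], "occasions,", length(x$years), "years\n")
  print(table(x$traps$trap_type))
  invisible(x)
}

trap_type_levels <- function(registry) {
  TRAP_TYPES[TRAP_TYPES %in% unique(registry$traps$trap_type)]
}

#' Assemble a detection dataset from an event table
#'
#' @param detections data.frame with columns `individual_id`, `sex`
#'   (`"F"`/`"M"`), `year`, `occasion`, `trap_id`; one row per detection
#'   event (duplicates collapse to a single binary detection).
#' @param registry a [trap_registry()].
#' @param boundary study boundary: an `n x 2` vertex matrix, or a string
#'   `"buffer:<km>"` to use a rectangle around the traps (see
#'   [buffer_rectangle()]).
#' @return object of class `capture_data`: list with `individuals`
#'   (data.frame `id`, `sex`), `years`, `y_spatial[i,j,k,t]`,
#'   `y_nonspatial[i,k,m,t]`, `trap_types`, `boundary`, `detections`.
#' @export
capture_data <- function(detections, registry, boundary = "buffer:25") {
  detections <- as.data.frame(detections)
  need <- c("individual_id", "sex", "year", "occasion", "trap_id")
  if (!all(need %in% names(detections))) {
    stop("detections must have columns ", paste(need, collapse = ", "))
  }
  detections$individual_id <- as.character(detections$individual_id)
  detections$trap_id <- as.character(detections$trap_id)
  detections$year <- as.integer(detections$year)
  detections$occasion <- as.integer(detections$occasion)
  if (!all(detections$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")

  jraw <- match(detections$trap_id, registry$traps$trap_id)
  if (anyNA(jraw)) {
    bad <- which(is.na(jraw))[1]
    stop("detections row ", bad, ": unknown trap_id '",
         detections$trap_id[bad], "'")
  }
  traw <- match(detections$year, registry$years)
  if (anyNA(traw)) {
    bad <- which(is.na(traw))[1]
    stop("detections row ", bad, ": year ", detections$year[bad],
         " not in the trap registry")
  }
  K <- dim(registry$effort)[2]
  if (any(detections$occasion < 1 | detections$occasion > K)) {
    bad <- which(detections$occasion < 1 | detections$occasion > K)[1]
    stop("detections row ", bad, ": occasion out of range 1..", K)
  }
  eff_at <- registry$effort[cbind(jraw, detections$occasion, traw)]
  if (any(eff_at <= 0)) {
    bad <- which(eff_at <= 0)[1]
    stop("detections row ", bad, ": detection at trap '",
         detections$trap_id[bad], "', occasion ", detections$occasion[bad],
         ", year ", detections$year[bad],
         " which has zero effort (effort/detection mismatch)")
  }

  sex_tab <- unique(detections[, c("individual_id", "sex")])
  if (anyDuplicated(sex_tab$individual_id)) {
    stop("inconsistent sex labels for some individual_id")
  }
  individuals <- data.frame(id = sex_tab$individual_id, sex = sex_tab$sex,
                            stringsAsFactors = FALSE)
  individuals <- individuals[order(individuals$id), , drop = FALSE]
  rownames(individuals) <- NULL

  years <- registry$years
  types <- trap_type_levels(registry)
  n <- nrow(individuals); J <- nrow(registry$traps); Tn <- length(years)
  ii <- match(detections$individual_id, individuals$id)
  y_sp <- array(0L, dim = c(n, J, K, Tn),
                dimnames = list(individuals$id, registry$traps$trap_id,
                                NULL, years))
  y_sp[cbind(ii, jraw, detections$occasion, traw)] <- 1L
  mi <- match(registry$traps$trap_type, types)
  y_ns <- collapse_to_types(y_sp, mi, length(types))
  dimnames(y_ns) <- list(individuals$id, NULL, types, years)

  if (is.character(boundary)) {
    if (!grepl("^buffer:", boundary)) {
      stop("boundary must be a vertex matrix or 'buffer:<km>'")
    }
    bw <- as.numeric(sub("^buffer:", "", boundary))
    boundary <- buffer_rectangle(
      cbind(registry$traps$x_km, registry$traps$y_km), bw)
  }
  boundary <- as.matrix(boundary)

  structure(
    list(individuals = individuals, years = years, y_spatial = y_sp,
         y_nonspatial = y_ns, trap_types = types,
         trap_type_of_trap = registry$traps$trap_type,
         boundary = boundary, detections = detections),
    class = "capture_data")
}

# OR-reduce the per-trap array over traps within each type
collapse_to_types <- function(y_sp, type_index, n_types) {
  d <- dim(y_sp)
  out <- array(0L, dim = c(d[1], d[3], n_types, d[4]))
  for (m in seq_len(n_types)) {
    js <- which(type_index == m)
    if (length(js)) {
      sub <- y_sp[, js, , , drop = FALSE]
      out[, , m, ] <- (apply(sub, c(1, 3, 4), max) > 0L) * 1L
    }
  }
  out
}

#' @export
print.capture_data <- function(x, ...) {
  cat("capture_data:", nrow(x$individuals), "individuals (",
      sum(x$individuals$sex == "F"), "F /", sum(x$individuals$sex == "M"),
      "M ),", length(x$years), "years,", dim(x$y_spatial)[2], "traps\n")
  invisible(x)
}

#' Read a detection dataset and trap registry from delimited files
#'
#' Files are comma-delimited with a header row. `detections` has columns
#' `individual_id, sex, year, occasion, trap_id`; `traps` has
#' `trap_id, trap_type, x_km, y_km`; `effort` has
#' `trap_id, year, occasion, days` (absent rows mean zero effort / trap not
#' deployed). Every detection must reference a known trap at a
#' positive-effort trap-occasion.
#'
#' @param detections_path,traps_path,effort_path file paths.
#' @param boundary_spec vertex matrix or `"buffer:<km>"` string.
#' @param reference_days per-type reference trap-days.
#' @return list with elements `dataset` ([capture_data]) and `traps`
#'   ([trap_registry]).
#' @export
read_dataset <- function(detections_path, traps_path, effort_path,
                         boundary_spec = "buffer:25",
                         reference_days = default_reference_days()) {
  for (p in c(detections_path, traps_path, effort_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  traps <- read.csv(traps_path, stringsAsFactors = FALSE)
  effort <- read.csv(effort_path, stringsAsFactors = FALSE)
  dets <- read.csv(detections_path, stringsAsFactors = FALSE)
  registry <- trap_registry(traps, effort, reference_days = reference_days)
  dataset <- capture_data(dets, registry, boundary = boundary_spec)
  list(dataset = dataset, traps = registry)
}

#' Write a dataset + registry to the standard delimited files
#'
#' Inverse of [read_dataset()]: writes `detections.csv`, `traps.csv` and
#' `effort.csv` into `dir`.
#'
#' @param dataset a [capture_data] object.
#' @param registry the matching [trap_registry].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("detections.csv", "traps.csv", "effort.csv"))
  write.csv(dataset$detections[, c("individual_id", "sex", "year",
                                   "occasion", "trap_id")],
            paths[1], row.names = FALSE)
  write.csv(registry$traps, paths[2], row.names = FALSE)
  eff <- registry$effort
  idx <- which(eff > 0, arr.ind = TRUE)
  effdf <- data.frame(trap_id = registry$traps$trap_id[idx[, 1]],
                      year = registry$years[idx[, 3]],
                      occasion = idx[, 2],
                      days = eff[idx])
  write.csv(effdf, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Observed home-range centres and distance-to-edge covariate
#'
#' For every detected individual, computes the centroid of the minimum
#' convex polygon around the traps where it was detected (all years pooled)
#' and the distance from that centre to the study-area edge (DEDGE, km).
#'
#' @param dataset a [capture_data] object.
#' @param registry the matching [trap_registry].
#' @return data.frame with columns `individual_id`, `x`, `y`,
#'   `n_traps_used`, `dedge`.
#' @export
observed_centres <- function(dataset, registry) {
  xy <- cbind(registry$traps$x_km, registry$traps$y_km)
  n <- nrow(dataset$individuals)
  out <- data.frame(individual_id = dataset$individuals$id,
                    x = NA_real_, y = NA_real_,
                    n_traps_used = NA_integer_, dedge = NA_real_)
  used <- apply(dataset$y_spatial, c(1, 2), max) > 0
  for (i in seq_len(n)) {
    js <- which(used[i, ])
    ctr <- observed_centre(xy[js, , drop = FALSE])
    out$x[i] <- ctr[1]; out$y[i] <- ctr[2]
    out$n_traps_used[i] <- length(js)
    out$dedge[i] <- distance_to_edge(ctr, dataset$boundary)
  }
  out
}

#' Descriptive detection summaries by year and trap type
#'
#' Per stratum (each study year, each trap type, and a `Total` row):
#' number of individuals detected, counts by sex, mean detection events per
#' animal per year (events divided by the number of individual-years with at
#' least one event in the stratum), and the percentage of those
#' individual-years with more than one event.
#'
#' @param dataset a [capture_data] object.
#' @return data.frame, one row per stratum.
#' @export
tabulate_detections <- function(dataset) {
  ev <- dataset$detections
  if (nrow(ev) == 0L) stop("tabulate_detections: empty dataset")
  sex_of <- stats::setNames(dataset$individuals$sex, dataset$individuals$id)

  one <- function(label, sub) {
    if (nrow(sub) == 0L) {
      return(data.frame(stratum = label, n_individuals = 0L, n_female = 0L,
                        n_male = 0L, mean_detections_per_year = NA_real_,
                        pct_gt1_detection = NA_real_))
    }
    ids <- unique(sub$individual_id)
    iy <- table(paste(sub$individual_id, sub$year))
    data.frame(stratum = label,
               n_individuals = length(ids),
               n_female = sum(sex_of[ids] == "F"),
               n_male = sum(sex_of[ids] == "M"),
               mean_detections_per_year = round(nrow(sub) / length(iy), 1),
               pct_gt1_detection = round(100 * mean(iy > 1), 1))
  }
  rows <- list()
  for (yr in dataset$years) {
    rows[[length(rows) + 1L]] <- one(as.character(yr), ev[ev$year == yr, ])
  }
  trap_ids <- dimnames(dataset$y_spatial)[[2]]
  ev_type <- dataset$trap_type_of_trap[match(ev$trap_id, trap_ids)]
  for (m in dataset$trap_types) {
    rows[[length(rows) + 1L]] <- one(m, ev[ev_type == m, ])
  }
  rows[[length(rows) + 1L]] <- one("Total", ev)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
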