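# Model fitting: Metropolis-within-Gibbs with data augmentation.
#
# The compiled chains (src/chains.cpp) carry the per-iteration work; this
# file prepares their inputs from a capture_data + trap_registry pair, runs
# several independent chains, and wraps draws, diagnostics and summaries.

#' MCMC configuration
#'
#' @param n_chains number of independent chains (default 3).
#' @param n_iter iterations per chain *including* burn-in (default 30000).
#' @param n_burnin discarded burn-in iterations (default 5000).
#' @param augment number of all-zero augmented individuals appended to the
#'   detected ones. Default `NULL` picks 280 for combined-sex models and 200
#'   for single-sex models (the grizzly monitoring settings); simulation
#'   fits should set it explicitly to cover the expected superpopulation.
#' @param seed base integer seed; chain `c` uses `seed + 7919 * c`.
#' @param rhat_threshold Gelman-Rubin convergence bound (default 1.1).
#' @param max_cycles if > 0, a fit whose key parameters exceed
#'   `rhat_threshold` is rerun with `cycle_iter` extra iterations, up to
#'   this many times (the simulation-study protocol).
#' @param cycle_iter iterations added per convergence cycle (default 5000).
#' @param sex_model `"none"` (ignore sex), `"both"` (combined-sex model with
#'   sex effects and latent sex for augmented animals), `"female"` or
#'   `"male"` (fit that sex only).
#' @param beta_structure structure of the logit-scale detection baselines:
#'   `"auto"`, `"constant"`, `"type"`, `"type_sex"`, `"occasion_type"` or
#'   `"occasion_type_sex"`. `"auto"` uses `"constant"` for one trap type
#'   without sex effects and `"occasion_type_sex"` otherwise.
#' @param sigma_by_sex SCR only: sex-specific half-normal scale (default
#'   TRUE for combined-sex models).
#' @param sigma_max upper bound of the Uniform prior on sigma, km (15).
#' @param buffer_km SCR state-space buffer around the traps when the
#'   dataset's boundary is not used (default 25).
#' @param dedge_max truncation of imputed DEDGE values, km; default the
#'   maximum observed DEDGE.
#' @param ft_thin record Freeman-Tukey discrepancies every `ft_thin`-th
#'   retained iteration (0 disables; default 10).
#' @param centre_thin SCR: record activity-centre draws every
#'   `centre_thin`-th retained iteration (0 disables).
#' @param z_thin record latent alive-state draws every `z_thin`-th retained
#'   iteration (0 disables; intended for small diagnostic fits).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 30000, n_burnin = 5000,
                        augment = NULL, seed = 1, rhat_threshold = 1.1,
                        max_cycles = 0, cycle_iter = 5000,
                        sex_model = c("none", "both", "female", "male"),
                        beta_structure = "auto", sigma_by_sex = NULL,
                        sigma_max = 15, buffer_km = 25, dedge_max = NULL,
                        ft_thin = 10, centre_thin = 0, z_thin = 0) {
  sex_model <- match.arg(sex_model)
  stopifnot(n_iter > n_burnin, n_burnin >= 0, n_chains >= 1)
  structure(list(
    n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
    augment = augment, seed = seed, rhat_threshold = rhat_threshold,
    max_cycles = max_cycles, cycle_iter = cycle_iter, sex_model = sex_model,
    beta_structure = beta_structure, sigma_by_sex = sigma_by_sex,
    sigma_max = sigma_max, buffer_km = buffer_km, dedge_max = dedge_max,
    ft_thin = ft_thin, centre_thin = centre_thin, z_thin = z_thin),
    class = "mcmc_config")
}

# restrict a dataset to one sex
subset_sex <- function(dataset, sex) {
  keep <- dataset$individuals$sex == sex
  if (!any(keep)) stop("no individuals of sex ", sex)
  ds <- dataset
  ds$individuals <- dataset$individuals[keep, , drop = FALSE]
  ds$y_spatial <- dataset$y_spatial[keep, , , , drop = FALSE]
  ds$y_nonspatial <- dataset$y_nonspatial[keep, , , , drop = FALSE]
  ds$detections <- dataset$detections[
    dataset$detections$individual_id %in% ds$individuals$id, , drop = FALSE]
  ds
}

# build the beta index array [K, M, S] (0-based) for a structure keyword,
# pruning indices that never touch an active cell; returns list(bidx, labels)
make_beta_index <- function(structure_kw, K, M, S, active_kmt, types) {
  if (structure_kw == "auto") {
    structure_kw <- if (M == 1 && S == 1) "constant" else "occasion_type_sex"
  }
  idx <- array(0L, dim = c(K, M, S))
  lab <- function(k, m, s) {
    parts <- character(0)
    if (grepl("occasion", structure_kw)) parts <- c(parts, paste0("k", k))
    if (grepl("type", structure_kw)) parts <- c(parts, types[m])
    if (grepl("sex", structure_kw)) parts <- c(parts, c("F", "M")[s])
    if (!length(parts)) parts <- "const"
    paste(parts, collapse = ":")
  }
  labels_full <- array("", dim = c(K, M, S))
  for (s in seq_len(S)) for (m in seq_len(M)) for (k in seq_len(K)) {
    labels_full[k, m, s] <- lab(k, m, s)
  }
  # active labels: those used by at least one active (k, m, t) cell
  act_km <- apply(active_kmt, c(1, 2), any)
  used <- unique(as.vector(vapply(seq_len(S), function(s) {
    labels_full[, , s][act_km]
  }, character(sum(act_km)))))
  used <- sort(used)
  for (s in seq_len(S)) {
    idx[, , s] <- matrix(match(labels_full[, , s], used) - 1L, K, M)
  }
  idx[is.na(idx)] <- 0L  # inactive cells: index irrelevant
  list(bidx = idx, labels = used, structure = structure_kw)
}

# assemble shared individual-level inputs (sex groups, detection years)
prep_individuals <- function(dataset, sex_model, augment) {
  n_obs <- if (is.null(dataset)) 0L else nrow(dataset$individuals)
  S <- if (sex_model == "both") 2L else 1L
  sexg_obs <- if (n_obs == 0) integer(0)
    else if (S == 2) ifelse(dataset$individuals$sex == "M", 1L, 0L)
    else rep(0L, n_obs)
  sexg <- c(sexg_obs, rep(if (S == 2) -1L else 0L, augment))
  list(n = n_obs + augment, n_obs = n_obs, S = S, sex_group = sexg)
}

det_years <- function(dataset, n, Tn) {
  det <- matrix(0L, n, Tn)
  if (!is.null(dataset) && nrow(dataset$individuals) > 0) {
    n_obs <- nrow(dataset$individuals)
    det[seq_len(n_obs), ] <-
      (apply(dataset$y_nonspatial, c(1, 4), max) > 0) * 1L
  }
  det
}

prep_cr_inputs <- function(dataset, registry, config, use_dedge) {
  types <- trap_type_levels(registry)
  K <- dim(registry$effort)[2]; M <- length(types)
  Tn <- length(registry$years)
  nd <- ndays_by_type(registry)
  ref <- registry$reference_days[types]
  e_kmt <- sweep(nd, 2, ref, "/")
  ind <- prep_individuals(dataset, config$sex_model,
                          default_augment(config))
  bi <- make_beta_index(config$beta_structure, K, M, ind$S, e_kmt > 0, types)

  # group cells by (year, sex stratum, beta index, effort exponent)
  gt <- gs <- gb <- gn <- integer(0); ge <- numeric(0)
  cell_group <- list()
  for (s in seq_len(ind$S)) for (t in seq_len(Tn)) {
    em <- matrix(e_kmt[, , t], K, M)
    cells <- which(em > 0, arr.ind = TRUE)
    if (nrow(cells) == 0) next
    key <- paste(bi$bidx[cbind(cells[, 1], cells[, 2], s)],
                 signif(e_kmt[cbind(cells[, 1], cells[, 2], t)], 12))
    for (u in unique(key)) {
      sel <- cells[key == u, , drop = FALSE]
      gt <- c(gt, t - 1L); gs <- c(gs, s - 1L)
      gb <- c(gb, bi$bidx[sel[1, 1], sel[1, 2], s])
      ge <- c(ge, e_kmt[sel[1, 1], sel[1, 2], t])
      gn <- c(gn, nrow(sel))
      cell_group[[length(gt)]] <- cbind(sel, t)
    }
  }
  NG <- length(gt)
  cnt <- matrix(0L, ind$n, max(NG, 1))
  if (!is.null(dataset) && ind$n_obs > 0) {
    y <- dataset$y_nonspatial
    for (g in seq_len(NG)) {
      sel <- cell_group[[g]]
      tot <- 0L
      for (r in seq_len(nrow(sel))) {
        tot <- tot + y[, sel[r, 1], sel[r, 2], sel[r, 3]]
      }
      cnt[seq_len(ind$n_obs), g] <- as.integer(tot)
    }
  }

  dedge <- rep(NA_real_, ind$n)
  dedge_max <- config$dedge_max
  if (use_dedge) {
    if (is.null(dataset) || ind$n_obs == 0) {
      if (is.null(dedge_max)) dedge_max <- 18.5
    } else {
      oc <- observed_centres(dataset, registry)
      dedge[seq_len(ind$n_obs)] <- oc$dedge
      if (is.null(dedge_max)) dedge_max <- max(oc$dedge)
      if (dedge_max <= 0) dedge_max <- 1e-3
    }
  } else if (is.null(dedge_max)) dedge_max <- 18.5

  list(data = list(
         n = ind$n, n_obs = ind$n_obs, T = Tn,
         det_yr = det_years(dataset, ind$n, Tn),
         grp_t = gt, grp_s = gs, grp_b = gb, grp_ncells = gn, grp_e = ge,
         grp_cnt = cnt, nb = length(bi$labels), S = ind$S,
         sex_group = ind$sex_group, dedge = dedge),
       beta_labels = bi$labels, dedge_max = dedge_max, n_obs = ind$n_obs,
       n = ind$n, S = ind$S, Tn = Tn)
}

prep_scr_inputs <- function(dataset, registry, config) {
  types <- trap_type_levels(registry)
  K <- dim(registry$effort)[2]; M <- length(types)
  Tn <- length(registry$years); J <- nrow(registry$traps)
  act <- (registry$effort > 0) * 1L
  ind <- prep_individuals(dataset, config$sex_model,
                          default_augment(config))
  act_kmt <- array(0L, dim = c(K, M, Tn))
  for (m in seq_len(M)) {
    js <- which(registry$traps$trap_type == types[m])
    act_kmt[, m, ] <- (apply(act[js, , , drop = FALSE], c(2, 3), max) > 0) * 1L
  }
  bi <- make_beta_index(config$beta_structure, K, M, ind$S,
                        act_kmt > 0, types)

  dets <- matrix(0L, 0, 4)
  centres_init <- matrix(NA_real_, ind$n, 2)
  if (!is.null(dataset) && ind$n_obs > 0) {
    w <- which(dataset$y_spatial == 1L, arr.ind = TRUE)
    dets <- cbind(w[, 1] - 1L, w[, 2] - 1L, w[, 3] - 1L, w[, 4] - 1L)
    oc <- observed_centres(dataset, registry)
    centres_init[seq_len(ind$n_obs), ] <- cbind(oc$x, oc$y)
  }

  bb <- dataset_state_space(dataset, registry, config)
  list(data = list(
         n = ind$n, n_obs = ind$n_obs, T = Tn,
         det_yr = det_years(dataset, ind$n, Tn),
         trapxy = cbind(registry$traps$x_km, registry$traps$y_km),
         trap_type = match(registry$traps$trap_type, types) - 1L,
         act = as.integer(act), bidx = as.integer(bi$bidx),
         K = K, M = M, S = ind$S, nb = length(bi$labels),
         sex_group = ind$sex_group, dets = dets,
         centres_init = centres_init),
       beta_labels = bi$labels, n_obs = ind$n_obs, n = ind$n, S = ind$S,
       Tn = Tn, state_space = bb)
}

# SCR state space: bounding rectangle of the dataset boundary if present,
# otherwise a buffer_km rectangle around the traps
dataset_state_space <- function(dataset, registry, config) {
  if (!is.null(dataset) && !is.null(dataset$boundary)) {
    b <- dataset$boundary
    rect <- cbind(range(b[, 1]), range(b[, 2]))
  } else {
    r <- buffer_rectangle(cbind(registry$traps$x_km, registry$traps$y_km),
                          config$buffer_km)
    rect <- cbind(range(r[, 1]), range(r[, 2]))
  }
  list(xlim = rect[, 1], ylim = rect[, 2],
       area = diff(rect[, 1]) * diff(rect[, 2]))
}

default_augment <- function(config) {
  if (!is.null(config$augment)) return(config$augment)
  if (config$sex_model == "both") 280L else 200L
}

#' Fit an open-population capture-recapture model
#'
#' Runs the data-augmentation Metropolis-within-Gibbs sampler for one of the
#' three model families:
#' `"cr"` (non-spatial, no individual covariates), `"cr_dedge"` (non-spatial
#' with the distance-to-edge covariate and truncated-gamma imputation) or
#' `"scr"` (spatial, half-normal detection from latent activity centres).
#' Priors: logit-scale baselines and the DEDGE slope Uniform(-10, 10); the
#' DEDGE gamma shape and rate Uniform(0, 30); sigma Uniform(0, `sigma_max`);
#' survival, entry probabilities and `p_male` Uniform(0, 1); activity
#' centres uniform on the rectangular state space.
#'
#' @param dataset a [capture_data] object (or `NULL` for a prior-only run).
#' @param registry the matching [trap_registry].
#' @param model `"cr"`, `"cr_dedge"` or `"scr"`.
#' @param config an [mcmc_config()].
#' @return object of class `opcr_fit`: list with per-chain draw matrices
#'   (`draws`), acceptance rates, Gelman-Rubin statistics (`rhat`), the
#'   state-space `area` (km2, SCR), and fitting metadata.
#' @export
run_mcmc <- function(dataset, registry, model = c("cr", "cr_dedge", "scr"),
                     config = mcmc_config()) {
  model <- match.arg(model)
  if (!is.null(dataset) && config$sex_model %in% c("female", "male")) {
    dataset <- subset_sex(dataset, if (config$sex_model == "female") "F" else "M")
  }
  n_iter <- config$n_iter
  cycles_used <- 0L
  repeat {
    fit <- run_mcmc_once(dataset, registry, model, config, n_iter)
    fit$cycles_used <- cycles_used
    key <- fit$rhat[!is.na(fit$rhat)]
    if (!length(key) || max(key) < config$rhat_threshold ||
        cycles_used >= config$max_cycles) {
      fit$converged <- !length(key) || max(key) < config$rhat_threshold
      return(fit)
    }
    n_iter <- n_iter + config$cycle_iter
    cycles_used <- cycles_used + 1L
  }
}

run_mcmc_once <- function(dataset, registry, model, config, n_iter) {
  Tn <- length(registry$years)
  if (model %in% c("cr", "cr_dedge")) {
    use_dedge <- model == "cr_dedge"
    prep <- prep_cr_inputs(dataset, registry, config, use_dedge)
    cfg <- list(n_iter = n_iter, n_burnin = config$n_burnin,
                use_dedge = use_dedge, dedge_max = prep$dedge_max,
                ft_thin = config$ft_thin, z_thin = config$z_thin)
    parnames <- c(paste0("beta[", prep$beta_labels, "]"),
                  "beta_dedge", "shape_dedge", "rate_dedge", "p_male",
                  if (Tn > 1) paste0("phi[", seq_len(Tn - 1), "]"),
                  paste0("gamma[", seq_len(Tn), "]"),
                  paste0("N[", seq_len(Tn), "]"),
                  paste0("B[", seq_len(Tn), "]"), "T_obs", "T_rep")
    runner <- function() .cr_chain_cpp(prep$data, cfg)
    area <- NA_real_
  } else {
    prep <- prep_scr_inputs(dataset, registry, config)
    sbs <- config$sigma_by_sex
    if (is.null(sbs)) sbs <- prep$S > 1
    cfg <- list(n_iter = n_iter, n_burnin = config$n_burnin,
                sigma_by_sex = sbs, sigma_max = config$sigma_max,
                xlo = prep$state_space$xlim[1], xhi = prep$state_space$xlim[2],
                ylo = prep$state_space$ylim[1], yhi = prep$state_space$ylim[2],
                ft_thin = config$ft_thin, centre_thin = config$centre_thin,
                z_thin = config$z_thin)
    nsig <- if (sbs) prep$S else 1L
    signames <- if (nsig == 2) c("sigma[F]", "sigma[M]") else "sigma"
    parnames <- c(paste0("g0_logit[", prep$beta_labels, "]"), signames,
                  "p_male",
                  if (Tn > 1) paste0("phi[", seq_len(Tn - 1), "]"),
                  paste0("gamma[", seq_len(Tn), "]"),
                  paste0("N[", seq_len(Tn), "]"),
                  paste0("B[", seq_len(Tn), "]"), "T_obs", "T_rep")
    runner <- function() .scr_chain_cpp(prep$data, cfg)
    area <- prep$state_space$area
  }

  draws <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  centres <- vector("list", config$n_chains)
  zdraws <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    res <- runner()
    d <- res$draws
    colnames(d) <- parnames
    draws[[ch]] <- d
    accept[[ch]] <- res$accept
    if (!is.null(res$centres)) centres[[ch]] <- res$centres
    if (!is.null(res$z)) zdraws[[ch]] <- res$z
  }

  rhat <- if (config$n_chains >= 2) {
    gelman_rubin(lapply(draws, function(d) {
      d[, !colnames(d) %in% c("T_obs", "T_rep"), drop = FALSE]
    }))
  } else NA_real_
  structure(list(
    model = model, draws = draws, accept = accept, rhat = rhat,
    area = area, years = registry$years, n_obs = prep$n_obs,
    n_augmented = prep$n - prep$n_obs, sex_model = config$sex_model,
    config = config, n_iter = n_iter, centres = centres, z = zdraws,
    beta_labels = prep$beta_labels),
    class = "opcr_fit")
}

#' @export
print.opcr_fit <- function(x, ...) {
  cat("opcr_fit:", x$model, "model,", x$sex_model, "sex model,",
      length(x$draws), "chains x", nrow(x$draws[[1]]), "kept iterations\n")
  cat("  individuals:", x$n_obs, "detected +", x$n_augmented, "augmented\n")
  if (!is.na(x$area)) cat("  state-space area:", round(x$area), "km^2\n")
  rr <- x$rhat[!is.na(x$rhat)]
  if (length(rr)) cat("  max Gelman-Rubin:", round(max(rr), 3), "\n")
  invisible(x)
}

#' Combined posterior draws of a fit
#' @param fit an `opcr_fit`.
#' @return matrix with all chains stacked.
#' @export
posterior_matrix <- function(fit) do.call(rbind, fit$draws)

#' One full-conditional draw of the latent alive states
#'
#' Reference implementation of the forward-filter backward-sample update
#' used inside the compiled chains. Each individual's state path over years
#' moves through not-yet-entered -> alive -> dead; entry happens with
#' probability `gamma[t]` (only for individuals never yet alive, the
#' availability rule), survival with `phi[t]`. Detected individual-years are
#' pinned alive; undetected years weigh the all-zero history likelihood.
#'
#' @param ll1 matrix `[n, T]`: log-likelihood of each individual-year's
#'   detection history given the animal is alive.
#' @param detected matrix `[n, T]` of 0/1 detection indicators.
#' @param phi survival probabilities, length `T - 1`.
#' @param gamma entry probabilities, length `T`.
#' @return list with `alive` (`[n, T]` 0/1) and `state` (`[n, T]` in
#'   `{"available", "alive", "dead"}` coded 0/1/2).
#' @export
update_alive_states <- function(ll1, detected, phi, gamma) {
  n <- nrow(ll1); Tn <- ncol(ll1)
  stopifnot(length(gamma) == Tn, length(phi) >= Tn - 1)
  state <- matrix(0L, n, Tn)
  for (i in seq_len(n)) {
    fwd <- matrix(0, 3, Tn)
    for (t in seq_len(Tn)) {
      if (detected[i, t] == 1) e <- c(0, 1, 0)
      else {
        shift <- max(0, ll1[i, t])
        e <- c(exp(-shift), exp(ll1[i, t] - shift), exp(-shift))
      }
      if (t == 1) f <- c((1 - gamma[1]) * e[1], gamma[1] * e[2], 0)
      else {
        p <- fwd[, t - 1]
        f <- c(p[1] * (1 - gamma[t]) * e[1],
               (p[1] * gamma[t] + p[2] * phi[t - 1]) * e[2],
               (p[2] * (1 - phi[t - 1]) + p[3]) * e[3])
      }
      fwd[, t] <- f / sum(f)
    }
    state[i, Tn] <- sample.int(3, 1, prob = fwd[, Tn]) - 1L
    for (t in seq(Tn - 1, length.out = Tn - 1, by = -1)) {
      w <- switch(state[i, t + 1] + 1L,
                  c(fwd[1, t] * (1 - gamma[t + 1]), 0, 0),
                  c(fwd[1, t] * gamma[t + 1], fwd[2, t] * phi[t], 0),
                  c(0, fwd[2, t] * (1 - phi[t]), fwd[3, t]))
      state[i, t] <- sample.int(3, 1, prob = w) - 1L
    }
  }
  list(alive = (state == 1L) * 1L, state = state)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within-chain variance ratio, computed per parameter
#' column. Parameters that are constant across all chains return 1 (a
#' degenerate chain has converged trivially).
#'
#' @param chains list of equal-dimension draw matrices (>= 2 chains), or a
#'   list of numeric vectors for a single parameter.
#' @return named vector of PSRF values.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("gelman_rubin needs at least 2 chains")
  if (is.null(dim(chains[[1]]))) chains <- lapply(chains, as.matrix)
  nr <- vapply(chains, nrow, 1L)
  if (length(unique(nr)) != 1) stop("chains must have equal length")
  n <- nr[1]; m <- length(chains)
  p <- ncol(chains[[1]])
  out <- numeric(p)
  names(out) <- colnames(chains[[1]])
  for (j in seq_len(p)) {
    xs <- vapply(chains, function(d) d[, j], numeric(n))
    W <- mean(apply(xs, 2, var))
    B_n <- var(colMeans(xs))              # B/n
    if (!is.finite(W) || W < 1e-300) { out[j] <- 1.0; next }
    vhat <- (n - 1) / n * W + B_n * (1 + 1 / m)
    out[j] <- sqrt(vhat / W)
  }
  out
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples.
#'
#' @param samples numeric vector of posterior draws.
#' @param mass interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0) stop("hpd_interval: no samples")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  w <- x[seq(m, n)] - x[seq_len(n - m + 1)]
  i <- which.min(w)
  c(x[i], x[i + m - 1])
}

#' Bayesian posterior predictive P-value (Freeman-Tukey)
#'
#' The chains record, on a thinned schedule, the summed Freeman-Tukey
#' discrepancies of the observed data and of data replicated from the
#' current parameters. The P-value is `Pr(T_obs > T_rep)`; values below
#' 0.05 or above 0.95 flag lack of fit.
#'
#' @param fit an `opcr_fit` with Freeman-Tukey recording enabled.
#' @return list with `p_value` and logical `lack_of_fit`.
#' @export
bayes_pvalue <- function(fit) {
  d <- posterior_matrix(fit)
  ok <- is.finite(d[, "T_obs"]) & is.finite(d[, "T_rep"])
  if (!any(ok)) stop("fit was run with ft_thin = 0; no discrepancies recorded")
  p <- mean(d[ok, "T_obs"] > d[ok, "T_rep"])
  list(p_value = p, lack_of_fit = p < 0.05 || p > 0.95)
}
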