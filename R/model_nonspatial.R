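# Non-spatial (CR / CR_dedge) observation model.
#
# Detection of individual i at trap type m on occasion k in year t, given the
# animal is alive, is Bernoulli with
#   logit(p_ikm) = beta[k, m, sex_i] + beta_dedge * DEDGE_i
# scaled for survey effort by a proportional-hazard transform
#   p_eff = 1 - (1 - p)^(NDays_kmt / ReferenceDays_m).
# The plain CR variant fixes beta_dedge = 0 and drops the DEDGE imputation.

#' Proportional-hazard effort scaling of a detection probability
#'
#' Scales a per-occasion baseline detection probability by active trap-days:
#' `1 - (1 - p)^(n_days / reference_days)`. The result is 0 when `n_days`
#' is 0 and approaches 1 as effort grows.
#'
#' @param p_base baseline detection probability in `[0, 1]`.
#' @param n_days nonnegative active trap-days.
#' @param reference_days positive reference trap-days for the trap type.
#' @return scaled probability, same length as the longest argument.
#' @export
effort_scaled_p <- function(p_base, n_days, reference_days) {
  if (any(p_base < 0 | p_base > 1)) stop("p_base must be in [0, 1]")
  if (any(n_days < 0)) stop("n_days must be nonnegative")
  if (any(reference_days <= 0)) stop("reference_days must be positive")
  1 - (1 - p_base)^(n_days / reference_days)
}

#' Cumulative detection probability across trap types
#'
#' Probability of at least one detection within a sampling occasion given
#' independent per-type probabilities: `1 - prod(1 - p)`.
#'
#' @param p_by_type vector of per-trap-type detection probabilities.
#' @return scalar probability.
#' @export
cumulative_detection_p <- function(p_by_type) {
  if (any(p_by_type < 0 | p_by_type > 1)) stop("probabilities must be in [0, 1]")
  1 - prod(1 - p_by_type)
}

#' Per-cell detection probability of the non-spatial model
#'
#' Inverse-logit of the linear predictor `beta + beta_dedge * dedge`, then
#' effort-scaled via [effort_scaled_p()].
#'
#' @param beta logit-scale baseline for the trap type / occasion / sex cell.
#' @param beta_dedge logit-scale slope on distance to edge (0 for plain CR).
#' @param dedge distance from home-range centre to study-area edge, km.
#' @param n_days,reference_days effort scaling inputs.
#' @return detection probability.
#' @export
detection_p <- function(beta, beta_dedge = 0, dedge = 0, n_days = 1,
                        reference_days = 1) {
  effort_scaled_p(plogis(beta + beta_dedge * dedge), n_days, reference_days)
}

#' Truncated-gamma draws of the distance-to-edge covariate
#'
#' Draws `n` values from `Gamma(shape, rate)` truncated to `[0, upper]`,
#' used to impute DEDGE for augmented (never-detected) individuals. Sampling
#' is by rejection; when the acceptance probability `P(X <= upper)` falls
#' below 5% the sampler switches to the inverse-CDF construction, so draws
#' are always produced.
#'
#' @param shape,rate gamma parameters (> 0).
#' @param n number of draws.
#' @param upper truncation point, km (maximum observed DEDGE; 18.5 in the
#'   grizzly application).
#' @param seed optional integer seed.
#' @return numeric vector of `n` draws, all `<= upper`.
#' @export
impute_dedge <- function(shape, rate, n, upper = 18.5, seed = NULL) {
  stopifnot(shape > 0, rate > 0, upper > 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  acc <- pgamma(upper, shape, rate)
  if (acc < 0.05) {
    return(qgamma(runif(n) * acc, shape, rate))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rgamma(ceiling((n - length(out)) / acc) + 8, shape, rate)
    out <- c(out, draw[draw <= upper])
  }
  out[seq_len(n)]
}

# log-density of the truncated gamma prior on [0, upper]
dtruncgamma_log <- function(x, shape, rate, upper) {
  ifelse(x >= 0 & x <= upper,
         dgamma(x, shape, rate, log = TRUE) -
           pgamma(upper, shape, rate, log.p = TRUE),
         -Inf)
}

# total trap-days by occasion x type x year for a registry
ndays_by_type <- function(registry) {
  types <- trap_type_levels(registry)
  K <- dim(registry$effort)[2]; Tn <- length(registry$years)
  nd <- array(0, dim = c(K, length(types), Tn))
  for (m in seq_along(types)) {
    js <- which(registry$traps$trap_type == types[m])
    nd[, m, ] <- apply(registry$effort[js, , , drop = FALSE], c(2, 3), sum)
  }
  nd
}

#' Log-likelihood of the non-spatial observation model
#'
#' Sums Bernoulli log-mass of the per-trap-type detection histories over
#' individual-years with `z = 1`; individual-years with `z = 0` contribute
#' nothing but must have all-zero histories.
#'
#' @param params list with `beta` (array `[K, M, S]` of logit baselines, `S`
#'   the number of sex groups), `beta_dedge` (scalar), `dedge` (per
#'   individual, km) and `sex_group` (1-based index per individual).
#' @param z matrix `[n, T]` of alive indicators covering every individual in
#'   `dataset` (augmented individuals included, in the same order).
#' @param dataset a [capture_data] object (its `y_nonspatial` view is used);
#'   augmented all-zero individuals may be represented by extra `z` rows
#'   beyond `nrow(dataset$individuals)`.
#' @param registry the matching [trap_registry] (effort and reference days).
#' @return scalar log-likelihood.
#' @export
cr_log_likelihood <- function(params, z, dataset, registry) {
  y <- dataset$y_nonspatial
  n_obs <- dim(y)[1]; K <- dim(y)[2]; M <- dim(y)[3]; Tn <- dim(y)[4]
  n <- nrow(z)
  stopifnot(n >= n_obs, ncol(z) == Tn)
  nd <- ndays_by_type(registry)
  ref <- registry$reference_days[trap_type_levels(registry)]
  ll <- 0
  for (i in seq_len(n)) {
    yi <- if (i <= n_obs) y[i, , , , drop = FALSE] else
      array(0L, dim = c(1, K, M, Tn))
    s <- params$sex_group[i]
    for (t in seq_len(Tn)) {
      if (z[i, t] == 0) {
        if (sum(yi[1, , , t]) > 0) {
          stop("impossible state: individual ", i,
               " has detections in year ", t, " but z = 0")
        }
        next
      }
      for (m in seq_len(M)) {
        for (k in seq_len(K)) {
          e <- nd[k, m, t] / ref[m]
          if (e <= 0) next
          p <- plogis(params$beta[k, m, s] +
                        params$beta_dedge * params$dedge[i])
          peff <- 1 - (1 - p)^e
          ll <- ll + ifelse(yi[1, k, m, t] == 1, log(peff), log1p(-peff))
        }
      }
    }
  }
  unname(ll)
}
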