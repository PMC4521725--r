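# Spatial (SCR) observation model: latent activity centres on a buffered
# rectangular state space, half-normal distance decay of detection.

#' Half-normal detection probability
#'
#' `g0 * exp(-d^2 / (2 sigma^2))`: detection probability at distance `d`
#' from the activity centre, with baseline `g0` at the centre and spatial
#' scale `sigma` (km).
#'
#' @param distance nonnegative distance(s), km.
#' @param g0 baseline detection probability in `[0, 1]`.
#' @param sigma positive scale, km.
#' @return probability (vectorised over `distance`).
#' @export
halfnormal_p <- function(distance, g0, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(g0 < 0 | g0 > 1)) stop("g0 must be in [0, 1]")
  if (any(distance < 0)) stop("distance must be nonnegative")
  g0 * exp(-distance^2 / (2 * sigma^2))
}

#' Log-likelihood of the SCR observation model
#'
#' Sums Bernoulli log-mass over active trap-occasion cells for every
#' individual-year with `z = 1`, with per-cell probability
#' `halfnormal_p(d_ij, g0[k, m, s], sigma_s)`. Detections at inactive cells
#' are an error.
#'
#' @param params list with `g0` (array `[K, M, S]` of baseline detection
#'   probabilities by occasion, trap type and sex group), `sigma` (length-`S`
#'   vector, km), `centres` (`[n, 2]` activity centres) and `sex_group`
#'   (1-based, per individual).
#' @param z matrix `[n, T]` of alive indicators (augmented rows may extend
#'   beyond the observed individuals).
#' @param dataset a [capture_data] object (its `y_spatial` view is used).
#' @param registry the matching [trap_registry].
#' @param activity_mask optional logical array `[J, K, T]`; defaults to
#'   `registry$effort > 0`.
#' @return scalar log-likelihood.
#' @export
scr_log_likelihood <- function(params, z, dataset, registry,
                               activity_mask = NULL) {
  y <- dataset$y_spatial
  n_obs <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; Tn <- dim(y)[4]
  n <- nrow(z)
  stopifnot(n >= n_obs, ncol(z) == Tn, nrow(params$centres) == n)
  if (is.null(activity_mask)) activity_mask <- registry$effort > 0
  types <- trap_type_levels(registry)
  mj <- match(registry$traps$trap_type, types)
  xy <- cbind(registry$traps$x_km, registry$traps$y_km)
  ll <- 0
  for (i in seq_len(n)) {
    s <- params$sex_group[i]
    d <- sqrt((params$centres[i, 1] - xy[, 1])^2 +
              (params$centres[i, 2] - xy[, 2])^2)
    for (t in seq_len(Tn)) {
      yit <- if (i <= n_obs) matrix(y[i, , , t], J, K) else matrix(0L, J, K)
      if (z[i, t] == 0) {
        if (sum(yit) > 0) {
          stop("impossible state: individual ", i,
               " has detections in year ", t, " but z = 0")
        }
        next
      }
      for (j in seq_len(J)) {
        for (k in seq_len(K)) {
          if (!activity_mask[j, k, t]) {
            if (yit[j, k] == 1) {
              stop("detection at inactive trap-occasion (trap ", j,
                   ", occasion ", k, ", year ", t, ")")
            }
            next
          }
          p <- halfnormal_p(d[j], params$g0[k, mj[j], s], params$sigma[s])
          ll <- ll + ifelse(yit[j, k] == 1, log(p), log1p(-p))
        }
      }
    }
  }
  unname(ll)
}

#' Random-walk proposal for a latent activity centre
#'
#' Symmetric Gaussian random-walk proposal on a rectangular state space.
#' Proposals falling outside the rectangle are rejected by returning the
#' current point (an ordinary Metropolis rejection against the uniform
#' prior's zero density outside), so the stationary prior remains uniform
#' on the rectangle and proposals never lie outside the bounds.
#'
#' @param current length-2 point inside the state space.
#' @param step proposal standard deviation, km.
#' @param state_space list with `xlim`, `ylim` (each length-2).
#' @param seed optional integer seed.
#' @return list with `point` (length-2) and `accepted_bounds` (logical,
#'   FALSE when the proposal fell outside and the current point is kept).
#' @export
propose_centre <- function(current, step, state_space, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prop <- current + rnorm(2, 0, step)
  inside <- prop[1] >= state_space$xlim[1] && prop[1] <= state_space$xlim[2] &&
            prop[2] >= state_space$ylim[1] && prop[2] <= state_space$ylim[2]
  if (!inside) {
    return(list(point = current, accepted_bounds = FALSE))
  }
  list(point = prop, accepted_bounds = TRUE)
}
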