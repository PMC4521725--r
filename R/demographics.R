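# Derived demographic quantities from posterior draws.
#
# Per retained iteration the chains record N_t (animals alive), B_t (first
# entries) and phi_t. Per-capita recruitment for the transition into year t
# is R_t = B_t / N_{t-1}; population growth over that transition is
# lambda_t = phi_{t-1->t} + R_t; multi-year averages are geometric means
# over the year transitions, taken within each MCMC iteration.

#' Derive demographic quantities from posterior draws
#'
#' @param fit an `opcr_fit`, or a matrix of stacked draws containing
#'   `N[t]`, `B[t]` and `phi[t]` columns.
#' @param area state-space area in km2 (defaults to the fit's area; density
#'   columns are omitted when unavailable).
#' @param density_scale density reporting scale in km2 (default 1000, i.e.
#'   animals per 1000 km2).
#' @return matrix with one row per draw: per-transition `R[t]`, `lambda[t]`,
#'   geometric-mean `phi_avg`, `R_avg`, `lambda_avg`, the per-draw mean
#'   abundance `N_avg`, and (given an area) densities `D[t]` and `D_avg`.
#'   Draws where some `N_{t-1}` is zero yield `NA` recruitment (never a
#'   division by zero).
#' @export
derive_demographics <- function(fit, area = NULL, density_scale = 1000) {
  d <- if (inherits(fit, "opcr_fit")) posterior_matrix(fit) else fit
  if (is.null(area) && inherits(fit, "opcr_fit")) area <- fit$area
  ncol_of <- function(stub) sum(grepl(paste0("^", stub, "\\["), colnames(d)))
  Tn <- ncol_of("N")
  if (Tn < 2) stop("derive_demographics needs at least 2 years")
  N <- d[, paste0("N[", seq_len(Tn), "]"), drop = FALSE]
  B <- d[, paste0("B[", seq_len(Tn), "]"), drop = FALSE]
  phi <- d[, paste0("phi[", seq_len(Tn - 1), "]"), drop = FALSE]

  R <- B[, -1, drop = FALSE] / N[, -Tn, drop = FALSE]
  R[N[, -Tn, drop = FALSE] == 0] <- NA_real_
  lambda <- phi + R
  gm <- function(x) exp(rowMeans(log(x)))
  out <- cbind(R, lambda,
               phi_avg = gm(phi), R_avg = gm(R), lambda_avg = gm(lambda),
               N_avg = rowMeans(N))
  colnames(out)[seq_len(2 * (Tn - 1))] <-
    c(paste0("R[", 2:Tn, "]"), paste0("lambda[", 2:Tn, "]"))
  if (!is.null(area) && is.finite(area)) {
    D <- N / area * density_scale
    colnames(D) <- paste0("D[", seq_len(Tn), "]")
    out <- cbind(out, D, D_avg = rowMeans(D))
  }
  out
}

#' Posterior summary table
#'
#' Median, 95% highest-posterior-density interval and coefficient of
#' variation (posterior SD / posterior mean x 100) per parameter, in the
#' layout used for demographic reporting.
#'
#' @param draws matrix of posterior draws (columns = parameters), an
#'   `opcr_fit`, or the output of [derive_demographics()].
#' @param mass HPD mass (default 0.95).
#' @param model,sex optional labels prepended as columns.
#' @return data.frame with columns `model`, `sex`, `parameter`, `median`,
#'   `hpd_lower`, `hpd_upper`, `cv`.
#' @export
summarize_posterior <- function(draws, mass = 0.95, model = "", sex = "") {
  if (inherits(draws, "opcr_fit")) {
    if (!nzchar(model)) model <- draws$model
    if (!nzchar(sex)) sex <- draws$sex_model
    draws <- posterior_matrix(draws)
  }
  draws <- as.matrix(draws)
  rows <- lapply(colnames(draws), function(p) {
    x <- draws[, p]
    x <- x[is.finite(x)]
    if (!length(x)) {
      return(data.frame(model = model, sex = sex, parameter = p,
                        median = NA_real_, hpd_lower = NA_real_,
                        hpd_upper = NA_real_, cv = NA_real_))
    }
    h <- hpd_interval(x, mass)
    mu <- mean(x)
    data.frame(model = model, sex = sex, parameter = p,
               median = median(x), hpd_lower = h[1], hpd_upper = h[2],
               cv = if (abs(mu) > 1e-300) 100 * sd(x) / mu else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demographic summary of a fitted model
#'
#' Convenience wrapper: derives the demographic quantities and returns the
#' posterior summary table for survival, recruitment, growth, abundance and
#' (SCR) density.
#'
#' @param fit an `opcr_fit`.
#' @param density_scale density reporting scale in km2 (default 1000).
#' @return data.frame as in [summarize_posterior()].
#' @export
demographic_summary <- function(fit, density_scale = 1000) {
  dem <- derive_demographics(fit, density_scale = density_scale)
  d <- posterior_matrix(fit)
  keep_dem <- c("phi_avg", "R_avg", "lambda_avg", "N_avg",
                if ("D_avg" %in% colnames(dem)) "D_avg")
  Tn <- sum(grepl("^N\\[", colnames(d)))
  keep_raw <- c(paste0("N[", seq_len(Tn), "]"),
                if (Tn > 1) paste0("phi[", seq_len(Tn - 1), "]"),
                grep("^sigma", colnames(d), value = TRUE))
  summarize_posterior(cbind(dem[, keep_dem, drop = FALSE],
                            d[, keep_raw, drop = FALSE]),
                      model = fit$model, sex = fit$sex_model)
}
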