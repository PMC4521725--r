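# Shared fixtures and independent oracles (built in code, no stored data).

# -- a small 3-type registry: 2 hair traps, 2 bear rubs, 1 crossing,
#    2 years, ragged occasions (hair active occasions 1-2, rubs 1-3,
#    crossing 1-4), unit "active trap" effort
tiny_registry <- function() {
  traps <- data.frame(
    trap_id = c("h1", "h2", "r1", "r2", "x1"),
    trap_type = c("hair_trap", "hair_trap", "bear_rub", "bear_rub",
                  "highway_crossing"),
    x_km = c(2, 6, 1, 7, 4), y_km = c(2, 2, 6, 6, 4))
  eff <- array(0, dim = c(5, 4, 2),
               dimnames = list(traps$trap_id, NULL, 1:2))
  eff[1:2, 1:2, ] <- 1
  eff[3:4, 1:3, ] <- 1
  eff[5, 1:4, ] <- 1
  trap_registry(traps, eff, years = 1:2,
                reference_days = c(hair_trap = 2, bear_rub = 3,
                                   highway_crossing = 4))
}

tiny_detections <- function() {
  data.frame(
    individual_id = c("a", "a", "a", "b", "b", "c"),
    sex = c("F", "F", "F", "M", "M", "F"),
    year = c(1, 1, 2, 1, 2, 2),
    occasion = c(1, 1, 3, 2, 4, 2),
    trap_id = c("h1", "h2", "r1", "r2", "x1", "h2"))
}

tiny_dataset <- function() {
  capture_data(tiny_detections(), tiny_registry(), boundary = "buffer:5")
}

# -- single-type one-trap registry for scalar-probability checks
unit_registry <- function(K = 1, years = 1, ref = 1, days = 1) {
  traps <- data.frame(trap_id = "t1", trap_type = "generic",
                      x_km = 0, y_km = 0)
  eff <- array(days, dim = c(1, K, years),
               dimnames = list("t1", NULL, seq_len(years)))
  trap_registry(traps, eff, years = seq_len(years),
                reference_days = c(generic = ref))
}

# -- independent brute-force CR likelihood: expand every cell, use dbinom
cr_ll_brute <- function(params, z, dataset, registry) {
  y <- dataset$y_nonspatial
  types <- c("bear_rub", "hair_trap", "highway_crossing", "generic")
  types <- types[types %in% unique(registry$traps$trap_type)]
  K <- dim(y)[2]; M <- dim(y)[3]; Tn <- dim(y)[4]
  n <- nrow(z); n_obs <- dim(y)[1]
  ll <- 0
  for (i in seq_len(n)) for (t in seq_len(Tn)) {
    if (z[i, t] == 0) next
    for (m in seq_len(M)) for (k in seq_len(K)) {
      js <- which(registry$traps$trap_type == types[m])
      nd <- sum(registry$effort[js, k, t])
      if (nd == 0) next
      e <- nd / registry$reference_days[[types[m]]]
      p <- plogis(params$beta[k, m, params$sex_group[i]] +
                    params$beta_dedge * params$dedge[i])
      peff <- 1 - (1 - p)^e
      yv <- if (i <= n_obs) y[i, k, m, t] else 0L
      ll <- ll + dbinom(yv, 1, peff, log = TRUE)
    }
  }
  ll
}

# -- independent brute-force SCR likelihood
scr_ll_brute <- function(params, z, dataset, registry) {
  y <- dataset$y_spatial
  types <- c("bear_rub", "hair_trap", "highway_crossing", "generic")
  types <- types[types %in% unique(registry$traps$trap_type)]
  J <- dim(y)[2]; K <- dim(y)[3]; Tn <- dim(y)[4]
  n <- nrow(z); n_obs <- dim(y)[1]
  ll <- 0
  for (i in seq_len(n)) for (t in seq_len(Tn)) {
    if (z[i, t] == 0) next
    for (j in seq_len(J)) for (k in seq_len(K)) {
      if (registry$effort[j, k, t] <= 0) next
      d <- sqrt((params$centres[i, 1] - registry$traps$x_km[j])^2 +
                (params$centres[i, 2] - registry$traps$y_km[j])^2)
      m <- match(registry$traps$trap_type[j], types)
      s <- params$sex_group[i]
      p <- params$g0[k, m, s] * exp(-d^2 / (2 * params$sigma[s]^2))
      yv <- if (i <= n_obs) y[i, j, k, t] else 0L
      ll <- ll + dbinom(yv, 1, p, log = TRUE)
    }
  }
  ll
}

# random small CR/SCR fixture on the tiny registry (detections drawn first,
# dataset rebuilt from the resulting event table)
random_tiny_fixture <- function(seed, n_ind = 4) {
  set.seed(seed)
  reg <- tiny_registry()
  ids <- letters[seq_len(n_ind)]
  sexes <- sample(c("F", "M"), n_ind, replace = TRUE)
  ev <- list()
  for (i in seq_len(n_ind)) {
    for (t in 1:2) for (j in 1:5) for (k in 1:4) {
      if (reg$effort[j, k, t] > 0 && runif(1) < 0.25) {
        ev[[length(ev) + 1L]] <- data.frame(
          individual_id = ids[i], sex = sexes[i], year = t, occasion = k,
          trap_id = reg$traps$trap_id[j])
      }
    }
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev)) return(NULL)
  list(registry = reg,
       dataset = capture_data(ev, reg, boundary = "buffer:5"))
}

# -- exact path posterior for the single-augmented-individual two-year toy:
#    one never-detected individual, K occasions/year with effort exponent 1,
#    single baseline beta ~ U(-10, 10), phi/gamma ~ U(0, 1).
#    Returns probabilities of the (z1, z2) paths 00, 01, 10, 11.
toy_path_posterior <- function(K) {
  lik_alive_years <- function(a) {
    if (a == 0) return(1)
    integrate(function(b) (1 - plogis(b))^(K * a) / 20,
              lower = -10, upper = 10)$value
  }
  # uniform phi/gamma integrate to 1/2 per Bernoulli factor for every path
  w <- c(`00` = lik_alive_years(0), `01` = lik_alive_years(1),
         `10` = lik_alive_years(1), `11` = lik_alive_years(2)) / 4
  w / sum(w)
}

# z-path frequencies of a fitted toy model (n = 1 individual)
toy_path_frequencies <- function(fit) {
  z <- do.call(rbind, fit$z)  # columns: (i=1,t=1), (i=1,t=2)
  key <- paste0(z[, 1], z[, 2])
  tab <- table(factor(key, levels = c("00", "01", "10", "11")))
  as.numeric(tab) / sum(tab)
}
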