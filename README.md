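# opcr — open-population spatial and non-spatial capture–recapture

`opcr` estimates demographic parameters of wildlife populations from
multi-year detection histories of individually identified animals — the kind
of data produced by DNA hair-snag monitoring of bears and other wide-ranging
carnivores. It is written for quantitative ecologists and monitoring
programs that need abundance, density, apparent survival (φ), per-capita
recruitment (R) and population growth (λ = φ + R) with full posterior
uncertainty, and that want to compare non-spatial and spatial estimators on
the same data.

## Models

All models are open-population (Jolly–Seber type) with Bayesian data
augmentation: the detected animals are padded with all-zero
pseudo-individuals and a latent yearly alive indicator

> z_it ~ Bernoulli( φ_t · z_{i,t−1} + γ_t · (1 − z_{i,t−1}) ),

with recruitment restricted to never-yet-alive individuals (no re-entry).
Abundance N_t is the number of alive individuals per year; R_t = B_t /
N_{t−1} from the first-entry counts B_t; averages across year transitions
are per-iteration geometric means. Three detection sub-models are available:

* **CR** — non-spatial: logit(p_km) = β_mk per trap type m and occasion k
  (plus sex effects), effort-scaled by the proportional-hazard transform
  p_eff = 1 − (1 − p)^(NDays/ReferenceDays);
* **CR_dedge** — CR plus a distance-to-study-area-edge covariate
  logit(p_ikm) = β_mk + β_dedge · DEDGE_i, with DEDGE imputed from a
  truncated Gamma(shape, rate) for augmented individuals;
* **SCR** — spatial: latent activity centres s_i on a buffered state space
  and half-normal detection p_ijk = g0_km · exp(−d_ij² / 2σ²), with
  sex-specific σ in combined-sex fits.

Sampling is Metropolis-within-Gibbs with compiled (Rcpp) cores:
forward-filter/backward-sample updates for the alive states, conjugate Beta
draws for φ_t and γ_t, adaptive random-walk Metropolis for detection
parameters, and a Freeman–Tukey posterior predictive check. A calibrated
simulator generates both a square-grid scenario design and a grizzly-like
three-detector design, and `run_simulation_study()` scores bias,
credible-interval coverage and power across scenarios. See the vignette
(`vignettes/open-population-capture-recapture.Rmd`) for the full model
account and design choices.

## Worked example

Simulate the high-density / high-detection scenario (10 × 10 trap grid,
spacing = σ = 1 km, D = 1 animal/km², g0 = 0.5, φ = 0.8, R = 0.1, three
years of five occasions) and fit the spatial model:

```r
library(opcr)
sim <- simulate_scenario(scenario_config(density = 1.0, g0 = 0.5), seed = 11)
fit <- run_mcmc(sim$dataset, sim$traps, model = "scr",
                config = mcmc_config(n_chains = 3, n_iter = 3000,
                                     n_burnin = 1000, augment = 150,
                                     sex_model = "none",
                                     beta_structure = "constant", seed = 5))
demographic_summary(fit, density_scale = 1)
```

```
   model  sex  parameter   median hpd_lower hpd_upper     cv
1    scr none    phi_avg   0.7961    0.7505    0.8406  2.920
2    scr none      R_avg   0.0819    0.0652    0.0994 10.706
3    scr none lambda_avg   0.8853    0.8357    0.9291  2.733
4    scr none      N_avg 175.3333  168.0000  183.0000  2.217
5    scr none      D_avg   0.8946    0.8571    0.9337  2.217
6    scr none       N[1] 199.0000  189.0000  208.0000  2.459
...
11   scr none      sigma   1.0039    0.9890    1.0214  0.846
```

The generating values were φ = 0.8, R = 0.1, λ = 0.9, σ = 1 km and true
abundances N = (196, 177, 160): the posterior medians recover survival,
growth, the detection scale and yearly abundance closely, with recruitment
slightly low in this single realisation (truth 0.1 against an HPD of
0.065–0.099 — individual replicates scatter; the simulation study averages
over many). `bayes_pvalue(fit)` gives the goodness-of-fit check, and
`gelman_rubin()` / `hpd_interval()` the convergence and interval
diagnostics (here max R̂ = 1.008).

The same interface fits the non-spatial models (`model = "cr"` or
`"cr_dedge"`) and multi-detector data from `simulate_grizzly_design()` or
from delimited files via `read_dataset()`.

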