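#' Configuration for the synthetic river-monitoring data generator
#'
#' Describes a stylized year of monthly benthic sampling at several stations
#' on a small, unpolluted river: seasonal physicochemical cycles (temperature
#' peaking in mid-summer, discharge in April, conductivity in autumn),
#' dissolved oxygen as a decreasing affine function of temperature (a strong
#' negative T-DO correlation), TDS as an exact multiple of EC (perfect
#' collinearity), and a planted functional link from the environment to the
#' Margalef diversity of the invertebrate community, used for recovery
#' testing of the symbolic-regression pipeline.
#'
#' @param n_stations Number of sampling stations (default 6).
#' @param n_months Number of consecutive monthly samples per station
#'   (default 12, a full calendar year starting in January).
#' @param taxon_pool Number of taxa that can possibly occur (default 30).
#' @param env_means Named numeric vector of seasonal baselines for
#'   `temperature` (deg C), `discharge_q` (flow units), `ph`, `ec`
#'   (umhos/cm) and `bod5` (mg/L).
#' @param env_amplitudes Named numeric vector of annual sinusoid amplitudes
#'   for the same five variables (same units).
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   planted Margalef target (dimensionless, default 0.05).
#' @param planted_formula Ground-truth map from environment to target
#'   Margalef value: `"margalef_eq"` (default) is
#'   DO/T + 2 DO/(T + EC + BOD5); `"do_over_t"` is DO/T.
#' @param tds_ec_ratio Fixed TDS/EC proportionality constant
#'   (mg cm / (L umhos), default 0.64).
#' @param seed Integer random seed; identical seed and configuration give
#'   bit-identical output.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_stations = 6L,
                             n_months = 12L,
                             taxon_pool = 30L,
                             env_means = c(temperature = 19, discharge_q = 4,
                                           ph = 7.8, ec = 300, bod5 = 1.8),
                             env_amplitudes = c(temperature = 9, discharge_q = 1,
                                                ph = 0.15, ec = 60, bod5 = 0.5),
                             noise_sd = 0.05,
                             planted_formula = c("margalef_eq", "do_over_t"),
                             tds_ec_ratio = 0.64,
                             seed = 1L) {
  check_scalar_number(n_stations, "n_stations", min = 1)
  check_scalar_number(n_months, "n_months", min = 2)
  check_scalar_number(taxon_pool, "taxon_pool", min = 2)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(tds_ec_ratio, "tds_ec_ratio", min = 1e-12)
  check_scalar_number(seed, "seed")
  vars <- c("temperature", "discharge_q", "ph", "ec", "bod5")
  if (!all(vars %in% names(env_means)) || !all(vars %in% names(env_amplitudes))) {
    stop("env_means and env_amplitudes must name all of: ",
         paste(vars, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_stations = as.integer(n_stations),
    n_months = as.integer(n_months),
    taxon_pool = as.integer(taxon_pool),
    env_means = env_means[vars],
    env_amplitudes = env_amplitudes[vars],
    noise_sd = noise_sd,
    planted_formula = match.arg(planted_formula),
    tds_ec_ratio = tds_ec_ratio,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Month of the annual peak and residual (between-station) noise sd for each
# sinusoid-driven variable; DO is derived from temperature, not a sinusoid.
.env_peak_month <- c(temperature = 7, discharge_q = 4, ph = 9, ec = 9, bod5 = 8)
.env_noise_sd   <- c(temperature = 0.8, discharge_q = 1.5, ph = 0.15,
                     ec = 20, bod5 = 0.3)
.do_intercept <- 12.2   # mg/L at 0 deg C
.do_slope     <- -0.155 # mg/L per deg C
.do_noise_sd  <- 0.78  # calibrated so cor(T, DO) is close to -0.79

planted_target <- function(env, formula) {
  switch(formula,
    margalef_eq = evaluate_margalef_equation(env$do_mgl, env$temperature,
                                             env$ec, env$bod5),
    do_over_t = env$do_mgl / env$temperature,
    stop("unknown planted formula: ", formula, call. = FALSE)
  )
}

#' Generate a synthetic physicochemical monitoring table
#'
#' One record per station-month. Temperature follows an annual sinusoid
#' peaking in July; dissolved oxygen is an affine decreasing function of
#' temperature plus noise; discharge peaks in April; TDS is exactly
#' `tds_ec_ratio * ec`; pH is clamped to \[6, 9\] and all concentrations to
#' positive ranges. Stations differ only by i.i.d. noise.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `station`, `month`, `temperature`,
#'   `discharge_q`, `ph`, `do_mgl`, `ec`, `bod5`, `tds`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    station <- rep(sprintf("S%d", seq_len(config$n_stations)),
                   each = config$n_months)
    month <- rep(seq_len(config$n_months), times = config$n_stations)
    moy <- ((month - 1L) %% 12L) + 1L  # month of year for seasonality
    n <- length(month)
    cyc <- function(var) {
      config$env_means[[var]] +
        config$env_amplitudes[[var]] *
          cos(2 * pi * (moy - .env_peak_month[[var]]) / 12) +
        rnorm(n, 0, .env_noise_sd[[var]])
    }
    temperature <- pmax(cyc("temperature"), 0.5)
    discharge_q <- pmax(cyc("discharge_q"), 0.2)
    ph <- pmin(pmax(cyc("ph"), 6), 9)
    do_mgl <- pmax(.do_intercept + .do_slope * temperature +
                     rnorm(n, 0, .do_noise_sd), 0.5)
    ec <- pmax(cyc("ec"), 50)
    bod5 <- pmax(cyc("bod5"), 0.1)
    data.frame(station = station, month = month,
               temperature = temperature, discharge_q = discharge_q,
               ph = ph, do_mgl = do_mgl, ec = ec, bod5 = bod5,
               tds = config$tds_ec_ratio * ec,
               stringsAsFactors = FALSE)
  })
}

#' Ground truth for a synthetic dataset
#'
#' The planted, noise-free Margalef target for every sample, reproducible
#' from the configuration alone.
#'
#' @param env Environment table from [generate_environment()].
#' @param config A [generator_config()].
#' @return A list of class `"ground_truth"` with the planted formula id,
#'   the noise level, and a `targets` data frame
#'   (`station`, `month`, `mi_target`).
#' @export
ground_truth <- function(env, config) {
  stopifnot(inherits(config, "generator_config"))
  structure(list(
    planted_formula = config$planted_formula,
    noise_sd = config$noise_sd,
    targets = data.frame(station = env$station, month = env$month,
                         mi_target = planted_target(env, config$planted_formula),
                         stringsAsFactors = FALSE)
  ), class = "ground_truth")
}

#' Generate synthetic community count vectors tracking a planted diversity
#'
#' For each sample the total number of individuals N is drawn uniformly from
#' 50-500; the noisy target MI* = planted value + N(0, noise_sd) is inverted
#' through the Margalef formula to a taxon richness
#' s = clamp(round(1 + MI* ln N), 1, taxon_pool); the N individuals are then
#' allocated over s taxa (drawn from the pool) by a Dirichlet(1)-multinomial
#' with every chosen taxon guaranteed at least one individual, so the realized
#' Margalef index is exactly (s - 1)/ln N and approximates MI*.
#'
#' @param env Environment table aligned with `truth$targets`.
#' @param truth A [ground_truth()] object.
#' @param config A [generator_config()].
#' @return A wide count data frame: `station`, `month`, then one column per
#'   taxon in the pool (zeros for absent taxa).
#' @export
generate_community <- function(env, truth, config) {
  stopifnot(inherits(config, "generator_config"), inherits(truth, "ground_truth"))
  if (nrow(env) != nrow(truth$targets) ||
      any(env$station != truth$targets$station) ||
      any(env$month != truth$targets$month)) {
    stop("environment table and ground truth are not aligned by sample key",
         call. = FALSE)
  }
  community_seed <- config$seed %% 2147483646L + 1L
  with_seed(community_seed, {
    n <- nrow(env)
    pool <- config$taxon_pool
    counts <- matrix(0L, nrow = n, ncol = pool,
                     dimnames = list(NULL, sprintf("taxon_%02d", seq_len(pool))))
    for (i in seq_len(n)) {
      N <- sample(50:500, 1L)
      mi_star <- truth$targets$mi_target[i] + rnorm(1L, 0, config$noise_sd)
      s <- max(1L, min(pool, N, as.integer(round(1 + mi_star * log(N)))))
      taxa <- sample.int(pool, s)
      w <- rgamma(s, shape = 1)          # Dirichlet(1) weights
      alloc <- rep(1L, s)                # guarantee presence of each taxon
      if (N > s) {
        alloc <- alloc + as.integer(rmultinom(1L, N - s, w / sum(w)))
      }
      counts[i, taxa] <- alloc
    }
    cbind(data.frame(station = env$station, month = env$month,
                     stringsAsFactors = FALSE),
          as.data.frame(counts))
  })
}

#' Generate a complete aligned synthetic dataset
#'
#' @param config A [generator_config()].
#' @return A list with `environment` (physicochemical table), `counts`
#'   (community table) and `truth` (planted targets), sharing
#'   (station, month) keys row for row.
#' @export
generate_dataset <- function(config = generator_config()) {
  env <- generate_environment(config)
  truth <- ground_truth(env, config)
  counts <- generate_community(env, truth, config)
  list(environment = env, counts = counts, truth = truth)
}
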