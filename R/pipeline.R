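#' Closed-form Margalef-index equation from water chemistry
#'
#' Evaluates MI = DO/T + 2*DO/(T + EC + BOD5), the rational form selected by
#' the symbolic-regression study for an unpolluted river: diversity rises
#' with dissolved oxygen and falls with temperature, conductivity and organic
#' load. The caller chooses the input scale (raw units as listed, or
#' standardized \[0, 1\] values); the form is evaluated as given either way.
#'
#' @param do_mgl Dissolved oxygen (mg/L).
#' @param temperature Water temperature (deg C); must be nonzero.
#' @param ec Electrical conductivity (umhos/cm).
#' @param bod5 Five-day biological oxygen demand (mg/L);
#'   `temperature + ec + bod5` must be nonzero.
#' @return Numeric vector of Margalef-index values.
#' @export
evaluate_margalef_equation <- function(do_mgl, temperature, ec, bod5) {
  if (any(temperature == 0) || any(temperature + ec + bod5 == 0)) {
    stop("undefined equation: zero denominator (temperature, or T + EC + BOD5)",
         call. = FALSE)
  }
  do_mgl / temperature + (2 * do_mgl) / (temperature + ec + bod5)
}

#' Percent error of a model-calculated summary statistic
#'
#' `100 * |observed - calculated| / |observed|`, the convention used to
#' compare observed and fitted means/standard deviations.
#'
#' @param observed_stat Observed statistic (nonzero).
#' @param calculated_stat Model-calculated statistic.
#' @return Percentage (>= 0).
#' @export
estimation_error_percent <- function(observed_stat, calculated_stat) {
  if (any(observed_stat == 0)) {
    stop("estimation error undefined: observed statistic is zero",
         call. = FALSE)
  }
  100 * abs(observed_stat - calculated_stat) / abs(observed_stat)
}

#' Multi-restart genetic programming
#'
#' Runs `n_runs` independent [evolve()] searches, each with its own seed
#' spawned from the master seed in `config`, and scores every best-of-run
#' tree on the validation split as well. Mirrors the protocol of selecting a
#' final equation from 100 restarts of a stochastic search.
#'
#' @param config A [gp_config()]; its `seed` is the master seed (required).
#' @param n_runs Number of restarts (>= 1).
#' @param train_predictors,train_targets Training split.
#' @param validation_predictors,validation_targets Optional validation split.
#' @return A list of class `"gp_multistart"` of per-run results; each element
#'   is a `gp_run` with added `run_index` and (when a validation split is
#'   given) `validation_fitness`.
#' @export
run_multistart_gp <- function(config, n_runs, train_predictors, train_targets,
                              validation_predictors = NULL,
                              validation_targets = NULL) {
  stopifnot(inherits(config, "gp_config"))
  check_scalar_number(n_runs, "n_runs", min = 1)
  if (is.null(config$seed)) {
    stop("run_multistart_gp needs a master seed in the GP configuration",
         call. = FALSE)
  }
  seeds <- with_seed(config$seed, sample.int(2147483646L, n_runs))
  results <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    res <- tryCatch(
      evolve(cfg_i, train_predictors, train_targets),
      error = function(e) {
        stop(sprintf("GP run %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
    res$run_index <- i
    if (!is.null(validation_predictors)) {
      res$validation_fitness <- fitness(
        evaluate_tree(res$best_tree, validation_predictors),
        validation_targets
      )
    }
    results[[i]] <- res
  }
  structure(results, class = "gp_multistart")
}

#' Variable-presence tally across GP restarts
#'
#' The percentage of restarts whose best-of-run expression contains each
#' predictor as a terminal — a crude variable-importance measure: predictors
#' the search keeps rediscovering are the ones carrying signal.
#'
#' @param results A `gp_multistart` (or plain list of `gp_run`) collection.
#' @param var_names Predictor names, in column order.
#' @return A data frame with columns `variable` and `percent` (0-100).
#' @export
tally_variable_presence <- function(results, var_names) {
  if (length(results) < 1L) stop("no GP results to tally", call. = FALSE)
  present <- vapply(results, function(res) {
    seq_along(var_names) %in% tree_variables(res$best_tree)
  }, logical(length(var_names)))
  present <- matrix(present, nrow = length(var_names))
  data.frame(variable = var_names,
             percent = 100 * rowMeans(present),
             stringsAsFactors = FALSE)
}

#' Select the best equation from a set of GP restarts
#'
#' Picks the run with the highest training-set Pearson correlation; ties are
#' broken by lower training rmse, then by lower run index, so the choice is
#' deterministic and permutation-invariant.
#'
#' @param results A `gp_multistart` (or plain list of `gp_run`) collection.
#' @return The winning `gp_run`.
#' @export
select_best_equation <- function(results) {
  if (length(results) < 1L) stop("no GP results to select from", call. = FALSE)
  r <- vapply(results, function(x) x$train_fitness$pearson_r, numeric(1))
  rmse <- vapply(results, function(x) x$train_fitness$rmse, numeric(1))
  idx <- vapply(results, function(x) {
    if (is.null(x$run_index)) NA_integer_ else as.integer(x$run_index)
  }, integer(1))
  if (anyNA(idx)) idx <- seq_along(results)
  results[[order(-r, rmse, idx)[1]]]
}

#' Observed-versus-calculated fit summary for train and validation splits
#'
#' For each split: observed and calculated means and sample standard
#' deviations (n - 1 denominator), the percent estimation error of each,
#' squared Pearson correlation, mean square error and its root.
#'
#' @param observed_train,calculated_train Training-split vectors (length >= 2).
#' @param observed_validation,calculated_validation Validation-split vectors
#'   (length >= 2).
#' @return A data frame with one row per split.
#' @export
summarize_fit <- function(observed_train, calculated_train,
                          observed_validation, calculated_validation) {
  one <- function(split, obs, calc) {
    if (length(obs) < 2L || length(obs) != length(calc)) {
      stop("insufficient data: each split needs >= 2 aligned values",
           call. = FALSE)
    }
    r <- if (sd(obs) == 0 || sd(calc) == 0) 0 else cor(obs, calc)
    data.frame(
      split = split,
      mean_observed = mean(obs),
      mean_calculated = mean(calc),
      mean_error_pct = estimation_error_percent(mean(obs), mean(calc)),
      sd_observed = sd(obs),
      sd_calculated = sd(calc),
      sd_error_pct = estimation_error_percent(sd(obs), sd(calc)),
      r_squared = r^2,
      mse = mean((obs - calc)^2),
      rmse = sqrt(mean((obs - calc)^2)),
      stringsAsFactors = FALSE
    )
  }
  rbind(one("train", observed_train, calculated_train),
        one("validation", observed_validation, calculated_validation))
}

#' Full bioassessment analysis pipeline
#'
#' Orchestrates the whole study design on a count table and an aligned
#' physicochemical table: diversity indices; Pearson correlation screen of
#' indices against the environment; 2-means seasonal clustering with
#' winter-cluster exclusion; collinearity pruning (dropping TDS in favour of
#' EC); min-max standardization; an 80/20 train/validation split; varimax
#' PCA of the retained predictors; multi-restart GP symbolic regression for
#' each of the three indices; variable-presence tallies; selection of the
#' index whose restarts correlate best with observations; and an
#' observed-versus-calculated fit summary and per-sample series for the
#' winning equation.
#'
#' @param counts Community count table (see [read_counts_csv()]).
#' @param env Physicochemical table (see [read_env_csv()]).
#' @param config An [analysis_config()].
#' @return A list of class `"benthic_report"` with sections `diversity`,
#'   `correlation_matrix`, `cluster`, `retained_keys`, `kept_predictors`,
#'   `dropped_predictors`, `pca`, `split`, `gp` (per-index restarts),
#'   `presence_tally`, `index_scores`, `selected_index`, `equation`,
#'   `fit_summary`, and `series`.
#' @export
full_pipeline <- function(counts, env, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  log_stage("indices", "computing diversity indices")
  div <- compute_indices_table(counts)
  data <- merge(div, env, by = c("station", "month"), sort = FALSE)
  if (nrow(data) != nrow(div)) {
    stop("pipeline stage 'merge': count and environment tables do not align",
         call. = FALSE)
  }
  data <- data[order(data$station, data$month), ]
  rownames(data) <- paste(data$station, data$month, sep = ":")
  env_vars <- c("temperature", "discharge_q", "ph", "do_mgl", "ec", "bod5",
                "tds")
  index_vars <- c("shannon", "simpson", "margalef")

  log_stage("screen", "correlation matrix of indices and environment")
  corr_all <- pearson_correlation_matrix(data[, c(env_vars, index_vars)])

  log_stage("cluster", "2-means seasonal stratification")
  features <- minmax_standardize(data[, c(env_vars, index_vars)])
  clus <- kmeans_cluster(features$values, k = config$k, seed = config$seed)
  retained <- exclude_winter_cluster(clus, data$month,
                                     winter_months = config$winter_months)
  sub <- data[retained, ]
  corr <- if (config$correlation_all_months) corr_all else
    pearson_correlation_matrix(sub[, c(env_vars, index_vars)])

  log_stage("prune", "collinearity pruning of predictors")
  kept <- drop_collinear(pearson_correlation_matrix(sub[, env_vars]),
                         threshold = config$collinearity_threshold,
                         keep_priority = config$collinearity_priority)
  dropped <- setdiff(env_vars, kept)

  log_stage("standardize", "min-max scaling of predictors and targets")
  scaler <- minmax_standardize(sub[, c(kept, index_vars)])
  split <- train_validation_split(rownames(sub),
                                  fraction = config$split_fraction,
                                  seed = config$seed)

  log_stage("pca", "varimax-rotated principal components")
  pca <- pca_varimax(scaler$values[, kept, drop = FALSE],
                     n_components = config$n_components)

  X_train <- scaler$values[split$train, kept, drop = FALSE]
  X_val <- scaler$values[split$validation, kept, drop = FALSE]
  index_seeds <- with_seed(config$seed,
                           sample.int(2147483646L, length(index_vars)))
  gp_runs <- list()
  tallies <- list()
  scores <- numeric(0)
  for (i in seq_along(index_vars)) {
    idx <- index_vars[i]
    log_stage("gp", sprintf("%d restart(s) for the %s index",
                            config$n_runs, idx))
    cfg <- config$gp
    cfg$seed <- index_seeds[i]
    runs <- run_multistart_gp(cfg, config$n_runs,
                              X_train, scaler$values[split$train, idx],
                              X_val, scaler$values[split$validation, idx])
    gp_runs[[idx]] <- runs
    tallies[[idx]] <- tally_variable_presence(runs, kept)
    scores[idx] <- mean(vapply(runs, function(x) x$train_fitness$pearson_r,
                               numeric(1)))
  }
  selected <- names(scores)[which.max(scores)]
  best <- select_best_equation(gp_runs[[selected]])

  log_stage("report", sprintf("selected index: %s", selected))
  calc_train_std <- evaluate_tree(best$best_tree, X_train)
  calc_val_std <- evaluate_tree(best$best_tree, X_val)
  obs_train <- sub[split$train, selected]
  obs_val <- sub[split$validation, selected]
  calc_train <- minmax_invert(scaler, calc_train_std, variable = selected)
  calc_val <- minmax_invert(scaler, calc_val_std, variable = selected)
  fit <- summarize_fit(obs_train, calc_train, obs_val, calc_val)

  series <- rbind(
    data.frame(station = sub[split$train, "station"],
               month = sub[split$train, "month"], split = "train",
               observed = obs_train, calculated = calc_train,
               stringsAsFactors = FALSE),
    data.frame(station = sub[split$validation, "station"],
               month = sub[split$validation, "month"], split = "validation",
               observed = obs_val, calculated = calc_val,
               stringsAsFactors = FALSE)
  )
  series <- series[order(series$station, series$month), ]
  rownames(series) <- NULL

  structure(list(
    diversity = div,
    correlation_matrix = corr,
    cluster = clus,
    retained_keys = retained,
    kept_predictors = kept,
    dropped_predictors = dropped,
    pca = pca,
    split = split,
    gp = gp_runs,
    presence_tally = tallies,
    index_scores = scores,
    selected_index = selected,
    equation = list(
      prefix = tree_to_string(best$best_tree, kept),
      infix = tree_to_infix(best$best_tree, kept),
      train_fitness = best$train_fitness,
      validation_fitness = best$validation_fitness,
      run_index = best$run_index
    ),
    fit_summary = fit,
    series = series,
    config = config
  ), class = "benthic_report")
}
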