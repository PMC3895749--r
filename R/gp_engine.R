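#' Configuration for a genetic-programming symbolic-regression run
#'
#' Defaults follow the study protocol where one is stated (mutation rate 0.1,
#' population 300, 500 generations, function set +, -, *, protected /) and
#' canonical Koza settings elsewhere (crossover 0.9 with reproduction filling
#' the remainder, tournament size 3, ramped half-and-half initialization at
#' depths 2-6, depth cap 12 enforced by offspring rejection).
#'
#' @param population_size Individuals per generation (>= 2, default 300).
#' @param generations Number of generations (default 500).
#' @param crossover_rate Probability an offspring is produced by subtree
#'   crossover (default 0.9).
#' @param mutation_rate Probability of subtree mutation (default 0.1); any
#'   remaining probability mass is reproduction of a tournament winner.
#' @param tournament_size Tournament size for parent selection (default 3).
#' @param init_depth Length-2 integer vector, min/max depth at
#'   initialization (default `c(2, 6)`).
#' @param max_depth Hard depth cap; offspring exceeding it are replaced by a
#'   parent copy (default 12).
#' @param function_set Subset of `c("add", "sub", "mul", "div")`.
#' @param constant_range Interval for ephemeral random constants
#'   (default `c(0, 1)`, the scale of standardized predictors); `NULL`
#'   disables constants.
#' @param constant_prob Probability a terminal is a constant rather than a
#'   variable (default 0.2; ignored when constants are disabled).
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (default 1).
#' @param stop_rmse Early-stop threshold: the run ends once the best training
#'   rmse is at or below it (default 0 = run all generations). Affects
#'   runtime only; the best-ever individual is returned either way.
#' @param seed Integer seed for the run, or `NULL` to use the current RNG
#'   stream.
#' @return A list of class `"gp_config"`.
#' @export
gp_config <- function(population_size = 300L,
                      generations = 500L,
                      crossover_rate = 0.9,
                      mutation_rate = 0.1,
                      tournament_size = 3L,
                      init_depth = c(2L, 6L),
                      max_depth = 12L,
                      function_set = c("add", "sub", "mul", "div"),
                      constant_range = c(0, 1),
                      constant_prob = 0.2,
                      elitism = 1L,
                      stop_rmse = 0,
                      seed = NULL) {
  check_scalar_number(population_size, "population_size", min = 2)
  check_scalar_number(generations, "generations", min = 1)
  check_scalar_number(crossover_rate, "crossover_rate", min = 0, max = 1)
  check_scalar_number(mutation_rate, "mutation_rate", min = 0, max = 1)
  if (crossover_rate + mutation_rate > 1 + 1e-12) {
    stop("crossover_rate + mutation_rate must not exceed 1", call. = FALSE)
  }
  check_scalar_number(tournament_size, "tournament_size", min = 1)
  stopifnot(length(init_depth) == 2L, init_depth[1] >= 1,
            init_depth[2] >= init_depth[1])
  check_scalar_number(max_depth, "max_depth", min = init_depth[2])
  function_set <- match.arg(function_set, c("add", "sub", "mul", "div"),
                            several.ok = TRUE)
  if (!is.null(constant_range)) {
    stopifnot(is.numeric(constant_range), length(constant_range) == 2L,
              constant_range[1] <= constant_range[2])
  }
  check_scalar_number(constant_prob, "constant_prob", min = 0, max = 1)
  check_scalar_number(elitism, "elitism", min = 0, max = population_size - 1)
  check_scalar_number(stop_rmse, "stop_rmse", min = 0)
  if (!is.null(seed)) check_scalar_number(seed, "seed")
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    crossover_rate = crossover_rate,
    mutation_rate = mutation_rate,
    tournament_size = as.integer(tournament_size),
    init_depth = as.integer(init_depth),
    max_depth = as.integer(max_depth),
    function_set = function_set,
    constant_range = constant_range,
    constant_prob = constant_prob,
    elitism = as.integer(elitism),
    stop_rmse = stop_rmse,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "gp_config")
}

#' Goodness of fit of a prediction vector
#'
#' Root-mean-square error and Pearson correlation between predictions and
#' targets. A constant (zero-variance) prediction vector — or a constant
#' target — has its correlation reported as 0, the worst value, rather than
#' undefined; non-finite predictions yield an infinite rmse.
#'
#' @param predictions,targets Equal-length numeric vectors (length >= 2).
#' @return A list with `rmse` and `pearson_r`.
#' @export
fitness <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) < 2L) {
    stop("predictions and targets must be equal-length vectors (>= 2)",
         call. = FALSE)
  }
  if (!all(is.finite(predictions))) {
    return(list(rmse = Inf, pearson_r = 0))
  }
  rmse <- sqrt(mean((predictions - targets)^2))
  r <- if (sd(predictions) == 0 || sd(targets) == 0) 0
       else cor(predictions, targets)
  list(rmse = rmse, pearson_r = r)
}

# --- genetic operators on postfix genomes ---------------------------------

subtree_span <- function(tree, node) {
  start <- subtree_start_cpp(tree$code, node)
  c(start, node)
}

splice_subtree <- function(host, span, code, value) {
  new_gp_tree(
    c(host$code[seq_len(span[1] - 1L)], code,
      if (span[2] < length(host$code)) host$code[(span[2] + 1L):length(host$code)]),
    c(host$value[seq_len(span[1] - 1L)], value,
      if (span[2] < length(host$code)) host$value[(span[2] + 1L):length(host$code)])
  )
}

# Koza-style crossover-point choice: operator (internal) nodes with
# probability 0.9, leaves otherwise, so whole building blocks are exchanged
# more often than single terminals.
pick_crossover_node <- function(code) {
  internal <- which(code > 0L)
  pool <- if (length(internal) && runif(1) < 0.9) internal
          else which(code <= 0L)
  pool[sample.int(length(pool), 1L)]
}

crossover_trees <- function(p1, p2, max_depth) {
  s1 <- subtree_span(p1, pick_crossover_node(p1$code))
  s2 <- subtree_span(p2, pick_crossover_node(p2$code))
  child <- splice_subtree(p1, s1, p2$code[s2[1]:s2[2]], p2$value[s2[1]:s2[2]])
  if (postfix_depth_cpp(child$code) > max_depth) p1 else child
}

mutate_tree <- function(p, config, n_variables) {
  span <- subtree_span(p, sample.int(length(p$code), 1L))
  sub <- gen_subtree(1L, 1L, sample(2:4, 1L), "grow", n_variables,
                     config$function_set, config$constant_range,
                     config$constant_prob)
  child <- splice_subtree(p, span, sub$code, sub$value)
  if (postfix_depth_cpp(child$code) > config$max_depth) p else child
}

tournament_pick <- function(rmse, size) {
  cand <- sample.int(length(rmse), min(size, length(rmse)))
  cand[which.min(rmse[cand])]
}

#' Evolve a symbolic-regression expression for a training set
#'
#' Tree-based genetic programming minimizing training rmse: ramped
#' half-and-half initialization, tournament selection, subtree crossover and
#' mutation at the configured rates (reproduction for the remainder),
#' elitism, and a depth cap enforced by rejecting oversized offspring in
#' favor of a parent copy. The best-ever individual and the per-generation
#' best-rmse trajectory are returned; with elitism >= 1 the trajectory is
#' non-increasing.
#'
#' @param config A [gp_config()].
#' @param predictors Numeric matrix or data frame of training predictors.
#' @param targets Numeric target vector, one value per row.
#' @return A list of class `"gp_run"`: `best_tree`, `train_fitness`
#'   (rmse and Pearson r on the training data), `trajectory`,
#'   `generations_run`, `n_variables`, `var_names`, `seed`, and `warnings`.
#' @export
evolve <- function(config, predictors, targets) {
  stopifnot(inherits(config, "gp_config"))
  X <- as.matrix(as.data.frame(predictors))
  storage.mode(X) <- "double"
  if (nrow(X) != length(targets) || length(targets) < 2L) {
    stop("predictor rows and target length must match (>= 2 samples)",
         call. = FALSE)
  }
  warns <- character(0)
  if (sd(targets) == 0) {
    warns <- c(warns, "constant target vector: correlations are degenerate")
    warning("constant target vector: correlations are degenerate",
            call. = FALSE)
  }
  n_vars <- ncol(X)
  run <- function() {
    pop <- lapply(seq_len(config$population_size), function(i) {
      random_tree(config, n_vars,
                  method = if (i %% 2L == 0L) "full" else "grow")
    })
    score <- function(tree) {
      fitness(eval_postfix_cpp(tree$code, tree$value, X), targets)
    }
    fits <- lapply(pop, score)
    rmse <- vapply(fits, `[[`, numeric(1), "rmse")
    best_i <- which.min(rmse)
    best <- list(tree = pop[[best_i]], fit = fits[[best_i]])
    trajectory <- numeric(0)
    gens_run <- 0L
    for (gen in seq_len(config$generations)) {
      new_pop <- vector("list", config$population_size)
      new_fits <- vector("list", config$population_size)
      n_elite <- config$elitism
      if (n_elite > 0L) {
        elite <- order(rmse)[seq_len(n_elite)]
        new_pop[seq_len(n_elite)] <- pop[elite]
        new_fits[seq_len(n_elite)] <- fits[elite]
      }
      for (i in seq.int(n_elite + 1L, config$population_size)) {
        u <- runif(1)
        if (u < config$crossover_rate) {
          p1 <- tournament_pick(rmse, config$tournament_size)
          p2 <- tournament_pick(rmse, config$tournament_size)
          child <- crossover_trees(pop[[p1]], pop[[p2]], config$max_depth)
        } else if (u < config$crossover_rate + config$mutation_rate) {
          p1 <- tournament_pick(rmse, config$tournament_size)
          child <- mutate_tree(pop[[p1]], config, n_vars)
        } else {
          child <- pop[[tournament_pick(rmse, config$tournament_size)]]
        }
        new_pop[[i]] <- child
        new_fits[[i]] <- score(child)
      }
      pop <- new_pop
      fits <- new_fits
      rmse <- vapply(fits, `[[`, numeric(1), "rmse")
      gen_best <- which.min(rmse)
      if (rmse[gen_best] < best$fit$rmse) {
        best <- list(tree = pop[[gen_best]], fit = fits[[gen_best]])
      }
      trajectory <- c(trajectory, best$fit$rmse)
      gens_run <- gen
      if (config$stop_rmse > 0 && best$fit$rmse <= config$stop_rmse) break
    }
    structure(list(
      best_tree = best$tree,
      train_fitness = best$fit,
      trajectory = trajectory,
      generations_run = gens_run,
      n_variables = n_vars,
      var_names = colnames(X),
      seed = config$seed,
      warnings = warns
    ), class = "gp_run")
  }
  if (is.null(config$seed)) run() else with_seed(config$seed, run())
}

#' @export
print.gp_run <- function(x, ...) {
  cat("<gp_run>", x$generations_run, "generations; train rmse",
      format(x$train_fitness$rmse, digits = 6), "r",
      format(x$train_fitness$pearson_r, digits = 4), "\n ",
      tree_to_string(x$best_tree, x$var_names), "\n")
  invisible(x)
}
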