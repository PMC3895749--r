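# Independent oracles and small fixture builders, deliberately written as
# plain loops so they share no code path with the package implementation.

oracle_shannon <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (c_i in counts) {
    if (c_i > 0) {
      p <- c_i / total
      acc <- acc - p * log(p)
    }
  }
  acc
}

oracle_simpson <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (c_i in counts) {
    if (c_i > 0) acc <- acc + (c_i / total)^2
  }
  1 - acc
}

oracle_margalef <- function(counts) {
  s <- 0
  for (c_i in counts) if (c_i > 0) s <- s + 1
  (s - 1) / log(sum(counts))
}

# Two-pass Pearson correlation from the definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Recursive-descent evaluation of a postfix genome, independent of the C++
# stack machine: rebuilds nested structure then evaluates per row.
oracle_eval_tree <- function(tree, X) {
  X <- as.matrix(X)
  stack <- list()
  for (i in seq_along(tree$code)) {
    ci <- tree$code[i]
    if (ci < 0) {
      stack[[length(stack) + 1L]] <- X[, -ci]
    } else if (ci == 0) {
      stack[[length(stack) + 1L]] <- rep(tree$value[i], nrow(X))
    } else {
      b <- stack[[length(stack)]]
      a <- stack[[length(stack) - 1L]]
      stack[[length(stack)]] <- NULL
      res <- switch(ci, a + b, a - b, a * b, {
        out <- a / b
        out[abs(b) <= 1e-9] <- 1
        out
      })
      stack[[length(stack)]] <- res
    }
  }
  stack[[1L]]
}

# A random valid abundance vector with >= 2 individuals.
random_counts <- function(max_taxa = 12, max_count = 60) {
  s <- sample(1:max_taxa, 1)
  counts <- rpois(s, lambda = runif(1, 1, max_count / 2))
  if (sum(counts) < 2) counts[1] <- counts[1] + 2
  counts
}

# Small, fast GP configuration for structural tests.
tiny_gp <- function(...) {
  gp_config(population_size = 30, generations = 5, init_depth = c(2, 3),
            max_depth = 6, ...)
}
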