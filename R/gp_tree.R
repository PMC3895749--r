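# Expression trees for symbolic regression.
#
# A tree is stored as a postfix-ordered genome: an integer `code` vector
# (positive = binary operator, 0 = ephemeral constant, negative = 1-based
# predictor index) plus an aligned `value` vector holding constant values.
# Postfix keeps subtree extraction, crossover and C++ stack evaluation cheap.

.op_codes <- c(add = 1L, sub = 2L, mul = 3L, div = 4L)
.op_infix <- c(add = "+", sub = "-", mul = "*", div = "/")

new_gp_tree <- function(code, value) {
  tree <- structure(list(code = as.integer(code), value = as.double(value)),
                    class = "gp_tree")
  postfix_depth_cpp(tree$code)  # stack-validates the genome
  tree
}

#' Protected division
#'
#' Total version of division used inside evolved expressions: returns
#' `numerator / denominator` when `|denominator| > 1e-9`, and 1 otherwise,
#' so tree evaluation is defined everywhere.
#'
#' @param numerator,denominator Numeric vectors (recycled as usual).
#' @return Numeric vector.
#' @export
protected_divide <- function(numerator, denominator) {
  out <- numerator / denominator
  guard <- abs(denominator) <= 1e-9
  out[guard] <- 1.0
  out
}

#' Number of levels in an expression tree (a lone terminal has depth 1)
#' @param tree A `gp_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) postfix_depth_cpp(tree$code)

#' Node count of an expression tree
#' @param tree A `gp_tree`.
#' @return Integer number of nodes.
#' @export
tree_size <- function(tree) length(tree$code)

#' Predictor variables referenced by an expression tree
#' @param tree A `gp_tree`.
#' @return Sorted integer vector of 1-based predictor indices.
#' @export
tree_variables <- function(tree) sort(unique(-tree$code[tree$code < 0]))

# Recursive generator emitting a postfix genome. `method` "full" forces
# operators down to the target depth; "grow" may close branches early but
# never above `min_depth`.
gen_subtree <- function(level, min_depth, max_depth, method, n_variables,
                        function_set, constant_range, constant_prob) {
  make_terminal <- function() {
    if (!is.null(constant_range) && runif(1) < constant_prob) {
      list(code = 0L, value = runif(1, constant_range[1], constant_range[2]))
    } else {
      list(code = -sample.int(n_variables, 1L), value = NA_real_)
    }
  }
  pick_op <- level < max_depth &&
    (level < min_depth || method == "full" || runif(1) < 0.5)
  if (!pick_op) return(make_terminal())
  op <- .op_codes[[sample(function_set, 1L)]]
  l <- gen_subtree(level + 1L, min_depth, max_depth, method, n_variables,
                   function_set, constant_range, constant_prob)
  r <- gen_subtree(level + 1L, min_depth, max_depth, method, n_variables,
                   function_set, constant_range, constant_prob)
  list(code = c(l$code, r$code, op), value = c(l$value, r$value, NA_real_))
}

#' Draw a random expression tree
#'
#' Ramped initialization: a target depth is drawn uniformly from
#' `config$init_depth` and the tree built by the "grow" or "full" method
#' (chosen at random), so every draw has depth within the configured range.
#' Terminals are predictor variables or, with probability
#' `config$constant_prob`, ephemeral constants uniform on
#' `config$constant_range`.
#'
#' @param config A [gp_config()].
#' @param n_variables Number of available predictors (>= 1).
#' @param method `"grow"`, `"full"`, or `NULL` to choose at random.
#' @return A `gp_tree`.
#' @export
random_tree <- function(config, n_variables, method = NULL) {
  check_scalar_number(n_variables, "n_variables", min = 1)
  if (is.null(method)) method <- sample(c("grow", "full"), 1L)
  target <- sample(config$init_depth[1]:config$init_depth[2], 1L)
  g <- gen_subtree(1L, config$init_depth[1], target, method,
                   as.integer(n_variables), config$function_set,
                   config$constant_range, config$constant_prob)
  new_gp_tree(g$code, g$value)
}

#' Evaluate an expression tree over a predictor matrix
#'
#' Row-wise recursive evaluation with protected operators; output is finite
#' for finite, moderately scaled inputs (the intended use is standardized
#' \[0, 1\] predictors).
#'
#' @param tree A `gp_tree`.
#' @param predictors Numeric matrix or data frame; tree variables `x1..xk`
#'   refer to its columns.
#' @return Numeric vector with one prediction per row.
#' @export
evaluate_tree <- function(tree, predictors) {
  X <- as.matrix(as.data.frame(predictors))
  storage.mode(X) <- "double"
  vars <- tree_variables(tree)
  if (length(vars) && max(vars) > ncol(X)) {
    stop(sprintf("malformed tree: variable x%d unbound (matrix has %d columns)",
                 max(vars), ncol(X)), call. = FALSE)
  }
  eval_postfix_cpp(tree$code, tree$value, X)
}

format_gp_constant <- function(v) trimws(formatC(v, digits = 12, format = "g"))

#' Canonical prefix serialization of an expression tree
#'
#' Writes trees as e.g. `"add(x1, 0.5)"`; constants are printed to 12
#' significant digits so that [parse_tree()] round-trips structure and values.
#'
#' @param tree A `gp_tree`.
#' @param var_names Optional character vector of predictor names; defaults to
#'   `x1..xk`.
#' @return A single string.
#' @export
tree_to_string <- function(tree, var_names = NULL) {
  stack <- character(0)
  for (i in seq_along(tree$code)) {
    c_i <- tree$code[i]
    if (c_i < 0) {
      nm <- if (is.null(var_names)) paste0("x", -c_i) else var_names[-c_i]
      stack <- c(stack, nm)
    } else if (c_i == 0) {
      stack <- c(stack, format_gp_constant(tree$value[i]))
    } else {
      n <- length(stack)
      op <- names(.op_codes)[match(c_i, .op_codes)]
      stack <- c(stack[seq_len(n - 2L)],
                 sprintf("%s(%s, %s)", op, stack[n - 1L], stack[n]))
    }
  }
  stack
}

#' Human-readable infix rendering of an expression tree
#'
#' @inheritParams tree_to_string
#' @return A single string, fully parenthesized.
#' @export
tree_to_infix <- function(tree, var_names = NULL) {
  stack <- character(0)
  for (i in seq_along(tree$code)) {
    c_i <- tree$code[i]
    if (c_i < 0) {
      nm <- if (is.null(var_names)) paste0("x", -c_i) else var_names[-c_i]
      stack <- c(stack, nm)
    } else if (c_i == 0) {
      stack <- c(stack, format_gp_constant(tree$value[i]))
    } else {
      n <- length(stack)
      op <- .op_infix[[names(.op_codes)[match(c_i, .op_codes)]]]
      stack <- c(stack[seq_len(n - 2L)],
                 sprintf("(%s %s %s)", stack[n - 1L], op, stack[n]))
    }
  }
  stack
}

#' Parse the canonical prefix serialization back into a tree
#'
#' Inverse of [tree_to_string()] under default variable naming: accepts
#' operator applications `op(left, right)` for `op` in add/sub/mul/div,
#' variables `x<k>` and numeric constants. Malformed input raises a parse
#' error reporting the character position.
#'
#' @param text A single string.
#' @param n_variables Number of predictors available; variable indices above
#'   this bound are rejected.
#' @return A `gp_tree`.
#' @export
parse_tree <- function(text, n_variables) {
  stopifnot(is.character(text), length(text) == 1L)
  check_scalar_number(n_variables, "n_variables", min = 1)
  src <- text
  pos <- 1L
  fail <- function(msg) {
    stop(sprintf("parse error at position %d: %s (in \"%s\")", pos, msg, src),
         call. = FALSE)
  }
  skip_ws <- function() {
    while (pos <= nchar(src) && substr(src, pos, pos) %in% c(" ", "\t")) {
      pos <<- pos + 1L
    }
  }
  token <- function() {
    skip_ws()
    if (pos > nchar(src)) fail("unexpected end of input")
    ch <- substr(src, pos, pos)
    if (ch %in% c("(", ")", ",")) {
      pos <<- pos + 1L
      return(ch)
    }
    m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*|^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                 substr(src, pos, nchar(src)))
    if (m == -1L) fail(sprintf("unexpected character '%s'", ch))
    tok <- substr(src, pos, pos + attr(m, "match.length") - 1L)
    pos <<- pos + attr(m, "match.length")
    tok
  }
  expr <- function() {
    tok <- token()
    if (tok %in% names(.op_codes)) {
      if (!identical(token(), "(")) fail("expected '('")
      l <- expr()
      if (!identical(token(), ",")) fail("expected ','")
      r <- expr()
      if (!identical(token(), ")")) fail("expected ')'")
      list(code = c(l$code, r$code, .op_codes[[tok]]),
           value = c(l$value, r$value, NA_real_))
    } else if (grepl("^x[0-9]+$", tok)) {
      idx <- as.integer(sub("^x", "", tok))
      if (idx < 1L || idx > n_variables) {
        fail(sprintf("variable %s out of range 1..%d", tok, n_variables))
      }
      list(code = -idx, value = NA_real_)
    } else if (grepl("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?$", tok)) {
      list(code = 0L, value = as.double(tok))
    } else {
      fail(sprintf("unknown token '%s'", tok))
    }
  }
  g <- expr()
  skip_ws()
  if (pos <= nchar(src)) fail("trailing input")
  new_gp_tree(g$code, g$value)
}

#' @export
print.gp_tree <- function(x, ...) {
  cat("<gp_tree> depth", tree_depth(x), "nodes", tree_size(x), "\n ",
      tree_to_string(x), "\n")
  invisible(x)
}
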