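#' Diversity indices for benthic macroinvertebrate samples
#'
#' Shannon, Simpson and Margalef diversity indices computed from a vector of
#' taxon counts (individuals per taxon in one station-month sample). All three
#' use natural logarithms; taxa with zero count contribute nothing
#' (the limit 0 * log 0 = 0).
#'
#' * Shannon: \eqn{SHI = -\sum_i P_i \ln P_i} with \eqn{P_i} the relative
#'   abundance of taxon i; ranges over \[0, ln s\] and is maximal for a
#'   perfectly even community.
#' * Simpson: \eqn{SI = 1 - \sum_i P_i^2}; the probability that two randomly
#'   drawn individuals belong to different taxa; ranges over \[0, 1 - 1/s\].
#' * Margalef: \eqn{MI = (s - 1) / \ln N}, a richness measure normalized by
#'   the number of individuals N; requires N >= 2.
#'
#' @param counts Numeric vector of non-negative taxon counts with at least one
#'   positive entry. Names, if present, are taken as taxon identifiers.
#' @return A single non-negative number.
#' @examples
#' shannon_index(c(5, 5, 5, 5))   # log(4)
#' simpson_index(c(50, 50))       # 0.5
#' margalef_index(rep(10, 10))    # 9 / log(100)
#' @name diversity_indices
NULL

check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L) {
    stop("'counts' must be a non-empty numeric vector of taxon counts",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("taxon counts must be non-negative integers without missing values",
         call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all taxon counts are zero: not a valid sample", call. = FALSE)
  }
  invisible(counts)
}

#' @rdname diversity_indices
#' @export
shannon_index <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  0 - sum(p * log(p))  # the leading 0 avoids IEEE negative zero when s = 1
}

#' @rdname diversity_indices
#' @export
simpson_index <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  1 - sum(p^2)
}

#' @rdname diversity_indices
#' @export
margalef_index <- function(counts) {
  check_counts(counts)
  n_total <- sum(counts)
  if (n_total <= 1) {
    stop("Margalef index needs at least 2 individuals (log N must be > 0)",
         call. = FALSE)
  }
  (sum(counts > 0) - 1) / log(n_total)
}

#' Diversity indices for a whole station-by-month count table
#'
#' Applies [shannon_index()], [simpson_index()] and [margalef_index()] to each
#' row of a wide community count table and returns one record per sample,
#' preserving the station/month keys and row order.
#'
#' @param counts A data frame with columns `station`, `month`, and one integer
#'   column per taxon (the dialect written by [write_counts_csv()]).
#' @return A data frame with columns `station`, `month`, `shannon`, `simpson`,
#'   `margalef`.
#' @export
compute_indices_table <- function(counts) {
  if (!is.data.frame(counts) || !all(c("station", "month") %in% names(counts))) {
    stop("'counts' must be a data frame with 'station' and 'month' columns",
         call. = FALSE)
  }
  taxon_cols <- setdiff(names(counts), c("station", "month"))
  if (length(taxon_cols) == 0L) {
    stop("count table has no taxon columns", call. = FALSE)
  }
  key <- paste(counts$station, counts$month, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- counts[duplicated(key), c("station", "month"), drop = FALSE]
    stop(sprintf("duplicate sample key(s): %s",
                 paste(sprintf("(%s, %s)", dup$station, dup$month),
                       collapse = ", ")), call. = FALSE)
  }
  mat <- as.matrix(counts[, taxon_cols, drop = FALSE])
  out <- data.frame(
    station  = counts$station,
    month    = counts$month,
    shannon  = apply(mat, 1L, shannon_index),
    simpson  = apply(mat, 1L, simpson_index),
    margalef = apply(mat, 1L, margalef_index),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
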