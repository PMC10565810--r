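# k-modes clustering of categorical vectors (Huang-style alternation):
# simple-matching dissimilarity for assignment, per-column modes for the
# centers. Written for bit-reproducibility: all tie-breaks are fixed and
# randomness enters only through the seeded restarts.

.smd <- function(row, centers) {
  # simple-matching dissimilarity of one row against every center
  rowSums(sweep(centers, 2L, row, `!=`))
}

.column_mode <- function(m) {
  # per-column mode; ties resolved toward the largest value in sort order
  # (for a 0/1 label matrix the "present" value wins ties)
  apply(m, 2L, function(col) {
    t <- table(col)
    v <- names(t)[t == max(t)]
    out <- v[length(v)]
    if (is.numeric(col)) as.numeric(out) else out
  })
}

.kmodes_once <- function(m, k, seed) {
  set.seed(seed)
  n <- nrow(m)
  # distinct rows as candidate seeds so no two initial centers coincide
  keys <- apply(m, 1L, paste, collapse = "\r")
  first <- which(!duplicated(keys))
  centers <- m[first[sample.int(length(first), k)], , drop = FALSE]
  assign_prev <- rep(0L, n)
  cost_history <- integer(0)
  for (iter in seq_len(100L)) {
    d <- t(apply(m, 1L, .smd, centers = centers))
    if (k == 1L) d <- matrix(d, ncol = 1L)
    assignments <- apply(d, 1L, which.min)   # ties: lowest cluster id
    cost_history <- c(cost_history,
                      as.integer(sum(d[cbind(seq_len(n), assignments)])))
    new_centers <- centers
    for (c_id in seq_len(k)) {
      idx <- which(assignments == c_id)
      if (length(idx) > 0L) {
        new_centers[c_id, ] <- .column_mode(m[idx, , drop = FALSE])
      }   # empty cluster keeps its center (deterministic)
    }
    if (identical(assignments, assign_prev) &&
        identical(new_centers, centers)) break
    assign_prev <- assignments
    centers <- new_centers
  }
  cost <- cost_history[length(cost_history)]
  list(centers = centers, assignments = assignments, cost = cost,
       cost_history = cost_history)
}

#' k-modes clustering of categorical data
#'
#' Partitions rows of a categorical matrix into `k` clusters by
#' alternating (a) assignment of every row to the center with minimum
#' simple-matching dissimilarity (number of differing columns; ties go to
#' the lowest cluster id) and (b) recomputation of each center as the
#' per-column mode of its members (ties resolved toward the
#' largest/"present" value), iterating to a fixed point. The best of
#' `n_init` seeded restarts by total cost is returned, so results are
#' fully determined by `(seed, n_init)`.
#'
#' @param m Matrix of categorical values (typically the 0/1 label matrix
#'   from [encode_labels()]); rows are observations.
#' @param k Number of clusters, at most the number of distinct rows.
#' @param n_init Number of random restarts.
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @return An object of class `kmodes_model`: `k`, `centers` (k x p
#'   matrix), `assignments` (cluster id per row), `cost` (total
#'   mismatches to own center), `cost_history` of the winning run.
#' @export
kmodes_cluster <- function(m, k, n_init = 10L, seed) {
  m <- as.matrix(m)
  if (nrow(m) == 0L) stop("empty matrix")
  if (missing(seed)) stop("seed is required for reproducible clustering")
  k <- as.integer(k)
  n_distinct <- nrow(unique(m))
  if (k < 1L) stop("k must be >= 1")
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct rows (", n_distinct, ")")
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- .kmodes_once(m, k, seed = seed + r - 1L)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  structure(
    list(k = k, centers = best$centers, assignments = best$assignments,
         cost = best$cost, cost_history = best$cost_history,
         n_init = n_init, seed = seed),
    class = "kmodes_model"
  )
}

#' @export
print.kmodes_model <- function(x, ...) {
  cat("<kmodes_model> k = ", x$k, ", cost = ", x$cost, ", sizes: ",
      paste(tabulate(x$assignments, x$k), collapse = "/"), "\n", sep = "")
  invisible(x)
}
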