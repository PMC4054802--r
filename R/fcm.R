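#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distances: memberships are
#' initialized at random (seeded), then centers (membership^m weighted
#' means) and memberships (inverse-distance-ratio rule) are updated
#' alternately until the objective `sum(U^m * d^2)` changes by less than
#' `tol` or `max_iter` is reached. A point coinciding with one or more
#' centers receives full membership split equally among the coincident
#' centers.
#'
#' @param x `N x p` numeric matrix of points, `N > c`.
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier, `> 1`.
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the membership initialization.
#' @return An object of class `fcm_result`: list with `centers` (`c x p`),
#'   `membership` (`N x c`, rows sum to 1), `objective_trace`
#'   (non-increasing), `hard_counts` (points per cluster by maximal
#'   membership), and `iterations`.
#' @export
fcm <- function(x, c = 2L, m = 2, tol = 1e-5, max_iter = 300L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (c < 2L) stop("c must be at least 2")
  if (n <= c) stop("fcm needs more points than clusters (N > c)")
  if (m <= 1) stop("fuzzifier m must be > 1")

  u <- withr::with_seed(seed, {
    u0 <- matrix(runif(n * c), n, c)
    u0 / rowSums(u0)
  })

  sq_dist <- function(centers) {
    ## N x c matrix of squared Euclidean distances
    d2 <- outer(rowSums(x^2), rep(1, c)) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * x %*% t(centers)
    pmax(d2, 0)
  }

  trace <- numeric(0)
  obj_prev <- Inf
  iter <- 0L
  centers <- NULL
  d2 <- NULL
  for (iter in seq_len(max_iter)) {
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    d2 <- sq_dist(centers)
    ## membership update; exact zeros get full membership on the
    ## coincident center(s)
    zero <- d2 < .Machine$double.eps
    inv <- 1 / pmax(d2, .Machine$double.eps)^(1 / (m - 1))
    u_new <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    u <- u_new
    obj <- sum(u^m * d2)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) && abs(obj_prev - obj) < tol) break
    obj_prev <- obj
  }

  hard <- max.col(u, ties.method = "first")
  res <- list(
    centers = centers,
    membership = u,
    objective_trace = trace,
    hard_counts = tabulate(hard, nbins = c),
    iterations = iter
  )
  class(res) <- "fcm_result"
  res
}

#' @export
print.fcm_result <- function(x, ...) {
  cat("Fuzzy c-means result: ", nrow(x$membership), " points, ",
      nrow(x$centers), " clusters, ", x$iterations, " iterations\n", sep = "")
  cat("hard counts:", x$hard_counts, "\n")
  print(x$centers)
  invisible(x)
}

#' Center of the most populated fuzzy cluster
#'
#' Returns the cluster center with the largest hard-membership count.
#' Ties are broken deterministically: clusters are sorted lexicographically
#' by their center coordinates and the first maximal-count cluster in that
#' order wins.
#'
#' @param result An [fcm()] result.
#' @return Numeric vector, the winning cluster center.
#' @export
largest_cluster <- function(result) {
  stopifnot(inherits(result, "fcm_result"))
  cen <- result$centers
  ord <- do.call(order, lapply(seq_len(ncol(cen)), function(j) cen[, j]))
  counts <- result$hard_counts[ord]
  win <- ord[which.max(counts)]
  result$centers[win, ]
}
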