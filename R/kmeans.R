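# k-means with k-means++ seeding, explicit restarts, and farthest-point
# repair of empty clusters. Lloyd iterations are delegated to stats::kmeans;
# this wrapper only controls seeding and restart selection so that the whole
# procedure is deterministic for a fixed seed.

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) <= 0) {
        idx[j] <- sample.int(n, 1L) # all points coincide with a center
      } else {
        idx[j] <- sample.int(n, 1L, prob = prob)
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  x[idx, , drop = FALSE]
}

# one Lloyd run; empty clusters are reseeded from the point farthest from its
# assigned centroid, then the run is repeated (bounded number of repairs)
lloyd_run <- function(x, centers, iter_max) {
  for (attempt in 1:10) {
    empty <- FALSE
    fit <- withCallingHandlers(
      stats::kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd"),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w))) {
          empty <<- TRUE
          invokeRestart("muffleWarning")
        } else if (grepl("did not converge", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    sizes <- tabulate(fit$cluster, nbins = nrow(centers))
    if (!empty && all(sizes > 0L)) return(fit)
    # farthest point from its current centroid becomes the new seed for each
    # empty cluster
    d2 <- rowSums((x - fit$centers[fit$cluster, , drop = FALSE])^2)
    centers <- fit$centers
    for (j in which(sizes == 0L)) {
      far <- which.max(d2)
      centers[j, ] <- x[far, ]
      d2[far] <- -Inf
    }
    centers[!is.finite(centers)] <- 0
  }
  fit
}

#' k-means with restarts and k-means++ seeding
#'
#' Deterministic (per `seed`) k-means: `restarts` independent k-means++
#' seedings, each refined by Lloyd iterations (`stats::kmeans`), keeping the
#' solution with the lowest total within-cluster sum of squares. Empty
#' clusters are repaired by reseeding from the farthest point.
#'
#' @param x Numeric matrix (observations in rows).
#' @param k Number of clusters (`1 <= k <= nrow(x)`).
#' @param seed Integer seed controlling all randomness.
#' @param iter_max Maximum Lloyd iterations per restart (default 2000).
#' @param restarts Number of random restarts (default 250).
#' @return List with `centers` (`k x ncol(x)`), `cluster` (integer labels),
#'   `inertia` (best total within-cluster sum of squares).
#' @export
kmeans_restarts <- function(x, k, seed = 1L, iter_max = 2000L, restarts = 250L) {
  x <- as.matrix(x)
  if (!is_count(k) || k > nrow(x)) {
    stop_invalid_parameter(sprintf(
      "`k` must be an integer in [1, %d] (got %s).", nrow(x), format(k)
    ))
  }
  if (!is_count(restarts) || !is_count(iter_max)) {
    stop_invalid_parameter("`restarts` and `iter_max` must be positive integers.")
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    if (k == 1L) {
      ctr <- matrix(colMeans(x), 1L, ncol(x), dimnames = list(NULL, colnames(x)))
      fit <- list(
        centers = ctr,
        cluster = rep(1L, nrow(x)),
        tot.withinss = sum((x - ctr[rep(1L, nrow(x)), , drop = FALSE])^2)
      )
    } else {
      fit <- lloyd_run(x, centers, iter_max)
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(
    centers = unname(best$centers),
    cluster = as.integer(best$cluster),
    inertia = best$tot.withinss
  )
}
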