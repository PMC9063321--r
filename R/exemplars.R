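#' Extract continuous trajectory sub-segments for one subject
#'
#' Collects every run of `tau` temporally consecutive embedded points along
#' the subject's averaged 2D trajectory: one segment per start index
#' `j = 1..W - tau + 1`.
#'
#' @param embedding An `evo_embedding`.
#' @param subject_id Subject whose trajectory to segment.
#' @param tau Segment duration in windows (default 44, twice the 22-TR
#'   analysis window).
#' @return Tibble with columns `subject_id`, `start`, and `points` (a list
#'   column of `tau x 2` coordinate matrices).
#' @export
extract_segments <- function(embedding, subject_id, tau = 44) {
  if (!is_count(tau, min = 2L)) stop_invalid_parameter("`tau` must be an integer >= 2.")
  pts <- subject_coords(embedding, subject_id)
  w <- nrow(pts)
  if (w < tau) {
    stop_invalid_input(sprintf(
      "Subject '%s' has %d embedded frames, fewer than tau = %d.",
      subject_id, w, tau
    ))
  }
  starts <- seq_len(w - tau + 1L)
  tibble(
    subject_id = subject_id,
    start = starts,
    points = lapply(starts, function(j) pts[j:(j + tau - 1L), , drop = FALSE])
  )
}

#' Linearize one continuous trajectory segment
#'
#' Summarizes a segment of consecutive embedded points by the ordinary
#' least-squares slope of y on x (clipped to `[-slope_bound, slope_bound]`;
#' a vertical segment takes `+slope_bound` by convention), the centroid of
#' its points, its length (the maximum pairwise distance among the points),
#' and its net temporal displacement (last minus first point, used later to
#' orient exemplars).
#'
#' @param points Numeric `tau x 2` matrix of consecutive embedded coordinates.
#' @param slope_bound Positive clipping bound for the slope (see
#'   [compute_slope_bound()]).
#' @return One-row tibble: `x`, `y`, `slope`, `length`, `dx`, `dy`.
#' @export
linearize_segment <- function(points, slope_bound) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || all(points[, 1L] == points[1L, 1L] & points[, 2L] == points[1L, 2L])) {
    stop_degenerate("Segment has fewer than 2 distinct points.",
                    class = "evodfnc_degenerate_segment")
  }
  if (!is.numeric(slope_bound) || slope_bound <= 0) {
    stop_invalid_parameter("`slope_bound` must be positive.")
  }
  xc <- points[, 1L] - mean(points[, 1L])
  yc <- points[, 2L] - mean(points[, 2L])
  sxx <- sum(xc^2)
  slope <- if (sxx == 0) slope_bound else sum(xc * yc) / sxx
  slope <- min(max(slope, -slope_bound), slope_bound)
  # max pairwise distance; tau is small so the O(tau^2) scan is cheap
  dm <- as.matrix(stats::dist(points))
  tibble(
    x = mean(points[, 1L]), y = mean(points[, 2L]),
    slope = slope, length = max(dm),
    dx = points[nrow(points), 1L] - points[1L, 1L],
    dy = points[nrow(points), 2L] - points[1L, 2L]
  )
}

#' Slope clipping bound for linearized segments
#'
#' The bound is the largest coordinate magnitude in the embedding,
#' `max(|x|, |y|)`, which keeps near-vertical least-squares slopes from
#' dominating the spatial components of the exemplar clustering.
#'
#' @param embedding An `evo_embedding` (or a coordinate matrix).
#' @return Positive scalar.
#' @export
compute_slope_bound <- function(embedding) {
  coords <- if (inherits(embedding, "evo_embedding")) embedding$coords else as.matrix(embedding)
  if (length(coords) == 0L) stop_invalid_input("Empty embedding.")
  max(abs(coords))
}

#' Linearize all subjects' trajectory segments
#'
#' Convenience wrapper: extracts every subject's continuous sub-segments and
#' linearizes them against a common slope bound.
#'
#' @inheritParams extract_segments
#' @param slope_bound Slope clipping bound; defaults to
#'   [compute_slope_bound()] of the embedding.
#' @return Tibble of linearized segments: `subject_id`, `start`, `x`, `y`,
#'   `slope`, `length`, `dx`, `dy`.
#' @export
linearize_cohort <- function(embedding, tau = 44,
                             slope_bound = compute_slope_bound(embedding)) {
  subjects <- unique(embedding$frame_index$subject_id)
  purrr::map_dfr(subjects, function(s) {
    segs <- extract_segments(embedding, s, tau)
    lin <- purrr::map_dfr(segs$points, linearize_segment, slope_bound = slope_bound)
    dplyr::bind_cols(segs[c("subject_id", "start")], lin)
  })
}

#' Temporal orientation of an exemplar
#'
#' An exemplar is a line segment; which end is "time 1" is decided by the
#' member segments: the sign of the dot product between the exemplar's unit
#' direction vector `(1, slope)/||.||` and the mean temporal displacement
#' (last minus first point) of the member segments. A zero dot product maps
#' to +1.
#'
#' @param slope Exemplar slope.
#' @param dx,dy Member segments' temporal displacements.
#' @return `+1` or `-1`.
#' @export
orient_exemplar <- function(slope, dx, dy) {
  u <- c(1, slope) / sqrt(1 + slope^2)
  dp <- u[1L] * mean(dx) + u[2L] * mean(dy)
  if (dp < 0) -1 else 1
}

#' Cluster linearized segments into linear trajectory exemplars
#'
#' k-means on the `(x, y, slope)` triples of the linearized segments (slopes
#' already clipped); each cluster centroid induces an exemplar whose length
#' is the mean member segment length and whose temporal direction comes from
#' [orient_exemplar()].
#'
#' @param lts Tibble of linearized segments from [linearize_cohort()].
#' @param k Number of exemplars (default 10).
#' @param seed Integer seed (default 1).
#' @param iter_max,restarts k-means control (defaults 2000 / 250).
#' @param slope_bound The slope bound used during linearization (stored).
#' @param tau Segment duration (stored).
#' @return An object of class `evo_exemplar_set`: `exemplars` tibble (`id`,
#'   `x`, `y`, `slope`, `length`, `sign`), `membership` (the input tibble
#'   plus a `cluster` column), `k`, `slope_bound`, `tau`, `inertia`.
#' @export
cluster_linear_segments <- function(lts, k = 10, seed = 1L, iter_max = 2000L,
                                    restarts = 250L, slope_bound = NULL,
                                    tau = NULL) {
  feat <- as.matrix(lts[, c("x", "y", "slope")])
  if (!is_count(k) || k > nrow(feat)) {
    stop_invalid_parameter(sprintf(
      "`k` must be an integer in [1, %d].", nrow(feat)
    ))
  }
  fit <- kmeans_restarts(feat, k, seed = seed, iter_max = iter_max, restarts = restarts)
  membership <- mutate(lts, cluster = fit$cluster)
  exemplars <- purrr::map_dfr(seq_len(k), function(j) {
    m <- membership[membership$cluster == j, ]
    tibble(
      id = j,
      x = fit$centers[j, 1L], y = fit$centers[j, 2L], slope = fit$centers[j, 3L],
      length = mean(m$length),
      sign = orient_exemplar(fit$centers[j, 3L], m$dx, m$dy)
    )
  })
  structure(
    list(
      exemplars = exemplars, membership = membership, k = as.integer(k),
      slope_bound = slope_bound, tau = tau, inertia = fit$inertia, seed = seed
    ),
    class = "evo_exemplar_set"
  )
}

#' @export
print.evo_exemplar_set <- function(x, ...) {
  cat(sprintf(
    "<evo_exemplar_set> %d exemplars from %d linearized segments (slope bound %s)\n",
    x$k, nrow(x$membership),
    if (is.null(x$slope_bound)) "unset" else format(x$slope_bound, digits = 4)
  ))
  print(x$exemplars)
  invisible(x)
}

#' Full exemplar stage on an embedding
#'
#' Extracts and linearizes every subject's sub-segments and clusters them
#' into `k` linear trajectory exemplars.
#'
#' @inheritParams extract_segments
#' @inheritParams cluster_linear_segments
#' @return An `evo_exemplar_set`.
#' @export
exemplars_from_embedding <- function(embedding, tau = 44, k = 10, seed = 1L,
                                     iter_max = 2000L, restarts = 250L) {
  sb <- compute_slope_bound(embedding)
  lts <- linearize_cohort(embedding, tau = tau, slope_bound = sb)
  cluster_linear_segments(lts, k = k, seed = seed, iter_max = iter_max,
                          restarts = restarts, slope_bound = sb, tau = tau)
}

#' Evenly spaced points along an oriented exemplar
#'
#' Divides the exemplar's line segment (length `length`, slope `slope`,
#' centered at `(x, y)`) into `tau` evenly spaced points, with point 1 at the
#' tail end given by the direction sign and spacing `length / (tau - 1)`.
#'
#' @param exemplar One row of an `evo_exemplar_set$exemplars` tibble (or any
#'   list with `x`, `y`, `slope`, `length`, `sign`).
#' @param tau Number of points (>= 2).
#' @return `tau x 2` coordinate matrix.
#' @export
sample_exemplar_points <- function(exemplar, tau = 44) {
  if (!is_count(tau, min = 2L)) stop_invalid_parameter("`tau` must be an integer >= 2.")
  d <- exemplar$length
  if (is.null(d) || !is.finite(d) || d <= 0) {
    stop_degenerate("Exemplar has zero length.", class = "evodfnc_degenerate_exemplar")
  }
  u <- c(1, exemplar$slope) / sqrt(1 + exemplar$slope^2) * exemplar$sign
  offs <- seq(-d / 2, d / 2, length.out = tau)
  cbind(exemplar$x + offs * u[1L], exemplar$y + offs * u[2L])
}

#' Exemplar-cluster membership occupancy
#'
#' Fraction of a subject's linearized segments assigned to each exemplar
#' cluster; the entries sum to one. This is the embedding-intrinsic
#' counterpart of motif representational importance.
#'
#' @param exemplar_set An `evo_exemplar_set`.
#' @param subject_id Subject to summarize; omit for a cohort tibble.
#' @return Numeric vector of length `k`, or a tibble (`subject_id`,
#'   `cluster`, `occupancy`).
#' @export
exemplar_membership_occupancy <- function(exemplar_set, subject_id = NULL) {
  if (!inherits(exemplar_set, "evo_exemplar_set")) {
    stop_invalid_input("`exemplar_set` must come from cluster_linear_segments().")
  }
  m <- exemplar_set$membership
  if (is.null(subject_id)) {
    return(
      m |>
        group_by(.data$subject_id) |>
        reframe(occupancy = label_occupancy(.data$cluster, exemplar_set$k)) |>
        group_by(.data$subject_id) |>
        mutate(cluster = dplyr::row_number(), .before = "occupancy") |>
        ungroup()
    )
  }
  rows <- m$subject_id == subject_id
  if (!any(rows)) stop_not_found(sprintf("Unknown subject '%s'.", subject_id))
  label_occupancy(m$cluster[rows], exemplar_set$k)
}

#' Inertia-versus-k table for exemplar clustering
#'
#' Reports total within-cluster inertia for a sweep of cluster counts, the
#' raw material for an elbow plot.
#'
#' @param lts Linearized-segment tibble.
#' @param ks Integer vector of cluster counts to try.
#' @param seed,iter_max,restarts Passed to [kmeans_restarts()] (restarts
#'   default 50 for the sweep).
#' @return Tibble with columns `k`, `inertia`.
#' @export
exemplar_inertia_table <- function(lts, ks = 2:15, seed = 1L, iter_max = 2000L,
                                   restarts = 50L) {
  feat <- as.matrix(lts[, c("x", "y", "slope")])
  purrr::map_dfr(ks, function(k) {
    tibble(k = k,
           inertia = kmeans_restarts(feat, k, seed = seed, iter_max = iter_max,
                                     restarts = restarts)$inertia)
  })
}
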