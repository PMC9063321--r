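# standardize rows to zero mean / unit sum of squares so that Pearson
# correlation between two rows is a plain dot product; zero-variance rows are
# flagged and zeroed (their correlations are defined as 0)
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  zero <- ss <= 1e-14 * max(ss, 1e-300)
  ss[zero] <- 1
  list(z = xc / ss, zero = zero)
}

#' Frame-wise correlations between a window and every motif
#'
#' Entry `(t, k)` is the Pearson correlation, across the `D` connectivity
#' features, between observed frame `t` of the window and frame `t` of motif
#' `k`. A zero-variance frame (observed or motif) yields correlation 0 for
#' the affected entries, with a warning.
#'
#' @param window Numeric `tau x D` matrix of observed frames.
#' @param motifs An `evo_motif_set` with matching `tau` and `D`.
#' @return Numeric `tau x K` matrix.
#' @export
framewise_correlations <- function(window, motifs) {
  window <- as.matrix(window)
  if (nrow(window) != motifs$tau || ncol(window) != motifs$d) {
    stop_invalid_input(sprintf(
      "`window` must be %d x %d to match the motif set.", motifs$tau, motifs$d
    ))
  }
  zw <- standardize_rows(window)
  k <- length(motifs$motifs)
  out <- matrix(0, motifs$tau, k)
  any_zero <- any(zw$zero)
  for (j in seq_len(k)) {
    zm <- standardize_rows(motifs$motifs[[j]])
    out[, j] <- rowSums(zw$z * zm$z)
    if (any(zm$zero)) any_zero <- TRUE
    out[zw$zero | zm$zero, j] <- 0
  }
  if (any_zero) {
    warn("Zero-variance frame encountered; affected correlations set to 0.",
         class = "evodfnc_zero_variance_frame")
  }
  pmin(pmax(out, -1), 1)
}

#' Motif weights for one observed window
#'
#' In `"argmax"` mode (the default definition of representational
#' importance), each of the `tau` frames votes for the motif whose
#' corresponding frame correlates best with it (ties toward the smallest
#' motif id), and the weight of motif `k` is its share of the votes — so the
#' weights are multiples of `1/tau` and sum to 1. In `"meancorr"` mode the
#' weight is the mean frame-wise correlation over the window.
#'
#' @inheritParams framewise_correlations
#' @param mode `"argmax"` or `"meancorr"`.
#' @return Numeric vector of length `K`.
#' @export
ri_weights <- function(window, motifs, mode = c("argmax", "meancorr")) {
  mode <- match.arg(mode)
  fc <- framewise_correlations(window, motifs)
  ri_weights_from_corr(fc, mode)
}

ri_weights_from_corr <- function(fc, mode) {
  if (mode == "argmax") {
    lab <- apply(fc, 1L, which.max) # which.max: first max = smallest motif id
    tabulate(lab, nbins = ncol(fc)) / nrow(fc)
  } else {
    colMeans(fc)
  }
}

#' Representational-importance time series for one subject
#'
#' Slides a length-`tau` window (step 1) along the subject's dFNC sequence
#' and computes the motif weight vector of every window, yielding a
#' `(W - tau + 1) x K` weight matrix.
#'
#' @param sequence An `evo_dfnc_sequence`.
#' @param motifs An `evo_motif_set`.
#' @param mode `"argmax"` or `"meancorr"` (see [ri_weights()]).
#' @return An object of class `evo_ri`: `subject_id`, `weights`, `mode`,
#'   `tau`.
#' @export
ri_series <- function(sequence, motifs, mode = c("argmax", "meancorr")) {
  mode <- match.arg(mode)
  frames <- sequence$frames
  w <- nrow(frames)
  tau <- motifs$tau
  if (w < tau) {
    stop_invalid_input(sprintf(
      "Subject '%s' has %d windows, fewer than tau = %d.",
      sequence$subject_id, w, tau
    ))
  }
  # correlate all frames against every motif frame position in one pass:
  # cross[w, t, k] = cor(observed frame w, motif k frame t)
  zf <- standardize_rows(frames)
  n_ri <- w - tau + 1L
  k <- length(motifs$motifs)
  votes_best <- NULL
  cross <- array(0, dim = c(w, tau, k))
  any_zero <- FALSE
  for (j in seq_len(k)) {
    zm <- standardize_rows(motifs$motifs[[j]])
    cc <- tcrossprod(zf$z, zm$z) # w x tau
    cc[zf$zero, ] <- 0
    cc[, zm$zero] <- 0
    if (any(zm$zero)) any_zero <- TRUE
    cross[, , j] <- cc
  }
  if (any(zf$zero)) any_zero <- TRUE
  if (any_zero) {
    warn("Zero-variance frame encountered; affected correlations set to 0.",
         class = "evodfnc_zero_variance_frame")
  }
  weights <- matrix(0, n_ri, k)
  for (i in seq_len(n_ri)) {
    fc <- matrix(0, tau, k)
    idx <- i:(i + tau - 1L)
    for (j in seq_len(k)) fc[, j] <- cross[cbind(idx, seq_len(tau), j)]
    weights[i, ] <- ri_weights_from_corr(pmin(pmax(fc, -1), 1), mode)
  }
  structure(
    list(subject_id = sequence$subject_id, weights = weights, mode = mode,
         tau = tau),
    class = "evo_ri"
  )
}

#' Representational importance for a whole cohort
#'
#' @param seqs List of `evo_dfnc_sequence` objects.
#' @inheritParams ri_series
#' @return An object of class `evo_ri_cohort`: `series` (named list of
#'   `evo_ri`), `stacked` (all weight rows), `index` tibble (`subject_id`,
#'   `window`), `mode`, `tau`.
#' @export
ri_cohort <- function(seqs, motifs, mode = c("argmax", "meancorr")) {
  mode <- match.arg(mode)
  series <- lapply(seqs, ri_series, motifs = motifs, mode = mode)
  names(series) <- vapply(series, `[[`, character(1), "subject_id")
  stacked <- do.call(rbind, lapply(series, `[[`, "weights"))
  index <- purrr::map_dfr(series, function(s) {
    tibble(subject_id = s$subject_id, window = seq_len(nrow(s$weights)))
  })
  structure(
    list(series = series, stacked = stacked, index = index, mode = mode,
         tau = motifs$tau),
    class = "evo_ri_cohort"
  )
}

#' Subject-level motif importance features
#'
#' Reduces each subject's weight time series to one value per motif (the
#' temporal mean by default, median optionally), giving the subject-by-motif
#' feature matrix used in group models.
#'
#' @param ri An `evo_ri_cohort`.
#' @param reduce `"mean"` (default) or `"median"`.
#' @return Numeric matrix, subjects in rows (rownames = subject ids), motifs
#'   in columns.
#' @export
subject_mean_ri <- function(ri, reduce = c("mean", "median")) {
  reduce <- match.arg(reduce)
  f <- if (reduce == "mean") colMeans else function(m) apply(m, 2L, stats::median)
  out <- t(vapply(ri$series, function(s) f(s$weights), numeric(ncol(ri$stacked))))
  rownames(out) <- names(ri$series)
  colnames(out) <- paste0("motif", seq_len(ncol(out)))
  out
}

#' Cluster motif weight vectors into meta-states
#'
#' k-means over all subjects' time-indexed weight vectors; each centroid
#' defines a meta-motif (see [induce_meta()]) and cluster membership defines
#' meta-state occupancy.
#'
#' @param ri An `evo_ri_cohort` (or a plain weight matrix plus `index`).
#' @param m Number of meta-states (default 10).
#' @param seed Integer seed (default 1).
#' @param iter_max,restarts k-means control (defaults 2000 / 500).
#' @param index Row index tibble when `ri` is a plain matrix.
#' @return An object of class `evo_meta_states`: `centroids` (`M x K`),
#'   `assignments` tibble (`subject_id`, `window`, `cluster`), `m`.
#' @export
cluster_weight_vectors <- function(ri, m = 10, seed = 1L, iter_max = 2000L,
                                   restarts = 500L, index = NULL) {
  if (inherits(ri, "evo_ri_cohort")) {
    x <- ri$stacked
    index <- ri$index
  } else {
    x <- as.matrix(ri)
    if (is.null(index)) {
      index <- tibble(subject_id = "s1", window = seq_len(nrow(x)))
    }
  }
  fit <- kmeans_restarts(x, m, seed = seed, iter_max = iter_max, restarts = restarts)
  structure(
    list(
      centroids = fit$centers,
      assignments = mutate(index, cluster = fit$cluster),
      m = as.integer(m), inertia = fit$inertia, seed = seed
    ),
    class = "evo_meta_states"
  )
}

#' Induce a meta-motif from a weight centroid
#'
#' A meta-motif is the centroid-weighted sum of the basis motifs:
#' `frames = sum_k centroid[k] * motif_k` (no renormalization).
#'
#' @param motifs An `evo_motif_set`.
#' @param centroid Numeric weight vector of length `K`.
#' @return An object of class `evo_motif` whose `frames` is the weighted sum.
#' @export
induce_meta <- function(motifs, centroid) {
  if (length(centroid) != length(motifs$motifs)) {
    stop_invalid_input("`centroid` must have one weight per motif.")
  }
  frames <- Reduce(`+`, purrr::map2(motifs$motifs, centroid, function(f, w) w * f))
  structure(list(id = NA_integer_, frames = frames, exemplar_id = NA_integer_),
            class = "evo_motif")
}

#' Induce every meta-motif of a meta-state set
#'
#' @param motifs An `evo_motif_set`.
#' @param meta An `evo_meta_states`.
#' @return An `evo_motif_set` of `M` meta-motifs.
#' @export
induce_meta_all <- function(motifs, meta) {
  frames <- lapply(seq_len(meta$m), function(j) induce_meta(motifs, meta$centroids[j, ])$frames)
  names(frames) <- paste0("meta", seq_len(meta$m))
  structure(
    list(motifs = frames, tau = motifs$tau, n_neighbors = motifs$n_neighbors,
         d = motifs$d),
    class = "evo_motif_set"
  )
}

#' Meta-state occupancy rates
#'
#' Fraction of a subject's time-indexed weight vectors assigned to each
#' meta-state cluster; the entries sum to one.
#'
#' @param meta An `evo_meta_states`.
#' @param subject_id Subject to summarize; omit for a cohort tibble.
#' @return Numeric vector of length `M`, or a tibble (`subject_id`,
#'   `cluster`, `occupancy`).
#' @export
meta_occupancy <- function(meta, subject_id = NULL) {
  if (!inherits(meta, "evo_meta_states")) {
    stop_invalid_input("`meta` must come from cluster_weight_vectors().")
  }
  a <- meta$assignments
  if (nrow(a) == 0L) stop_invalid_input("Empty meta-state assignment.")
  if (is.null(subject_id)) {
    return(
      a |>
        group_by(.data$subject_id) |>
        reframe(occupancy = label_occupancy(.data$cluster, meta$m)) |>
        group_by(.data$subject_id) |>
        mutate(cluster = dplyr::row_number(), .before = "occupancy") |>
        ungroup()
    )
  }
  rows <- a$subject_id == subject_id
  if (!any(rows)) stop_not_found(sprintf("Unknown subject '%s'.", subject_id))
  label_occupancy(a$cluster[rows], meta$m)
}

#' Project new weight vectors onto existing meta-states
#'
#' Nearest-centroid assignment for subjects that were not part of the
#' original weight-vector clustering.
#'
#' @param ri An `evo_ri` (one subject) or weight matrix.
#' @param meta An `evo_meta_states`.
#' @return Integer cluster labels.
#' @export
assign_meta <- function(ri, meta) {
  x <- if (inherits(ri, "evo_ri")) ri$weights else as.matrix(ri)
  d2 <- vapply(seq_len(meta$m), function(j) {
    rowSums((x - matrix(meta$centroids[j, ], nrow(x), ncol(x), byrow = TRUE))^2)
  }, numeric(nrow(x)))
  max.col(-matrix(d2, nrow(x), meta$m), ties.method = "first")
}
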