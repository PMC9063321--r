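#' Construct a network timecourse object
#'
#' Wraps a `T x N` matrix of network timecourses (rows = TRs, columns =
#' networks, e.g. ICA-derived resting-state network timecourses) with its
#' subject id and sampling interval.
#'
#' @param values Numeric `T x N` matrix, no missing values, every column with
#'   nonzero variance.
#' @param subject_id Subject identifier (string).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @return An object of class `evo_timecourse`.
#' @export
timecourse <- function(values, subject_id, tr_seconds = 2) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop_invalid_input("`values` must be a finite numeric matrix with no missing values.")
  }
  if (ncol(values) < 2L) stop_invalid_input("At least 2 networks are required.")
  v <- apply(values, 2L, stats::var)
  if (any(v <= 0)) {
    stop_invalid_input(sprintf(
      "Networks with zero variance over the scan: %s.",
      paste(colnames(values)[v <= 0], collapse = ", ")
    ))
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop_invalid_parameter("`tr_seconds` must be positive.")
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("net", seq_len(ncol(values)))
  structure(
    list(
      subject_id = as.character(subject_id), values = values,
      tr_seconds = tr_seconds
    ),
    class = "evo_timecourse"
  )
}

#' @export
print.evo_timecourse <- function(x, ...) {
  cat(sprintf(
    "<evo_timecourse> subject %s: %d TRs x %d networks (TR = %gs)\n",
    x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds
  ))
  invisible(x)
}

# weighted Pearson correlation of the columns of x under observation weights w
weighted_corr <- function(x, w) {
  w <- w / sum(w)
  mu <- drop(crossprod(x, w))
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc * w, xc)
  v <- diag(cv)
  bad <- v <= 1e-14 * max(v, 0)
  if (any(bad)) return(list(corr = NULL, bad = which(bad)))
  sd <- sqrt(v)
  corr <- cv / tcrossprod(sd)
  corr <- pmin(pmax(corr, -1), 1)
  diag(corr) <- 1
  list(corr = corr, bad = integer(0))
}

#' Compute tapered sliding-window dynamic connectivity
#'
#' Slides a tapered rectangular window (see [build_taper()]) along the
#' timecourses and, in each window, computes the weighted Pearson correlation
#' matrix between all network pairs, vectorized with [vectorize_upper()].
#' For `N` networks each window yields `D = N(N-1)/2` features; with step 1
#' there are `W = T - window_len + 1` windows.
#'
#' @param tc An [timecourse()] object (or a plain numeric matrix, in which
#'   case `subject_id` defaults to `"s1"`).
#' @param window_len Window length in TRs (default 22).
#' @param sigma Gaussian taper width in TRs, `Inf` for a pure rectangle
#'   (default 3).
#' @param step Window advance in TRs (default 1).
#' @param fisher_z Apply Fisher z-transform (`atanh`) to the correlations
#'   (default `FALSE`; when enabled, features are no longer bounded by 1).
#' @return An object of class `evo_dfnc_sequence` with elements `subject_id`,
#'   `frames` (`W x D` matrix), `window_len`, `step`, `sigma`,
#'   `network_names`.
#' @export
compute_windowed_dfnc <- function(tc, window_len = 22, sigma = 3, step = 1,
                                  fisher_z = FALSE) {
  if (is.matrix(tc)) tc <- timecourse(tc, "s1")
  if (!inherits(tc, "evo_timecourse")) {
    stop_invalid_input("`tc` must be an `evo_timecourse` or numeric matrix.")
  }
  if (!is_count(step)) stop_invalid_parameter("`step` must be a positive integer.")
  x <- tc$values
  n_t <- nrow(x)
  if (n_t < window_len) {
    stop_invalid_input(sprintf(
      "Subject %s has %d TRs, fewer than window_len = %d.",
      tc$subject_id, n_t, window_len
    ))
  }
  w <- build_taper(window_len, sigma)
  n_w <- floor((n_t - window_len) / step) + 1L
  starts <- 1L + (seq_len(n_w) - 1L) * as.integer(step)
  d <- ncol(x) * (ncol(x) - 1L) / 2L
  frames <- matrix(NA_real_, n_w, d)
  nm <- colnames(x)
  pair_idx <- which(upper.tri(diag(ncol(x))), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1L], pair_idx[, 2L]), , drop = FALSE]
  colnames(frames) <- paste(nm[pair_idx[, 1L]], nm[pair_idx[, 2L]], sep = "|")
  for (i in seq_len(n_w)) {
    seg <- x[starts[i]:(starts[i] + window_len - 1L), , drop = FALSE]
    wc <- weighted_corr(seg, w)
    if (length(wc$bad) > 0L) {
      stop_degenerate(
        sprintf(
          "Zero weighted variance for subject %s, window %d (start TR %d), network(s) %s.",
          tc$subject_id, i, starts[i], paste(nm[wc$bad], collapse = ", ")
        ),
        class = "evodfnc_degenerate_window"
      )
    }
    frames[i, ] <- vectorize_upper(wc$corr)
  }
  if (fisher_z) frames <- atanh(pmin(pmax(frames, -1 + 1e-15), 1 - 1e-15))
  structure(
    list(
      subject_id = tc$subject_id, frames = frames,
      window_len = as.integer(window_len), step = as.integer(step),
      sigma = sigma, network_names = nm
    ),
    class = "evo_dfnc_sequence"
  )
}

#' @export
print.evo_dfnc_sequence <- function(x, ...) {
  cat(sprintf(
    "<evo_dfnc_sequence> subject %s: %d windows x %d features (window %d TRs, step %d)\n",
    x$subject_id, nrow(x$frames), ncol(x$frames), x$window_len, x$step
  ))
  invisible(x)
}

#' Stack per-subject dFNC sequences into one frame matrix
#'
#' Row order is preserved end-to-end: row `i` of the stacked matrix always
#' refers to the subject/window recorded in row `i` of the index.
#'
#' @param seqs List of `evo_dfnc_sequence` objects.
#' @return An object of class `evo_dfnc_stack`: `frames` (all subjects'
#'   windows stacked) and `index`, a tibble with columns `subject_id`,
#'   `window`, `row`.
#' @export
stack_dfnc <- function(seqs) {
  if (inherits(seqs, "evo_dfnc_sequence")) seqs <- list(seqs)
  dims <- vapply(seqs, function(s) ncol(s$frames), integer(1))
  if (length(unique(dims)) != 1L) {
    stop_invalid_input("All subjects must share the same feature dimension.")
  }
  frames <- do.call(rbind, lapply(seqs, `[[`, "frames"))
  index <- purrr::map_dfr(seqs, function(s) {
    tibble(subject_id = s$subject_id, window = seq_len(nrow(s$frames)))
  })
  index$row <- seq_len(nrow(index))
  structure(
    list(
      frames = frames, index = index,
      window_len = seqs[[1L]]$window_len,
      network_names = seqs[[1L]]$network_names
    ),
    class = "evo_dfnc_stack"
  )
}

#' Time-blind snapshot dFNC states (k-means baseline)
#'
#' Clusters all subjects' windowed connectivity frames, ignoring temporal
#' order, into `k` snapshot states (the conventional "dFNC state" baseline
#' against which evolving motifs are contrasted).
#'
#' @param stacked An [stack_dfnc()] object.
#' @param k Number of states (default 5).
#' @param seed Integer seed (default 1).
#' @param iter_max,restarts k-means control, see [kmeans_restarts()];
#'   defaults 2000 iterations and 250 restarts.
#' @return An object of class `evo_snap_states`: `centroids` (`k x D`),
#'   `assignments` tibble (`subject_id`, `window`, `state`), `k`, `inertia`.
#' @export
cluster_snapshots <- function(stacked, k = 5, seed = 1L, iter_max = 2000L,
                              restarts = 250L) {
  if (!inherits(stacked, "evo_dfnc_stack")) {
    stop_invalid_input("`stacked` must come from stack_dfnc().")
  }
  fit <- kmeans_restarts(stacked$frames, k, seed = seed, iter_max = iter_max,
                         restarts = restarts)
  structure(
    list(
      centroids = fit$centers,
      assignments = mutate(stacked$index, state = fit$cluster),
      k = as.integer(k), inertia = fit$inertia, seed = seed
    ),
    class = "evo_snap_states"
  )
}

# shared helper: fraction of labels per cluster for one subject
label_occupancy <- function(labels, n_levels) {
  tabulate(labels, nbins = n_levels) / length(labels)
}

#' Snapshot-state occupancy rates
#'
#' Fraction of a subject's windows assigned to each snapshot state; the
#' entries sum to one.
#'
#' @param states An [cluster_snapshots()] result.
#' @param subject_id Subject to summarize; omit to get a tibble for the whole
#'   cohort.
#' @return For one subject, a numeric vector of length `k`; otherwise a
#'   tibble with columns `subject_id`, `state`, `occupancy`.
#' @export
snapshot_occupancy <- function(states, subject_id = NULL) {
  if (!inherits(states, "evo_snap_states")) {
    stop_invalid_input("`states` must come from cluster_snapshots().")
  }
  if (is.null(subject_id)) {
    return(
      states$assignments |>
        group_by(.data$subject_id) |>
        reframe(occupancy = label_occupancy(.data$state, states$k)) |>
        group_by(.data$subject_id) |>
        mutate(state = dplyr::row_number(), .before = "occupancy") |>
        ungroup()
    )
  }
  rows <- states$assignments$subject_id == subject_id
  if (!any(rows)) stop_not_found(sprintf("Unknown subject '%s'.", subject_id))
  label_occupancy(states$assignments$state[rows], states$k)
}
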