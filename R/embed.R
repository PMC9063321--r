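#' Planar embedding configuration
#'
#' Parameters for the multi-run averaged UMAP embedding of windowed
#' connectivity frames. Defaults are the values used throughout the package:
#' 25 nearest neighbors, minimum embedded distance 0.75, 25 independent runs
#' averaged pointwise.
#'
#' @param n_neighbors UMAP nearest-neighbor count (>= 2, default 25).
#' @param min_dist UMAP minimum embedded distance in (0, 1) (default 0.75).
#' @param n_runs Number of independent embedding runs to average (default 25).
#' @param base_seed Integer; run `r` uses seed `base_seed + r` (default 1).
#' @param align_runs If `TRUE` (default), runs 2..R are mapped onto run 1 by
#'   the best-fit similarity (orthogonal Procrustes) transform before
#'   averaging, guarding against the rotation/reflection indeterminacy of
#'   independent UMAP runs; `FALSE` averages the raw run coordinates.
#' @return An object of class `evo_embed_config`.
#' @export
embed_config <- function(n_neighbors = 25, min_dist = 0.75, n_runs = 25,
                         base_seed = 1L, align_runs = TRUE) {
  if (!is_count(n_neighbors, min = 2L)) {
    stop_invalid_parameter("`n_neighbors` must be an integer >= 2.")
  }
  if (!is.numeric(min_dist) || min_dist <= 0 || min_dist >= 1) {
    stop_invalid_parameter("`min_dist` must lie in (0, 1).")
  }
  if (!is_count(n_runs)) stop_invalid_parameter("`n_runs` must be a positive integer.")
  structure(
    list(
      n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
      n_runs = as.integer(n_runs), base_seed = as.integer(base_seed),
      align_runs = isTRUE(align_runs)
    ),
    class = "evo_embed_config"
  )
}

#' One UMAP embedding run
#'
#' Embeds the stacked frames into 2D with UMAP (spectral initialization,
#' single-threaded optimizer) deterministically for a given
#' `(base_seed, run_index)` pair. Row order is preserved.
#'
#' @param frames Numeric matrix of stacked dFNC frames (or an
#'   [stack_dfnc()] object).
#' @param config An [embed_config()].
#' @param run_index Which run this is (seed offset), default 1.
#' @return List with `run_index` and `coords` (`nrow(frames) x 2`).
#' @export
embed_once <- function(frames, config = embed_config(), run_index = 1L) {
  if (inherits(frames, "evo_dfnc_stack")) frames <- frames$frames
  frames <- as.matrix(frames)
  if (nrow(frames) < config$n_neighbors + 1L) {
    stop_invalid_parameter(sprintf(
      "Need at least n_neighbors + 1 = %d frames (got %d).",
      config$n_neighbors + 1L, nrow(frames)
    ))
  }
  set.seed(config$base_seed + as.integer(run_index))
  coords <- uwot::umap(
    frames,
    n_neighbors = config$n_neighbors, min_dist = config$min_dist,
    init = "spectral", n_threads = 1, n_sgd_threads = 0, verbose = FALSE
  )
  coords <- matrix(as.numeric(coords), nrow(coords), 2L) # drop uwot attributes
  list(run_index = as.integer(run_index), coords = coords)
}

# best-fit similarity transform (rotation/reflection + scale + translation)
# mapping x onto y, via the closed-form orthogonal Procrustes solution
procrustes_map <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2L, cx)
  y0 <- sweep(y, 2L, cy)
  sv <- svd(crossprod(y0, x0))
  rot <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(x0^2)
  sweep(s * (x0 %*% rot), 2L, cy, `+`)
}

#' Average multiple embedding runs
#'
#' Pointwise mean of the run coordinates. With `align_runs = FALSE` this is
#' the literal coordinate average over runs; with `align_runs = TRUE`, runs
#' 2..R are first mapped onto run 1 by the best-fit similarity transform,
#' guarding against UMAP's rotation/reflection indeterminacy.
#'
#' @param runs List of [embed_once()] results.
#' @param index Optional tibble identifying each row (e.g. from
#'   [stack_dfnc()]'s `index`).
#' @param config The [embed_config()] used (stored for provenance).
#' @param align_runs Override of `config$align_runs`.
#' @return An object of class `evo_embedding`: `coords`
#'   (`total frames x 2`), `frame_index`, `config`.
#' @export
average_runs <- function(runs, index = NULL, config = embed_config(),
                         align_runs = config$align_runs) {
  coords_list <- lapply(runs, `[[`, "coords")
  n <- vapply(coords_list, nrow, integer(1))
  if (length(unique(n)) != 1L) {
    stop_invalid_input("All runs must embed the same number of frames.")
  }
  if (isTRUE(align_runs) && length(coords_list) > 1L) {
    ref <- coords_list[[1L]]
    coords_list <- c(list(ref), lapply(coords_list[-1L], procrustes_map, y = ref))
  }
  coords <- Reduce(`+`, coords_list) / length(coords_list)
  if (is.null(index)) {
    index <- tibble(subject_id = "s1", window = seq_len(nrow(coords)),
                    row = seq_len(nrow(coords)))
  }
  structure(
    list(coords = coords, frame_index = index, config = config),
    class = "evo_embedding"
  )
}

#' Stabilized planar embedding of a dFNC cohort
#'
#' Runs UMAP `n_runs` times on all subjects' stacked frames (group-level
#' embedding) and averages the runs pointwise. Averaging stabilizes the
#' embedding while preserving within-subject trajectory continuity.
#'
#' @param stacked An [stack_dfnc()] object.
#' @param config An [embed_config()].
#' @return An `evo_embedding` (see [average_runs()]).
#' @export
embed_dfnc <- function(stacked, config = embed_config()) {
  if (!inherits(stacked, "evo_dfnc_stack")) {
    stop_invalid_input("`stacked` must come from stack_dfnc().")
  }
  runs <- lapply(seq_len(config$n_runs), function(r) {
    embed_once(stacked$frames, config, run_index = r)
  })
  average_runs(runs, index = stacked$index, config = config)
}

#' @export
print.evo_embedding <- function(x, ...) {
  cat(sprintf(
    "<evo_embedding> %d frames, %d subjects (n_neighbors = %d, min_dist = %g, runs = %d)\n",
    nrow(x$coords), length(unique(x$frame_index$subject_id)),
    x$config$n_neighbors, x$config$min_dist, x$config$n_runs
  ))
  invisible(x)
}

subject_coords <- function(embedding, subject_id) {
  rows <- embedding$frame_index$subject_id == subject_id
  if (!any(rows)) stop_not_found(sprintf("Unknown subject '%s'.", subject_id))
  embedding$coords[embedding$frame_index$row[rows][order(embedding$frame_index$window[rows])], ,
                   drop = FALSE]
}

#' Within-subject trajectory continuity diagnostic
#'
#' Ratio of the median 2D distance between a subject's temporally consecutive
#' embedded frames to the median distance among `n_pairs` random frame pairs
#' drawn across the whole embedding. Values well below 1 indicate that the
#' embedding preserves the temporal smoothness of the native trajectories.
#'
#' @param embedding An `evo_embedding`.
#' @param subject_id Subject to evaluate (needs >= 3 embedded frames).
#' @param n_pairs Number of random reference pairs (default 1000).
#' @param seed Seed for the random pairs (default 1).
#' @return Nonnegative scalar; smaller is smoother.
#' @export
continuity_ratio <- function(embedding, subject_id, n_pairs = 1000L, seed = 1L) {
  pts <- subject_coords(embedding, subject_id)
  if (nrow(pts) < 3L) {
    stop_invalid_input(sprintf(
      "Subject '%s' has %d embedded frames; at least 3 required.",
      subject_id, nrow(pts)
    ))
  }
  consec <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  all_pts <- embedding$coords
  set.seed(seed)
  i <- sample.int(nrow(all_pts), n_pairs, replace = TRUE)
  j <- sample.int(nrow(all_pts), n_pairs, replace = TRUE)
  ref <- sqrt(rowSums((all_pts[i, , drop = FALSE] - all_pts[j, , drop = FALSE])^2))
  stats::median(consec) / stats::median(ref)
}
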