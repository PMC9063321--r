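#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an effect table
#'
#' @param x An `evo_effects` object.
#' @param ... Unused.
#' @return A tibble with one row per (feature, predictor) test.
#' @export
tidy.evo_effects <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an effect table
#'
#' @param x An `evo_effects` object.
#' @param alpha Significance level applied to the corrected q-values
#'   (default 0.05).
#' @param ... Unused.
#' @return Tibble with `model`, `n_subjects`, `n_tests`, `n_significant`,
#'   `correction`.
#' @export
glance.evo_effects <- function(x, alpha = 0.05, ...) {
  tibble(
    model = attr(x, "model"), n_subjects = attr(x, "n_subjects"),
    n_tests = nrow(x), n_significant = sum(x$q.value < alpha),
    correction = attr(x, "correction")
  )
}

#' Tidy a snapshot-state clustering
#'
#' @param x An `evo_snap_states` object.
#' @param ... Unused.
#' @return Assignments tibble (`subject_id`, `window`, `row`, `state`).
#' @export
tidy.evo_snap_states <- function(x, ...) x$assignments

#' @export
glance.evo_snap_states <- function(x, ...) {
  tibble(k = x$k, n_frames = nrow(x$assignments), inertia = x$inertia)
}

#' Tidy an exemplar set
#'
#' @param x An `evo_exemplar_set`.
#' @param ... Unused.
#' @return The exemplar tibble (`id`, `x`, `y`, `slope`, `length`, `sign`).
#' @export
tidy.evo_exemplar_set <- function(x, ...) x$exemplars

#' @export
glance.evo_exemplar_set <- function(x, ...) {
  tibble(k = x$k, n_segments = nrow(x$membership), slope_bound = x$slope_bound,
         tau = x$tau, inertia = x$inertia)
}

#' Tidy an embedding
#'
#' @param x An `evo_embedding`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `window`, `x`, `y`.
#' @export
tidy.evo_embedding <- function(x, ...) {
  cx <- x$coords[, 1L]
  cy <- x$coords[, 2L]
  mutate(x$frame_index, x = cx, y = cy) |>
    select(-"row")
}

#' Tidy a motif set into long format
#'
#' @param x An `evo_motif_set`.
#' @param ... Unused.
#' @return Tibble with `motif`, `frame`, `feature`, `value`.
#' @export
tidy.evo_motif_set <- function(x, ...) {
  purrr::imap_dfr(x$motifs, function(m, nm) {
    tibble(
      motif = nm,
      frame = rep(seq_len(nrow(m)), ncol(m)),
      feature = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m)
    )
  })
}

#' @export
glance.evo_motif_set <- function(x, ...) {
  tibble(n_motifs = length(x$motifs), tau = x$tau, d = x$d,
         window_values = x$tau * x$d, lift_neighbors = x$n_neighbors)
}

#' Tidy a representational-importance cohort
#'
#' @param x An `evo_ri_cohort`.
#' @param ... Unused.
#' @return Long tibble with `subject_id`, `window`, `motif`, `weight`.
#' @export
tidy.evo_ri_cohort <- function(x, ...) {
  k <- ncol(x$stacked)
  tidyr::uncount(x$index, weights = k) |>
    mutate(motif = rep(seq_len(k), nrow(x$index)),
           weight = as.vector(t(x$stacked)))
}
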