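#' Lift one 2D point back to connectivity space
#'
#' The data-driven inverse of the embedding at a query point: the unweighted
#' mean of the `n` dFNC frames whose embedded coordinates are spatially
#' nearest (Euclidean distance in the plane) to the query. Neighbors are
#' drawn from all subjects' frames jointly; distance ties at the n-th
#' neighbor break toward the lower frame index.
#'
#' @param point Length-2 numeric vector (x, y).
#' @param embedding An `evo_embedding`.
#' @param frames Stacked dFNC frame matrix (or an [stack_dfnc()] object)
#'   row-aligned with the embedding.
#' @param n Number of nearest neighbors to average (default 25, matching the
#'   embedding's neighborhood size).
#' @return Numeric feature vector of length `D`.
#' @export
lift_point <- function(point, embedding, frames, n = 25) {
  if (inherits(frames, "evo_dfnc_stack")) frames <- frames$frames
  coords <- embedding$coords
  if (is.null(coords) || nrow(coords) == 0L) stop_invalid_input("Empty embedding.")
  if (!is_count(n) || n > nrow(coords)) {
    stop_invalid_parameter(sprintf("`n` must be an integer in [1, %d].", nrow(coords)))
  }
  if (nrow(frames) != nrow(coords)) {
    stop_invalid_input("`frames` and embedding must have the same number of rows.")
  }
  d2 <- (coords[, 1L] - point[1L])^2 + (coords[, 2L] - point[2L])^2
  nn <- order(d2)[seq_len(n)] # radix order: ties resolve to the lower index
  colMeans(frames[nn, , drop = FALSE])
}

#' Lift a 2D exemplar to a multiframe evolving motif
#'
#' Applies [lift_point()] to each of `tau` evenly spaced points along the
#' oriented exemplar segment, producing a `tau x D` evolving connectivity
#' motif (EVOdFNC).
#'
#' @param exemplar One row of an `evo_exemplar_set$exemplars` tibble.
#' @inheritParams lift_point
#' @param tau Motif duration in frames (default 44).
#' @return An object of class `evo_motif`: `id`, `frames` (`tau x D`),
#'   `exemplar_id`.
#' @export
lift_exemplar <- function(exemplar, embedding, frames, tau = 44, n = 25) {
  pts <- sample_exemplar_points(exemplar, tau)
  if (inherits(frames, "evo_dfnc_stack")) frames <- frames$frames
  lifted <- t(apply(pts, 1L, lift_point, embedding = embedding, frames = frames, n = n))
  structure(
    list(id = exemplar$id, frames = lifted, exemplar_id = exemplar$id),
    class = "evo_motif"
  )
}

#' Lift every exemplar in a set
#'
#' @param exemplar_set An `evo_exemplar_set`.
#' @inheritParams lift_exemplar
#' @return An object of class `evo_motif_set`: `motifs` (list of `tau x D`
#'   frame matrices in exemplar id order), `tau`, `n_neighbors`, `d`.
#' @export
lift_all <- function(exemplar_set, embedding, frames, tau = 44, n = 25) {
  if (inherits(frames, "evo_dfnc_stack")) frames <- frames$frames
  motifs <- lapply(seq_len(nrow(exemplar_set$exemplars)), function(i) {
    lift_exemplar(exemplar_set$exemplars[i, ], embedding, frames, tau = tau, n = n)$frames
  })
  names(motifs) <- paste0("motif", exemplar_set$exemplars$id)
  structure(
    list(
      motifs = motifs, tau = as.integer(tau), n_neighbors = as.integer(n),
      d = ncol(frames)
    ),
    class = "evo_motif_set"
  )
}

#' @export
print.evo_motif_set <- function(x, ...) {
  cat(sprintf(
    "<evo_motif_set> %d evolving motifs, %d frames x %d features each (lift n = %d)\n",
    length(x$motifs), x$tau, x$d, x$n_neighbors
  ))
  invisible(x)
}
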