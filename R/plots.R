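#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_col geom_hline facet_wrap scale_fill_gradient2 coord_fixed labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot an averaged embedding
#'
#' Scatter of the embedded frames, one color per subject, showing the
#' continuous per-subject trajectories the embedding is designed to preserve.
#'
#' @param object An `evo_embedding`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evo_embedding <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x, y = .data$y, color = .data$subject_id)) +
    geom_point(size = 0.5, alpha = 0.6, show.legend = FALSE) +
    coord_fixed() +
    labs(x = "embedding x", y = "embedding y",
         title = "Averaged planar embedding of windowed connectivity") +
    theme_minimal()
}

#' Plot linear trajectory exemplars over the embedding
#'
#' @param object An `evo_exemplar_set`.
#' @param embedding Optional `evo_embedding` drawn underneath.
#' @param tau Points per exemplar used to draw the oriented segment.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evo_exemplar_set <- function(object, embedding = NULL, tau = 2, ...) {
  segs <- purrr::map_dfr(seq_len(nrow(object$exemplars)), function(i) {
    ex <- object$exemplars[i, ]
    p <- sample_exemplar_points(ex, max(tau, 2))
    tibble(id = ex$id, x0 = p[1L, 1L], y0 = p[1L, 2L],
           x1 = p[nrow(p), 1L], y1 = p[nrow(p), 2L])
  })
  g <- ggplot()
  if (!is.null(embedding)) {
    bg <- tidy(embedding)
    g <- g + geom_point(data = bg, aes(x = .data$x, y = .data$y),
                        color = "grey80", size = 0.4)
  }
  g +
    geom_segment(
      data = segs,
      aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          color = factor(.data$id)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")), linewidth = 0.9
    ) +
    coord_fixed() +
    labs(x = "embedding x", y = "embedding y", color = "exemplar",
         title = "Linear trajectory exemplars") +
    theme_minimal()
}

#' Plot an evolving motif as a frame strip
#'
#' Each frame is devectorized to its network-by-network correlation matrix
#' and drawn as a heatmap; frames advance left to right. By default every
#' other frame is shown. The color range is symmetric, bounded at the 95th
#' percentile of the motif set's magnitudes.
#'
#' @param object An `evo_motif_set`.
#' @param motif Which motif to display (default 1).
#' @param every Frame subsampling stride (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evo_motif_set <- function(object, motif = 1, every = 2, ...) {
  frames <- object$motifs[[motif]]
  q <- stats::quantile(abs(unlist(object$motifs)), 0.95)
  keep <- seq(1L, nrow(frames), by = every)
  df <- purrr::map_dfr(keep, function(t) {
    m <- devectorize_upper(frames[t, ], diag_value = NA)
    tibble(frame = t, row = rep(seq_len(nrow(m)), ncol(m)),
           col = rep(seq_len(ncol(m)), each = nrow(m)), value = as.vector(m))
  })
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~frame, nrow = 4) +
    scale_fill_gradient2(limits = c(-q, q), oob = scales_squish) +
    ggplot2::scale_y_reverse() +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "corr",
         title = sprintf("Evolving motif %s", names(object$motifs)[motif])) +
    theme_minimal()
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1L]), range[2L])
}

#' Plot an effect table
#'
#' Bar chart of the test statistics per feature and predictor with the
#' corrected-significance features highlighted.
#'
#' @param object An `evo_effects` table.
#' @param alpha q-value significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evo_effects <- function(object, alpha = 0.05, ...) {
  df <- mutate(as_tibble(object), significant = .data$q.value < alpha)
  ggplot(df, aes(x = .data$feature, y = .data$statistic,
                 fill = .data$significant)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    facet_wrap(~predictor) +
    labs(x = NULL, y = "t statistic",
         title = sprintf("%s model (correction: %s)", attr(object, "model"),
                         attr(object, "correction"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
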