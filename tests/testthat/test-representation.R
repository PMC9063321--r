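make_two_motifs <- function(tau = 4, d = 6, seed = 1) {
  set.seed(seed)
  toy_motif_set(list(matrix(rnorm(tau * d), tau, d),
                     matrix(rnorm(tau * d), tau, d)))
}

test_that("framewise correlations match the direct Pearson formula", {
  motifs <- make_two_motifs()
  set.seed(2)
  window <- matrix(rnorm(24), 4, 6)
  fc <- framewise_correlations(window, motifs)
  for (t in 1:4) {
    for (k in 1:2) {
      expect_equal(fc[t, k], cor(window[t, ], motifs$motifs[[k]][t, ]),
                   tolerance = 1e-12)
    }
  }
  # identity and mean-negation extremes
  self_fc <- framewise_correlations(motifs$motifs[[2]], motifs)
  expect_equal(self_fc[, 2], rep(1, 4), tolerance = 1e-12)
  neg <- -sweep(motifs$motifs[[1]], 1, rowMeans(motifs$motifs[[1]])) +
    rowMeans(motifs$motifs[[1]])
  expect_equal(framewise_correlations(neg, motifs)[, 1], rep(-1, 4),
               tolerance = 1e-12)
  expect_error(framewise_correlations(window[1:3, ], motifs),
               class = "evodfnc_invalid_input")
})

test_that("zero-variance frames yield correlation 0 with a classed warning", {
  motifs <- make_two_motifs()
  window <- motifs$motifs[[1]]
  window[2, ] <- 7 # flat frame
  expect_warning(fc <- framewise_correlations(window, motifs),
                 class = "evodfnc_zero_variance_frame")
  expect_identical(fc[2, ], c(0, 0))
})

test_that("argmax weights count best-matching frames as multiples of 1/tau", {
  tau <- 4
  d <- 6
  set.seed(3)
  p1 <- rnorm(d)
  p2 <- rnorm(d)
  motifs <- toy_motif_set(list(
    matrix(rep(p1, each = tau), tau, d), matrix(rep(p2, each = tau), tau, d)
  ))
  window <- rbind(p2, p2, p1, p2) # argmax labels 2, 2, 1, 2
  expect_equal(ri_weights(window, motifs, mode = "argmax"), c(0.25, 0.75))
  expect_equal(ri_weights(window, motifs, mode = "meancorr"),
               colMeans(framewise_correlations(window, motifs)), tolerance = 1e-12)
  one <- toy_motif_set(list(matrix(rep(p1, each = tau), tau, d)))
  expect_identical(ri_weights(window, one, mode = "argmax"), 1)
  for (s in 1:10) {
    set.seed(100 + s)
    w <- ri_weights(matrix(rnorm(tau * d), tau, d), motifs, mode = "argmax")
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(abs(w * tau - round(w * tau)) < 1e-12))
  }
})

test_that("argmax ties break toward the smallest motif id", {
  tau <- 2
  d <- 4
  p <- c(1, 2, 3, 4)
  motifs <- toy_motif_set(list(matrix(rep(p, each = tau), tau, d),
                               matrix(rep(p, each = tau), tau, d)))
  w <- suppressWarnings(ri_weights(matrix(rep(p, each = tau), tau, d), motifs))
  expect_identical(w, c(1, 0))
})

test_that("the RI series slides one window per step and matches ri_weights", {
  set.seed(4)
  motifs <- make_two_motifs(tau = 5, d = 8, seed = 5)
  frames <- matrix(rnorm(12 * 8), 12, 8)
  sq <- structure(list(subject_id = "s1", frames = frames, window_len = 5L,
                       step = 1L, sigma = Inf, network_names = NULL),
                  class = "evo_dfnc_sequence")
  rs <- ri_series(sq, motifs)
  expect_identical(dim(rs$weights), c(8L, 2L))
  for (r in c(1, 4, 8)) {
    expect_equal(rs$weights[r, ],
                 ri_weights(frames[r:(r + 4), ], motifs), tolerance = 1e-12)
  }
  single <- structure(list(subject_id = "s1", frames = frames[1:5, ],
                           window_len = 5L, step = 1L, sigma = Inf,
                           network_names = NULL),
                      class = "evo_dfnc_sequence")
  expect_identical(nrow(ri_series(single, motifs)$weights), 1L)
  short <- structure(list(subject_id = "s1", frames = frames[1:4, ],
                          window_len = 5L, step = 1L, sigma = Inf,
                          network_names = NULL),
                     class = "evo_dfnc_sequence")
  expect_error(ri_series(short, motifs), class = "evodfnc_invalid_input")
})

test_that("a sequence built from one motif carries its weight everywhere", {
  tau <- 6
  d <- 10
  set.seed(6)
  base <- rnorm(d)
  # slowly drifting motif: high autocorrelation across its frames
  m2 <- t(sapply(seq_len(tau), function(t) base + 0.1 * t + rnorm(d, sd = 0.05)))
  m1 <- matrix(rnorm(tau * d), tau, d) # unrelated noise motif
  motifs <- toy_motif_set(list(m1, m2))
  frames <- do.call(rbind, replicate(3, m2, simplify = FALSE)) # W = 18
  sq <- structure(list(subject_id = "s1", frames = frames, window_len = 6L,
                       step = 1L, sigma = Inf, network_names = NULL),
                  class = "evo_dfnc_sequence")
  rs <- ri_series(sq, motifs)
  expect_true(all(rs$weights[, 2] > 0.8))
})

test_that("weight-vector clustering: grand mean, planted one-hot recovery", {
  set.seed(7)
  x <- matrix(runif(60), 20, 3)
  x <- x / rowSums(x)
  one <- cluster_weight_vectors(x, m = 1, seed = 1, restarts = 5)
  expect_equal(drop(one$centroids), colMeans(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  hot <- diag(3)[rep(1:3, each = 15), ] + matrix(rnorm(135, sd = 0.02), 45, 3)
  ms <- cluster_weight_vectors(hot, m = 3, seed = 2, restarts = 20)
  expect_identical(length(unique(paste(ms$assignments$cluster,
                                       rep(1:3, each = 15)))), 3L)
  expect_true(all(abs(apply(ms$centroids, 1, max) - 1) < 0.05))
  expect_error(cluster_weight_vectors(x, m = 21, seed = 1),
               class = "evodfnc_invalid_parameter")
})

test_that("meta-motifs are centroid-weighted sums of the basis motifs", {
  motifs <- make_two_motifs(tau = 3, d = 5, seed = 8)
  e2 <- induce_meta(motifs, c(0, 1))
  expect_identical(e2$frames, motifs$motifs[[2]])
  unif <- induce_meta(motifs, c(0.5, 0.5))
  expect_equal(unif$frames, (motifs$motifs[[1]] + motifs$motifs[[2]]) / 2)
  c1 <- c(0.3, 0.7)
  c2 <- c(1.1, -0.4)
  expect_equal(induce_meta(motifs, c1 + c2)$frames,
               induce_meta(motifs, c1)$frames + induce_meta(motifs, c2)$frames,
               tolerance = 1e-12)
  expect_error(induce_meta(motifs, c(1, 2, 3)), class = "evodfnc_invalid_input")
})

test_that("meta occupancy counts cluster shares per subject", {
  meta <- structure(
    list(centroids = matrix(0, 3, 2),
         assignments = tibble::tibble(
           subject_id = rep(c("s1", "s2"), c(8, 4)),
           window = c(1:8, 1:4),
           cluster = c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L)
         ),
         m = 3L, inertia = 0, seed = 1L),
    class = "evo_meta_states"
  )
  expect_equal(meta_occupancy(meta, "s1"), c(0.25, 0.25, 0.5))
  expect_equal(meta_occupancy(meta, "s2"), c(0, 1, 0))
  tab <- meta_occupancy(meta)
  expect_equal(as.numeric(tapply(tab$occupancy, tab$subject_id, sum)), c(1, 1),
               tolerance = 1e-12)
  expect_error(meta_occupancy(meta, "zz"), class = "evodfnc_not_found")
  # nearest-centroid projection of new weight vectors
  meta$centroids <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_identical(assign_meta(rbind(c(0.9, 0.1), c(0.1, 0.95), c(0.5, 0.49)), meta),
                   c(1L, 2L, 3L))
})

test_that("subject-mean RI reduces the weight series per motif", {
  motifs <- make_two_motifs(tau = 4, d = 6, seed = 9)
  seqs <- lapply(1:3, function(i) {
    set.seed(20 + i)
    structure(list(subject_id = paste0("s", i),
                   frames = matrix(rnorm(9 * 6), 9, 6), window_len = 4L,
                   step = 1L, sigma = Inf, network_names = NULL),
              class = "evo_dfnc_sequence")
  })
  rc <- ri_cohort(seqs, motifs)
  f <- subject_mean_ri(rc)
  expect_identical(dim(f), c(3L, 2L))
  expect_equal(unname(f["s2", ]), colMeans(rc$series$s2$weights), tolerance = 1e-12)
  expect_equal(unname(rowSums(f)), rep(1, 3), tolerance = 1e-12)
  fm <- subject_mean_ri(rc, reduce = "median")
  expect_equal(unname(fm["s1", ]), apply(rc$series$s1$weights, 2, median))
})
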