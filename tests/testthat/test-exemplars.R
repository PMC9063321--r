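test_that("segment extraction yields W - tau + 1 segments of tau points", {
  set.seed(1)
  emb <- toy_embedding(matrix(rnorm(137 * 2), 137, 2), "s1")
  segs <- extract_segments(emb, "s1", tau = 44)
  expect_identical(nrow(segs), 94L)
  expect_true(all(vapply(segs$points, nrow, integer(1)) == 44L))
  expect_identical(nrow(extract_segments(toy_embedding(matrix(rnorm(20), 10, 2), "s1"),
                                         "s1", tau = 10)), 1L)
  expect_error(extract_segments(emb, "s1", tau = 138),
               class = "evodfnc_invalid_input")
})

test_that("linearization: collinear, vertical, and random-segment oracles", {
  pts <- cbind(seq(-2, 2, length.out = 9), 2 * seq(-2, 2, length.out = 9))
  lin <- linearize_segment(pts, slope_bound = 10)
  expect_equal(lin$slope, 2)
  expect_equal(c(lin$x, lin$y), colMeans(pts))
  expect_equal(lin$length, sqrt(sum((pts[9, ] - pts[1, ])^2)))

  vert <- cbind(rep(1.5, 6), seq(0, 5, length.out = 6))
  expect_equal(linearize_segment(vert, slope_bound = 7)$slope, 7)

  set.seed(5)
  rp <- matrix(rnorm(20), 10, 2)
  lin_r <- linearize_segment(rp, slope_bound = 100)
  xc <- rp[, 1] - mean(rp[, 1])
  yc <- rp[, 2] - mean(rp[, 2])
  expect_equal(lin_r$slope, sum(xc * yc) / sum(xc^2), tolerance = 1e-12)
  best <- 0
  for (i in 1:9) for (j in (i + 1):10) best <- max(best, sqrt(sum((rp[i, ] - rp[j, ])^2)))
  expect_equal(lin_r$length, best, tolerance = 1e-12)

  dense <- cbind(seq(0, 3, length.out = 50), seq(0, 4, length.out = 50))
  expect_equal(linearize_segment(dense, 10)$length, 5, tolerance = 1e-12)

  expect_error(linearize_segment(matrix(1, 5, 2), 10),
               class = "evodfnc_degenerate_segment")
})

test_that("slope bound is the maximum coordinate magnitude", {
  co <- rbind(c(5, 1), c(-3, 3), c(2, -3))
  expect_identical(compute_slope_bound(toy_embedding(co)), 5)
  th <- seq(0, 2 * pi, length.out = 50)
  expect_equal(compute_slope_bound(cbind(cos(th), sin(th))), 1)
  set.seed(2)
  r <- matrix(rnorm(60), 30, 2)
  expect_identical(compute_slope_bound(r), max(abs(r)))
})

test_that("clustering linearized segments recovers planted triple clouds", {
  set.seed(9)
  planted <- matrix(c(0, 0, 0, 10, 10, 2, -10, 5, -2, 5, -10, 1), 4, 3, byrow = TRUE)
  labels <- rep(1:4, each = 25)
  lts <- tibble::tibble(
    subject_id = "s1", start = seq_along(labels),
    x = planted[labels, 1] + rnorm(100, sd = 0.1),
    y = planted[labels, 2] + rnorm(100, sd = 0.1),
    slope = planted[labels, 3] + rnorm(100, sd = 0.05),
    length = runif(100, 1, 2), dx = 1, dy = 0
  )
  ex <- cluster_linear_segments(lts, k = 4, seed = 3, restarts = 20)
  expect_identical(length(unique(paste(ex$membership$cluster, labels))), 4L)
  # exemplar length lies within member length range
  for (j in 1:4) {
    members <- ex$membership[ex$membership$cluster == j, ]
    expect_gte(ex$exemplars$length[j], min(members$length))
    expect_lte(ex$exemplars$length[j], max(members$length))
  }
  ex2 <- cluster_linear_segments(lts, k = 4, seed = 3, restarts = 20)
  expect_identical(ex$exemplars, ex2$exemplars)
  expect_error(cluster_linear_segments(lts, k = 101, seed = 1),
               class = "evodfnc_invalid_parameter")
})

test_that("exemplar orientation follows the members' temporal displacement", {
  expect_identical(orient_exemplar(0, dx = c(1, 2, 0.5), dy = c(0, 0, 0)), 1)
  expect_identical(orient_exemplar(0, dx = -c(1, 2, 0.5), dy = c(0, 0, 0)), -1)
  # mixed members: mean displacement (0.5, 1), exemplar slope 2
  u <- c(1, 2) / sqrt(5)
  expect_identical(orient_exemplar(2, dx = c(2, -1), dy = c(3, -1)),
                   ifelse(sum(u * c(0.5, 1)) < 0, -1, 1))
  expect_identical(orient_exemplar(1, dx = c(1, -1), dy = c(-1, 1)), 1) # zero dot
})

test_that("evenly spaced exemplar points: endpoints, centering, spacing", {
  ex <- tibble::tibble(id = 1L, x = 0, y = 0, slope = 0, length = 4.3, sign = 1)
  p2 <- sample_exemplar_points(ex, tau = 2)
  expect_equal(p2, cbind(c(-2.15, 2.15), c(0, 0)))
  p44 <- sample_exemplar_points(ex, tau = 44)
  expect_equal(colMeans(p44), c(0, 0), tolerance = 1e-12)
  expect_equal(diff(p44[, 1]), rep(0.1, 43), tolerance = 1e-12)
  expect_equal(p44[1, 1], -2.15)
  rev_ex <- dplyr::mutate(ex, sign = -1)
  expect_equal(sample_exemplar_points(rev_ex, 2)[1, 1], 2.15)
  degenerate <- dplyr::mutate(ex, length = 0)
  expect_error(sample_exemplar_points(degenerate, 44),
               class = "evodfnc_degenerate_exemplar")
})

test_that("two planted straight line-flows are recovered within 5%", {
  set.seed(14)
  tau <- 8
  traj <- function(x0, y0, slope, n, subj) {
    xs <- seq(x0 - 1.5, x0 + 1.5, length.out = n)
    tibble::tibble(subject_id = subj, x = xs,
                   y = y0 + slope * (xs - x0) + rnorm(n, sd = 0.01))
  }
  flows <- dplyr::bind_rows(
    purrr::map(1:6, ~traj(2, 3, 0.5, 40, paste0("a", .x))),
    purrr::map(1:6, ~traj(-3, -2, -1.5, 40, paste0("b", .x)))
  )
  emb <- toy_embedding(as.matrix(flows[c("x", "y")]), flows$subject_id)
  ex <- exemplars_from_embedding(emb, tau = tau, k = 2, seed = 2, restarts = 20)
  got <- ex$exemplars[order(ex$exemplars$x), ]
  expect_equal(got$x, c(-3, 2), tolerance = 0.05)
  expect_equal(got$y, c(-2, 3), tolerance = 0.05)
  expect_equal(got$slope, c(-1.5, 0.5), tolerance = 0.05)
  # slopes never exceed the bound
  expect_true(all(abs(ex$membership$slope) <= compute_slope_bound(emb) + 1e-12))
  # temporal orientation: trajectories run left to right
  expect_identical(ex$exemplars$sign, c(1, 1))
})

test_that("membership occupancy sums to one and matches hand counts", {
  m <- tibble::tibble(
    subject_id = rep("s1", 8), start = 1:8, x = 0, y = 0, slope = 0,
    length = 1, dx = 1, dy = 0, cluster = c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
  exset <- structure(
    list(exemplars = NULL, membership = m, k = 3L, slope_bound = 1,
         tau = 4L, inertia = 0, seed = 1L),
    class = "evo_exemplar_set"
  )
  expect_equal(exemplar_membership_occupancy(exset, "s1"), c(0.25, 0.25, 0.5))
  expect_equal(sum(exemplar_membership_occupancy(exset, "s1")), 1, tolerance = 1e-12)
  expect_error(exemplar_membership_occupancy(exset, "zz"), class = "evodfnc_not_found")
})
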