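test_that("upper-triangle vectorization has the fixed row-major order and round-trips", {
  expect_equal(vectorize_upper(diag(4)), rep(0, 6))
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- -0.2
  m[2, 3] <- m[3, 2] <- 0.9
  expect_equal(vectorize_upper(m), c(0.5, -0.2, 0.9))
  expect_length(vectorize_upper(random_corr(47, seed = 3)), 1081)
  c47 <- random_corr(47, seed = 5)
  expect_identical(devectorize_upper(vectorize_upper(c47)), unname(c47))
  asym <- diag(3)
  asym[1, 2] <- 0.5
  expect_error(vectorize_upper(asym), class = "evodfnc_invalid_input")
})

test_that("perfectly (anti)correlated networks give +/-1 in every window", {
  set.seed(7)
  base <- rnorm(60)
  tc_pos <- timecourse(cbind(a = base, b = 3 * base + 1), "pos")
  seq_pos <- compute_windowed_dfnc(tc_pos, window_len = 10, sigma = 3)
  expect_equal(unname(seq_pos$frames[, 1]), rep(1, nrow(seq_pos$frames)))
  tc_neg <- timecourse(cbind(a = base, b = -base), "neg")
  seq_neg <- compute_windowed_dfnc(tc_neg, window_len = 10, sigma = Inf)
  expect_equal(unname(seq_neg$frames[, 1]), rep(-1, nrow(seq_neg$frames)))
})

test_that("rectangular windowed dFNC equals a per-window Pearson oracle", {
  for (draw in 1:100) {
    set.seed(draw)
    x <- matrix(rnorm(30 * 3), 30, 3)
    s <- compute_windowed_dfnc(timecourse(x, "o"), window_len = 10, sigma = Inf)
    expect_identical(nrow(s$frames), 21L)
    w <- sample(21, 1)
    oracle <- cor(x[w:(w + 9), ])
    # explicit row-major comparison for all three pairs
    expect_equal(unname(s$frames[w, ]),
                 c(oracle[1, 2], oracle[1, 3], oracle[2, 3]), tolerance = 1e-12)
  }
})

test_that("tapered windowed dFNC equals the weighted-correlation oracle (cov.wt)", {
  set.seed(11)
  x <- matrix(rnorm(40 * 4), 40, 4)
  s <- compute_windowed_dfnc(timecourse(x, "wt"), window_len = 12, sigma = 2)
  w <- build_taper(12, 2)
  for (i in c(1, 10, 29)) {
    oracle <- stats::cov.wt(x[i:(i + 11), ], wt = w, cor = TRUE, method = "ML")$cor
    expect_equal(unname(s$frames[i, ]), vectorize_upper(oracle), tolerance = 1e-12)
  }
})

test_that("47 networks produce 1081 features per frame", {
  set.seed(2)
  x <- matrix(rnorm(25 * 47), 25, 47)
  s <- compute_windowed_dfnc(timecourse(x, "n47"), window_len = 22)
  expect_identical(ncol(s$frames), 1081L)
  expect_true(all(abs(s$frames) <= 1))
})

test_that("window count follows floor((T - window_len)/step) + 1", {
  set.seed(3)
  x <- matrix(rnorm(50 * 3), 50, 3)
  expect_identical(nrow(compute_windowed_dfnc(timecourse(x, "a"), 22)$frames), 29L)
  expect_identical(nrow(compute_windowed_dfnc(timecourse(x, "a"), 22, step = 3)$frames), 10L)
})

test_that("a zero-variance network inside a window raises a named degenerate error", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60, 3)
  x[1:30, 2] <- 5 # flat early stretch, varying later: passes global check
  colnames(x) <- c("alpha", "beta", "gamma")
  err <- expect_error(
    compute_windowed_dfnc(timecourse(x, "subjX"), window_len = 10, sigma = Inf),
    class = "evodfnc_degenerate_window"
  )
  expect_match(conditionMessage(err), "subjX")
  expect_match(conditionMessage(err), "beta")
  expect_match(conditionMessage(err), "window 1")
})

test_that("successive-frame distance shrinks monotonically with window length", {
  tc <- smooth_timecourse(n_t = 150, n = 6, seed = 9)
  msd <- sapply(c(10, 20, 30, 40), function(wl) {
    f <- compute_windowed_dfnc(tc, window_len = wl, sigma = Inf)$frames
    mean((f[-1, ] - f[-nrow(f), ])^2)
  })
  expect_true(all(diff(msd) < 0))
})

test_that("snapshot clustering matches planted blobs and is seed-stable", {
  set.seed(21)
  centers <- matrix(c(0, 0, 8, 8, -8, 8), 3, 2, byrow = TRUE)
  labels <- rep(1:3, each = 40)
  x <- centers[labels, ] + matrix(rnorm(240, sd = 0.4), 120, 2)
  fit <- kmeans_restarts(x, 3, seed = 5, restarts = 10)
  expect_identical(length(unique(paste(fit$cluster, labels))), 3L) # bijective map
  fit2 <- kmeans_restarts(x, 3, seed = 5, restarts = 10)
  expect_identical(fit, fit2)
  # independent route: stats::kmeans with many random starts reaches the same inertia
  set.seed(1)
  ref <- stats::kmeans(x, 3, nstart = 25, iter.max = 100)
  expect_equal(fit$inertia, ref$tot.withinss, tolerance = 1e-8)
})

test_that("k-means edge cases: k = 1 grand mean, k too large rejected", {
  set.seed(6)
  x <- matrix(rnorm(40), 20, 2)
  fit <- kmeans_restarts(x, 1, seed = 1, restarts = 3)
  expect_equal(drop(fit$centers), colMeans(x), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(kmeans_restarts(x, 21, seed = 1), class = "evodfnc_invalid_parameter")
})

test_that("snapshot occupancy counts fractions that sum to one", {
  a <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), c(10, 6)),
    window = c(1:10, 1:6), row = 1:16,
    state = c(rep(1L, 4), rep(3L, 6), rep(2L, 6))
  )
  states <- toy_snap_states(a, k = 3)
  expect_equal(snapshot_occupancy(states, "s1"), c(0.4, 0, 0.6))
  expect_equal(snapshot_occupancy(states, "s2"), c(0, 1, 0))
  tab <- snapshot_occupancy(states)
  sums <- tapply(tab$occupancy, tab$subject_id, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
  expect_error(snapshot_occupancy(states, "nope"), class = "evodfnc_not_found")
})

test_that("stacking preserves row indexing end-to-end", {
  seqs <- lapply(1:3, function(i) {
    compute_windowed_dfnc(smooth_timecourse(60, 4, seed = i), window_len = 10)
  })
  stacked <- stack_dfnc(seqs)
  expect_identical(nrow(stacked$frames), nrow(stacked$index))
  for (i in c(1, 60, 120)) {
    s <- stacked$index$subject_id[i]
    w <- stacked$index$window[i]
    orig <- seqs[[match(s, vapply(seqs, `[[`, "", "subject_id"))]]
    expect_identical(stacked$frames[i, ], orig$frames[w, ])
  }
})
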