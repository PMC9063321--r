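test_that("anchor patterns are positive definite with the planted block structure", {
  anchors <- make_anchor_patterns(3, 12, 3, contrast = 0.6, seed = 2)
  for (a in anchors) {
    expect_equal(unname(diag(a$matrix)), rep(1, 12))
    expect_gt(min(eigen(a$matrix, symmetric = TRUE, only.values = TRUE)$values), 1e-6)
    same <- outer(a$modules, a$modules, `==`)
    off <- !diag(12)
    within_mean <- mean(a$matrix[same & off])
    between_mean <- mean(a$matrix[!same])
    expect_gte(within_mean - between_mean, 0.5)
  }
  faint <- make_anchor_patterns(1, 8, 2, contrast = 0.01, seed = 1)[[1]]$matrix
  expect_lt(max(abs(faint[!diag(8)])), 0.02)
  expect_error(make_anchor_patterns(1, 8, 9, seed = 1),
               class = "evodfnc_invalid_parameter")
})

test_that("motif interpolation is convex with exact endpoints", {
  anchors <- make_anchor_patterns(2, 10, 2, contrast = 0.5, seed = 3)
  motif <- make_motif(anchors[[1]], anchors[[2]], l = 9)
  expect_identical(motif[[1]], anchors[[1]]$matrix)
  expect_identical(motif[[9]], anchors[[2]]$matrix)
  expect_equal(motif[[5]], (anchors[[1]]$matrix + anchors[[2]]$matrix) / 2)
  for (m in motif) {
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(make_motif(anchors[[1]], anchors[[2]], l = 1),
               class = "evodfnc_invalid_parameter")
})

test_that("subject simulation is deterministic with the target shape", {
  cfg <- synth_config(seed = 4)
  anchors <- make_anchor_patterns(2, cfg$n_networks, 3, seed = 5)
  lib <- list(make_motif(anchors[[1]], anchors[[2]], cfg$motif_duration))
  sched <- tibble::tibble(motif_id = c(1L, NA, 1L),
                          start = c(1L, 66L, 94L), duration = c(65L, 28L, 65L))
  tc1 <- simulate_subject(sched, lib, anchors[[1]]$matrix, cfg, "sA", seed = 11)
  tc2 <- simulate_subject(sched, lib, anchors[[1]]$matrix, cfg, "sA", seed = 11)
  expect_identical(tc1$values, tc2$values)
  expect_identical(dim(tc1$values), c(158L, 12L))
  bad <- tibble::tibble(motif_id = c(1L, NA), start = c(1L, 60L),
                        duration = c(65L, 28L))
  expect_error(simulate_subject(bad, lib, anchors[[1]]$matrix, cfg, "sA", 1),
               class = "evodfnc_invalid_input")
})

test_that("a long constant-covariance scan reproduces its anchor correlation", {
  anchors <- make_anchor_patterns(1, 8, 2, contrast = 0.5, seed = 6)
  cfg <- synth_config(n_timepoints = 5000L, n_networks = 8L,
                      motif_duration = 100L, noise_sd = 0, seed = 6)
  sched <- tibble::tibble(motif_id = NA_integer_, start = 1L, duration = 5000L)
  tc <- simulate_subject(sched, list(), anchors[[1]]$matrix, cfg, "lln", seed = 12)
  expect_lt(max(abs(cor(tc$values) - anchors[[1]]$matrix)), 0.05)
})

test_that("cohort simulation plants the configured group usage difference", {
  cohort <- simulate_cohort(synth_config(seed = 1))
  expect_identical(nrow(cohort$manifest), 20L)
  expect_identical(sum(cohort$manifest$diagnosis), 10L)
  usage <- cohort$ground_truth$usage
  g0 <- sum(usage$motif1_slots[usage$diagnosis == 0])
  g1 <- sum(usage$motif1_slots[usage$diagnosis == 1])
  # 20 slots per group at p = 1/3 vs 2/3: check each within its 99.9% band
  expect_true(g0 >= qbinom(5e-4, 20, 1 / 3) && g0 <= qbinom(1 - 5e-4, 20, 1 / 3))
  expect_true(g1 >= qbinom(5e-4, 20, 2 / 3) && g1 <= qbinom(1 - 5e-4, 20, 2 / 3))
  expect_gt(g1, g0)
  # ground-truth motifs live at the pipeline's feature dimension and tau
  for (mf in cohort$ground_truth$motif_frames) {
    expect_identical(dim(mf), c(44L, 66L))
    expect_true(all(abs(mf) <= 1))
  }
  # patients have complete symptom scores, controls have none
  pats <- cohort$manifest[cohort$manifest$diagnosis == 1, ]
  ctrl <- cohort$manifest[cohort$manifest$diagnosis == 0, ]
  expect_false(anyNA(pats[evodfnc:::PANSS_COLS]))
  expect_true(all(is.na(ctrl[evodfnc:::PANSS_COLS])))
})

test_that("invalid configurations are reported with every violation", {
  err <- expect_error(synth_config(n_timepoints = 100L, base_usage = 2,
                                   noise_sd = -1),
                      class = "evodfnc_invalid_config")
  msg <- conditionMessage(err)
  expect_match(msg, "base_usage")
  expect_match(msg, "noise_sd")
  expect_match(msg, "two motif slots")
})

test_that("written cohorts round-trip through the manifest reader", {
  cohort <- simulate_cohort(synth_config(n_per_group = c(2L, 2L), seed = 3))
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(cohort, dir)
  expect_identical(validate_manifest(manifest_path), character(0))
  back <- read_cohort(manifest_path)
  expect_identical(names(back$timecourses), cohort$manifest$subject_id)
  expect_equal(back$timecourses[[1]]$values, cohort$timecourses[[1]]$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})
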