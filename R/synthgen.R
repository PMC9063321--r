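#' Block-structured anchor connectivity patterns
#'
#' Generates `n_patterns` synthetic anchor correlation matrices: networks are
#' partitioned into modules; within-module correlation is `+contrast`, a
#' random selection of between-module blocks gets `-contrast / 2`, everything
#' else is near zero. Each matrix is ridge-adjusted onto the positive
#' definite cone (minimum eigenvalue > 1e-6) with unit diagonal.
#'
#' @param n_patterns Number of anchor patterns.
#' @param n_networks Number of networks `N`.
#' @param n_modules Number of modules (`<= n_networks`).
#' @param contrast Block correlation strength in (0, 1) (default 0.6).
#' @param seed Integer seed.
#' @return List of anchors; each has `id`, `matrix` (`N x N`), `modules`
#'   (module label per network).
#' @export
make_anchor_patterns <- function(n_patterns, n_networks, n_modules,
                                 contrast = 0.6, seed = 1L) {
  if (!is_count(n_patterns) || !is_count(n_networks, 2L) || !is_count(n_modules)) {
    stop_invalid_parameter("Counts must be positive integers.")
  }
  if (n_modules > n_networks) stop_invalid_parameter("`n_modules` must be <= `n_networks`.")
  if (contrast <= 0 || contrast >= 1) stop_invalid_parameter("`contrast` must lie in (0, 1).")
  set.seed(seed)
  lapply(seq_len(n_patterns), function(p) {
    modules <- sample(rep_len(seq_len(n_modules), n_networks))
    c_mat <- matrix(0, n_networks, n_networks)
    for (a in seq_len(n_modules)) {
      for (b in seq_len(n_modules)) {
        val <- if (a == b) contrast else if (stats::runif(1) < 0.4) -contrast / 2 else 0
        c_mat[modules == a, modules == b] <- val
      }
    }
    c_mat <- (c_mat + t(c_mat)) / 2
    diag(c_mat) <- 1
    c_mat <- ridge_to_spd(c_mat)
    list(id = p, matrix = c_mat, modules = modules)
  })
}

ridge_to_spd <- function(c_mat, min_eig = 1e-6, max_ridge = 10) {
  ridge <- 0
  repeat {
    adj <- (c_mat + ridge * diag(nrow(c_mat))) / (1 + ridge)
    if (min(eigen(adj, symmetric = TRUE, only.values = TRUE)$values) > min_eig) {
      return(adj)
    }
    ridge <- if (ridge == 0) 0.05 else ridge * 2
    if (ridge > max_ridge) {
      abort("Could not ridge-adjust the pattern to positive definiteness.",
            class = "evodfnc_generation_error")
    }
  }
}

#' Linearly evolving connectivity motif
#'
#' A motif is a smooth morph between two anchor patterns: `L` convex
#' interpolants `C(u) = (1 - u) A + u B` at evenly spaced `u` in `[0, 1]`.
#' Convexity of the positive definite cone guarantees every interpolant is a
#' valid correlation matrix.
#'
#' @param anchor_a,anchor_b Anchors from [make_anchor_patterns()] (or plain
#'   correlation matrices).
#' @param l Number of interpolation steps (>= 2).
#' @return List of `L` correlation matrices.
#' @export
make_motif <- function(anchor_a, anchor_b, l) {
  if (!is_count(l, 2L)) stop_invalid_parameter("`l` must be an integer >= 2.")
  a <- if (is.list(anchor_a)) anchor_a$matrix else anchor_a
  b <- if (is.list(anchor_b)) anchor_b$matrix else anchor_b
  u <- seq(0, 1, length.out = l)
  lapply(u, function(ui) (1 - ui) * a + ui * b)
}

#' Synthetic cohort configuration
#'
#' Fixes the conditions the generator emulates: a resting-state cohort with
#' smooth within-subject evolution of the windowed correlation structure, two
#' (by default) planted evolving motifs shared across subjects, a
#' between-group difference in motif usage, and covariates. Defaults: 158
#' analyzable TRs at TR = 2 s; each motif is a 65-TR morph between two
#' distinct block-pattern anchors, so at the 22-TR window resolution a motif
#' spans exactly 44 windows; motif slots sit at the start and end of the scan
#' with a low-contrast rest period between them; group 0 draws motif 1 in
#' each slot with probability `base_usage`, group 1 with
#' `min(1, usage_ratio * base_usage)`.
#'
#' @param n_per_group Integer pair: controls (diagnosis 0), patients
#'   (diagnosis 1). Default `c(10, 10)`.
#' @param n_timepoints Scan length in TRs (default 158).
#' @param n_networks Number of networks (default 12; use 47 for full scale).
#' @param tr_seconds TR in seconds (default 2).
#' @param n_motifs Number of planted motifs (default 2).
#' @param motif_duration Motif duration in TRs (default 65
#'   `= 44 + 22 - 1`).
#' @param base_usage Group-0 probability of drawing motif 1 per slot
#'   (default 1/3).
#' @param usage_ratio Group-1 / group-0 odds of motif 1 (default 2).
#' @param contrast Anchor block contrast (default 0.6).
#' @param rest_contrast Contrast of the between-slot rest anchor (default
#'   0.15).
#' @param noise_sd Additive white measurement noise sd (default 0.1).
#' @param window_len,sigma The analysis window the ground truth is rendered
#'   at (defaults 22 / 3).
#' @param covariate_usage_effects Named numeric vector of logit effects of
#'   standardized covariates (`age`, `gender`, `meanFD`) on motif-1 usage
#'   (default all 0).
#' @param seed Master seed (default 1).
#' @return An object of class `evo_synth_config`.
#' @export
synth_config <- function(n_per_group = c(10L, 10L), n_timepoints = 158L,
                         n_networks = 12L, tr_seconds = 2, n_motifs = 2L,
                         motif_duration = 65L, base_usage = 1 / 3,
                         usage_ratio = 2, contrast = 0.6, rest_contrast = 0.15,
                         noise_sd = 0.1, window_len = 22L, sigma = 3,
                         covariate_usage_effects = c(age = 0, gender = 0, meanFD = 0),
                         seed = 1L) {
  problems <- character(0)
  if (length(n_per_group) != 2L || !all(vapply(n_per_group, is_count, logical(1)))) {
    problems <- c(problems, "`n_per_group` must be two positive integers.")
  }
  for (nm in c("n_timepoints", "n_networks", "n_motifs", "motif_duration", "window_len")) {
    if (!is_count(get(nm))) problems <- c(problems, sprintf("`%s` must be a positive integer.", nm))
  }
  if (is.numeric(base_usage) && (base_usage < 0 || base_usage > 1)) {
    problems <- c(problems, "`base_usage` must lie in [0, 1].")
  }
  if (is.numeric(usage_ratio) && usage_ratio <= 0) {
    problems <- c(problems, "`usage_ratio` must be positive.")
  }
  if (is.numeric(noise_sd) && noise_sd < 0) problems <- c(problems, "`noise_sd` must be >= 0.")
  if (is_count(n_timepoints) && is_count(motif_duration) &&
      n_timepoints < 2L * motif_duration + 1L) {
    problems <- c(problems, "`n_timepoints` must fit two motif slots plus a rest gap.")
  }
  if (length(problems) > 0L) {
    abort(paste(c("Invalid synthetic-cohort configuration:", problems), collapse = "\n  "),
          class = "evodfnc_invalid_config")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), n_timepoints = as.integer(n_timepoints),
      n_networks = as.integer(n_networks), tr_seconds = tr_seconds,
      n_motifs = as.integer(n_motifs), motif_duration = as.integer(motif_duration),
      base_usage = base_usage, usage_ratio = usage_ratio, contrast = contrast,
      rest_contrast = rest_contrast, noise_sd = noise_sd,
      window_len = as.integer(window_len), sigma = sigma,
      covariate_usage_effects = covariate_usage_effects, seed = as.integer(seed)
    ),
    class = "evo_synth_config"
  )
}

# per-TR target correlation matrices for one subject's schedule
schedule_covariances <- function(schedule, motif_lib, rest_matrix, n_timepoints) {
  covs <- vector("list", n_timepoints)
  for (t in seq_len(n_timepoints)) covs[[t]] <- rest_matrix
  for (i in seq_len(nrow(schedule))) {
    seg <- schedule[i, ]
    if (!is.na(seg$motif_id)) {
      frames <- motif_lib[[seg$motif_id]]
      idx <- seg$start:(seg$start + seg$duration - 1L)
      stopifnot(length(idx) == length(frames))
      covs[idx] <- frames
    }
  }
  covs
}

#' Simulate one subject's network timecourses
#'
#' At each TR the target covariance is the schedule's (interpolated) motif
#' matrix, or the rest anchor outside motif slots; the sample is
#' `x_t = chol(C_t)' z_t + noise_sd * e_t` with independent standard normal
#' `z_t`, `e_t`.
#'
#' @param schedule Tibble with columns `motif_id` (NA for rest), `start`,
#'   `duration` (TRs), tiling `[1, n_timepoints]`.
#' @param motif_lib List of motifs (each a list of per-TR correlation
#'   matrices, see [make_motif()]).
#' @param rest_matrix Rest-anchor correlation matrix.
#' @param config An [synth_config()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @return An [timecourse()] object.
#' @export
simulate_subject <- function(schedule, motif_lib, rest_matrix, config,
                             subject_id = "s1", seed = 1L) {
  covered <- sum(schedule$duration)
  if (covered != config$n_timepoints ||
      any(schedule$start != cumsum(c(1L, utils::head(schedule$duration, -1L))))) {
    stop_invalid_input("`schedule` segments must tile [1, n_timepoints] without overlap.")
  }
  covs <- schedule_covariances(
    schedule[!is.na(schedule$motif_id), , drop = FALSE],
    motif_lib, rest_matrix, config$n_timepoints
  )
  set.seed(seed)
  n <- config$n_networks
  x <- matrix(NA_real_, config$n_timepoints, n)
  for (t in seq_len(config$n_timepoints)) {
    ch <- tryCatch(chol(covs[[t]]), error = function(e) {
      abort(sprintf("Target covariance at TR %d is not positive definite.", t),
            class = "evodfnc_generation_error")
    })
    x[t, ] <- drop(crossprod(ch, stats::rnorm(n)))
  }
  if (config$noise_sd > 0) {
    x <- x + config$noise_sd * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  }
  colnames(x) <- paste0("net", seq_len(n))
  timecourse(x, subject_id, tr_seconds = config$tr_seconds)
}

# window-resolution rendering of a planted motif: the analysis taper applied
# to the per-TR target matrices, renormalized to correlation form
motif_at_window_resolution <- function(motif_frames, window_len, sigma) {
  w <- build_taper(window_len, sigma)
  n_w <- length(motif_frames) - window_len + 1L
  t(vapply(seq_len(n_w), function(j) {
    cm <- Reduce(`+`, purrr::map2(motif_frames[j:(j + window_len - 1L)], w, `*`))
    vectorize_upper(stats::cov2cor(cm))
  }, numeric(nrow(motif_frames[[1L]]) * (nrow(motif_frames[[1L]]) - 1L) / 2L)))
}

#' Simulate a full synthetic cohort
#'
#' Builds the anchor patterns and motif library, draws each subject's motif
#' schedule (two slots per scan; group 1 favors motif 1 by
#' `usage_ratio`), simulates timecourses, samples covariates, and records the
#' ground truth needed for recovery tests: true schedules, per-motif
#' window-resolution frame sequences, and empirical group usage rates.
#'
#' @param config An [synth_config()].
#' @return An object of class `evo_synth_cohort`: `timecourses` (list of
#'   [timecourse()]), `manifest` tibble, `ground_truth` list (`schedules`,
#'   `motif_frames`, `usage`, `anchors`, `config`).
#' @export
simulate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "evo_synth_config")) {
    stop_invalid_input("`config` must come from synth_config().")
  }
  set.seed(config$seed)
  # anchors: one low-contrast rest pattern + two distinct endpoints per motif
  n_anchor <- 2L * config$n_motifs
  anchors <- make_anchor_patterns(
    n_anchor, config$n_networks, n_modules = 3L,
    contrast = config$contrast, seed = config$seed + 1L
  )
  rest <- make_anchor_patterns(
    1L, config$n_networks, n_modules = 3L,
    contrast = config$rest_contrast, seed = config$seed + 2L
  )[[1L]]$matrix
  motif_lib <- lapply(seq_len(config$n_motifs), function(m) {
    make_motif(anchors[[2L * m - 1L]], anchors[[2L * m]], config$motif_duration)
  })
  n_total <- sum(config$n_per_group)
  diagnosis <- rep(c(0L, 1L), config$n_per_group)
  subject_ids <- sprintf("sub%03d", seq_len(n_total))
  age <- round(stats::rnorm(n_total, 38, 11))
  gender <- stats::rbinom(n_total, 1L, 0.5)
  mean_fd <- round(exp(stats::rnorm(n_total, log(0.15), 0.4)), 4)
  eff <- config$covariate_usage_effects
  dur <- config$motif_duration
  gap <- config$n_timepoints - 2L * dur
  schedules <- vector("list", n_total)
  timecourses <- vector("list", n_total)
  # draw every schedule from the cohort-level stream before any timecourse is
  # simulated: simulate_subject() seeds its own stream and must not perturb
  # the slot draws
  for (i in seq_len(n_total)) {
    p1 <- if (diagnosis[i] == 1L) min(1, config$usage_ratio * config$base_usage) else config$base_usage
    lin <- stats::qlogis(min(max(p1, 1e-6), 1 - 1e-6)) +
      eff[["age"]] * (age[i] - 38) / 11 +
      eff[["gender"]] * (gender[i] - 0.5) +
      eff[["meanFD"]] * (mean_fd[i] - 0.15) / 0.07
    p1 <- stats::plogis(lin)
    others <- if (config$n_motifs > 1L) {
      # note sample(2:2, ...) would expand to 1:2; keep length-1 pools literal
      if (config$n_motifs == 2L) rep(2L, 2L) else sample(2:config$n_motifs, 2L, replace = TRUE)
    } else {
      rep(1L, 2L)
    }
    slot_motifs <- ifelse(stats::runif(2L) < p1, 1L, others)
    schedules[[i]] <- tibble(
      motif_id = c(slot_motifs[1L], NA_integer_, slot_motifs[2L]),
      start = c(1L, dur + 1L, dur + gap + 1L),
      duration = c(dur, gap, dur)
    )
  }
  names(schedules) <- subject_ids
  panss <- matrix(NA_real_, n_total, length(PANSS_COLS),
                  dimnames = list(NULL, PANSS_COLS))
  pat <- diagnosis == 1L
  panss[pat, ] <- sample(1:7, sum(pat) * length(PANSS_COLS), replace = TRUE)
  for (i in seq_len(n_total)) {
    # prime stride keeps subject streams distinct across nearby master seeds
    timecourses[[i]] <- simulate_subject(
      schedules[[i]], motif_lib, rest, config,
      subject_id = subject_ids[i], seed = config$seed + 7919L * i
    )
  }
  names(timecourses) <- subject_ids
  manifest <- tibble(
    subject_id = subject_ids, file = NA_character_, diagnosis = diagnosis,
    age = age, gender = gender, meanFD = mean_fd
  )
  manifest <- dplyr::bind_cols(manifest, as_tibble(panss))
  usage <- purrr::map_dfr(seq_len(n_total), function(i) {
    s <- schedules[[i]]
    tibble(subject_id = subject_ids[i], diagnosis = diagnosis[i],
           motif1_slots = sum(s$motif_id == 1L, na.rm = TRUE),
           total_slots = sum(!is.na(s$motif_id)))
  })
  motif_frames <- lapply(motif_lib, motif_at_window_resolution,
                         window_len = config$window_len, sigma = config$sigma)
  structure(
    list(
      timecourses = timecourses, manifest = manifest,
      ground_truth = list(
        schedules = schedules, motif_frames = motif_frames, usage = usage,
        anchors = anchors, rest = rest, config = config
      )
    ),
    class = "evo_synth_cohort"
  )
}

#' @export
print.evo_synth_cohort <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat(sprintf(
    "<evo_synth_cohort> %d subjects (%d + %d), %d TRs x %d networks, %d planted motifs\n",
    length(x$timecourses), cfg$n_per_group[1L], cfg$n_per_group[2L],
    cfg$n_timepoints, cfg$n_networks, cfg$n_motifs
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline input format
#'
#' One CSV per subject (rows = TRs, columns = networks, header row) plus a
#' `manifest.csv` and a `ground_truth.json`.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$file <- paste0(manifest$subject_id, ".csv")
  for (i in seq_along(cohort$timecourses)) {
    tc <- cohort$timecourses[[i]]
    utils::write.csv(as.data.frame(tc$values),
                     file.path(dir, manifest$file[i]), row.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  write_json_file(
    list(
      usage = gt$usage,
      schedules = lapply(gt$schedules, function(s) as.list(s)),
      config = unclass(gt$config)
    ),
    file.path(dir, "ground_truth.json")
  )
  invisible(file.path(dir, "manifest.csv"))
}
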