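#' Full pipeline configuration
#'
#' Collects every stage parameter with the package's reference defaults:
#' 22-TR tapered window (sigma 3), motif duration `tau = 44` (twice the
#' window), UMAP with 25 neighbors / min_dist 0.75 averaged over 25 runs,
#' `K = 10` exemplars, 25-neighbor lifting, `M = 10` meta-states, 5 snapshot
#' states, k-means with 2000 iterations and 250 restarts (500 for weight
#' vectors), argmax-mode representational importance, BH correction.
#'
#' @param window_len Window length in TRs (default 22).
#' @param sigma Taper width in TRs (default 3, `Inf` = rectangle).
#' @param step Window step in TRs (default 1).
#' @param tau Motif duration in windows; defaults to `2 * window_len`.
#' @param n_neighbors,min_dist,n_runs,align_runs Embedding parameters (see
#'   [embed_config()]).
#' @param k Number of exemplars / motifs (default 10).
#' @param n_lift Lifting neighbor count (default 25).
#' @param m Number of meta-states (default 10).
#' @param snap_k Number of snapshot states (default 5).
#' @param mode Representational-importance mode, `"argmax"` or `"meancorr"`.
#' @param correction Multiple-comparison method, `"bh"` or `"bonferroni"`.
#' @param iter_max k-means iteration cap (default 2000).
#' @param restarts k-means restarts for snapshots and exemplars (default
#'   250).
#' @param meta_restarts k-means restarts for weight vectors (default 500).
#' @param fisher_z Fisher z-transform dFNC features (default `FALSE`).
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `evo_config` (a named list).
#' @export
evo_config <- function(window_len = 22L, sigma = 3, step = 1L,
                       tau = 2L * window_len, n_neighbors = 25L,
                       min_dist = 0.75, n_runs = 25L, align_runs = TRUE,
                       k = 10L, n_lift = 25L, m = 10L, snap_k = 5L,
                       mode = c("argmax", "meancorr"),
                       correction = c("bh", "bonferroni"),
                       iter_max = 2000L, restarts = 250L, meta_restarts = 500L,
                       fisher_z = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  cfg <- list(
    window_len = as.integer(window_len), sigma = sigma, step = as.integer(step),
    tau = as.integer(tau), n_neighbors = as.integer(n_neighbors),
    min_dist = min_dist, n_runs = as.integer(n_runs),
    align_runs = isTRUE(align_runs), k = as.integer(k),
    n_lift = as.integer(n_lift), m = as.integer(m), snap_k = as.integer(snap_k),
    mode = mode, correction = correction, iter_max = as.integer(iter_max),
    restarts = as.integer(restarts), meta_restarts = as.integer(meta_restarts),
    fisher_z = isTRUE(fisher_z), seed = as.integer(seed)
  )
  structure(cfg, class = "evo_config")
}

#' Validate a cohort manifest
#'
#' Checks column presence and types, timecourse file existence, network-count
#' consistency across subjects, and symptom completeness for patients. The
#' report lists every violation rather than stopping at the first.
#'
#' @param manifest Manifest tibble or path to a manifest CSV.
#' @param dir Directory timecourse files are resolved against (defaults to
#'   the manifest's directory for a path, `"."` otherwise).
#' @return Character vector of violations (empty if well formed).
#' @export
validate_manifest <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop_invalid_input(sprintf("Cannot read '%s'.", manifest))
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- as_tibble(utils::read.csv(manifest))
  }
  if (is.null(dir)) dir <- "."
  violations <- character(0)
  required <- c("subject_id", "file", "diagnosis", "age", "gender", "meanFD")
  miss <- setdiff(required, names(manifest))
  if (length(miss) > 0L) {
    violations <- c(violations, sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    return(violations)
  }
  if (!all(manifest$diagnosis %in% c(0, 1))) {
    violations <- c(violations, "diagnosis must be 0/1")
  }
  if (!all(manifest$gender %in% c(0, 1))) {
    violations <- c(violations, "gender must be 0/1")
  }
  for (col in c("age", "meanFD")) {
    if (!is.numeric(manifest[[col]]) || anyNA(manifest[[col]])) {
      violations <- c(violations, sprintf("%s must be numeric with no missing values", col))
    }
  }
  have_panss <- all(PANSS_COLS %in% names(manifest))
  if (have_panss) {
    pats <- manifest[manifest$diagnosis == 1, , drop = FALSE]
    bad <- pats$subject_id[!stats::complete.cases(pats[PANSS_COLS])]
    if (length(bad) > 0L) {
      violations <- c(violations, sprintf(
        "incomplete symptom scores for patient(s): %s", paste(bad, collapse = ", ")
      ))
    }
  }
  n_cols <- rep(NA_integer_, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    if (is.na(manifest$file[i]) || !file.exists(path)) {
      violations <- c(violations, sprintf(
        "timecourse file not found for subject %s: %s", manifest$subject_id[i],
        manifest$file[i]
      ))
    } else {
      hdr <- utils::read.csv(path, nrows = 1L)
      n_cols[i] <- ncol(hdr)
    }
  }
  known <- which(!is.na(n_cols))
  if (length(known) > 1L && length(unique(n_cols[known])) > 1L) {
    tab <- split(manifest$subject_id[known], n_cols[known])
    desc <- vapply(names(tab), function(nn) {
      sprintf("%s networks: %s", nn, paste(tab[[nn]], collapse = ", "))
    }, character(1))
    violations <- c(violations, sprintf(
      "inconsistent network count across subjects (%s)", paste(desc, collapse = "; ")
    ))
  }
  violations
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return List with `timecourses` (list of [timecourse()]) and `manifest`
#'   tibble.
#' @export
read_cohort <- function(manifest_path) {
  violations <- validate_manifest(manifest_path)
  if (length(violations) > 0L) {
    stop_invalid_input(paste(c("Invalid manifest:", violations), collapse = "\n  "))
  }
  dir <- dirname(manifest_path)
  manifest <- as_tibble(utils::read.csv(manifest_path))
  tcs <- lapply(seq_len(nrow(manifest)), function(i) {
    vals <- as.matrix(utils::read.csv(file.path(dir, manifest$file[i])))
    timecourse(vals, manifest$subject_id[i])
  })
  names(tcs) <- manifest$subject_id
  list(timecourses = tcs, manifest = manifest)
}

log_line <- function(bundle_dir, stage, msg) {
  line <- sprintf("%s | %s | %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  if (!is.null(bundle_dir)) {
    cat(line, "\n", sep = "", file = file.path(bundle_dir, "log.txt"), append = TRUE)
  }
  message(line)
}

stage_done <- function(bundle_dir, stage) {
  !is.null(bundle_dir) && file.exists(file.path(bundle_dir, stage, ".done"))
}

mark_done <- function(bundle_dir, stage) {
  if (!is.null(bundle_dir)) {
    file.create(file.path(bundle_dir, stage, ".done"))
  }
}

stage_dir <- function(bundle_dir, stage) {
  if (is.null(bundle_dir)) return(NULL)
  d <- file.path(bundle_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the full evolving-motif pipeline
#'
#' Executes, in order: windowed dFNC (+ snapshot-state baseline), multi-run
#' averaged embedding, exemplar extraction, lifting, representational
#' importance and meta-states, and the covariate-adjusted group model (plus
#' the symptom model when the manifest carries complete symptom scores).
#' With `out_dir` set, every stage's outputs are persisted as delimited text
#' plus JSON metadata, and stages whose outputs already exist are loaded
#' instead of recomputed, so a bundle can resume any downstream stage.
#'
#' @param input Path to a manifest CSV, or an in-memory cohort: either an
#'   [simulate_cohort()] result or a list with `timecourses` and `manifest`.
#' @param config An [evo_config()].
#' @param out_dir Optional bundle directory.
#' @param through Last stage to execute: one of `"dfnc"`, `"snap"`,
#'   `"embedding"`, `"exemplars"`, `"lift"`, `"represent"`, `"stats"`
#'   (default; the full pipeline). Earlier stages always run (or are loaded
#'   from the bundle).
#' @return An object of class `evo_bundle`: `config`, `manifest`, `dfnc`
#'   (list of sequences), `stacked`, `snap`, `embedding`, `exemplars`,
#'   `motifs`, `ri`, `meta`, `effects` (list of effect tables), `dir`.
#' @export
run_pipeline <- function(input, config = evo_config(), out_dir = NULL,
                         through = c("stats", "dfnc", "snap", "embedding",
                                     "exemplars", "lift", "represent")) {
  through <- match.arg(through)
  partial <- function(...) {
    structure(c(list(config = config, manifest = manifest, dir = out_dir),
                list(...)),
              class = "evo_bundle")
  }
  if (is.character(input)) input <- read_cohort(input)
  tcs <- input$timecourses
  manifest <- input$manifest
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out_dir)) {
    write_json_file(unclass(config), file.path(out_dir, "config.json"))
  }

  # --- stage: dfnc -----------------------------------------------------------
  t0 <- Sys.time()
  if (stage_done(out_dir, "dfnc")) {
    sd <- file.path(out_dir, "dfnc")
    seqs <- lapply(manifest$subject_id, function(s) {
      structure(
        list(subject_id = s, frames = read_matrix_tsv(file.path(sd, paste0(s, ".tsv"))),
             window_len = config$window_len, step = config$step,
             sigma = config$sigma, network_names = NULL),
        class = "evo_dfnc_sequence"
      )
    })
    log_line(out_dir, "dfnc", "loaded from bundle")
  } else {
    seqs <- lapply(tcs, compute_windowed_dfnc, window_len = config$window_len,
                   sigma = config$sigma, step = config$step,
                   fisher_z = config$fisher_z)
    sd <- stage_dir(out_dir, "dfnc")
    if (!is.null(sd)) {
      for (s in seqs) write_matrix_tsv(s$frames, file.path(sd, paste0(s$subject_id, ".tsv")))
      write_json_file(
        list(window_len = config$window_len, sigma = config$sigma,
             step = config$step, fisher_z = config$fisher_z,
             n_features = ncol(seqs[[1L]]$frames),
             window_values = config$tau * ncol(seqs[[1L]]$frames)),
        file.path(sd, "meta.json")
      )
      mark_done(out_dir, "dfnc")
    }
    log_line(out_dir, "dfnc", sprintf(
      "window_len=%d sigma=%s step=%d -> %d subjects x %d windows x %d features [%.1fs]",
      config$window_len, format(config$sigma), config$step, length(seqs),
      nrow(seqs[[1L]]$frames), ncol(seqs[[1L]]$frames),
      as.numeric(Sys.time() - t0, units = "secs")
    ))
  }
  names(seqs) <- vapply(seqs, `[[`, character(1), "subject_id")
  stacked <- stack_dfnc(seqs)
  if (through == "dfnc") return(partial(dfnc = seqs, stacked = stacked))

  # --- stage: snapshot states ------------------------------------------------
  t0 <- Sys.time()
  if (stage_done(out_dir, "snap")) {
    sd <- file.path(out_dir, "snap")
    snap <- structure(
      list(centroids = unname(read_matrix_tsv(file.path(sd, "centroids.tsv"), header = FALSE)),
           assignments = as_tibble(utils::read.delim(file.path(sd, "assignments.tsv"))),
           k = config$snap_k, inertia = read_json_file(file.path(sd, "meta.json"))$inertia,
           seed = config$seed),
      class = "evo_snap_states"
    )
    log_line(out_dir, "snap", "loaded from bundle")
  } else {
    snap <- cluster_snapshots(stacked, k = config$snap_k, seed = config$seed + 10L,
                              iter_max = config$iter_max, restarts = config$restarts)
    sd <- stage_dir(out_dir, "snap")
    if (!is.null(sd)) {
      write_matrix_tsv(snap$centroids, file.path(sd, "centroids.tsv"), col_names = NULL)
      utils::write.table(snap$assignments, file.path(sd, "assignments.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_json_file(list(k = snap$k, inertia = snap$inertia, seed = snap$seed),
                      file.path(sd, "meta.json"))
      mark_done(out_dir, "snap")
    }
    log_line(out_dir, "snap", sprintf(
      "k=%d seed=%d restarts=%d inertia=%.4g [%.1fs]", config$snap_k,
      config$seed + 10L, config$restarts, snap$inertia,
      as.numeric(Sys.time() - t0, units = "secs")
    ))
  }

  if (through == "snap") {
    return(partial(dfnc = seqs, stacked = stacked, snap = snap))
  }

  # --- stage: embedding ------------------------------------------------------
  t0 <- Sys.time()
  ecfg <- embed_config(n_neighbors = config$n_neighbors, min_dist = config$min_dist,
                       n_runs = config$n_runs, base_seed = config$seed + 100L,
                       align_runs = config$align_runs)
  if (stage_done(out_dir, "embedding")) {
    sd <- file.path(out_dir, "embedding")
    embedding <- structure(
      list(coords = unname(read_matrix_tsv(file.path(sd, "coords.tsv"), header = FALSE)),
           frame_index = as_tibble(utils::read.delim(file.path(sd, "frame_index.tsv"))),
           config = ecfg),
      class = "evo_embedding"
    )
    log_line(out_dir, "embedding", "loaded from bundle")
  } else {
    embedding <- embed_dfnc(stacked, ecfg)
    sd <- stage_dir(out_dir, "embedding")
    if (!is.null(sd)) {
      write_matrix_tsv(embedding$coords, file.path(sd, "coords.tsv"), col_names = NULL)
      utils::write.table(embedding$frame_index, file.path(sd, "frame_index.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_json_file(unclass(ecfg), file.path(sd, "meta.json"))
      mark_done(out_dir, "embedding")
    }
    log_line(out_dir, "embedding", sprintf(
      "n_neighbors=%d min_dist=%g runs=%d base_seed=%d align=%s [%.1fs]",
      ecfg$n_neighbors, ecfg$min_dist, ecfg$n_runs, ecfg$base_seed,
      ecfg$align_runs, as.numeric(Sys.time() - t0, units = "secs")
    ))
  }

  if (through == "embedding") {
    return(partial(dfnc = seqs, stacked = stacked, snap = snap,
                   embedding = embedding))
  }

  # --- stage: exemplars ------------------------------------------------------
  t0 <- Sys.time()
  if (stage_done(out_dir, "exemplars")) {
    sd <- file.path(out_dir, "exemplars")
    meta <- read_json_file(file.path(sd, "meta.json"))
    exemplars <- structure(
      list(exemplars = as_tibble(utils::read.delim(file.path(sd, "exemplars.tsv"))),
           membership = as_tibble(utils::read.delim(file.path(sd, "segments.tsv"))),
           k = config$k, slope_bound = meta$slope_bound, tau = config$tau,
           inertia = meta$inertia, seed = meta$seed),
      class = "evo_exemplar_set"
    )
    log_line(out_dir, "exemplars", "loaded from bundle")
  } else {
    exemplars <- exemplars_from_embedding(
      embedding, tau = config$tau, k = config$k, seed = config$seed + 200L,
      iter_max = config$iter_max, restarts = config$restarts
    )
    sd <- stage_dir(out_dir, "exemplars")
    if (!is.null(sd)) {
      utils::write.table(exemplars$membership, file.path(sd, "segments.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(exemplars$exemplars, file.path(sd, "exemplars.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_json_file(list(k = exemplars$k, tau = config$tau,
                           slope_bound = exemplars$slope_bound,
                           inertia = exemplars$inertia, seed = exemplars$seed),
                      file.path(sd, "meta.json"))
      mark_done(out_dir, "exemplars")
    }
    log_line(out_dir, "exemplars", sprintf(
      "tau=%d k=%d seed=%d slope_bound=%.4g [%.1fs]", config$tau, config$k,
      config$seed + 200L, exemplars$slope_bound,
      as.numeric(Sys.time() - t0, units = "secs")
    ))
  }

  if (through == "exemplars") {
    return(partial(dfnc = seqs, stacked = stacked, snap = snap,
                   embedding = embedding, exemplars = exemplars))
  }

  # --- stage: lifting --------------------------------------------------------
  t0 <- Sys.time()
  if (stage_done(out_dir, "lift")) {
    sd <- file.path(out_dir, "lift")
    mot <- lapply(seq_len(config$k), function(j) {
      unname(read_matrix_tsv(file.path(sd, sprintf("motif%02d.tsv", j)), header = FALSE))
    })
    names(mot) <- paste0("motif", seq_len(config$k))
    motifs <- structure(
      list(motifs = mot, tau = config$tau, n_neighbors = config$n_lift,
           d = ncol(mot[[1L]])),
      class = "evo_motif_set"
    )
    log_line(out_dir, "lift", "loaded from bundle")
  } else {
    motifs <- lift_all(exemplars, embedding, stacked$frames,
                       tau = config$tau, n = config$n_lift)
    sd <- stage_dir(out_dir, "lift")
    if (!is.null(sd)) {
      for (j in seq_along(motifs$motifs)) {
        write_matrix_tsv(motifs$motifs[[j]],
                         file.path(sd, sprintf("motif%02d.tsv", j)), col_names = NULL)
      }
      write_json_file(list(tau = motifs$tau, n_neighbors = motifs$n_neighbors,
                           d = motifs$d, window_values = motifs$tau * motifs$d),
                      file.path(sd, "meta.json"))
      mark_done(out_dir, "lift")
    }
    log_line(out_dir, "lift", sprintf(
      "tau=%d n=%d -> %d motifs of %d x %d [%.1fs]", config$tau, config$n_lift,
      length(motifs$motifs), motifs$tau, motifs$d,
      as.numeric(Sys.time() - t0, units = "secs")
    ))
  }

  if (through == "lift") {
    return(partial(dfnc = seqs, stacked = stacked, snap = snap,
                   embedding = embedding, exemplars = exemplars,
                   motifs = motifs))
  }

  # --- stage: representation -------------------------------------------------
  t0 <- Sys.time()
  if (stage_done(out_dir, "represent")) {
    sd <- file.path(out_dir, "represent")
    ri_stacked <- unname(read_matrix_tsv(file.path(sd, "ri_weights.tsv"), header = FALSE))
    ri_index <- as_tibble(utils::read.delim(file.path(sd, "ri_index.tsv")))
    series <- lapply(split(seq_len(nrow(ri_index)), ri_index$subject_id), function(rows) {
      structure(list(subject_id = ri_index$subject_id[rows[1L]],
                     weights = ri_stacked[rows, , drop = FALSE],
                     mode = config$mode, tau = config$tau),
                class = "evo_ri")
    })
    series <- series[unique(ri_index$subject_id)]
    ri <- structure(
      list(series = series, stacked = ri_stacked, index = ri_index,
           mode = config$mode, tau = config$tau),
      class = "evo_ri_cohort"
    )
    meta_meta <- read_json_file(file.path(sd, "meta.json"))
    meta <- structure(
      list(centroids = unname(read_matrix_tsv(file.path(sd, "meta_centroids.tsv"), header = FALSE)),
           assignments = as_tibble(utils::read.delim(file.path(sd, "meta_assignments.tsv"))),
           m = config$m, inertia = meta_meta$inertia, seed = meta_meta$seed),
      class = "evo_meta_states"
    )
    log_line(out_dir, "represent", "loaded from bundle")
  } else {
    ri <- ri_cohort(seqs, motifs, mode = config$mode)
    meta <- cluster_weight_vectors(ri, m = config$m, seed = config$seed + 300L,
                                   iter_max = config$iter_max,
                                   restarts = config$meta_restarts)
    sd <- stage_dir(out_dir, "represent")
    if (!is.null(sd)) {
      write_matrix_tsv(ri$stacked, file.path(sd, "ri_weights.tsv"), col_names = NULL)
      utils::write.table(ri$index, file.path(sd, "ri_index.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_matrix_tsv(meta$centroids, file.path(sd, "meta_centroids.tsv"), col_names = NULL)
      utils::write.table(meta$assignments, file.path(sd, "meta_assignments.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_json_file(list(mode = config$mode, m = meta$m, inertia = meta$inertia,
                           seed = meta$seed,
                           window_values = motifs$tau * motifs$d),
                      file.path(sd, "meta.json"))
      mark_done(out_dir, "represent")
    }
    log_line(out_dir, "represent", sprintf(
      "mode=%s m=%d seed=%d [%.1fs]", config$mode, config$m, config$seed + 300L,
      as.numeric(Sys.time() - t0, units = "secs")
    ))
  }

  if (through == "represent") {
    return(partial(dfnc = seqs, stacked = stacked, snap = snap,
                   embedding = embedding, exemplars = exemplars,
                   motifs = motifs, ri = ri, meta = meta))
  }

  # --- stage: stats ----------------------------------------------------------
  t0 <- Sys.time()
  if (stage_done(out_dir, "stats")) {
    sd <- file.path(out_dir, "stats")
    effects <- list(group = as_tibble(utils::read.delim(file.path(sd, "group_effects.tsv"))))
    if (file.exists(file.path(sd, "symptom_effects.tsv"))) {
      effects$symptom <- as_tibble(utils::read.delim(file.path(sd, "symptom_effects.tsv")))
    }
    log_line(out_dir, "stats", "loaded from bundle")
  } else {
    features <- subject_mean_ri(ri)
    effects <- list(group = fit_group_model(features, manifest,
                                            correction = config$correction))
    has_panss <- all(PANSS_COLS %in% names(manifest)) &&
      !anyNA(manifest[manifest$diagnosis == 1, PANSS_COLS])
    n_pat <- sum(manifest$diagnosis == 1)
    if (has_panss && n_pat > length(PANSS_COLS) + 4L) {
      effects$symptom <- fit_symptom_model(features, manifest,
                                           correction = config$correction)
    }
    sd <- stage_dir(out_dir, "stats")
    if (!is.null(sd)) {
      utils::write.table(effects$group, file.path(sd, "group_effects.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (!is.null(effects$symptom)) {
        utils::write.table(effects$symptom, file.path(sd, "symptom_effects.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      write_json_file(
        list(models = names(effects), correction = config$correction,
             n = nrow(manifest), formula_group = "feature ~ gender + age + meanFD + diagnosis",
             formula_symptom = "feature ~ panss_* + age + gender + meanFD (patients)"),
        file.path(sd, "meta.json")
      )
      mark_done(out_dir, "stats")
    }
    log_line(out_dir, "stats", sprintf(
      "models=%s correction=%s [%.1fs]", paste(names(effects), collapse = ","),
      config$correction, as.numeric(Sys.time() - t0, units = "secs")
    ))
  }

  structure(
    list(config = config, manifest = manifest, dfnc = seqs, stacked = stacked,
         snap = snap, embedding = embedding, exemplars = exemplars,
         motifs = motifs, ri = ri, meta = meta, effects = effects,
         dir = out_dir),
    class = "evo_bundle"
  )
}

#' @export
print.evo_bundle <- function(x, ...) {
  cat(sprintf(
    "<evo_bundle> %d subjects | %d motifs (tau = %d) | %d meta-states | models: %s\n",
    nrow(x$manifest), length(x$motifs$motifs), x$motifs$tau, x$meta$m,
    paste(names(x$effects), collapse = ", ")
  ))
  invisible(x)
}
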