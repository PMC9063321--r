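# deterministic random correlation-like symmetric matrix with unit diagonal
random_corr <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3 * n), 3 * n, n)
  r <- stats::cov2cor(crossprod(x))
  r <- (r + t(r)) / 2 # exact symmetry
  diag(r) <- 1
  r
}

# wrap plain coordinates (+ optional subject labels) as an embedding object
toy_embedding <- function(coords, subject_id = "s1") {
  coords <- as.matrix(coords)
  if (length(subject_id) == 1L) subject_id <- rep(subject_id, nrow(coords))
  idx <- tibble::tibble(subject_id = subject_id,
                        window = stats::ave(seq_along(subject_id), subject_id,
                                            FUN = seq_along),
                        row = seq_len(nrow(coords)))
  structure(list(coords = coords, frame_index = idx, config = embed_config()),
            class = "evo_embedding")
}

# motif set directly from a list of tau x d matrices
toy_motif_set <- function(frames_list, n_neighbors = 25L) {
  structure(
    list(motifs = frames_list, tau = nrow(frames_list[[1L]]),
         n_neighbors = as.integer(n_neighbors), d = ncol(frames_list[[1L]])),
    class = "evo_motif_set"
  )
}

# snapshot-state object with hand-chosen assignments
toy_snap_states <- function(assignments, k) {
  structure(
    list(centroids = matrix(0, k, 2), assignments = assignments,
         k = as.integer(k), inertia = 0, seed = 1L),
    class = "evo_snap_states"
  )
}

# smooth oscillatory timecourses (plus a dash of noise so no window is flat)
smooth_timecourse <- function(n_t = 120, n = 5, seed = 1) {
  set.seed(seed)
  t <- seq_len(n_t)
  x <- sapply(seq_len(n), function(j) {
    sin(2 * pi * t / (30 + 7 * j) + j) + 0.3 * rnorm(n_t)
  })
  timecourse(x, sprintf("smooth%d", seed))
}

# small manifest for model tests
toy_manifest <- function(n, seed = 1, patients_only = FALSE) {
  set.seed(seed)
  diagnosis <- if (patients_only) rep(1L, n) else rep(c(0L, 1L), length.out = n)
  m <- tibble::tibble(
    subject_id = sprintf("t%03d", seq_len(n)), file = NA_character_,
    diagnosis = diagnosis, age = round(rnorm(n, 38, 10)),
    gender = rbinom(n, 1, 0.5), meanFD = round(exp(rnorm(n, log(0.15), 0.3)), 4)
  )
  for (col in evodfnc:::PANSS_COLS) {
    m[[col]] <- ifelse(m$diagnosis == 1, sample(1:7, n, replace = TRUE), NA_real_)
  }
  m
}
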