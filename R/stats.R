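PANSS_COLS <- c(
  "panss_delusions", "panss_grandiosity", "panss_hallucinations",
  "panss_suspiciousness", "panss_preoccupation", "panss_unusual_thought"
)

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg step-up FDR (default) or Bonferroni, via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Corrected q-values, monotone in `p`.
#' @export
correct_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_invalid_input("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

# align a feature matrix with manifest rows; features: matrix with subject
# rownames, or tibble with a subject_id column
align_features <- function(features, manifest) {
  if (is.data.frame(features)) {
    ids <- features$subject_id
    features <- as.matrix(features[, setdiff(names(features), "subject_id"), drop = FALSE])
    rownames(features) <- ids
  }
  features <- as.matrix(features)
  if (is.null(rownames(features))) {
    if (nrow(features) != nrow(manifest)) {
      stop_invalid_input("`features` rows cannot be matched to the manifest.")
    }
    rownames(features) <- manifest$subject_id
  }
  missing <- setdiff(manifest$subject_id, rownames(features))
  if (length(missing) > 0L) {
    stop_invalid_input(sprintf(
      "Features missing for subjects: %s.", paste(missing, collapse = ", ")
    ))
  }
  features[manifest$subject_id, , drop = FALSE]
}

check_design <- function(x, label) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    abort(
      sprintf("%s design is rank deficient; collinear column(s): %s.",
              label, paste(bad, collapse = ", ")),
      class = "evodfnc_singular_design"
    )
  }
}

# per-feature OLS of each column of y on design x, reporting the requested
# coefficients; zero-variance responses get estimate 0 / p 1 by convention
ols_effect_rows <- function(y, x, predictors) {
  check_design(x, "Model")
  n <- nrow(x)
  df <- n - ncol(x)
  if (df < 1L) {
    abort(sprintf("Too few subjects (n = %d) for %d predictors.", n, ncol(x)),
          class = "evodfnc_invalid_design")
  }
  xtx_inv <- chol2inv(chol(crossprod(x)))
  coefs <- xtx_inv %*% crossprod(x, y) # p x F
  resid <- y - x %*% coefs
  sigma2 <- colSums(resid^2) / df
  feature_names <- colnames(y)
  if (is.null(feature_names)) feature_names <- paste0("feature", seq_len(ncol(y)))
  zero_var <- apply(y, 2L, function(col) stats::var(col) <= 0)
  purrr::map_dfr(predictors, function(pr) {
    j <- match(pr, colnames(x))
    se <- sqrt(sigma2 * xtx_inv[j, j])
    est <- coefs[j, ]
    tt <- ifelse(se > 0, est / se, 0)
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    est[zero_var] <- 0
    tt[zero_var] <- 0
    p[zero_var] <- 1
    tibble(feature = feature_names, predictor = pr, estimate = unname(est),
           statistic = unname(tt), p.value = unname(p), n = n)
  })
}

new_effect_table <- function(tbl, model, correction, n) {
  tbl$q.value <- correct_pvalues(tbl$p.value, method = correction)
  tbl <- tbl[, c("feature", "predictor", "estimate", "statistic",
                 "p.value", "q.value", "n")]
  structure(tbl, class = c("evo_effects", class(tibble())),
            model = model, correction = correction, n_subjects = n)
}

#' Covariate-adjusted group (diagnosis) model
#'
#' For each feature column, fits ordinary least squares of the feature on
#' gender, age, mean frame displacement and diagnosis (with intercept), and
#' reports the two-sided t test of the diagnosis coefficient, corrected
#' across features.
#'
#' @param features Subject-by-feature numeric matrix (rownames = subject ids)
#'   or tibble with a `subject_id` column.
#' @param manifest Cohort tibble with columns `subject_id`, `diagnosis`
#'   (0/1), `age`, `gender` (0/1), `meanFD`.
#' @param correction `"bh"` (default) or `"bonferroni"`.
#' @return An `evo_effects` tibble: `feature`, `predictor`, `estimate`,
#'   `statistic`, `p.value`, `q.value`, `n`.
#' @export
fit_group_model <- function(features, manifest, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  need <- c("subject_id", "diagnosis", "age", "gender", "meanFD")
  if (!all(need %in% names(manifest))) {
    stop_invalid_input(sprintf(
      "Manifest must contain columns: %s.", paste(need, collapse = ", ")
    ))
  }
  if (anyNA(manifest[need])) stop_invalid_input("Missing covariate values in the manifest.")
  y <- align_features(features, manifest)
  x <- cbind(
    `(Intercept)` = 1, gender = manifest$gender, age = manifest$age,
    meanFD = manifest$meanFD, diagnosis = manifest$diagnosis
  )
  tbl <- ols_effect_rows(y, x, "diagnosis")
  new_effect_table(tbl, "group", correction, nrow(x))
}

#' Positive-symptom model (patients only)
#'
#' For each feature, fits OLS on the six positive symptom scores entered
#' jointly (so each symptom's effect is corrected for the others) plus age,
#' gender and mean frame displacement, within the patient group. Reports one
#' row per feature x symptom, corrected across all of them.
#'
#' @inheritParams fit_group_model
#' @param manifest Cohort tibble; patients (`diagnosis == 1`) must have
#'   complete `panss_*` columns (`delusions`, `grandiosity`,
#'   `hallucinations`, `suspiciousness`, `preoccupation`, `unusual_thought`).
#' @return An `evo_effects` tibble with one row per feature-symptom pair.
#' @export
fit_symptom_model <- function(features, manifest, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  pats <- manifest[manifest$diagnosis == 1, , drop = FALSE]
  if (nrow(pats) == 0L) stop_invalid_input("No patients (diagnosis == 1) in the manifest.")
  if (!all(PANSS_COLS %in% names(pats)) || anyNA(pats[PANSS_COLS])) {
    stop_invalid_input("Patients must have complete positive-symptom scores.")
  }
  if (anyNA(pats[c("age", "gender", "meanFD")])) {
    stop_invalid_input("Missing covariate values for patients.")
  }
  y <- align_features(features, pats)
  x <- cbind(
    `(Intercept)` = 1, as.matrix(pats[PANSS_COLS]),
    age = pats$age, gender = pats$gender, meanFD = pats$meanFD
  )
  if (nrow(x) <= ncol(x)) {
    abort(sprintf(
      "Symptom model needs more than %d patients (got %d).", ncol(x), nrow(x)
    ), class = "evodfnc_invalid_design")
  }
  tbl <- ols_effect_rows(y, x, PANSS_COLS)
  new_effect_table(tbl, "symptom", correction, nrow(x))
}
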