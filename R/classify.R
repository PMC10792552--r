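# IES-sensitivity classification: binary labeling by cumulative IES
# duration, bounded log normalization of event delays, l2-regularized
# logistic regression evaluated by stratified group k-fold cross-validation
# (no subject ever split across train and validation), scored by ROC-AUC.

#' IES-sensitivity label
#'
#' A recording is IES-sensitive (positive) when its cumulative IES duration
#' strictly exceeds 30 s — the regime in which the gamma rebound appears.
#'
#' @param delta_ies Cumulative IES duration(s), seconds (>= 0).
#' @param threshold_s Class boundary in seconds.
#' @return Logical vector.
#' @export
label_sensitivity <- function(delta_ies, threshold_s = 30) {
  if (any(delta_ies < 0, na.rm = TRUE)) stop_invalid("delta_ies must be >= 0")
  delta_ies > threshold_s
}

#' Normalize an event delay for the classifier
#'
#' `tau* = log(1 + 100 / ((tau - tau_iso_start) + 0.1))` (natural log), a
#' strictly decreasing map of the delay with a finite value `log(1001)` at
#' zero delay and limit 0 as the delay grows. Absent events (`NA`) map to
#' 0, the infinite-delay limit: an event that never happened.
#'
#' @param tau Event time(s) in seconds (absolute, or already a delay when
#'   `tau_iso_start = 0`).
#' @param tau_iso_start Induction time subtracted from `tau`.
#' @return Dimensionless feature value(s).
#' @export
normalize_feature <- function(tau, tau_iso_start = 0) {
  out <- rep(0, length(tau))
  pres <- !is.na(tau)
  d <- tau[pres] - tau_iso_start
  if (any(d < 0)) stop_invalid("event time precedes tau_iso_start")
  out[pres] <- log(1 + 100 / (d + 0.1))
  out
}

#' Stratified group k-fold assignment
#'
#' Partitions recordings into `k` folds so that all recordings of one
#' subject share a fold (group constraint) while the folds' positive
#' fractions stay as close as possible to the cohort fraction
#' (stratification). Subjects are assigned greedily, largest first, to the
#' fold that keeps positives and sizes most balanced; ties are broken by a
#' seeded shuffle, making the assignment deterministic under `seed`.
#'
#' @param labels Logical/0-1 vector, one per recording.
#' @param groups Subject identifier per recording.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per recording.
#' @export
stratified_group_folds <- function(labels, groups, k = 4, seed = 1) {
  labels <- as.logical(labels)
  groups <- as.character(groups)
  subj <- unique(groups)
  n_pos <- vapply(subj, function(s) sum(labels[groups == s]), numeric(1))
  n_rec <- vapply(subj, function(s) sum(groups == s), numeric(1))
  ord <- with_seed(seed, sample(seq_along(subj)))
  ord <- ord[order(-n_rec[ord], -n_pos[ord])]
  fold_pos <- numeric(k); fold_n <- numeric(k)
  assign_to <- integer(length(subj))
  target_frac <- sum(labels) / length(labels)
  for (i in ord) {
    score <- vapply(seq_len(k), function(f) {
      np <- fold_pos[f] + n_pos[i]; nn <- fold_n[f] + n_rec[i]
      abs(np / nn - target_frac) + 0.01 * nn
    }, numeric(1))
    f <- which.min(score)
    assign_to[i] <- f
    fold_pos[f] <- fold_pos[f] + n_pos[i]
    fold_n[f] <- fold_n[f] + n_rec[i]
  }
  assign_to[match(groups, subj)]
}

#' Fit and cross-validate the IES-sensitivity classifier
#'
#' l2-regularized logistic regression (regularization constant `C = 1`,
#' unpenalized intercept) on normalized event-delay features, evaluated by
#' stratified group k-fold: per-fold models are fitted on the training
#' folds and scored on the held-out fold; the primary metric is the ROC-AUC
#' pooled over all out-of-fold predictions (per-fold AUCs also reported).
#'
#' @param cohort `data.frame` with columns `recording_id`, `subject_id`,
#'   `delta_ies_s`, and one column per feature (event delays in seconds
#'   from induction; `NA` for absent events).
#' @param features Character vector of feature column names, a subset of
#'   the event-delay columns.
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment).
#' @param C Inverse regularization strength.
#' @return An `ies_cv` list: `auc_pooled`, `auc_per_fold`, `folds`,
#'   `coefficients` (per fold), `predictions` (out-of-fold scores),
#'   `features`.
#' @export
fit_evaluate <- function(cohort, features, k = 4, seed = 1, C = 1) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c("subject_id", "delta_ies_s", features),
                          names(cohort))
  if (length(missing_cols))
    stop_invalid("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  y <- label_sensitivity(cohort$delta_ies_s)
  if (sum(y) < k || sum(!y) < k)
    stop_invalid("need at least k recordings in each class")
  x <- vapply(features, function(f) normalize_feature(cohort[[f]]),
              numeric(nrow(cohort)))
  x <- matrix(x, nrow = nrow(cohort),
              dimnames = list(NULL, features))
  # glmnet needs >= 2 columns; an all-zero pad column leaves the fit, the
  # penalty and the predictions unchanged
  if (ncol(x) == 1) x <- cbind(x, .pad = 0)
  folds <- stratified_group_folds(y, cohort$subject_id, k, seed)
  pred <- rep(NA_real_, nrow(cohort))
  coefs <- vector("list", k)
  auc_fold <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2)
      stop_invalid("fold ", f, " has a single-class training set")
    lam <- 1 / (sum(tr) * C)
    if (all(apply(x[tr, , drop = FALSE], 2, stats::var) < 1e-12)) {
      # no predictor variation: the model is uninformative, score at chance
      pred[te] <- 0.5
      coefs[[f]] <- c(`(Intercept)` = 0)
    } else {
      fit <- suppressWarnings(            # small folds trip glmnet's n check
        glmnet::glmnet(x[tr, , drop = FALSE], factor(y[tr]),
                       family = "binomial", alpha = 0, lambda = lam,
                       standardize = FALSE, thresh = 1e-10, maxit = 1e6))
      pred[te] <- as.numeric(stats::predict(fit, x[te, , drop = FALSE],
                                            type = "response"))
      coefs[[f]] <- stats::setNames(as.numeric(stats::coef(fit)),
                                    rownames(stats::coef(fit)))
    }
    if (length(unique(y[te])) == 2)
      auc_fold[f] <- roc_auc(y[te], pred[te])
  }
  structure(list(auc_pooled = roc_auc(y, pred), auc_per_fold = auc_fold,
                 folds = folds, coefficients = coefs, predictions = pred,
                 labels = y, features = features),
            class = "ies_cv")
}

# ROC-AUC with positives scoring high (Mann-Whitney convention).
roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = as.integer(labels),
                                 predictor = scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' @export
print.ies_cv <- function(x, ...) {
  cat(sprintf("<ies_cv> %d-fold stratified group CV on features: %s\n",
              length(x$auc_per_fold), paste(x$features, collapse = ", ")))
  cat(sprintf("  pooled out-of-fold ROC-AUC: %.3f\n", x$auc_pooled))
  cat("  per-fold ROC-AUC:",
      paste(sprintf("%.3f", x$auc_per_fold), collapse = ", "), "\n")
  invisible(x)
}

#' Build a cohort table from per-recording analyses
#'
#' Convenience constructor mapping a list of [extract_event_chain()]
#' results plus cumulative IES durations to the classifier's input layout.
#'
#' @param events_list List of `event_times`.
#' @param delta_ies Numeric vector of cumulative IES durations (s).
#' @param subject_id Subject identifier per recording.
#' @param protocol Optional protocol tag per recording.
#' @return `data.frame` cohort table.
#' @export
cohort_table <- function(events_list, delta_ies, subject_id,
                         protocol = NA_character_) {
  grab <- function(nm) vapply(events_list, function(e)
    e[[nm]] %||% NA_real_, numeric(1))
  data.frame(
    recording_id = seq_along(events_list),
    subject_id = subject_id,
    protocol = protocol,
    delta_ies_s = delta_ies,
    tau_theta_decay_s = grab("tau_theta_decay"),
    tau_delta_app_s = grab("tau_delta_app"),
    tau_theta_disp_s = grab("tau_theta_disp"),
    tau_delta_disp_s = grab("tau_delta_disp"),
    tau_ies1_s = grab("tau_ies1"),
    stringsAsFactors = FALSE)
}
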