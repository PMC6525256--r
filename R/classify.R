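#' PCA feature reduction fitted on training pixels only
#'
#' Principal component analysis (centered, unscaled) on a training feature
#' matrix; the smallest number of leading components whose cumulative
#' variance reaches `variance_kept` is retained. The fitted projection —
#' training means and rotation — is applied unchanged to test pixels, so no
#' test information leaks into the reduction. Constant channels are dropped
#' with a warning.
#'
#' @param x numeric matrix, rows = pixels, columns = feature channels (>= 2)
#' @param variance_kept fraction of variance to retain, in `(0, 1]`
#' @return `list(scores, projection)`; apply the projection to new data with
#'   `predict(projection, newdata)`
#' @export
pca_reduce <- function(x, variance_kept = 0.99) {
  if (!is.matrix(x) || ncol(x) < 2L)
    abort_param("pca_reduce needs a matrix with at least 2 channels")
  if (variance_kept <= 0 || variance_kept > 1)
    abort_param("variance_kept must be in (0, 1]")
  sds <- apply(x, 2L, stats::sd)
  keep_cols <- sds > 1e-12
  if (!all(keep_cols)) {
    warning(sprintf("dropping %d constant channel(s): %s", sum(!keep_cols),
                    paste(colnames(x)[!keep_cols], collapse = ", ")),
            call. = FALSE)
    x <- x[, keep_cols, drop = FALSE]
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= variance_kept - 1e-12)[1L]
  proj <- structure(list(rotation = pr$rotation[, seq_len(k), drop = FALSE],
                         center = pr$center, keep_cols = keep_cols,
                         n_components = k),
                    class = "ssv_pca")
  list(scores = pr$x[, seq_len(k), drop = FALSE], projection = proj)
}

#' @export
predict.ssv_pca <- function(object, newdata, ...) {
  newdata <- newdata[, object$keep_cols, drop = FALSE]
  sweep(newdata, 2L, object$center) %*% object$rotation
}

#' @export
print.ssv_pca <- function(x, ...) {
  cat(sprintf("ssv_pca: %d components over %d channels\n",
              x$n_components, sum(x$keep_cols)))
  invisible(x)
}

# --- classifier delegation ---------------------------------------------------
# The contribution under study is the features, not the learners; classifiers
# are delegated to established implementations. "adaboost" maps to shallow
# boosted trees (depth-2 xgboost, the AdaBoost-with-tree-learner analogue);
# "robustboost_like" to shrunken, row-subsampled boosting, a variant tolerant
# of label noise.

ssv_classifiers <- c("adaboost", "robustboost_like", "svm_linear", "svm_rbf",
                     "random_forest")

fit_classifier <- function(x, y, classifier, seed) {
  classifier <- match.arg(classifier, ssv_classifiers)
  y <- as.integer(as.logical(y))
  set.seed(seed)
  model <- switch(classifier,
    svm_linear = e1071::svm(x = x, y = factor(y), kernel = "linear",
                            scale = TRUE),
    svm_rbf = e1071::svm(x = x, y = factor(y), kernel = "radial",
                         scale = TRUE),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = factor(y), probability = TRUE,
      num.trees = 200L, seed = seed, num.threads = 1L),
    adaboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2L,
                    eta = 0.3, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = 100L, verbose = 0),
    robustboost_like = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L,
                    eta = 0.1, subsample = 0.7, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = 150L, verbose = 0)
  )
  structure(list(model = model, classifier = classifier),
            class = "ssv_classifier")
}

predict_scores <- function(fit, x) {
  switch(fit$classifier,
    svm_linear = ,
    svm_rbf = {
      dv <- attr(stats::predict(fit$model, x, decision.values = TRUE),
                 "decision.values")
      # decision value sign depends on factor-level ordering; orient to "1"
      if (grepl("^0/1", colnames(dv)[1L])) -dv[, 1L] else dv[, 1L]
    },
    random_forest = stats::predict(fit$model, data = as.data.frame(x),
                                   num.threads = 1L)$predictions[, "1"],
    adaboost = ,
    robustboost_like = stats::predict(
      fit$model, xgboost::xgb.DMatrix(x, nthread = 1L))
  )
}

# Stratified random subsample: `frac` of each class, with a floor per class
# (capped at availability) so tiny phantoms stay trainable.
subsample_training <- function(labels, frac, min_per_class) {
  idx <- lapply(c(0L, 1L), function(cl) {
    i <- which(labels == cl)
    n <- min(length(i), max(floor(frac * length(i)), min_per_class))
    sample(i, n)
  })
  sort(unlist(idx))
}

#' Leave-one-patient-out training and evaluation
#'
#' For each patient in turn, all of that patient's images form the test
#' fold and every other patient's labeled pixels form the training pool —
#' fold assignment is by patient, never by image, so within-patient
#' correlation cannot leak. Per fold: PCA is fitted on the full training
#' pixels, a stratified random subsample (default 1\%, floored at
#' `min_per_class` pixels per class) fits the classifier, and all labeled
#' held-out pixels are scored. AUC is threshold-free; MCC uses the
#' threshold that maximizes MCC on the training scores. Deterministic for
#' a fixed `seed`.
#'
#' @param dataset list of entries, each
#'   `list(features, labels, patient_id, image_id)` where `features` is a
#'   pixels x channels matrix and `labels` a 0/1 vector (pixels align
#'   across the two); build one with [dataset_from_stacks()]
#' @param classifier one of `"adaboost"`, `"robustboost_like"`,
#'   `"svm_linear"`, `"svm_rbf"`, `"random_forest"`
#' @param subsample_frac training subsample fraction
#' @param seed integer seed controlling subsampling and classifier fitting
#' @param variance_kept PCA variance fraction retained
#' @param min_per_class subsample floor per class per fold
#' @return data frame with one row per held-out patient: `held_out_patient`,
#'   `mcc`, `auc`, `tp`, `tn`, `fp`, `fn`, `threshold`, `status`
#' @export
train_eval_lopo <- function(dataset, classifier = "random_forest",
                            subsample_frac = 0.01, seed = 1L,
                            variance_kept = 0.99, min_per_class = 500L) {
  classifier <- match.arg(classifier, ssv_classifiers)
  pats <- vapply(dataset, `[[`, "", "patient_id")
  upats <- unique(pats)
  if (length(upats) < 2L)
    abort_data("leave-one-patient-out needs at least 2 distinct patients (got %d)",
               length(upats))
  rows <- vector("list", length(upats))
  for (fi in seq_along(upats)) {
    pat <- upats[fi]
    tr <- do.call(rbind, lapply(dataset[pats != pat], `[[`, "features"))
    ytr <- unlist(lapply(dataset[pats != pat], `[[`, "labels"))
    te <- do.call(rbind, lapply(dataset[pats == pat], `[[`, "features"))
    yte <- unlist(lapply(dataset[pats == pat], `[[`, "labels"))
    if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L) {
      rows[[fi]] <- data.frame(held_out_patient = pat, mcc = NA_real_,
                               auc = NA_real_, tp = NA, tn = NA, fp = NA,
                               fn = NA, threshold = NA_real_,
                               status = "skipped: missing class")
      next
    }
    set.seed((seed * 1009L + fi) %% 2147483647L)
    red <- pca_reduce(tr, variance_kept)
    sub <- subsample_training(ytr, subsample_frac, min_per_class)
    fit <- fit_classifier(red$scores[sub, , drop = FALSE], ytr[sub],
                          classifier,
                          seed = (seed * 2003L + fi) %% 2147483647L)
    # operating point from training scores only (capped for speed)
    thr_idx <- if (length(ytr) > 50000L) sample(length(ytr), 50000L)
               else seq_along(ytr)
    str <- predict_scores(fit, red$scores[thr_idx, , drop = FALSE])
    op <- best_mcc_threshold(str, ytr[thr_idx])
    ste <- predict_scores(fit, predict(red$projection, te))
    cm <- confusion_at(ste, yte, op$threshold)
    rows[[fi]] <- data.frame(held_out_patient = pat,
                             mcc = suppressMessages(mcc(cm)),
                             auc = auc(ste, yte),
                             tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
                             threshold = op$threshold, status = "ok")
  }
  do.call(rbind, rows)
}

#' Assemble a LOPO dataset from feature stacks and label masks
#'
#' Extracts the labeled (non-ignore), valid pixels of each image into a
#' features/labels pair keyed by patient.
#'
#' @param stacks list of [feature_stack()]s
#' @param masks list of matching [label_mask()]s
#' @param valid_masks optional list of logical validity matrices
#' @return a dataset list for [train_eval_lopo()]
#' @export
dataset_from_stacks <- function(stacks, masks, valid_masks = NULL) {
  if (length(stacks) != length(masks))
    abort_param("stacks and masks differ in length")
  lapply(seq_along(stacks), function(i) {
    s <- stacks[[i]]; m <- masks[[i]]
    use <- !is.na(m$labels)
    if (!is.null(valid_masks)) use <- use & valid_masks[[i]]
    nm <- channel_names(s)
    feats <- vapply(seq_along(nm), function(ci) s[, , ci][use],
                    numeric(sum(use)))
    colnames(feats) <- nm
    list(features = feats, labels = m$labels[use],
         patient_id = m$patient_id, image_id = m$image_id)
  })
}
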