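#' Stratified k-fold assignment
#'
#' Assigns each observation to one of `k` folds with per-class balance
#' within one observation of the global proportions. In each of the `k`
#' rotations, fold `f` is the test set, fold `f+1` (cyclically) is the
#' validation set and the remaining folds form the training set — an
#' 80/10/10 split at `k = 10`.
#'
#' @param labels Binary outcome vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per observation.
#' @export
stratified_cv_split <- function(labels, k = 10, seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both outcome classes must be present")
  tab <- table(labels)
  if (any(tab < k)) {
    abort(paste0("class ", names(tab)[tab < k][1], " has fewer than k = ", k,
                 " members"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    # rotate the round-robin start between classes so fold sizes balance
    fold[idx] <- ((offset + seq_along(idx) - 1) %% k) + 1
    offset <- offset + length(idx)
  }
  fold
}

cv_roles <- function(fold, f, k) {
  test <- fold == f
  val <- fold == (f %% k) + 1
  list(test = test, val = val, train = !test & !val)
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation with midranks for ties: the probability that a
#' random positive outscores a random negative, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUROC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validated AUROC
#'
#' Runs the full pipeline per fold — scaler, covariate prior and model all
#' fitted on that fold's training data, early stopping on its validation
#' fold, scoring by the marginal predictive on its test fold — and reports
#' the per-fold AUROC with mean and standard error of the mean.
#'
#' @param data Cohort tibble (original scale) with outcome column `y`.
#' @param schema A [tavr_schema()].
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and per-fold fits).
#' @param config A [train_config()].
#' @param keep_fits Keep the per-fold fitted models (needed for
#'   [predictor_importance()]).
#' @param ... Passed to [fit_model()] (e.g. backbone, compressor, rois).
#' @return A `tavr_cv` with `folds`, `scores`, `mean_auroc`, `sem`.
#' @export
cross_validate <- function(data, schema, k = 10, seed = 1,
                           config = train_config(), keep_fits = TRUE, ...) {
  fold <- stratified_cv_split(data$y, k = k, seed = seed)
  fits <- vector("list", k)
  folds <- list()
  scores <- list()
  for (f in seq_len(k)) {
    roles <- cv_roles(fold, f, k)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- fit_model(data[roles$train, ], data[roles$val, ], schema, cfg, ...)
    test <- data[roles$test, ]
    pred <- predict(fit, test, ...)
    a <- auroc(pred$.pred, test$y)
    folds[[f]] <- tibble(fold = f, auroc = a, n_test = nrow(test))
    scores[[f]] <- tibble(
      fold = f,
      patient_id = if ("patient_id" %in% names(test)) test$patient_id else
        as.character(which(roles$test)),
      score = pred$.pred, label = test$y, branch = pred$.branch
    )
    if (keep_fits) fits[[f]] <- fit
  }
  folds <- dplyr::bind_rows(folds)
  structure(
    list(
      folds = folds, scores = dplyr::bind_rows(scores),
      mean_auroc = mean(folds$auroc),
      sem = sd(folds$auroc) / sqrt(k),
      k = k, seed = seed, fold_assignment = fold,
      fits = if (keep_fits) fits, config = config
    ),
    class = "tavr_cv"
  )
}

#' @export
print.tavr_cv <- function(x, ...) {
  cat("<tavr_cv> ", x$k, "-fold stratified CV: AUROC ",
    sprintf("%.3f +/- %.3f (SEM)", x$mean_auroc, x$sem), "\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate a fixed model across stratified folds
#'
#' Scores an already-fitted (or constructed) model on every test fold of
#' the stratified rotation without refitting, producing an object
#' compatible with [predictor_importance()]. Useful for evaluating a
#' pretrained model or a generative ground truth.
#'
#' @param data Cohort tibble with outcome `y`.
#' @param fit A `tavr_fit` (or compatible structure).
#' @param k,seed Fold structure.
#' @return A `tavr_cv`.
#' @export
evaluate_model_cv <- function(data, fit, k = 10, seed = 1) {
  fold <- stratified_cv_split(data$y, k = k, seed = seed)
  folds <- list()
  for (f in seq_len(k)) {
    test <- data[fold == f, ]
    pred <- predict(fit, test)
    folds[[f]] <- tibble(fold = f, auroc = auroc(pred$.pred, test$y),
                         n_test = nrow(test))
  }
  folds <- dplyr::bind_rows(folds)
  structure(
    list(
      folds = folds, scores = NULL, mean_auroc = mean(folds$auroc),
      sem = sd(folds$auroc) / sqrt(k), k = k, seed = seed,
      fold_assignment = fold, fits = rep(list(fit), k), config = NULL
    ),
    class = "tavr_cv"
  )
}

#' Predictor importance by evaluation-time marginalization
#'
#' Withholds a group of predictors from the test folds (masking them, so
#' the fitted model marginalizes them out) and reports the resulting AUROC
#' drop, mean over folds with its SEM, without any refitting. Group members
#' are covariate names, measurement column names (`J_*`), or `"image"` for
#' the whole feature block.
#'
#' @param cv A [cross_validate()] result with kept fits.
#' @param data The same cohort the CV ran on.
#' @param groups Named list of character vectors.
#' @return Tibble with one row per group, sorted by mean drop.
#' @export
predictor_importance <- function(cv, data, groups) {
  if (is.null(cv$fits)) abort("cross_validate must be run with keep_fits = TRUE")
  schema <- cv$fits[[1]]$schema
  known <- c(schema$names, j_names(data), "image")
  for (g in names(groups)) {
    bad <- setdiff(groups[[g]], known)
    if (length(bad)) {
      abort(paste0("unknown group member(s) in '", g, "': ",
                   paste(bad, collapse = ", ")))
    }
  }
  out <- list()
  for (g in names(groups)) {
    drops <- numeric(cv$k)
    for (f in seq_len(cv$k)) {
      roles <- cv_roles(cv$fold_assignment, f, cv$k)
      test <- data[roles$test, ]
      masked <- test
      for (mb in groups[[g]]) {
        if (mb == "image") {
          for (nm in f_names(masked)) masked[[nm]] <- NA_real_
          if ("image_id" %in% names(masked)) masked$image_id <- NA_character_
        } else {
          masked[[mb]] <- NA_real_
        }
      }
      base <- cv$folds$auroc[cv$folds$fold == f]
      pred <- predict(cv$fits[[f]], masked)
      drops[f] <- base - auroc(pred$.pred, test$y)
    }
    out[[g]] <- tibble(
      group = g, mean_drop = mean(drops),
      sem = sd(drops) / sqrt(cv$k)
    )
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$mean_drop))
  class(res) <- c("tavr_importance", class(res))
  res
}

#' Logistic-regression baselines with imputation or deletion
#'
#' Plain per-fold logistic regression on the tabular predictors (optionally
#' plus the measurements), using the same stratified splits as
#' [cross_validate()] with the training and validation folds pooled for
#' fitting. Missing entries are either imputed with the training-fold mean
#' or handled by listwise deletion of incomplete training rows (test rows
#' are always scored with training-mean imputation).
#'
#' @param data Cohort tibble with outcome `y`.
#' @param schema A [tavr_schema()].
#' @param predictors `"A"` (covariates only) or `"AJ"` (plus measurements).
#' @param missing `"mean_imputation"` or `"complete_case"`.
#' @param k,seed Fold structure, matching [cross_validate()].
#' @return Tibble with per-fold AUROC plus `mean` / `sem` attributes.
#' @export
baseline_logistic <- function(data, schema, predictors = c("A", "AJ"),
                              missing = c("mean_imputation", "complete_case"),
                              k = 10, seed = 1) {
  predictors <- match.arg(predictors)
  missing <- match.arg(missing)
  cols <- schema$names
  if (predictors == "AJ") cols <- c(cols, j_names(data))
  fold <- stratified_cv_split(data$y, k = k, seed = seed)
  res <- numeric(k)
  for (f in seq_len(k)) {
    roles <- cv_roles(fold, f, k)
    tr <- data[roles$train | roles$val, c(cols, "y")]
    te <- data[roles$test, c(cols, "y")]
    mu <- vapply(tr[cols], function(x) mean(x, na.rm = TRUE), 0)
    mu[is.na(mu)] <- 0
    if (missing == "complete_case") {
      keep <- complete.cases(tr[cols])
      tr_fit <- tr[keep, ]
    } else {
      tr_fit <- tr
      for (nm in cols) tr_fit[[nm]][is.na(tr_fit[[nm]])] <- mu[nm]
    }
    for (nm in cols) te[[nm]][is.na(te[[nm]])] <- mu[nm]
    if (nrow(tr_fit) < 5 || length(unique(tr_fit$y)) < 2) {
      warn("degenerate training fold after deletion; scoring at 0.5")
      sc <- rep(0.5, nrow(te))
    } else {
      fit <- suppressWarnings(
        glm(y ~ ., data = tr_fit, family = binomial())
      )
      sc <- suppressWarnings(predict(fit, te, type = "response"))
    }
    res[f] <- auroc(sc, te$y)
  }
  out <- tibble(fold = seq_len(k), auroc = res)
  attr(out, "mean") <- mean(res)
  attr(out, "sem") <- sd(res) / sqrt(k)
  out
}
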