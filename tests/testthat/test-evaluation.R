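test_that("stratified folds balance classes and partition the data", {
  set.seed(71)
  labels <- c(rep(1, 44), rep(0, 56))
  fold <- stratified_cv_split(labels, k = 10, seed = 2)
  tab <- table(fold)
  expect_true(all(tab == 10))
  pos_per_fold <- tapply(labels, fold, sum)
  expect_true(all(pos_per_fold %in% c(4, 5)))
  # every observation in exactly one test fold
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 100)
  # reproducibility
  expect_identical(fold, stratified_cv_split(labels, k = 10, seed = 2))
  expect_false(identical(fold, stratified_cv_split(labels, k = 10, seed = 3)))
  expect_error(stratified_cv_split(c(rep(0, 50), rep(1, 5)), k = 10), "fewer")
  expect_error(stratified_cv_split(rep(1, 30), k = 3), "both")
})

test_that("train/validation/test roles rotate cyclically at 80/10/10", {
  labels <- rep(c(0, 1), 50)
  fold <- stratified_cv_split(labels, k = 10, seed = 1)
  r <- tavrisk:::cv_roles(fold, 3, 10)
  expect_equal(sum(r$test), 10)
  expect_equal(sum(r$val), 10)
  expect_equal(sum(r$train), 80)
  expect_true(all(fold[r$val] == 4))
  r10 <- tavrisk:::cv_roles(fold, 10, 10)
  expect_true(all(fold[r10$val] == 1)) # wraps around
})

test_that("auroc implements midrank Mann-Whitney", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auroc(c(0.5, 0.5, 0.5), c(1, 0, 1)), 0.5)
  # two positive-negative pairs: one concordant, one discordant
  expect_equal(auroc(c(0.8, 0.6, 0.4), c(1, 0, 1)), 0.5)
  expect_error(auroc(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("auroc equals exhaustive pairwise concordance and the pROC reference", {
  set.seed(72)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1) # ties likely
    a <- auroc(scores, labels)
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(a, mean(pairs), tolerance = 1e-12)
    expect_equal(a, as.numeric(suppressMessages(
      pROC::auc(labels, scores, direction = "<")
    )), tolerance = 1e-12)
  }
})

test_that("cross-validation separates a strong-signal cohort and not shuffled labels", {
  truth <- make_true_params(4, 2, 2, seed = 81, n_continuous = 4,
                            effect_scale = 6, sigma_I = 0.3)
  coh <- generate_cohort(truth, 400, seed = 82)
  cfg <- train_config(optimizer = "lbfgs", lbfgs_maxit = 80, seed = 1)
  cv <- cross_validate(coh, truth$schema, k = 5, seed = 2, config = cfg,
                       keep_fits = FALSE)
  expect_gte(cv$mean_auroc, 0.95)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$folds$auroc >= 0 & cv$folds$auroc <= 1))

  shuf <- coh
  set.seed(83)
  shuf$y <- sample(shuf$y)
  cv0 <- cross_validate(shuf, truth$schema, k = 5, seed = 2, config = cfg,
                        keep_fits = FALSE)
  expect_lt(abs(cv0$mean_auroc - 0.5), 3 * max(cv0$sem, 0.02))

  # SEM of identical fold values is zero
  expect_equal(sd(c(0.7, 0.7, 0.7)) / sqrt(3), 0)
})

test_that("test rows never leak into training", {
  truth <- make_true_params(4, 2, 2, seed = 91, n_continuous = 2)
  coh <- generate_cohort(truth, 200, seed = 92)
  cfg <- train_config(max_epochs = 3, seed = 7)
  fold <- stratified_cv_split(coh$y, k = 5, seed = 3)
  roles <- tavrisk:::cv_roles(fold, 1, 5)
  f_ref <- fit_model(coh[roles$train, ], coh[roles$val, ], truth$schema, cfg)
  # permute the test rows' covariates: the training trace must not move
  coh2 <- coh
  idx <- which(roles$test)
  set.seed(94)
  for (nm in c(truth$schema$names, paste0("J_", 1:2))) {
    coh2[[nm]][idx] <- sample(coh2[[nm]][idx])
  }
  f_perm <- fit_model(coh2[roles$train, ], coh2[roles$val, ], truth$schema, cfg)
  expect_identical(f_ref$trace, f_perm$trace)
})

test_that("predictor importance finds planted signal and ignores inert predictors", {
  # construct a model where x1 carries most of the outcome signal, x3 none
  sch <- tavr_schema(paste0("x", 1:4), rep("continuous", 4))
  prior <- structure(
    list(mean = rep(0, 4), var = rep(1, 4), rate = rep(NA_real_, 4),
         schema = sch),
    class = "tavr_prior"
  )
  params <- tavr_params(
    beta = matrix(0, 4, 2), phi = matrix(0.5, 2, 1),
    alpha_I = c(0.3, 0.3), alpha_A = c(2, 0.3, 0, 0.2), b_Y = 0,
    sigma_I = 0.7, sigma_J = 0.7
  )
  truth <- structure(list(schema = sch, prior = prior, params = params),
                     class = "tavr_truth")
  coh <- generate_cohort(truth, 1500, seed = 95)
  fit <- as_fixed_fit(params, prior, sch)
  cv <- evaluate_model_cv(coh, fit, k = 5, seed = 4)
  imp <- predictor_importance(cv, coh, groups = list(
    x1 = "x1", x2 = "x2", inert = "x3", image = "image"
  ))
  expect_equal(imp$group[1], "x1") # planted predictor ranks first
  expect_equal(imp$mean_drop[imp$group == "inert"], 0, tolerance = 1e-12)
  expect_error(
    predictor_importance(cv, coh, groups = list(bad = "nope")),
    "unknown"
  )
  # empty group: no drop anywhere
  imp0 <- predictor_importance(cv, coh, groups = list(none = character(0)))
  expect_equal(imp0$mean_drop, 0, tolerance = 1e-12)
})

test_that("withholding every predictor collapses the scores to a constant", {
  sch <- tavr_schema(c("x1", "x2"), rep("continuous", 2))
  prior <- structure(
    list(mean = c(0, 0), var = c(1, 1), rate = rep(NA_real_, 2), schema = sch),
    class = "tavr_prior"
  )
  params <- tavr_params(
    beta = matrix(0.3, 2, 2), phi = matrix(0.5, 2, 1),
    alpha_I = c(0.4, 0.2), alpha_A = c(0.8, -0.5), b_Y = 0.1,
    sigma_I = 0.7, sigma_J = 0.7
  )
  truth <- structure(list(schema = sch, prior = prior, params = params),
                     class = "tavr_truth")
  coh <- generate_cohort(truth, 200, seed = 96)
  masked <- coh
  for (nm in c("x1", "x2", "J_1", "f_1", "f_2")) masked[[nm]] <- NA_real_
  pred <- predictive_outcome(masked, params, prior)
  expect_equal(length(unique(round(pred$.pred, 12))), 1)
  expect_equal(auroc(pred$.pred, coh$y), 0.5)
})

test_that("logistic baseline reduces to plain logistic regression without missingness", {
  truth <- make_true_params(4, 2, 2, seed = 97, n_continuous = 2,
                            effect_scale = 2)
  coh <- generate_cohort(truth, 300, seed = 98)
  bl <- baseline_logistic(coh, truth$schema, "A", "mean_imputation",
                          k = 5, seed = 6)
  # reference: identical folds, plain glm
  fold <- stratified_cv_split(coh$y, k = 5, seed = 6)
  roles <- tavrisk:::cv_roles(fold, 1, 5)
  tr <- coh[roles$train | roles$val, c(truth$schema$names, "y")]
  te <- coh[roles$test, c(truth$schema$names, "y")]
  g <- suppressWarnings(glm(y ~ ., data = tr, family = binomial()))
  ref <- auroc(predict(g, te, type = "response"), te$y)
  expect_equal(bl$auroc[1], ref, tolerance = 1e-12)
  expect_equal(nrow(bl), 5)
  # deletion baseline runs and scores every fold even under heavy missingness
  cohm <- impose_missingness(coh, missingness_spec("MCAR", a_rate = 0.4,
    j_rate = 0, image_rate = 0), truth$schema, seed = 99)
  bl2 <- baseline_logistic(cohm, truth$schema, "A", "complete_case",
                           k = 5, seed = 6)
  expect_true(all(is.finite(bl2$auroc)))
})

test_that("tidy, glance and autoplot methods cover the result types", {
  truth <- make_true_params(3, 2, 2, seed = 101, n_continuous = 2)
  coh <- generate_cohort(truth, 150, seed = 102)
  cfg <- train_config(max_epochs = 3, seed = 2)
  fit <- fit_model(coh[1:120, ], coh[121:150, ], truth$schema, cfg)
  td <- tidy(fit)
  expect_true(all(c("term", "block", "estimate") %in% names(td)))
  expect_equal(nrow(td), 3 * 2 + 2 * 2 + 2 + 3 + 3)
  gl <- glance(fit)
  expect_equal(gl$d_A, 3)
  cv <- evaluate_model_cv(coh, as_fixed_fit(truth$params, truth$prior,
                                            truth$schema), k = 3, seed = 1)
  expect_s3_class(autoplot(cv), "gg")
  expect_s3_class(autoplot(fit), "gg")
  imp <- predictor_importance(cv, coh, groups = list(x01 = "x01"))
  expect_s3_class(autoplot(imp), "gg")
  expect_equal(nrow(tidy(cv)), 3)
  expect_equal(glance(cv)$k, 3)
})
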