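test_that("sigmoid-Gaussian expectation: symmetry, degeneracy, quadrature", {
  # symmetry at zero mean, exact at zero variance
  expect_equal(sigmoid_gaussian_expectation(0, 5), 0.5)
  expect_equal(sigmoid_gaussian_expectation(0, 0.01), 0.5)
  expect_equal(sigmoid_gaussian_expectation(2, 0), plogis(2))
  expect_error(sigmoid_gaussian_expectation(0, -1), "non-negative")
  # quadrature oracle at (1, 4)
  expect_lt(
    abs(sigmoid_gaussian_expectation(1, 4) - gh_sigmoid_expectation(1, 4)),
    0.01
  )
})

test_that("sigmoid-Gaussian expectation is monotone in mean and shrinks to 1/2 with variance", {
  m <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(sigmoid_gaussian_expectation(m, 2)) > 0))
  v <- seq(0, 25, by = 1)
  up <- sigmoid_gaussian_expectation(1.5, v)
  expect_true(all(diff(up) < 0)) # decreasing toward 0.5 for positive mean
  expect_true(all(up > 0.5))
  dn <- sigmoid_gaussian_expectation(-1.5, v)
  expect_true(all(diff(dn) > 0))
  expect_true(all(dn < 0.5))
})

test_that("marginal with no missingness reduces exactly to the complete log-joint", {
  set.seed(21)
  prior <- fix_prior()
  for (rep in 1:10) {
    p <- rnd_params()
    obs <- rnd_obs(y = rbinom(1, 1, 0.5))
    expect_equal(
      marginal_log_joint(obs, p, prior),
      complete_log_joint(obs, p, prior),
      tolerance = 1e-10
    )
  }
})

test_that("one missing binary covariate averages the two complete evaluations", {
  set.seed(22)
  schema <- fix_schema()
  prior <- fix_prior()
  prior$rate[3] <- 0.5
  p <- rnd_params()
  obs <- rnd_obs()
  o0 <- obs; o0$x3 <- 0
  o1 <- obs; o1$x3 <- 1
  om <- obs; om$x3 <- NA
  # each complete evaluation already carries its own p(x3 = v) = 1/2 factor,
  # so the two-term enumeration is their sum — i.e. the average of the two
  # conditional joints
  expect_equal(
    marginal_log_joint(om, p, prior),
    log(exp(complete_log_joint(o0, p, prior)) +
          exp(complete_log_joint(o1, p, prior))),
    tolerance = 1e-10
  )
})

test_that("closed-form marginals match the Monte-Carlo oracle in every missingness class", {
  set.seed(23)
  prior <- fix_prior()
  classes <- missingness_classes()
  for (cl in names(classes)) {
    ar <- classes[[cl]]
    ok_pm <- 0
    n_rep <- 8
    for (rep in seq_len(n_rep)) {
      p <- rnd_params()
      obs <- rnd_obs(ar$am, ar$jm, ar$img, y = rbinom(1, 1, 0.5))
      lm <- marginal_log_joint(obs, p, prior)
      # probit-matched oracle: bias-free against the closed form
      pm <- mc_marginal_oracle(obs, p, prior,
        n_samples = 5e4, seed = rep,
        method = "probit-matched"
      )
      if (abs(exp(lm) - pm$value) <= 3 * pm$se + 1e-12) ok_pm <- ok_pm + 1
      # exact-sigmoid oracle: independent, allow the documented probit bias
      ex <- mc_marginal_oracle(obs, p, prior, n_samples = 5e4, seed = rep)
      expect_lt(
        abs(exp(lm) - ex$value),
        3 * ex$se + 0.02 * ex$value + 1e-12
      )
    }
    expect_gte(ok_pm, n_rep - 1)
  }
})

test_that("oracle is deterministic given a seed and exact with nothing missing", {
  set.seed(24)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- rnd_obs()
  mc <- mc_marginal_oracle(obs, p, prior, n_samples = 2000, seed = 9)
  expect_equal(mc$value, exp(complete_log_joint(obs, p, prior)))
  expect_equal(mc$se, 0)
  obs2 <- rnd_obs(a_miss = 1L)
  m1 <- mc_marginal_oracle(obs2, p, prior, n_samples = 5000, seed = 3)
  m2 <- mc_marginal_oracle(obs2, p, prior, n_samples = 5000, seed = 3)
  expect_identical(m1$value, m2$value)
  expect_error(mc_marginal_oracle(obs2, p, prior, n_samples = 10), "1000")
})

test_that("oracle standard error shrinks like 1/sqrt(n)", {
  set.seed(25)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- rnd_obs(a_miss = 1L, img = FALSE)
  se1 <- mc_marginal_oracle(obs, p, prior, n_samples = 4000, seed = 5)$se
  se2 <- mc_marginal_oracle(obs, p, prior, n_samples = 16000, seed = 5)$se
  expect_equal(se1 / se2, 2, tolerance = 0.35)
})

test_that("predictive outcome: vanishing image weight and noise limits", {
  set.seed(26)
  prior <- fix_prior()
  schema <- fix_schema()
  for (rep in 1:5) {
    p <- rnd_params()
    obs <- rnd_obs(img = FALSE)
    obs$y <- NULL
    a <- as.numeric(obs[1, schema$names])
    target <- plogis(sum(p$alpha_A * a) + p$b_Y)
    p0 <- p
    p0$alpha_I <- rep(0, 3)
    expect_equal(predictive_outcome(obs, p0, prior)$.pred, target_of(p0, a),
      tolerance = 1e-10
    )
    ps <- p
    ps$log_sigma_I <- log(1e-12) # sigma_I -> 0: all correction terms vanish
    expect_equal(predictive_outcome(obs, ps, prior)$.pred, target_of(ps, a),
      tolerance = 1e-8
    )
  }
})

test_that("predictive outcome matches posterior-sampling Monte Carlo when the image is missing", {
  set.seed(27)
  prior <- fix_prior()
  ok <- 0
  for (rep in 1:8) {
    p <- rnd_params()
    obs <- rnd_obs(img = FALSE)
    pr <- predictive_outcome(obs, p, prior)$.pred
    mc <- mc_marginal_oracle(obs, p, prior,
      n_samples = 1e5, seed = rep, what = "predict"
    )
    if (abs(pr - mc$value) <= 3 * mc$se + 0.005) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("with an image present the measurements never influence prediction", {
  set.seed(28)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- rnd_obs(a_miss = c(1L, 3L)) # image present, missing covariates
  obs$y <- NULL
  p1 <- predictive_outcome(obs, p, prior)$.pred
  obs$J_1 <- obs$J_1 + 5
  obs$J_2 <- NA
  p2 <- predictive_outcome(obs, p, prior)$.pred
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(predictive_outcome(obs, p, prior)$.branch, "image")
})

test_that("fully empty observation yields the prior-marginal outcome probability", {
  set.seed(29)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- tibble::tibble(
    x1 = NA_real_, x2 = NA_real_, x3 = NA_real_, x4 = NA_real_,
    J_1 = NA_real_, J_2 = NA_real_
  )
  pr <- predictive_outcome(obs, p, prior)$.pred
  mc <- mc_marginal_oracle(dplyr::mutate(obs, y = 1), p, prior,
    n_samples = 2e5, seed = 4, what = "predict"
  )
  expect_lt(abs(pr - mc$value), 3 * mc$se + 0.01)
  expect_equal(predictive_outcome(obs, p, prior)$.branch, "tabular")
})

test_that("marginal normalizes over Y for a fully missing observation", {
  set.seed(30)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- tibble::tibble(
    x1 = NA_real_, x2 = NA_real_, x3 = NA_real_, x4 = NA_real_,
    J_1 = NA_real_, J_2 = NA_real_, y = 1
  )
  l1 <- marginal_log_joint(obs, p, prior)
  obs$y <- 0
  l0 <- marginal_log_joint(obs, p, prior)
  expect_equal(exp(l1) + exp(l0), 1, tolerance = 0.01)
})

test_that("marginalization is invariant to covariate dimension order", {
  set.seed(31)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- rnd_obs(a_miss = c(2L, 4L), j_miss = 1L, img = FALSE)
  l_ref <- marginal_log_joint(obs, p, prior)
  perm <- c(3, 1, 4, 2)
  schema_p <- tavr_schema(fix_schema()$names[perm], fix_schema()$kinds[perm])
  prior_p <- structure(
    list(
      mean = prior$mean[perm], var = prior$var[perm],
      rate = prior$rate[perm], schema = schema_p
    ),
    class = "tavr_prior"
  )
  p_p <- p
  p_p$beta <- p$beta[perm, ]
  p_p$alpha_A <- p$alpha_A[perm]
  obs_p <- obs[, c(schema_p$names, "J_1", "J_2", "y")]
  expect_equal(marginal_log_joint(obs_p, p_p, prior_p), l_ref, tolerance = 1e-10)
})

test_that("errors route the caller to the right entry point", {
  set.seed(32)
  prior <- fix_prior()
  p <- rnd_params()
  obs <- rnd_obs(a_miss = 1L)
  obs$y <- NA_real_
  expect_error(marginal_log_joint(obs, p, prior), "predictive_outcome")
})

test_that("enumeration refuses pathologically many missing binary covariates", {
  d_A <- 25
  kinds <- rep("binary", d_A)
  sch <- tavr_schema(sprintf("b%02d", 1:d_A), kinds)
  prior <- structure(
    list(
      mean = rep(NA_real_, d_A), var = rep(NA_real_, d_A),
      rate = rep(0.5, d_A), schema = sch
    ),
    class = "tavr_prior"
  )
  p <- tavr_params(
    beta = matrix(0, d_A, 2), phi = matrix(0, 2, 1), alpha_I = c(0, 0),
    alpha_A = rep(0, d_A), b_Y = 0, sigma_I = 1, sigma_J = 1
  )
  row <- as.list(setNames(rep(NA_real_, d_A), sch$names))
  row$J_1 <- NA_real_
  row$y <- 1
  expect_error(
    marginal_log_joint(tibble::as_tibble(row), p, prior),
    "> 20"
  )
})
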