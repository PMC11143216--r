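# Shared small-model fixtures: a 4-covariate schema (2 continuous, 2 binary),
# a hand-set prior, and generators for random parameters and observations at
# the d_A=4, d_f=3, d_J=2 scale used throughout the marginalization checks.

fix_schema <- function() {
  tavr_schema(paste0("x", 1:4), c("continuous", "continuous", "binary", "binary"))
}

fix_prior <- function(schema = fix_schema()) {
  structure(
    list(
      mean = c(0.2, -0.1, NA, NA), var = c(1.1, 0.8, NA, NA),
      rate = c(NA, NA, 0.4, 0.7), schema = schema
    ),
    class = "tavr_prior"
  )
}

# Parameter scales mirror fitted clinical models on standardized data:
# O(0.5) link weights, O(0.25) outcome log-odds weights, near-unit noise.
rnd_params <- function(d_A = 4, d_f = 3, d_J = 2) {
  tavr_params(
    beta = matrix(rnorm(d_A * d_f, 0, 0.5), d_A, d_f),
    phi = matrix(rnorm(d_f * d_J, 0, 0.5), d_f, d_J),
    alpha_I = rnorm(d_f, 0, 0.25),
    alpha_A = rnorm(d_A, 0, 0.25),
    b_Y = rnorm(1, 0, 0.5),
    sigma_I = runif(1, 0.7, 1.3),
    sigma_J = runif(1, 0.7, 1.3)
  )
}

# One observation as a one-row tibble; a_miss/j_miss index missing entries,
# img toggles the image features.
rnd_obs <- function(a_miss = integer(), j_miss = integer(), img = TRUE,
                    y = 1, d_f = 3, d_J = 2, schema = fix_schema()) {
  a <- c(rnorm(2), rbinom(2, 1, 0.5))
  a[a_miss] <- NA
  f <- rnorm(d_f)
  J <- rnorm(d_J)
  J[j_miss] <- NA
  row <- as.list(setNames(a, schema$names))
  row <- c(row, setNames(as.list(J), paste0("J_", seq_len(d_J))))
  if (img) row <- c(row, setNames(as.list(f), paste0("f_", seq_len(d_f))))
  row$y <- y
  tibble::as_tibble(row)
}

# The six missingness classes exercised by the closed-form-vs-oracle checks.
missingness_classes <- function() {
  list(
    cont_A = list(am = 1L, jm = integer(), img = TRUE),
    bin_A = list(am = 3L, jm = integer(), img = TRUE),
    image_fullJ = list(am = integer(), jm = integer(), img = FALSE),
    image_partJ = list(am = integer(), jm = 2L, img = FALSE),
    image_noJ = list(am = integer(), jm = 1:2, img = FALSE),
    mixed = list(am = c(1L, 3L), jm = 2L, img = FALSE)
  )
}

# 64-node Gauss-Hermite quadrature for E[sigmoid(X)], X ~ N(m, v): the
# independent oracle for the probit approximation.
gh_sigmoid_expectation <- function(m, v, nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  sum(gh$w * plogis(m + sqrt(2 * v) * gh$x)) / sqrt(pi)
}

# covariate-only predictive target used in the missing-image limit checks
target_of <- function(p, a) plogis(sum(p$alpha_A * a) + p$b_Y)
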