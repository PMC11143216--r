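#' Construct the probabilistic model parameters
#'
#' Holds the parameters of the generative model: `beta` maps covariates to
#' the mean of the latent image features, `phi` maps features to the mean of
#' the manual measurements, `alpha_I`/`alpha_A`/`b_Y` form the logistic
#' outcome head, and `sigma_I`/`sigma_J` are the isotropic standard
#' deviations of the feature and measurement links (stored on the log scale
#' for optimisation).
#'
#' @param beta `d_A x d_f` matrix.
#' @param phi `d_f x d_J` matrix.
#' @param alpha_I Feature weight vector, length `d_f`.
#' @param alpha_A Covariate weight vector, length `d_A`.
#' @param b_Y Scalar intercept.
#' @param sigma_I,sigma_J Positive scalars.
#' @return A `tavr_params` object.
#' @export
tavr_params <- function(beta, phi, alpha_I, alpha_A, b_Y, sigma_I, sigma_J) {
  beta <- as.matrix(beta)
  phi <- as.matrix(phi)
  d_A <- nrow(beta)
  d_f <- ncol(beta)
  d_J <- ncol(phi)
  stopifnot(
    nrow(phi) == d_f, length(alpha_I) == d_f, length(alpha_A) == d_A,
    length(b_Y) == 1, sigma_I > 0, sigma_J > 0
  )
  structure(
    list(
      beta = beta, phi = phi,
      alpha_I = as.numeric(alpha_I), alpha_A = as.numeric(alpha_A),
      b_Y = as.numeric(b_Y),
      log_sigma_I = log(sigma_I), log_sigma_J = log(sigma_J),
      d_A = d_A, d_f = d_f, d_J = d_J
    ),
    class = "tavr_params"
  )
}

#' @export
print.tavr_params <- function(x, ...) {
  cat("<tavr_params> d_A=", x$d_A, " d_f=", x$d_f, " d_J=", x$d_J,
    "  sigma_I=", signif(exp(x$log_sigma_I), 4),
    " sigma_J=", signif(exp(x$log_sigma_J), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Random initialisation of model parameters
#'
#' Weights start near zero (`Normal(0, 0.01^2)`), the intercept at the logit
#' of the training prevalence, and both noise scales at 1.
#'
#' @param d_A,d_f,d_J Dimensions.
#' @param prevalence Training outcome prevalence used to set `b_Y`.
#' @param seed Integer seed.
#' @return A `tavr_params`.
#' @export
init_params <- function(d_A, d_f, d_J, prevalence = 0.5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tavr_params(
    beta = matrix(rnorm(d_A * d_f, 0, 0.01), d_A, d_f),
    phi = matrix(rnorm(d_f * d_J, 0, 0.01), d_f, d_J),
    alpha_I = rnorm(d_f, 0, 0.01),
    alpha_A = rnorm(d_A, 0, 0.01),
    b_Y = qlogis(min(max(prevalence, 1e-3), 1 - 1e-3)),
    sigma_I = 1, sigma_J = 1
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# --- flat-vector packing for the optimizer ------------------------------

pack_params <- function(p) {
  c(
    as.numeric(p$beta), as.numeric(p$phi), p$alpha_I, p$alpha_A, p$b_Y,
    p$log_sigma_I, p$log_sigma_J
  )
}

unpack_params <- function(theta, d_A, d_f, d_J) {
  i <- 0
  take <- function(n) {
    if (n == 0) return(numeric(0))
    out <- theta[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  p <- list(
    beta = matrix(take(d_A * d_f), d_A, d_f),
    phi = matrix(take(d_f * d_J), d_f, d_J),
    alpha_I = take(d_f),
    alpha_A = take(d_A),
    b_Y = take(1),
    log_sigma_I = take(1),
    log_sigma_J = take(1),
    d_A = d_A, d_f = d_f, d_J = d_J
  )
  class(p) <- "tavr_params"
  p
}

param_dim <- function(d_A, d_f, d_J) d_A * d_f + d_f * d_J + d_f + d_A + 3
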