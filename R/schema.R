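#' Define the tabular covariate schema
#'
#' A schema names the covariate vector `A` and declares each dimension as
#' continuous or binary. Continuous covariates are modelled with Gaussian
#' priors (and are z-scored by the training scaler), binary covariates with
#' Bernoulli priors and values in \{0, 1\}.
#'
#' @param names Character vector of unique covariate names.
#' @param kinds Character vector, one of `"continuous"` or `"binary"` per
#'   covariate.
#' @return A `tavr_schema` object.
#' @examples
#' tavr_schema(c("age", "male"), c("continuous", "binary"))
#' @export
tavr_schema <- function(names, kinds) {
  stopifnot(is.character(names), length(names) == length(kinds))
  if (anyDuplicated(names)) {
    abort("covariate names must be unique")
  }
  kinds <- match.arg(kinds, c("continuous", "binary"), several.ok = TRUE)
  structure(
    list(names = names, kinds = kinds, d_A = length(names)),
    class = "tavr_schema"
  )
}

#' @export
print.tavr_schema <- function(x, ...) {
  cat("<tavr_schema> ", x$d_A, " covariates (",
    sum(x$kinds == "continuous"), " continuous, ",
    sum(x$kinds == "binary"), " binary)\n",
    sep = ""
  )
  invisible(x)
}

schema_cont <- function(schema) which(schema$kinds == "continuous")
schema_bin <- function(schema) which(schema$kinds == "binary")

# Column names of the measurement block in a cohort tibble.
j_names <- function(data) grep("^J_", names(data), value = TRUE)
f_names <- function(data) grep("^f_", names(data), value = TRUE)

check_cohort <- function(data, schema) {
  missing_cols <- setdiff(schema$names, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "cohort is missing covariate columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (nm in schema$names[schema$kinds == "binary"]) {
    v <- data[[nm]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad)) {
      abort(paste0(
        "binary covariate '", nm, "' has non-{0,1} value in row ", bad[1]
      ))
    }
  }
  invisible(data)
}

#' Fit the covariate prior p(A) by maximum marginal likelihood
#'
#' Hyperparameters of the per-dimension priors are set to maximise the
#' marginal likelihood of the observed covariate entries in `data`:
#' continuous dimensions get the sample mean and the maximum-likelihood
#' (1/n) variance over their observed entries, binary dimensions get the
#' observed fraction, clipped to `[1e-3, 1 - 1e-3]` so that degenerate
#' training folds never yield infinite log-probabilities. The prior is held
#' fixed during model training.
#'
#' @param data Cohort tibble with one column per covariate; `NA` = missing.
#' @param schema A [tavr_schema()].
#' @return A `tavr_prior` with fields `mean`, `var` (continuous dims) and
#'   `rate` (binary dims), each of length `d_A` with `NA` where not
#'   applicable.
#' @export
fit_prior <- function(data, schema) {
  check_cohort(data, schema)
  d <- schema$d_A
  mu <- v <- rate <- rep(NA_real_, d)
  for (k in seq_len(d)) {
    x <- data[[schema$names[k]]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      abort(paste0(
        "covariate '", schema$names[k],
        "' is fully missing; cannot fit its prior"
      ))
    }
    if (schema$kinds[k] == "continuous") {
      mu[k] <- mean(x)
      v[k] <- mean((x - mu[k])^2)
      if (v[k] <= 0) v[k] <- 1e-6 # degenerate constant column
    } else {
      rate[k] <- min(max(mean(x), 1e-3), 1 - 1e-3)
    }
  }
  structure(
    list(mean = mu, var = v, rate = rate, schema = schema),
    class = "tavr_prior"
  )
}

#' @export
print.tavr_prior <- function(x, ...) {
  cat("<tavr_prior> over", x$schema$d_A, "covariates\n")
  invisible(x)
}

# Log p(A_obs) for one filled covariate row: sum of prior log-densities over
# the *observed* dimensions listed in `obs_idx`.
prior_obs_logdens <- function(a_row, obs_idx, prior) {
  if (!length(obs_idx)) return(0)
  sch <- prior$schema
  tot <- 0
  for (k in obs_idx) {
    if (sch$kinds[k] == "continuous") {
      tot <- tot + dnorm(a_row[k], prior$mean[k], sqrt(prior$var[k]), log = TRUE)
    } else {
      r <- prior$rate[k]
      tot <- tot + a_row[k] * log(r) + (1 - a_row[k]) * log(1 - r)
    }
  }
  unname(tot)
}

#' Fit a standardisation scaler on training data
#'
#' Continuous covariates and all measurement (`J_`) columns are z-scored with
#' training-fold means and standard deviations; binary covariates, outcome
#' and feature columns are left untouched. The isotropic covariances of the
#' latent-feature and measurement links presuppose a common scale across
#' heterogeneous clinical units, hence standardisation is always fitted on
#' the training fold only and applied to validation/test folds.
#'
#' @param data Training cohort tibble.
#' @param schema A [tavr_schema()].
#' @return A `tavr_scaler`.
#' @export
fit_scaler <- function(data, schema) {
  cols <- c(schema$names[schema$kinds == "continuous"], j_names(data))
  center <- scale <- setNames(numeric(length(cols)), cols)
  for (nm in cols) {
    x <- data[[nm]]
    x <- x[!is.na(x)]
    center[nm] <- if (length(x)) mean(x) else 0
    s <- if (length(x) > 1) sd(x) else 1
    scale[nm] <- if (is.na(s) || s <= 0) 1 else s
  }
  structure(list(center = center, scale = scale), class = "tavr_scaler")
}

#' Apply (or invert) a fitted scaler
#'
#' @param data Cohort tibble.
#' @param scaler A [fit_scaler()] result.
#' @param invert If `TRUE`, map standardised values back to original units.
#' @return The transformed tibble.
#' @export
apply_scaler <- function(data, scaler, invert = FALSE) {
  for (nm in intersect(names(scaler$center), names(data))) {
    if (invert) {
      data[[nm]] <- data[[nm]] * scaler$scale[nm] + scaler$center[nm]
    } else {
      data[[nm]] <- (data[[nm]] - scaler$center[nm]) / scaler$scale[nm]
    }
  }
  data
}
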