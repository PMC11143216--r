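#' Draw a ground-truth model for simulation studies
#'
#' Samples a complete generative model (schema, covariate priors and all
#' probabilistic parameters) with a controllable outcome signal strength.
#' Continuous covariate priors are standard-normal-like (the real pipeline
#' standardises covariates, so standardized units are the natural scale);
#' binary rates are drawn away from the extremes. Weight scales shrink with
#' dimension so that the latent features, measurements and outcome log-odds
#' all stay O(1), matching what fitted clinical models look like. The
#' outcome intercept is calibrated by simulation so the marginal prevalence
#' hits `prevalence`.
#'
#' @param d_A,d_f,d_J Dimensions.
#' @param effect_scale Multiplier on the outcome weights `alpha_I`,
#'   `alpha_A` (0 = no signal).
#' @param prevalence Target marginal outcome prevalence.
#' @param n_continuous Number of continuous covariates (default: 40% of
#'   `d_A`, rounded, mirroring the 10/25 split of the clinical table).
#' @param sigma_I,sigma_J Noise scales of the feature and measurement links.
#' @param fix_effect_norm If `TRUE`, rescale the outcome weight vectors so
#'   their root-mean-square equals its design value exactly, randomising
#'   only the direction. With few covariates the chi-distributed norm of a
#'   random draw fluctuates strongly; fixing it guarantees that a simulated
#'   recovery experiment actually instantiates its designed signal size.
#' @param seed Integer seed.
#' @return A `tavr_truth`: list with `schema`, `prior`, `params`.
#' @export
make_true_params <- function(d_A, d_f, d_J, effect_scale = 1,
                             prevalence = 0.44, n_continuous = NULL,
                             sigma_I = 0.7, sigma_J = 0.7,
                             fix_effect_norm = FALSE, seed = 1) {
  stopifnot(d_A > 0, d_f > 0, d_J >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(n_continuous)) n_continuous <- max(1, round(0.4 * d_A))
  kinds <- c(
    rep("continuous", n_continuous),
    rep("binary", d_A - n_continuous)
  )
  schema <- tavr_schema(sprintf("x%02d", seq_len(d_A)), kinds)
  mu <- v <- rate <- rep(NA_real_, d_A)
  mu[kinds == "continuous"] <- 0
  v[kinds == "continuous"] <- 1
  rate[kinds == "binary"] <- runif(sum(kinds == "binary"), 0.15, 0.85)
  prior <- structure(
    list(mean = mu, var = v, rate = rate, schema = schema),
    class = "tavr_prior"
  )
  params <- tavr_params(
    beta = matrix(rnorm(d_A * d_f, 0, 1 / sqrt(d_A)), d_A, d_f),
    phi = matrix(rnorm(d_f * d_J, 0, 1 / sqrt(d_f)), d_f, d_J),
    alpha_I = effect_scale * rnorm(d_f, 0, 0.8 / sqrt(d_f)),
    alpha_A = effect_scale * rnorm(d_A, 0, 0.8 / sqrt(d_A)),
    b_Y = 0, sigma_I = sigma_I, sigma_J = sigma_J
  )
  if (fix_effect_norm && effect_scale > 0) {
    to_rms <- function(x, rms) x * rms / sqrt(mean(x^2))
    params$alpha_A <- to_rms(params$alpha_A, effect_scale * 0.8 / sqrt(d_A))
    params$alpha_I <- to_rms(params$alpha_I, effect_scale * 0.8 / sqrt(d_f))
  }
  # calibrate the intercept to the target prevalence by simulation:
  # eta = alpha_A' A + alpha_I' eps_I + b, with eps_I ~ N(0, sigma_I^2 I)
  ns <- 20000
  As <- sample_covariates(prior, ns)
  base <- as.numeric(As %*% params$alpha_A) +
    rnorm(ns, 0, sigma_I * sqrt(sum(params$alpha_I^2)))
  params$b_Y <- uniroot(
    function(b) mean(plogis(base + b)) - prevalence,
    c(-20, 20), tol = 1e-10
  )$root
  structure(
    list(schema = schema, prior = prior, params = params),
    class = "tavr_truth"
  )
}

sample_covariates <- function(prior, n) {
  sch <- prior$schema
  A <- matrix(0, n, sch$d_A)
  for (k in seq_len(sch$d_A)) {
    A[, k] <- if (sch$kinds[k] == "continuous") {
      rnorm(n, prior$mean[k], sqrt(prior$var[k]))
    } else {
      rbinom(n, 1, prior$rate[k])
    }
  }
  colnames(A) <- sch$names
  A
}

#' Sample a complete cohort from a ground-truth model
#'
#' Follows the generative factorisation exactly: covariates from their
#' priors, latent features `f ~ N(beta' A, sigma_I^2 I)`, measurements
#' `J ~ N(phi' f, sigma_J^2 I)` and the outcome from the logistic head.
#' The feature columns `f_*` stand in for the (synthetic) image.
#'
#' @param truth A [make_true_params()] result.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, covariate, `f_*`, `J_*` and `y`
#'   columns.
#' @export
generate_cohort <- function(truth, n, seed = 1) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- truth$params
  sI <- exp(p$log_sigma_I)
  sJ <- exp(p$log_sigma_J)
  A <- sample_covariates(truth$prior, n)
  FM <- A %*% p$beta + matrix(rnorm(n * p$d_f, 0, sI), n, p$d_f)
  JM <- FM %*% p$phi + matrix(rnorm(n * p$d_J, 0, sJ), n, p$d_J)
  eta <- as.numeric((FM - A %*% p$beta) %*% p$alpha_I) +
    as.numeric(A %*% p$alpha_A) + p$b_Y
  y <- rbinom(n, 1, plogis(eta))
  out <- as_tibble(as.data.frame(A))
  colnames(FM) <- paste0("f_", seq_len(p$d_f))
  if (p$d_J > 0) colnames(JM) <- paste0("J_", seq_len(p$d_J))
  dplyr::bind_cols(
    tibble(patient_id = sprintf("P%05d", seq_len(n))),
    out, as_tibble(as.data.frame(FM)),
    if (p$d_J > 0) as_tibble(as.data.frame(JM)),
    tibble(y = y)
  )
}

#' Missingness specification
#'
#' @param mechanism `"MCAR"` or `"MAR"`. Under MAR, per-variable missingness
#'   probability is a logistic function of the first continuous covariate
#'   (an age-like variable), which itself is never masked.
#' @param a_rate Missing rate for covariates (scalar or per-covariate).
#' @param j_rate Missing rate for measurements (scalar or per-dimension).
#' @param image_rate Probability that the whole image (all `f_*`) is
#'   missing; default 0.49, mirroring a registry where 51% of patients have
#'   a usable CT volume.
#' @param mar_strength Slope of the MAR logistic dependence.
#' @return A `tavr_missingness`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR"), a_rate = 0.1,
                             j_rate = 0.2, image_rate = 0.49,
                             mar_strength = 1) {
  mechanism <- match.arg(mechanism)
  rates <- c(a_rate, j_rate, image_rate)
  if (any(rates < 0 | rates > 1)) abort("missing rates must be in [0, 1]")
  structure(
    list(
      mechanism = mechanism, a_rate = a_rate, j_rate = j_rate,
      image_rate = image_rate, mar_strength = mar_strength
    ),
    class = "tavr_missingness"
  )
}

#' Impose a missingness mechanism on a complete cohort
#'
#' Masks entries with `NA` according to the specification. The image is
#' all-or-nothing per row (all `f_*` columns together); the outcome is
#' never masked.
#'
#' @param data Complete cohort tibble from [generate_cohort()].
#' @param spec A [missingness_spec()].
#' @param schema The cohort's [tavr_schema()].
#' @param seed Integer seed.
#' @return The masked tibble.
#' @export
impose_missingness <- function(data, spec, schema, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(data)
  cont <- schema$names[schema$kinds == "continuous"]
  anchor <- if (length(cont)) cont[1] else NULL

  rate_of <- function(base_rate) {
    if (spec$mechanism == "MCAR" || is.null(anchor)) {
      rep(base_rate, n)
    } else {
      # logistic MAR: offset chosen so the mean rate matches base_rate
      x <- data[[anchor]]
      off <- uniroot(
        function(c0) mean(plogis(c0 + spec$mar_strength * x)) - base_rate,
        c(-30, 30)
      )$root
      plogis(off + spec$mar_strength * x)
    }
  }

  a_rates <- rep(spec$a_rate, length.out = schema$d_A)
  for (k in seq_len(schema$d_A)) {
    nm <- schema$names[k]
    if (identical(nm, anchor) && spec$mechanism == "MAR") next
    mask <- runif(n) < rate_of(a_rates[k])
    data[[nm]][mask] <- NA
  }
  jn <- j_names(data)
  j_rates <- rep(spec$j_rate, length.out = length(jn))
  for (i in seq_along(jn)) {
    mask <- runif(n) < rate_of(j_rates[i])
    data[[jn[i]]][mask] <- NA
  }
  fn <- f_names(data)
  if (length(fn)) {
    img_miss <- runif(n) < rate_of(spec$image_rate)
    for (nm in fn) data[[nm]][img_miss] <- NA
  }
  data
}

#' Simulate a registry-like cohort in one call
#'
#' The `"paper-like"` preset mirrors the study conditions of the TAVR
#' registry analysis: 25 covariates (10 continuous, 15 binary), 15 manual
#' measurements, 16 image features, n = 1449, 44% outcome prevalence and a
#' 49% image-missing rate; covariates and measurements get modest MCAR
#' missingness (10% / 20%), in the range of the registry's per-variable
#' missing fractions. The `"small"` preset is a desk-scale version for
#' quick experiments.
#'
#' @param preset `"paper-like"` or `"small"`.
#' @param n Cohort size (preset default if `NULL`).
#' @param seed Integer seed.
#' @param effect_scale Outcome signal strength.
#' @return List with `data` (masked cohort), `truth` and `spec`.
#' @export
simulate_cohort <- function(preset = c("paper-like", "small"), n = NULL,
                            seed = 1, effect_scale = 1) {
  preset <- match.arg(preset)
  if (preset == "paper-like") {
    truth <- make_true_params(
      d_A = 25, d_f = 16, d_J = 15, effect_scale = effect_scale,
      prevalence = 0.44, n_continuous = 10, seed = seed
    )
    n <- n %||% 1449
    spec <- missingness_spec("MCAR", a_rate = 0.1, j_rate = 0.2, image_rate = 0.49)
  } else {
    truth <- make_true_params(
      d_A = 6, d_f = 4, d_J = 3, effect_scale = effect_scale,
      prevalence = 0.44, n_continuous = 3, seed = seed
    )
    n <- n %||% 400
    spec <- missingness_spec("MCAR", a_rate = 0.1, j_rate = 0.2, image_rate = 0.49)
  }
  data <- generate_cohort(truth, n, seed = seed + 1)
  data <- impose_missingness(data, spec, truth$schema, seed = seed + 2)
  list(data = data, truth = truth, spec = spec)
}

# ---- tube phantoms ------------------------------------------------------

phantom_curve <- function(shape, dims_mm, margin) {
  lo <- margin
  hi <- dims_mm - margin
  mid <- dims_mm / 2
  switch(shape,
    straight = function(t) cbind(mid[1], mid[2], lo[3] + t * (hi[3] - lo[3])),
    arc = function(t) {
      # quarter arc in the x-z plane around (cx, mid_y, cz)
      rad <- 0.8 * min(hi[1] - lo[1], hi[3] - lo[3])
      cx <- mid[1] - rad / 2
      cz <- lo[3]
      ang <- pi / 2 * t
      cbind(cx + rad * cos(ang), mid[2], cz + rad * sin(ang))
    },
    helix = function(t) {
      rad <- 0.25 * min(dims_mm[1], dims_mm[2]) - margin[1] / 2
      cbind(
        mid[1] + rad * cos(2 * pi * t),
        mid[2] + rad * sin(2 * pi * t),
        lo[3] + t * (hi[3] - lo[3])
      )
    },
    abort(paste0("unknown phantom shape '", shape, "'"))
  )
}

#' Render a tube phantom with known centerline landmarks
#'
#' Builds a volume containing a tube of given radius around an analytic
#' curve (straight, circular-arc or helical), with a bright core against a
#' dark background and optional Gaussian noise. The five landmarks are
#' exact points on the analytic curve, so every stage of the straightening
#' pipeline can be validated against known geometry.
#'
#' @param shape `"straight"`, `"arc"` or `"helix"`.
#' @param dims Volume size in voxels (1 mm isotropic spacing).
#' @param radius Tube radius in mm, or a function of arc parameter
#'   `t in [0,1]` returning the local radius (for feature-encoded tubes).
#' @param core,background Intensities (HU-like).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed (noise only).
#' @return List with `volume` (a `tavr_volume`), `landmarks`
#'   (a `tavr_landmarks`) and `curve_fn` (the analytic centerline).
#' @export
render_phantom_volume <- function(shape = "straight", dims = c(64, 64, 80),
                                  radius = 8, core = 300, background = -50,
                                  noise_sd = 0, seed = 1) {
  spacing <- c(1, 1, 1)
  dims_mm <- (dims - 1) * spacing
  rmax <- if (is.function(radius)) max(vapply(seq(0, 1, 0.01), radius, 0)) else radius
  margin <- rep(rmax + 2, 3)
  fn <- phantom_curve(shape, dims_mm, margin)
  tpts <- seq(0, 1, length.out = 257)
  cpts <- fn(tpts)
  if (any(sweep(cpts, 2, rep(rmax, 3)) < 0) ||
    any(sweep(cpts, 2, dims_mm - rmax, "-") > 0)) {
    abort("tube exits the volume; shrink the radius or enlarge the volume")
  }
  vol <- array(background, dims)
  # stamp spheres along a dense sampling of the curve
  for (i in seq_along(tpts)) {
    r <- if (is.function(radius)) radius(tpts[i]) else radius
    ctr <- cpts[i, ]
    lo <- pmax(floor(ctr - r) + 1, 1)
    hi <- pmin(ceiling(ctr + r) + 1, dims)
    xs <- lo[1]:hi[1]
    ys <- lo[2]:hi[2]
    zs <- lo[3]:hi[3]
    dx2 <- ((xs - 1) - ctr[1])^2
    dy2 <- ((ys - 1) - ctr[2])^2
    dz2 <- ((zs - 1) - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- vol[xs, ys, zs]
    sub[d2 <= r^2] <- core
    vol[xs, ys, zs] <- sub
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vol <- vol + array(rnorm(length(vol), 0, noise_sd), dims)
  }
  lms <- landmark_set(fn(seq(0, 1, length.out = 5)))
  list(
    volume = volume_grid(vol, spacing = spacing, origin = c(0, 0, 0)),
    landmarks = lms, curve_fn = fn
  )
}

#' Encode a feature vector into a tube phantom's radius profile
#'
#' Maps `d_f = 16` bounded features invertibly to the radii of 16
#' consecutive bands along the tube, so that a trainable backbone *can*
#' recover the features from the rendered volume. Used for end-to-end
#' image-to-outcome tests with planted image signal.
#'
#' @param features Numeric vector in `[-1, 1]`, length 16.
#' @param base_radius Band radius at feature 0 (mm).
#' @param radius_gain mm of radius per unit feature.
#' @param ... Passed to [render_phantom_volume()].
#' @return As [render_phantom_volume()], plus `radii`.
#' @export
link_features_to_phantom <- function(features, base_radius = 7,
                                     radius_gain = 3, ...) {
  if (length(features) != 16) abort("expected 16 features")
  if (any(abs(features) > 1)) abort("features must lie in [-1, 1]")
  radii <- base_radius + radius_gain * features
  rfun <- function(t) radii[pmin(16L, floor(t * 16) + 1L)]
  out <- render_phantom_volume(shape = "straight", radius = rfun, ...)
  out$radii <- radii
  out
}

#' @rdname link_features_to_phantom
#' @param radii Band radii as returned in `$radii`.
#' @return `phantom_features_from_radii()`: the feature vector.
#' @export
phantom_features_from_radii <- function(radii, base_radius = 7,
                                        radius_gain = 3) {
  (radii - base_radius) / radius_gain
}
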