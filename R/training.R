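#' Training configuration
#'
#' @param lr Adam learning rate for the probabilistic parameters.
#' @param lr_backbone Adam learning rate for backbone/compressor weights.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param use_auxiliary_J Keep the measurement link in the model; set
#'   `FALSE` for the no-auxiliary-output ablation.
#' @param optimizer `"adam"` (minibatch, required for backbone training) or
#'   `"lbfgs"` (full-batch quasi-Newton on the probabilistic parameters;
#'   deterministic and tighter-converging for feature-column cohorts).
#' @param lbfgs_maxit Iteration cap for the L-BFGS path.
#' @param log_file Optional JSONL file receiving one record per epoch.
#' @param verbose Print per-epoch objectives.
#' @return A `tavr_train_config`.
#' @export
train_config <- function(lr = 1e-2, lr_backbone = 1e-3, batch_size = 32,
                         max_epochs = 60, patience = 10, seed = 1,
                         use_auxiliary_J = TRUE,
                         optimizer = c("adam", "lbfgs"), lbfgs_maxit = 200,
                         log_file = NULL, verbose = FALSE) {
  stopifnot(lr > 0, lr_backbone > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1)
  structure(
    list(
      lr = lr, lr_backbone = lr_backbone, batch_size = batch_size,
      max_epochs = max_epochs, patience = patience, seed = seed,
      use_auxiliary_J = use_auxiliary_J,
      optimizer = match.arg(optimizer), lbfgs_maxit = lbfgs_maxit,
      log_file = log_file, verbose = verbose
    ),
    class = "tavr_train_config"
  )
}

batch_subset <- function(batch, idx) {
  list(
    A = batch$A[idx, , drop = FALSE], J = batch$J[idx, , drop = FALSE],
    FM = if (is.null(batch$FM)) NULL else batch$FM[idx, , drop = FALSE],
    img = batch$img[idx], y = batch$y[idx], n = length(idx),
    amask = batch$amask[idx, , drop = FALSE],
    jmask = batch$jmask[idx, , drop = FALSE],
    key = batch$key[idx], schema = batch$schema
  )
}

#' Training objective: negative mean marginal log-likelihood
#'
#' The mean over observations of minus the marginal log-joint, each row
#' marginalized according to its own missingness pattern; complete rows use
#' the full factorised log-joint including the latent-feature link (which
#' identifies `beta` on complete data). With `use_aux = FALSE` the
#' measurement factor is removed everywhere.
#'
#' @param data Cohort tibble on the model (standardized) scale.
#' @param params A [tavr_params()].
#' @param prior A [fit_prior()] result.
#' @param use_aux Keep the measurement link.
#' @return Scalar loss.
#' @export
training_objective <- function(data, params, prior, use_aux = TRUE) {
  batch <- as_batch(data, prior$schema, params$d_f, params$d_J)
  ll <- tavr_engine(batch, params, prior, mode = "joint", use_aux = use_aux)$ll
  if (any(!is.finite(ll))) {
    abort(paste0(
      "non-finite log-likelihood for rows: ",
      paste(head(which(!is.finite(ll)), 10), collapse = ", ")
    ))
  }
  -mean(ll)
}

# Features and parameter-gradients for image rows under the tiny-backbone
# training path. V: n_img x 64 pooled patches.
backbone_features <- function(V, backbone, compressor) {
  E <- V %*% t(backbone$W)
  Ew <- E * matrix(compressor$weights, nrow(E), compressor$D, byrow = TRUE)
  FM <- t(rowsum(t(Ew), rep(seq_len(compressor$d_f), each = compressor$chunk_size)))
  list(FM = FM, E = E)
}

backbone_grad <- function(V, E, DF, backbone, compressor) {
  expand <- rep(seq_len(compressor$d_f), each = compressor$chunk_size)
  DFe <- DF[, expand, drop = FALSE]
  dwc <- colSums(DFe * E)
  DE <- DFe * matrix(compressor$weights, nrow(E), compressor$D, byrow = TRUE)
  dW <- crossprod(DE, V)
  c(as.numeric(dW), dwc)
}

#' Fit the probabilistic model (and optionally the backbone) by maximum
#' likelihood
#'
#' Minimises the negative mean marginal log-likelihood over the training
#' cohort with minibatch Adam, using analytic gradients of every
#' missingness-pattern marginal. The covariate prior and the scaler are
#' fitted on the training fold only; early stopping monitors the validation
#' objective and the best-validation parameters are returned. With a
#' backbone, image features are recomputed from the current weights every
#' epoch and the likelihood gradient is backpropagated into the backbone
#' and compression layer (joint training).
#'
#' @param train,val Cohort tibbles on the original scale.
#' @param schema A [tavr_schema()].
#' @param config A [train_config()].
#' @param d_f Feature dimension (default: inferred from `f_*` columns, or
#'   the compressor).
#' @param backbone,compressor Optional [tiny_backbone()] /
#'   [chunk_compressor()] for joint image training.
#' @param rois Named list of 64^3 ROI arrays; rows reference them through
#'   an `image_id` column (`NA` = no image).
#' @return A `tavr_fit`.
#' @export
fit_model <- function(train, val, schema, config = train_config(),
                      d_f = NULL, backbone = NULL, compressor = NULL,
                      rois = NULL) {
  scaler <- fit_scaler(train, schema)
  ts <- apply_scaler(train, scaler)
  vs <- apply_scaler(val, scaler)
  prior <- fit_prior(ts, schema)
  use_aux <- config$use_auxiliary_J

  with_images <- !is.null(backbone)
  if (with_images) {
    stopifnot(!is.null(compressor), !is.null(rois), "image_id" %in% names(train))
    d_f <- compressor$d_f
    pool_all <- function(data) {
      ids <- data$image_id
      has <- !is.na(ids)
      V <- t(vapply(
        ids[has],
        function(id) pool_volume(normalize_intensity(
          if (inherits(rois[[id]], "tavr_roi")) rois[[id]]$intensities else rois[[id]]
        ), backbone$pool),
        numeric(64)
      ))
      list(V = V, has = has)
    }
    tr_pool <- pool_all(ts)
    va_pool <- pool_all(vs)
    ts[paste0("f_", seq_len(d_f))] <- NA_real_
    vs[paste0("f_", seq_len(d_f))] <- NA_real_
  } else if (is.null(d_f)) {
    d_f <- length(f_names(train))
    if (d_f == 0) abort("no f_ feature columns and no backbone given")
  }
  d_J <- length(j_names(train))
  d_A <- schema$d_A

  batch <- as_batch(ts, schema, d_f, d_J)
  vbatch <- as_batch(vs, schema, d_f, d_J)
  n <- batch$n

  set_features <- function(b, pool, W_feats) {
    b$FM[which(pool$has), ] <- W_feats
    b$img <- pool$has
    # pattern key changes with image presence; recompute
    b$key <- paste(
      apply(b$amask, 1, paste, collapse = ""),
      if (d_J > 0) apply(b$jmask, 1, paste, collapse = "") else
        rep("", b$n),
      as.integer(b$img),
      sep = "|"
    )
    b
  }
  if (with_images) {
    batch$FM <- matrix(NA_real_, n, d_f)
    vbatch$FM <- matrix(NA_real_, vbatch$n, d_f)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  params <- init_params(d_A, d_f, d_J,
    prevalence = mean(batch$y), seed = config$seed
  )
  theta <- pack_params(params)
  np <- length(theta)

  if (config$optimizer == "lbfgs" && !with_images) {
    rw <- rep(1 / n, n)
    tr_hist <- numeric(0)
    fn <- function(th) {
      p <- unpack_params(th, d_A, d_f, d_J)
      v <- -mean(tavr_engine(batch, p, prior, mode = "joint",
                             use_aux = use_aux)$ll)
      tr_hist[length(tr_hist) + 1] <<- v
      v
    }
    gr <- function(th) {
      p <- unpack_params(th, d_A, d_f, d_J)
      -tavr_engine(batch, p, prior, mode = "joint", use_aux = use_aux,
                   want_grad = TRUE, rw = rw)$grad
    }
    opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$lbfgs_maxit))
    params <- unpack_params(opt$par, d_A, d_f, d_J)
    va_obj <- -mean(tavr_engine(vbatch, params, prior, mode = "joint",
                                use_aux = use_aux)$ll)
    if (!is.finite(opt$value) || !is.finite(va_obj)) {
      abort("non-finite objective after L-BFGS optimization")
    }
    return(structure(
      list(
        params = params, prior = prior, scaler = scaler, schema = schema,
        config = config, use_aux = use_aux,
        trace = tibble(epoch = seq_along(tr_hist), train = tr_hist,
                       val = NA_real_),
        best_epoch = length(tr_hist), best_val = va_obj, n_train = n,
        backbone = NULL, compressor = NULL
      ),
      class = "tavr_fit"
    ))
  }
  omega <- if (with_images) pack_omega(backbone, compressor) else numeric(0)
  x <- c(theta, omega)
  lr_vec <- c(rep(config$lr, np), rep(config$lr_backbone, length(omega)))
  m_ad <- v_ad <- numeric(length(x))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0

  eval_obj <- function(b, pool = NULL) {
    if (with_images) {
      ub <- unpack_omega(x[np + seq_along(omega)], backbone, compressor)
      bf <- backbone_features(pool$V, ub$backbone, ub$compressor)
      b <- set_features(b, pool, bf$FM)
    }
    p <- unpack_params(x[seq_len(np)], d_A, d_f, d_J)
    ll <- tavr_engine(b, p, prior, mode = "joint", use_aux = use_aux)$ll
    if (any(!is.finite(ll))) {
      abort(paste0(
        "non-finite loss; offending rows: ",
        paste(head(which(!is.finite(ll)), 10), collapse = ", ")
      ))
    }
    -mean(ll)
  }

  trace <- list()
  best_val <- Inf
  best_x <- x
  best_epoch <- 0
  wait <- 0

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    if (with_images) {
      ub <- unpack_omega(x[np + seq_along(omega)], backbone, compressor)
      bb <- ub$backbone; cc <- ub$compressor
      bf <- backbone_features(tr_pool$V, bb, cc)
      batch <- set_features(batch, tr_pool, bf$FM)
      E_tr <- bf$E
      img_row <- which(tr_pool$has)
    }
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      sb <- batch_subset(batch, idx)
      p <- unpack_params(x[seq_len(np)], d_A, d_f, d_J)
      res <- tavr_engine(sb, p, prior,
        mode = "joint", use_aux = use_aux,
        want_grad = TRUE, rw = rep(1 / length(idx), length(idx))
      )
      g <- -res$grad
      if (with_images) {
        sel <- match(intersect(idx, img_row), img_row)
        g_om <- numeric(length(omega))
        if (length(sel)) {
          loc <- which(sb$img)
          DF <- -res$grad_F[loc, , drop = FALSE]
          rows_in_pool <- match(idx[loc], img_row)
          g_om <- backbone_grad(
            tr_pool$V[rows_in_pool, , drop = FALSE],
            E_tr[rows_in_pool, , drop = FALSE], DF, bb, cc
          )
        }
        g <- c(g, g_om)
      }
      step <- step + 1
      m_ad <- b1 * m_ad + (1 - b1) * g
      v_ad <- b2 * v_ad + (1 - b2) * g^2
      mhat <- m_ad / (1 - b1^step)
      vhat <- v_ad / (1 - b2^step)
      x <- x - lr_vec * mhat / (sqrt(vhat) + eps)
    }
    tr_obj <- eval_obj(batch, if (with_images) tr_pool)
    va_obj <- eval_obj(vbatch, if (with_images) va_pool)
    trace[[epoch]] <- tibble(epoch = epoch, train = tr_obj, val = va_obj)
    if (!is.null(config$log_file)) {
      log_event(config$log_file, list(
        event = "epoch", epoch = epoch, train = tr_obj, val = va_obj,
        seed = config$seed
      ))
    }
    if (config$verbose) {
      cat(sprintf("epoch %3d  train %.4f  val %.4f\n", epoch, tr_obj, va_obj))
    }
    if (va_obj < best_val - 1e-8) {
      best_val <- va_obj
      best_x <- x
      best_epoch <- epoch
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }

  params <- unpack_params(best_x[seq_len(np)], d_A, d_f, d_J)
  if (with_images) {
    ub <- unpack_omega(best_x[np + seq_along(omega)], backbone, compressor)
    backbone <- ub$backbone
    compressor <- ub$compressor
  }
  structure(
    list(
      params = params, prior = prior, scaler = scaler, schema = schema,
      config = config, use_aux = use_aux,
      trace = dplyr::bind_rows(trace), best_epoch = best_epoch,
      best_val = best_val, n_train = n,
      backbone = if (with_images) backbone,
      compressor = if (with_images) compressor
    ),
    class = "tavr_fit"
  )
}

#' @rdname fit_model
#' @export
fit_without_auxiliary <- function(train, val, schema, config = train_config(),
                                  ...) {
  config$use_auxiliary_J <- FALSE
  fit_model(train, val, schema, config, ...)
}

#' @export
print.tavr_fit <- function(x, ...) {
  cat("<tavr_fit> d_A=", x$params$d_A, " d_f=", x$params$d_f,
    " d_J=", x$params$d_J,
    if (!x$use_aux) " (no auxiliary measurements)", "\n",
    "  best epoch ", x$best_epoch, ", validation objective ",
    signif(x$best_val, 5), "\n",
    sep = ""
  )
  invisible(x)
}

#' Wrap explicit parameters as a fixed "fit"
#'
#' Packages a parameter set, prior and schema (e.g. a generative ground
#' truth) into a `tavr_fit`-compatible object with an identity scaler, so
#' it can be used with [predict.tavr_fit()], [evaluate_model_cv()] and
#' [predictor_importance()].
#'
#' @param params A [tavr_params()].
#' @param prior A matching prior.
#' @param schema The covariate schema.
#' @param use_aux Whether the measurement link is active.
#' @return A `tavr_fit`.
#' @export
as_fixed_fit <- function(params, prior, schema, use_aux = TRUE) {
  structure(
    list(
      params = params, prior = prior,
      scaler = structure(
        list(center = setNames(numeric(0), character(0)),
             scale = setNames(numeric(0), character(0))),
        class = "tavr_scaler"
      ),
      schema = schema, use_aux = use_aux, config = NULL,
      trace = NULL, best_epoch = NA_integer_, best_val = NA_real_,
      backbone = NULL, compressor = NULL
    ),
    class = "tavr_fit"
  )
}

#' Predict outcome probabilities with a fitted model
#'
#' Applies the training-fold scaler, computes image features for rows with
#' ROIs (backbone fits only) and routes every row through the appropriate
#' marginal predictive branch.
#'
#' @param object A `tavr_fit`.
#' @param newdata Cohort tibble on the original scale.
#' @param rois Named ROI list for backbone fits.
#' @param ... Unused.
#' @return `newdata` with `.pred` and `.branch` columns.
#' @export
predict.tavr_fit <- function(object, newdata, rois = NULL, ...) {
  ns <- apply_scaler(newdata, object$scaler)
  if (!is.null(object$backbone)) {
    d_f <- object$compressor$d_f
    ns[paste0("f_", seq_len(d_f))] <- NA_real_
    if (!is.null(rois) && "image_id" %in% names(ns)) {
      has <- which(!is.na(ns$image_id))
      for (i in has) {
        f <- extract_features(rois[[ns$image_id[i]]], object$backbone,
          object$compressor)
        ns[i, paste0("f_", seq_len(d_f))] <- as.list(f)
      }
    }
  }
  out <- predictive_outcome(ns, object$params, object$prior,
    use_aux = object$use_aux)
  newdata$.pred <- out$.pred
  newdata$.branch <- out$.branch
  newdata
}
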