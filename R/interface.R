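CHECKPOINT_VERSION <- "1"

#' Read a cohort CSV
#'
#' One row per patient; header names must cover the schema's covariates.
#' Blank cells map to `NA` (missing masks); binary covariates must be 0, 1
#' or blank; measurement columns are prefixed `J_`, feature columns `f_`,
#' the outcome column is `y`. Extra columns other than `patient_id` /
#' `image_id` are dropped with a warning; non-numeric cells in numeric
#' columns are an error naming the cell.
#'
#' @param path CSV file path.
#' @param schema A [tavr_schema()].
#' @return Cohort tibble.
#' @export
read_cohort <- function(path, schema) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  keep_chr <- intersect(c("patient_id", "image_id"), names(raw))
  numeric_cols <- c(
    schema$names, grep("^[Jf]_", names(raw), value = TRUE),
    intersect("y", names(raw))
  )
  missing_cols <- setdiff(schema$names, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort CSV lacks covariate columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), c(numeric_cols, keep_chr))
  if (length(extra)) {
    warn(paste0("ignoring extra columns: ", paste(extra, collapse = ", ")))
  }
  out <- raw[, c(keep_chr, numeric_cols)]
  for (nm in numeric_cols) {
    x <- trimws(out[[nm]])
    x[x == "" | x == "NA"] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      abort(paste0(
        "non-numeric value '", x[bad[1]], "' in column '", nm,
        "', row ", bad[1]
      ))
    }
    out[[nm]] <- v
  }
  check_cohort(out, schema)
  if ("y" %in% names(out)) {
    bad <- which(!is.na(out$y) & !out$y %in% c(0, 1))
    if (length(bad)) {
      abort(paste0("outcome column y has non-{0,1} value in row ", bad[1]))
    }
  }
  out
}

#' @rdname read_cohort
#' @param data Cohort tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

params_to_list <- function(p) {
  list(
    beta = as.numeric(p$beta), phi = as.numeric(p$phi),
    alpha_I = p$alpha_I, alpha_A = p$alpha_A, b_Y = p$b_Y,
    log_sigma_I = p$log_sigma_I, log_sigma_J = p$log_sigma_J,
    d_A = p$d_A, d_f = p$d_f, d_J = p$d_J
  )
}

params_from_list <- function(l) {
  p <- list(
    beta = matrix(l$beta, l$d_A, l$d_f),
    phi = matrix(l$phi, l$d_f, l$d_J),
    alpha_I = l$alpha_I, alpha_A = l$alpha_A, b_Y = l$b_Y,
    log_sigma_I = l$log_sigma_I, log_sigma_J = l$log_sigma_J,
    d_A = l$d_A, d_f = l$d_f, d_J = l$d_J
  )
  class(p) <- "tavr_params"
  p
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single versioned JSON container holding the schema,
#' the covariate prior, the scaler, the fitted parameters and the training
#' configuration, stamped with the package version and a content hash.
#' Loading verifies the hash and refuses tampered or incompatible files.
#'
#' @param fit A `tavr_fit`.
#' @param path Destination file.
#' @return `save_checkpoint()`: the path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  payload <- list(
    version = CHECKPOINT_VERSION,
    package_version = as.character(utils::packageVersion("tavrisk")),
    schema = list(names = fit$schema$names, kinds = fit$schema$kinds),
    prior = fit$prior[c("mean", "var", "rate")],
    scaler = list(
      center = as.list(fit$scaler$center),
      scale = as.list(fit$scaler$scale)
    ),
    params = params_to_list(fit$params),
    use_aux = fit$use_aux,
    config = fit$config[c(
      "lr", "lr_backbone", "batch_size", "max_epochs", "patience", "seed",
      "use_auxiliary_J"
    )],
    best_epoch = fit$best_epoch
  )
  txt <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                       digits = NA, null = "null"))
  container <- list(
    format = "tavrisk-checkpoint",
    content_hash = rlang::hash(txt),
    payload = txt
  )
  jsonlite::write_json(container, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: a `tavr_fit`-compatible object.
#' @export
load_checkpoint <- function(path) {
  container <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(container$format, "tavrisk-checkpoint")) {
    abort("not a tavrisk checkpoint file")
  }
  if (!identical(rlang::hash(container$payload), container$content_hash)) {
    abort("checkpoint refused: content hash mismatch (file was modified)")
  }
  l <- jsonlite::parse_json(container$payload, simplifyVector = TRUE)
  if (!identical(as.character(l$version), CHECKPOINT_VERSION)) {
    abort(paste0("unsupported checkpoint version: ", l$version))
  }
  h <- container$content_hash
  schema <- tavr_schema(l$schema$names, l$schema$kinds)
  prior <- structure(
    list(
      mean = as.numeric(l$prior$mean), var = as.numeric(l$prior$var),
      rate = as.numeric(l$prior$rate), schema = schema
    ),
    class = "tavr_prior"
  )
  scaler <- structure(
    list(
      center = unlist(l$scaler$center), scale = unlist(l$scaler$scale)
    ),
    class = "tavr_scaler"
  )
  fit <- structure(
    list(
      params = params_from_list(l$params), prior = prior, scaler = scaler,
      schema = schema, use_aux = isTRUE(l$use_aux), config = l$config,
      best_epoch = l$best_epoch
    ),
    class = "tavr_fit"
  )
  attr(fit, "stored_hash") <- h
  fit
}

#' Score a cohort with a saved or in-memory model
#'
#' Routes every patient to the marginal predictive branch dictated by their
#' missingness pattern and returns (or writes) per-patient probabilities
#' with the branch label: `"image"` when features are available (manual
#' measurements are then ignored), `"measurements"` when only measurements
#' are, `"tabular"` otherwise.
#'
#' @param model A `tavr_fit` or a checkpoint path.
#' @param data Cohort tibble or CSV path.
#' @param rois Optional named ROI list for backbone models.
#' @param out Optional output CSV path.
#' @return Tibble with `patient_id` (if present), `.pred`, `.branch`.
#' @export
predict_cohort <- function(model, data, rois = NULL, out = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(data)) data <- read_cohort(data, model$schema)
  missing_cols <- setdiff(model$schema$names, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "cohort does not match checkpoint schema; missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  pred <- predict(model, data, rois = rois)
  res <- dplyr::bind_cols(
    if ("patient_id" %in% names(data)) tibble(patient_id = data$patient_id),
    tibble(.pred = pred$.pred, .branch = pred$.branch)
  )
  if (!is.null(out)) readr::write_csv(res, out)
  res
}

#' Append a structured event to a JSONL log
#'
#' @param path Log file (created if absent).
#' @param event Named list; a timestamp and package version are added.
#' @export
log_event <- function(path, event) {
  event$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  event$package <- as.character(utils::packageVersion("tavrisk"))
  cat(jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA), "\n",
    file = path, append = TRUE, sep = ""
  )
  invisible(path)
}

#' Hash a configuration for provenance stamps
#'
#' @param ... Objects identifying a run (configs, schema, seeds).
#' @return A short character hash.
#' @export
config_hash <- function(...) rlang::hash(list(...))
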