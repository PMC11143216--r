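#' Tidy a fitted model
#'
#' One row per scalar parameter, in a long tibble: outcome-head weights,
#' link matrices (with row/column indices) and noise scales.
#'
#' @param x A `tavr_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `block`, `estimate`.
#' @export
tidy.tavr_fit <- function(x, ...) {
  p <- x$params
  sn <- x$schema$names
  dplyr::bind_rows(
    tibble(
      term = paste0("beta[", rep(sn, p$d_f), ",f", rep(seq_len(p$d_f), each = p$d_A), "]"),
      block = "beta", estimate = as.numeric(p$beta)
    ),
    if (p$d_J > 0) tibble(
      term = paste0("phi[f", rep(seq_len(p$d_f), p$d_J), ",J", rep(seq_len(p$d_J), each = p$d_f), "]"),
      block = "phi", estimate = as.numeric(p$phi)
    ),
    tibble(
      term = paste0("alpha_I[f", seq_len(p$d_f), "]"),
      block = "alpha_I", estimate = p$alpha_I
    ),
    tibble(
      term = paste0("alpha_A[", sn, "]"),
      block = "alpha_A", estimate = p$alpha_A
    ),
    tibble(
      term = c("b_Y", "sigma_I", "sigma_J"), block = "scalar",
      estimate = c(p$b_Y, exp(p$log_sigma_I), exp(p$log_sigma_J))
    )
  )
}

#' @rdname tidy.tavr_fit
#' @export
glance.tavr_fit <- function(x, ...) {
  tibble(
    n_train = x$n_train %||% NA_integer_,
    d_A = x$params$d_A, d_f = x$params$d_f, d_J = x$params$d_J,
    best_epoch = x$best_epoch,
    val_objective = x$best_val %||% NA_real_,
    use_aux = x$use_aux
  )
}

#' Tidy cross-validation results
#'
#' @param x A `tavr_cv`.
#' @param ... Unused.
#' @return Per-fold tibble (`tidy`) or one-row summary (`glance`).
#' @export
tidy.tavr_cv <- function(x, ...) x$folds

#' @rdname tidy.tavr_cv
#' @export
glance.tavr_cv <- function(x, ...) {
  tibble(k = x$k, mean_auroc = x$mean_auroc, sem = x$sem, seed = x$seed)
}

#' Plot the cross-validated AUROC per fold
#'
#' @param object A `tavr_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tavr_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = factor(.data$fold), y = .data$auroc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_auroc, linetype = 2) +
    ggplot2::labs(
      x = "fold", y = "AUROC",
      title = sprintf("AUROC %.3f ± %.3f (SEM)", object$mean_auroc, object$sem)
    ) +
    ggplot2::coord_cartesian(ylim = c(0.4, 1))
}

#' Plot training and validation objective traces
#'
#' @param object A `tavr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tavr_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("train", "val"),
    names_to = "set", values_to = "objective"
  )
  ggplot2::ggplot(tr, ggplot2::aes(.data$epoch, .data$objective, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(y = "negative mean log-likelihood")
}

#' Plot predictor importance
#'
#' @param object A [predictor_importance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tavr_importance <- function(object, ...) {
  d <- dplyr::mutate(object, group = factor(.data$group, rev(.data$group)))
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_drop, .data$group)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data$mean_drop - .data$sem,
        xmax = .data$mean_drop + .data$sem
      ),
      height = 0.3
    ) +
    ggplot2::labs(x = "AUROC drop when withheld", y = NULL)
}
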