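#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model
#'
#' One row per free parameter with its block, estimate and standard error;
#' item rows additionally carry the implied guessing/slip probabilities.
#'
#' @param x an `lgcdm_fit`.
#' @param ... unused.
#' @return a tibble with columns `term`, `block`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (Wald z against 0) and, for item parameters,
#'   `g` and `s`.
#' @method tidy lgcdm_fit
#' @export
tidy.lgcdm_fit <- function(x, ...) {
  est <- setNames(x$par, x$info$names)
  out <- tibble(term = names(est), block = param_block(names(est)),
                estimate = unname(est), std.error = unname(x$se))
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  gs <- guess_slip(x$estimates$f, x$estimates$d)
  out$g <- NA_real_; out$s <- NA_real_
  out$g[x$info$idx_f] <- gs$g
  out$s[x$info$idx_f] <- gs$s
  out
}

#' One-row model summary
#'
#' @param x an `lgcdm_fit`.
#' @param ... unused.
#' @return a one-row tibble: family, logLik, AIC, BIC, parameter and person
#'   counts, convergence flag, starts used.
#' @method glance lgcdm_fit
#' @export
glance.lgcdm_fit <- function(x, ...) {
  tibble(family = x$spec$family, logLik = x$loglik,
         AIC = x$aic, BIC = x$bic,
         n_params = x$n_params, n_persons = x$n_persons,
         converged = x$converged, n_starts = x$n_starts_used)
}

#' Tidy a recovery study
#'
#' @param x an `lgcdm_recovery`.
#' @param level `"blocks"` (default) or `"parameters"`.
#' @param ... unused.
#' @return the requested summary tibble.
#' @method tidy lgcdm_recovery
#' @export
tidy.lgcdm_recovery <- function(x, level = c("blocks", "parameters"), ...) {
  level <- match.arg(level)
  if (level == "blocks") x$blocks else x$parameters
}

#' @method glance lgcdm_recovery
#' @export
glance.lgcdm_recovery <- function(x, ...) {
  tibble(design = x$design, n_persons = x$n_persons, family = x$family,
         n_reps = x$n_reps, n_converged = x$n_converged)
}

#' Plot item parameter estimates
#'
#' Dot-and-interval plot of the RDINA item parameters (f and d, with
#' approximate 95% Wald intervals when standard errors are available).
#'
#' @param object an `lgcdm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lgcdm_fit
#' @export
autoplot.lgcdm_fit <- function(object, ...) {
  td <- tidy.lgcdm_fit(object) |>
    dplyr::filter(.data$block %in% c("item_f", "item_d")) |>
    dplyr::mutate(item = sub("^[fd]_", "", .data$term),
                  parameter = ifelse(.data$block == "item_f", "f (false alarm)",
                                     "d (discrimination)"))
  td$item <- factor(td$item, levels = unique(td$item))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$item, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "logit estimate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot recovery %Bias by block
#'
#' @param object an `lgcdm_recovery`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lgcdm_recovery
#' @export
autoplot.lgcdm_recovery <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(x = .data$block, y = .data$pct_bias)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% Bias",
                  title = paste0(object$design, " (n = ", object$n_persons, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot estimated mastery growth curves
#'
#' The model-implied marginal mastery probability of each attribute at each
#' occasion (per covariate group for conditional models).
#'
#' @param fit an `lgcdm_fit`.
#' @return a ggplot.
#' @export
plot_growth <- function(fit) {
  stopifnot(inherits(fit, "lgcdm_fit"))
  env <- make_env(fit$spec, fit$data)
  pbar <- drop(fit$attr_prob %*% env$wn)
  cl <- env$cells
  attrs <- colnames(fit$spec$qmatrix)
  df <- tibble(attribute = factor(attrs[cl$k], levels = attrs),
               time = env$cell_t, z = factor(env$cell_z),
               prevalence = pbar)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$prevalence,
                                   colour = .data$attribute,
                                   linetype = .data$z)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "occasion (time code)", y = "P(mastery)",
                  linetype = "covariate z") +
    ggplot2::theme_minimal()
}
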