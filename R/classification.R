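#' Posterior attribute mastery probabilities
#'
#' For each person and occasion, the posterior probability of mastering
#' each attribute given the person's complete response record (all items,
#' all occasions), obtained by summing pattern-and-node posteriors.
#'
#' @param fit an `lgcdm_fit`.
#' @return a tibble with columns `person_id`, `time`, `attribute`,
#'   `posterior`.
#' @export
posterior_attribute_probs <- function(fit) {
  stopifnot(inherits(fit, "lgcdm_fit"))
  A <- fit$posterior  # n x T x K
  d <- dim(A)
  attrs <- colnames(fit$spec$qmatrix)
  tidyr::expand_grid(
    attribute = factor(attrs, levels = attrs),
    time = fit$data$occasions,
    person_id = fit$data$person_ids
  ) |>
    dplyr::mutate(posterior = as.vector(A)) |>
    dplyr::arrange(.data$person_id, .data$time, .data$attribute) |>
    dplyr::select("person_id", "time", "attribute", "posterior")
}

#' Modal (MAP) attribute classification
#'
#' Classifies each person-occasion as master iff the posterior exceeds 0.5;
#' exact ties are classified as non-mastery (deterministic rule) and their
#' count is reported via a message.
#'
#' @inheritParams posterior_attribute_probs
#' @return tibble like [posterior_attribute_probs()] with a 0/1 `map`
#'   column.
#' @export
map_patterns <- function(fit) {
  out <- posterior_attribute_probs(fit) |>
    dplyr::mutate(map = as.integer(.data$posterior > 0.5))
  nties <- sum(out$posterior == 0.5)
  if (nties > 0) {
    inform(paste0(nties, " posterior(s) exactly 0.5 classified as non-mastery."))
  }
  out
}

#' Unique response-pattern table
#'
#' Collapses the data to unique (response record, covariate) patterns with
#' their frequencies `n_s` and, per attribute, the pattern's maximum
#' posterior `max(p, 1 - p)` at each occasion. The proportion correctly
#' classified is the `n_s`-weighted mean of that maximum.
#'
#' @inheritParams posterior_attribute_probs
#' @return a tibble with `pattern` (string key), `time`, `attribute`, `n`
#'   and `max_posterior`.
#' @export
pattern_table <- function(fit) {
  y <- fit$data$y
  d <- dim(y)
  key <- apply(matrix(y, d[1], d[2] * d[3]), 1, paste, collapse = "")
  key <- paste0(key, "|z=", fit$data$z)
  posterior_attribute_probs(fit) |>
    dplyr::mutate(pattern = key[match(.data$person_id, fit$data$person_ids)],
                  max_posterior = pmax(.data$posterior, 1 - .data$posterior)) |>
    dplyr::summarise(n = dplyr::n(),
                     max_posterior = .data$max_posterior[1],
                     .by = c("pattern", "time", "attribute"))
}

#' Proportion correctly classified
#'
#' The expected proportion of cases whose modal attribute classification is
#' correct: the frequency-weighted mean over unique response patterns of
#' the maximum posterior `max(p, 1 - p)`.
#'
#' @param pt a pattern table from [pattern_table()] (or any tibble with
#'   columns `attribute`, `n`, `max_posterior`).
#' @return tibble with one `pc` per attribute.
#' @export
proportion_correct <- function(pt) {
  if (nrow(pt) == 0 || sum(pt$n) == 0) abort("empty pattern table.")
  pt |>
    dplyr::summarise(pc = sum(.data$n * .data$max_posterior) / sum(.data$n),
                     .by = "attribute")
}

#' Chance-corrected classification quality (lambda)
#'
#' `lambda = (Pc - m) / (1 - m)` with `m = max(p, 1 - p)` the larger
#' marginal class share of the attribute: the relative reduction in
#' classification error over assigning everyone to the larger class.
#'
#' @param pc proportion correctly classified.
#' @param prevalence marginal mastery probability `p(alpha_k = 1)` in (0,1).
#' @return lambda (vectorized); `NA` with a warning when `m = 1`.
#' @examples
#' lambda_stat(0.91, 0.57) # ~0.79
#' @export
lambda_stat <- function(pc, prevalence) {
  stopifnot(all(prevalence > 0 & prevalence < 1, na.rm = TRUE))
  m <- pmax(prevalence, 1 - prevalence)
  out <- (pc - m) / (1 - m)
  if (any(m >= 1 - 1e-12)) {
    warn("degenerate prevalence (m = 1); lambda undefined.")
    out[m >= 1 - 1e-12] <- NA_real_
  }
  out
}

#' Model-implied attribute prevalence
#'
#' The marginal mastery probability of each attribute implied by the fitted
#' model, integrating the random effects by quadrature and averaging over
#' occasions and the empirical covariate distribution (the latent class
#' sizes).
#'
#' @inheritParams posterior_attribute_probs
#' @return tibble with one `prevalence` per attribute.
#' @export
attribute_prevalence <- function(fit) {
  stopifnot(inherits(fit, "lgcdm_fit"))
  env <- make_env(fit$spec, fit$data)
  # node-marginal attribute probability per structural cell
  pbar <- drop(fit$attr_prob %*% env$wn)  # ncell
  cl <- env$cells
  wz <- as.numeric(table(env$zi)[as.character(seq_len(env$Z))]) / env$n
  w <- wz[cl$z] / env$T
  attrs <- colnames(fit$spec$qmatrix)
  tibble(attribute = factor(attrs, levels = attrs),
         prevalence = as.numeric(tapply(pbar * w, cl$k, sum)))
}

#' Classification quality report
#'
#' Per-attribute proportion correctly classified, lambda, and model-implied
#' prevalence, with cases pooled over occasions (each person-occasion is a
#' case).
#'
#' @inheritParams posterior_attribute_probs
#' @return a tibble with columns `attribute`, `pc`, `lambda`, `prevalence`.
#' @export
classification_report <- function(fit) {
  pc <- posterior_attribute_probs(fit) |>
    dplyr::summarise(pc = mean(pmax(.data$posterior, 1 - .data$posterior)),
                     .by = "attribute")
  prev <- attribute_prevalence(fit)
  dplyr::left_join(pc, prev, by = "attribute") |>
    dplyr::mutate(lambda = lambda_stat(.data$pc, .data$prevalence)) |>
    dplyr::select("attribute", "pc", "lambda", "prevalence")
}
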