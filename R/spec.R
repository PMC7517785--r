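#' Model specification
#'
#' Describes which model to fit and how. Four families are supported:
#'
#' * `rdina` — RDINA latent class model; occasions (if several) are pooled
#'   as independent cases with occasion-invariant attribute prevalences.
#' * `rdina_cov` — RDINA with an attribute-level covariate effect
#'   (`logit p(alpha_k) = b_k + h_k z`), still without growth terms.
#' * `lg_uncond` — attribute mastery logits follow a latent growth curve
#'   with person-level random intercept and slope; needs >= 2 occasions.
#' * `lg_cond` — the growth model with covariate effects on the attribute
#'   level and on the growth factors.
#'
#' `constraints` controls identification of the growth intercept: with
#' `b = "free"` (default) the random-intercept mean `mu0` is held at
#' `constraints$mu0` (default 0) because it is collinear with the
#' difficulties; with `b = "sum_zero"` the difficulties are effect-coded
#' (sum to zero) and `mu0` is estimated. The intercept-level covariate
#' effect `h0` is always held fixed (default 0) for the same reason.
#'
#' @param family model family, one of `"rdina"`, `"rdina_cov"`,
#'   `"lg_uncond"`, `"lg_cond"`.
#' @param qmatrix a [qmatrix()].
#' @param time_codes numeric occasion codes, strictly increasing, first 0
#'   (e.g. `c(0, 1)` for a pre/post design).
#' @param estimation `"pm"` (posterior mode; default) or `"ml"`.
#' @param quad Gauss-Hermite nodes per random-effect dimension.
#' @param eps_quad nodes for the time-specific error integral.
#' @param sigma0,sigma1 fixed scales of the random intercept and slope.
#' @param eps_sd fixed SD of the time-specific error; 0 disables it (the
#'   generator and the fitter always share this setting).
#' @param constraints list with elements `b` (`"free"` or `"sum_zero"`),
#'   `mu0` (fixed value when `b = "free"`), `h0` (always fixed).
#' @param prior_sd SD of the normal smoothing prior used by `"pm"`.
#' @return an object of class `lgcdm_spec`.
#' @export
lgcdm_spec <- function(family = c("lg_uncond", "lg_cond", "rdina", "rdina_cov"),
                       qmatrix, time_codes = c(0, 1),
                       estimation = c("pm", "ml"),
                       quad = 9, eps_quad = 9,
                       sigma0 = 1, sigma1 = 1, eps_sd = 1,
                       constraints = list(), prior_sd = 3) {
  family <- match.arg(family)
  estimation <- match.arg(estimation)
  if (!inherits(qmatrix, "qmatrix")) qmatrix <- qmatrix(qmatrix)
  time_codes <- as.numeric(time_codes)
  if (length(time_codes) >= 1) {
    if (is.unsorted(time_codes, strictly = TRUE)) {
      abort("`time_codes` must be strictly increasing.")
    }
    if (time_codes[1] != 0) {
      abort("the first occasion must be coded 0 (pretest baseline).")
    }
  }
  if (family %in% c("lg_uncond", "lg_cond") && length(time_codes) < 2) {
    abort("growth models need at least 2 measurement occasions.")
  }
  cons <- modifyList(list(b = "free", mu0 = 0, h0 = 0), constraints)
  bad <- setdiff(names(constraints), c("b", "mu0", "h0"))
  if (length(bad)) abort(paste0("unknown constraint: ", bad[1]))
  if (!cons$b %in% c("free", "sum_zero")) {
    abort('`constraints$b` must be "free" or "sum_zero".')
  }
  structure(list(family = family, qmatrix = qmatrix,
                 time_codes = time_codes,
                 estimation = estimation, quad = quad, eps_quad = eps_quad,
                 sigma0 = sigma0, sigma1 = sigma1, eps_sd = eps_sd,
                 constraints = cons, prior_sd = prior_sd),
            class = "lgcdm_spec")
}

#' @export
print.lgcdm_spec <- function(x, ...) {
  cat("<lgcdm_spec> family =", x$family,
      "| J =", nrow(x$qmatrix), "items, K =", ncol(x$qmatrix),
      "attributes, T =", length(x$time_codes), "occasions\n")
  cat("  estimation:", x$estimation,
      "| quadrature:", x$quad, "per random dim,", x$eps_quad, "for eps",
      "| eps_sd:", x$eps_sd, "\n")
  cat("  constraints: b", x$constraints$b,
      if (x$constraints$b == "free") paste0("(mu0 fixed at ", x$constraints$mu0, ")")
      else "(mu0 free)",
      "| h0 fixed at", x$constraints$h0, "\n")
  invisible(x)
}

#' Longitudinal response container
#'
#' Holds a persons x occasions x items 0/1 response array together with an
#' optional person-level covariate. Most users create one via
#' [read_responses()], [as_lgcdm_data()] or [simulate_lgcdm()].
#'
#' @param y 3-d array `[person, occasion, item]` of 0/1 responses (NA for
#'   missing).
#' @param z person-level covariate vector (defaults to all 0).
#' @param person_ids,occasions,item_ids labels; occasions are the numeric
#'   time codes.
#' @return an object of class `lgcdm_data`.
#' @export
lgcdm_data <- function(y, z = NULL, person_ids = NULL, occasions = NULL,
                       item_ids = NULL) {
  stopifnot(is.array(y), length(dim(y)) == 3)
  vals <- y[!is.na(y)]
  if (!all(vals %in% c(0, 1))) abort("responses must be 0, 1 or NA.")
  n <- dim(y)[1]; Tn <- dim(y)[2]; J <- dim(y)[3]
  z <- z %||% rep(0, n)
  stopifnot(length(z) == n)
  structure(list(y = y, z = as.numeric(z),
                 person_ids = person_ids %||% dimnames(y)[[1]] %||% seq_len(n),
                 occasions = as.numeric(occasions %||% (seq_len(Tn) - 1)),
                 item_ids = item_ids %||% dimnames(y)[[3]] %||% paste0("Y", seq_len(J))),
            class = "lgcdm_data")
}

#' @export
print.lgcdm_data <- function(x, ...) {
  d <- dim(x$y)
  cat("<lgcdm_data> ", d[1], " persons x ", d[2], " occasions x ", d[3],
      " items (", sum(is.na(x$y)), " missing)\n", sep = "")
  if (any(x$z != 0)) {
    cat("  covariate z:", paste(names(table(x$z)), "=", table(x$z), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.lgcdm_data <- function(x) dim(x$y)

#' Tidy a response container into long format
#'
#' @param x an `lgcdm_data` object.
#' @param ... unused.
#' @return a tibble with columns `person_id`, `time`, `item_id`, `response`,
#'   `z`.
#' @method as_tibble lgcdm_data
#' @export
as_tibble.lgcdm_data <- function(x, ...) {
  d <- dim(x$y)
  tidyr::expand_grid(
    item_id = factor(x$item_ids, levels = x$item_ids),
    time = x$occasions,
    person_id = x$person_ids
  ) |>
    dplyr::mutate(response = as.vector(x$y),
                  z = rep(x$z, times = d[2] * d[3])) |>
    dplyr::arrange(.data$person_id, .data$time, .data$item_id) |>
    dplyr::select("person_id", "time", "item_id", "response", "z")
}
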