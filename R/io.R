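#' Read longitudinal item responses from CSV
#'
#' Two layouts are supported. `"long"` expects columns `person_id`, `time`,
#' `item_id`, `response` (and optionally `z`); `"wide"` expects one row per
#' person-occasion with columns `person_id`, `time`, one column per item,
#' and optionally `z`. Persons and items are ordered lexicographically by
#' id so that downstream pattern collapsing is deterministic; missing cells
#' are preserved as `NA`.
#'
#' @param path CSV path (comma separator, `.` decimal, `NA` missing).
#' @param layout `"long"` or `"wide"`.
#' @param covariates optional CSV path with columns `person_id`, `z`
#'   (overrides any `z` column in the response file).
#' @param item_ids optional item ordering (defaults to lexicographic).
#' @return an [lgcdm_data()].
#' @export
read_responses <- function(path, layout = c("long", "wide"),
                           covariates = NULL, item_ids = NULL) {
  layout <- match.arg(layout)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (layout == "wide") {
    need <- c("person_id", "time")
    if (!all(need %in% names(df))) {
      abort("wide layout needs columns `person_id` and `time`.")
    }
    df <- tidyr::pivot_longer(df,
                              cols = -dplyr::any_of(c("person_id", "time", "z")),
                              names_to = "item_id", values_to = "response")
  }
  need <- c("person_id", "time", "item_id", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  bad <- which(!(is.na(df$response) | df$response %in% c(0, 1)))
  if (length(bad)) {
    abort(paste0("non-binary response value '", df$response[bad[1]],
                 "' in row ", bad[1], "."))
  }
  dup <- duplicated(df[c("person_id", "time", "item_id")])
  if (any(dup)) {
    abort(paste0("duplicate (person, time, item) record in row ", which(dup)[1], "."))
  }
  persons <- sort(unique(as.character(df$person_id)))
  items <- item_ids %||% sort(unique(as.character(df$item_id)))
  times <- sort(unique(df$time))
  n <- length(persons); Tn <- length(times); J <- length(items)
  y <- array(NA_real_, c(n, Tn, J))
  y[cbind(match(as.character(df$person_id), persons),
          match(df$time, times),
          match(as.character(df$item_id), items))] <- df$response
  z <- rep(0, n)
  if (!is.null(covariates)) {
    cv <- readr::read_csv(covariates, show_col_types = FALSE)
    z <- cv$z[match(persons, as.character(cv$person_id))]
    if (anyNA(z)) abort("covariate file does not cover every person.")
  } else if ("z" %in% names(df)) {
    zz <- df |> dplyr::distinct(.data$person_id, .data$z)
    if (anyNA(zz$z) || nrow(zz) != n) {
      abort("column `z` must be constant within person and non-missing.")
    }
    z <- zz$z[match(persons, as.character(zz$person_id))]
  }
  lgcdm_data(y, z = z, person_ids = persons, occasions = times, item_ids = items)
}

#' Write responses to CSV (long layout)
#'
#' @param data an [lgcdm_data()].
#' @param path output CSV path.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' Convert a long tibble to a response container
#'
#' @param df tibble with columns `person_id`, `time`, `item_id`,
#'   `response`, optionally `z`.
#' @param item_ids optional item ordering.
#' @return an [lgcdm_data()].
#' @export
as_lgcdm_data <- function(df, item_ids = NULL) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  readr::write_csv(df, tf)
  read_responses(tf, "long", item_ids = item_ids)
}

fit_payload <- function(fit) {
  if (inherits(fit, "lgcdm_fit_record")) return(unclass(fit))
  stopifnot(inherits(fit, "lgcdm_fit"))
  sp <- fit$spec
  list(
    package = "lgcdm", version = fit$version,
    config = list(family = sp$family, estimation = sp$estimation,
                  time_codes = sp$time_codes, quad = sp$quad,
                  eps_quad = sp$eps_quad, sigma0 = sp$sigma0,
                  sigma1 = sp$sigma1, eps_sd = sp$eps_sd,
                  constraints = sp$constraints, prior_sd = sp$prior_sd,
                  qmatrix = unclass(unname(sp$qmatrix[, , drop = FALSE])),
                  item_ids = rownames(sp$qmatrix),
                  attribute_ids = colnames(sp$qmatrix),
                  n_starts = fit$n_starts_used),
    par = as.list(setNames(fit$par, fit$info$names)),
    se = as.list(setNames(fit$se, fit$info$names)),
    loglik = fit$loglik, objective = fit$objective,
    n_params = fit$n_params, n_persons = fit$n_persons,
    aic = fit$aic, bic = fit$bic,
    converged = fit$converged, best_start = fit$best_start)
}

#' Serialize / restore a fitted model
#'
#' `write_fit()` stores every numeric field of the fit (estimates, standard
#' errors, log-likelihood, information criteria, configuration echo and
#' package version) as JSON at full precision, so
#' write -> read -> write reproduces the file byte for byte. The per-person
#' posterior cache is not serialized; recompute it by refitting or via
#' [posterior_attribute_probs()] on the original fit.
#'
#' @param fit an `lgcdm_fit` (or a record from [read_fit()]).
#' @param path JSON path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(fit_payload(fit), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @return `read_fit()` returns the stored record (class
#'   `lgcdm_fit_record`); a version mismatch with the installed package
#'   produces a warning, not an error.
#' @export
read_fit <- function(path) {
  rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(paste0("cannot parse fit file '", path, "': ",
                                 conditionMessage(e)))
                  })
  if (!is.list(rec) || is.null(rec$package) || rec$package != "lgcdm") {
    abort(paste0("'", path, "' is not an lgcdm fit file."))
  }
  cur <- as.character(utils::packageVersion("lgcdm"))
  if (!identical(rec$version, cur)) {
    warn(paste0("fit file written by lgcdm ", rec$version,
                ", reading with ", cur, "."))
  }
  structure(rec, class = "lgcdm_fit_record")
}
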