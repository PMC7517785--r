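# Monte-Carlo parameter-recovery and model cross-fitting machinery.
#
# Bias(x)   = mean_r (est_r - truth)
# %Bias(x)  = |Bias(x) / truth| * 100      (undefined when |truth| < 1e-8)
# MSE(x)    = mean_r (est_r - truth)^2
# Block summaries average the per-parameter statistics within a block
# (unweighted), so tiny true values visibly inflate a block's %Bias.

truth_vector <- function(design, spec, info) {
  g <- design$growth
  up <- list(f = design$items$f, d = design$items$d, growth = g)
  items <- rownames(spec$qmatrix)
  tr <- c(setNames(up$f, paste0("f_", items)),
          setNames(up$d, paste0("d_", items)))
  K <- length(g$b)
  fam <- spec$family
  tr <- c(tr, setNames(g$b, paste0("b_", seq_len(K))))
  if (fam %in% c("lg_uncond", "lg_cond")) {
    if (info$sum_zero) tr <- c(tr, mu0 = g$mu0)
    tr <- c(tr, mu1 = g$mu1)
  }
  if (fam %in% c("rdina_cov", "lg_cond")) {
    tr <- c(tr, setNames(g$h, paste0("h_", seq_len(K))))
  }
  if (fam == "lg_cond") tr <- c(tr, h1 = g$h1)
  tr
}

estimate_vector <- function(fit) {
  up <- fit$estimates
  items <- rownames(fit$spec$qmatrix)
  K <- length(up$growth$b)
  fam <- fit$spec$family
  est <- c(setNames(up$f, paste0("f_", items)),
           setNames(up$d, paste0("d_", items)),
           setNames(up$growth$b, paste0("b_", seq_len(K))))
  if (fam %in% c("lg_uncond", "lg_cond")) {
    if (fit$info$sum_zero) est <- c(est, mu0 = up$growth$mu0)
    est <- c(est, mu1 = up$growth$mu1)
  }
  if (fam %in% c("rdina_cov", "lg_cond")) {
    est <- c(est, setNames(up$growth$h, paste0("h_", seq_len(K))))
  }
  if (fam == "lg_cond") est <- c(est, h1 = up$growth$h1)
  est
}

param_block <- function(nm) {
  dplyr::case_when(
    startsWith(nm, "f_") ~ "item_f",
    startsWith(nm, "d_") ~ "item_d",
    startsWith(nm, "b_") ~ "attribute_difficulty",
    nm %in% c("mu0", "mu1") ~ "random_effect_mean",
    startsWith(nm, "h_") ~ "intervention_effect",
    nm == "h1" ~ "intervention_slope",
    TRUE ~ "other")
}

summarise_recovery <- function(est_mat, truth) {
  nm <- names(truth)
  bias <- colMeans(est_mat) - truth
  pct <- ifelse(abs(truth) < 1e-8, NA_real_, abs(bias / truth) * 100)
  if (anyNA(pct)) {
    inform(paste0("excluded from %Bias (true value ~ 0): ",
                  paste(nm[is.na(pct)], collapse = ", ")))
  }
  mse <- colMeans(sweep(est_mat, 2, truth)^2)
  pars <- tibble(parameter = nm, block = param_block(nm), truth = unname(truth),
                 mean_est = unname(colMeans(est_mat)), bias = unname(bias),
                 pct_bias = unname(pct), mse = unname(mse))
  blocks <- pars |>
    dplyr::summarise(bias = mean(.data$bias),
                     pct_bias = mean(.data$pct_bias, na.rm = TRUE),
                     mse = mean(.data$mse), n_params = dplyr::n(),
                     .by = "block")
  list(parameters = pars, blocks = blocks)
}

#' Parameter-recovery study
#'
#' Simulates `n_reps` data sets from a design, refits the (by default)
#' generating family to each, and summarizes Bias, %Bias and MSE per
#' parameter and per parameter block. Replication seeds are spawned
#' deterministically from `seed`; non-converged replications are excluded
#' and counted.
#'
#' @param design a [sim_design()].
#' @param n_reps number of replications (>= 2).
#' @param seed study seed.
#' @param fit_spec specification used for fitting; defaults to the design's
#'   generating specification with effect-coded attribute difficulties
#'   (`b = "sum_zero"`, random-intercept mean estimated), the convention
#'   under which the growth intercept is identified.
#' @param control an [lgcdm_control()]; the default uses a single
#'   deterministic start and no standard errors for speed.
#' @return an object of class `lgcdm_recovery`: list with `parameters` and
#'   `blocks` tibbles, convergence counts and metadata.
#' @export
recovery_study <- function(design, n_reps, seed,
                           fit_spec = NULL,
                           control = lgcdm_control(n_starts = 1, se = FALSE)) {
  stopifnot(inherits(design, "sim_design"), n_reps >= 2)
  spec <- fit_spec %||% {
    sp <- design$spec
    if (sp$family %in% c("lg_uncond", "lg_cond")) sp$constraints$b <- "sum_zero"
    sp
  }
  info <- par_info(spec)
  truth <- truth_vector(design, spec, info)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  seeds <- sample.int(2147483646, n_reps)
  ests <- vector("list", n_reps)
  ok <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    dat <- simulate_lgcdm(design, seeds[r])
    fit <- tryCatch(suppressWarnings(fit_lgcdm(dat, spec, control)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      ests[[r]] <- estimate_vector(fit)
      ok[r] <- TRUE
    }
  }
  if (mean(ok) < 0.5) {
    abort(paste0("recovery study failed: only ", sum(ok), "/", n_reps,
                 " replications converged."))
  }
  est_mat <- do.call(rbind, ests[ok])
  stopifnot(identical(colnames(est_mat), names(truth)))
  sm <- summarise_recovery(est_mat, truth)
  structure(list(parameters = sm$parameters, blocks = sm$blocks,
                 n_reps = n_reps, n_converged = sum(ok),
                 design = design$name, n_persons = design$n_persons,
                 family = spec$family, seed = seed, rep_seeds = seeds,
                 estimates = est_mat),
            class = "lgcdm_recovery")
}

#' @export
print.lgcdm_recovery <- function(x, ...) {
  cat("<lgcdm_recovery>", x$design, "n =", x$n_persons,
      "|", x$n_converged, "/", x$n_reps, "replications converged\n")
  print(x$blocks)
  invisible(x)
}

#' Block %Bias from a recovery study
#'
#' @param x an `lgcdm_recovery`.
#' @param block block name (e.g. `"intervention_effect"`).
#' @return the block's %Bias (scalar).
#' @export
block_pct_bias <- function(x, block) {
  stopifnot(inherits(x, "lgcdm_recovery"))
  i <- match(block, x$blocks$block)
  if (is.na(i)) abort(paste0("no block named '", block, "'."))
  x$blocks$pct_bias[i]
}

candidate_spec <- function(family, design) {
  sp <- design$spec
  out <- lgcdm_spec(family, sp$qmatrix, time_codes = sp$time_codes,
                    estimation = sp$estimation, quad = sp$quad,
                    eps_quad = sp$eps_quad, sigma0 = sp$sigma0,
                    sigma1 = sp$sigma1, eps_sd = sp$eps_sd)
  if (family %in% c("lg_uncond", "lg_cond")) out$constraints$b <- "sum_zero"
  out
}

#' Cross-fitting study
#'
#' Fits several candidate model families (including deliberately
#' misspecified ones without the growth component) to data generated from
#' one design, and compares information criteria, classification quality
#' and parameter %Bias against the generating truths. Reproduces the
#' consequence of ignoring the longitudinal structure.
#'
#' @param design the generating [sim_design()].
#' @param families candidate families; must include the generating family.
#' @param n_reps replications.
#' @param seed study seed.
#' @param control fitting control (defaults as in [recovery_study()]).
#' @return an object of class `lgcdm_crossfit`: a `table` tibble with one
#'   row per family (mean AIC/BIC, mean Pc, block %Bias columns), the
#'   BIC-selected `winner`, and per-replication details.
#' @export
cross_fit_study <- function(design, families, n_reps, seed,
                            control = lgcdm_control(n_starts = 1, se = FALSE)) {
  stopifnot(inherits(design, "sim_design"), n_reps >= 1)
  if (!design$spec$family %in% families) {
    abort("`families` must include the generating family.")
  }
  specs <- lapply(setNames(families, families), candidate_spec, design = design)
  infos <- lapply(specs, par_info)
  truths <- lapply(families, function(fm) truth_vector(design, specs[[fm]], infos[[fm]]))
  names(truths) <- families
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  seeds <- sample.int(2147483646, n_reps)
  percell <- list()
  ests <- lapply(setNames(families, families), function(fm) list())
  for (r in seq_len(n_reps)) {
    dat <- simulate_lgcdm(design, seeds[r])
    for (fm in families) {
      fit <- tryCatch(suppressWarnings(fit_lgcdm(dat, specs[[fm]], control)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        percell[[length(percell) + 1]] <-
          tibble(rep = r, family = fm, converged = FALSE,
                 aic = NA_real_, bic = NA_real_, pc = NA_real_)
        next
      }
      pc <- mean(classification_report(fit)$pc)
      percell[[length(percell) + 1]] <-
        tibble(rep = r, family = fm, converged = fit$converged,
               aic = fit$aic, bic = fit$bic, pc = pc)
      if (fit$converged) {
        ests[[fm]][[length(ests[[fm]]) + 1]] <- estimate_vector(fit)
      }
    }
  }
  per_rep <- dplyr::bind_rows(percell)
  rows <- lapply(families, function(fm) {
    em <- do.call(rbind, ests[[fm]])
    d <- per_rep |> dplyr::filter(.data$family == fm, .data$converged)
    if (is.null(em) || nrow(d) == 0) {
      return(tibble(family = fm, n_converged = 0L))
    }
    sm <- summarise_recovery(em, truths[[fm]])
    bl <- function(b) {
      i <- match(b, sm$blocks$block)
      if (is.na(i)) NA_real_ else sm$blocks$pct_bias[i]
    }
    tibble(family = fm, n_converged = nrow(d),
           aic = mean(d$aic), bic = mean(d$bic), pc = mean(d$pc),
           pct_bias_item = mean(c(bl("item_f"), bl("item_d"))),
           pct_bias_attribute = bl("attribute_difficulty"),
           pct_bias_intervention = bl("intervention_effect"),
           pct_bias_random = bl("random_effect_mean"))
  })
  table <- dplyr::bind_rows(rows)
  winner <- table$family[which.min(table$bic)]
  structure(list(table = table, winner = winner, per_rep = per_rep,
                 design = design$name, n_persons = design$n_persons,
                 n_reps = n_reps, seed = seed),
            class = "lgcdm_crossfit")
}

#' @export
print.lgcdm_crossfit <- function(x, ...) {
  cat("<lgcdm_crossfit>", x$design, "n =", x$n_persons,
      "| BIC selects:", x$winner, "\n")
  print(x$table)
  invisible(x)
}
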