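#' Control parameters for model fitting
#'
#' @param max_em_iter maximum EM iterations before the quasi-Newton polish.
#' @param em_tol relative log-likelihood change that ends the EM phase.
#' @param nr_iter maximum iterations of the polish (`nlminb` with analytic
#'   gradient).
#' @param nr_tol gradient infinity-norm declaring convergence.
#' @param n_starts number of starting-value sets (start 1 is deterministic;
#'   the rest perturb it with seeded N(0, 0.5) noise).
#' @param seed seed for the start-value perturbations.
#' @param se compute standard errors from the observed information.
#' @param verbose log one line per start.
#' @export
lgcdm_control <- function(max_em_iter = 40, em_tol = 1e-6, nr_iter = 300,
                          nr_tol = 1e-3, n_starts = 5, seed = 1,
                          se = TRUE, verbose = FALSE) {
  list(max_em_iter = max_em_iter, em_tol = em_tol, nr_iter = nr_iter,
       nr_tol = nr_tol, n_starts = n_starts, seed = seed, se = se,
       verbose = verbose)
}

# log prior (posterior-mode smoothing): independent normals on every free
# logit-scale parameter
pm_penalty <- function(par, prior_sd) sum(dnorm(par, 0, prior_sd, log = TRUE))

#' Posterior-mode smoothing penalty
#'
#' The log prior added to the log-likelihood under posterior-mode
#' estimation: independent normal(0, `prior_sd`) densities on every free
#' logit-scale parameter, which keeps estimates off the boundary of the
#' parameter space.
#'
#' @param par free parameter vector.
#' @param prior_sd prior standard deviation (> 0).
#' @return the summed log prior density.
#' @export
posterior_mode_penalty <- function(par, prior_sd) {
  stopifnot(prior_sd > 0)
  pm_penalty(par, prior_sd)
}

#' Information criteria
#'
#' `AIC = -2 logLik + 2 p`, `BIC = -2 logLik + p log(n)` with `n` the
#' number of persons.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_persons number of persons.
#' @return named vector with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, n_params, n_persons) {
  stopifnot(n_persons >= 1)
  c(aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n_persons))
}

# one EM pass: E-step stats -> closed-form item update + Newton update of the
# structural block on the expected complete-data log-likelihood
em_update <- function(par, spec, env, info, ev) {
  up <- ev$up
  # --- items (exact argmax of the expected complete-data log-likelihood)
  if (env$factorized) {
    EB <- matrix(ev$Abar, env$n * env$T, env$K)[, env$att, drop = FALSE]
  } else {
    EB <- matrix(ev$Pbar, env$n * env$T, env$M) %*% env$eta
  }
  r1 <- colSums(EB * env$Y0) / pmax(colSums(EB * env$Obs), 1e-300)
  r0 <- colSums((1 - EB) * env$Y0) / pmax(colSums((1 - EB) * env$Obs), 1e-300)
  r1 <- pmin(pmax(r1, 1e-10), 1 - 1e-10)
  r0 <- pmin(pmax(r0, 1e-10), 1 - 1e-10)
  f_new <- qlogis(r0)
  d_new <- qlogis(r1) - qlogis(r0)
  # --- structural block: Newton with step halving on the Q-function
  sidx <- info$idx_s
  theta <- par[sidx]
  if (length(theta)) {
    Xd <- env$X
    esd <- if (spec$family %in% c("lg_uncond", "lg_cond")) spec$eps_sd else 0
    xq <- env$eps$nodes; wq <- env$eps$weights
    ncell <- nrow(env$cells); N <- env$N; Q <- length(xq)
    lin0 <- drop(Xd$X %*% theta) + Xd$off        # ncell
    linN <- lin0 + env$nodeadd                   # ncell x N
    # expected counts per (cell, node, eps-node)
    n1 <- array(0, c(ncell, N, Q)); n0 <- array(0, c(ncell, N, Q))
    for (qq in seq_len(Q)) {
      phi <- plogis(linN + esd * xq[qq])
      n1[, , qq] <- ev$S1 * wq[qq] * phi / ev$p
      n0[, , qq] <- ev$S0 * wq[qq] * (1 - phi) / (1 - ev$p)
    }
    cellrep <- rep(seq_len(ncell), times = N * Q)
    Xe <- Xd$X[cellrep, , drop = FALSE]
    offe <- Xd$off[cellrep] +
      as.numeric(env$nodeadd)[rep(seq_len(ncell * N), times = Q)] +
      esd * rep(xq, each = ncell * N)
    v1 <- as.numeric(n1); v0 <- as.numeric(n0); vt <- v1 + v0
    qfun <- function(th) {
      phi <- clip_prob(plogis(offe + drop(Xe %*% th)))
      sum(v1 * log(phi) + v0 * log1p(-phi))
    }
    q_old <- qfun(theta)
    for (it in 1:3) {
      phi <- clip_prob(plogis(offe + drop(Xe %*% theta)))
      gr <- drop(crossprod(Xe, v1 - vt * phi))
      H <- crossprod(Xe * (vt * phi * (1 - phi)), Xe)
      step <- tryCatch(solve(H, gr), error = function(e) gr / max(diag(H), 1))
      lam <- 1
      repeat {
        cand <- theta + lam * step
        if (qfun(cand) >= q_old - 1e-10) { theta <- cand; q_old <- qfun(cand); break }
        lam <- lam / 2
        if (lam < 1e-4) break
      }
    }
  }
  out <- par
  out[info$idx_f] <- f_new
  out[info$idx_d] <- d_new
  out[sidx] <- theta
  out
}

run_one_start <- function(par, spec, env, info, control) {
  pm <- spec$estimation == "pm"
  obj <- function(p) {
    ev <- eval_model(p, spec, env, info, want_stats = FALSE)
    -(ev$ll + if (pm) pm_penalty(p, spec$prior_sd) else 0)
  }
  gr <- function(p) {
    ev <- eval_model(p, spec, env, info, want_stats = TRUE)
    g <- model_grad(ev, spec, env, info)
    -(g + if (pm) -p / spec$prior_sd^2 else 0)
  }
  # EM phase (maximum likelihood; monotone by construction)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(control$max_em_iter)) {
    ev <- eval_model(par, spec, env, info, want_stats = TRUE)
    trace <- c(trace, ev$ll)
    if (is.finite(ll_old) &&
        abs(ev$ll - ll_old) < control$em_tol * (abs(ll_old) + 1)) break
    ll_old <- ev$ll
    par <- em_update(par, spec, env, info, ev)
  }
  # quasi-Newton polish on the exact (penalized) objective
  op <- nlminb(par, obj, gradient = gr,
               control = list(iter.max = control$nr_iter,
                              eval.max = 2 * control$nr_iter,
                              rel.tol = 1e-9))
  par <- op$par
  gmax <- max(abs(gr(par)))
  ev <- eval_model(par, spec, env, info, want_stats = FALSE)
  list(par = par, loglik = ev$ll,
       objective = ev$ll + if (pm) pm_penalty(par, spec$prior_sd) else 0,
       converged = (op$convergence == 0) || (gmax <= control$nr_tol),
       gmax = gmax, em_trace = trace, nr_message = op$message)
}

#' Fit a latent growth cognitive diagnostic model
#'
#' Fits the model family described by `spec` to longitudinal item responses
#' by marginal maximum likelihood or posterior mode, using an EM phase
#' (closed-form item updates, Newton updates of the growth block on the
#' expected complete-data log-likelihood) followed by a quasi-Newton polish
#' of the exact marginal objective with its analytic gradient. Random
#' effects are integrated by fixed Gauss-Hermite quadrature.
#'
#' @param data an [lgcdm_data()] object (see [read_responses()],
#'   [simulate_lgcdm()]).
#' @param spec an [lgcdm_spec()].
#' @param control an [lgcdm_control()] list.
#' @return an object of class `lgcdm_fit` with estimates, standard errors,
#'   log-likelihood, AIC/BIC, convergence information, and the per-person
#'   posterior attribute probabilities. Methods: [tidy()], [glance()],
#'   [autoplot.lgcdm_fit()], [classification_report()].
#' @examples
#' \donttest{
#' des <- builtin_design("sim1_uncond", n_persons = 200)
#' dat <- simulate_lgcdm(des, seed = 1)
#' sp <- des$spec
#' sp$constraints$b <- "sum_zero"
#' fit <- fit_lgcdm(dat, sp, lgcdm_control(n_starts = 1, se = FALSE))
#' glance(fit)
#' }
#' @export
fit_lgcdm <- function(data, spec, control = lgcdm_control()) {
  stopifnot(inherits(data, "lgcdm_data"), inherits(spec, "lgcdm_spec"))
  env <- make_env(spec, data)
  info <- par_info(spec)
  if (env$n < 2 * info$n_free) {
    warn(paste0("only ", env$n, " persons for ", info$n_free,
                " free parameters; estimates may be unstable."))
  }
  base <- default_start(spec, info)
  noise <- matrix(0, control$n_starts, info$n_free)
  if (control$n_starts > 1) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(control$seed)
    noise[-1, ] <- rnorm((control$n_starts - 1) * info$n_free, 0, 0.5)
  }
  runs <- vector("list", control$n_starts)
  for (s in seq_len(control$n_starts)) {
    runs[[s]] <- tryCatch(
      run_one_start(base + noise[s, ], spec, env, info, control),
      error = function(e) list(objective = -Inf, converged = FALSE, error = conditionMessage(e)))
    if (control$verbose) {
      inform(sprintf("start %d: objective %.4f converged %s", s,
                     runs[[s]]$objective %||% NA_real_,
                     isTRUE(runs[[s]]$converged)))
    }
  }
  objs <- vapply(runs, function(r) r$objective %||% -Inf, numeric(1))
  conv <- vapply(runs, function(r) isTRUE(r$converged), logical(1))
  if (!any(is.finite(objs))) {
    abort("all starting values failed; no fit available.")
  }
  best <- which.max(objs)  # ties broken by lowest start index
  run <- runs[[best]]
  if (!any(conv)) {
    warn("no start converged; returning the best partial result.")
  }
  par <- run$par
  up <- unpack_pars(par, spec, info)
  if (any(up$d < 0)) {
    warn(paste0("negative discrimination d_j at convergence for item(s) ",
                paste(rownames(spec$qmatrix)[up$d < 0], collapse = ", "),
                "; monotonicity in eta is violated there."))
  }
  ev <- eval_model(par, spec, env, info, want_stats = TRUE)
  ic <- information_criteria(run$loglik, info$n_free, env$n)
  se <- rep(NA_real_, info$n_free)
  if (control$se) se <- fit_se(par, spec, env, info)
  fit <- structure(list(
    spec = spec, data = data, par = par, se = setNames(se, info$names),
    estimates = up, info = info,
    loglik = run$loglik, objective = run$objective,
    n_params = info$n_free, n_persons = env$n,
    aic = unname(ic["aic"]), bic = unname(ic["bic"]),
    converged = run$converged, gmax = run$gmax,
    em_trace = run$em_trace,
    n_starts_used = control$n_starts, best_start = best,
    posterior = ev$Abar, attr_prob = ev$p, env_cells = env$cells,
    control = control, version = as.character(utils::packageVersion("lgcdm"))),
    class = "lgcdm_fit")
  fit
}

# observed information from central differences of the analytic gradient
fit_se <- function(par, spec, env, info, h = 1e-4) {
  pm <- spec$estimation == "pm"
  gfun <- function(p) {
    ev <- eval_model(p, spec, env, info, want_stats = TRUE)
    model_grad(ev, spec, env, info) + if (pm) -p / spec$prior_sd^2 else 0
  }
  n <- length(par)
  Hm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * (1 + abs(par[j]))
    pp <- par; pp[j] <- pp[j] + hj
    pm_ <- par; pm_[j] <- pm_[j] - hj
    Hm[, j] <- (gfun(pp) - gfun(pm_)) / (2 * hj)
  }
  Hm <- -(Hm + t(Hm)) / 2
  V <- tryCatch(solve(Hm), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    warn("observed information is singular or indefinite; standard errors reported as NA.")
    return(rep(NA_real_, n))
  }
  sqrt(diag(V))
}

#' @export
print.lgcdm_fit <- function(x, ...) {
  cat("<lgcdm_fit> family =", x$spec$family,
      "| logLik", format(x$loglik, nsmall = 2),
      "| AIC", format(round(x$aic, 2)),
      "| BIC", format(round(x$bic, 2)), "\n")
  cat("  ", x$n_params, " free parameters, ", x$n_persons, " persons, ",
      "converged: ", x$converged, " (best of ", x$n_starts_used, " starts)\n", sep = "")
  invisible(x)
}

#' @export
logLik.lgcdm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Local identification check
#'
#' Numerically differentiates the map from free parameters to response-
#' pattern probabilities and reports the rank of the Jacobian; the model is
#' locally identified at the given parameters iff the Jacobian has full
#' column rank. All `2^(J*T)` patterns are enumerated when `J*T <= 16`,
#' otherwise a random subsample of at least `4 * n_free` patterns is used
#' (per covariate group).
#'
#' @param spec an [lgcdm_spec()].
#' @param par free parameter vector (e.g. `fit$par`); defaults to the
#'   deterministic starting values.
#' @param z covariate values defining the groups (default `c(0, 1)` for
#'   covariate families, `0` otherwise).
#' @param tol singular values below `tol * max(sv)` count as zero.
#' @param seed seed for the pattern subsample.
#' @return list with `rank`, `n_free`, `full_rank`, `singular_values`.
#' @export
check_local_identification <- function(spec, par = NULL, z = NULL,
                                       tol = 1e-6, seed = 1) {
  info <- par_info(spec)
  par <- par %||% default_start(spec, info)
  J <- info$J
  Tn <- if (spec$family %in% c("lg_uncond", "lg_cond")) length(spec$time_codes) else 1
  z <- z %||% if (spec$family %in% c("rdina_cov", "lg_cond")) c(0, 1) else 0
  JT <- J * Tn
  if (JT <= 16) {
    pats <- as.matrix(expand.grid(rep(list(0:1), JT), KEEP.OUT.ATTRS = FALSE))
  } else {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    npat <- max(4 * info$n_free, 64)
    pats <- matrix(rbinom(npat * JT, 1, 0.5), npat, JT)
  }
  probs <- function(p) {
    up <- unpack_pars(p, spec, info)
    out <- numeric(0)
    for (zz in z) {
      y <- array(t(pats), c(J, Tn, nrow(pats)))  # item fastest -> rearrange
      y <- aperm(y, c(3, 2, 1))
      dat <- lgcdm_data(y, z = rep(zz, nrow(pats)))
      sp <- spec
      if (Tn == 1) sp$time_codes <- 0
      out <- c(out, exp(suppressWarnings(
        person_loglik(dat, sp, up$f, up$d, up$growth))))
    }
    out
  }
  h <- 1e-5
  Jm <- matrix(0, length(z) * nrow(pats), info$n_free)
  for (j in seq_len(info$n_free)) {
    pp <- par; pp[j] <- pp[j] + h
    pmn <- par; pmn[j] <- pmn[j] - h
    Jm[, j] <- (probs(pp) - probs(pmn)) / (2 * h)
  }
  sv <- svd(Jm, nu = 0, nv = 0)$d
  rank <- sum(sv > tol * max(sv))
  list(rank = rank, n_free = info$n_free, full_rank = rank == info$n_free,
       singular_values = sv)
}

# helpers to save/restore the RNG state around internally seeded draws
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}
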