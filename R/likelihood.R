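# Marginal likelihood machinery.
#
# A person's likelihood integrates, over Gauss-Hermite nodes for the random
# intercept/slope, the product across occasions of the pattern-mixture
# likelihood; the time-specific error is integrated analytically into each
# attribute probability by a 1-d quadrature. Two computational paths exist:
# a factorized one for single-attribute Q-matrices (the pattern sum
# factorizes over attributes) and a general 2^K-pattern path. Both call the
# compiled E-step; they agree to machine precision (tested).

make_env <- function(spec, data) {
  q <- spec$qmatrix
  J <- nrow(q); K <- ncol(q)
  dy <- dim(data$y)
  if (dy[3] != J) abort("data and Q-matrix disagree on the number of items.")
  n <- dy[1]; Tn <- dy[2]
  lg <- spec$family %in% c("lg_uncond", "lg_cond")
  if (lg) {
    if (Tn != length(spec$time_codes)) {
      abort(paste0("growth models need data occasions matching `time_codes`; got ",
                   Tn, " occasions in data vs ", length(spec$time_codes), " codes."))
    }
    tcodes <- spec$time_codes
  } else {
    tcodes <- rep(0, Tn)  # occasion-invariant prevalences
  }
  if (spec$family %in% c("rdina_cov", "lg_cond") && all(data$z == data$z[1])) {
    warn("covariate model requested but the covariate is constant.")
  }
  uz <- sort(unique(data$z))
  zi <- match(data$z, uz)
  Z <- length(uz)

  # quadrature grid over active random-effect dimensions
  if (lg) {
    r <- gh_rule(spec$quad)
    g0 <- if (spec$sigma0 > 0) r else list(nodes = 0, weights = 1)
    g1 <- if (spec$sigma1 > 0) r else list(nodes = 0, weights = 1)
    x0 <- rep(g0$nodes, times = length(g1$nodes))
    x1 <- rep(g1$nodes, each = length(g0$nodes))
    wn <- rep(g0$weights, times = length(g1$nodes)) *
      rep(g1$weights, each = length(g0$nodes))
    er <- if (spec$eps_sd > 0) gh_rule(spec$eps_quad) else list(nodes = 0, weights = 1)
  } else {
    x0 <- 0; x1 <- 0; wn <- 1
    er <- list(nodes = 0, weights = 1)
  }
  N <- length(wn)

  # response matrices (cases = person x occasion, person varying fastest)
  Ym <- matrix(data$y, n * Tn, J)
  Obs <- 1 - is.na(Ym) * 1
  Y0 <- ifelse(is.na(Ym), 0, Ym)

  factorized <- is_single_attribute(q)
  env <- list(spec = spec, n = n, T = Tn, J = J, K = K, Z = Z,
              uz = uz, zi = zi, tcodes = tcodes,
              x0 = x0, x1 = x1, wn = wn, N = N, eps = er,
              Y0 = Y0, Obs = Obs, factorized = factorized)
  if (factorized) {
    env$att <- max.col(q)  # the single attribute each item measures
  } else {
    env$patterns <- attribute_patterns(K)
    env$M <- nrow(env$patterns)
    env$eta <- eta_table(q, env$patterns)
  }
  # structural cell grid (k fastest, then occasion, then covariate group),
  # matching the S1/S0 array layout of the compiled E-step
  cells <- expand.grid(k = seq_len(K), t = seq_len(Tn), z = seq_len(Z),
                       KEEP.OUT.ATTRS = FALSE)
  env$cells <- cells
  env$cell_t <- tcodes[cells$t]
  env$cell_z <- uz[cells$z]
  # node additions to the linear predictor (parameter-independent)
  s0 <- if (lg) spec$sigma0 else 0
  s1 <- if (lg) spec$sigma1 else 0
  env$nodeadd <- outer(rep(1, nrow(cells)), s0 * x0) +
    outer(env$cell_t, s1 * x1)
  env$X <- struct_design(spec, env)
  env
}

# design matrix mapping free structural parameters to the fixed part of the
# attribute logit; offsets hold the constrained contributions
struct_design <- function(spec, env) {
  K <- env$K
  cl <- env$cells
  fam <- spec$family
  sum_zero <- spec$constraints$b == "sum_zero" && fam %in% c("lg_uncond", "lg_cond")
  cols <- list()
  if (sum_zero) {
    for (k in seq_len(K - 1)) {
      cols[[paste0("b_", k)]] <- (cl$k == k) - (cl$k == K)
    }
    cols[["mu0"]] <- rep(1, nrow(cl))
  } else {
    for (k in seq_len(K)) cols[[paste0("b_", k)]] <- (cl$k == k) * 1
  }
  if (fam %in% c("lg_uncond", "lg_cond")) {
    cols[["mu1"]] <- env$cell_t
  }
  if (fam == "rdina_cov") {
    for (k in seq_len(K)) cols[[paste0("h_", k)]] <- (cl$k == k) * env$cell_z
  }
  if (fam == "lg_cond") {
    for (k in seq_len(K)) cols[[paste0("h_", k)]] <- (cl$k == k) * env$cell_z
    cols[["h1"]] <- env$cell_z * env$cell_t
  }
  X <- do.call(cbind, cols)
  off <- rep(0, nrow(cl))
  if (fam %in% c("lg_uncond", "lg_cond")) {
    if (!sum_zero) off <- off + spec$constraints$mu0
    if (fam == "lg_cond") off <- off + spec$constraints$h0 * env$cell_z
  }
  list(X = X, off = off)
}

# attribute probabilities (and the mixing derivative factor) per structural
# cell and node, with the time-specific error integrated out
attr_prob_table <- function(lin_fixed, env, want_s = FALSE) {
  spec <- env$spec
  lin <- lin_fixed + env$nodeadd  # (cells x N)
  p <- 0; s <- 0
  xq <- env$eps$nodes; wq <- env$eps$weights
  esd <- if (spec$family %in% c("lg_uncond", "lg_cond")) spec$eps_sd else 0
  for (qq in seq_along(xq)) {
    phi <- plogis(lin + esd * xq[qq])
    p <- p + wq[qq] * phi
    if (want_s) s <- s + wq[qq] * phi * (1 - phi)
  }
  p <- clip_prob(p)
  list(p = p, s = s)
}

# fixed part of the attribute logit per structural cell, from growth params
lin_fixed_cells <- function(growth, env) {
  cl <- env$cells
  growth$b[cl$k] + growth$h[cl$k] * env$cell_z +
    growth$mu0 + growth$h0 * env$cell_z +
    (growth$mu1 + growth$h1 * env$cell_z) * env$cell_t
}

# per-attribute (factorized) or per-pattern (general) response likelihoods
item_tables <- function(f, d, env) {
  lp1 <- log(clip_prob(plogis(f + d))); lq1 <- log1p(-clip_prob(plogis(f + d)))
  lp0 <- log(clip_prob(plogis(f)));     lq0 <- log1p(-clip_prob(plogis(f)))
  if (env$factorized) {
    Mk <- outer(env$att, seq_len(env$K), `==`) * 1  # J x K
    LU1 <- env$Y0 %*% (lp1 * Mk) + (env$Obs - env$Y0) %*% (lq1 * Mk)
    LU0 <- env$Y0 %*% (lp0 * Mk) + (env$Obs - env$Y0) %*% (lq0 * Mk)
    sh <- pmax(LU1, LU0)
    list(U1 = exp(LU1 - sh), U0 = exp(LU0 - sh), shift = sum(sh))
  } else {
    LP <- t(env$eta) * lp1 + t(1 - env$eta) * lp0  # J x M
    LQ <- t(env$eta) * lq1 + t(1 - env$eta) * lq0
    LU <- env$Y0 %*% LP + (env$Obs - env$Y0) %*% LQ  # (nT) x M
    sh <- apply(LU, 1, max)
    list(U = exp(LU - sh), shift = sum(sh))
  }
}

# one likelihood (and optionally E-step) evaluation at a free-parameter vector
eval_model <- function(par, spec, env, info, want_stats = FALSE) {
  up <- unpack_pars(par, spec, info)
  lin <- lin_fixed_cells(up$growth, env)
  tabs <- attr_prob_table(lin, env, want_s = want_stats)
  it <- item_tables(up$f, up$d, env)
  if (env$factorized) {
    es <- estep_factored(it$U1, it$U0, as.numeric(tabs$p), env$wn, env$zi,
                         env$n, env$T, env$K, env$Z, env$N, want_stats)
  } else {
    prior <- pattern_prior(tabs$p, env)
    es <- estep_general(it$U, as.numeric(prior), env$wn, env$zi, env$patterns,
                        env$n, env$T, env$M, env$K, env$Z, env$N, want_stats)
  }
  ll <- sum(es$ll) + it$shift
  out <- list(ll = ll, ll_i = es$ll, up = up, p = tabs$p, s = tabs$s)
  if (want_stats) {
    out$Abar <- array(es$Abar, c(env$n, env$T, env$K))
    out$S1 <- matrix(es$S1, nrow(env$cells), env$N)
    out$S0 <- matrix(es$S0, nrow(env$cells), env$N)
    if (!env$factorized) out$Pbar <- array(es$Pbar, c(env$n, env$T, env$M))
  }
  out
}

# pattern priors per (cell-block, node) for the general path: M x T x Z x N
pattern_prior <- function(p, env) {
  K <- env$K; Tn <- env$T; Z <- env$Z; N <- env$N; M <- env$M
  pr <- array(0, c(M, Tn, Z, N))
  lpat <- env$patterns; l1 <- lpat; l0 <- 1 - lpat
  for (nn in seq_len(N)) for (zz in seq_len(Z)) for (tt in seq_len(Tn)) {
    idx <- (seq_len(K)) + K * ((tt - 1) + Tn * (zz - 1))
    pk <- p[cbind(idx, nn)]
    pr[, tt, zz, nn] <- exp(l1 %*% log(pk) + l0 %*% log(1 - pk))
  }
  pr
}

# analytic gradient of the marginal log-likelihood at `par`, reusing an
# E-step evaluation (Fisher's identity: the score is the posterior
# expectation of the complete-data score)
model_grad <- function(ev, spec, env, info) {
  up <- ev$up
  # item block
  p1 <- clip_prob(plogis(up$f + up$d)); p0 <- clip_prob(plogis(up$f))
  if (env$factorized) {
    EB <- matrix(ev$Abar, env$n * env$T, env$K)[, env$att, drop = FALSE]
  } else {
    PB <- matrix(ev$Pbar, env$n * env$T, env$M)
    EB <- PB %*% env$eta
  }
  M1 <- sweep(EB, 2, p1, `*`) + sweep(1 - EB, 2, p0, `*`)
  gf <- colSums(env$Y0 - env$Obs * M1)
  gd <- colSums(EB * (env$Y0 - sweep(env$Obs, 2, p1, `*`)))
  # structural block
  r <- ev$S1 - (ev$S1 + ev$S0) * ev$p
  W <- rowSums(r * ev$s / (ev$p * (1 - ev$p)))
  gs <- drop(crossprod(env$X$X, W))
  setNames(c(gf, gd, gs), info$names)
}

#' Per-person marginal log-likelihood
#'
#' Computes each person's marginal log-likelihood under any of the four
#' model families at explicitly supplied parameter values (no fitting).
#' Useful for model checking and for validating the vectorized likelihood
#' against independent implementations.
#'
#' @param data an [lgcdm_data()] object.
#' @param spec an [lgcdm_spec()].
#' @param f,d item parameter vectors.
#' @param growth a [growth_params()] object (for `rdina` families only `b`
#'   and `h` are used).
#' @return numeric vector of per-person log-likelihood contributions.
#' @export
person_loglik <- function(data, spec, f, d, growth) {
  if (any(!is.finite(c(f, d, growth$b, growth$mu0, growth$mu1,
                       growth$h, growth$h0, growth$h1)))) {
    abort("non-finite parameter value supplied to person_loglik().")
  }
  env <- make_env(spec, data)
  lin <- lin_fixed_cells(growth, env)
  tabs <- attr_prob_table(lin, env)
  it <- item_tables(f, d, env)
  if (env$factorized) {
    es <- estep_factored(it$U1, it$U0, as.numeric(tabs$p), env$wn, env$zi,
                         env$n, env$T, env$K, env$Z, env$N, FALSE)
    sh <- rowSums(matrix(attr_shift_f(f, d, env), env$n))
  } else {
    prior <- pattern_prior(tabs$p, env)
    es <- estep_general(it$U, as.numeric(prior), env$wn, env$zi, env$patterns,
                        env$n, env$T, env$M, env$K, env$Z, env$N, FALSE)
    sh <- rowSums(matrix(attr_shift_g(f, d, env), env$n))
  }
  es$ll + sh
}

# per-person rescaling shifts (shared with item_tables; recomputed here so
# person_loglik can report per-person values)
attr_shift_f <- function(f, d, env) {
  lp1 <- log(clip_prob(plogis(f + d))); lq1 <- log1p(-clip_prob(plogis(f + d)))
  lp0 <- log(clip_prob(plogis(f)));     lq0 <- log1p(-clip_prob(plogis(f)))
  Mk <- outer(env$att, seq_len(env$K), `==`) * 1
  LU1 <- env$Y0 %*% (lp1 * Mk) + (env$Obs - env$Y0) %*% (lq1 * Mk)
  LU0 <- env$Y0 %*% (lp0 * Mk) + (env$Obs - env$Y0) %*% (lq0 * Mk)
  pmax(LU1, LU0)
}

attr_shift_g <- function(f, d, env) {
  lp1 <- log(clip_prob(plogis(f + d))); lq1 <- log1p(-clip_prob(plogis(f + d)))
  lp0 <- log(clip_prob(plogis(f)));     lq0 <- log1p(-clip_prob(plogis(f)))
  LP <- t(env$eta) * lp1 + t(1 - env$eta) * lp0
  LQ <- t(env$eta) * lq1 + t(1 - env$eta) * lq0
  LU <- env$Y0 %*% LP + (env$Obs - env$Y0) %*% LQ
  apply(LU, 1, max)
}
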