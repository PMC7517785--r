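#' Conjunctive ideal response
#'
#' Under the deterministic-input noisy-"and" rule an item can only be solved
#' when every required attribute is mastered: the ideal response is
#' `prod(alpha^q)`, i.e. 1 iff `alpha_k >= q_k` for all k.
#'
#' @param alpha 0/1 mastery vector.
#' @param q_row 0/1 requirement vector for one item (a Q-matrix row).
#' @return 0 or 1.
#' @examples
#' ideal_response(c(1, 0), c(1, 1)) # 0: a required attribute is missing
#' @export
ideal_response <- function(alpha, q_row) {
  if (length(alpha) != length(q_row)) {
    abort("`alpha` and `q_row` must have the same length.")
  }
  as.integer(all(alpha >= q_row))
}

#' RDINA item response probability
#'
#' The reparameterized DINA model puts the item response on the logit scale:
#' `logit P(Y = 1 | eta) = f + d * eta (+ l * z)`, where `f` is the
#' false-alarm logit (log-odds of a correct answer without the required
#' skills), `d` the item discrimination, and `l` an optional item-level
#' covariate effect.
#'
#' @param f,d item false-alarm and discrimination logits (recycled).
#' @param eta ideal response(s), 0/1.
#' @param l optional item-level covariate coefficient(s).
#' @param z optional covariate value; requires `l`.
#' @return response probability in (0, 1).
#' @examples
#' rdina_prob(-2.09, 1.97, eta = 0) # ~0.110
#' rdina_prob(-2.09, 1.97, eta = 1) # ~0.470
#' @export
rdina_prob <- function(f, d, eta, l = NULL, z = NULL) {
  if (!is.null(z) && is.null(l)) {
    abort("a covariate value `z` was supplied but the items have no `l` coefficients.")
  }
  lin <- f + d * eta
  if (!is.null(z)) lin <- lin + l * z
  plogis(lin)
}

#' Guessing and slip from RDINA parameters
#'
#' Recovers the classical DINA guessing and slip probabilities from the
#' logit-scale RDINA parameters: `g = logistic(f)` and
#' `s = 1 - logistic(f + d)`.
#'
#' @param f,d numeric vectors of item parameters.
#' @return a tibble with columns `g` and `s`.
#' @seealso [fd_from_guess_slip()] for the inverse map.
#' @export
guess_slip <- function(f, d) {
  stopifnot(length(f) == length(d), all(is.finite(f)), all(is.finite(d)))
  tibble(g = plogis(f), s = 1 - plogis(f + d))
}

#' @rdname guess_slip
#' @param g,s guessing and slip probabilities in (0, 1).
#' @export
fd_from_guess_slip <- function(g, s) {
  stopifnot(all(g > 0 & g < 1), all(s > 0 & s < 1))
  tibble(f = qlogis(g), d = qlogis(1 - s) - qlogis(g))
}

#' Attribute growth parameters
#'
#' Bundles the attribute-level parameters of the latent growth diagnostic
#' model: fixed difficulties `b_k`, the random intercept/slope distribution
#' (`mu0`, `mu1` means; `sigma0`, `sigma1` scales, fixed at 1 by default for
#' identification), covariate effects (`h` per attribute, `h0`/`h1` on the
#' intercept and slope), and the time-specific error scale `eps_sd`.
#'
#' An unconditional model has `h`, `h0`, `h1` all zero. Note that `mu0` and
#' `h0` enter every attribute logit identically to `b_k` and `h_k`
#' respectively, so they are separately interpretable but not separately
#' identifiable from data; see the methods vignette.
#'
#' @param b numeric vector of attribute difficulty logits (length K).
#' @param mu0,mu1 means of the random intercept and slope.
#' @param sigma0,sigma1 scales (SDs) of the random intercept and slope.
#' @param h per-attribute covariate main effects (length K or scalar).
#' @param h0,h1 covariate effects on the random intercept and slope.
#' @param eps_sd SD of the time-specific error (set 0 to disable).
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(b, mu0 = 0, mu1 = 0, sigma0 = 1, sigma1 = 1,
                          h = 0, h0 = 0, h1 = 0, eps_sd = 1) {
  K <- length(b)
  h <- rep_len(h, K)
  stopifnot(sigma0 >= 0, sigma1 >= 0, eps_sd >= 0,
            length(mu0) == 1, length(mu1) == 1,
            length(h0) == 1, length(h1) == 1)
  structure(list(b = as.numeric(b), mu0 = mu0, mu1 = mu1,
                 sigma0 = sigma0, sigma1 = sigma1,
                 h = as.numeric(h), h0 = h0, h1 = h1, eps_sd = eps_sd),
            class = "growth_params")
}

is_unconditional <- function(p) all(p$h == 0) && p$h0 == 0 && p$h1 == 0

#' Attribute mastery logit
#'
#' The linear predictor of attribute mastery for attribute `k` at time code
#' `t`, covariate value `z`, and standard-normal deviates `(zeta, gamma,
#' eps)` for the random intercept, random slope, and time-specific error:
#'
#' `b_k + (mu0 + sigma0*zeta + h0*z) + (mu1 + sigma1*gamma + h1*z)*t + h_k*z
#'  + eps_sd*eps`
#'
#' With `z = 0` and all covariate effects zero this is the unconditional
#' growth curve logit.
#'
#' @param params a [growth_params()] object.
#' @param k attribute index.
#' @param t time code (first occasion is 0).
#' @param z covariate value (0 for none).
#' @param zeta,gamma,eps standard-normal deviates (0 gives the mean curve).
#' @return the logit value (vectorized over the deviates).
#' @export
attribute_logit <- function(params, k, t, z = 0, zeta = 0, gamma = 0, eps = 0) {
  stopifnot(inherits(params, "growth_params"), k >= 1, k <= length(params$b))
  params$b[k] + params$h[k] * z +
    (params$mu0 + params$sigma0 * zeta + params$h0 * z) +
    (params$mu1 + params$sigma1 * gamma + params$h1 * z) * t +
    params$eps_sd * eps
}

#' Gauss-Hermite quadrature for a standard normal
#'
#' Nodes and weights rescaled so that `sum(w * g(x))` approximates
#' `E[g(X)]`, `X ~ N(0,1)`; weights sum to 1.
#'
#' @param n number of nodes (>= 1).
#' @return list with `nodes` and `weights`.
#' @export
gh_rule <- function(n) {
  stopifnot(n >= 1)
  gq <- statmod::gauss.quad(n, kind = "hermite")
  list(nodes = gq$nodes * sqrt(2), weights = gq$weights / sqrt(pi))
}

#' Marginal attribute mastery probability
#'
#' Integrates the logistic attribute-mastery curve over the random
#' intercept, random slope, and time-specific error by Gauss-Hermite
#' quadrature, giving the population prevalence of attribute `k` at
#' `(t, z)`. Dimensions whose scale parameter is zero drop out exactly.
#'
#' @inheritParams attribute_logit
#' @param quad a quadrature rule from [gh_rule()]; needs >= 3 nodes.
#' @return probability in (0, 1).
#' @export
marginal_attribute_prob <- function(params, k, t, z = 0, quad = gh_rule(9)) {
  if (is.null(quad$nodes) || length(quad$nodes) < 3) {
    abort("`quad` must supply at least 3 Gauss-Hermite nodes.")
  }
  x <- quad$nodes; w <- quad$weights
  # tensor over the active random dimensions only
  dims <- list(
    zeta  = params$sigma0 > 0,
    gamma = params$sigma1 > 0 && t != 0,
    eps   = params$eps_sd > 0
  )
  grids <- lapply(dims, function(on) if (on) x else 0)
  wts <- lapply(dims, function(on) if (on) w else 1)
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  gw <- Reduce(`*`, expand.grid(wts, KEEP.OUT.ATTRS = FALSE))
  lin <- attribute_logit(params, k, t, z,
                         zeta = g$zeta, gamma = g$gamma, eps = g$eps)
  sum(gw * plogis(lin))
}

#' Probability of an attribute-mastery pattern
#'
#' Under attribute independence the probability of the mastery pattern
#' `alpha` is the product of per-attribute Bernoulli terms.
#'
#' @param attr_probs per-attribute mastery probabilities in (0, 1).
#' @param pattern 0/1 mastery vector of the same length.
#' @return probability; the values over all `2^K` patterns sum to 1.
#' @export
pattern_prob <- function(attr_probs, pattern) {
  stopifnot(length(attr_probs) == length(pattern),
            all(attr_probs > 0 & attr_probs < 1))
  prod(ifelse(pattern == 1, attr_probs, 1 - attr_probs))
}

# vectorized: probabilities of all patterns (rows of `patterns`)
pattern_probs <- function(attr_probs, patterns = attribute_patterns(length(attr_probs))) {
  exp(patterns %*% log(attr_probs) + (1 - patterns) %*% log(1 - attr_probs))[, 1]
}

#' Item-level growth parameters and logit
#'
#' An alternative placement of the growth curve at the item level: the item
#' logit gains a time slope `rho_j`, a person-item random intercept `xi`,
#' and an error `phi`. Provided for simulation and extension; no estimator
#' is attached to this variant.
#'
#' @param xi_mean,xi_sd random intercept distribution.
#' @param rho item time slope(s).
#' @param phi_sd error SD.
#' @export
item_growth_params <- function(rho, xi_mean = 0, xi_sd = 1, phi_sd = 1) {
  structure(list(rho = rho, xi_mean = xi_mean, xi_sd = xi_sd, phi_sd = phi_sd),
            class = "item_growth_params")
}

#' @rdname item_growth_params
#' @param params an `item_growth_params` object.
#' @param f,d RDINA item parameters for item `j`.
#' @param j item index.
#' @param eta ideal response.
#' @param t time code.
#' @param xi,phi standard-normal deviates.
#' @return the item-level growth logit `f + d*eta + rho*t + xi' + phi'`,
#'   where the deviates are scaled by their SDs.
#' @export
item_growth_logit <- function(params, f, d, j, eta, t, xi = 0, phi = 0) {
  stopifnot(inherits(params, "item_growth_params"))
  rho <- rep_len(params$rho, max(j))[j]
  f[j] + d[j] * eta + rho * t +
    (params$xi_mean + params$xi_sd * xi) + params$phi_sd * phi
}
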