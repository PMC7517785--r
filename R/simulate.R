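# Built-in generating values for the two-occasion, 21-item, 4-attribute
# pre/post mathematics design (attributes: ratios/proportional relationships,
# measurement & data, number systems, geometry). Items map to a single
# attribute each. f = false-alarm logit, d = discrimination logit.
sim1_attr_map <- c(1, 2, 2, 3, 3, 3, 3, 3, 2, 2, 2, 2, 1, 1, 4, 4, 1, 4, 4, 4, 4)

sim1_items_uncond <- tibble::tibble(
  item = paste0("Y", 1:21),
  attribute = sim1_attr_map,
  f = c(-2.09, -0.24, -2.61, -1.87, -1.14, -0.74, -3.73, -0.96, -0.76, -0.97,
        -0.59, -1.38, -0.64, -2.61, -0.99, -0.70, -3.41, -0.27, -1.77, -1.41, -1.92),
  d = c(1.97, 2.06, 1.92, 1.87, 2.34, 1.88, 3.57, 1.14, 2.21, 2.84,
        3.09, 3.03, 2.01, 2.93, 1.91, 1.82, 1.94, 2.35, 1.96, 1.47, 1.63))

sim1_items_cond <- tibble::tibble(
  item = paste0("Y", 1:21),
  attribute = sim1_attr_map,
  f = c(-2.10, -0.24, -2.62, -1.88, -1.14, -0.74, -3.75, -0.96, -0.76, -0.97,
        -0.59, -1.38, -0.63, -2.60, -0.99, -0.70, -3.49, -0.27, -1.76, -1.41, -1.93),
  d = c(1.98, 2.06, 1.92, 1.87, 2.34, 1.89, 3.58, 1.14, 2.21, 2.84,
        3.09, 3.02, 1.99, 2.91, 1.91, 1.82, 2.02, 2.35, 1.96, 1.47, 1.64))

sim1_qmatrix <- function() {
  q <- matrix(0L, 21, 4)
  q[cbind(1:21, sim1_attr_map)] <- 1L
  qmatrix(q, item_ids = paste0("Y", 1:21), attribute_ids = paste0("A", 1:4))
}

# 30-item, 5-attribute Q-matrix for the three-occasion design: each
# attribute appears alone, in a pair, or in a triple the same number of
# times (transposed layout in the source table).
sim2_qmatrix <- function() {
  qt <- rbind(
    c(1,0,0,0,0, 1,0,0,0,0, 1,1,1,1,0, 0,0,0,0,0, 1,1,1,1,1, 1,0,0,0,0),
    c(0,1,0,0,0, 0,1,0,0,0, 1,0,0,0,1, 1,1,0,0,0, 1,1,1,0,0, 0,1,1,1,0),
    c(0,0,1,0,0, 0,0,1,0,0, 0,1,0,0,1, 0,0,1,1,0, 1,0,0,1,1, 0,1,1,0,1),
    c(0,0,0,1,0, 0,0,0,1,0, 0,0,1,0,0, 1,0,1,0,1, 0,1,0,1,0, 1,1,0,1,1),
    c(0,0,0,0,1, 0,0,0,0,1, 0,0,0,1,0, 0,1,0,1,1, 0,0,1,0,1, 1,0,1,1,1))
  qmatrix(t(qt), item_ids = paste0("Y", 1:30), attribute_ids = paste0("A", 1:5))
}

#' Simulation designs
#'
#' A simulation design bundles a model specification, the generating (true)
#' parameter values, the sample size and the covariate generator.
#'
#' @param spec an [lgcdm_spec()] describing the generating family.
#' @param items tibble with columns `f` and `d` (one row per item).
#' @param growth a [growth_params()] with the generating attribute-level
#'   values.
#' @param n_persons number of persons.
#' @param covariate function `n -> z` drawing the person covariate, or
#'   `NULL` for none (z = 0).
#' @param name design label.
#' @param metadata free-form notes carried along (e.g. which generating
#'   values are package defaults rather than published estimates).
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(spec, items, growth, n_persons,
                       covariate = NULL, name = "custom", metadata = list()) {
  stopifnot(inherits(spec, "lgcdm_spec"), inherits(growth, "growth_params"),
            nrow(items) == nrow(spec$qmatrix),
            length(growth$b) == ncol(spec$qmatrix))
  structure(list(spec = spec, items = items, growth = growth,
                 n_persons = n_persons, covariate = covariate,
                 name = name, metadata = metadata),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>", x$name, "| family", x$spec$family,
      "| n =", x$n_persons, "\n")
  invisible(x)
}

#' Built-in simulation designs
#'
#' `sim1_*`: the pre/post mathematics design (21 single-attribute items,
#' 4 attributes, 2 occasions) with the published item and growth estimates
#' as generating truths; the conditional variant adds a balanced binary
#' treatment covariate with attribute-level effects `h` and a slope effect
#' `h1`. The published intercept-level treatment shift (0.30) is collinear
#' with the attribute-level effects and therefore not separately
#' realizable; the design sets `h0 = 0` and records the published value in
#' `metadata$aliased_h0` (see the methods vignette).
#'
#' `sim2_*`: the three-occasion design (30 items, 5 attributes, balanced
#' Q-matrix). Its generating item values were not published; the design
#' uses g = s = 0.2 for every item and package-default growth values, all
#' flagged in `metadata$default_truths`.
#'
#' @param name one of `"sim1_uncond"`, `"sim1_cond"`, `"sim2_uncond"`,
#'   `"sim2_cond"`.
#' @param n_persons sample size (default 1000).
#' @return a [sim_design()].
#' @export
builtin_design <- function(name = c("sim1_uncond", "sim1_cond",
                                    "sim2_uncond", "sim2_cond"),
                           n_persons = 1000) {
  name <- match.arg(name)
  bern <- function(n) rbinom(n, 1, 0.5)
  if (startsWith(name, "sim1")) {
    q <- sim1_qmatrix()
    if (name == "sim1_uncond") {
      spec <- lgcdm_spec("lg_uncond", q, time_codes = c(0, 1))
      growth <- growth_params(b = c(-0.11, 0.16, -0.23, 0.16),
                              mu0 = 0.44, mu1 = 0.04)
      sim_design(spec, sim1_items_uncond, growth, n_persons,
                 covariate = NULL, name = name)
    } else {
      spec <- lgcdm_spec("lg_cond", q, time_codes = c(0, 1))
      growth <- growth_params(b = c(-0.45, -0.04, -0.44, -0.11),
                              mu0 = 0.46, mu1 = 0.03,
                              h = c(0.40, 0.09, 0.02, 0.24),
                              h0 = 0, h1 = 0.09)
      sim_design(spec, sim1_items_cond, growth, n_persons,
                 covariate = bern, name = name,
                 metadata = list(aliased_h0 = 0.30))
    }
  } else {
    q <- sim2_qmatrix()
    fd <- fd_from_guess_slip(rep(0.2, 30), rep(0.2, 30))
    items <- tibble(item = paste0("Y", 1:30), f = fd$f, d = fd$d)
    md <- list(default_truths = c("item parameters g = s = 0.2",
                                  "growth values are package defaults"))
    if (name == "sim2_uncond") {
      spec <- lgcdm_spec("lg_uncond", q, time_codes = c(0, 1, 2))
      growth <- growth_params(b = seq(-0.5, 0.5, length.out = 5),
                              mu0 = 0.5, mu1 = 0.3)
      sim_design(spec, items, growth, n_persons, covariate = NULL,
                 name = name, metadata = md)
    } else {
      spec <- lgcdm_spec("lg_cond", q, time_codes = c(0, 1, 2))
      growth <- growth_params(b = seq(-0.5, 0.5, length.out = 5),
                              mu0 = 0.5, mu1 = 0.3,
                              h = rep(0.3, 5), h0 = 0, h1 = 0.1)
      sim_design(spec, items, growth, n_persons, covariate = bern,
                 name = name, metadata = md)
    }
  }
}

#' Simulate longitudinal diagnostic responses
#'
#' Draws a data set from a simulation design: person covariates, standard
#' normal random-intercept/slope deviates, time-specific errors, attribute
#' mastery indicators from the logistic growth curve (independently across
#' attributes and occasions given the deviates), ideal responses through
#' the Q-matrix, and finally RDINA item responses. The true latent record
#' is attached as `attr(, "truth")`.
#'
#' @param design a [sim_design()].
#' @param seed integer seed; the same seed reproduces the data set exactly.
#' @return an [lgcdm_data()] with a `truth` attribute (list with `alpha`,
#'   `zeta`, `gamma`, the generating parameters and the design name).
#' @export
simulate_lgcdm <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  spec <- design$spec
  q <- spec$qmatrix
  J <- nrow(q); K <- ncol(q)
  lg <- spec$family %in% c("lg_uncond", "lg_cond")
  tcodes <- if (lg) spec$time_codes else
    rep(0, max(length(spec$time_codes), 1))
  Tn <- length(tcodes)
  n <- design$n_persons
  g <- design$growth
  z <- if (is.null(design$covariate)) rep(0, n) else design$covariate(n)
  zeta <- rnorm(n); gam <- rnorm(n)
  alpha <- array(0L, c(n, Tn, K))
  for (tt in seq_len(Tn)) {
    for (k in seq_len(K)) {
      eps <- rnorm(n)
      lin <- attribute_logit(g, k, tcodes[tt], z = z,
                             zeta = zeta, gamma = gam, eps = eps)
      alpha[, tt, k] <- rbinom(n, 1, plogis(lin))
    }
  }
  p1 <- plogis(design$items$f + design$items$d)
  p0 <- plogis(design$items$f)
  y <- array(0L, c(n, Tn, J))
  need <- rowSums(q)
  for (tt in seq_len(Tn)) {
    al <- matrix(alpha[, tt, ], n, K)
    eta <- (al %*% t(unclass(q)) == matrix(need, n, J, byrow = TRUE)) * 1
    pr <- sweep(eta, 2, p1, `*`) + sweep(1 - eta, 2, p0, `*`)
    y[, tt, ] <- rbinom(n * J, 1, pr)
  }
  dimnames(y) <- list(NULL, NULL, rownames(q))
  out <- lgcdm_data(y, z = z, occasions = tcodes, item_ids = rownames(q))
  attr(out, "truth") <- list(alpha = alpha, zeta = zeta, gamma = gam,
                             items = design$items, growth = g,
                             design = design$name, seed = seed)
  out
}
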