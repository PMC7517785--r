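test_that("ideal response is the conjunctive gate", {
  expect_identical(ideal_response(c(1, 1), c(1, 1)), 1L)
  expect_identical(ideal_response(c(1, 0), c(1, 1)), 0L)
  expect_identical(ideal_response(c(0, 1), c(0, 1)), 1L)
  expect_error(ideal_response(c(1, 0), c(1, 1, 0)), "same length")
})

test_that("RDINA response probabilities match direct logistic evaluation", {
  expect_equal(rdina_prob(0, 0, eta = 1), 0.5)
  expect_equal(rdina_prob(-2.09, 1.97, eta = 0), 0.110, tolerance = 1e-2)
  expect_equal(rdina_prob(-2.09, 1.97, eta = 1), 0.470, tolerance = 1e-2)
  expect_equal(rdina_prob(-1, 2, eta = 1, l = 0.5, z = 2), plogis(2))
  expect_error(rdina_prob(-1, 2, eta = 1, z = 1), "no `l`")
})

test_that("guess/slip transform round-trips through the logit map", {
  gs <- guess_slip(0, 0)
  expect_equal(gs$g, 0.5)
  expect_equal(gs$s, 0.5)
  set.seed(1)
  g <- runif(50, 0.01, 0.6); s <- runif(50, 0.01, 0.6)
  fd <- fd_from_guess_slip(g, s)
  back <- guess_slip(fd$f, fd$d)
  expect_equal(back$g, g, tolerance = 1e-12)
  expect_equal(back$s, s, tolerance = 1e-12)
})

test_that("attribute logit assembles growth, covariate and deviate terms", {
  g0 <- growth_params(b = 0)
  expect_equal(attribute_logit(g0, 1, t = 0), 0)
  gc <- growth_params(b = c(-0.45, -0.04, -0.44, -0.11), mu0 = 0.46, mu1 = 0.03,
                      h = c(0.40, 0.09, 0.02, 0.24), h0 = 0.30, h1 = 0.09)
  expect_equal(attribute_logit(gc, 1, t = 1, z = 1), 0.83, tolerance = 1e-12)
  gu <- growth_params(b = c(-0.11, 0.16, -0.23, 0.16), mu0 = 0.44, mu1 = 0.04)
  expect_equal(attribute_logit(gu, 1, t = 0), 0.33, tolerance = 1e-12)
  # with z = 0 and all covariate effects 0 the conditional formula reduces
  # bit-for-bit to the unconditional one
  gz <- growth_params(b = gu$b, mu0 = gu$mu0, mu1 = gu$mu1, h = 0, h0 = 0, h1 = 0)
  for (k in 1:4) for (t in 0:1) {
    expect_identical(attribute_logit(gz, k, t, z = 0, zeta = 0.3, gamma = -0.2, eps = 0.1),
                     attribute_logit(gu, k, t, z = 0, zeta = 0.3, gamma = -0.2, eps = 0.1))
  }
})

test_that("marginal attribute probability behaves like a logistic-normal mixture", {
  g <- growth_params(b = 0, mu0 = 0, mu1 = 0)
  expect_equal(marginal_attribute_prob(g, 1, t = 0), 0.5, tolerance = 1e-10)
  # strictly increasing in b
  bs <- seq(-2, 2, by = 0.5)
  ps <- vapply(bs, function(b) {
    marginal_attribute_prob(growth_params(b = b), 1, t = 1)
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  # degenerate mixture equals the plain logistic
  gd <- growth_params(b = 0.7, mu0 = 0.2, mu1 = 0.1, sigma0 = 0, sigma1 = 0, eps_sd = 0)
  expect_equal(marginal_attribute_prob(gd, 1, t = 2), plogis(0.7 + 0.2 + 0.2),
               tolerance = 1e-12)
  # quadrature convergence: at a 15-node base rule, doubling the nodes
  # changes the value by < 1e-8 across |b| <= 5 (the 9-node default is
  # accurate to ~1e-7, adequate for a probability; see the vignette)
  for (b in c(-5, -1, 0, 2, 5)) {
    gb <- growth_params(b = b)
    for (t in 0:1) {
      p15 <- marginal_attribute_prob(gb, 1, t = t, quad = gh_rule(15))
      p30 <- marginal_attribute_prob(gb, 1, t = t, quad = gh_rule(30))
      expect_lt(abs(p15 - p30), 1e-8)
    }
  }
  expect_error(marginal_attribute_prob(g, 1, 0, quad = list(nodes = 0, weights = 1)),
               "at least 3")
})

test_that("pattern probabilities multiply and normalize", {
  expect_equal(pattern_prob(c(0.5, 0.5), c(1, 0)), 0.25)
  expect_equal(pattern_prob(rep(1 - 1e-9, 3), c(1, 1, 1)), 1, tolerance = 1e-6)
  for (K in c(2, 4, 6)) {
    set.seed(K)
    p <- runif(K, 0.05, 0.95)
    pats <- attribute_patterns(K)
    tot <- sum(apply(pats, 1, function(a) pattern_prob(p, a)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("item-level growth logit nests the plain RDINA logit", {
  ig <- item_growth_params(rho = 0, xi_mean = 0, xi_sd = 1, phi_sd = 1)
  expect_equal(item_growth_logit(ig, f = 0, d = 0, j = 1, eta = 0, t = 0), 0)
  expect_equal(item_growth_logit(ig, f = -1, d = 2, j = 1, eta = 1, t = 3),
               -1 + 2)  # rho = 0, deviates 0: reduces to f + d*eta
  ig2 <- item_growth_params(rho = 0.5)
  expect_equal(item_growth_logit(ig2, f = -1, d = 2, j = 1, eta = 1, t = 2), 2)
})
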