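sim1_qmatrix_test <- function() {
  q <- matrix(0L, 21, 4)
  q[cbind(1:21, c(1, 2, 2, 3, 3, 3, 3, 3, 2, 2, 2, 2, 1, 1, 4, 4, 1, 4, 4, 4, 4))] <- 1L
  qmatrix(q)
}

# shared small data set: unconditional growth design, modest sample
small_uncond <- local({
  des <- builtin_design("sim1_uncond", n_persons = 150)
  list(des = des, dat = simulate_lgcdm(des, seed = 31))
})

test_that("EM iterations never decrease the log-likelihood", {
  sp <- small_uncond$des$spec
  sp$estimation <- "ml"
  sp$constraints$b <- "sum_zero"
  fit <- suppressWarnings(fit_lgcdm(small_uncond$dat, sp,
                                    lgcdm_control(n_starts = 1, se = FALSE,
                                                  max_em_iter = 30)))
  tr <- fit$em_trace
  expect_gte(length(tr), 5)
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("conditional model with a null covariate attains the unconditional loglik", {
  # nesting: with z identically 0 the covariate effects are pinned at 0 by
  # the prior and the two families maximize the same likelihood
  desu <- small_uncond$des
  spu <- desu$spec; spu$constraints$b <- "sum_zero"
  spc <- lgcdm_spec("lg_cond", desu$spec$qmatrix, time_codes = c(0, 1),
                    constraints = list(b = "sum_zero"))
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE, max_em_iter = 15)
  fitu <- suppressWarnings(fit_lgcdm(small_uncond$dat, spu, ctrl))
  fitc <- suppressWarnings(fit_lgcdm(small_uncond$dat, spc, ctrl))
  expect_equal(fitu$loglik, fitc$loglik, tolerance = 1e-6)
})

test_that("the optimum is stable under quadrature refinement", {
  sp <- small_uncond$des$spec
  sp$constraints$b <- "sum_zero"
  fit <- suppressWarnings(fit_lgcdm(small_uncond$dat, sp,
                                    lgcdm_control(n_starts = 1, se = FALSE,
                                                  max_em_iter = 15)))
  up <- fit$estimates
  sp15 <- sp; sp15$quad <- 15; sp15$eps_quad <- 15
  ll9 <- sum(person_loglik(small_uncond$dat, sp, up$f, up$d, up$growth))
  ll15 <- sum(person_loglik(small_uncond$dat, sp15, up$f, up$d, up$growth))
  expect_lt(abs(ll9 - ll15) / abs(ll9), 1e-6)
})

test_that("information criteria follow the standard definitions", {
  expect_equal(unname(information_criteria(-100, 5, 10)["aic"]), 210)
  expect_equal(unname(information_criteria(-100, 5, 100)["bic"]),
               200 + 5 * log(100))
  expect_equal(unname(information_criteria(-100, 0, 50)), c(200, 200))
})

test_that("posterior-mode penalty is maximal at zero and concave", {
  expect_gt(posterior_mode_penalty(rep(0, 4), 3),
            posterior_mode_penalty(c(0.5, 0, 0, 0), 3))
  x <- seq(-2, 2, by = 0.5)
  pen <- vapply(x, function(v) posterior_mode_penalty(v, 3), numeric(1))
  expect_true(all(diff(diff(pen)) < 0 + 1e-12))
})

test_that("a very diffuse prior recovers the ML solution", {
  q <- qmatrix(matrix(diag(2)[rep(1:2, 3), ], 6, 2))
  spm <- lgcdm_spec("rdina", q, time_codes = 0, estimation = "ml")
  spp <- lgcdm_spec("rdina", q, time_codes = 0, estimation = "pm",
                    prior_sd = 1e6)
  des <- sim_design(spm, tibble::tibble(f = rep(-1, 6), d = rep(2, 6)),
                    growth_params(b = c(0.3, -0.2), sigma0 = 0, sigma1 = 0,
                                  eps_sd = 0),
                    n_persons = 300)
  dat <- simulate_lgcdm(des, seed = 4)
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE)
  fm <- suppressWarnings(fit_lgcdm(dat, spm, ctrl))
  fp <- suppressWarnings(fit_lgcdm(dat, spp, ctrl))
  expect_equal(fm$par, fp$par, tolerance = 1e-4)
})

test_that("posterior-mode estimation keeps degenerate data off the boundary", {
  q <- qmatrix(matrix(1, 3, 1))
  sp <- lgcdm_spec("rdina", q, time_codes = 0, estimation = "pm")
  dat <- lgcdm_data(array(0, c(30, 1, 3)))
  fit <- suppressWarnings(fit_lgcdm(dat, sp, lgcdm_control(n_starts = 1, se = FALSE)))
  expect_true(all(is.finite(fit$par)))
  expect_true(fit$converged)
})

test_that("growth families refuse single-occasion data", {
  expect_error(lgcdm_spec("lg_uncond", sim1_qmatrix_test(), time_codes = 0),
               "at least 2")
  sp <- small_uncond$des$spec
  dat1 <- lgcdm_data(small_uncond$dat$y[, 1, , drop = FALSE])
  expect_error(fit_lgcdm(dat1, sp), "occasions")
})

test_that("multi-start fitting is reproducible and tie-stable", {
  q <- qmatrix(matrix(diag(2)[rep(1:2, 2), ], 4, 2))
  sp <- lgcdm_spec("rdina", q, time_codes = 0)
  des <- sim_design(sp, tibble::tibble(f = rep(-1, 4), d = rep(2, 4)),
                    growth_params(b = c(0.2, -0.2), sigma0 = 0, sigma1 = 0, eps_sd = 0),
                    n_persons = 120)
  dat <- simulate_lgcdm(des, seed = 9)
  ctrl <- lgcdm_control(n_starts = 3, seed = 7, se = FALSE)
  f1 <- suppressWarnings(fit_lgcdm(dat, sp, ctrl))
  f2 <- suppressWarnings(fit_lgcdm(dat, sp, ctrl))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$best_start, f2$best_start)
  expect_equal(f1$n_starts_used, 3)
})

test_that("local identification diagnostics detect rank deficits", {
  # 1 item / 1 attribute: 3 free parameters but only 2 pattern probabilities
  q1 <- qmatrix(matrix(1, 1, 1))
  sp1 <- lgcdm_spec("rdina", q1, time_codes = 0)
  chk <- check_local_identification(sp1)
  expect_false(chk$full_rank)
  expect_lte(chk$rank, 2)
  # constant covariate aliases h_k with b_k and h1 with mu1: deficit K + 1
  q3 <- qmatrix(matrix(1, 3, 1))
  spc <- lgcdm_spec("lg_cond", q3, time_codes = c(0, 1), quad = 5, eps_quad = 5)
  chk2 <- check_local_identification(spc, z = 1)
  expect_equal(chk2$rank, chk2$n_free - 2)
  # a well-separated single-attribute growth design is locally identified
  q6 <- qmatrix(matrix(diag(2)[rep(1:2, 3), ], 6, 2))
  spg <- lgcdm_spec("lg_uncond", q6, time_codes = c(0, 1), quad = 5,
                    eps_quad = 5, constraints = list(b = "sum_zero"))
  par <- lgcdm:::pack_pars(rep(-1, 6), rep(2, 6),
                           growth_params(b = c(0.3, -0.3), mu0 = 0.4, mu1 = 0.1),
                           spg)
  chk3 <- check_local_identification(spg, par = par)
  expect_true(chk3$full_rank)
})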