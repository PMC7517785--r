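# small fast design used throughout: RDINA, 6 single-attribute items
fast_design <- function(n = 200) {
  q <- qmatrix(matrix(diag(2)[rep(1:2, 3), ], 6, 2))
  sim_design(lgcdm_spec("rdina", q, time_codes = 0),
             tibble::tibble(f = rep(-1.2, 6), d = rep(2.4, 6)),
             growth_params(b = c(0.3, -0.2), sigma0 = 0, sigma1 = 0, eps_sd = 0),
             n_persons = n, name = "fast_rdina")
}

test_that("recovery studies are reproducible given (design, seed, reps)", {
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE)
  r1 <- suppressMessages(recovery_study(fast_design(), n_reps = 3, seed = 5, control = ctrl))
  r2 <- suppressMessages(recovery_study(fast_design(), n_reps = 3, seed = 5, control = ctrl))
  expect_identical(r1$blocks, r2$blocks)
  expect_identical(r1$estimates, r2$estimates)
  r3 <- suppressMessages(recovery_study(fast_design(), n_reps = 3, seed = 6, control = ctrl))
  expect_false(identical(r1$blocks$bias, r3$blocks$bias))
})

test_that("recovery %Bias machinery matches its definitions", {
  est <- rbind(c(1.1, -0.4), c(0.9, -0.6))
  truth <- c(a_1 = 1, a_2 = -0.5)  # 'a' prefix lands in block 'other'
  sm <- lgcdm:::summarise_recovery(est, truth)
  expect_equal(sm$parameters$bias, c(0, 0))
  expect_equal(sm$parameters$pct_bias, c(0, 0))
  expect_equal(sm$parameters$mse, c(0.01, 0.01))
  est2 <- rbind(c(1.2, -0.4), c(1.2, -0.4))
  sm2 <- lgcdm:::summarise_recovery(est2, truth)
  expect_equal(sm2$parameters$pct_bias, c(20, 20))
  # near-zero truths are excluded from %Bias with a note
  expect_message(
    sm3 <- lgcdm:::summarise_recovery(rbind(c(0.1, 1)), c(x_1 = 0, x_2 = 1)),
    "excluded")
  expect_true(is.na(sm3$parameters$pct_bias[1]))
  expect_equal(sm3$blocks$pct_bias[1], 0)  # block mean over finite entries
})

test_that("item-parameter MSE shrinks with sample size", {
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE)
  r_small <- suppressMessages(recovery_study(fast_design(150), n_reps = 4, seed = 21, control = ctrl))
  r_big <- suppressMessages(recovery_study(fast_design(1500), n_reps = 4, seed = 21, control = ctrl))
  mse <- function(r, b) r$blocks$mse[r$blocks$block == b]
  expect_lt(mse(r_big, "item_f"), mse(r_small, "item_f"))
  expect_lt(mse(r_big, "item_d"), mse(r_small, "item_d"))
})

test_that("noiseless data yield perfect latent classification", {
  q <- qmatrix(matrix(diag(2)[rep(1:2, 3), ], 6, 2))
  des <- sim_design(lgcdm_spec("lg_uncond", q, time_codes = c(0, 1)),
                    tibble::tibble(f = rep(-30, 6), d = rep(60, 6)),
                    growth_params(b = c(0.4, -0.4), mu0 = 0.3, mu1 = 0.1),
                    n_persons = 120)
  dat <- simulate_lgcdm(des, seed = 13)
  sp <- des$spec; sp$constraints$b <- "sum_zero"
  fit <- suppressWarnings(fit_lgcdm(dat, sp,
                                    lgcdm_control(n_starts = 1, se = FALSE,
                                                  max_em_iter = 10)))
  tr <- attr(dat, "truth")
  expect_identical(unname(fit$posterior > 0.5) * 1L, unname(tr$alpha) * 1L)
})

test_that("a single correct candidate reduces cross-fitting to recovery", {
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE)
  des <- fast_design(250)
  cf <- suppressMessages(cross_fit_study(des, families = "rdina", n_reps = 3,
                                         seed = 17, control = ctrl))
  rs <- suppressMessages(recovery_study(des, n_reps = 3, seed = 17, control = ctrl))
  expect_equal(cf$table$pct_bias_attribute,
               rs$blocks$pct_bias[rs$blocks$block == "attribute_difficulty"],
               tolerance = 1e-10)
  expect_equal(cf$table$pct_bias_item,
               mean(rs$blocks$pct_bias[rs$blocks$block %in% c("item_f", "item_d")]),
               tolerance = 1e-10)
  expect_error(cross_fit_study(des, families = "lg_uncond", n_reps = 2, seed = 1),
               "generating family")
})

test_that("the growth model is preferred over the static model on its own data", {
  des <- builtin_design("sim1_uncond", n_persons = 500)
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE, max_em_iter = 10)
  cf <- suppressMessages(cross_fit_study(des, families = c("rdina", "lg_uncond"),
                                         n_reps = 2, seed = 23, control = ctrl))
  tab <- cf$table
  expect_equal(cf$winner, "lg_uncond")
  expect_lt(tab$aic[tab$family == "lg_uncond"], tab$aic[tab$family == "rdina"])
  expect_lt(tab$bic[tab$family == "lg_uncond"], tab$bic[tab$family == "rdina"])
})
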