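test_that("lambda corrects classification for chance", {
  expect_equal(round(lambda_stat(0.91, 0.57), 2), 0.79)
  expect_equal(lambda_stat(0.57, 0.57), 0)
  expect_equal(lambda_stat(1, 0.3), 1)
  expect_true(is.na(suppressWarnings(lambda_stat(0.99, 1 - 1e-15))))
  # lambda <= Pc and bounded above by 1
  set.seed(2)
  pc <- runif(100, 0.5, 1); pr <- runif(100, 0.05, 0.95)
  lam <- lambda_stat(pc, pr)
  expect_true(all(lam <= pc + 1e-12))
  expect_true(all(lam <= 1))
})

test_that("proportion correct is the frequency-weighted mean of max posteriors", {
  pt <- tibble::tibble(attribute = "A1", n = c(60, 40), max_posterior = c(0.9, 0.8))
  expect_equal(proportion_correct(pt)$pc, 0.86)
  pt1 <- tibble::tibble(attribute = "A1", n = 5, max_posterior = 1)
  expect_equal(proportion_correct(pt1)$pc, 1)
  expect_error(proportion_correct(pt[0, ]), "empty")
})

test_that("posteriors match the brute-force Bayes rule", {
  for (s in c(5, 9, 14)) {
    inst <- random_instance(s, family = "lg_cond")
    sp <- inst$spec
    env <- suppressWarnings(lgcdm:::make_env(sp, inst$data))
    info <- lgcdm:::par_info(sp)
    par <- lgcdm:::pack_pars(inst$f, inst$d, inst$g, sp, info)
    up <- lgcdm:::unpack_pars(par, sp, info)  # constrained version actually used
    ev <- lgcdm:::eval_model(par, sp, env, info, want_stats = TRUE)
    for (i in 1:3) {
      o <- oracle_posterior(matrix(inst$y[i, , ], dim(inst$y)[2], dim(inst$y)[3]),
                            inst$z[i], unclass(inst$q), up$f, up$d, up$growth,
                            inst$tcodes, nquad = 5, neps = 5)
      expect_equal(matrix(ev$Abar[i, , ], dim(inst$y)[2], env$K), o,
                   tolerance = 1e-10)
    }
  }
})

test_that("a noiseless item pins its attribute posterior", {
  q <- qmatrix(matrix(1, 2, 1))
  sp <- lgcdm_spec("rdina", q, time_codes = 0)
  env <- lgcdm:::make_env(sp, lgcdm_data(array(c(1, 1), c(1, 1, 2))))
  info <- lgcdm:::par_info(sp)
  par <- lgcdm:::pack_pars(c(-12, -12), c(24, 24),
                           growth_params(b = 0, sigma0 = 0, sigma1 = 0, eps_sd = 0),
                           sp, info)
  ev <- lgcdm:::eval_model(par, sp, env, info, want_stats = TRUE)
  expect_gt(ev$Abar[1, 1, 1], 1 - 1e-6)
})

test_that("uninformative items leave the posterior at the prior prevalence", {
  q <- qmatrix(matrix(1, 3, 1))
  sp <- lgcdm_spec("rdina", q, time_codes = 0)
  env <- lgcdm:::make_env(sp, lgcdm_data(array(c(1, 0, 1), c(1, 1, 3))))
  info <- lgcdm:::par_info(sp)
  par <- lgcdm:::pack_pars(rep(-0.4, 3), rep(0, 3),  # d = 0: flat items
                           growth_params(b = 0.9, sigma0 = 0, sigma1 = 0, eps_sd = 0),
                           sp, info)
  ev <- lgcdm:::eval_model(par, sp, env, info, want_stats = TRUE)
  expect_equal(ev$Abar[1, 1, 1], plogis(0.9), tolerance = 1e-10)
})

test_that("classification report is consistent across groupings and fits", {
  des <- builtin_design("sim1_uncond", n_persons = 200)
  dat <- simulate_lgcdm(des, seed = 12)
  sp <- des$spec; sp$constraints$b <- "sum_zero"
  fit <- suppressWarnings(fit_lgcdm(dat, sp,
                                    lgcdm_control(n_starts = 1, se = FALSE,
                                                  max_em_iter = 10)))
  rep_ <- classification_report(fit)
  expect_true(all(rep_$pc >= 0.5 & rep_$pc <= 1))
  expect_true(all(rep_$lambda <= rep_$pc))
  expect_true(all(rep_$prevalence > 0 & rep_$prevalence < 1))
  # pattern-table (grouped) computation agrees with the per-person mean
  pt <- pattern_table(fit)
  pc_grouped <- proportion_correct(pt)
  expect_equal(sort(pc_grouped$pc), sort(rep_$pc), tolerance = 1e-10)
  # permuting persons leaves Pc unchanged
  perm <- sample(dim(dat)[1])
  dat2 <- lgcdm_data(dat$y[perm, , , drop = FALSE], z = dat$z[perm])
  fit2 <- suppressWarnings(fit_lgcdm(dat2, sp,
                                     lgcdm_control(n_starts = 1, se = FALSE,
                                                   max_em_iter = 10)))
  expect_equal(classification_report(fit2)$pc, rep_$pc, tolerance = 1e-6)
  # MAP patterns are deterministic 0/1
  mp <- suppressMessages(map_patterns(fit))
  expect_true(all(mp$map %in% 0:1))
  # Pc is calibrated: realized MAP accuracy against the true mastery states
  # tracks the expected proportion correct
  tr <- attr(dat, "truth")
  acc <- vapply(seq_len(4), function(k) {
    mean((fit$posterior[, , k] > 0.5) == (tr$alpha[, , k] == 1))
  }, numeric(1))
  expect_lt(max(abs(acc - rep_$pc)), 0.06)
})

test_that("model-implied prevalence rises with attribute ease", {
  q <- qmatrix(matrix(1, 4, 1))
  des <- function(b) {
    sim_design(lgcdm_spec("lg_uncond", q, time_codes = c(0, 1)),
               tibble::tibble(f = rep(-1.5, 4), d = rep(2.5, 4)),
               growth_params(b = b, mu0 = 0.2, mu1 = 0.1), n_persons = 150)
  }
  ctrl <- lgcdm_control(n_starts = 1, se = FALSE, max_em_iter = 10)
  sp <- lgcdm_spec("lg_uncond", q, time_codes = c(0, 1),
                   constraints = list(b = "sum_zero"))
  f_lo <- suppressWarnings(fit_lgcdm(simulate_lgcdm(des(-1), seed = 3), sp, ctrl))
  f_hi <- suppressWarnings(fit_lgcdm(simulate_lgcdm(des(1), seed = 3), sp, ctrl))
  expect_lt(attribute_prevalence(f_lo)$prevalence,
            attribute_prevalence(f_hi)$prevalence)
})
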