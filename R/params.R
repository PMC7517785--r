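# Free-parameter packing for each model family.
#
# The free vector is ordered (f_1..f_J, d_1..d_J, structural...). The
# structural block depends on the family and on the identification
# constraints:
#   rdina:      b_1..b_K            (attribute prevalence logits)
#   rdina_cov:  b_1..b_K, h_1..h_K
#   lg_uncond:  b (K free, mu0 fixed | K-1 effect-coded, mu0 free), mu1
#   lg_cond:    lg_uncond + h_1..h_K, h1
# h0 is never free (collinear with h); sigma0/sigma1/eps_sd are fixed by the
# spec (identification: random-effect deviates are standard normal).

par_info <- function(spec) {
  q <- spec$qmatrix
  J <- nrow(q); K <- ncol(q)
  items <- rownames(q)
  fam <- spec$family
  sum_zero <- spec$constraints$b == "sum_zero" && fam %in% c("lg_uncond", "lg_cond")
  sn <- switch(fam,
    rdina = paste0("b_", seq_len(K)),
    rdina_cov = c(paste0("b_", seq_len(K)), paste0("h_", seq_len(K))),
    lg_uncond = c(
      if (sum_zero) c(paste0("b_", seq_len(K - 1), recycle0 = TRUE), "mu0") else paste0("b_", seq_len(K)),
      "mu1"),
    lg_cond = c(
      if (sum_zero) c(paste0("b_", seq_len(K - 1), recycle0 = TRUE), "mu0") else paste0("b_", seq_len(K)),
      "mu1", paste0("h_", seq_len(K)), "h1")
  )
  nm <- c(paste0("f_", items), paste0("d_", items), sn)
  list(J = J, K = K, names = nm, struct_names = sn, sum_zero = sum_zero,
       n_free = length(nm),
       idx_f = seq_len(J), idx_d = J + seq_len(J),
       idx_s = 2L * J + seq_along(sn))
}

# free vector -> full named parameter set (growth_params + items)
unpack_pars <- function(par, spec, info = par_info(spec)) {
  K <- info$K
  f <- par[info$idx_f]; d <- par[info$idx_d]
  s <- par[info$idx_s]
  names(s) <- info$struct_names
  fam <- spec$family
  b <- numeric(K); mu0 <- 0; mu1 <- 0; h <- numeric(K); h1 <- 0
  if (fam %in% c("rdina", "rdina_cov")) {
    b <- unname(s[paste0("b_", seq_len(K))])
    if (fam == "rdina_cov") h <- unname(s[paste0("h_", seq_len(K))])
    growth <- growth_params(b = b, h = h, mu0 = 0, mu1 = 0,
                            sigma0 = 0, sigma1 = 0, h0 = 0, h1 = 0, eps_sd = 0)
  } else {
    if (info$sum_zero) {
      bdev <- unname(s[paste0("b_", seq_len(K - 1), recycle0 = TRUE)])
      b <- c(bdev, -sum(bdev))
      mu0 <- unname(s["mu0"])
    } else {
      b <- unname(s[paste0("b_", seq_len(K))])
      mu0 <- spec$constraints$mu0
    }
    mu1 <- unname(s["mu1"])
    if (fam == "lg_cond") {
      h <- unname(s[paste0("h_", seq_len(K))])
      h1 <- unname(s["h1"])
    }
    growth <- growth_params(b = b, mu0 = mu0, mu1 = mu1,
                            sigma0 = spec$sigma0, sigma1 = spec$sigma1,
                            h = h, h0 = spec$constraints$h0, h1 = h1,
                            eps_sd = spec$eps_sd)
  }
  list(f = f, d = d, growth = growth)
}

# inverse of unpack_pars for generating start values / truth comparisons
pack_pars <- function(f, d, growth, spec, info = par_info(spec)) {
  K <- info$K
  fam <- spec$family
  s <- switch(fam,
    rdina = growth$b,
    rdina_cov = c(growth$b, growth$h),
    lg_uncond = c(if (info$sum_zero) c(growth$b[seq_len(K - 1)], growth$mu0) else growth$b,
                  growth$mu1),
    lg_cond = c(if (info$sum_zero) c(growth$b[seq_len(K - 1)], growth$mu0) else growth$b,
                growth$mu1, growth$h, growth$h1))
  setNames(c(f, d, s), info$names)
}

default_start <- function(spec, info = par_info(spec)) {
  # neutral start: g = 0.2, s = 0.2, flat growth
  f0 <- qlogis(0.2)
  d0 <- qlogis(0.8) - qlogis(0.2)
  setNames(c(rep(f0, info$J), rep(d0, info$J), rep(0, length(info$struct_names))),
           info$names)
}
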