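# Independent brute-force implementations used as oracles. Everything here
# is written as plain nested loops from the model definition, deliberately
# sharing no code with the package's vectorized likelihood.

gh01 <- function(n) {
  g <- statmod::gauss.quad(n, kind = "hermite")
  list(x = g$nodes * sqrt(2), w = g$weights / sqrt(pi))
}

# marginal log-likelihood of one person's T x J response matrix
oracle_person_ll <- function(y, z, q, f, d, g, tcodes, nquad, neps) {
  K <- ncol(q); J <- nrow(q); Tn <- nrow(y)
  qa <- gh01(nquad); qe <- gh01(neps)
  x0 <- if (g$sigma0 > 0) qa$x else 0
  w0 <- if (g$sigma0 > 0) qa$w else 1
  x1 <- if (g$sigma1 > 0) qa$x else 0
  w1 <- if (g$sigma1 > 0) qa$w else 1
  pats <- as.matrix(expand.grid(rep(list(0:1), K)))
  tot <- 0
  for (a in seq_along(x0)) for (b2 in seq_along(x1)) {
    prodt <- 1
    for (tt in seq_len(Tn)) {
      s <- 0
      for (m in seq_len(nrow(pats))) {
        pm <- 1
        for (k in seq_len(K)) {
          lin <- g$b[k] + g$h[k] * z + g$mu0 + g$h0 * z + g$sigma0 * x0[a] +
            (g$mu1 + g$h1 * z + g$sigma1 * x1[b2]) * tcodes[tt]
          pk <- if (g$eps_sd > 0) {
            sum(qe$w * plogis(lin + g$eps_sd * qe$x))
          } else plogis(lin)
          pm <- pm * if (pats[m, k] == 1) pk else 1 - pk
        }
        lik <- 1
        for (j in seq_len(J)) {
          if (is.na(y[tt, j])) next
          eta <- prod(pats[m, ]^q[j, ])
          pj <- plogis(f[j] + d[j] * eta)
          lik <- lik * if (y[tt, j] == 1) pj else 1 - pj
        }
        s <- s + pm * lik
      }
      prodt <- prodt * s
    }
    tot <- tot + w0[a] * w1[b2] * prodt
  }
  log(tot)
}

# posterior P(alpha_tk = 1 | all of person's responses), by enumeration of
# nodes x per-occasion patterns
oracle_posterior <- function(y, z, q, f, d, g, tcodes, nquad, neps) {
  K <- ncol(q); J <- nrow(q); Tn <- nrow(y)
  qa <- gh01(nquad); qe <- gh01(neps)
  x0 <- if (g$sigma0 > 0) qa$x else 0
  w0 <- if (g$sigma0 > 0) qa$w else 1
  x1 <- if (g$sigma1 > 0) qa$x else 0
  w1 <- if (g$sigma1 > 0) qa$w else 1
  pats <- as.matrix(expand.grid(rep(list(0:1), K)))
  M <- nrow(pats)
  num <- matrix(0, Tn, K); den <- 0
  for (a in seq_along(x0)) for (b2 in seq_along(x1)) {
    st <- matrix(0, Tn, M)
    for (tt in seq_len(Tn)) for (m in seq_len(M)) {
      pm <- 1
      for (k in seq_len(K)) {
        lin <- g$b[k] + g$h[k] * z + g$mu0 + g$h0 * z + g$sigma0 * x0[a] +
          (g$mu1 + g$h1 * z + g$sigma1 * x1[b2]) * tcodes[tt]
        pk <- if (g$eps_sd > 0) sum(qe$w * plogis(lin + g$eps_sd * qe$x))
        else plogis(lin)
        pm <- pm * if (pats[m, k] == 1) pk else 1 - pk
      }
      lik <- 1
      for (j in seq_len(J)) {
        if (is.na(y[tt, j])) next
        eta <- prod(pats[m, ]^q[j, ])
        pj <- plogis(f[j] + d[j] * eta)
        lik <- lik * if (y[tt, j] == 1) pj else 1 - pj
      }
      st[tt, m] <- pm * lik
    }
    wnode <- w0[a] * w1[b2] * prod(rowSums(st))
    den <- den + wnode
    for (tt in seq_len(Tn)) for (k in seq_len(K)) {
      num[tt, k] <- num[tt, k] +
        wnode * sum(st[tt, pats[, k] == 1]) / sum(st[tt, ])
    }
  }
  num / den
}

# random small model instance for property tests
random_instance <- function(seed, family = NULL) {
  set.seed(seed)
  K <- sample(1:2, 1)
  J <- sample(2:4, 1)
  Tn <- sample(1:2, 1)
  if (is.null(family)) family <- sample(c("rdina", "rdina_cov", "lg_uncond", "lg_cond"), 1)
  if (family %in% c("lg_uncond", "lg_cond")) Tn <- 2
  qm <- matrix(0L, J, K)
  qm[cbind(seq_len(J), sample(seq_len(K), J, replace = TRUE))] <- 1L
  if (K == 2 && J >= 3 && runif(1) < 0.5) qm[J, ] <- 1L  # multi-attribute item
  q <- qmatrix(qm)
  lg <- family %in% c("lg_uncond", "lg_cond")
  g <- growth_params(
    b = round(runif(K, -1, 1), 2),
    mu0 = if (lg) round(runif(1, -0.5, 0.5), 2) else 0,
    mu1 = if (lg) round(runif(1, -0.3, 0.3), 2) else 0,
    sigma0 = if (lg) 1 else 0, sigma1 = if (lg) sample(0:1, 1) else 0,
    h = if (family %in% c("rdina_cov", "lg_cond")) round(runif(K, -0.5, 0.5), 2) else 0,
    h0 = 0,
    h1 = if (family == "lg_cond") round(runif(1, -0.2, 0.2), 2) else 0,
    eps_sd = if (lg) sample(0:1, 1) else 0)
  f <- round(runif(J, -2, 0), 2)
  d <- round(runif(J, 0.5, 2.5), 2)
  n <- 5
  y <- array(sample(c(0L, 1L), n * Tn * J, replace = TRUE), c(n, Tn, J))
  if (runif(1) < 0.3) y[1, 1, 1] <- NA  # missing cell
  z <- if (family %in% c("rdina_cov", "lg_cond")) rbinom(n, 1, 0.5) else rep(0, n)
  tcodes <- seq_len(Tn) - 1
  spec <- lgcdm_spec(family, q, time_codes = tcodes, quad = 5, eps_quad = 5,
                     sigma0 = g$sigma0, sigma1 = g$sigma1, eps_sd = g$eps_sd)
  list(spec = spec, q = q, f = f, d = d, g = g, tcodes = tcodes,
       data = lgcdm_data(y, z = z, occasions = tcodes), y = y, z = z)
}
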