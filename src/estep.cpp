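#include <Rcpp.h>
using namespace Rcpp;

// Inner loops of the marginal likelihood / E-step for the latent growth
// diagnostic models. Persons are conditionally independent; within a person
// the attribute indicators are independent across attributes and occasions
// given the quadrature node (random intercept/slope) and covariate group.
//
// Layouts (column-major, as passed from R):
//   U1, U0 : n x T x K   block likelihoods P(y_block | alpha_k = 1/0), rescaled
//   P      : K x T x Z x N attribute probabilities per node (eps integrated out)
//   wn     : N node weights, zi : 1-based covariate-group index per person
//
// Returns per-person log-likelihood contributions (up to the rescaling shifts
// handled in R) and, when requested, the posterior sufficient statistics:
//   Abar : n x T x K  posterior P(alpha_itk = 1 | all responses of person i)
//   S1,S0: K x T x Z x N  node-resolved expected counts of alpha = 1 / 0.

// [[Rcpp::export]]
List estep_factored(NumericVector U1, NumericVector U0, NumericVector P,
                    NumericVector wn, IntegerVector zi,
                    int n, int T, int K, int Z, int N, bool want_stats) {
  const double *u1 = U1.begin(), *u0 = U0.begin(), *p = P.begin();
  NumericVector ll(n);
  NumericVector Abar(want_stats ? n * T * K : 0);
  NumericVector S1(want_stats ? K * T * Z * N : 0);
  NumericVector S0(want_stats ? K * T * Z * N : 0);
  std::vector<double> G(N);
  std::vector<double> abuf(want_stats ? (size_t)N * T * K : 0);

  for (int i = 0; i < n; ++i) {
    int z = zi[i] - 1;
    double Li = 0.0;
    for (int nn = 0; nn < N; ++nn) {
      double g = 1.0;
      const double *pn = p + (size_t)K * (T * (z + (size_t)Z * nn));
      for (int t = 0; t < T; ++t) {
        for (int k = 0; k < K; ++k) {
          double pk = pn[k + K * t];
          double a1 = u1[i + (size_t)n * (t + T * k)];
          double a0 = u0[i + (size_t)n * (t + T * k)];
          double c = pk * a1 + (1.0 - pk) * a0;
          g *= c;
          if (want_stats)
            abuf[nn + (size_t)N * (t + T * k)] = c > 0 ? pk * a1 / c : 0.0;
        }
      }
      G[nn] = wn[nn] * g;
      Li += G[nn];
    }
    if (Li < 1e-300) Li = 1e-300;
    ll[i] = std::log(Li);
    if (!want_stats) continue;
    for (int nn = 0; nn < N; ++nn) {
      double rho = G[nn] / Li;
      if (rho < 1e-300) continue;
      for (int t = 0; t < T; ++t) {
        for (int k = 0; k < K; ++k) {
          double a = abuf[nn + (size_t)N * (t + T * k)];
          Abar[i + (size_t)n * (t + T * k)] += rho * a;
          size_t sidx = k + (size_t)K * (t + T * (z + (size_t)Z * nn));
          S1[sidx] += rho * a;
          S0[sidx] += rho * (1.0 - a);
        }
      }
    }
  }
  return List::create(_["ll"] = ll, _["Abar"] = Abar,
                      _["S1"] = S1, _["S0"] = S0);
}

// General-Q counterpart: the occasion likelihood sums over all 2^K attribute
// patterns. AlphaPat is the M x K pattern matrix; Prior holds the pattern
// prior per occasion/covariate-group/node. Also returns the node-marginal
// pattern posteriors Pbar (n x T x M), needed for item posteriors when items
// load on more than one attribute.

// [[Rcpp::export]]
List estep_general(NumericVector U, NumericVector Prior, NumericVector wn,
                   IntegerVector zi, NumericMatrix AlphaPat,
                   int n, int T, int M, int K, int Z, int N, bool want_stats) {
  const double *u = U.begin(), *pr = Prior.begin();
  NumericVector ll(n);
  NumericVector Abar(want_stats ? n * T * K : 0);
  NumericVector S1(want_stats ? K * T * Z * N : 0);
  NumericVector S0(want_stats ? K * T * Z * N : 0);
  NumericVector Pbar(want_stats ? (size_t)n * T * M : 0);
  std::vector<double> G(N * T), Gprod(N);

  for (int i = 0; i < n; ++i) {
    int z = zi[i] - 1;
    double Li = 0.0;
    for (int nn = 0; nn < N; ++nn) {
      double g = 1.0;
      for (int t = 0; t < T; ++t) {
        const double *prn = pr + (size_t)M * (t + T * (z + (size_t)Z * nn));
        double s = 0.0;
        for (int m = 0; m < M; ++m)
          s += prn[m] * u[i + (size_t)n * (t + T * m)];
        G[nn + N * t] = s;
        g *= s;
      }
      Gprod[nn] = wn[nn] * g;
      Li += Gprod[nn];
    }
    if (Li < 1e-300) Li = 1e-300;
    ll[i] = std::log(Li);
    if (!want_stats) continue;
    for (int nn = 0; nn < N; ++nn) {
      double rho = Gprod[nn] / Li;
      if (rho < 1e-300) continue;
      for (int t = 0; t < T; ++t) {
        const double *prn = pr + (size_t)M * (t + T * (z + (size_t)Z * nn));
        double gt = G[nn + N * t];
        if (gt <= 0) continue;
        for (int m = 0; m < M; ++m) {
          double pim = prn[m] * u[i + (size_t)n * (t + T * m)] / gt;
          if (pim <= 0) continue;
          Pbar[i + (size_t)n * (t + (size_t)T * m)] += rho * pim;
          for (int k = 0; k < K; ++k) {
            double ak = AlphaPat(m, k);
            size_t sidx = k + (size_t)K * (t + T * (z + (size_t)Z * nn));
            if (ak > 0.5) {
              Abar[i + (size_t)n * (t + T * k)] += rho * pim;
              S1[sidx] += rho * pim;
            } else {
              S0[sidx] += rho * pim;
            }
          }
        }
      }
    }
  }
  return List::create(_["ll"] = ll, _["Abar"] = Abar,
                      _["S1"] = S1, _["S0"] = S0, _["Pbar"] = Pbar);
}
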