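// Batched selective-scan kernel. Semantics are defined by the sequential
// reference implementation selective_scan() in R/ssm_mamba.R (zero-order
// hold discretization, diagonal state matrix); this kernel only removes
// the interpreter overhead of the per-position recurrence. Shapes:
//   U, delta, dY : (B, T, d_inner)
//   Bt, Ct, dB, dC : (B, T, d_state)
//   A : d_state (negative reals), D : d_inner
#include <Rcpp.h>
using namespace Rcpp;

static inline double phi_of(double a, double A, double dl) {
  // (exp(dl*A) - 1)/A with the A -> 0 limit dl
  return (std::fabs(A) < 1e-12) ? dl : (a - 1.0) / A;
}

// A equal to the integer ladder -(1..ns) lets exp(dl*A[s]) be built
// iteratively from a single exp(-dl) per position
static inline bool is_ladder(const Rcpp::NumericVector &A) {
  for (int s = 0; s < A.size(); ++s) {
    if (A[s] != -(double)(s + 1)) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".scan_forward_cpp")]]
NumericVector scan_forward_cpp(NumericVector U, NumericVector delta,
                               NumericVector Bt, NumericVector Ct,
                               NumericVector A, NumericVector D) {
  IntegerVector dim = U.attr("dim");
  const int B = dim[0], T = dim[1], di = dim[2];
  const int ns = A.size();
  NumericVector Y(B * T * di);
  Y.attr("dim") = dim;
  const bool ladder = is_ladder(A);
  std::vector<double> x((size_t)B * di * ns, 0.0);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < di; ++i) {
      const size_t off_u = (size_t)B * (t + (size_t)T * i);
      for (int b = 0; b < B; ++b) {
        const double u = U[off_u + b];
        const double dl = delta[off_u + b];
        const double e1 = ladder ? std::exp(-dl) : 0.0;
        double ac = 1.0;
        double y = D[i] * u;
        double *xr = &x[((size_t)b + (size_t)B * i) * ns];
        for (int s = 0; s < ns; ++s) {
          const double a = ladder ? (ac *= e1) : std::exp(dl * A[s]);
          const size_t off_s = (size_t)B * (t + (size_t)T * s) + b;
          xr[s] = a * xr[s] + phi_of(a, A[s], dl) * Bt[off_s] * u;
          y += Ct[off_s] * xr[s];
        }
        Y[off_u + b] = y;
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".scan_backward_cpp")]]
List scan_backward_cpp(NumericVector U, NumericVector delta,
                       NumericVector Bt, NumericVector Ct,
                       NumericVector A, NumericVector D,
                       NumericVector dY) {
  IntegerVector dim = U.attr("dim");
  const int B = dim[0], T = dim[1], di = dim[2];
  const int ns = A.size();
  IntegerVector dimS = Bt.attr("dim");
  // recompute the state trajectory (cheaper than shipping it through R)
  const bool ladder = is_ladder(A);
  std::vector<double> xh((size_t)B * di * ns * (T + 1), 0.0);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < di; ++i) {
      const size_t off_u = (size_t)B * (t + (size_t)T * i);
      for (int b = 0; b < B; ++b) {
        const double u = U[off_u + b];
        const double dl = delta[off_u + b];
        const size_t r = ((size_t)b + (size_t)B * i) * ns;
        const double e1 = ladder ? std::exp(-dl) : 0.0;
        double ac = 1.0;
        const double *xp = &xh[r + (size_t)t * B * di * ns];
        double *xn = &xh[r + (size_t)(t + 1) * B * di * ns];
        for (int s = 0; s < ns; ++s) {
          const double a = ladder ? (ac *= e1) : std::exp(dl * A[s]);
          const size_t off_s = (size_t)B * (t + (size_t)T * s) + b;
          xn[s] = a * xp[s] + phi_of(a, A[s], dl) * Bt[off_s] * u;
        }
      }
    }
  }
  NumericVector dU(B * T * di), ddelta(B * T * di);
  dU.attr("dim") = dim; ddelta.attr("dim") = dim;
  NumericVector dB(B * T * ns), dC(B * T * ns);
  dB.attr("dim") = dimS; dC.attr("dim") = dimS;
  NumericVector dD(di);
  std::vector<double> lam((size_t)B * di * ns, 0.0);
  for (int t = T - 1; t >= 0; --t) {
    for (int i = 0; i < di; ++i) {
      const size_t off_u = (size_t)B * (t + (size_t)T * i);
      for (int b = 0; b < B; ++b) {
        const double u = U[off_u + b];
        const double dl = delta[off_u + b];
        const double dy = dY[off_u + b];
        dD[i] += u * dy;
        double du = D[i] * dy, ddl = 0.0;
        const double e1 = ladder ? std::exp(-dl) : 0.0;
        double ac = 1.0;
        const size_t r = ((size_t)b + (size_t)B * i) * ns;
        const double *xt = &xh[r + (size_t)(t + 1) * B * di * ns];
        const double *xp = &xh[r + (size_t)t * B * di * ns];
        double *lr = &lam[r];
        for (int s = 0; s < ns; ++s) {
          const double a = ladder ? (ac *= e1) : std::exp(dl * A[s]);
          const double ph = phi_of(a, A[s], dl);
          const size_t off_s = (size_t)B * (t + (size_t)T * s) + b;
          dC[off_s] += xt[s] * dy;
          const double l = lr[s] + Ct[off_s] * dy;
          du += l * ph * Bt[off_s];
          dB[off_s] += l * ph * u;
          ddl += l * a * (xp[s] * A[s] + Bt[off_s] * u);
          lr[s] = l * a;
        }
        dU[off_u + b] = du;
        ddelta[off_u + b] = ddl;
      }
    }
  }
  return List::create(_["dU"] = dU, _["ddelta"] = ddelta, _["dB"] = dB,
                      _["dC"] = dC, _["dD"] = dD);
}
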