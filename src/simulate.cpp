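#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of the gene-circuit reaction-diffusion system
//
//   dv[a,i]/dt = R[a] * g(u[a,i]) + D[a] * Lap(v[a,])_i - lam[a] * v[a,i]
//   u[a,i]     = sum_b W[a,b] * x[b,i] + h[a],   x = rbind(maternal, v)
//
// on a uniform 1-D row of nuclei with zero-flux boundaries (the ghost node
// copies the boundary value, so the Laplacian sums to zero over the row).
// sigmoidForm: 0 = algebraic sigmoid 0.5*(1 + u/sqrt(1+u^2)),
//              1 = logistic 1/(1+exp(-u)).
//
// The regulatory sum is accumulated regulator-by-regulator so that W is
// walked down its columns (column-major, cache-friendly).

static inline double gfun(double u, int form) {
    if (form == 1) return 1.0 / (1.0 + std::exp(-u));
    return 0.5 * (1.0 + u / std::sqrt(1.0 + u * u));
}

// [[Rcpp::export]]
NumericMatrix simulate_circuit_cpp(NumericMatrix W, NumericVector h,
                                   NumericVector R, NumericVector D,
                                   NumericVector lam, NumericMatrix maternal,
                                   NumericMatrix v0, double dt, int nsteps,
                                   double spacing, int sigmoidForm) {
    const int ng = v0.nrow();     // zygotic genes
    const int nn = v0.ncol();     // nuclei
    const int nm = maternal.nrow();

    if (W.nrow() != ng || W.ncol() != nm + ng)
        stop("W must be n_genes x (n_maternal + n_genes)");
    if (maternal.ncol() != nn)
        stop("maternal inputs and state must share the nucleus grid");

    const double inv_h2 = 1.0 / (spacing * spacing);
    NumericMatrix v = clone(v0);
    NumericMatrix vnew(ng, nn);
    std::vector<double> u(ng);
    const double *w = W.begin(), *m = maternal.begin();
    double *pv = v.begin(), *pn = vnew.begin();

    for (int s = 0; s < nsteps; ++s) {
        for (int i = 0; i < nn; ++i) {
            const double *vi = pv + (size_t)i * ng;
            for (int a = 0; a < ng; ++a) u[a] = h[a];
            for (int b = 0; b < nm; ++b) {
                const double xb = m[(size_t)i * nm + b];
                const double *wc = w + (size_t)b * ng;
                for (int a = 0; a < ng; ++a) u[a] += wc[a] * xb;
            }
            for (int b = 0; b < ng; ++b) {
                const double xb = vi[b];
                const double *wc = w + (size_t)(nm + b) * ng;
                for (int a = 0; a < ng; ++a) u[a] += wc[a] * xb;
            }
            const double *vl = pv + (size_t)((i == 0) ? 0 : i - 1) * ng;
            const double *vr = pv + (size_t)((i == nn - 1) ? nn - 1 : i + 1) * ng;
            double *ni = pn + (size_t)i * ng;
            for (int a = 0; a < ng; ++a) {
                const double lap = (vl[a] + vr[a] - 2.0 * vi[a]) * inv_h2;
                ni[a] = vi[a] + dt * (R[a] * gfun(u[a], sigmoidForm) +
                                      D[a] * lap - lam[a] * vi[a]);
            }
        }
        std::swap(pv, pn);
    }
    if (pv == v.begin()) return v;
    return vnew;
}
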