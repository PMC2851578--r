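#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the two-component normal mixture regression
//   y = mu + sum_j X_j a_j + e,   e ~ N(0, sigma2e I)
//   a_j | delta_j = 1 ~ N(0, v1),   a_j | delta_j = 0 ~ N(0, v2),
//   delta_j ~ Bernoulli(pi)
// Indicators are drawn from the two-component marginal with a_j integrated
// out; sigma2e has a flat scaled-inverse-chi-square full conditional
// (nu = -2).  The caller passes X column-centred and y standardized.

namespace {
// log marginal likelihood of the single-marker residual contribution
// with the effect integrated out over N(0, v)
inline double log_ml(double xtr, double xtx, double s2e, double v) {
    return -0.5 * std::log1p(v * xtx / s2e)
        + 0.5 * xtr * xtr / (s2e * (xtx + s2e / v));
}
} // namespace

// [[Rcpp::export]]
List bm_gibbs_cpp(NumericMatrix X, NumericVector y, double pi1, double v1,
                  double v2, int n_iter, int burn_in) {
    const int n = X.nrow(), M = X.ncol();
    if (y.size() != n) stop("length(y) != nrow(X)");
    if (burn_in >= n_iter) stop("burn_in must be < n_iter");
    if (n <= 2) stop("need n > 2");

    std::vector<double> xtx(M);
    for (int j = 0; j < M; ++j) {
        const double* xj = &X(0, j);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
        xtx[j] = s;
    }

    std::vector<double> a(M, 0.0), r(n);
    std::vector<int> delta(M, 0);
    double mu = mean(y);
    for (int i = 0; i < n; ++i) r[i] = y[i] - mu;
    double sigma2e = 0.0;
    for (int i = 0; i < n; ++i) sigma2e += r[i] * r[i];
    sigma2e /= (2.0 * (n - 1));

    std::vector<double> a_sum(M, 0.0), d_sum(M, 0.0);
    double mu_sum = 0.0;
    NumericVector s2e_trace(n_iter);
    const double logpi1 = std::log(pi1), logpi0 = std::log1p(-pi1);
    int kept = 0;

    for (int it = 0; it < n_iter; ++it) {
        // intercept, flat prior
        double rbar = 0.0;
        for (int i = 0; i < n; ++i) rbar += r[i];
        rbar /= n;
        double mu_new = R::rnorm(rbar + mu, std::sqrt(sigma2e / n));
        double shift = mu - mu_new;
        for (int i = 0; i < n; ++i) r[i] += shift;
        mu = mu_new;

        for (int j = 0; j < M; ++j) {
            if (xtx[j] <= 0.0) continue;  // monomorphic column: effect stays 0
            const double* xj = &X(0, j);
            double xtr = 0.0;
            for (int i = 0; i < n; ++i) xtr += xj[i] * r[i];
            xtr += a[j] * xtx[j];         // residual with marker j excluded
            const double C1 = xtx[j] + sigma2e / v1;
            const double C0 = xtx[j] + sigma2e / v2;
            double lw1 = logpi1 - 0.5 * std::log1p(v1 * xtx[j] / sigma2e)
                + 0.5 * xtr * xtr / (sigma2e * C1);
            double lw0 = logpi0 - 0.5 * std::log1p(v2 * xtx[j] / sigma2e)
                + 0.5 * xtr * xtr / (sigma2e * C0);
            double p1 = 1.0 / (1.0 + std::exp(lw0 - lw1));
            int d = (unif_rand() < p1) ? 1 : 0;
            const double C = d ? C1 : C0;
            double a_new = R::rnorm(xtr / C, std::sqrt(sigma2e / C));
            double diff = a[j] - a_new;
            if (diff != 0.0)
                for (int i = 0; i < n; ++i) r[i] += xj[i] * diff;
            a[j] = a_new;
            delta[j] = d;
        }

        double rss = 0.0;
        for (int i = 0; i < n; ++i) rss += r[i] * r[i];
        sigma2e = rss / R::rchisq((double) n - 2.0);
        s2e_trace[it] = sigma2e;

        if (it >= burn_in) {
            ++kept;
            for (int j = 0; j < M; ++j) {
                a_sum[j] += a[j];
                d_sum[j] += delta[j];
            }
            mu_sum += mu;
        }
        if (it % 64 == 0) Rcpp::checkUserInterrupt();
    }

    NumericVector a_post(M), incl(M);
    for (int j = 0; j < M; ++j) {
        a_post[j] = a_sum[j] / kept;
        incl[j] = d_sum[j] / kept;
    }
    return List::create(_["effects"] = a_post,
                        _["inclusion_prob"] = incl,
                        _["mu"] = mu_sum / kept,
                        _["sigma2e_trace"] = s2e_trace);
}

// Variant with per-marker sampled QTL variances (the scheme of the cited
// Bayesian method): a marker is associated with a QTL with prior
// probability pi1; its effect variance then has a scaled
// inverse-chi-square prior with df nu0 and mean v1, while non-associated
// markers keep the fixed small variance v2.  The indicator and variance
// are updated jointly by Metropolis-Hastings with proposals from the
// prior (acceptance ratio = marginal-likelihood ratio with the effect
// integrated out), followed by a Gibbs draw of the effect.
// [[Rcpp::export]]
List bm_gibbs_mh_cpp(NumericMatrix X, NumericVector y, double pi1,
                     double v1, double v2, double nu0, int n_mh,
                     int n_iter, int burn_in) {
    const int n = X.nrow(), M = X.ncol();
    if (y.size() != n) stop("length(y) != nrow(X)");
    if (burn_in >= n_iter) stop("burn_in must be < n_iter");
    if (n <= 2) stop("need n > 2");
    const double S0 = v1 * (nu0 - 2.0);   // nu0*s2 so that prior mean = v1

    std::vector<double> xtx(M);
    for (int j = 0; j < M; ++j) {
        const double* xj = &X(0, j);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
        xtx[j] = s;
    }

    std::vector<double> a(M, 0.0), r(n), vj(M, v2);
    std::vector<int> delta(M, 0);
    double mu = mean(y);
    for (int i = 0; i < n; ++i) r[i] = y[i] - mu;
    double sigma2e = 0.0;
    for (int i = 0; i < n; ++i) sigma2e += r[i] * r[i];
    sigma2e /= (2.0 * (n - 1));

    std::vector<double> a_sum(M, 0.0), d_sum(M, 0.0);
    double mu_sum = 0.0;
    NumericVector s2e_trace(n_iter);
    int kept = 0;

    for (int it = 0; it < n_iter; ++it) {
        double rbar = 0.0;
        for (int i = 0; i < n; ++i) rbar += r[i];
        rbar /= n;
        double mu_new = R::rnorm(rbar + mu, std::sqrt(sigma2e / n));
        double shift = mu - mu_new;
        for (int i = 0; i < n; ++i) r[i] += shift;
        mu = mu_new;

        for (int j = 0; j < M; ++j) {
            if (xtx[j] <= 0.0) continue;
            const double* xj = &X(0, j);
            double xtr = 0.0;
            for (int i = 0; i < n; ++i) xtr += xj[i] * r[i];
            xtr += a[j] * xtx[j];
            double ll_cur = log_ml(xtr, xtx[j], sigma2e, vj[j]);
            for (int m = 0; m < n_mh; ++m) {
                int d_prop = (unif_rand() < pi1) ? 1 : 0;
                double v_prop = d_prop ? S0 / R::rchisq(nu0) : v2;
                double ll_prop = log_ml(xtr, xtx[j], sigma2e, v_prop);
                if (std::log(unif_rand()) < ll_prop - ll_cur) {
                    vj[j] = v_prop;
                    delta[j] = d_prop;
                    ll_cur = ll_prop;
                }
            }
            const double C = xtx[j] + sigma2e / vj[j];
            double a_new = R::rnorm(xtr / C, std::sqrt(sigma2e / C));
            double diff = a[j] - a_new;
            if (diff != 0.0)
                for (int i = 0; i < n; ++i) r[i] += xj[i] * diff;
            a[j] = a_new;
        }

        double rss = 0.0;
        for (int i = 0; i < n; ++i) rss += r[i] * r[i];
        sigma2e = rss / R::rchisq((double) n - 2.0);
        s2e_trace[it] = sigma2e;

        if (it >= burn_in) {
            ++kept;
            for (int j = 0; j < M; ++j) {
                a_sum[j] += a[j];
                d_sum[j] += delta[j];
            }
            mu_sum += mu;
        }
        if (it % 64 == 0) Rcpp::checkUserInterrupt();
    }

    NumericVector a_post(M), incl(M);
    for (int j = 0; j < M; ++j) {
        a_post[j] = a_sum[j] / kept;
        incl[j] = d_sum[j] / kept;
    }
    return List::create(_["effects"] = a_post,
                        _["inclusion_prob"] = incl,
                        _["mu"] = mu_sum / kept,
                        _["sigma2e_trace"] = s2e_trace);
}
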