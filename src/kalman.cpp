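#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

// Scalar-state Kalman recursions for one subject, operating on a row range
// [row0, row0+T) of the stacked visit-by-variable matrix `values` (NA =
// missing cell).  The state is the q=1 latent factor; the transition is a
// random walk whose innovation variance before visit t equals tau[t], the
// elapsed time since the previous visit (for the first visit, since the
// prior's time point).  The measurement update uses Sherman--Morrison, so a
// visit costs O(p) regardless of the number of observed components.
//
// If `store` is true the per-visit predicted/filtered moments and the
// innovations standardised by the diagonal of F_t are written out.
static double filter_range(const double* values, int vnrow, int p,
                           int row0, int T,
                           const double* tau, int tau0,
                           const double* f, const double* d,
                           double init_mean, double init_var,
                           bool store,
                           double* m_pred_v, double* a_pred_v,
                           double* m_filt_v, double* a_filt_v,
                           double* std_innov /* T x p, column-major */)
{
    double m = init_mean, a = init_var, ll = 0.0;

    for (int t = 0; t < T; ++t) {
        a += tau[tau0 + t];
        const double m_pred = m, a_pred = a;

        double s1 = 0.0, s2 = 0.0, q = 0.0, logdet_d = 0.0;
        int mt = 0;
        for (int k = 0; k < p; ++k) {
            const double yk = values[(size_t)k * vnrow + row0 + t];
            if (ISNAN(yk)) {
                if (store) std_innov[(size_t)k * T + t] = NA_REAL;
                continue;
            }
            const double v = yk - f[k] * m_pred;
            const double fk = f[k], dk = d[k];
            s1 += fk * fk / dk;
            s2 += fk * v / dk;
            q  += v * v / dk;
            logdet_d += std::log(dk);
            ++mt;
            if (store)
                std_innov[(size_t)k * T + t] = v / std::sqrt(fk * fk * a_pred + dk);
        }

        if (mt > 0) {
            const double denom = 1.0 + a_pred * s1;
            ll += -0.5 * (mt * LOG2PI + logdet_d + std::log(denom)
                          + (q - a_pred * s2 * s2 / denom));
            m = m_pred + a_pred * s2 / denom;
            a = a_pred / denom;
        }
        if (store) {
            m_pred_v[t] = m_pred; a_pred_v[t] = a_pred;
            m_filt_v[t] = m;      a_filt_v[t] = a;
        }
    }
    return ll;
}

// Reverse-mode (adjoint) gradient of one subject's filter log-likelihood
// with respect to the loadings f, d fixed.  The forward pass stores the
// per-visit predicted moments and the Sherman--Morrison scalars; the
// backward pass propagates adjoints of the filtered mean/variance.
static double filter_grad_range(const double* values, int vnrow, int p,
                                int row0, int T,
                                const double* tau, int tau0,
                                const double* f, const double* d,
                                double init_mean, double init_var,
                                double* grad /* accumulated, length p */)
{
    std::vector<double> mp(T), ap(T), S1(T), S2(T), DEN(T);
    double m = init_mean, a = init_var, ll = 0.0;

    for (int t = 0; t < T; ++t) {
        a += tau[tau0 + t];
        const double m_pred = m, a_pred = a;
        double s1 = 0.0, s2 = 0.0, q = 0.0, logdet_d = 0.0;
        int mt = 0;
        for (int k = 0; k < p; ++k) {
            const double yk = values[(size_t)k * vnrow + row0 + t];
            if (ISNAN(yk)) continue;
            const double v = yk - f[k] * m_pred;
            s1 += f[k] * f[k] / d[k];
            s2 += f[k] * v / d[k];
            q  += v * v / d[k];
            logdet_d += std::log(d[k]);
            ++mt;
        }
        mp[t] = m_pred; ap[t] = a_pred;
        S1[t] = s1; S2[t] = s2;
        if (mt > 0) {
            const double den = 1.0 + a_pred * s1;
            DEN[t] = den;
            ll += -0.5 * (mt * LOG2PI + logdet_d + std::log(den)
                          + (q - a_pred * s2 * s2 / den));
            m = m_pred + a_pred * s2 / den;
            a = a_pred / den;
        } else {
            DEN[t] = NA_REAL;  // marks a prediction-only visit
        }
    }

    double lm = 0.0, la = 0.0;   // adjoints of the filtered mean / variance
    for (int t = T - 1; t >= 0; --t) {
        if (ISNAN(DEN[t])) continue;   // no measurement update at this visit
        const double m_pred = mp[t], a_pred = ap[t];
        const double s1 = S1[t], s2 = S2[t], den = DEN[t];
        // partials of the visit log-likelihood term
        const double dL_ds1 = -a_pred / (2.0 * den)
            - a_pred * a_pred * s2 * s2 / (2.0 * den * den);
        const double dL_ds2 = a_pred * s2 / den;
        const double dL_dm  = s2 / den;     // via v_k = y_k - f_k m_pred
        const double dL_da  = -s1 / (2.0 * den)
            + s2 * s2 / (2.0 * den)
            - a_pred * s1 * s2 * s2 / (2.0 * den * den);
        // partials of the update m' = m_pred + a_pred s2 / den, a' = a_pred/den
        const double dmp_dm  = 1.0 - a_pred * s1 / den;
        const double dmp_da  = s2 / (den * den);
        const double dmp_ds2 = a_pred / den;
        const double dmp_ds1 = -a_pred * a_pred * s2 / (den * den);
        const double dap_da  = 1.0 / (den * den);
        const double dap_ds1 = -a_pred * a_pred / (den * den);

        const double ws1 = dL_ds1 + lm * dmp_ds1 + la * dap_ds1;
        const double ws2 = dL_ds2 + lm * dmp_ds2;
        const double wq  = -0.5;
        for (int k = 0; k < p; ++k) {
            const double yk = values[(size_t)k * vnrow + row0 + t];
            if (ISNAN(yk)) continue;
            const double v = yk - f[k] * m_pred;
            grad[k] += ws1 * (2.0 * f[k] / d[k])
                     + ws2 * ((v - f[k] * m_pred) / d[k])
                     + wq  * (-2.0 * v * m_pred / d[k]);
        }
        const double lm_new = dL_dm + lm * dmp_dm;
        const double la_new = dL_da + lm * dmp_da + la * dap_da;
        lm = lm_new;
        la = la_new;
        // the time update (m_pred = m_prev, a_pred = a_prev + tau) passes
        // the adjoints through unchanged
    }
    return ll;
}

// Panel log-likelihood and its gradient in the loadings, in one pass.
// [[Rcpp::export]]
List panel_loglik_grad_cpp(NumericMatrix values, IntegerVector start0,
                           IntegerVector len, NumericVector tau,
                           NumericVector f, NumericVector d,
                           double init_mean, double init_var)
{
    const int n = start0.size(), p = values.ncol();
    NumericVector grad(p);
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
        ll += filter_grad_range(values.begin(), values.nrow(), p,
                                start0[i], len[i], tau.begin(), start0[i],
                                f.begin(), d.begin(), init_mean, init_var,
                                grad.begin());
    return List::create(_["loglik"] = ll, _["gradient"] = grad);
}

// Exact Gaussian log-likelihood of a stacked panel under the random-walk
// one-factor model; subjects are independent so the panel value is the sum
// of per-subject filter likelihoods.
// [[Rcpp::export]]
double panel_loglik_cpp(NumericMatrix values, IntegerVector start0,
                        IntegerVector len, NumericVector tau,
                        NumericVector f, NumericVector d,
                        double init_mean, double init_var)
{
    const int n = start0.size();
    double ll = 0.0;
    const double* v = values.begin();
    for (int i = 0; i < n; ++i)
        ll += filter_range(v, values.nrow(), values.ncol(),
                           start0[i], len[i], tau.begin(), start0[i],
                           f.begin(), d.begin(), init_mean, init_var, false,
                           nullptr, nullptr, nullptr, nullptr, nullptr);
    return ll;
}

// Full filtering + fixed-interval (RTS) smoothing pass over the panel.
// Returns per-visit moments aligned with the rows of `values`.
// [[Rcpp::export]]
List kalman_panel_cpp(NumericMatrix values, IntegerVector start0,
                      IntegerVector len, NumericVector tau,
                      NumericVector f, NumericVector d,
                      double init_mean, double init_var)
{
    const int n = start0.size(), p = values.ncol(), nrow = values.nrow();
    NumericVector m_pred(nrow), a_pred(nrow), m_filt(nrow), a_filt(nrow);
    NumericVector m_sm(nrow), a_sm(nrow), ll_subj(n);
    NumericMatrix std_innov(nrow, p);

    std::vector<double> mp, ap, mf, af, si;
    for (int i = 0; i < n; ++i) {
        const int T = len[i], r0 = start0[i];
        mp.assign(T, 0.0); ap.assign(T, 0.0);
        mf.assign(T, 0.0); af.assign(T, 0.0);
        si.assign((size_t)T * p, NA_REAL);
        ll_subj[i] = filter_range(values.begin(), nrow, p, r0, T,
                                  tau.begin(), r0, f.begin(), d.begin(),
                                  init_mean, init_var, true,
                                  mp.data(), ap.data(), mf.data(), af.data(),
                                  si.data());
        // backward RTS pass; smoother gain C_t = a_filt[t] / a_pred[t+1]
        std::vector<double> ms(T), vs(T);
        ms[T - 1] = mf[T - 1]; vs[T - 1] = af[T - 1];
        for (int t = T - 2; t >= 0; --t) {
            const double C = af[t] / ap[t + 1];
            ms[t] = mf[t] + C * (ms[t + 1] - mp[t + 1]);
            vs[t] = af[t] + C * C * (vs[t + 1] - ap[t + 1]);
        }
        for (int t = 0; t < T; ++t) {
            m_pred[r0 + t] = mp[t]; a_pred[r0 + t] = ap[t];
            m_filt[r0 + t] = mf[t]; a_filt[r0 + t] = af[t];
            m_sm[r0 + t] = ms[t];   a_sm[r0 + t] = vs[t];
            for (int k = 0; k < p; ++k)
                std_innov(r0 + t, k) = si[(size_t)k * T + t];
        }
    }
    const double loglik_total = sum(ll_subj);
    return List::create(_["loglik"] = loglik_total,
                        _["loglik_subject"] = ll_subj,
                        _["pred_mean"] = m_pred, _["pred_var"] = a_pred,
                        _["filt_mean"] = m_filt, _["filt_var"] = a_filt,
                        _["smooth_mean"] = m_sm, _["smooth_var"] = a_sm,
                        _["std_innov"] = std_innov);
}

// Log-likelihood of the non-dynamic (confirmatory) one-factor model: every
// visit is an independent draw with factor ~ N(0, 1), covariance ff' + diag d
// restricted to the observed components.
// [[Rcpp::export]]
double cfm_loglik_cpp(NumericMatrix values, NumericVector f, NumericVector d)
{
    const int nrow = values.nrow(), p = values.ncol();
    double ll = 0.0;
    for (int r = 0; r < nrow; ++r) {
        double s1 = 0.0, s2 = 0.0, q = 0.0, logdet_d = 0.0;
        int mt = 0;
        for (int k = 0; k < p; ++k) {
            const double yk = values(r, k);
            if (ISNAN(yk)) continue;
            const double fk = f[k], dk = d[k];
            s1 += fk * fk / dk;
            s2 += fk * yk / dk;
            q  += yk * yk / dk;
            logdet_d += std::log(dk);
            ++mt;
        }
        if (mt > 0) {
            const double denom = 1.0 + s1;
            ll += -0.5 * (mt * LOG2PI + logdet_d + std::log(denom)
                          + (q - s2 * s2 / denom));
        }
    }
    return ll;
}

// Cross-sectional regression factor scores gamma' y per visit, with gamma
// computed on the observed subset of each visit; second column holds the
// posterior variance 1 - gamma' f.
// [[Rcpp::export]]
NumericMatrix cfm_scores_cpp(NumericMatrix values, NumericVector f,
                             NumericVector d)
{
    const int nrow = values.nrow(), p = values.ncol();
    NumericMatrix out(nrow, 2);
    for (int r = 0; r < nrow; ++r) {
        double s1 = 0.0, s2 = 0.0;
        int mt = 0;
        for (int k = 0; k < p; ++k) {
            const double yk = values(r, k);
            if (ISNAN(yk)) continue;
            s1 += f[k] * f[k] / d[k];
            s2 += f[k] * yk / d[k];
            ++mt;
        }
        if (mt > 0) {
            out(r, 0) = s2 / (1.0 + s1);
            out(r, 1) = 1.0 / (1.0 + s1);
        } else {
            out(r, 0) = 0.0;
            out(r, 1) = 1.0;
        }
    }
    return out;
}
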