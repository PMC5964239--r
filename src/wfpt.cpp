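#include <Rcpp.h>
using namespace Rcpp;

// First-passage density of a unit-variance Wiener process between absorbing
// boundaries 0 and a, evaluated at the LOWER boundary. Parameters: decision
// time t (> 0), drift v, boundary separation a, relative start w in (0,1).
// Series truncation follows the usual small-time / large-time switch with the
// number of terms chosen from the requested absolute error `err` on the
// normalized (a = 1, v = 0) density.
static double wfpt_lower(double t, double v, double a, double w, double err)
{
    if (t <= 0.0 || !R_finite(t)) return 0.0;
    double tt = t / (a * a); // normalized time

    // terms needed for the large-time series
    double kl;
    if (M_PI * tt * err < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    // terms needed for the small-time series
    double ks;
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }

    double p = 0.0;
    if (ks < kl) {
        int K = (int)std::ceil(ks);
        int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
        for (int k = lo; k <= hi; ++k) {
            double wk = w + 2.0 * k;
            p += wk * std::exp(-wk * wk / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    if (p < 0.0) p = 0.0; // truncation can leave tiny negatives
    return p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

// 11-point Gauss-Legendre nodes/weights on [-1, 1], used to integrate over a
// uniform starting-point range of width sz.
static const double GL_X[11] = {
    -0.9782286581460570, -0.8870625997680953, -0.7301520055740494,
    -0.5190961292068118, -0.2695431559523450, 0.0,
     0.2695431559523450,  0.5190961292068118,  0.7301520055740494,
     0.8870625997680953,  0.9782286581460570};
static const double GL_W[11] = {
    0.0556685671161737, 0.1255803694649046, 0.1862902109277343,
    0.2331937645919905, 0.2628045445102467, 0.2729250867779006,
    0.2628045445102467, 0.2331937645919905, 0.1862902109277343,
    0.1255803694649046, 0.0556685671161737};

static double wfpt_one(double t, bool upper, double a, double v, double t0,
                       double z, double sz, double err)
{
    double td = t - t0;
    if (td <= 0.0) return 0.0;
    // upper-boundary density by reflection: f_up(t; v, w) = f_low(t; -v, 1-w)
    double vv = upper ? -v : v;
    double w0 = upper ? 1.0 - z : z;
    if (sz <= 0.0) return wfpt_lower(td, vv, a, w0, err);
    double s = 0.0;
    for (int i = 0; i < 11; ++i) {
        double w = w0 + 0.5 * sz * GL_X[i];
        s += GL_W[i] * wfpt_lower(td, vv, a, w, err);
    }
    return 0.5 * s; // weights sum to 2; uniform average over the range
}

// [[Rcpp::export]]
NumericVector wfpt_d_cpp(NumericVector t, LogicalVector upper,
                         NumericVector a, NumericVector v, NumericVector t0,
                         NumericVector z, NumericVector sz, double err)
{
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        out[i] = wfpt_one(t[i], upper[i % upper.size()], a[i % a.size()],
                          v[i % v.size()], t0[i % t0.size()], z[i % z.size()],
                          sz[i % sz.size()], err);
    }
    return out;
}

// [[Rcpp::export]]
double wfpt_sumlog_cpp(NumericVector t, LogicalVector upper,
                       NumericVector a, NumericVector v, NumericVector t0,
                       NumericVector z, NumericVector sz, double err)
{
    int n = t.size();
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
        double d = wfpt_one(t[i], upper[i % upper.size()], a[i % a.size()],
                            v[i % v.size()], t0[i % t0.size()], z[i % z.size()],
                            sz[i % sz.size()], err);
        if (d <= 0.0 || !R_finite(d)) return R_NegInf;
        ll += std::log(d);
    }
    return ll;
}

// Euler-Maruyama simulation of the two-boundary decision diffusion (unit
// diffusion coefficient). Returns boundary hit (1 = upper/"long") and total
// RT including non-decision time t0. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export]]
List ddm_sim_cpp(int n, NumericVector a, NumericVector v, NumericVector t0,
                 NumericVector z, double dt, double max_t)
{
    RNGScope scope;
    IntegerVector choice(n);
    NumericVector rt(n);
    double sdt = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double ai = a[i % a.size()], vi = v[i % v.size()];
        double x = z[i % z.size()] * ai;
        double tcur = 0.0;
        int hit = -1;
        while (hit < 0 && tcur < max_t) {
            double xn = x + vi * dt + sdt * norm_rand();
            tcur += dt;
            if (xn >= ai) { hit = 1; }
            else if (xn <= 0.0) { hit = 0; }
            else {
                // Brownian-bridge correction: probability the path crossed a
                // boundary inside the step although both endpoints are interior
                double pu = std::exp(-2.0 * (ai - x) * (ai - xn) / dt);
                double pl = std::exp(-2.0 * x * xn / dt);
                double u = unif_rand();
                if (u < pu) hit = 1;
                else if (u < pu + pl) hit = 0;
            }
            x = xn;
        }
        choice[i] = (hit >= 0) ? hit : (x > ai / 2.0 ? 1 : 0);
        rt[i] = tcur + t0[i % t0.size()];
    }
    return List::create(_["upper"] = choice, _["t"] = rt);
}

// Endpoint of the first-stage accumulator dx = A dt + m sqrt(A) dB after
// n_steps Euler-Maruyama steps of size dt (full path simulated).
// [[Rcpp::export]]
NumericVector accumulator_sim_cpp(int n, double A, double m, int n_steps,
                                  double dt)
{
    RNGScope scope;
    NumericVector out(n);
    double drift = A * dt, diff = m * std::sqrt(A) * std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double x = 0.0;
        for (int s = 0; s < n_steps; ++s) x += drift + diff * norm_rand();
        out[i] = x;
    }
    return out;
}

// Label 8-connected components of a logical matrix (frequency x time plane).
// Returns an integer matrix; 0 = background, clusters numbered from 1.
// [[Rcpp::export]]
IntegerMatrix label_clusters_cpp(LogicalMatrix mask)
{
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> stack;
    int cur = 0;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j) || lab(i, j) != 0) continue;
            ++cur;
            stack.push_back(j * nr + i);
            lab(i, j) = cur;
            while (!stack.empty()) {
                int idx = stack.back();
                stack.pop_back();
                int ci = idx % nr, cj = idx / nr;
                for (int dj = -1; dj <= 1; ++dj) {
                    for (int di = -1; di <= 1; ++di) {
                        if (di == 0 && dj == 0) continue;
                        int ni = ci + di, nj = cj + dj;
                        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
                        if (mask(ni, nj) && lab(ni, nj) == 0) {
                            lab(ni, nj) = cur;
                            stack.push_back(nj * nr + ni);
                        }
                    }
                }
            }
        }
    }
    return lab;
}
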