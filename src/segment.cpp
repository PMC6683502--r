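#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Penalized changepoint solvers for the biweight (bounded squared-error) loss
//   gamma(u) = min(u^2, K^2)
// minimizing  sum_t gamma(y_t - theta_seg(t)) + beta * (#changepoints).
// With K large relative to the data range the loss never saturates and the
// objective reduces to ordinary least-squares segmentation.
//
// Two solvers share this objective:
//   * fpop_biweight: exact functional-pruning DP.  The cost-to-come
//     Q_t(theta) is propagated as a piecewise quadratic in the current
//     segment level theta; clipping against F_{t-1} + beta implements the
//     changepoint option.  Effectively linear-time on CNV-like profiles.
//   * dp_biweight: plain O(n^2) DP over the last changepoint position, each
//     segment cost evaluated exactly by a knot sweep.  Slow; test oracle.

// ---------------------------------------------------------------------------
// Exact minimization of sum_i min((y_i - theta)^2, K^2) over theta.
// ys must be sorted ascending.  The loss is piecewise quadratic in theta with
// knots at y_i +/- K; between consecutive knots the active (non-saturated)
// set is constant and the unconstrained minimizer is the active-point mean.
static void bw_cost_sorted(const std::vector<double>& ys, double K,
                           double& best_cost, double& best_theta) {
    const int m = (int)ys.size();
    const double K2 = K * K;
    if (m == 0) { best_cost = 0.0; best_theta = NA_REAL; return; }

    std::vector<double> ev(2 * m);
    for (int i = 0; i < m; ++i) { ev[i] = ys[i] - K; ev[m + i] = ys[i] + K; }
    std::inplace_merge(ev.begin(), ev.begin() + m, ev.end());

    best_cost = R_PosInf; best_theta = ys[0];
    int lo = 0, hi = 0;            // active set = ys[lo..hi)
    double s1 = 0.0, s2 = 0.0;     // sums of active ys and ys^2
    for (int k = 0; k < 2 * m; ++k) {
        double pos = ev[k];
        // the active set for theta in [ev[k], ev[k+1]]: entered by ev[k],
        // not exited before ev[k+1].  A point whose exit knot equals ev[k]
        // contributes exactly K^2 at that theta, so dropping it is exact.
        while (hi < m && ys[hi] - K <= pos) { s1 += ys[hi]; s2 += ys[hi] * ys[hi]; ++hi; }
        while (lo < hi && ys[lo] + K <= pos) { s1 -= ys[lo]; s2 -= ys[lo] * ys[lo]; ++lo; }
        double L = pos;
        double R = (k + 1 < 2 * m) ? ev[k + 1] : pos;
        int cnt = hi - lo;
        double cost, theta;
        if (cnt == 0) {
            cost = m * K2; theta = L;
        } else {
            theta = s1 / cnt;
            if (theta < L) theta = L;
            if (theta > R) theta = R;
            cost = (s2 - 2.0 * theta * s1 + cnt * theta * theta) + (m - cnt) * K2;
        }
        if (cost < best_cost) { best_cost = cost; best_theta = theta; }
    }
}

// [[Rcpp::export(name = ".bw_fit")]]
List bw_fit(NumericVector y, double K) {
    std::vector<double> ys(y.begin(), y.end());
    std::sort(ys.begin(), ys.end());
    double cost, theta;
    bw_cost_sorted(ys, K, cost, theta);
    return List::create(_["cost"] = cost, _["theta"] = theta);
}

// ---------------------------------------------------------------------------
// O(n^2) dynamic program with exact segment costs.  Oracle-grade, not fast.
// [[Rcpp::export(name = ".dp_biweight")]]
List dp_biweight(NumericVector y, double beta, double K) {
    const int n = y.size();
    std::vector<double> F(n + 1, 0.0);
    std::vector<int> back(n + 1, 1);
    for (int t = 1; t <= n; ++t) {
        std::vector<double> seg;           // sorted y[s..t] as s decreases
        seg.reserve(t);
        double best = R_PosInf; int bests = t;
        for (int s = t; s >= 1; --s) {
            double v = y[s - 1];
            seg.insert(std::upper_bound(seg.begin(), seg.end(), v), v);
            double cost, theta;
            bw_cost_sorted(seg, K, cost, theta);
            double cand = F[s - 1] + cost + (s > 1 ? beta : 0.0);
            // <= with s descending: ties resolve to the smallest s, i.e. the
            // longest last segment / fewest changepoints
            if (cand <= best) { best = cand; bests = s; }
        }
        F[t] = best; back[t] = bests;
    }
    std::vector<int> starts;
    for (int t = n; t >= 1; t = back[t] - 1) starts.push_back(back[t]);
    std::reverse(starts.begin(), starts.end());
    return List::create(_["starts"] = wrap(starts), _["objective"] = F[n]);
}

// ---------------------------------------------------------------------------
// Functional-pruning DP.  Q_t(theta) kept as ordered quadratic pieces.
struct Piece {
    double l, r;        // interval [l, r]
    double a, b, c;     // a*theta^2 + b*theta + c
    int label;          // start index of the last segment for this candidate
};

static inline double pval(const Piece& p, double x) {
    return (p.a * x + p.b) * x + p.c;
}

static void piece_min(const Piece& p, double& val, double& arg) {
    if (p.a > 0.0) {
        double v = -p.b / (2.0 * p.a);
        if (v < p.l) v = p.l;
        if (v > p.r) v = p.r;
        arg = v; val = pval(p, v);
    } else {
        double vl = pval(p, p.l), vr = pval(p, p.r);
        if (vl <= vr) { val = vl; arg = p.l; } else { val = vr; arg = p.r; }
    }
}

// [[Rcpp::export(name = ".fpop_biweight")]]
List fpop_biweight(NumericVector y, double beta, double K) {
    const int n = y.size();
    const double K2 = K * K;
    double ymin = *std::min_element(y.begin(), y.end());
    double ymax = *std::max_element(y.begin(), y.end());
    const double LO = ymin - K - 1.0, HI = ymax + K + 1.0;

    std::vector<Piece> Q;
    Q.push_back({LO, HI, 0.0, 0.0, 0.0, 1});
    std::vector<double> F(n + 1);
    std::vector<int> lab(n + 1);

    std::vector<Piece> tmp;
    for (int t = 1; t <= n; ++t) {
        if (t > 1) {
            // clip: Qtil = min(Q, F[t-1] + beta), new-segment label t
            const double cv = F[t - 1] + beta;
            tmp.clear();
            for (const Piece& p : Q) {
                if (p.a <= 0.0) {
                    if (p.c <= cv) tmp.push_back(p);
                    else tmp.push_back({p.l, p.r, 0.0, 0.0, cv, t});
                    continue;
                }
                double vmin = p.c - p.b * p.b / (4.0 * p.a);
                if (vmin >= cv) {
                    tmp.push_back({p.l, p.r, 0.0, 0.0, cv, t});
                    continue;
                }
                double disc = p.b * p.b - 4.0 * p.a * (p.c - cv);
                double sq = std::sqrt(std::max(disc, 0.0));
                double r1 = (-p.b - sq) / (2.0 * p.a);
                double r2 = (-p.b + sq) / (2.0 * p.a);
                if (r1 > p.l)
                    tmp.push_back({p.l, std::min(r1, p.r), 0.0, 0.0, cv, t});
                double il = std::max(p.l, r1), ir = std::min(p.r, r2);
                if (ir > il)
                    tmp.push_back({il, ir, p.a, p.b, p.c, p.label});
                if (r2 < p.r)
                    tmp.push_back({std::max(r2, p.l), p.r, 0.0, 0.0, cv, t});
            }
            // drop degenerate pieces, merge adjacent identical constants
            Q.clear();
            for (const Piece& p : tmp) {
                if (p.r <= p.l) continue;
                if (!Q.empty()) {
                    Piece& q = Q.back();
                    if (q.a == 0.0 && p.a == 0.0 && q.b == 0.0 && p.b == 0.0 &&
                        q.c == p.c && q.label == p.label) { q.r = p.r; continue; }
                }
                Q.push_back(p);
            }
        }
        // add loss min((y_t - theta)^2, K^2); the loss is continuous at the
        // knots y_t +/- K, so boundary attribution is immaterial
        const double v = y[t - 1];
        const double e1 = v - K, e2 = v + K;
        tmp.clear();
        for (const Piece& p : Q) {
            double c1 = std::min(std::max(e1, p.l), p.r);
            double c2 = std::min(std::max(e2, p.l), p.r);
            double pts[4] = {p.l, c1, c2, p.r};
            for (int ci = 0; ci < 3; ++ci) {
                double lo = pts[ci], hi = pts[ci + 1];
                if (hi <= lo) continue;
                Piece np = {lo, hi, p.a, p.b, p.c, p.label};
                double mid = 0.5 * (lo + hi);
                if (mid >= e1 && mid <= e2) {
                    np.a += 1.0; np.b -= 2.0 * v; np.c += v * v;
                } else {
                    np.c += K2;
                }
                tmp.push_back(np);
            }
        }
        Q = tmp;

        double bestv = R_PosInf; int bestlab = 1;
        for (const Piece& p : Q) {
            double val, arg; piece_min(p, val, arg);
            if (val < bestv) { bestv = val; bestlab = p.label; }
        }
        F[t] = bestv; lab[t] = bestlab;
    }

    std::vector<int> starts;
    for (int t = n; t >= 1; t = lab[t] - 1) starts.push_back(lab[t]);
    std::reverse(starts.begin(), starts.end());
    return List::create(_["starts"] = wrap(starts), _["objective"] = F[n]);
}
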