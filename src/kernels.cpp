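#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// one fused evaluation of sin and cos where the platform provides it
static inline void sincos_(double x, double *s, double *c) {
#if defined(__GLIBC__)
    sincos(x, s, c);
#else
    *s = std::sin(x);
    *c = std::cos(x);
#endif
}

// Coherent phase sum G(q_i, n_m) = sum_j w_j exp(i q_i (n_m . r_j)).
// Returned as an nq x M complex matrix; form factors are multiplied in R
// so beads of different widths can share the kernel.
// [[Rcpp::export]]
ComplexMatrix cpp_phase_sum(NumericMatrix pos, NumericVector w,
                            NumericVector q, NumericMatrix dirs) {
    const int n = pos.nrow(), nq = q.size(), M = dirs.nrow();
    ComplexMatrix G(nq, M);
    std::vector<double> proj(n), acc_re(nq), acc_im(nq);
    // arithmetic q grids admit a phase recurrence: e^{i q_{k+1} p} =
    // e^{i q_k p} e^{i dq p}, two sincos per (point, direction) instead of nq
    bool arithmetic = nq > 2;
    const double dq = nq > 1 ? q[1] - q[0] : 0.0;
    for (int i = 2; i < nq && arithmetic; ++i)
        if (std::fabs(q[i] - q[i - 1] - dq) > 1e-9 * std::fabs(dq))
            arithmetic = false;
    for (int m = 0; m < M; ++m) {
        const double dx = dirs(m, 0), dy = dirs(m, 1), dz = dirs(m, 2);
        for (int j = 0; j < n; ++j)
            proj[j] = dx * pos(j, 0) + dy * pos(j, 1) + dz * pos(j, 2);
        if (arithmetic) {
            std::fill(acc_re.begin(), acc_re.end(), 0.0);
            std::fill(acc_im.begin(), acc_im.end(), 0.0);
            for (int j = 0; j < n; ++j) {
                double cr, ci, dr, di;
                sincos_(q[0] * proj[j], &ci, &cr);
                sincos_(dq * proj[j], &di, &dr);
                const double wj = w[j];
                for (int i = 0; i < nq; ++i) {
                    acc_re[i] += wj * cr;
                    acc_im[i] += wj * ci;
                    const double nr = cr * dr - ci * di;
                    ci = cr * di + ci * dr;
                    cr = nr;
                }
            }
            for (int i = 0; i < nq; ++i) {
                G(i, m).r = acc_re[i];
                G(i, m).i = acc_im[i];
            }
        } else {
            for (int i = 0; i < nq; ++i) {
                const double qi = q[i];
                double re = 0.0, im = 0.0, s, c;
                for (int j = 0; j < n; ++j) {
                    sincos_(qi * proj[j], &s, &c);
                    re += w[j] * c;
                    im += w[j] * s;
                }
                G(i, m).r = re;
                G(i, m).i = im;
            }
        }
    }
    return G;
}

// Exact orientation-averaged Debye sum (no form factor):
// I(q) = sum_j sum_k w_j w_k sin(q r_jk) / (q r_jk), diagonal term w_j^2.
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix pos, NumericVector w, NumericVector q) {
    const int n = pos.nrow(), nq = q.size();
    NumericVector I(nq);
    double wsq = 0.0;
    for (int j = 0; j < n; ++j) wsq += w[j] * w[j];
    for (int i = 0; i < nq; ++i) I[i] = wsq;
    for (int j = 0; j < n; ++j) {
        for (int k = j + 1; k < n; ++k) {
            const double dx = pos(j, 0) - pos(k, 0);
            const double dy = pos(j, 1) - pos(k, 1);
            const double dz = pos(j, 2) - pos(k, 2);
            const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            const double ww = 2.0 * w[j] * w[k];
            for (int i = 0; i < nq; ++i) {
                const double x = q[i] * r;
                I[i] += ww * (x == 0.0 ? 1.0 : std::sin(x) / x);
            }
        }
    }
    return I;
}

static inline double clamp01(double t) {
    return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

// Ericson, Real-Time Collision Detection, closest points of two segments;
// raw-pointer core so the clash scans allocate nothing per pair.
static double seg_dist_raw(const double *p1, const double *d1, double l1,
                           const double *p2, const double *d2, double l2) {
    const double ax = d1[0] * l1, ay = d1[1] * l1, az = d1[2] * l1;
    const double bx = d2[0] * l2, by = d2[1] * l2, bz = d2[2] * l2;
    const double rx = p1[0] - p2[0], ry = p1[1] - p2[1], rz = p1[2] - p2[2];
    const double a = ax * ax + ay * ay + az * az;
    const double e = bx * bx + by * by + bz * bz;
    const double f = bx * rx + by * ry + bz * rz;
    const double c = ax * rx + ay * ry + az * rz;
    const double b = ax * bx + ay * by + az * bz;
    const double denom = a * e - b * b;
    double s = denom > 1e-12 ? clamp01((b * f - c * e) / denom) : 0.0;
    double t = e > 1e-12 ? (b * s + f) / e : 0.0;
    if (t < 0.0) {
        t = 0.0;
        s = a > 1e-12 ? clamp01(-c / a) : 0.0;
    } else if (t > 1.0) {
        t = 1.0;
        s = a > 1e-12 ? clamp01((b - c) / a) : 0.0;
    }
    const double qx = rx + s * ax - t * bx;
    const double qy = ry + s * ay - t * by;
    const double qz = rz + s * az - t * bz;
    return std::sqrt(qx * qx + qy * qy + qz * qz);
}

// Minimum distance between core segments [p1, p1 + l1 d1] and [p2, p2 + l2 d2].
// [[Rcpp::export]]
double cpp_seg_dist(NumericVector p1, NumericVector d1, double l1,
                    NumericVector p2, NumericVector d2, double l2) {
    return seg_dist_raw(p1.begin(), d1.begin(), l1, p2.begin(), d2.begin(), l2);
}

// copy one row of a 7-column segment table into contiguous doubles
static inline void seg_row(const NumericMatrix &m, int i, double *p,
                           double *d, double *l) {
    p[0] = m(i, 0); p[1] = m(i, 1); p[2] = m(i, 2);
    d[0] = m(i, 3); d[1] = m(i, 4); d[2] = m(i, 5);
    *l = m(i, 6);
}

// Any clash between candidate segments (k x 7: px py pz ax ay az len) and the
// ensemble segment table (rows with chain id), skipping the candidate's own
// chain. Distances below minDist count as clashes. Early exit.
// [[Rcpp::export]]
bool cpp_any_clash(NumericMatrix cand, NumericMatrix segs,
                   IntegerVector chainId, int selfChain, double minDist) {
    const int k = cand.nrow(), n = segs.nrow();
    double p1[3], d1[3], l1, p2[3], d2[3], l2;
    for (int i = 0; i < k; ++i) {
        seg_row(cand, i, p1, d1, &l1);
        for (int j = 0; j < n; ++j) {
            if (chainId[j] == selfChain) continue;
            seg_row(segs, j, p2, d2, &l2);
            if (seg_dist_raw(p1, d1, l1, p2, d2, l2) < minDist)
                return true;
        }
    }
    return false;
}

// Any core-core approach below minDist between segments of distinct chains.
// [[Rcpp::export]]
bool cpp_ensemble_clash(NumericMatrix segs, IntegerVector chainId,
                        double minDist) {
    const int n = segs.nrow();
    double p1[3], d1[3], l1, p2[3], d2[3], l2;
    for (int i = 0; i < n; ++i) {
        seg_row(segs, i, p1, d1, &l1);
        for (int j = i + 1; j < n; ++j) {
            if (chainId[j] == chainId[i]) continue;
            seg_row(segs, j, p2, d2, &l2);
            if (seg_dist_raw(p1, d1, l1, p2, d2, l2) < minDist)
                return true;
        }
    }
    return false;
}

// Histogram of all pairwise distances with bin width dr on [0, rmax].
// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix pos, double rmax, double dr) {
    const int n = pos.nrow();
    const int nb = (int)std::ceil(rmax / dr);
    NumericVector counts(nb);
    for (int j = 0; j < n; ++j) {
        for (int k = j + 1; k < n; ++k) {
            const double dx = pos(j, 0) - pos(k, 0);
            const double dy = pos(j, 1) - pos(k, 1);
            const double dz = pos(j, 2) - pos(k, 2);
            const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r < rmax) counts[(int)(r / dr)] += 1.0;
        }
    }
    return counts;
}
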