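#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// squared distance from (x, y) to segment (x1, y1)-(x2, y2)
static inline double seg_dist2(double x, double y,
                               double x1, double y1, double x2, double y2) {
    double dx = x2 - x1, dy = y2 - y1;
    double l2 = dx * dx + dy * dy;
    double t = 0.0;
    if (l2 > 0.0) {
        t = ((x - x1) * dx + (y - y1) * dy) / l2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    }
    double qx = x1 + t * dx - x, qy = y1 + t * dy - y;
    return qx * qx + qy * qy;
}

// Minimum Euclidean distance from each point to a polyline.
// When vertex x-coordinates are sorted ascending (the per-column resampled
// boundaries always are), segments are scanned outward from the point's
// column and the scan stops once the horizontal gap alone exceeds the best
// distance found; otherwise all segments are scanned.
// [[Rcpp::export]]
NumericVector dist_to_polyline_cpp(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
    const int np = px.size(), nv = vx.size();
    NumericVector out(np);
    if (nv == 0) stop("empty polyline");
    if (nv == 1) {
        for (int i = 0; i < np; ++i) {
            double dx = px[i] - vx[0], dy = py[i] - vy[0];
            out[i] = std::sqrt(dx * dx + dy * dy);
        }
        return out;
    }
    bool sorted = true;
    for (int j = 1; j < nv; ++j) if (vx[j] < vx[j - 1]) { sorted = false; break; }

    if (!sorted) {
        for (int i = 0; i < np; ++i) {
            double best = R_PosInf;
            for (int j = 0; j < nv - 1; ++j) {
                double d2 = seg_dist2(px[i], py[i], vx[j], vy[j], vx[j + 1], vy[j + 1]);
                if (d2 < best) best = d2;
            }
            out[i] = std::sqrt(best);
        }
        return out;
    }

    for (int i = 0; i < np; ++i) {
        const double x = px[i], y = py[i];
        // first vertex with vx >= x
        int lo = std::lower_bound(vx.begin(), vx.end(), x) - vx.begin();
        int jl = lo - 1;          // segment jl spans [vx[jl], vx[jl+1]]
        int jr = lo;
        if (jl < 0) jl = 0;
        if (jl > nv - 2) jl = nv - 2;
        if (jr > nv - 2) jr = nv - 2;
        double best = seg_dist2(x, y, vx[jl], vy[jl], vx[jl + 1], vy[jl + 1]);
        if (jr != jl) {
            double d2 = seg_dist2(x, y, vx[jr], vy[jr], vx[jr + 1], vy[jr + 1]);
            if (d2 < best) best = d2;
        }
        int l = jl - 1, r = jr + 1;
        while (l >= 0 || r <= nv - 2) {
            if (l >= 0) {
                double gap = x - vx[l + 1];
                if (gap > 0 && gap * gap > best) l = -1;
                else {
                    double d2 = seg_dist2(x, y, vx[l], vy[l], vx[l + 1], vy[l + 1]);
                    if (d2 < best) best = d2;
                    --l;
                }
            }
            if (r <= nv - 2) {
                double gap = vx[r] - x;
                if (gap > 0 && gap * gap > best) r = nv;
                else {
                    double d2 = seg_dist2(x, y, vx[r], vy[r], vx[r + 1], vy[r + 1]);
                    if (d2 < best) best = d2;
                    ++r;
                }
            }
        }
        out[i] = std::sqrt(best);
    }
    return out;
}

// Nearest seed under the anisotropic metric d^2 = dx^2 + (yscale*dy)^2.
// Seeds must be sorted ascending by sx; returns 1-based indices.
// [[Rcpp::export]]
IntegerVector nearest_seed_cpp(NumericVector px, NumericVector py,
                               NumericVector sx, NumericVector sy,
                               double yscale) {
    const int np = px.size(), ns = sx.size();
    if (ns == 0) stop("no seeds");
    IntegerVector out(np);
    for (int i = 0; i < np; ++i) {
        const double x = px[i], y = py[i];
        int lo = std::lower_bound(sx.begin(), sx.end(), x) - sx.begin();
        double best = R_PosInf;
        int bi = 0;
        int l = lo - 1, r = lo;
        while (l >= 0 || r < ns) {
            if (l >= 0) {
                double gap = x - sx[l];
                if (gap * gap > best) l = -1;
                else {
                    double dx = x - sx[l], dy = yscale * (y - sy[l]);
                    double d2 = dx * dx + dy * dy;
                    if (d2 < best) { best = d2; bi = l; }
                    --l;
                }
            }
            if (r < ns) {
                double gap = sx[r] - x;
                if (gap * gap > best) r = ns;
                else {
                    double dx = x - sx[r], dy = yscale * (y - sy[r]);
                    double d2 = dx * dx + dy * dy;
                    if (d2 < best) { best = d2; bi = r; }
                    ++r;
                }
            }
        }
        out[i] = bi + 1;
    }
    return out;
}
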