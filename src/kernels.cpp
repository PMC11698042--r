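#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <climits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (lower-envelope-of-parabolas,
// Felzenszwalb & Huttenlocher). Squared distances between integer grid points
// are integers, exactly representable in doubles, so the transform is exact.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; q++) {
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                   (2.0 * q - 2.0 * v[k]);
        while (s <= z[k]) {
            k--;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        double dq = (double)(q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
}

// squared Euclidean distance (grid units) from every pixel to nearest TRUE
// site; pixels with no site anywhere get Inf.  A large finite sentinel keeps
// the envelope arithmetic finite; any true site dominates it exactly.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix sites) {
    int H = sites.nrow(), W = sites.ncol();
    const double big = 4.0 * ((double)H * H + (double)W * W) + 1.0;
    NumericMatrix D(H, W);
    std::vector<double> f(std::max(H, W)), d(std::max(H, W));
    for (int j = 0; j < W; j++) {
        for (int i = 0; i < H; i++) f[i] = sites(i, j) ? 0.0 : big;
        dt1d(f, d, H);
        for (int i = 0; i < H; i++) D(i, j) = d[i];
    }
    for (int i = 0; i < H; i++) {
        for (int j = 0; j < W; j++) f[j] = D(i, j);
        dt1d(f, d, W);
        for (int j = 0; j < W; j++)
            D(i, j) = (d[j] >= big) ? std::numeric_limits<double>::infinity()
                                    : d[j];
    }
    return D;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (4- or 8-connectivity), deterministic:
// components numbered by first pixel in column-major scan order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_cc(LogicalMatrix mask, int connectivity) {
    int H = mask.nrow(), W = mask.ncol();
    IntegerMatrix lab(H, W);
    int next = 0;
    const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
    const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
    int nnb = (connectivity == 8) ? 8 : 4;
    std::queue<std::pair<int, int> > q;
    for (int j = 0; j < W; j++) {
        for (int i = 0; i < H; i++) {
            if (!mask(i, j) || lab(i, j) != 0) continue;
            next++;
            lab(i, j) = next;
            q.push(std::make_pair(i, j));
            while (!q.empty()) {
                std::pair<int, int> p = q.front(); q.pop();
                for (int t = 0; t < nnb; t++) {
                    int r = p.first + dr8[t], c = p.second + dc8[t];
                    if (r < 0 || r >= H || c < 0 || c >= W) continue;
                    if (mask(r, c) && lab(r, c) == 0) {
                        lab(r, c) = next;
                        q.push(std::make_pair(r, c));
                    }
                }
            }
        }
    }
    return lab;
}

// ---------------------------------------------------------------------------
// Polygon rasterization: even-odd scanline fill, painting pixels whose
// centers lie inside. Vertices are (x = col, y = row), 0-based pixel centers.
// Later polygons overwrite earlier ones.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polys(List xs, List ys, int nrow, int ncol) {
    IntegerMatrix lab(nrow, ncol);
    int npoly = xs.size();
    for (int p = 0; p < npoly; p++) {
        NumericVector px = xs[p], py = ys[p];
        int n = px.size();
        if (n < 3) continue;
        double ymin = *std::min_element(py.begin(), py.end());
        double ymax = *std::max_element(py.begin(), py.end());
        int r0 = std::max(0, (int)std::ceil(ymin));
        int r1 = std::min(nrow - 1, (int)std::floor(ymax));
        std::vector<double> xint;
        for (int r = r0; r <= r1; r++) {
            double y = (double)r;
            xint.clear();
            for (int e = 0; e < n; e++) {
                double y0 = py[e], y1 = py[(e + 1) % n];
                double x0 = px[e], x1 = px[(e + 1) % n];
                // half-open rule: edge crosses scanline if exactly one
                // endpoint is strictly above it
                if ((y0 <= y) != (y1 <= y)) {
                    xint.push_back(x0 + (y - y0) * (x1 - x0) / (y1 - y0));
                }
            }
            std::sort(xint.begin(), xint.end());
            for (size_t k = 0; k + 1 < xint.size(); k += 2) {
                int c0 = (int)std::ceil(xint[k]);
                int c1 = (int)std::ceil(xint[k + 1]) - 1;
                c0 = std::max(0, c0);
                c1 = std::min(ncol - 1, c1);
                for (int c = c0; c <= c1; c++) lab(r, c) = p + 1;
            }
        }
    }
    return lab;
}

// ---------------------------------------------------------------------------
// Minimum pixel-center distance between every pair of labels whose boundary
// pixels come within max_dist_px of each other. Boundary pixels suffice: the
// closest pair of pixels in two disjoint label sets is a boundary pair.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_label_gaps(IntegerMatrix labels, double max_dist_px) {
    int H = labels.nrow(), W = labels.ncol();
    int nlab = 0;
    for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++)
            if (labels(i, j) > nlab) nlab = labels(i, j);
    if (nlab < 2)
        return DataFrame::create(_["i"] = IntegerVector(0),
                                 _["j"] = IntegerVector(0),
                                 _["dist_px"] = NumericVector(0));
    // boundary pixels per label
    std::vector<std::vector<int> > br(nlab + 1), bc(nlab + 1);
    std::vector<int> rmin(nlab + 1, INT_MAX), rmax(nlab + 1, INT_MIN),
        cmin(nlab + 1, INT_MAX), cmax(nlab + 1, INT_MIN);
    for (int j = 0; j < W; j++) {
        for (int i = 0; i < H; i++) {
            int l = labels(i, j);
            if (l == 0) continue;
            bool edge = (i == 0 || j == 0 || i == H - 1 || j == W - 1);
            if (!edge) {
                edge = labels(i - 1, j) != l || labels(i + 1, j) != l ||
                       labels(i, j - 1) != l || labels(i, j + 1) != l;
            }
            if (edge) { br[l].push_back(i); bc[l].push_back(j); }
            rmin[l] = std::min(rmin[l], i); rmax[l] = std::max(rmax[l], i);
            cmin[l] = std::min(cmin[l], j); cmax[l] = std::max(cmax[l], j);
        }
    }
    std::vector<int> oi, oj;
    std::vector<double> od;
    double md2 = max_dist_px * max_dist_px;
    for (int a = 1; a <= nlab; a++) {
        if (br[a].empty()) continue;
        for (int b = a + 1; b <= nlab; b++) {
            if (br[b].empty()) continue;
            // bounding-box prefilter
            double dr = 0.0, dc = 0.0;
            if (rmin[b] > rmax[a]) dr = rmin[b] - rmax[a];
            else if (rmin[a] > rmax[b]) dr = rmin[a] - rmax[b];
            if (cmin[b] > cmax[a]) dc = cmin[b] - cmax[a];
            else if (cmin[a] > cmax[b]) dc = cmin[a] - cmax[b];
            if (dr * dr + dc * dc > md2) continue;
            long long best = LLONG_MAX;
            for (size_t u = 0; u < br[a].size(); u++) {
                int ra = br[a][u], ca = bc[a][u];
                for (size_t v = 0; v < br[b].size(); v++) {
                    long long ddr = ra - br[b][v], ddc = ca - bc[b][v];
                    long long d2 = ddr * ddr + ddc * ddc;
                    if (d2 < best) best = d2;
                }
            }
            if ((double)best <= md2) {
                oi.push_back(a); oj.push_back(b);
                od.push_back(std::sqrt((double)best));
            }
        }
    }
    return DataFrame::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                             _["dist_px"] = wrap(od));
}

// ---------------------------------------------------------------------------
// Local thickness.
//
// Convention: candidate disc centers live on the half-integer pixel grid;
// the admissible radius at a center is the exact Euclidean distance to the
// nearest background pixel *square* (pixels are unit squares; pixels outside
// the image count as background).  The local thickness of a foreground pixel
// p is the diameter of the largest admissible disc whose radius covers p's
// center.  A single isolated pixel has thickness 1 px and a w-pixel-wide bar
// has thickness w (the best centers sit between pixel rows).
//
// The nearest point of a unit square to a half-grid point has half-integer
// coordinates, so distances are computed exactly as an EDT on the doubled
// grid whose sites are all nodes covered by background squares; radius and
// coverage comparisons are integer, hence exact, and the brute-force
// reference used in the tests reproduces them bit for bit.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_local_thickness(LogicalMatrix mask) {
    int H = mask.nrow(), W = mask.ncol();
    NumericMatrix LT(H, W); // zero-filled
    // padded mask (1-px background ring)
    int PH = H + 2, PW = W + 2;
    // doubled grid over the padded domain: node (a,b) <-> padded (a/2, b/2)
    int DH = 2 * PH - 1, DW = 2 * PW - 1;
    LogicalMatrix sites(DH, DW); // nodes covered by background squares
    for (int pj = 0; pj < PW; pj++) {
        for (int pi = 0; pi < PH; pi++) {
            bool fg = (pi >= 1 && pi <= H && pj >= 1 && pj <= W) &&
                      mask(pi - 1, pj - 1);
            if (fg) continue;
            for (int da = -1; da <= 1; da++)
                for (int db = -1; db <= 1; db++) {
                    int a = 2 * pi + da, b = 2 * pj + db;
                    if (a >= 0 && a < DH && b >= 0 && b < DW)
                        sites(a, b) = true;
                }
        }
    }
    NumericMatrix d2m = cpp_edt_sq(sites); // squared dist, half-px units
    const int da8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
    const int db8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
    for (int b = 0; b < DW; b++) {
        for (int a = 0; a < DH; a++) {
            double d2 = d2m(a, b);
            if (d2 <= 0.0) continue;
            double rt = std::sqrt(d2);
            // domination pruning: skip centers whose disc is contained in a
            // neighbour's (conservative margin, so pruning is exact-safe)
            bool dom = false;
            for (int t = 0; t < 8 && !dom; t++) {
                int na = a + da8[t], nb = b + db8[t];
                if (na < 0 || na >= DH || nb < 0 || nb >= DW) continue;
                double dist = (t < 4) ? 1.0 : M_SQRT2;
                if (std::sqrt(d2m(na, nb)) >= rt + dist + 1e-7) dom = true;
            }
            if (dom) continue;
            double lt = rt; // diameter in px = radius in half-px units
            // paint integer pixels p (node coords 2*(p+1)) with q <= d2
            int rlo = (int)std::ceil(((double)a - rt) / 2.0) - 1;
            int rhi = (int)std::floor(((double)a + rt) / 2.0) - 1;
            int clo = (int)std::ceil(((double)b - rt) / 2.0) - 1;
            int chi = (int)std::floor(((double)b + rt) / 2.0) - 1;
            rlo = std::max(rlo, 0); rhi = std::min(rhi, H - 1);
            clo = std::max(clo, 0); chi = std::min(chi, W - 1);
            for (int pc = clo; pc <= chi; pc++) {
                for (int pr = rlo; pr <= rhi; pr++) {
                    double qa = (double)(2 * (pr + 1) - a);
                    double qb = (double)(2 * (pc + 1) - b);
                    double q = qa * qa + qb * qb;
                    if (q <= d2 && lt > LT(pr, pc)) LT(pr, pc) = lt;
                }
            }
        }
    }
    return LT;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding: seeds grow over the
// masked elevation surface, always expanding the globally lowest frontier
// pixel first. Ties are broken by insertion order, making the result
// deterministic for identical inputs.
// ---------------------------------------------------------------------------

struct WsNode {
    double elev;
    long long order;
    int r, c, label;
};
struct WsCmp {
    bool operator()(const WsNode &a, const WsNode &b) const {
        if (a.elev != b.elev) return a.elev > b.elev; // min-heap
        return a.order > b.order;
    }
};

// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(NumericMatrix elev, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
    int H = elev.nrow(), W = elev.ncol();
    IntegerMatrix lab(H, W);
    std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
    long long order = 0;
    const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
    for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++)
            if (seeds(i, j) > 0 && mask(i, j)) {
                WsNode nd = {elev(i, j), order++, i, j, seeds(i, j)};
                pq.push(nd);
            }
    while (!pq.empty()) {
        WsNode nd = pq.top(); pq.pop();
        if (lab(nd.r, nd.c) != 0) continue;
        lab(nd.r, nd.c) = nd.label;
        for (int t = 0; t < 4; t++) {
            int r = nd.r + dr[t], c = nd.c + dc[t];
            if (r < 0 || r >= H || c < 0 || c >= W) continue;
            if (!mask(r, c) || lab(r, c) != 0) continue;
            WsNode nx = {elev(r, c), order++, r, c, nd.label};
            pq.push(nx);
        }
    }
    return lab;
}

// ---------------------------------------------------------------------------
// Outer boundary of each label as an ordered closed contour of boundary
// pixel centers (Moore neighbour tracing, clockwise in (row, col) space).
// Returns a list of n x 2 matrices (x = col, y = row), 0-based.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_trace_boundaries(IntegerMatrix labels) {
    int H = labels.nrow(), W = labels.ncol();
    int nlab = 0;
    for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++)
            if (labels(i, j) > nlab) nlab = labels(i, j);
    List out(nlab);
    // first pixel of each label in column-major order
    std::vector<int> fr(nlab + 1, -1), fc(nlab + 1, -1);
    for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++) {
            int l = labels(i, j);
            if (l > 0 && fr[l] < 0) { fr[l] = i; fc[l] = j; }
        }
    // Moore neighbourhood in clockwise order starting west
    const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
    const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
    for (int l = 1; l <= nlab; l++) {
        if (fr[l] < 0) { out[l - 1] = R_NilValue; continue; }
        std::vector<int> br, bc;
        int sr = fr[l], sc = fc[l];
        br.push_back(sr); bc.push_back(sc);
        int cr = sr, cc = sc, dir = 0; // came from the west
        bool closed = false;
        long long guard = 4LL * (long long)H * W + 16;
        while (!closed && guard-- > 0) {
            bool moved = false;
            for (int t = 0; t < 8; t++) {
                int k = (dir + t) % 8;
                int r = cr + mr[k], c = cc + mc[k];
                if (r < 0 || r >= H || c < 0 || c >= W) continue;
                if (labels(r, c) == l) {
                    if (r == sr && c == sc) { closed = true; break; }
                    br.push_back(r); bc.push_back(c);
                    cr = r; cc = c;
                    dir = (k + 5) % 8; // backtrack direction + 1
                    moved = true;
                    break;
                }
            }
            if (!moved) break; // isolated pixel or fully traced
        }
        NumericMatrix m(br.size(), 2);
        for (size_t k = 0; k < br.size(); k++) {
            m(k, 0) = bc[k]; // x = col
            m(k, 1) = br[k]; // y = row
        }
        out[l - 1] = m;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Per-label pixel statistics used when building cell tables: area, centroid,
// per-channel intensity sums. Avoids repeated full-image scans from R.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_label_stats(IntegerMatrix labels, NumericVector channels, int nchan) {
    int H = labels.nrow(), W = labels.ncol();
    int nlab = 0;
    for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++)
            if (labels(i, j) > nlab) nlab = labels(i, j);
    NumericVector area(nlab), sr(nlab), sc(nlab);
    NumericMatrix isum(nlab, nchan);
    long long plane = (long long)H * W;
    for (int j = 0; j < W; j++) {
        for (int i = 0; i < H; i++) {
            int l = labels(i, j);
            if (l == 0) continue;
            area[l - 1] += 1.0;
            sr[l - 1] += i;
            sc[l - 1] += j;
            for (int ch = 0; ch < nchan; ch++)
                isum(l - 1, ch) += channels[(long long)ch * plane + (long long)j * H + i];
        }
    }
    return List::create(_["area_px"] = area, _["sum_row"] = sr,
                        _["sum_col"] = sc, _["intensity_sum"] = isum);
}
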