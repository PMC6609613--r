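#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Voxel arrays arrive as column-major 3D arrays flattened to vectors.
// Grey levels use 0 for voxels outside the VOI and 1..ng inside.

static inline R_xlen_t idx3(int i, int j, int k, const int* d) {
    return (R_xlen_t)i + (R_xlen_t)d[0] * ((R_xlen_t)j + (R_xlen_t)d[1] * k);
}

// The 13 unique 3D directions at Chebyshev distance 1 (half of the 26
// neighbourhood; the other half is covered by matrix symmetrisation).
static const int DIR13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export]]
NumericMatrix cpp_glcm_merged(IntegerVector levels, IntegerVector dims, int ng) {
    const int* d = INTEGER(dims);
    NumericMatrix m(ng, ng);
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                int g = levels[idx3(i, j, k, d)];
                if (g == 0) continue;
                for (int dd = 0; dd < 13; ++dd) {
                    int ii = i + DIR13[dd][0], jj = j + DIR13[dd][1], kk = k + DIR13[dd][2];
                    if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
                        continue;
                    int h = levels[idx3(ii, jj, kk, d)];
                    if (h == 0) continue;
                    m(g - 1, h - 1) += 1.0;
                    m(h - 1, g - 1) += 1.0;
                }
            }
    return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm_merged(IntegerVector levels, IntegerVector dims, int ng) {
    const int* d = INTEGER(dims);
    int maxdim = std::max(d[0], std::max(d[1], d[2]));
    // runs along diagonals can't exceed the largest axis length
    NumericMatrix m(ng, maxdim);
    for (int dd = 0; dd < 13; ++dd) {
        int dx = DIR13[dd][0], dy = DIR13[dd][1], dz = DIR13[dd][2];
        for (int k = 0; k < d[2]; ++k)
            for (int j = 0; j < d[1]; ++j)
                for (int i = 0; i < d[0]; ++i) {
                    int g = levels[idx3(i, j, k, d)];
                    if (g == 0) continue;
                    // start of a maximal run iff the predecessor is absent
                    int pi = i - dx, pj = j - dy, pk = k - dz;
                    if (pi >= 0 && pj >= 0 && pk >= 0 && pi < d[0] && pj < d[1] && pk < d[2]
                        && levels[idx3(pi, pj, pk, d)] == g)
                        continue;
                    int len = 1;
                    int ci = i + dx, cj = j + dy, ck = k + dz;
                    while (ci >= 0 && cj >= 0 && ck >= 0 && ci < d[0] && cj < d[1] && ck < d[2]
                           && levels[idx3(ci, cj, ck, d)] == g) {
                        ++len;
                        ci += dx; cj += dy; ck += dz;
                    }
                    m(g - 1, len - 1) += 1.0;
                }
    }
    return m;
}

// 26-connected components of equal grey level; returns a label array
// (0 outside the VOI, labels 1..nzones inside).
// [[Rcpp::export]]
IntegerVector cpp_label_zones(IntegerVector levels, IntegerVector dims) {
    const int* d = INTEGER(dims);
    R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                R_xlen_t p = idx3(i, j, k, d);
                if (levels[p] == 0 || lab[p] != 0) continue;
                int g = levels[p];
                lab[p] = ++next;
                stack.clear();
                stack.push_back(p);
                while (!stack.empty()) {
                    R_xlen_t q = stack.back();
                    stack.pop_back();
                    int qk = (int)(q / ((R_xlen_t)d[0] * d[1]));
                    R_xlen_t r = q - (R_xlen_t)qk * d[0] * d[1];
                    int qj = (int)(r / d[0]);
                    int qi = (int)(r % d[0]);
                    for (int dz = -1; dz <= 1; ++dz)
                        for (int dy = -1; dy <= 1; ++dy)
                            for (int dx = -1; dx <= 1; ++dx) {
                                if (!dx && !dy && !dz) continue;
                                int ii = qi + dx, jj = qj + dy, kk = qk + dz;
                                if (ii < 0 || jj < 0 || kk < 0 ||
                                    ii >= d[0] || jj >= d[1] || kk >= d[2])
                                    continue;
                                R_xlen_t s = idx3(ii, jj, kk, d);
                                if (levels[s] == g && lab[s] == 0) {
                                    lab[s] = next;
                                    stack.push_back(s);
                                }
                            }
                }
            }
    return lab;
}

// City-block distance from each mask voxel to the nearest voxel outside the
// mask; voxels on the mask (or image) border get distance 1.  Multi-source
// BFS over the 6-neighbourhood.  Returns 0 for voxels outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_cityblock_border_distance(IntegerVector mask, IntegerVector dims) {
    const int* d = INTEGER(dims);
    R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
    IntegerVector dist(n, 0);
    std::vector<R_xlen_t> frontier, nxt;
    const int N6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                R_xlen_t p = idx3(i, j, k, d);
                if (!mask[p]) continue;
                bool border = false;
                for (int t = 0; t < 6 && !border; ++t) {
                    int ii = i + N6[t][0], jj = j + N6[t][1], kk = k + N6[t][2];
                    if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]
                        || !mask[idx3(ii, jj, kk, d)])
                        border = true;
                }
                if (border) {
                    dist[p] = 1;
                    frontier.push_back(p);
                }
            }
    int level = 1;
    while (!frontier.empty()) {
        nxt.clear();
        for (R_xlen_t q : frontier) {
            int qk = (int)(q / ((R_xlen_t)d[0] * d[1]));
            R_xlen_t r = q - (R_xlen_t)qk * d[0] * d[1];
            int qj = (int)(r / d[0]);
            int qi = (int)(r % d[0]);
            for (int t = 0; t < 6; ++t) {
                int ii = qi + N6[t][0], jj = qj + N6[t][1], kk = qk + N6[t][2];
                if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
                    continue;
                R_xlen_t s = idx3(ii, jj, kk, d);
                if (mask[s] && dist[s] == 0) {
                    dist[s] = level + 1;
                    nxt.push_back(s);
                }
            }
        }
        frontier.swap(nxt);
        ++level;
    }
    return dist;
}

// NGTDM accumulators: per grey level i, n_i = number of VOI voxels of level i
// possessing at least one VOI neighbour, s_i = summed |i - neighbourhood mean|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
    const int* d = INTEGER(dims);
    NumericMatrix out(ng, 2);  // columns: n_i, s_i
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                int g = levels[idx3(i, j, k, d)];
                if (g == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int ii = i + dx, jj = j + dy, kk = k + dz;
                            if (ii < 0 || jj < 0 || kk < 0 ||
                                ii >= d[0] || jj >= d[1] || kk >= d[2])
                                continue;
                            int h = levels[idx3(ii, jj, kk, d)];
                            if (h > 0) { sum += h; ++cnt; }
                        }
                if (cnt == 0) continue;
                out(g - 1, 0) += 1.0;
                out(g - 1, 1) += std::fabs((double)g - sum / cnt);
            }
    return out;
}

// Moran's I and Geary's C with inverse-Euclidean-distance weights over all
// voxel pairs (coords in mm, one row per VOI voxel).
// [[Rcpp::export]]
NumericVector cpp_moran_geary(NumericMatrix coords, NumericVector vals) {
    int n = coords.nrow();
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += vals[i];
    mu /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (vals[i] - mu) * (vals[i] - mu);
    double wsum = 0.0, num_m = 0.0, num_g = 0.0;
    for (int i = 0; i < n; ++i) {
        double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
        double di = vals[i] - mu;
        for (int j = i + 1; j < n; ++j) {
            double dx = xi - coords(j, 0), dy = yi - coords(j, 1), dz = zi - coords(j, 2);
            double w = 1.0 / std::sqrt(dx * dx + dy * dy + dz * dz);
            wsum += w;
            num_m += w * di * (vals[j] - mu);
            double diff = vals[i] - vals[j];
            num_g += w * diff * diff;
        }
    }
    // pairs counted once; symmetric weights double the sums
    wsum *= 2.0; num_m *= 2.0; num_g *= 2.0;
    NumericVector out(2);
    if (ss <= 0.0 || n < 2) {
        out[0] = 1.0;   // perfectly flat field: maximal spatial agreement
        out[1] = 0.0;
    } else {
        out[0] = ((double)n / wsum) * (num_m / ss);
        out[1] = ((double)(n - 1) / (2.0 * wsum)) * (num_g / ss);
    }
    return out;
}

// [[Rcpp::export]]
double cpp_max_pairwise_distance(NumericMatrix pts) {
    int n = pts.nrow();
    std::vector<double> x(n), y(n), z(n);
    for (int i = 0; i < n; ++i) {
        x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
    }
    double best = 0.0;
    for (int i = 0; i < n; ++i) {
        double xi = x[i], yi = y[i], zi = z[i];
        for (int j = i + 1; j < n; ++j) {
            double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > best) best = d2;
        }
    }
    return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// Resampling
// ---------------------------------------------------------------------------

static inline double clampd(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear interpolation of src at continuous (0-based) source indices.
// cx, cy, cz give the per-axis coordinate of each target voxel centre;
// coordinates are clamped to the grid so out-of-grid samples take edge values.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector src, IntegerVector sdim,
                            NumericVector cx, NumericVector cy, NumericVector cz) {
    const int* d = INTEGER(sdim);
    int nx = cx.size(), ny = cy.size(), nz = cz.size();
    NumericVector out((R_xlen_t)nx * ny * nz);
    std::vector<int> ix0(nx), iy0(ny), iz0(nz);
    std::vector<double> fx(nx), fy(ny), fz(nz);
    for (int i = 0; i < nx; ++i) {
        double c = clampd(cx[i], 0.0, d[0] - 1.0);
        int i0 = (int)std::floor(c);
        if (i0 > d[0] - 2) i0 = std::max(0, d[0] - 2);
        ix0[i] = i0; fx[i] = d[0] == 1 ? 0.0 : c - i0;
    }
    for (int j = 0; j < ny; ++j) {
        double c = clampd(cy[j], 0.0, d[1] - 1.0);
        int j0 = (int)std::floor(c);
        if (j0 > d[1] - 2) j0 = std::max(0, d[1] - 2);
        iy0[j] = j0; fy[j] = d[1] == 1 ? 0.0 : c - j0;
    }
    for (int k = 0; k < nz; ++k) {
        double c = clampd(cz[k], 0.0, d[2] - 1.0);
        int k0 = (int)std::floor(c);
        if (k0 > d[2] - 2) k0 = std::max(0, d[2] - 2);
        iz0[k] = k0; fz[k] = d[2] == 1 ? 0.0 : c - k0;
    }
    R_xlen_t p = 0;
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i, ++p) {
                int x0 = ix0[i], y0 = iy0[j], z0 = iz0[k];
                int x1 = std::min(x0 + 1, d[0] - 1);
                int y1 = std::min(y0 + 1, d[1] - 1);
                int z1 = std::min(z0 + 1, d[2] - 1);
                double tx = fx[i], ty = fy[j], tz = fz[k];
                double c000 = src[idx3(x0, y0, z0, d)], c100 = src[idx3(x1, y0, z0, d)];
                double c010 = src[idx3(x0, y1, z0, d)], c110 = src[idx3(x1, y1, z0, d)];
                double c001 = src[idx3(x0, y0, z1, d)], c101 = src[idx3(x1, y0, z1, d)];
                double c011 = src[idx3(x0, y1, z1, d)], c111 = src[idx3(x1, y1, z1, d)];
                double c00 = c000 + tx * (c100 - c000), c10 = c010 + tx * (c110 - c010);
                double c01 = c001 + tx * (c101 - c001), c11 = c011 + tx * (c111 - c011);
                double c0 = c00 + ty * (c10 - c00), c1 = c01 + ty * (c11 - c01);
                out[p] = c0 + tz * (c1 - c0);
            }
    return out;
}

// Cubic B-spline prefilter (Unser recursive filter, pole sqrt(3)-2) with
// whole-sample mirror boundary, applied in place along each axis.
static double init_causal(const double* c, int n, R_xlen_t stride, double z) {
    double tol = 1e-12;
    int horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
    if (horizon < n) {
        double zn = z, sum = c[0];
        for (int i = 1; i < horizon; ++i) {
            sum += zn * c[(R_xlen_t)i * stride];
            zn *= z;
        }
        return sum;
    }
    double zn = z, iz = 1.0 / z;
    double z2n = std::pow(z, n - 1);
    double sum = c[0] + z2n * c[(R_xlen_t)(n - 1) * stride];
    z2n = z2n * z2n * iz;
    for (int i = 1; i < n - 1; ++i) {
        sum += (zn + z2n) * c[(R_xlen_t)i * stride];
        zn *= z;
        z2n *= iz;
    }
    return sum / (1.0 - std::pow(z, 2 * n - 2));
}

static void filter_line(double* c, int n, R_xlen_t stride, double z) {
    if (n == 1) return;
    const double gain = (1.0 - z) * (1.0 - 1.0 / z);
    for (int i = 0; i < n; ++i) c[(R_xlen_t)i * stride] *= gain;
    c[0] = init_causal(c, n, stride, z);
    for (int i = 1; i < n; ++i)
        c[(R_xlen_t)i * stride] += z * c[(R_xlen_t)(i - 1) * stride];
    c[(R_xlen_t)(n - 1) * stride] = (z / (z * z - 1.0)) *
        (z * c[(R_xlen_t)(n - 2) * stride] + c[(R_xlen_t)(n - 1) * stride]);
    for (int i = n - 2; i >= 0; --i)
        c[(R_xlen_t)i * stride] = z * (c[(R_xlen_t)(i + 1) * stride] - c[(R_xlen_t)i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector arr, IntegerVector dims) {
    const int* d = INTEGER(dims);
    NumericVector out = clone(arr);
    double* c = REAL(out);
    const double z = std::sqrt(3.0) - 2.0;
    R_xlen_t nxy = (R_xlen_t)d[0] * d[1];
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            filter_line(c + (R_xlen_t)j * d[0] + (R_xlen_t)k * nxy, d[0], 1, z);
    for (int k = 0; k < d[2]; ++k)
        for (int i = 0; i < d[0]; ++i)
            filter_line(c + i + (R_xlen_t)k * nxy, d[1], d[0], z);
    for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i)
            filter_line(c + i + (R_xlen_t)j * d[0], d[2], nxy, z);
    return out;
}

static inline int mirror_index(int i, int n) {
    if (n == 1) return 0;
    int period = 2 * n - 2;
    i = std::abs(i) % period;
    return i < n ? i : period - i;
}

static inline void bspline_w(double t, double* w) {
    // cubic B-spline weights for offsets -1, 0, 1, 2 at fraction t in [0,1)
    double t2 = t * t, t3 = t2 * t;
    w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
    w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
    w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
    w[3] = t3 / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_bspline_eval(NumericVector coef, IntegerVector sdim,
                               NumericVector cx, NumericVector cy, NumericVector cz) {
    const int* d = INTEGER(sdim);
    int nx = cx.size(), ny = cy.size(), nz = cz.size();
    NumericVector out((R_xlen_t)nx * ny * nz);
    std::vector<int> bx(4 * nx), by(4 * ny), bz(4 * nz);
    std::vector<double> wx(4 * nx), wy(4 * ny), wz(4 * nz);
    for (int i = 0; i < nx; ++i) {
        double c = clampd(cx[i], 0.0, d[0] - 1.0);
        int i0 = (int)std::floor(c);
        double w[4];
        bspline_w(c - i0, w);
        for (int m = 0; m < 4; ++m) {
            bx[4 * i + m] = mirror_index(i0 - 1 + m, d[0]);
            wx[4 * i + m] = w[m];
        }
    }
    for (int j = 0; j < ny; ++j) {
        double c = clampd(cy[j], 0.0, d[1] - 1.0);
        int j0 = (int)std::floor(c);
        double w[4];
        bspline_w(c - j0, w);
        for (int m = 0; m < 4; ++m) {
            by[4 * j + m] = mirror_index(j0 - 1 + m, d[1]);
            wy[4 * j + m] = w[m];
        }
    }
    for (int k = 0; k < nz; ++k) {
        double c = clampd(cz[k], 0.0, d[2] - 1.0);
        int k0 = (int)std::floor(c);
        double w[4];
        bspline_w(c - k0, w);
        for (int m = 0; m < 4; ++m) {
            bz[4 * k + m] = mirror_index(k0 - 1 + m, d[2]);
            wz[4 * k + m] = w[m];
        }
    }
    R_xlen_t p = 0;
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i, ++p) {
                double acc = 0.0;
                for (int mk = 0; mk < 4; ++mk) {
                    double wk = wz[4 * k + mk];
                    if (wk == 0.0) continue;
                    for (int mj = 0; mj < 4; ++mj) {
                        double wjk = wy[4 * j + mj] * wk;
                        for (int mi = 0; mi < 4; ++mi)
                            acc += wx[4 * i + mi] * wjk *
                                coef[idx3(bx[4 * i + mi], by[4 * j + mj], bz[4 * k + mk], d)];
                    }
                }
                out[p] = acc;
            }
    return out;
}

// ---------------------------------------------------------------------------
// Iso-surface mesh (marching tetrahedra at iso level 0.5)
// ---------------------------------------------------------------------------

struct MeshAcc {
    double area = 0.0;
    double volume = 0.0;
    std::vector<double> verts;  // flat x,y,z triples of triangle vertices
};

static void emit_tri(MeshAcc& acc,
                     const double* a, const double* b, const double* c,
                     const double* inside_pt) {
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nrm[3] = {u[1] * v[2] - u[2] * v[1],
                     u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
    double cen[3] = {(a[0] + b[0] + c[0]) / 3.0,
                     (a[1] + b[1] + c[1]) / 3.0,
                     (a[2] + b[2] + c[2]) / 3.0};
    double dir[3] = {cen[0] - inside_pt[0], cen[1] - inside_pt[1], cen[2] - inside_pt[2]};
    const double* p1 = b;
    const double* p2 = c;
    if (nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2] < 0.0) {
        p1 = c; p2 = b;
        nrm[0] = -nrm[0]; nrm[1] = -nrm[1]; nrm[2] = -nrm[2];
    }
    acc.area += 0.5 * std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    // divergence theorem: signed volume of tetrahedron (origin, a, p1, p2)
    acc.volume += (a[0] * (p1[1] * p2[2] - p1[2] * p2[1]) -
                   a[1] * (p1[0] * p2[2] - p1[2] * p2[0]) +
                   a[2] * (p1[0] * p2[1] - p1[1] * p2[0])) / 6.0;
    acc.verts.insert(acc.verts.end(), {a[0], a[1], a[2],
                                       p1[0], p1[1], p1[2],
                                       p2[0], p2[1], p2[2]});
}

static void edge_point(const double* p, const double* q, double vp, double vq,
                       double iso, double* out) {
    double t = (iso - vp) / (vq - vp);
    out[0] = p[0] + t * (q[0] - p[0]);
    out[1] = p[1] + t * (q[1] - p[1]);
    out[2] = p[2] + t * (q[2] - p[2]);
}

static void march_tet(MeshAcc& acc, const double pts[4][3], const double val[4],
                      double iso) {
    bool in[4];
    int nin = 0;
    for (int t = 0; t < 4; ++t) {
        in[t] = val[t] >= iso;
        if (in[t]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4];
    int a = 0, b = 0;
    for (int t = 0; t < 4; ++t) (in[t] ? ins[a++] : outs[b++]) = t;
    double e[4][3];
    if (nin == 1) {
        for (int t = 0; t < 3; ++t)
            edge_point(pts[ins[0]], pts[outs[t]], val[ins[0]], val[outs[t]], iso, e[t]);
        emit_tri(acc, e[0], e[1], e[2], pts[ins[0]]);
    } else if (nin == 3) {
        for (int t = 0; t < 3; ++t)
            edge_point(pts[ins[t]], pts[outs[0]], val[ins[t]], val[outs[0]], iso, e[t]);
        emit_tri(acc, e[0], e[1], e[2], pts[ins[0]]);
    } else {
        // quad: crossings on edges p-r, p-s, q-s, q-r form a cycle
        int p = ins[0], q = ins[1], r = outs[0], s = outs[1];
        edge_point(pts[p], pts[r], val[p], val[r], iso, e[0]);
        edge_point(pts[p], pts[s], val[p], val[s], iso, e[1]);
        edge_point(pts[q], pts[s], val[q], val[s], iso, e[2]);
        edge_point(pts[q], pts[r], val[q], val[r], iso, e[3]);
        emit_tri(acc, e[0], e[1], e[2], pts[p]);
        emit_tri(acc, e[0], e[2], e[3], pts[q]);
    }
}

// 6-tetrahedron decomposition of each cell around the main diagonal.
static const int TET6[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

// Mesh the iso-surface of a scalar occupancy field.  The field is
// implicitly padded with zeros so the surface closes at the image boundary.
// Voxel centres sit at index * spacing (mm).  Returns area (mm^2), volume
// (mm^3) and the triangle vertices (mm) for diameter computations.
// [[Rcpp::export]]
List cpp_mesh_field(NumericVector mask, IntegerVector dims, NumericVector spacing,
                    double iso) {
    const int* d = INTEGER(dims);
    MeshAcc acc;
    double pts[8][3];
    double val[8];
    // cells span padded index range [-1, d]; corner c of cell (i,j,k) is
    // voxel (i+cx, j+cy, k+cz) with bit order (x, y, z)
    for (int k = -1; k < d[2]; ++k)
        for (int j = -1; j < d[1]; ++j)
            for (int i = -1; i < d[0]; ++i) {
                int occ = 0;
                for (int c = 0; c < 8; ++c) {
                    int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
                    double v = 0.0;
                    if (ci >= 0 && cj >= 0 && ck >= 0 &&
                        ci < d[0] && cj < d[1] && ck < d[2])
                        v = mask[idx3(ci, cj, ck, d)];
                    val[c] = v;
                    if (v >= iso) ++occ;
                    pts[c][0] = ci * spacing[0];
                    pts[c][1] = cj * spacing[1];
                    pts[c][2] = ck * spacing[2];
                }
                if (occ == 0 || occ == 8) continue;
                for (int t = 0; t < 6; ++t) {
                    double tp[4][3], tv[4];
                    for (int c = 0; c < 4; ++c) {
                        int v8 = TET6[t][c];
                        tp[c][0] = pts[v8][0];
                        tp[c][1] = pts[v8][1];
                        tp[c][2] = pts[v8][2];
                        tv[c] = val[v8];
                    }
                    march_tet(acc, tp, tv, iso);
                }
            }
    int ntri = (int)(acc.verts.size() / 9);
    NumericMatrix verts(3 * ntri, 3);
    for (int t = 0; t < 3 * ntri; ++t) {
        verts(t, 0) = acc.verts[3 * t];
        verts(t, 1) = acc.verts[3 * t + 1];
        verts(t, 2) = acc.verts[3 * t + 2];
    }
    return List::create(_["area"] = acc.area,
                        _["volume"] = std::fabs(acc.volume),
                        _["vertices"] = verts);
}
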