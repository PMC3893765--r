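#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact Euclidean distance transform, separable lower-envelope algorithm
// (Felzenszwalb & Huttenlocher, Theory of Computing 2012). Works one axis at
// a time on squared distances; `step` is the physical voxel spacing along the
// axis, so anisotropic grids are handled exactly.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform of sampled function f at abscissae i*step.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step, int n) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = -1;  // envelope built from finite parabolas only
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue;
        double xq = q * step;
        double s = 0.0;
        while (k >= 0) {
            double xv = v[k] * step;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * (xq - xv));
            if (s <= z[k]) --k; else break;
        }
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
        } else {
            ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
        }
    }
    if (k < 0) {
        // whole line empty: propagate infinity
        for (int q = 0; q < n; ++q) d[q] = INF;
        return;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * step;
        while (z[k + 1] < xq) ++k;
        double dx = xq - v[k] * step;
        d[q] = dx * dx + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(NumericVector mask, IntegerVector dim,
                       NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dim");
    NumericVector out(n);
    // seed: 0 on target voxels, +inf elsewhere
    for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] != 0) ? 0.0 : INF;

    std::vector<double> f, d;

    // pass along x (fastest-varying index)
    f.resize(nx); d.resize(nx);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
            for (int x = 0; x < nx; ++x) f[x] = out[base + x];
            dt1d(f, d, spacing[0], nx);
            for (int x = 0; x < nx; ++x) out[base + x] = d[x];
        }

    // pass along y
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + x;
            for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
            dt1d(f, d, spacing[1], ny);
            for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
        }

    // pass along z
    f.resize(nz); d.resize(nz);
    const R_xlen_t zstride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int z = 0; z < nz; ++z) f[z] = out[base + z * zstride];
            dt1d(f, d, spacing[2], nz);
            for (int z = 0; z < nz; ++z) out[base + z * zstride] = d[z];
        }

    return out;
}
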