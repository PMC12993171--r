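#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm).
// LARGE stands in for +Inf; grids are at most a few hundred voxels per axis,
// so q^2 never approaches it.
static const double LARGE = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -LARGE;
    z[1] = LARGE;
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
        z[k + 1] = LARGE;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        double dq = (double)q - v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++)
        out[i] = (mask[i] == TRUE) ? 0.0 : LARGE;

    std::vector<double> f, d;

    // pass along x
    f.resize(nx); d.resize(nx);
    for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
            for (int x = 0; x < nx; x++) f[x] = out[base + x];
            dt1d(f, d, nx);
            for (int x = 0; x < nx; x++) out[base + x] = d[x];
        }

    // pass along y
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; z++)
        for (int x = 0; x < nx; x++) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + x;
            for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
            dt1d(f, d, ny);
            for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
        }

    // pass along z
    f.resize(nz); d.resize(nz);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
            R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * nxy];
            dt1d(f, d, nz);
            for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nxy] = d[z];
        }

    out.attr("dim") = dims;
    return out;
}
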