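#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected-component labeling on a 3D binary grid.
//
// Labels are assigned in column-major scan order (the R array layout), so the
// component containing the first true voxel in that order gets label 1. BFS
// keeps recursion depth bounded on large confluent lesions.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
    if (connectivity != 6 && connectivity != 26)
        stop("connectivity must be 6 or 26");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n, 0);

    // neighbour offsets
    std::vector<int> dx, dy, dz;
    for (int k = -1; k <= 1; ++k)
        for (int j = -1; j <= 1; ++j)
            for (int i = -1; i <= 1; ++i) {
                if (i == 0 && j == 0 && k == 0) continue;
                int manh = std::abs(i) + std::abs(j) + std::abs(k);
                if (connectivity == 6 && manh != 1) continue;
                dx.push_back(i); dy.push_back(j); dz.push_back(k);
            }
    const int noff = (int)dx.size();

    int next = 0;
    std::queue<R_xlen_t> q;
    for (R_xlen_t idx = 0; idx < n; ++idx) {
        if (!mask[idx] || labels[idx] != 0) continue;
        ++next;
        labels[idx] = next;
        q.push(idx);
        while (!q.empty()) {
            R_xlen_t cur = q.front(); q.pop();
            int cz = (int)(cur / ((R_xlen_t)nx * ny));
            int rem = (int)(cur % ((R_xlen_t)nx * ny));
            int cy = rem / nx, cx = rem % nx;
            for (int m = 0; m < noff; ++m) {
                int x = cx + dx[m], y = cy + dy[m], z = cz + dz[m];
                if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
                R_xlen_t nb = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
                if (mask[nb] && labels[nb] == 0) {
                    labels[nb] = next;
                    q.push(nb);
                }
            }
        }
    }
    labels.attr("n_components") = next;
    return labels;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform with per-axis physical spacing
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas algorithm applied
// separably along each axis with sample spacing w).
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
    static const double INF = std::numeric_limits<double>::infinity();
    std::vector<int> ids;
    ids.reserve(n);
    for (int i = 0; i < n; ++i)
        if (f[i] < INF) ids.push_back(i);
    if (ids.empty()) {
        std::fill(d.begin(), d.begin() + n, INF);
        return;
    }
    const int m = (int)ids.size();
    std::vector<int> v(m);
    std::vector<double> z(m + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int qj = 1; qj < m; ++qj) {
        double pq = ids[qj] * w;
        double s;
        while (true) {
            double pv = ids[v[k]] * w;
            s = ((f[ids[qj]] + pq * pq) - (f[ids[v[k]]] + pv * pv)) / (2 * pq - 2 * pv);
            if (s <= z[k] && k > 0) { --k; continue; }
            break;
        }
        ++k;
        v[k] = qj;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int qi = 0; qi < n; ++qi) {
        double pq = qi * w;
        while (z[k + 1] < pq) ++k;
        double diff = pq - ids[v[k]] * w;
        d[qi] = diff * diff + f[ids[v[k]]];
    }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
    const double INF = std::numeric_limits<double>::infinity();
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

    int maxdim = std::max(nx, std::max(ny, nz));
    std::vector<double> f(maxdim), d(maxdim);

    // along x
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
            for (int x = 0; x < nx; ++x) f[x] = out[base + x];
            dt1d(f, d, nx, spacing[0]);
            for (int x = 0; x < nx; ++x) out[base + x] = d[x];
        }
    // along y
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + x;
            for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
            dt1d(f, d, ny, spacing[1]);
            for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
        }
    // along z
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nxy];
            dt1d(f, d, nz, spacing[2]);
            for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = d[z];
        }
    return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (reflective boundaries), used to regularize a
// binary occupancy field before isosurface extraction.
// ---------------------------------------------------------------------------

static void conv1d(std::vector<double>& line, const std::vector<double>& kern,
                   std::vector<double>& tmp) {
    int n = (int)line.size();
    int r = ((int)kern.size() - 1) / 2;
    tmp.resize(n);
    for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
            int k = i + j;
            if (k < 0) k = -k - 1;            // reflect
            if (k >= n) k = 2 * n - k - 1;
            acc += line[k] * kern[j + r];
        }
        tmp[i] = acc;
    }
    line = tmp;
}

// [[Rcpp::export(name = ".gauss_smooth3d")]]
NumericVector gauss_smooth3d(NumericVector vol, IntegerVector dims, double sigma) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector out = clone(vol);
    if (sigma <= 0) return out;
    int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int i = -r; i <= r; ++i) {
        kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
        s += kern[i + r];
    }
    for (double& k : kern) k /= s;

    std::vector<double> line, tmp;
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    line.reserve(std::max(nx, std::max(ny, nz)));
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
            line.assign(&out[base], &out[base] + nx);
            conv1d(line, kern, tmp);
            for (int x = 0; x < nx; ++x) out[base + x] = line[x];
        }
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            line.resize(ny);
            R_xlen_t base = (R_xlen_t)z * nxy + x;
            for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
            conv1d(line, kern, tmp);
            for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
        }
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            line.resize(nz);
            R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nxy];
            conv1d(line, kern, tmp);
            for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = line[z];
        }
    return out;
}
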