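#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Incremental 3D convex hull (beneath-beyond), returning hull volume and
// surface area. Inputs are voxel-corner point clouds, which are never
// degenerate: any whole voxel contributes 8 corners spanning a box.
// ---------------------------------------------------------------------------

struct Face {
    int a, b, c;
    double nx, ny, nz, off; // outward normal (not normalized) and offset
    bool alive;
};

static inline void face_plane(const std::vector<double>& X,
                              const std::vector<double>& Y,
                              const std::vector<double>& Z,
                              Face& f, double ix, double iy, double iz) {
    double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
    double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
    f.nx = uy * vz - uz * vy;
    f.ny = uz * vx - ux * vz;
    f.nz = ux * vy - uy * vx;
    f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
    // orient away from the interior reference point
    if (f.nx * ix + f.ny * iy + f.nz * iz > f.off) {
        std::swap(f.b, f.c);
        f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
    }
}

// [[Rcpp::export(name = ".hull3d_metrics")]]
List hull3d_metrics(NumericMatrix pts) {
    const int n = pts.nrow();
    if (n < 4) stop("convex hull needs at least 4 points");
    std::vector<double> X(n), Y(n), Z(n);
    double lo[3], hi[3];
    for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
    for (int i = 0; i < n; ++i) {
        X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
        for (int j = 0; j < 3; ++j) {
            lo[j] = std::min(lo[j], pts(i, j));
            hi[j] = std::max(hi[j], pts(i, j));
        }
    }
    double diag = 0;
    for (int j = 0; j < 3; ++j) diag += (hi[j] - lo[j]) * (hi[j] - lo[j]);
    diag = std::sqrt(diag);
    if (diag <= 0) stop("degenerate point set: all points coincide");
    const double eps = 1e-9 * diag * diag; // compare against unnormalized planes

    // initial tetrahedron: two extremes, furthest from line, furthest from plane
    int i0 = 0, i1 = 0;
    for (int i = 1; i < n; ++i) {
        if (X[i] < X[i0] || (X[i] == X[i0] && (Y[i] < Y[i0] || (Y[i] == Y[i0] && Z[i] < Z[i0])))) i0 = i;
        if (X[i] > X[i1] || (X[i] == X[i1] && (Y[i] > Y[i1] || (Y[i] == Y[i1] && Z[i] > Z[i1])))) i1 = i;
    }
    if (i0 == i1) stop("degenerate point set");
    double dx = X[i1] - X[i0], dy = Y[i1] - Y[i0], dz = Z[i1] - Z[i0];
    int i2 = -1; double best = 0;
    for (int i = 0; i < n; ++i) {
        double px = X[i] - X[i0], py = Y[i] - Y[i0], pz = Z[i] - Z[i0];
        double cx = dy * pz - dz * py, cy = dz * px - dx * pz, cz = dx * py - dy * px;
        double d2 = cx * cx + cy * cy + cz * cz;
        if (d2 > best) { best = d2; i2 = i; }
    }
    if (i2 < 0 || best <= 0) stop("degenerate point set: collinear");
    double ux = X[i2] - X[i0], uy = Y[i2] - Y[i0], uz = Z[i2] - Z[i0];
    double nx0 = dy * uz - dz * uy, ny0 = dz * ux - dx * uz, nz0 = dx * uy - dy * ux;
    int i3 = -1; best = 0;
    for (int i = 0; i < n; ++i) {
        double d = std::fabs(nx0 * (X[i] - X[i0]) + ny0 * (Y[i] - Y[i0]) + nz0 * (Z[i] - Z[i0]));
        if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0 || best <= 0) stop("degenerate point set: coplanar");

    double ix = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
    double iy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
    double iz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

    std::vector<Face> faces;
    faces.reserve(256);
    int quad[4] = { i0, i1, i2, i3 };
    for (int drop = 0; drop < 4; ++drop) {
        Face f;
        int v[3], k = 0;
        for (int j = 0; j < 4; ++j) if (j != drop) v[k++] = quad[j];
        f.a = v[0]; f.b = v[1]; f.c = v[2];
        f.alive = true;
        face_plane(X, Y, Z, f, ix, iy, iz);
        faces.push_back(f);
    }

    std::vector<int> visible;
    std::unordered_set<long long> vis_edges;
    std::vector<std::pair<int, int> > horizon;
    for (int p = 0; p < n; ++p) {
        if (p == i0 || p == i1 || p == i2 || p == i3) continue;
        visible.clear();
        for (int fi = 0; fi < (int)faces.size(); ++fi) {
            if (!faces[fi].alive) continue;
            const Face& f = faces[fi];
            if (f.nx * X[p] + f.ny * Y[p] + f.nz * Z[p] - f.off > eps)
                visible.push_back(fi);
        }
        if (visible.empty()) continue;
        vis_edges.clear();
        for (int fi : visible) {
            const Face& f = faces[fi];
            vis_edges.insert((long long)f.a * n + f.b);
            vis_edges.insert((long long)f.b * n + f.c);
            vis_edges.insert((long long)f.c * n + f.a);
        }
        horizon.clear();
        for (int fi : visible) {
            const Face& f = faces[fi];
            int e[3][2] = { { f.a, f.b }, { f.b, f.c }, { f.c, f.a } };
            for (int j = 0; j < 3; ++j)
                if (!vis_edges.count((long long)e[j][1] * n + e[j][0]))
                    horizon.push_back(std::make_pair(e[j][0], e[j][1]));
        }
        for (int fi : visible) faces[fi].alive = false;
        for (size_t h = 0; h < horizon.size(); ++h) {
            Face f;
            f.a = horizon[h].first; f.b = horizon[h].second; f.c = p;
            f.alive = true;
            face_plane(X, Y, Z, f, ix, iy, iz);
            faces.push_back(f);
        }
    }

    double vol = 0.0, area = 0.0;
    int nf = 0;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
        if (!faces[fi].alive) continue;
        const Face& f = faces[fi];
        double ax = X[f.a] - ix, ay = Y[f.a] - iy, az = Z[f.a] - iz;
        double bx = X[f.b] - ix, by = Y[f.b] - iy, bz = Z[f.b] - iz;
        double cx = X[f.c] - ix, cy = Y[f.c] - iy, cz = Z[f.c] - iz;
        vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx)) / 6.0;
        double nlen = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
        area += nlen / 2.0;
        ++nf;
    }
    return List::create(_["volume"] = vol, _["area"] = area, _["n_faces"] = nf);
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra: each grid cell is split into six
// tetrahedra sharing the main diagonal; the isosurface of the per-tet linear
// interpolant is triangulated and its area accumulated. Intersections lie on
// shared tet edges, so the surface is watertight across cells.
// ---------------------------------------------------------------------------

static const int TETS[6][4] = {
    { 0, 1, 5, 7 }, { 0, 5, 4, 7 }, { 0, 4, 6, 7 },
    { 0, 6, 2, 7 }, { 0, 2, 3, 7 }, { 0, 3, 1, 7 }
};

static inline double tri_area(const double p[3], const double q[3], const double r[3]) {
    double ux = q[0] - p[0], uy = q[1] - p[1], uz = q[2] - p[2];
    double vx = r[0] - p[0], vy = r[1] - p[1], vz = r[2] - p[2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void edge_point(const double va, const double vb,
                              const double pa[3], const double pb[3],
                              double level, double out[3]) {
    double t = (level - va) / (vb - va);
    if (!std::isfinite(t)) t = 0.5;
    if (t < 0) t = 0; else if (t > 1) t = 1;
    for (int j = 0; j < 3; ++j) out[j] = pa[j] + t * (pb[j] - pa[j]);
}

// [[Rcpp::export(name = ".isosurface_area")]]
double isosurface_area(NumericVector vol, IntegerVector dims,
                       NumericVector spacing, double level) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    double area = 0.0;

    double corner[8][3];
    double fv[8];
    for (int z = 0; z + 1 < nz; ++z)
        for (int y = 0; y + 1 < ny; ++y)
            for (int x = 0; x + 1 < nx; ++x) {
                bool any_in = false, any_out = false;
                for (int c = 0; c < 8; ++c) {
                    int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
                    fv[c] = vol[(R_xlen_t)cz * nxy + (R_xlen_t)cy * nx + cx];
                    corner[c][0] = cx * spacing[0];
                    corner[c][1] = cy * spacing[1];
                    corner[c][2] = cz * spacing[2];
                    if (fv[c] > level) any_in = true; else any_out = true;
                }
                if (!any_in || !any_out) continue;
                for (int t = 0; t < 6; ++t) {
                    int vin[4], vout[4], nin = 0, nout = 0;
                    for (int j = 0; j < 4; ++j) {
                        int c = TETS[t][j];
                        if (fv[c] > level) vin[nin++] = c; else vout[nout++] = c;
                    }
                    if (nin == 0 || nin == 4) continue;
                    if (nin == 1 || nin == 3) {
                        int apex = (nin == 1) ? vin[0] : vout[0];
                        int* base = (nin == 1) ? vout : vin;
                        double p0[3], p1[3], p2[3];
                        edge_point(fv[apex], fv[base[0]], corner[apex], corner[base[0]], level, p0);
                        edge_point(fv[apex], fv[base[1]], corner[apex], corner[base[1]], level, p1);
                        edge_point(fv[apex], fv[base[2]], corner[apex], corner[base[2]], level, p2);
                        area += tri_area(p0, p1, p2);
                    } else { // 2 in, 2 out: quad section
                        double p00[3], p01[3], p11[3], p10[3];
                        edge_point(fv[vin[0]], fv[vout[0]], corner[vin[0]], corner[vout[0]], level, p00);
                        edge_point(fv[vin[0]], fv[vout[1]], corner[vin[0]], corner[vout[1]], level, p01);
                        edge_point(fv[vin[1]], fv[vout[1]], corner[vin[1]], corner[vout[1]], level, p11);
                        edge_point(fv[vin[1]], fv[vout[0]], corner[vin[1]], corner[vout[0]], level, p10);
                        area += tri_area(p00, p01, p11);
                        area += tri_area(p00, p11, p10);
                    }
                }
            }
    return area;
}
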