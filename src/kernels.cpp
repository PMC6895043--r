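#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
}

// Sum of truncated isotropic Gaussians on a regular grid.
// Grid is column-major with x fastest; `origin` is the centre of voxel
// (0,0,0).  Contributions beyond `rcut` from an atom are dropped.
// [[Rcpp::export]]
NumericVector cpp_splat(const NumericMatrix& xyz, const NumericVector& amp,
                        const IntegerVector& gdim, const NumericVector& origin,
                        const NumericVector& voxel, double sigma, double rcut) {
    const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
    NumericVector out((R_xlen_t)nx * ny * nz);
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    const double rcut2 = rcut * rcut;
    for (int a = 0; a < xyz.nrow(); ++a) {
        const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
        const double w = amp[a];
        int i0 = (int)std::ceil((ax - rcut - origin[0]) / voxel[0]);
        int i1 = (int)std::floor((ax + rcut - origin[0]) / voxel[0]);
        int j0 = (int)std::ceil((ay - rcut - origin[1]) / voxel[1]);
        int j1 = (int)std::floor((ay + rcut - origin[1]) / voxel[1]);
        int k0 = (int)std::ceil((az - rcut - origin[2]) / voxel[2]);
        int k1 = (int)std::floor((az + rcut - origin[2]) / voxel[2]);
        if (i1 < 0 || j1 < 0 || k1 < 0 || i0 >= nx || j0 >= ny || k0 >= nz)
            continue;  // atom outside the grid support: contributes nothing
        i0 = clampi(i0, 0, nx - 1); i1 = clampi(i1, 0, nx - 1);
        j0 = clampi(j0, 0, ny - 1); j1 = clampi(j1, 0, ny - 1);
        k0 = clampi(k0, 0, nz - 1); k1 = clampi(k1, 0, nz - 1);
        for (int k = k0; k <= k1; ++k) {
            const double dz = origin[2] + k * voxel[2] - az;
            const double dz2 = dz * dz;
            if (dz2 > rcut2) continue;
            for (int j = j0; j <= j1; ++j) {
                const double dy = origin[1] + j * voxel[1] - ay;
                const double dyz2 = dz2 + dy * dy;
                if (dyz2 > rcut2) continue;
                const R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
                for (int i = i0; i <= i1; ++i) {
                    const double dx = origin[0] + i * voxel[0] - ax;
                    const double d2 = dyz2 + dx * dx;
                    if (d2 <= rcut2)
                        out[base + i] += w * std::exp(-d2 * inv2s2);
                }
            }
        }
    }
    return out;
}

// 12-6 energy between two disjoint atom sets (each unordered cross pair
// counted once):  sum eps_ij [ (r_ij/d)^12 - 2 (r_ij/d)^6 ],
// r_ij = ra_i + rb_j, eps_ij = sqrt(ea_i * eb_j).  Pairs beyond `cutoff`
// contribute zero; coincident atoms give +Inf.
// [[Rcpp::export]]
double cpp_clash_pair(const NumericMatrix& xa, const NumericVector& ea,
                      const NumericVector& ra, const NumericMatrix& xb,
                      const NumericVector& eb, const NumericVector& rb,
                      double cutoff) {
    const double c2 = cutoff * cutoff;
    double E = 0.0;
    for (int i = 0; i < xa.nrow(); ++i) {
        const double xi = xa(i, 0), yi = xa(i, 1), zi = xa(i, 2);
        for (int j = 0; j < xb.nrow(); ++j) {
            const double dx = xi - xb(j, 0);
            const double dy = yi - xb(j, 1);
            const double dz = zi - xb(j, 2);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > c2) continue;
            if (d2 < 1e-24) return R_PosInf;
            const double rij = ra[i] + rb[j];
            const double s2 = rij * rij / d2;
            const double s6 = s2 * s2 * s2;
            E += std::sqrt(ea[i] * eb[j]) * (s6 * s6 - 2.0 * s6);
        }
    }
    return E;
}

// Running sums for Pearson CC after swapping one body's density
// contribution: c' = calc - oldb + newb.  Returns (sum c', sum c'^2,
// sum obs*c').
// [[Rcpp::export]]
NumericVector cpp_cc_sums(const NumericVector& obs, const NumericVector& calc,
                          const NumericVector& oldb, const NumericVector& newb) {
    const R_xlen_t n = obs.size();
    double s1 = 0.0, s2 = 0.0, sxy = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        const double c = calc[i] - oldb[i] + newb[i];
        s1 += c;
        s2 += c * c;
        sxy += obs[i] * c;
    }
    return NumericVector::create(s1, s2, sxy);
}

// 1-based linear indices of voxels whose centre lies strictly closer than
// `radius` to any of the given atoms.
// [[Rcpp::export]]
IntegerVector cpp_voxel_mask(const NumericMatrix& xyz, const IntegerVector& gdim,
                             const NumericVector& origin, const NumericVector& voxel,
                             double radius) {
    const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
    const double r2 = radius * radius;
    std::vector<bool> hit((size_t)nx * ny * nz, false);
    for (int a = 0; a < xyz.nrow(); ++a) {
        const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
        int i0 = clampi((int)std::ceil((ax - radius - origin[0]) / voxel[0]), 0, nx - 1);
        int i1 = clampi((int)std::floor((ax + radius - origin[0]) / voxel[0]), 0, nx - 1);
        int j0 = clampi((int)std::ceil((ay - radius - origin[1]) / voxel[1]), 0, ny - 1);
        int j1 = clampi((int)std::floor((ay + radius - origin[1]) / voxel[1]), 0, ny - 1);
        int k0 = clampi((int)std::ceil((az - radius - origin[2]) / voxel[2]), 0, nz - 1);
        int k1 = clampi((int)std::floor((az + radius - origin[2]) / voxel[2]), 0, nz - 1);
        for (int k = k0; k <= k1; ++k) {
            const double dz = origin[2] + k * voxel[2] - az;
            for (int j = j0; j <= j1; ++j) {
                const double dy = origin[1] + j * voxel[1] - ay;
                const double dyz2 = dz * dz + dy * dy;
                if (dyz2 >= r2) continue;
                const size_t base = ((size_t)k * ny + j) * nx;
                for (int i = i0; i <= i1; ++i) {
                    const double dx = origin[0] + i * voxel[0] - ax;
                    if (dyz2 + dx * dx < r2) hit[base + i] = true;
                }
            }
        }
    }
    std::vector<int> idx;
    for (size_t t = 0; t < hit.size(); ++t)
        if (hit[t]) idx.push_back((int)t + 1);
    return wrap(idx);
}
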