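#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx): column-major, so the flat
// index of voxel (z, y, x) is z + nz * (y + ny * x). z is the page axis.

// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask, int nz, int ny, int nx) {
    // 26-connected component labelling by iterative flood fill.
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    IntegerVector out(n, 0);
    std::vector<R_xlen_t> stack;
    int next_label = 0;
    for (R_xlen_t start = 0; start < n; ++start) {
        if (!mask[start] || out[start] != 0) continue;
        ++next_label;
        out[start] = next_label;
        stack.push_back(start);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int z = (int)(v % nz);
            int y = (int)((v / nz) % ny);
            int x = (int)(v / ((R_xlen_t)nz * ny));
            for (int dx = -1; dx <= 1; ++dx) {
                int xx = x + dx;
                if (xx < 0 || xx >= nx) continue;
                for (int dy = -1; dy <= 1; ++dy) {
                    int yy = y + dy;
                    if (yy < 0 || yy >= ny) continue;
                    for (int dz = -1; dz <= 1; ++dz) {
                        int zz = z + dz;
                        if (zz < 0 || zz >= nz) continue;
                        R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                        if (mask[w] && out[w] == 0) {
                            out[w] = next_label;
                            stack.push_back(w);
                        }
                    }
                }
            }
        }
    }
    return out;
}

struct Offset {
    int dz, dy, dx, d2;
};

// [[Rcpp::export]]
IntegerVector cpp_build_shells(const IntegerVector& labels, int nz, int ny, int nx,
                               int radius) {
    // Shell voxels: background voxels within Euclidean distance `radius`
    // (voxel units) of at least one labelled voxel. Ownership goes to the
    // label with the nearest voxel; ties to the smaller label id. Labelled
    // (nucleus) voxels are never part of any shell.
    std::vector<Offset> offs;
    for (int dz = -radius; dz <= radius; ++dz)
        for (int dy = -radius; dy <= radius; ++dy)
            for (int dx = -radius; dx <= radius; ++dx) {
                int d2 = dz * dz + dy * dy + dx * dx;
                if (d2 > 0 && d2 <= radius * radius)
                    offs.push_back({dz, dy, dx, d2});
            }
    std::sort(offs.begin(), offs.end(),
              [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });

    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    IntegerVector out(n, 0);
    const int* L = INTEGER(labels);
    int* O = INTEGER(out);
    const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
    const int no = (int)offs.size();
    for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
            R_xlen_t row = y * sy + x * sx;
            bool inner_yx = (x >= radius && x < nx - radius &&
                             y >= radius && y < ny - radius);
            for (int z = 0; z < nz; ++z) {
                R_xlen_t v = row + z;
                if (L[v] != 0) continue;
                int best_d2 = INT_MAX, best_lab = 0;
                if (inner_yx && z >= radius && z < nz - radius) {
                    for (int oi = 0; oi < no; ++oi) {
                        const Offset& o = offs[oi];
                        if (o.d2 > best_d2) break;
                        int lab = L[v + o.dz + (R_xlen_t)o.dy * sy +
                                    (R_xlen_t)o.dx * sx];
                        if (lab == 0) continue;
                        if (o.d2 < best_d2 || lab < best_lab) {
                            best_d2 = o.d2;
                            best_lab = lab;
                        }
                    }
                } else {
                    for (int oi = 0; oi < no; ++oi) {
                        const Offset& o = offs[oi];
                        if (o.d2 > best_d2) break;
                        int zz = z + o.dz, yy = y + o.dy, xx = x + o.dx;
                        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                            xx < 0 || xx >= nx)
                            continue;
                        int lab = L[zz + (R_xlen_t)sy * yy + (R_xlen_t)sx * xx];
                        if (lab == 0) continue;
                        if (o.d2 < best_d2 || lab < best_lab) {
                            best_d2 = o.d2;
                            best_lab = lab;
                        }
                    }
                }
                if (best_lab > 0) O[v] = best_lab;
            }
        }
    }
    return out;
}

static std::vector<double> gauss_kernel(double sigma) {
    int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * r + 1);
    double s = 0.0;
    for (int i = -r; i <= r; ++i) {
        double w = std::exp(-0.5 * (double)i * i / (sigma * sigma));
        k[i + r] = w;
        s += w;
    }
    for (double& w : k) w /= s;
    return k;
}

static void conv_axis(std::vector<double>& a, int nz, int ny, int nx, int axis,
                      const std::vector<double>& k) {
    // In-place separable convolution along one axis with reflect boundary.
    int r = ((int)k.size() - 1) / 2;
    int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
    std::vector<double> line(len);
    R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nz : (R_xlen_t)nz * ny);
    int n1 = axis == 0 ? ny : nz;
    int n2 = axis == 2 ? ny : nx;
    R_xlen_t s1 = axis == 0 ? nz : 1;
    R_xlen_t s2 = axis == 2 ? nz : (R_xlen_t)nz * ny;
    const double* kc = k.data() + r;
    for (int i1 = 0; i1 < n1; ++i1) {
        for (int i2 = 0; i2 < n2; ++i2) {
            R_xlen_t base = i1 * s1 + i2 * s2;
            for (int j = 0; j < len; ++j) line[j] = a[base + (R_xlen_t)j * stride];
            int lo = std::min(r, len);
            int hi = std::max(len - r, lo);
            for (int j = lo; j < hi; ++j) {          // interior: no clamping
                double acc = 0.0;
                const double* lj = line.data() + j;
                for (int t = -r; t <= r; ++t) acc += kc[t] * lj[t];
                a[base + (R_xlen_t)j * stride] = acc;
            }
            auto clamped = [&](int jb) {             // boundary: reflect+clamp
                double acc = 0.0;
                for (int t = -r; t <= r; ++t) {
                    int jj = jb + t;
                    if (jj < 0) jj = -jj - 1;
                    if (jj >= len) jj = 2 * len - jj - 1;
                    if (jj < 0) jj = 0;              // very short axes
                    if (jj >= len) jj = len - 1;
                    acc += kc[t] * line[jj];
                }
                a[base + (R_xlen_t)jb * stride] = acc;
            };
            for (int jb = 0; jb < lo; ++jb) clamped(jb);
            for (int jb = hi; jb < len; ++jb) clamped(jb);
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(const NumericVector& vol, int nz, int ny, int nx,
                                double sigma_z, double sigma_y, double sigma_x) {
    std::vector<double> a(vol.begin(), vol.end());
    if (sigma_z > 0) conv_axis(a, nz, ny, nx, 0, gauss_kernel(sigma_z));
    if (sigma_y > 0) conv_axis(a, nz, ny, nx, 1, gauss_kernel(sigma_y));
    if (sigma_x > 0) conv_axis(a, nz, ny, nx, 2, gauss_kernel(sigma_x));
    return NumericVector(a.begin(), a.end());
}

// [[Rcpp::export]]
List cpp_gradient_laplacian(const NumericVector& vol, int nz, int ny, int nx,
                            double dz, double dy, double dx) {
    // Central-difference gradient magnitude and Laplacian in physical units.
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    NumericVector grad(n), lap(n);
    const double* a = REAL(vol);
    double* gr = REAL(grad);
    double* lp = REAL(lap);
    const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
    for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
            R_xlen_t row = y * sy + x * sx;
            for (int z = 0; z < nz; ++z) {
                R_xlen_t v = row + z;
                R_xlen_t zp = z + 1 < nz ? v + 1 : v, zm = z > 0 ? v - 1 : v;
                R_xlen_t yp = y + 1 < ny ? v + sy : v, ym = y > 0 ? v - sy : v;
                R_xlen_t xp = x + 1 < nx ? v + sx : v, xm = x > 0 ? v - sx : v;
                double gz = (a[zp] - a[zm]) / ((zp != v && zm != v ? 2.0 : 1.0) * dz);
                double gy = (a[yp] - a[ym]) / ((yp != v && ym != v ? 2.0 : 1.0) * dy);
                double gx = (a[xp] - a[xm]) / ((xp != v && xm != v ? 2.0 : 1.0) * dx);
                gr[v] = std::sqrt(gz * gz + gy * gy + gx * gx);
                lp[v] = (a[zp] - 2.0 * a[v] + a[zm]) / (dz * dz) +
                        (a[yp] - 2.0 * a[v] + a[ym]) / (dy * dy) +
                        (a[xp] - 2.0 * a[v] + a[xm]) / (dx * dx);
            }
        }
    }
    return List::create(_["gradient"] = grad, _["laplacian"] = lap);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(const NumericMatrix& Xt,
                                 const IntegerVector& tree_offsets,
                                 const IntegerVector& left,
                                 const IntegerVector& right,
                                 const IntegerVector& splitvar,
                                 const NumericVector& splitval,
                                 const NumericVector& pred) {
    // Mean terminal-node probability over trees; numeric splits send
    // value <= splitval to the left child (ranger convention).
    // Xt is features x observations so one observation is contiguous.
    const int p = Xt.nrow();
    const R_xlen_t n = Xt.ncol();
    const int ntree = tree_offsets.size();
    const double* x = REAL(Xt);
    const int* off = INTEGER(tree_offsets);
    const int* lf = INTEGER(left);
    const int* rg = INTEGER(right);
    const int* sv = INTEGER(splitvar);
    const double* sp = REAL(splitval);
    const double* pr = REAL(pred);
    NumericVector out(n);
    double* o = REAL(out);
    for (R_xlen_t i = 0; i < n; ++i) {
        const double* xi = x + i * p;
        double acc = 0.0;
        for (int t = 0; t < ntree; ++t) {
            const int base = off[t];
            int node = base;
            while (lf[node] >= 0) {
                node = base + (xi[sv[node]] <= sp[node] ? lf[node] : rg[node]);
            }
            acc += pr[node];
        }
        o[i] = acc / ntree;
    }
    return out;
}
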