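#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Separable 3D Gaussian filter with zero padding. The 1D kernels are
// truncated at `truncate` standard deviations and renormalised to unit sum,
// so filtering a {0,1} mask yields values in [0, 1]. sigma is in voxels; a
// zero sigma along an axis leaves that axis untouched.

static std::vector<double> gauss_kernel(double sigma, double truncate, int &radius) {
    if (sigma <= 0.0) { radius = 0; return std::vector<double>(1, 1.0); }
    radius = (int)std::ceil(truncate * sigma);
    std::vector<double> k(2 * radius + 1);
    double sum = 0.0;
    for (int i = -radius; i <= radius; ++i) {
        double v = std::exp(-0.5 * (i / sigma) * (i / sigma));
        k[i + radius] = v;
        sum += v;
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= sum;
    return k;
}

static void conv_axis(std::vector<double> &vals, int nx, int ny, int nz,
                      const std::vector<double> &kern, int radius, int axis) {
    if (radius == 0) return;
    std::vector<double> tmp(vals.size());
    int n[3] = {nx, ny, nz};
    R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
    int na = n[axis];
    R_xlen_t sa = stride[axis];
    // iterate over all lines along `axis`
    int nb = n[(axis + 1) % 3], nc = n[(axis + 2) % 3];
    R_xlen_t sb = stride[(axis + 1) % 3], sc = stride[(axis + 2) % 3];
    for (int c = 0; c < nc; ++c) {
        for (int b = 0; b < nb; ++b) {
            R_xlen_t base = sb * b + sc * c;
            for (int a = 0; a < na; ++a) {
                double acc = 0.0;
                int lo = std::max(0, a - radius), hi = std::min(na - 1, a + radius);
                for (int t = lo; t <= hi; ++t)
                    acc += kern[t - a + radius] * vals[base + sa * t];
                tmp[base + sa * a] = acc;
            }
        }
    }
    vals.swap(tmp);
}

// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector values, IntegerVector dims,
                                NumericVector sigma_vox, double truncate) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    std::vector<double> vals(values.begin(), values.end());
    for (int axis = 0; axis < 3; ++axis) {
        int radius;
        std::vector<double> k = gauss_kernel(sigma_vox[axis], truncate, radius);
        conv_axis(vals, nx, ny, nz, k, radius, axis);
    }
    return NumericVector(vals.begin(), vals.end());
}

// Binary dilation/erosion by an arbitrary structuring element given as a
// matrix of integer offsets (one row per element voxel).

// [[Rcpp::export]]
LogicalVector binary_morph_cpp(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix offsets, bool dilate) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int noff = offsets.nrow();
    LogicalVector out((R_xlen_t)nx * ny * nz);
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i, ++idx) {
                bool hit = dilate ? false : true;
                for (int o = 0; o < noff; ++o) {
                    int ii = i + offsets(o, 0), jj = j + offsets(o, 1),
                        kk = k + offsets(o, 2);
                    bool v;
                    if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                        v = false; // outside the grid counts as background
                    else
                        v = mask[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
                    if (dilate) {
                        if (v) { hit = true; break; }
                    } else {
                        if (!v) { hit = false; break; }
                    }
                }
                out[idx] = hit;
            }
        }
    }
    return out;
}

// Connected-component labelling (26-connectivity), returning integer labels
// 1..ncomp in first-voxel order; 0 is background.

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n);
    int cur = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++cur;
        stack.push_back(s);
        lab[s] = cur;
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
            for (int dk = -1; dk <= 1; ++dk) {
                for (int dj = -1; dj <= 1; ++dj) {
                    for (int di = -1; di <= 1; ++di) {
                        if (di == 0 && dj == 0 && dk == 0) continue;
                        int ii = i + di, jj = j + dj, kk = k + dk;
                        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                            continue;
                        R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                        if (mask[w] && lab[w] == 0) {
                            lab[w] = cur;
                            stack.push_back(w);
                        }
                    }
                }
            }
        }
    }
    return lab;
}
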