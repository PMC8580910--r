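#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lanczos-windowed sinc interpolation (radius 4) for resampling a volume
// onto a target grid. `map` is the 4x4 affine sending target voxel indices
// (0-based) to source voxel indices. Kernel weights are renormalised to unit
// sum over the in-bounds taps, so constant images stay constant and exact
// integer coordinates reproduce source values.

static inline double lanczos4(double x) {
    if (x == 0.0) return 1.0;
    double ax = std::fabs(x);
    if (ax >= 4.0) return 0.0;
    double px = M_PI * x;
    return 4.0 * std::sin(px) * std::sin(px / 4.0) / (px * px);
}

// [[Rcpp::export]]
NumericVector resample_lanczos_cpp(NumericVector src, IntegerVector sdim,
                                   NumericMatrix map, IntegerVector tdim) {
    const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
    const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    NumericVector out((R_xlen_t)tx * ty * tz);

    double wx[8], wy[8], wz[8];
    int ixs[8], iys[8], izs[8];

    R_xlen_t idx = 0;
    for (int k = 0; k < tz; ++k) {
        for (int j = 0; j < ty; ++j) {
            for (int i = 0; i < tx; ++i, ++idx) {
                double cx = map(0, 0) * i + map(0, 1) * j + map(0, 2) * k + map(0, 3);
                double cy = map(1, 0) * i + map(1, 1) * j + map(1, 2) * k + map(1, 3);
                double cz = map(2, 0) * i + map(2, 1) * j + map(2, 2) * k + map(2, 3);

                int bx = (int)std::floor(cx), by = (int)std::floor(cy),
                    bz = (int)std::floor(cz);
                int nxt = 0, nyt = 0, nzt = 0;
                for (int t = -3; t <= 4; ++t) {
                    int ix = bx + t;
                    if (ix >= 0 && ix < sx) {
                        double w = lanczos4(cx - ix);
                        if (w != 0.0) { ixs[nxt] = ix; wx[nxt] = w; ++nxt; }
                    }
                    int iy = by + t;
                    if (iy >= 0 && iy < sy) {
                        double w = lanczos4(cy - iy);
                        if (w != 0.0) { iys[nyt] = iy; wy[nyt] = w; ++nyt; }
                    }
                    int iz = bz + t;
                    if (iz >= 0 && iz < sz) {
                        double w = lanczos4(cz - iz);
                        if (w != 0.0) { izs[nzt] = iz; wz[nzt] = w; ++nzt; }
                    }
                }
                if (nxt == 0 || nyt == 0 || nzt == 0) { out[idx] = 0.0; continue; }

                double acc = 0.0, wsum = 0.0;
                for (int c = 0; c < nzt; ++c) {
                    R_xlen_t offz = (R_xlen_t)sx * sy * izs[c];
                    for (int b = 0; b < nyt; ++b) {
                        double wyz = wy[b] * wz[c];
                        R_xlen_t offyz = offz + (R_xlen_t)sx * iys[b];
                        for (int a = 0; a < nxt; ++a) {
                            double w = wx[a] * wyz;
                            acc += w * src[offyz + ixs[a]];
                            wsum += w;
                        }
                    }
                }
                out[idx] = (wsum != 0.0) ? acc / wsum : 0.0;
            }
        }
    }
    return out;
}

// Nearest-neighbour resampling for label/mask volumes; out-of-bounds -> 0.
// [[Rcpp::export]]
NumericVector resample_nearest_cpp(NumericVector src, IntegerVector sdim,
                                   NumericMatrix map, IntegerVector tdim) {
    const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
    const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    NumericVector out((R_xlen_t)tx * ty * tz);
    R_xlen_t idx = 0;
    for (int k = 0; k < tz; ++k) {
        for (int j = 0; j < ty; ++j) {
            for (int i = 0; i < tx; ++i, ++idx) {
                double cx = map(0, 0) * i + map(0, 1) * j + map(0, 2) * k + map(0, 3);
                double cy = map(1, 0) * i + map(1, 1) * j + map(1, 2) * k + map(1, 3);
                double cz = map(2, 0) * i + map(2, 1) * j + map(2, 2) * k + map(2, 3);
                int ix = (int)std::lround(cx), iy = (int)std::lround(cy),
                    iz = (int)std::lround(cz);
                if (ix < 0 || ix >= sx || iy < 0 || iy >= sy || iz < 0 || iz >= sz) {
                    out[idx] = 0.0;
                } else {
                    out[idx] = src[(R_xlen_t)ix + (R_xlen_t)sx * (iy + (R_xlen_t)sy * iz)];
                }
            }
        }
    }
    return out;
}
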