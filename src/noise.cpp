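#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3D simplex noise after Gustavson's reference implementation:
// skewing to a simplicial grid, 12 cube-edge gradients, radial falloff
// (0.6 - d^2)^4 and a final x32 scaling into [-1, 1].

static const int GRAD3[12][3] = {
    {1, 1, 0},  {-1, 1, 0},  {1, -1, 0}, {-1, -1, 0},
    {1, 0, 1},  {-1, 0, 1},  {1, 0, -1}, {-1, 0, -1},
    {0, 1, 1},  {0, -1, 1},  {0, 1, -1}, {0, -1, -1}};

static inline double simplex3_point(double xin, double yin, double zin,
                                    const int *perm) {
    const double F3 = 1.0 / 3.0;
    const double G3 = 1.0 / 6.0;

    double s = (xin + yin + zin) * F3;
    int i = (int)std::floor(xin + s);
    int j = (int)std::floor(yin + s);
    int k = (int)std::floor(zin + s);
    double t = (i + j + k) * G3;
    double x0 = xin - (i - t);
    double y0 = yin - (j - t);
    double z0 = zin - (k - t);

    int i1, j1, k1, i2, j2, k2;
    if (x0 >= y0) {
        if (y0 >= z0)      { i1 = 1; j1 = 0; k1 = 0; i2 = 1; j2 = 1; k2 = 0; }
        else if (x0 >= z0) { i1 = 1; j1 = 0; k1 = 0; i2 = 1; j2 = 0; k2 = 1; }
        else               { i1 = 0; j1 = 0; k1 = 1; i2 = 1; j2 = 0; k2 = 1; }
    } else {
        if (y0 < z0)       { i1 = 0; j1 = 0; k1 = 1; i2 = 0; j2 = 1; k2 = 1; }
        else if (x0 < z0)  { i1 = 0; j1 = 1; k1 = 0; i2 = 0; j2 = 1; k2 = 1; }
        else               { i1 = 0; j1 = 1; k1 = 0; i2 = 1; j2 = 1; k2 = 0; }
    }

    double x1 = x0 - i1 + G3,       y1 = y0 - j1 + G3,       z1 = z0 - k1 + G3;
    double x2 = x0 - i2 + 2.0 * G3, y2 = y0 - j2 + 2.0 * G3, z2 = z0 - k2 + 2.0 * G3;
    double x3 = x0 - 1.0 + 3.0 * G3, y3 = y0 - 1.0 + 3.0 * G3, z3 = z0 - 1.0 + 3.0 * G3;

    int ii = i & 255, jj = j & 255, kk = k & 255;
    int gi0 = perm[ii + perm[jj + perm[kk]]] % 12;
    int gi1 = perm[ii + i1 + perm[jj + j1 + perm[kk + k1]]] % 12;
    int gi2 = perm[ii + i2 + perm[jj + j2 + perm[kk + k2]]] % 12;
    int gi3 = perm[ii + 1 + perm[jj + 1 + perm[kk + 1]]] % 12;

    double n = 0.0;
    double t0 = 0.6 - x0 * x0 - y0 * y0 - z0 * z0;
    if (t0 > 0) {
        t0 *= t0;
        n += t0 * t0 * (GRAD3[gi0][0] * x0 + GRAD3[gi0][1] * y0 + GRAD3[gi0][2] * z0);
    }
    double t1 = 0.6 - x1 * x1 - y1 * y1 - z1 * z1;
    if (t1 > 0) {
        t1 *= t1;
        n += t1 * t1 * (GRAD3[gi1][0] * x1 + GRAD3[gi1][1] * y1 + GRAD3[gi1][2] * z1);
    }
    double t2 = 0.6 - x2 * x2 - y2 * y2 - z2 * z2;
    if (t2 > 0) {
        t2 *= t2;
        n += t2 * t2 * (GRAD3[gi2][0] * x2 + GRAD3[gi2][1] * y2 + GRAD3[gi2][2] * z2);
    }
    double t3 = 0.6 - x3 * x3 - y3 * y3 - z3 * z3;
    if (t3 > 0) {
        t3 *= t3;
        n += t3 * t3 * (GRAD3[gi3][0] * x3 + GRAD3[gi3][1] * y3 + GRAD3[gi3][2] * z3);
    }
    return 32.0 * n;
}

// [[Rcpp::export]]
NumericVector simplex3_cpp(NumericMatrix points, IntegerVector perm) {
    if (perm.size() != 512) stop("permutation table must have 512 entries");
    int n = points.nrow();
    std::vector<int> p(512);
    for (int i = 0; i < 512; ++i) p[i] = perm[i];
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = simplex3_point(points(i, 0), points(i, 1), points(i, 2), p.data());
    return out;
}

// Multi-octave (fractal) combination: sum_n gamma^(n-1) * eta(lacunarity^(n-1) * p),
// optionally normalised by sum_n gamma^(n-1) so the result stays in [-1, 1].
// [[Rcpp::export]]
NumericVector fractal3_cpp(NumericMatrix points, IntegerVector perm, int octaves,
                           double persistence, double lacunarity, bool normalize) {
    if (perm.size() != 512) stop("permutation table must have 512 entries");
    if (octaves < 1) stop("octaves must be >= 1");
    int n = points.nrow();
    std::vector<int> p(512);
    for (int i = 0; i < 512; ++i) p[i] = perm[i];
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double x = points(i, 0), y = points(i, 1), z = points(i, 2);
        double amp = 1.0, freq = 1.0, total = 0.0, norm = 0.0;
        for (int o = 0; o < octaves; ++o) {
            total += amp * simplex3_point(x * freq, y * freq, z * freq, p.data());
            norm += amp;
            amp *= persistence;
            freq *= lacunarity;
        }
        out[i] = normalize ? total / norm : total;
    }
    return out;
}
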