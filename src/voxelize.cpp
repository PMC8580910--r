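#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Parity (even-odd) voxelization of a closed triangle mesh given in
// voxel-index coordinates: a voxel is inside iff a ray from its centre along
// +x crosses the surface an odd number of times. Rays are cast at a fixed
// sub-voxel offset from the integer lattice so that they never hit mesh
// edges or vertices of meshes in general position, which keeps the crossing
// count per column even for watertight input.

// [[Rcpp::export]]
LogicalVector voxelize_parity_cpp(NumericMatrix verts, IntegerMatrix faces,
                                  IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int nface = faces.nrow();
    // offsets applied to ray (y, z) coordinates; irrational-ish, tiny
    const double ey = 3.719e-7, ez = 7.413e-7;

    std::vector<std::vector<double> > cols((size_t)ny * nz);

    for (int fidx = 0; fidx < nface; ++fidx) {
        int a = faces(fidx, 0), b = faces(fidx, 1), c = faces(fidx, 2);
        double x1 = verts(a, 0), y1 = verts(a, 1), z1 = verts(a, 2);
        double x2 = verts(b, 0), y2 = verts(b, 1), z2 = verts(b, 2);
        double x3 = verts(c, 0), y3 = verts(c, 1), z3 = verts(c, 2);

        double ylo = std::min(y1, std::min(y2, y3)), yhi = std::max(y1, std::max(y2, y3));
        double zlo = std::min(z1, std::min(z2, z3)), zhi = std::max(z1, std::max(z2, z3));
        int j0 = std::max(0, (int)std::ceil(ylo - ey));
        int j1 = std::min(ny - 1, (int)std::floor(yhi - ey));
        int k0 = std::max(0, (int)std::ceil(zlo - ez));
        int k1 = std::min(nz - 1, (int)std::floor(zhi - ez));
        if (j0 > j1 || k0 > k1) continue;

        // signed area of the (y, z) projection
        double det = (y2 - y1) * (z3 - z1) - (y3 - y1) * (z2 - z1);
        if (det == 0.0) continue; // ray-parallel face: grazing, measure zero

        for (int j = j0; j <= j1; ++j) {
            double py = j + ey;
            for (int k = k0; k <= k1; ++k) {
                double pz = k + ez;
                // barycentric coordinates in the projection
                double l1 = ((y2 - py) * (z3 - pz) - (y3 - py) * (z2 - pz)) / det;
                double l2 = ((y3 - py) * (z1 - pz) - (y1 - py) * (z3 - pz)) / det;
                double l3 = 1.0 - l1 - l2;
                if (l1 <= 0.0 || l2 <= 0.0 || l3 <= 0.0) continue;
                double xc = l1 * x1 + l2 * x2 + l3 * x3;
                cols[(size_t)j + (size_t)ny * k].push_back(xc);
            }
        }
    }

    LogicalVector out((R_xlen_t)nx * ny * nz);
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            std::vector<double> &xs = cols[(size_t)j + (size_t)ny * k];
            if (xs.empty()) continue;
            if (xs.size() % 2 != 0)
                stop("odd ray-crossing count: mesh is not closed");
            std::sort(xs.begin(), xs.end());
            for (size_t m = 0; m + 1 < xs.size(); m += 2) {
                int ilo = std::max(0, (int)std::ceil(xs[m]));
                int ihi = std::min(nx - 1, (int)std::floor(xs[m + 1]));
                for (int i = ilo; i <= ihi; ++i)
                    out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = TRUE;
            }
        }
    }
    return out;
}
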