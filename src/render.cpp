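#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation in index space. `vol` is a dim1 x dim2 x dim3 array
// (R column-major). Points outside the support [0, dim-1]^3 return 0.
static inline double trilinear_at(const double* vol, const int* dim,
                                  double ix, double iy, double iz) {
    if (ix < 0.0 || iy < 0.0 || iz < 0.0 ||
        ix > dim[0] - 1.0 || iy > dim[1] - 1.0 || iz > dim[2] - 1.0)
        return 0.0;
    int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
    // clamp so that points exactly on the upper face use the last cell
    if (x0 > dim[0] - 2) x0 = dim[0] - 2;
    if (y0 > dim[1] - 2) y0 = dim[1] - 2;
    if (z0 > dim[2] - 2) z0 = dim[2] - 2;
    double fx = ix - x0, fy = iy - y0, fz = iz - z0;
    const R_xlen_t sx = 1, sy = dim[0], sz = (R_xlen_t)dim[0] * dim[1];
    const double* p = vol + x0 * sx + y0 * sy + z0 * sz;
    double c00 = p[0]      * (1 - fx) + p[sx]           * fx;
    double c10 = p[sy]     * (1 - fx) + p[sx + sy]      * fx;
    double c01 = p[sz]     * (1 - fx) + p[sx + sz]      * fx;
    double c11 = p[sy + sz]* (1 - fx) + p[sx + sy + sz] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".cppSampleTrilinear")]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix points) {
    const int n = points.nrow();
    NumericVector out(n);
    int d[3] = { dim[0], dim[1], dim[2] };
    for (int i = 0; i < n; ++i) {
        double ix = (points(i, 0) - origin[0]) / spacing[0];
        double iy = (points(i, 1) - origin[1]) / spacing[1];
        double iz = (points(i, 2) - origin[2]) / spacing[2];
        out[i] = trilinear_at(REAL(vol), d, ix, iy, iz);
    }
    return out;
}

// Slab clipping of a ray p(t) = o + t*u against [lo, hi]^3. Returns false if
// the ray misses the box; otherwise [t0, t1] is the parameter interval inside.
static inline bool clip_box(const double o[3], const double u[3],
                            const double lo[3], const double hi[3],
                            double& t0, double& t1) {
    t0 = 0.0;
    t1 = R_PosInf;
    for (int k = 0; k < 3; ++k) {
        if (std::fabs(u[k]) < 1e-12) {
            if (o[k] < lo[k] || o[k] > hi[k]) return false;
        } else {
            double ta = (lo[k] - o[k]) / u[k];
            double tb = (hi[k] - o[k]) / u[k];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
            if (t0 > t1) return false;
        }
    }
    return true;
}

// Perspective ray-cast DRR. The pose moves the volume in world space, so world
// sample points are pulled back through `invPose` (4x4, row index first) into
// the volume's native frame before voxel lookup. Accumulation per pixel is
// step * sum(trilinear samples) -- a Riemann line integral in mm units.
// Detector rows advance along `detV`, columns along `detU`; pixel (1,1) of the
// returned matrix is the top-left detector corner.
// [[Rcpp::export(name = ".cppRenderDRR")]]
List cpp_render_drr(NumericVector vol, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix invPose, NumericVector source,
                             NumericVector detCenter, NumericVector detU,
                             NumericVector detV, int nrow, int ncol,
                             double pixelSpacing, double step) {
    NumericMatrix img(nrow, ncol);
    int d[3] = { dim[0], dim[1], dim[2] };
    const double* v = REAL(vol);

    // volume support in its native world frame (trilinear support)
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
        lo[k] = origin[k];
        hi[k] = origin[k] + spacing[k] * (d[k] - 1.0);
    }
    // source pulled back into the volume frame (shared by every ray)
    double so[3];
    for (int k = 0; k < 3; ++k)
        so[k] = invPose(k, 0) * source[0] + invPose(k, 1) * source[1] +
                invPose(k, 2) * source[2] + invPose(k, 3);

    const double r0 = (nrow - 1.0) / 2.0, c0 = (ncol - 1.0) / 2.0;
    long raysHit = 0;
    for (int r = 0; r < nrow; ++r) {
        for (int c = 0; c < ncol; ++c) {
            // pixel position in world, then pulled back into the volume frame
            double pw[3], pv[3];
            for (int k = 0; k < 3; ++k)
                pw[k] = detCenter[k] + detU[k] * (c - c0) * pixelSpacing +
                        detV[k] * (r - r0) * pixelSpacing;
            for (int k = 0; k < 3; ++k)
                pv[k] = invPose(k, 0) * pw[0] + invPose(k, 1) * pw[1] +
                        invPose(k, 2) * pw[2] + invPose(k, 3);
            double u[3];
            double nrm = 0.0;
            for (int k = 0; k < 3; ++k) {
                u[k] = pv[k] - so[k];
                nrm += u[k] * u[k];
            }
            nrm = std::sqrt(nrm);
            if (nrm <= 0.0) continue;
            for (int k = 0; k < 3; ++k) u[k] /= nrm;

            double t0, t1;
            if (!clip_box(so, u, lo, hi, t0, t1)) continue;
            if (t0 < 0.0) t0 = 0.0; // never sample behind the source
            long nsteps = (long)std::floor((t1 - t0) / step);
            if (nsteps > 0) ++raysHit;
            double acc = 0.0;
            for (long s = 0; s < nsteps; ++s) {
                double t = t0 + (s + 0.5) * step;
                double ix = (so[0] + t * u[0] - origin[0]) / spacing[0];
                double iy = (so[1] + t * u[1] - origin[1]) / spacing[1];
                double iz = (so[2] + t * u[2] - origin[2]) / spacing[2];
                acc += trilinear_at(v, d, ix, iy, iz);
            }
            img(r, c) = acc * step;
        }
    }
    return List::create(Named("image") = img, Named("raysHit") = (double)raysHit);
}
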