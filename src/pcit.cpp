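#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT trio scan. For every unordered trio {x,y,z} of genes with direct
// correlations r_xy, r_xz, r_yz, the three first-order partials
//   r_ab.c = (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))
// give the trio tolerance
//   eps = ((r_xy.z / r_xy) + (r_xz.y / r_xz) + (r_yz.x / r_yz)) / 3
// (signed ratios). An edge (a,b) is eliminated when, for the third gene c,
//   |r_ab| <= |eps * r_ac|  and  |r_ab| <= |eps * r_bc|.
// Trios where any direct |r| <= 1e-12 cannot eliminate (undefined ratio).
// The input must be symmetric with off-diagonal entries clipped inside
// (-1, 1); the R wrapper enforces this.
//
// When track = true the minimum absolute partial correlation observed for
// each pair across all third genes is returned as well (used by the
// alternative "partial" magnitude filter).
// [[Rcpp::export]]
List pcit_core_cpp(NumericMatrix R, bool track) {
    const int n = R.nrow();
    const double FLOOR = 1e-12;
    LogicalMatrix elim(n, n);
    NumericMatrix minp(track ? n : 1, track ? n : 1);
    if (track) std::fill(minp.begin(), minp.end(), R_PosInf);

    // 1/sqrt(1 - r^2), symmetric; columns are contiguous
    NumericMatrix inv(n, n);
    for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
            double r = R(i, j);
            inv(i, j) = 1.0 / std::sqrt(1.0 - r * r);
        }

    for (int x = 0; x < n - 2; ++x) {
        const double *Rx = &R(0, x), *Ix = &inv(0, x);
        for (int y = x + 1; y < n - 1; ++y) {
            const double *Ry = &R(0, y), *Iy = &inv(0, y);
            const double rxy = Rx[y];
            const double ixy = Ix[y];
            const double axy = std::fabs(rxy);
            for (int z = y + 1; z < n; ++z) {
                const double rxz = Rx[z], ryz = Ry[z];
                const double pxy = (rxy - rxz * ryz) * Ix[z] * Iy[z];
                const double pxz = (rxz - rxy * ryz) * ixy * Iy[z];
                const double pyz = (ryz - rxy * rxz) * ixy * Ix[z];
                if (track) {
                    double a;
                    a = std::fabs(pxy);
                    if (a < minp(x, y)) minp(x, y) = minp(y, x) = a;
                    a = std::fabs(pxz);
                    if (a < minp(x, z)) minp(x, z) = minp(z, x) = a;
                    a = std::fabs(pyz);
                    if (a < minp(y, z)) minp(y, z) = minp(z, y) = a;
                }
                const double axz = std::fabs(rxz), ayz = std::fabs(ryz);
                if (axy <= FLOOR || axz <= FLOOR || ayz <= FLOOR) continue;
                const double eps =
                    (pxy / rxy + pxz / rxz + pyz / ryz) / 3.0;
                const double ae = std::fabs(eps);
                if (axy <= ae * axz && axy <= ae * ayz)
                    elim(x, y) = elim(y, x) = true;
                if (axz <= ae * axy && axz <= ae * ayz)
                    elim(x, z) = elim(z, x) = true;
                if (ayz <= ae * axy && ayz <= ae * axz)
                    elim(y, z) = elim(z, y) = true;
            }
        }
        Rcpp::checkUserInterrupt();
    }

    LogicalMatrix sig(n, n);
    for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) sig(i, j) = (i != j) && !elim(i, j);
    if (track)
        return List::create(_["significant"] = sig,
                            _["minAbsPartial"] = minp);
    return List::create(_["significant"] = sig);
}
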