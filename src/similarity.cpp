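#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded contour-point similarity. For every reference contour point the
// nearest floating contour point is searched (Euclidean distance) inside the
// Chebyshev window of half-width ceil(bBand) centered at the same pixel; the
// point scores 1 for an exact hit, w1 for 0 < d <= aBand, w2 for
// aBand < d <= bBand and 0 otherwise (including no point in the window).
// Returns the mean score over reference points. `refPts` is Nx2 (row, col),
// 1-based; `floatEdge` is the floating image's logical edge map.
// [[Rcpp::export(name = ".cppContourSimilarity")]]
double cpp_contour_similarity(IntegerMatrix refPts, LogicalMatrix floatEdge,
                              double aBand, double bBand, double w1, double w2) {
    const int n = refPts.nrow();
    const int nr = floatEdge.nrow(), nc = floatEdge.ncol();
    const int win = (int)std::ceil(bBand);
    const double b2 = bBand * bBand;
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
        int pr = refPts(i, 0) - 1, pc = refPts(i, 1) - 1;
        double best2 = R_PosInf;
        for (int dr = -win; dr <= win; ++dr) {
            int rr = pr + dr;
            if (rr < 0 || rr >= nr) continue;
            for (int dc = -win; dc <= win; ++dc) {
                int cc = pc + dc;
                if (cc < 0 || cc >= nc) continue;
                if (floatEdge(rr, cc)) {
                    double d2 = (double)dr * dr + (double)dc * dc;
                    if (d2 < best2) best2 = d2;
                }
            }
        }
        if (!R_FINITE(best2) || best2 > b2) continue;
        double d = std::sqrt(best2);
        if (d == 0.0) total += 1.0;
        else if (d <= aBand) total += w1;
        else total += w2;
    }
    return total / n;
}
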