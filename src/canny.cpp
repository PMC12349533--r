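#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Separable Gaussian blur with kernel radius ceil(3*sigma); edges handled by
// clamping (replicate padding). sigma <= 0 skips smoothing.
static void gaussian_blur(const NumericMatrix& in, NumericMatrix& out, double sigma) {
    const int nr = in.nrow(), nc = in.ncol();
    if (sigma <= 0.0) {
        out = clone(in);
        return;
    }
    int rad = (int)std::ceil(3.0 * sigma);
    std::vector<double> k(2 * rad + 1);
    double s = 0.0;
    for (int i = -rad; i <= rad; ++i) {
        k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
        s += k[i + rad];
    }
    for (double& w : k) w /= s;
    NumericMatrix tmp(nr, nc);
    for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
            double a = 0.0;
            for (int i = -rad; i <= rad; ++i) {
                int cc = std::min(std::max(c + i, 0), nc - 1);
                a += k[i + rad] * in(r, cc);
            }
            tmp(r, c) = a;
        }
    for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
            double a = 0.0;
            for (int i = -rad; i <= rad; ++i) {
                int rr = std::min(std::max(r + i, 0), nr - 1);
                a += k[i + rad] * tmp(rr, c);
            }
            out(r, c) = a;
        }
}

// Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
// suppression quantized to 4 directions, hysteresis by flood fill from strong
// pixels through weak ones (8-connectivity). Thresholds apply to the Sobel
// gradient magnitude; low/high < 0 requests automatic thresholds, either as
// `lowA`/`highA` fractions of the maximum magnitude (quantileMode = false) or
// as the `lowA`/`highA` quantiles (type-7) of the positive magnitudes
// (quantileMode = true). Returns a logical matrix of edge pixels.
// [[Rcpp::export(name = ".cppCanny")]]
LogicalMatrix cpp_canny(NumericMatrix img, double sigma, double low, double high,
                        double lowA, double highA, bool quantileMode) {
    const int nr = img.nrow(), nc = img.ncol();
    NumericMatrix sm(nr, nc);
    gaussian_blur(img, sm, sigma);

    NumericMatrix mag(nr, nc);
    std::vector<signed char> dir(nr * nc, 0); // 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
    for (int r = 1; r < nr - 1; ++r) {
        for (int c = 1; c < nc - 1; ++c) {
            double gx = (sm(r - 1, c + 1) + 2 * sm(r, c + 1) + sm(r + 1, c + 1)) -
                        (sm(r - 1, c - 1) + 2 * sm(r, c - 1) + sm(r + 1, c - 1));
            double gy = (sm(r + 1, c - 1) + 2 * sm(r + 1, c) + sm(r + 1, c + 1)) -
                        (sm(r - 1, c - 1) + 2 * sm(r - 1, c) + sm(r - 1, c + 1));
            double m = std::sqrt(gx * gx + gy * gy);
            mag(r, c) = m;
            if (m > 0) {
                double ang = std::atan2(gy, gx); // radians, row = image y
                double deg = ang * 180.0 / M_PI;
                if (deg < 0) deg += 180.0;
                signed char q;
                if (deg < 22.5 || deg >= 157.5) q = 0;
                else if (deg < 67.5) q = 1;
                else if (deg < 112.5) q = 2;
                else q = 3;
                dir[r + (R_xlen_t)c * nr] = q;
            }
        }
    }

    if (low < 0 || high < 0) {
        if (quantileMode) {
            std::vector<double> pos;
            pos.reserve((size_t)nr * nc);
            for (int r = 0; r < nr; ++r)
                for (int c = 0; c < nc; ++c)
                    if (mag(r, c) > 0) pos.push_back(mag(r, c));
            if (pos.empty()) return LogicalMatrix(nr, nc);
            std::sort(pos.begin(), pos.end());
            auto quant = [&](double q) {
                double h = (pos.size() - 1) * q;
                size_t i = (size_t)std::floor(h);
                double f = h - i;
                double v = pos[i];
                if (i + 1 < pos.size()) v += f * (pos[i + 1] - pos[i]);
                return v;
            };
            if (low < 0) low = quant(lowA);
            if (high < 0) high = quant(highA);
        } else {
            double mx = 0.0;
            for (int r = 0; r < nr; ++r)
                for (int c = 0; c < nc; ++c)
                    if (mag(r, c) > mx) mx = mag(r, c);
            if (mx <= 0.0) return LogicalMatrix(nr, nc);
            if (low < 0) low = lowA * mx;
            if (high < 0) high = highA * mx;
        }
    }
    if (high < low) std::swap(low, high);

    // non-maximum suppression along the gradient direction
    LogicalMatrix strong(nr, nc), cand(nr, nc);
    const int dr[4] = { 0, 1, 1, 1 };  // perpendicular-to-edge neighbor offsets
    const int dc[4] = { 1, 1, 0, -1 };
    for (int r = 1; r < nr - 1; ++r) {
        for (int c = 1; c < nc - 1; ++c) {
            double m = mag(r, c);
            if (m < low || m <= 0) continue;
            int q = dir[r + (R_xlen_t)c * nr];
            double m1 = mag(r + dr[q], c + dc[q]);
            double m2 = mag(r - dr[q], c - dc[q]);
            // strict against the forward neighbor so plateau ties keep a
            // single one-pixel-wide ridge
            if (m > m1 && m >= m2) {
                cand(r, c) = TRUE;
                if (m >= high) strong(r, c) = TRUE;
            }
        }
    }

    // hysteresis: keep candidates 8-connected to a strong pixel
    LogicalMatrix edge(nr, nc);
    std::vector<std::pair<int, int> > stack;
    for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
            if (strong(r, c)) {
                edge(r, c) = TRUE;
                stack.push_back(std::make_pair(r, c));
            }
    while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int i = -1; i <= 1; ++i)
            for (int j = -1; j <= 1; ++j) {
                int rr = p.first + i, cc = p.second + j;
                if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
                if (cand(rr, cc) && !edge(rr, cc)) {
                    edge(rr, cc) = TRUE;
                    stack.push_back(std::make_pair(rr, cc));
                }
            }
    }
    return edge;
}
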