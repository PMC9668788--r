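#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// Neighbourhood offsets for 6 (face), 18 (face+edge) or 26 (face+edge+corner)
// connectivity on a 3D lattice.
static std::vector<std::array<int, 3> > neighbourOffsets(int connectivity) {
    std::vector<std::array<int, 3> > offs;
    for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                std::array<int, 3> o = {{dx, dy, dz}};
                offs.push_back(o);
            }
        }
    }
    return offs;
}

// Label maximal connected clusters of a 3D logical array. Labels are assigned
// in order of each cluster's minimum linear (column-major) index, so the
// labelling is deterministic: scanning voxels in storage order, a new label is
// opened the first time an unvisited foreground voxel is met.
// [[Rcpp::export(name = ".ccLabel")]]
IntegerVector ccLabel(LogicalVector mask, IntegerVector dims, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n, 0);
    std::vector<std::array<int, 3> > offs = neighbourOffsets(connectivity);
    std::vector<R_xlen_t> stack;
    int current = 0;
    for (R_xlen_t idx = 0; idx < n; ++idx) {
        if (!mask[idx] || labels[idx] != 0) continue;
        ++current;
        labels[idx] = current;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int z = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t k = 0; k < offs.size(); ++k) {
                int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[w] && labels[w] == 0) {
                    labels[w] = current;
                    stack.push_back(w);
                }
            }
        }
    }
    labels.attr("maxLabel") = current;
    return labels;
}

// Interpolating cubic (Catmull-Rom) kernel weights for fractional offset t in
// [0,1); taps at floor(u)-1 .. floor(u)+2. Exact on linear fields.
static inline void cubicWeights(double t, double w[4]) {
    double t2 = t * t, t3 = t2 * t;
    w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
    w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
    w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
    w[3] = 0.5 * (t3 - t2);
}

// Sample the source volume at integer indices that may sit one step outside
// the grid: out-of-range taps are resolved by linear extrapolation along the
// offending axis, keeping the cubic kernel exact on linear fields up to the
// grid boundary.
static double sampleExt(const double* src, int sx, int sy, int sz, int x,
                        int y, int z) {
    if (z < 0)
        return sz < 2 ? sampleExt(src, sx, sy, sz, x, y, 0)
                      : 2.0 * sampleExt(src, sx, sy, sz, x, y, 0) -
                            sampleExt(src, sx, sy, sz, x, y, 1);
    if (z >= sz)
        return sz < 2 ? sampleExt(src, sx, sy, sz, x, y, sz - 1)
                      : 2.0 * sampleExt(src, sx, sy, sz, x, y, sz - 1) -
                            sampleExt(src, sx, sy, sz, x, y, sz - 2);
    if (y < 0)
        return sy < 2 ? sampleExt(src, sx, sy, sz, x, 0, z)
                      : 2.0 * sampleExt(src, sx, sy, sz, x, 0, z) -
                            sampleExt(src, sx, sy, sz, x, 1, z);
    if (y >= sy)
        return sy < 2 ? sampleExt(src, sx, sy, sz, x, sy - 1, z)
                      : 2.0 * sampleExt(src, sx, sy, sz, x, sy - 1, z) -
                            sampleExt(src, sx, sy, sz, x, sy - 2, z);
    if (x < 0)
        return sx < 2 ? sampleExt(src, sx, sy, sz, 0, y, z)
                      : 2.0 * sampleExt(src, sx, sy, sz, 0, y, z) -
                            sampleExt(src, sx, sy, sz, 1, y, z);
    if (x >= sx)
        return sx < 2 ? sampleExt(src, sx, sy, sz, sx - 1, y, z)
                      : 2.0 * sampleExt(src, sx, sy, sz, sx - 1, y, z) -
                            sampleExt(src, sx, sy, sz, sx - 2, y, z);
    return src[(R_xlen_t)x + (R_xlen_t)sx * (y + (R_xlen_t)sy * z)];
}

// Resample a 3D scalar field from a source axis-aligned grid onto a target
// grid. mode 0 = nearest neighbour, 1 = cubic interpolation. Voxel centre of
// index i sits at world position origin + i * spacing (0-based indices).
// Target voxels whose continuous source index falls outside the source extent
// receive `fill`.
// [[Rcpp::export(name = ".resampleGrid")]]
NumericVector resampleGrid(NumericVector src, IntegerVector sdim,
                           NumericVector sspacing, NumericVector sorigin,
                           IntegerVector tdim, NumericVector tspacing,
                           NumericVector torigin, int mode, double fill) {
    const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
    const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    NumericVector out((R_xlen_t)tx * ty * tz);

    R_xlen_t o = 0;
    for (int k = 0; k < tz; ++k) {
        double wz = torigin[2] + k * tspacing[2];
        double uz = (wz - sorigin[2]) / sspacing[2];
        for (int j = 0; j < ty; ++j) {
            double wy = torigin[1] + j * tspacing[1];
            double uy = (wy - sorigin[1]) / sspacing[1];
            for (int i = 0; i < tx; ++i, ++o) {
                double wx = torigin[0] + i * tspacing[0];
                double ux = (wx - sorigin[0]) / sspacing[0];
                if (mode == 0) {
                    long rx = std::lround(ux), ry = std::lround(uy),
                         rz = std::lround(uz);
                    if (rx < 0 || rx >= sx || ry < 0 || ry >= sy || rz < 0 ||
                        rz >= sz) {
                        out[o] = fill;
                    } else {
                        out[o] = src[(R_xlen_t)rx + sx * (ry + (R_xlen_t)sy * rz)];
                    }
                } else {
                    if (ux < 0.0 || ux > sx - 1.0 || uy < 0.0 || uy > sy - 1.0 ||
                        uz < 0.0 || uz > sz - 1.0) {
                        out[o] = fill;
                        continue;
                    }
                    int fx = (int)std::floor(ux), fy = (int)std::floor(uy),
                        fz = (int)std::floor(uz);
                    double wxv[4], wyv[4], wzv[4];
                    cubicWeights(ux - fx, wxv);
                    cubicWeights(uy - fy, wyv);
                    cubicWeights(uz - fz, wzv);
                    const double* sp = &src[0];
                    double acc = 0.0;
                    for (int c = 0; c < 4; ++c) {
                        double az = wzv[c];
                        if (az == 0.0) continue;
                        int zz = fz - 1 + c;
                        for (int b = 0; b < 4; ++b) {
                            double ay = az * wyv[b];
                            if (ay == 0.0) continue;
                            int yy = fy - 1 + b;
                            bool inyz = yy >= 0 && yy < sy && zz >= 0 &&
                                        zz < sz;
                            R_xlen_t base = inyz ?
                                sx * (yy + (R_xlen_t)sy * zz) : 0;
                            for (int a = 0; a < 4; ++a) {
                                if (wxv[a] == 0.0) continue;
                                int xx = fx - 1 + a;
                                double s = (inyz && xx >= 0 && xx < sx)
                                    ? sp[base + xx]
                                    : sampleExt(sp, sx, sy, sz, xx, yy, zz);
                                acc += ay * wxv[a] * s;
                            }
                        }
                    }
                    out[o] = acc;
                }
            }
        }
    }
    return out;
}

// One round of binary dilation (grow = true) or erosion (grow = false) with
// the 6-connected (face) structuring element.
// [[Rcpp::export(name = ".morphStep")]]
LogicalVector morphStep(LogicalVector mask, IntegerVector dims, bool grow) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    LogicalVector out(n);
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x, ++idx) {
                bool v = mask[idx];
                if (grow ? v : !v) {
                    out[idx] = v;
                    continue;
                }
                bool hit = false;
                for (int k = 0; k < 6 && !hit; ++k) {
                    static const int d[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                                                {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
                    int xx = x + d[k][0], yy = y + d[k][1], zz = z + d[k][2];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                        zz >= nz) {
                        // outside the volume counts as background
                        if (!grow) hit = true;
                        continue;
                    }
                    R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                    if (grow ? mask[w] : !mask[w]) hit = true;
                }
                out[idx] = grow ? hit : !hit;
            }
        }
    }
    return out;
}
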