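// Texture-matrix accumulation kernels for 3D masked regions of interest.
// All matrices are computed over the full 3D neighbourhood: the 13 unique
// voxel directions for co-occurrence and run-length, and the 26-connected
// neighbourhood for size-zone, dependence and gray-tone-difference
// statistics. Gray levels are 1-based integers; voxels outside the mask
// never contribute.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int DIR13[13][3] = {
    {0, 0, 1}, {0, 1, -1}, {0, 1, 0}, {0, 1, 1},
    {1, -1, -1}, {1, -1, 0}, {1, -1, 1},
    {1, 0, -1}, {1, 0, 0}, {1, 0, 1},
    {1, 1, -1}, {1, 1, 0}, {1, 1, 1}};

static inline int lin(int z, int y, int x, int d1, int d2) {
    return z + d1 * (y + d2 * x);
}

// [[Rcpp::export(name = ".cpp_glcm")]]
NumericMatrix cpp_glcm(IntegerVector gray, LogicalVector mask,
                       IntegerVector dims, int ngray) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    NumericMatrix P(ngray, ngray);
    for (int x = 0; x < d3; ++x)
        for (int y = 0; y < d2; ++y)
            for (int z = 0; z < d1; ++z) {
                int i = lin(z, y, x, d1, d2);
                if (!mask[i]) continue;
                int gi = gray[i];
                for (int d = 0; d < 13; ++d) {
                    int zz = z + DIR13[d][0], yy = y + DIR13[d][1],
                        xx = x + DIR13[d][2];
                    if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 ||
                        xx < 0 || xx >= d3)
                        continue;
                    int j = lin(zz, yy, xx, d1, d2);
                    if (!mask[j]) continue;
                    int gj = gray[j];
                    P(gi - 1, gj - 1) += 1.0;
                    P(gj - 1, gi - 1) += 1.0;
                }
            }
    return P;
}

// [[Rcpp::export(name = ".cpp_glrlm")]]
NumericMatrix cpp_glrlm(IntegerVector gray, LogicalVector mask,
                        IntegerVector dims, int ngray) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    int maxrun = std::max(std::max(d1, d2), d3);
    NumericMatrix P(ngray, maxrun);
    for (int d = 0; d < 13; ++d) {
        int dz = DIR13[d][0], dy = DIR13[d][1], dx = DIR13[d][2];
        for (int x = 0; x < d3; ++x)
            for (int y = 0; y < d2; ++y)
                for (int z = 0; z < d1; ++z) {
                    int i = lin(z, y, x, d1, d2);
                    if (!mask[i]) continue;
                    int g = gray[i];
                    // run start: predecessor invalid or different gray
                    int pz = z - dz, py = y - dy, px = x - dx;
                    bool prev_ok = pz >= 0 && pz < d1 && py >= 0 && py < d2 &&
                                   px >= 0 && px < d3;
                    if (prev_ok) {
                        int pi = lin(pz, py, px, d1, d2);
                        if (mask[pi] && gray[pi] == g) continue;
                    }
                    int len = 1;
                    int zz = z + dz, yy = y + dy, xx = x + dx;
                    while (zz >= 0 && zz < d1 && yy >= 0 && yy < d2 &&
                           xx >= 0 && xx < d3) {
                        int j = lin(zz, yy, xx, d1, d2);
                        if (!mask[j] || gray[j] != g) break;
                        ++len;
                        zz += dz; yy += dy; xx += dx;
                    }
                    P(g - 1, len - 1) += 1.0;
                }
    }
    return P;
}

// Connected zones (26-connectivity) of equal gray level; returns one row
// per zone: (gray level, zone size).
// [[Rcpp::export(name = ".cpp_glszm_zones")]]
IntegerMatrix cpp_glszm_zones(IntegerVector gray, LogicalVector mask,
                              IntegerVector dims) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    int n = d1 * d2 * d3;
    std::vector<char> visited(n, 0);
    std::vector<int> zg, zs;
    std::vector<int> stack;
    for (int x0 = 0; x0 < d3; ++x0)
        for (int y0 = 0; y0 < d2; ++y0)
            for (int z0 = 0; z0 < d1; ++z0) {
                int i0 = lin(z0, y0, x0, d1, d2);
                if (!mask[i0] || visited[i0]) continue;
                int g = gray[i0];
                int size = 0;
                stack.clear();
                stack.push_back(i0);
                visited[i0] = 1;
                while (!stack.empty()) {
                    int i = stack.back();
                    stack.pop_back();
                    ++size;
                    int x = i / (d1 * d2), r = i % (d1 * d2);
                    int y = r / d1, z = r % d1;
                    for (int dz = -1; dz <= 1; ++dz)
                        for (int dy = -1; dy <= 1; ++dy)
                            for (int dx = -1; dx <= 1; ++dx) {
                                if (!dz && !dy && !dx) continue;
                                int zz = z + dz, yy = y + dy, xx = x + dx;
                                if (zz < 0 || zz >= d1 || yy < 0 ||
                                    yy >= d2 || xx < 0 || xx >= d3)
                                    continue;
                                int j = lin(zz, yy, xx, d1, d2);
                                if (!mask[j] || visited[j] || gray[j] != g)
                                    continue;
                                visited[j] = 1;
                                stack.push_back(j);
                            }
                }
                zg.push_back(g);
                zs.push_back(size);
            }
    IntegerMatrix out(zg.size(), 2);
    for (size_t k = 0; k < zg.size(); ++k) {
        out(k, 0) = zg[k];
        out(k, 1) = zs[k];
    }
    return out;
}

// Dependence matrix: P(g, k) where k = 1 + number of 26-neighbours inside
// the mask whose gray level differs from the centre by at most alpha.
// [[Rcpp::export(name = ".cpp_gldm")]]
NumericMatrix cpp_gldm(IntegerVector gray, LogicalVector mask,
                       IntegerVector dims, int ngray, int alpha) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    NumericMatrix P(ngray, 27);
    for (int x = 0; x < d3; ++x)
        for (int y = 0; y < d2; ++y)
            for (int z = 0; z < d1; ++z) {
                int i = lin(z, y, x, d1, d2);
                if (!mask[i]) continue;
                int g = gray[i], dep = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dz && !dy && !dx) continue;
                            int zz = z + dz, yy = y + dy, xx = x + dx;
                            if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 ||
                                xx < 0 || xx >= d3)
                                continue;
                            int j = lin(zz, yy, xx, d1, d2);
                            if (!mask[j]) continue;
                            if (std::abs(gray[j] - g) <= alpha) ++dep;
                        }
                P(g - 1, dep) += 1.0;
            }
    return P;
}

// Gray-tone difference accumulators: per gray level, the count n_i of
// valid voxels and the sum s_i of |g - mean(neighbour grays)|.
// [[Rcpp::export(name = ".cpp_ngtdm")]]
NumericMatrix cpp_ngtdm(IntegerVector gray, LogicalVector mask,
                        IntegerVector dims, int ngray) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    NumericMatrix out(ngray, 2);  // columns: n_i, s_i
    for (int x = 0; x < d3; ++x)
        for (int y = 0; y < d2; ++y)
            for (int z = 0; z < d1; ++z) {
                int i = lin(z, y, x, d1, d2);
                if (!mask[i]) continue;
                int g = gray[i];
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dz && !dy && !dx) continue;
                            int zz = z + dz, yy = y + dy, xx = x + dx;
                            if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 ||
                                xx < 0 || xx >= d3)
                                continue;
                            int j = lin(zz, yy, xx, d1, d2);
                            if (!mask[j]) continue;
                            sum += gray[j];
                            ++cnt;
                        }
                if (cnt == 0) continue;
                out(g - 1, 0) += 1.0;
                out(g - 1, 1) += std::fabs(g - sum / cnt);
            }
    return out;
}
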