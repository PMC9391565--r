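#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spatially variant, tissue-dependent positron-range blur.
//
// The kernel rho_k at source voxel k is composed from uniform per-material
// kernels: for kernel offset h, rho_k(h) = K_{mat(k+h)}(h) with the material
// looked up at the destination voxel (clamped to the volume at the edges),
// then renormalized to unit sum.  The forward operator spreads the content
// of each source voxel over its neighbours with rho_k ("spread from
// source"); mass leaving the volume is lost (no edge renormalization).
// The adjoint gathers at k with the same rho_k:
//   forward:  y[j] = sum_k rho_k(j - k) x[k]
//   adjoint:  z[k] = sum_j rho_k(j - k) y[j]
//
// Voxels whose full kernel-sized neighbourhood is a single material use the
// uniform kernel of that material directly (the composition renormalization
// is then a no-op); the classification comes precomputed from
// cpp_homog_map.  The apply loops run over the edge-clipped kernel box with
// unit stride along x in both the kernel and the volume, which keeps them
// vectorizable.

static inline int clampi(int v, int lo, int hi)
{
    return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
IntegerVector cpp_homog_map(IntegerVector labels, IntegerVector dim,
                            IntegerVector half)
{
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = R_xlen_t(nx) * ny * nz;
    std::vector<int> mn(labels.begin(), labels.end());
    std::vector<int> mx(labels.begin(), labels.end());
    std::vector<int> tmn(n), tmx(n);

    // separable running min/max over the clamped window, axis by axis
    const int hs[3] = { half[0], half[1], half[2] };
    const int ns[3] = { nx, ny, nz };
    const R_xlen_t strides[3] = { 1, nx, R_xlen_t(nx) * ny };
    for (int ax = 0; ax < 3; ++ax) {
        const int h = hs[ax], nax = ns[ax];
        if (h == 0) continue;
        const R_xlen_t st = strides[ax];
        for (R_xlen_t i = 0; i < n; ++i) {
            int c;
            if (ax == 0) c = (int)(i % nx);
            else if (ax == 1) c = (int)((i / nx) % ny);
            else c = (int)(i / (R_xlen_t(nx) * ny));
            const int lo = clampi(c - h, 0, nax - 1);
            const int hi = clampi(c + h, 0, nax - 1);
            int vmin = mn[i + (R_xlen_t)(lo - c) * st];
            int vmax = mx[i + (R_xlen_t)(lo - c) * st];
            for (int cc = lo + 1; cc <= hi; ++cc) {
                const R_xlen_t j = i + (R_xlen_t)(cc - c) * st;
                if (mn[j] < vmin) vmin = mn[j];
                if (mx[j] > vmax) vmax = mx[j];
            }
            tmn[i] = vmin; tmx[i] = vmax;
        }
        mn.swap(tmn); mx.swap(tmx);
    }

    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (mn[i] == mx[i]) ? labels[i] : -1;
    return out;
}

// Compose the kernel at one voxel into buf (unit-sum normalized).
// `interior` means the whole kernel box lies inside the volume.
static void compose_at(const int* lab, int nx, int ny, int nz,
                       const double* kern, int K3,
                       int kx, int ky, int kz, int hx, int hy, int hz,
                       int ix, int iy, int iz, bool interior, double* buf)
{
    double s = 0.0;
    int o = 0;
    if (interior) {
        const R_xlen_t k0 = ix + R_xlen_t(nx) * (iy + R_xlen_t(ny) * iz);
        for (int dz = -hz; dz <= hz; ++dz)
            for (int dy = -hy; dy <= hy; ++dy) {
                const R_xlen_t base =
                    k0 + dz * R_xlen_t(nx) * ny + dy * R_xlen_t(nx);
                for (int dx = -hx; dx <= hx; ++dx, ++o) {
                    const int m = lab[base + dx];
                    const double v = kern[o + R_xlen_t(K3) * m];
                    buf[o] = v;
                    s += v;
                }
            }
    } else {
        for (int dz = -hz; dz <= hz; ++dz) {
            const int jz = clampi(iz + dz, 0, nz - 1);
            for (int dy = -hy; dy <= hy; ++dy) {
                const int jy = clampi(iy + dy, 0, ny - 1);
                const R_xlen_t base = R_xlen_t(nx) * (jy + R_xlen_t(ny) * jz);
                for (int dx = -hx; dx <= hx; ++dx, ++o) {
                    const int jx = clampi(ix + dx, 0, nx - 1);
                    const int m = lab[base + jx];
                    const double v = kern[o + R_xlen_t(K3) * m];
                    buf[o] = v;
                    s += v;
                }
            }
        }
    }
    if (s > 0) {
        const double inv = 1.0 / s;
        for (int i = 0; i < K3; ++i) buf[i] *= inv;
    }
    (void)kx; (void)ky; (void)kz;
}

// [[Rcpp::export]]
NumericVector cpp_compose_kernel(IntegerVector labels, IntegerVector dim,
                                 NumericMatrix kernels, IntegerVector ksize,
                                 IntegerVector voxel0)
{
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int kx = ksize[0], ky = ksize[1], kz = ksize[2];
    const int hx = kx / 2, hy = ky / 2, hz = kz / 2;
    const int K3 = kx * ky * kz;
    const int ix = voxel0[0], iy = voxel0[1], iz = voxel0[2];
    const bool interior = ix >= hx && ix < nx - hx && iy >= hy &&
        iy < ny - hy && iz >= hz && iz < nz - hz;
    NumericVector out(K3);
    compose_at(labels.begin(), nx, ny, nz, kernels.begin(), K3,
               kx, ky, kz, hx, hy, hz, ix, iy, iz, interior, out.begin());
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_pr_blur(NumericVector x, IntegerVector dim,
                          IntegerVector labels, IntegerVector homog,
                          NumericMatrix kernels, IntegerVector ksize,
                          bool adjoint, LogicalVector mask)
{
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int kx = ksize[0], ky = ksize[1], kz = ksize[2];
    const int hx = kx / 2, hy = ky / 2, hz = kz / 2;
    const int K3 = kx * ky * kz;
    const bool use_mask = mask.size() > 0;
    const R_xlen_t sy = nx, sz = R_xlen_t(nx) * ny;

    const double* in = x.begin();
    const double* kmat = kernels.begin();
    const int* lab = labels.begin();
    NumericVector out_v(R_xlen_t(nx) * ny * nz);
    double* out = out_v.begin();
    std::vector<double> buf(K3);

    // per-material nonzero span of each kernel row (dy, dz): compact
    // kernels (water, bone) then skip their structurally zero entries
    const int nmat = kernels.ncol();
    const int nrow = ky * kz;
    std::vector<int> row_lo(nmat * nrow), row_hi(nmat * nrow);
    for (int m = 0; m < nmat; ++m)
        for (int rw = 0; rw < nrow; ++rw) {
            const double* krow = kmat + R_xlen_t(K3) * m + rw * kx;
            int lo = kx, hi = -1;
            for (int i = 0; i < kx; ++i)
                if (krow[i] != 0.0) { if (lo == kx) lo = i; hi = i; }
            row_lo[m * nrow + rw] = lo - hx;
            row_hi[m * nrow + rw] = hi - hx;
        }

    R_xlen_t k = 0;
    for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
            for (int ix = 0; ix < nx; ++ix, ++k) {
                if (!adjoint && in[k] == 0.0) continue;
                if (adjoint && use_mask && !mask[k]) continue;
                const bool interior =
                    ix >= hx && ix < nx - hx &&
                    iy >= hy && iy < ny - hy &&
                    iz >= hz && iz < nz - hz;
                const int hm = homog[k];
                const double* kern;
                const int* rlo = nullptr;
                const int* rhi = nullptr;
                if (hm >= 0) {
                    kern = kmat + R_xlen_t(K3) * hm;
                    rlo = row_lo.data() + hm * nrow;
                    rhi = row_hi.data() + hm * nrow;
                } else {
                    compose_at(lab, nx, ny, nz, kmat, K3, kx, ky, kz,
                               hx, hy, hz, ix, iy, iz, interior,
                               buf.data());
                    kern = buf.data();
                }
                // clip the kernel box to the volume
                const int dxlo = ix - hx < 0 ? -ix : -hx;
                const int dxhi = ix + hx > nx - 1 ? nx - 1 - ix : hx;
                const int dylo = iy - hy < 0 ? -iy : -hy;
                const int dyhi = iy + hy > ny - 1 ? ny - 1 - iy : hy;
                const int dzlo = iz - hz < 0 ? -iz : -hz;
                const int dzhi = iz + hz > nz - 1 ? nz - 1 - iz : hz;
                if (adjoint) {
                    double acc = 0.0;
                    for (int dz = dzlo; dz <= dzhi; ++dz)
                        for (int dy = dylo; dy <= dyhi; ++dy) {
                            int lo = dxlo, hi = dxhi;
                            if (rlo) {
                                const int rw = (dy + hy) + (dz + hz) * ky;
                                if (rlo[rw] > lo) lo = rlo[rw];
                                if (rhi[rw] < hi) hi = rhi[rw];
                            }
                            if (lo > hi) continue;
                            const double* inrow = in + k + dz * sz + dy * sy;
                            const double* krow = kern +
                                (dy + hy) * kx + (dz + hz) * kx * ky + hx;
                            for (int dx = lo; dx <= hi; ++dx)
                                acc += krow[dx] * inrow[dx];
                        }
                    out[k] = acc;
                } else {
                    const double xv = in[k];
                    for (int dz = dzlo; dz <= dzhi; ++dz)
                        for (int dy = dylo; dy <= dyhi; ++dy) {
                            int lo = dxlo, hi = dxhi;
                            if (rlo) {
                                const int rw = (dy + hy) + (dz + hz) * ky;
                                if (rlo[rw] > lo) lo = rlo[rw];
                                if (rhi[rw] < hi) hi = rhi[rw];
                            }
                            if (lo > hi) continue;
                            double* outrow = out + k + dz * sz + dy * sy;
                            const double* krow = kern +
                                (dy + hy) * kx + (dz + hz) * kx * ky + hx;
                            for (int dx = lo; dx <= hi; ++dx)
                                outrow[dx] += xv * krow[dx];
                        }
                }
            }
    return out_v;
}
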