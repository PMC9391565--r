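#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable stationary blur with zero boundary (mass crossing the volume
// edge is lost; interior-supported images are conserved when each 1-D
// kernel is unit-sum).  Symmetric kernels make the operator self-adjoint.

static void blur_axis(const double* in, double* out,
                      int nx, int ny, int nz, int axis,
                      const double* k, int klen)
{
    const int h = klen / 2;
    const R_xlen_t strides[3] = { 1, nx, R_xlen_t(nx) * ny };
    const int ns[3] = { nx, ny, nz };
    const R_xlen_t st = strides[axis];
    const int nax = ns[axis];
    const R_xlen_t n = R_xlen_t(nx) * ny * nz;
    for (R_xlen_t i = 0; i < n; ++i) {
        int c;
        if (axis == 0) c = (int)(i % nx);
        else if (axis == 1) c = (int)((i / nx) % ny);
        else c = (int)(i / (R_xlen_t(nx) * ny));
        double acc = 0.0;
        const int lo = c - h < 0 ? -c : -h;
        const int hi = c + h > nax - 1 ? nax - 1 - c : h;
        for (int d = lo; d <= hi; ++d)
            acc += k[d + h] * in[i + (R_xlen_t)d * st];
        out[i] = acc;
    }
}

// [[Rcpp::export]]
NumericVector cpp_separable_blur(NumericVector x, IntegerVector dim,
                                 NumericVector kx, NumericVector ky,
                                 NumericVector kz)
{
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = R_xlen_t(nx) * ny * nz;
    NumericVector out(n);
    std::vector<double> tmp(n);
    blur_axis(x.begin(), out.begin(), nx, ny, nz, 0, kx.begin(), kx.size());
    blur_axis(out.begin(), tmp.data(), nx, ny, nz, 1, ky.begin(), ky.size());
    blur_axis(tmp.data(), out.begin(), nx, ny, nz, 2, kz.begin(), kz.size());
    return out;
}
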