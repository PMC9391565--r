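#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Stacked-2D parallel-beam projector with exact voxel intersection lengths
// (incremental Amanatides-Woo traversal).  The identical traversal drives
// forward and back projection, so the pair is an exact matrix transpose.
//
// Conventions (mm, volume centre at the origin):
//   voxel (ix, iy), 0-based, has its centre at
//     x = (ix + 0.5 - nx/2) * vx,   y = (iy + 0.5 - ny/2) * vy
//   the LOR at angle theta and radial offset r is
//     p(t) = r * (-sin(theta), cos(theta)) + t * (cos(theta), sin(theta))
//   radial bin s is centred at (s + 0.5 - n_radial/2) * radial_spacing.
// Each axial plane is traced independently.

static void trace_ray(double theta, double r,
                      int nx, int ny, double vx, double vy,
                      const double* plane_in, double* plane_out,
                      double* bin_acc, double bin_val, bool forward)
{
    const double c = std::cos(theta), s = std::sin(theta);
    const double px = -r * s, py = r * c;
    const double dx = c, dy = s;
    const double xmin = -0.5 * nx * vx, ymin = -0.5 * ny * vy;
    const double xmax = -xmin, ymax = -ymin;
    const double INF = std::numeric_limits<double>::infinity();
    const double EPS = 1e-12;

    double tmin = -INF, tmax = INF;
    if (std::fabs(dx) > EPS) {
        double t0 = (xmin - px) / dx, t1 = (xmax - px) / dx;
        if (t0 > t1) std::swap(t0, t1);
        if (t0 > tmin) tmin = t0;
        if (t1 < tmax) tmax = t1;
    } else if (px <= xmin || px >= xmax) {
        return;
    }
    if (std::fabs(dy) > EPS) {
        double t0 = (ymin - py) / dy, t1 = (ymax - py) / dy;
        if (t0 > t1) std::swap(t0, t1);
        if (t0 > tmin) tmin = t0;
        if (t1 < tmax) tmax = t1;
    } else if (py <= ymin || py >= ymax) {
        return;
    }
    if (!(tmax - tmin > EPS)) return;

    const double ex = px + dx * tmin, ey = py + dy * tmin;
    int ix = (int)std::floor((ex - xmin) / vx);
    int iy = (int)std::floor((ey - ymin) / vy);
    if (ix < 0) ix = 0; else if (ix > nx - 1) ix = nx - 1;
    if (iy < 0) iy = 0; else if (iy > ny - 1) iy = ny - 1;

    const int stepx = dx > 0 ? 1 : -1;
    const int stepy = dy > 0 ? 1 : -1;
    double tnx, tny, tdx, tdy;
    if (std::fabs(dx) > EPS) {
        tdx = vx / std::fabs(dx);
        tnx = ((ix + (stepx > 0 ? 1 : 0)) * vx + xmin - px) / dx;
    } else { tdx = INF; tnx = INF; }
    if (std::fabs(dy) > EPS) {
        tdy = vy / std::fabs(dy);
        tny = ((iy + (stepy > 0 ? 1 : 0)) * vy + ymin - py) / dy;
    } else { tdy = INF; tny = INF; }

    double t = tmin;
    while (t < tmax - EPS) {
        double tn = tnx < tny ? tnx : tny;
        if (tn > tmax) tn = tmax;
        const double len = tn - t;
        if (len > 0) {
            const int idx = ix + nx * iy;
            if (forward) *bin_acc += len * plane_in[idx];
            else         plane_out[idx] += len * bin_val;
        }
        if (tnx <= tny) {
            ix += stepx; tnx += tdx;
            if (ix < 0 || ix >= nx) break;
        } else {
            iy += stepy; tny += tdy;
            if (iy < 0 || iy >= ny) break;
        }
        t = tn;
    }
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector img, IntegerVector dim,
                                  NumericVector voxel, NumericVector angles,
                                  int n_radial, double radial_spacing)
{
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int na = angles.size();
    NumericVector sino(R_xlen_t(n_radial) * na * nz);
    const double* im = img.begin();
    double* sn = sino.begin();
    for (int p = 0; p < nz; ++p) {
        const double* plane = im + R_xlen_t(nx) * ny * p;
        for (int a = 0; a < na; ++a) {
            const double th = angles[a];
            for (int s = 0; s < n_radial; ++s) {
                const double r = (s + 0.5 - 0.5 * n_radial) * radial_spacing;
                double acc = 0.0;
                trace_ray(th, r, nx, ny, voxel[0], voxel[1],
                          plane, nullptr, &acc, 0.0, true);
                sn[s + R_xlen_t(n_radial) * (a + R_xlen_t(na) * p)] = acc;
            }
        }
    }
    return sino;
}

// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector sino, IntegerVector dim,
                               NumericVector voxel, NumericVector angles,
                               int n_radial, double radial_spacing)
{
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int na = angles.size();
    NumericVector img(R_xlen_t(nx) * ny * nz);
    const double* sn = sino.begin();
    double* im = img.begin();
    for (int p = 0; p < nz; ++p) {
        double* plane = im + R_xlen_t(nx) * ny * p;
        for (int a = 0; a < na; ++a) {
            const double th = angles[a];
            for (int s = 0; s < n_radial; ++s) {
                const double val =
                    sn[s + R_xlen_t(n_radial) * (a + R_xlen_t(na) * p)];
                if (val == 0.0) continue;
                const double r = (s + 0.5 - 0.5 * n_radial) * radial_spacing;
                trace_ray(th, r, nx, ny, voxel[0], voxel[1],
                          nullptr, plane, nullptr, val, false);
            }
        }
    }
    return img;
}
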