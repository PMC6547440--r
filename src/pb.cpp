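#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>

using namespace Rcpp;

// node index in R array order: ix fastest, dims (nx, ny, nz)
static inline R_xlen_t idx3(int ix, int iy, int iz, int nx, int ny) {
  return (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
}

// Stamp spheres of per-atom radius onto a logical lattice.
static void stamp(std::vector<char> &mask, const NumericMatrix &xyz,
                  const NumericVector &radii, double extra,
                  const NumericVector &origin, double h,
                  int nx, int ny, int nz, char value) {
  for (int a = 0; a < xyz.nrow(); ++a) {
    double r = radii[a] + extra;
    if (r <= 0) continue;
    double r2 = r * r;
    double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    int lx = std::max(0, (int)std::ceil((cx - r - origin[0]) / h));
    int ux = std::min(nx - 1, (int)std::floor((cx + r - origin[0]) / h));
    int ly = std::max(0, (int)std::ceil((cy - r - origin[1]) / h));
    int uy = std::min(ny - 1, (int)std::floor((cy + r - origin[1]) / h));
    int lz = std::max(0, (int)std::ceil((cz - r - origin[2]) / h));
    int uz = std::min(nz - 1, (int)std::floor((cz + r - origin[2]) / h));
    for (int iz = lz; iz <= uz; ++iz) {
      double dz = origin[2] + iz * h - cz, dz2 = dz * dz;
      for (int iy = ly; iy <= uy; ++iy) {
        double dy = origin[1] + iy * h - cy, d2 = dz2 + dy * dy;
        if (d2 > r2) continue;
        for (int ix = lx; ix <= ux; ++ix) {
          double dx = origin[0] + ix * h - cx;
          if (d2 + dx * dx <= r2) mask[idx3(ix, iy, iz, nx, ny)] = value;
        }
      }
    }
  }
}

// Dielectric and ion-accessibility masks.
// interior: molecular-surface interior approximated by the two-pass
// "expand by probe, then erode by probe" lattice method.
// ion_excluded: within (vdW + stern) of any atom.
// [[Rcpp::export]]
List cpp_pb_masks(NumericMatrix xyz, NumericVector radii,
                  NumericVector origin, double h, IntegerVector dims,
                  double probe, double stern) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> vdw(n, 0), expanded(n, 0), ion(n, 0);
  stamp(vdw, xyz, radii, 0.0, origin, h, nx, ny, nz, 1);
  stamp(expanded, xyz, radii, probe, origin, h, nx, ny, nz, 1);
  stamp(ion, xyz, radii, stern, origin, h, nx, ny, nz, 1);

  // erosion: an expanded node within `probe` of any exterior node becomes
  // solvent; the distance to the exterior region is realized at its boundary
  // nodes (exterior nodes 6-adjacent to the expanded region), so stamping
  // probe spheres from those seeds suffices.
  std::vector<char> interior(expanded);
  if (probe > 0) {
    int pr = (int)std::floor(probe / h);
    double p2 = probe * probe;
    // precompute sphere offsets
    std::vector<std::array<int, 3>> offs;
    for (int dz = -pr; dz <= pr; ++dz)
      for (int dy = -pr; dy <= pr; ++dy)
        for (int dx = -pr; dx <= pr; ++dx)
          if ((double)(dx * dx + dy * dy + dz * dz) * h * h <= p2)
            offs.push_back({dx, dy, dz});
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          R_xlen_t id = idx3(ix, iy, iz, nx, ny);
          if (expanded[id]) continue;
          bool seed = false;  // exterior node touching the expanded region
          if (ix > 0 && expanded[id - 1]) seed = true;
          else if (ix < nx - 1 && expanded[id + 1]) seed = true;
          else if (iy > 0 && expanded[id - nx]) seed = true;
          else if (iy < ny - 1 && expanded[id + nx]) seed = true;
          else if (iz > 0 && expanded[id - (R_xlen_t)nx * ny]) seed = true;
          else if (iz < nz - 1 && expanded[id + (R_xlen_t)nx * ny]) seed = true;
          if (!seed) continue;
          for (const auto &o : offs) {
            int jx = ix + o[0], jy = iy + o[1], jz = iz + o[2];
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
              continue;
            interior[idx3(jx, jy, jz, nx, ny)] = 0;
          }
        }
    // vdW cores always count as interior
    for (R_xlen_t i = 0; i < n; ++i) if (vdw[i]) interior[i] = 1;
  }
  LogicalVector interiorR(n), ionR(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    interiorR[i] = interior[i] != 0;
    ionR[i] = ion[i] != 0;
  }
  return List::create(_["interior"] = interiorR, _["ion_excluded"] = ionR);
}

// Red-black successive over-relaxation for the linearized PB equation.
// phi carries preset boundary values on the six faces (held fixed);
// rho_term = 4*pi*lambda_B*q/h per node (kT/e units);
// salt_term = (kappa*h)^2 * eps_out at ion-accessible nodes, 0 elsewhere.
// [[Rcpp::export]]
List cpp_pb_sor(IntegerVector dims, LogicalVector interior,
                LogicalVector ion_excluded, NumericVector rho_term,
                NumericVector phi, double eps_in, double eps_out,
                double kap2h2, double tol, int maxit) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if ((R_xlen_t)phi.size() != n) stop("phi size mismatch");
  std::vector<double> eps(n);
  std::vector<double> salt(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    eps[i] = interior[i] ? eps_in : eps_out;
    salt[i] = (interior[i] || ion_excluded[i]) ? 0.0 : kap2h2 * eps_out;
  }
  double *p = REAL(phi);
  const double *rho = REAL(rho_term);
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  // precompute link dielectrics (harmonic mean) and inverse denominators:
  // they are constant across sweeps, keeping the hot loop division-free
  auto hmean = [](double a, double b) { return 2.0 * a * b / (a + b); };
  std::vector<double> ex(n, 0), ey(n, 0), ez(n, 0), invden(n, 0);
  for (R_xlen_t i = 0; i + 1 < n; ++i) ex[i] = hmean(eps[i], eps[i + 1]);
  for (R_xlen_t i = 0; i + nx < n; ++i) ey[i] = hmean(eps[i], eps[i + nx]);
  for (R_xlen_t i = 0; i + sxy < n; ++i) ez[i] = hmean(eps[i], eps[i + sxy]);
  for (int iz = 1; iz < nz - 1; ++iz)
    for (int iy = 1; iy < ny - 1; ++iy)
      for (int ix = 1; ix < nx - 1; ++ix) {
        R_xlen_t id = idx3(ix, iy, iz, nx, ny);
        invden[id] = 1.0 / (ex[id - 1] + ex[id] + ey[id - nx] + ey[id] +
                            ez[id - sxy] + ez[id] + salt[id]);
      }
  // Jacobi spectral-radius estimate -> optimal SOR relaxation factor
  double rj = (std::cos(M_PI / nx) + std::cos(M_PI / ny) +
               std::cos(M_PI / nz)) / 3.0;
  double omega = 2.0 / (1.0 + std::sqrt(1.0 - rj * rj));
  double maxdiff = 0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    maxdiff = 0;
    for (int colour = 0; colour < 2; ++colour) {
      for (int iz = 1; iz < nz - 1; ++iz)
        for (int iy = 1; iy < ny - 1; ++iy) {
          int x0 = 1 + ((iy + iz + 1 + colour) % 2);
          R_xlen_t row = (R_xlen_t)nx * iy + sxy * iz;
          for (int ix = x0; ix < nx - 1; ix += 2) {
            R_xlen_t id = row + ix;
            double num = ex[id - 1] * p[id - 1] + ex[id] * p[id + 1] +
                         ey[id - nx] * p[id - nx] + ey[id] * p[id + nx] +
                         ez[id - sxy] * p[id - sxy] + ez[id] * p[id + sxy] +
                         rho[id];
            double d = num * invden[id] - p[id];
            p[id] += omega * d;
            double ad = std::fabs(d);
            if (ad > maxdiff) maxdiff = ad;
          }
        }
    }
    if (maxdiff < tol) break;
  }
  if (maxdiff >= tol)
    stop("PB solver did not converge in %d sweeps (max residual %g kT/e)",
         maxit, maxdiff);
  return List::create(_["iterations"] = it, _["residual"] = maxdiff,
                      _["omega"] = omega);
}
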