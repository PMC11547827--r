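// Finite-difference linearized Poisson-Boltzmann solver.
//
// Successive over-relaxation on a 7-point stencil over a cubic grid.
// Dielectric is assigned on cell faces from the face midpoint (eps_in
// inside any atom's solvation sphere, eps_out otherwise); Debye-Hueckel
// screening applies outside the Stern-adjusted solute (radius + 2 A).
// Charges are spread to the 8 surrounding nodes (trilinear); boundary
// values are Debye-screened Coulomb. The reaction-field energy is
// 0.5 * sum q_i (phi_solvated - phi_vacuum)_i with the vacuum reference
// solved on the identical grid so the grid self-energy cancels.
//
// Units: lengths in Angstrom, charges in e, energies in kcal/mol,
// potentials in kcal/(mol e); Coulomb constant 332.0637 kcal A / (mol e^2).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KCOUL = 332.0637;
static const double RT298 = 0.59249; // kcal/mol at 298.15 K
static const double STERN = 2.0;     // Stern layer thickness, A

struct Grid {
  int nx, ny, nz;
  double h, x0, y0, z0;
  inline int idx(int i, int j, int k) const { return (k * ny + j) * nx + i; }
};

static inline bool inside_solute(double x, double y, double z,
                                 const NumericMatrix& xyz,
                                 const NumericVector& rad, double pad) {
  for (int a = 0; a < xyz.nrow(); ++a) {
    double dx = x - xyz(a, 0), dy = y - xyz(a, 1), dz = z - xyz(a, 2);
    double r = rad[a] + pad;
    if (dx * dx + dy * dy + dz * dz < r * r) return true;
  }
  return false;
}

// solve one state; returns phi at every node
static std::vector<double> solve_state(const Grid& g,
                                       const NumericMatrix& xyz,
                                       const NumericVector& q,
                                       const NumericVector& rad,
                                       double eps_in, double eps_out,
                                       double kappa2_eps, // eps_out*kappa^2
                                       bool vacuum,
                                       int max_iter, double tol,
                                       double omega, double& resid_out) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const size_t N = (size_t)nx * ny * nz;
  const double h = g.h;

  // face dielectric maps (x-faces between i,i+1 etc.)
  std::vector<float> ex(N, (float)eps_out), ey(N, (float)eps_out),
      ez(N, (float)eps_out), kap(N, 0.0f);
  if (vacuum) {
    std::fill(ex.begin(), ex.end(), (float)eps_in);
    std::fill(ey.begin(), ey.end(), (float)eps_in);
    std::fill(ez.begin(), ez.end(), (float)eps_in);
  } else {
    // mark only near the atoms: loop atoms, stamp their spheres
    for (int a = 0; a < xyz.nrow(); ++a) {
      double r = rad[a];
      int i0 = std::max(0, (int)std::floor((xyz(a,0) - r - g.x0) / h) - 1);
      int i1 = std::min(nx - 1, (int)std::ceil((xyz(a,0) + r - g.x0) / h) + 1);
      int j0 = std::max(0, (int)std::floor((xyz(a,1) - r - g.y0) / h) - 1);
      int j1 = std::min(ny - 1, (int)std::ceil((xyz(a,1) + r - g.y0) / h) + 1);
      int k0 = std::max(0, (int)std::floor((xyz(a,2) - r - g.z0) / h) - 1);
      int k1 = std::min(nz - 1, (int)std::ceil((xyz(a,2) + r - g.z0) / h) + 1);
      double r2 = r * r;
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            double x = g.x0 + i * h, y = g.y0 + j * h, z = g.z0 + k * h;
            double dx, dy, dz;
            size_t id = g.idx(i, j, k);
            // x-face midpoint (i+1/2, j, k)
            dx = x + 0.5 * h - xyz(a,0); dy = y - xyz(a,1); dz = z - xyz(a,2);
            if (dx*dx + dy*dy + dz*dz < r2) ex[id] = (float)eps_in;
            // y-face midpoint
            dx = x - xyz(a,0); dy = y + 0.5 * h - xyz(a,1);
            if (dx*dx + dy*dy + dz*dz < r2) ey[id] = (float)eps_in;
            // z-face midpoint
            dy = y - xyz(a,1); dz = z + 0.5 * h - xyz(a,2);
            if (dx*dx + dy*dy + dz*dz < r2) ez[id] = (float)eps_in;
          }
    }
    if (kappa2_eps > 0) {
      std::fill(kap.begin(), kap.end(), (float)kappa2_eps);
      for (int a = 0; a < xyz.nrow(); ++a) {
        double r = rad[a] + STERN;
        int i0 = std::max(0, (int)std::floor((xyz(a,0) - r - g.x0) / h));
        int i1 = std::min(nx - 1, (int)std::ceil((xyz(a,0) + r - g.x0) / h));
        int j0 = std::max(0, (int)std::floor((xyz(a,1) - r - g.y0) / h));
        int j1 = std::min(ny - 1, (int)std::ceil((xyz(a,1) + r - g.y0) / h));
        int k0 = std::max(0, (int)std::floor((xyz(a,2) - r - g.z0) / h));
        int k1 = std::min(nz - 1, (int)std::ceil((xyz(a,2) + r - g.z0) / h));
        double r2 = r * r;
        for (int k = k0; k <= k1; ++k)
          for (int j = j0; j <= j1; ++j)
            for (int i = i0; i <= i1; ++i) {
              double dx = g.x0 + i * h - xyz(a,0);
              double dy = g.y0 + j * h - xyz(a,1);
              double dz = g.z0 + k * h - xyz(a,2);
              if (dx*dx + dy*dy + dz*dz < r2) kap[g.idx(i,j,k)] = 0.0f;
            }
      }
    }
  }

  // charge on nodes (trilinear spread), scaled source term 4 pi k q / h
  std::vector<double> src(N, 0.0);
  for (int a = 0; a < xyz.nrow(); ++a) {
    double gx = (xyz(a,0) - g.x0) / h, gy = (xyz(a,1) - g.y0) / h,
           gz = (xyz(a,2) - g.z0) / h;
    int i = (int)std::floor(gx), j = (int)std::floor(gy),
        k = (int)std::floor(gz);
    double fx = gx - i, fy = gy - j, fz = gz - k;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          src[g.idx(i + di, j + dj, k + dk)] +=
              4.0 * M_PI * KCOUL * q[a] * w / h;
        }
  }

  // Dirichlet boundary: screened Coulomb
  std::vector<double> phi(N, 0.0);
  double eps_b = vacuum ? eps_in : eps_out;
  double kappa = (vacuum || kappa2_eps <= 0)
                     ? 0.0 : std::sqrt(kappa2_eps / eps_out);
  auto bval = [&](double x, double y, double z) {
    double v = 0.0;
    for (int a = 0; a < xyz.nrow(); ++a) {
      double dx = x - xyz(a,0), dy = y - xyz(a,1), dz = z - xyz(a,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-6) r = 1e-6;
      v += KCOUL * q[a] * std::exp(-kappa * r) / (eps_b * r);
    }
    return v;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 ||
            k == nz - 1)
          phi[g.idx(i, j, k)] =
              bval(g.x0 + i * h, g.y0 + j * h, g.z0 + k * h);

  // SOR sweeps (red-black not needed for plain SOR correctness)
  double h2 = h * h;
  double resid = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    resid = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          size_t id = g.idx(i, j, k);
          double exm = ex[g.idx(i - 1, j, k)], exp_ = ex[id];
          double eym = ey[g.idx(i, j - 1, k)], eyp = ey[id];
          double ezm = ez[g.idx(i, j, k - 1)], ezp = ez[id];
          double num = exm * phi[id - 1] + exp_ * phi[id + 1] +
                       eym * phi[id - nx] + eyp * phi[id + nx] +
                       ezm * phi[id - (size_t)nx * ny] +
                       ezp * phi[id + (size_t)nx * ny] + src[id];
          double den = exm + exp_ + eym + eyp + ezm + ezp + h2 * kap[id];
          double newv = num / den;
          double dchange = newv - phi[id];
          phi[id] += omega * dchange;
          double ad = std::fabs(dchange);
          if (ad > resid) resid = ad;
        }
    if (resid < tol) break;
  }
  resid_out = resid;
  return phi;
}

static double interp_phi(const Grid& g, const std::vector<double>& phi,
                         double x, double y, double z) {
  double gx = (x - g.x0) / g.h, gy = (y - g.y0) / g.h, gz = (z - g.z0) / g.h;
  int i = (int)std::floor(gx), j = (int)std::floor(gy),
      k = (int)std::floor(gz);
  double fx = gx - i, fy = gy - j, fz = gz - k;
  double v = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di)
        v += phi[g.idx(i + di, j + dj, k + dk)] *
             (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
  return v;
}

// [[Rcpp::export(name = ".pb_solve_cpp")]]
List pb_solve_cpp(NumericMatrix xyz, NumericVector charge,
                  NumericVector radius, double spacing, double margin,
                  double eps_in, double eps_out, double ionic_strength,
                  int max_iter, double tol, double omega) {
  int n = xyz.nrow();
  if (n == 0) stop("no atoms");
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int a = 0; a < n; ++a) {
    xmin = std::min(xmin, xyz(a,0) - radius[a]);
    xmax = std::max(xmax, xyz(a,0) + radius[a]);
    ymin = std::min(ymin, xyz(a,1) - radius[a]);
    ymax = std::max(ymax, xyz(a,1) + radius[a]);
    zmin = std::min(zmin, xyz(a,2) - radius[a]);
    zmax = std::max(zmax, xyz(a,2) + radius[a]);
  }
  Grid g;
  g.h = spacing;
  g.x0 = xmin - margin; g.y0 = ymin - margin; g.z0 = zmin - margin;
  g.nx = (int)std::ceil((xmax + margin - g.x0) / spacing) + 1;
  g.ny = (int)std::ceil((ymax + margin - g.y0) / spacing) + 1;
  g.nz = (int)std::ceil((zmax + margin - g.z0) / spacing) + 1;
  if ((double)g.nx * g.ny * g.nz > 3.5e7)
    stop("PB grid too large (%d x %d x %d); increase spacing or reduce margin",
         g.nx, g.ny, g.nz);

  // eps_out * kappa^2; ionic strength in mol/L -> number density in A^-3
  double kappa2_eps = 8.0 * M_PI * KCOUL * (ionic_strength * 6.022e-4) / RT298;

  double res_s = 0.0, res_v = 0.0;
  std::vector<double> phi_s =
      solve_state(g, xyz, charge, radius, eps_in, eps_out, kappa2_eps,
                  false, max_iter, tol, omega, res_s);
  std::vector<double> phi_v =
      solve_state(g, xyz, charge, radius, eps_in, eps_out, 0.0, true,
                  max_iter, tol, omega, res_v);
  if (res_s >= tol || res_v >= tol)
    stop("PB solver did not converge: residual %g (solvated) / %g (vacuum)",
         res_s, res_v);

  NumericVector per_atom(n);
  double total = 0.0;
  for (int a = 0; a < n; ++a) {
    double dphi = interp_phi(g, phi_s, xyz(a,0), xyz(a,1), xyz(a,2)) -
                  interp_phi(g, phi_v, xyz(a,0), xyz(a,1), xyz(a,2));
    per_atom[a] = 0.5 * charge[a] * dphi;
    total += per_atom[a];
  }
  return List::create(_["total"] = total, _["per_atom"] = per_atom,
                      _["spacing"] = spacing,
                      _["dims"] = IntegerVector::create(g.nx, g.ny, g.nz),
                      _["residual"] = std::max(res_s, res_v));
}
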