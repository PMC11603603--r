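#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Internal unit system: Angstrom, femtosecond, a.m.u.; energies in kcal/mol.
// 1 kcal/mol = ACC_FACTOR amu A^2/fs^2.
static const double ACC_FACTOR = 4.184e-4;
static const double KB = 1.987204259e-3; // kcal/(mol K)

// Symmetric pair-type index for (a, b), 1-based types, a <= b.
// Returns 0-based index into the rows of the coefficient matrix.
static inline int pair_index(int a, int b, int n_types) {
  if (a > b) std::swap(a, b);
  // pairs with smaller first index: sum_{i=1}^{a-1} (n_types - i + 1)
  int before = (a - 1) * n_types - ((a - 1) * (a - 2)) / 2;
  return before + (b - a);
}

// [[Rcpp::export]]
int cpp_pair_index(int a, int b, int n_types) {
  return pair_index(a, b, n_types) + 1;
}

// Gaussian radial basis modulated by a cosine cutoff envelope.
// phi_m(r) = exp(-(r - mu_m)^2 / (2 w^2)) * 0.5 * (1 + cos(pi r / rc))
static inline void rbf_eval(double r, double mu, double w, double rc,
                            double &phi, double &dphi) {
  double g = std::exp(-(r - mu) * (r - mu) / (2.0 * w * w));
  double fc = 0.5 * (1.0 + std::cos(M_PI * r / rc));
  double dfc = -0.5 * M_PI / rc * std::sin(M_PI * r / rc);
  phi = g * fc;
  dphi = g * (-(r - mu) / (w * w) * fc + dfc);
}

// [[Rcpp::export]]
double cpp_rbf_energy(NumericMatrix coords, IntegerVector types, int n_types,
                      NumericMatrix coef, NumericVector centers,
                      double width, double cutoff) {
  int n = coords.nrow(), M = centers.size();
  double U = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= cutoff) continue;
      int p = pair_index(types[i], types[j], n_types);
      for (int m = 0; m < M; ++m) {
        double phi, dphi;
        rbf_eval(r, centers[m], width, cutoff, phi, dphi);
        U += coef(p, m) * phi;
      }
    }
  }
  return U;
}

// [[Rcpp::export]]
NumericMatrix cpp_rbf_forces(NumericMatrix coords, IntegerVector types,
                             int n_types, NumericMatrix coef,
                             NumericVector centers, double width,
                             double cutoff) {
  int n = coords.nrow(), M = centers.size();
  NumericMatrix F(n, 3);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= cutoff || r < 1e-12) continue;
      int p = pair_index(types[i], types[j], n_types);
      double dU = 0.0;
      for (int m = 0; m < M; ++m) {
        double phi, dphi;
        rbf_eval(r, centers[m], width, cutoff, phi, dphi);
        dU += coef(p, m) * dphi;
      }
      double fx = -dU * dx / r, fy = -dU * dy / r, fz = -dU * dz / r;
      F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
      F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
    }
  }
  return F;
}

// Force design matrix for the linear radial-basis potential: the predicted
// force vector (column-major flattening of the n x 3 force matrix) equals
// D %*% theta where theta is the column-major flattening of the coefficient
// matrix (n_pair_types x M).
// [[Rcpp::export]]
NumericMatrix cpp_rbf_design(NumericMatrix coords, IntegerVector types,
                             int n_types, int n_pair_types,
                             NumericVector centers, double width,
                             double cutoff) {
  int n = coords.nrow(), M = centers.size();
  NumericMatrix D(3 * n, n_pair_types * M);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= cutoff || r < 1e-12) continue;
      int p = pair_index(types[i], types[j], n_types);
      for (int m = 0; m < M; ++m) {
        double phi, dphi;
        rbf_eval(r, centers[m], width, cutoff, phi, dphi);
        int q = m * n_pair_types + p; // column-major flattening of coef
        double gx = -dphi * dx / r, gy = -dphi * dy / r, gz = -dphi * dz / r;
        D(i, q) += gx;         D(j, q) -= gx;
        D(n + i, q) += gy;     D(n + j, q) -= gy;
        D(2 * n + i, q) += gz; D(2 * n + j, q) -= gz;
      }
    }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Closed-form toy force field: harmonic bonds, double-well bonds, harmonic
// angles, Lennard-Jones pairs, harmonic tethers. Term tables use 1-based atom
// indices stored as doubles.
// ---------------------------------------------------------------------------

static void toy_eval(const NumericMatrix &x, const List &ff, double *U,
                     NumericMatrix *F) {
  int n = x.nrow();
  NumericMatrix bonds = ff["bonds"];       // i j k r0
  NumericMatrix dwells = ff["dwells"];     // i j h w r0 tilt
  NumericMatrix angles = ff["angles"];     // i j k ka theta0
  NumericMatrix lj = ff["lj"];             // i j eps sigma
  NumericMatrix tethers = ff["tethers"];   // i kt
  NumericMatrix tcenters = ff["tcenters"]; // per-tether reference position
  if (U) *U = 0.0;

  auto pair_geom = [&](int i, int j, double &dx, double &dy, double &dz,
                       double &r) {
    dx = x(i, 0) - x(j, 0);
    dy = x(i, 1) - x(j, 1);
    dz = x(i, 2) - x(j, 2);
    r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-6)
      stop("overlapping atoms: distance %g A between atoms %d and %d",
           r, i + 1, j + 1);
  };
  auto add_pair_force = [&](int i, int j, double dUdr, double dx, double dy,
                            double dz, double r) {
    if (!F) return;
    double fx = -dUdr * dx / r, fy = -dUdr * dy / r, fz = -dUdr * dz / r;
    (*F)(i, 0) += fx; (*F)(i, 1) += fy; (*F)(i, 2) += fz;
    (*F)(j, 0) -= fx; (*F)(j, 1) -= fy; (*F)(j, 2) -= fz;
  };

  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double k = bonds(b, 2), r0 = bonds(b, 3), dx, dy, dz, r;
    pair_geom(i, j, dx, dy, dz, r);
    if (U) *U += 0.5 * k * (r - r0) * (r - r0);
    add_pair_force(i, j, k * (r - r0), dx, dy, dz, r);
  }
  for (int b = 0; b < dwells.nrow(); ++b) {
    int i = (int)dwells(b, 0) - 1, j = (int)dwells(b, 1) - 1;
    double h = dwells(b, 2), w = dwells(b, 3), r0 = dwells(b, 4),
           tilt = dwells(b, 5), dx, dy, dz, r;
    pair_geom(i, j, dx, dy, dz, r);
    double u = (r - r0) / w;
    if (U) *U += h * (u * u - 1.0) * (u * u - 1.0) + tilt * u;
    add_pair_force(i, j, (4.0 * h * u * (u * u - 1.0) + tilt) / w,
                   dx, dy, dz, r);
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = (int)angles(a, 0) - 1, j = (int)angles(a, 1) - 1,
        k = (int)angles(a, 2) - 1;
    double ka = angles(a, 3), th0 = angles(a, 4);
    double ax = x(i, 0) - x(j, 0), ay = x(i, 1) - x(j, 1),
           az = x(i, 2) - x(j, 2);
    double bx = x(k, 0) - x(j, 0), by = x(k, 1) - x(j, 1),
           bz = x(k, 2) - x(j, 2);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    double cth = (ax * bx + ay * by + az * bz) / (la * lb);
    cth = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, cth));
    double th = std::acos(cth), sth = std::sqrt(1.0 - cth * cth);
    if (U) *U += 0.5 * ka * (th - th0) * (th - th0);
    if (F) {
      double coef = -ka * (th - th0) / sth; // dU/d(cos theta)... chain rule
      // d(cos)/d ri = b/(la lb) - cos * a/la^2 ; d(cos)/d rk symmetric
      double gix = coef * (bx / (la * lb) - cth * ax / (la * la));
      double giy = coef * (by / (la * lb) - cth * ay / (la * la));
      double giz = coef * (bz / (la * lb) - cth * az / (la * la));
      double gkx = coef * (ax / (la * lb) - cth * bx / (lb * lb));
      double gky = coef * (ay / (la * lb) - cth * by / (lb * lb));
      double gkz = coef * (az / (la * lb) - cth * bz / (lb * lb));
      (*F)(i, 0) -= gix; (*F)(i, 1) -= giy; (*F)(i, 2) -= giz;
      (*F)(k, 0) -= gkx; (*F)(k, 1) -= gky; (*F)(k, 2) -= gkz;
      (*F)(j, 0) += gix + gkx; (*F)(j, 1) += giy + gky;
      (*F)(j, 2) += giz + gkz;
    }
  }
  for (int p = 0; p < lj.nrow(); ++p) {
    int i = (int)lj(p, 0) - 1, j = (int)lj(p, 1) - 1;
    double eps = lj(p, 2), sig = lj(p, 3), dx, dy, dz, r;
    pair_geom(i, j, dx, dy, dz, r);
    double s6 = std::pow(sig / r, 6.0), s12 = s6 * s6;
    if (U) *U += 4.0 * eps * (s12 - s6);
    add_pair_force(i, j, 4.0 * eps * (-12.0 * s12 + 6.0 * s6) / r,
                   dx, dy, dz, r);
  }
  for (int t = 0; t < tethers.nrow(); ++t) {
    int i = (int)tethers(t, 0) - 1;
    double kt = tethers(t, 1);
    double dx = x(i, 0) - tcenters(t, 0), dy = x(i, 1) - tcenters(t, 1),
           dz = x(i, 2) - tcenters(t, 2);
    if (U) *U += 0.5 * kt * (dx * dx + dy * dy + dz * dz);
    if (F) {
      (*F)(i, 0) -= kt * dx; (*F)(i, 1) -= kt * dy; (*F)(i, 2) -= kt * dz;
    }
  }
  (void)n;
}

// [[Rcpp::export]]
double cpp_toy_energy(NumericMatrix coords, List ff) {
  double U;
  toy_eval(coords, ff, &U, nullptr);
  return U;
}

// [[Rcpp::export]]
NumericMatrix cpp_toy_forces(NumericMatrix coords, List ff) {
  NumericMatrix F(coords.nrow(), 3);
  toy_eval(coords, ff, nullptr, &F);
  return F;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator. Forces in kcal/mol/A, masses in a.m.u.,
// velocities in A/fs, dt in fs, gamma in 1/fs. Uses R's RNG so that seeded
// runs are reproducible from set.seed(); the O-step noise matrix is drawn in
// column-major order to match matrix(rnorm(3 n), n, 3) on the R side.
// ---------------------------------------------------------------------------

struct ToyFF {
  List ff;
  void forces(const NumericMatrix &x, NumericMatrix &F) {
    std::fill(F.begin(), F.end(), 0.0);
    toy_eval(x, ff, nullptr, &F);
  }
  double energy(const NumericMatrix &x) {
    double U; toy_eval(x, ff, &U, nullptr); return U;
  }
};

struct RbfFF {
  IntegerVector types; int n_types; NumericMatrix coef;
  NumericVector centers; double width, cutoff;
  void forces(const NumericMatrix &x, NumericMatrix &F) {
    NumericMatrix G = cpp_rbf_forces(x, types, n_types, coef, centers,
                                     width, cutoff);
    std::copy(G.begin(), G.end(), F.begin());
  }
  double energy(const NumericMatrix &x) {
    return cpp_rbf_energy(x, types, n_types, coef, centers, width, cutoff);
  }
};

template <typename FF>
List run_baoab(NumericMatrix coords, NumericMatrix vel, NumericVector mass,
               double dt, double gamma, double temperature, int n_steps,
               int output_stride, bool save_velocities, FF &ff) {
  int n = coords.nrow();
  NumericMatrix x = clone(coords), v = clone(vel), F(n, 3);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> sigv(n), invm(n);
  for (int i = 0; i < n; ++i) {
    sigv[i] = std::sqrt(KB * temperature * ACC_FACTOR / mass[i]);
    invm[i] = ACC_FACTOR / mass[i];
  }
  int n_saved = n_steps / output_stride + 1;
  NumericVector traj(n_saved * n * 3);
  NumericVector vtraj(save_velocities ? n_saved * n * 3 : 0);
  NumericVector energies(n_saved);
  int saved = 0;
  auto save_frame = [&]() {
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < n; ++i) {
        traj[saved + n_saved * (i + (size_t)n * d)] = x(i, d);
        if (save_velocities)
          vtraj[saved + n_saved * (i + (size_t)n * d)] = v(i, d);
      }
    energies[saved] = ff.energy(x);
    ++saved;
  };
  ff.forces(x, F);
  save_frame();
  double half = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) += half * F(i, d) * invm[i];
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += half * v(i, d);
    for (int d = 0; d < 3; ++d) // column-major to match R's rnorm fill
      for (int i = 0; i < n; ++i)
        v(i, d) = c1 * v(i, d) + c2 * sigv[i] * norm_rand();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += half * v(i, d);
    ff.forces(x, F);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        if (!std::isfinite(F(i, d)))
          stop("non-finite force at step %d", step);
        v(i, d) += half * F(i, d) * invm[i];
      }
    if (step % output_stride == 0) save_frame();
  }
  traj.attr("dim") = IntegerVector::create(n_saved, n, 3);
  List out = List::create(_["coords"] = traj, _["energies"] = energies,
                          _["finalCoords"] = x, _["finalVelocities"] = v,
                          _["nSteps"] = n_steps);
  if (save_velocities) {
    vtraj.attr("dim") = IntegerVector::create(n_saved, n, 3);
    out["velocities"] = vtraj;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_toy(NumericMatrix coords, NumericMatrix vel, NumericVector mass,
                 double dt, double gamma, double temperature, int n_steps,
                 int output_stride, bool save_velocities, List ff) {
  ToyFF f{ff};
  return run_baoab(coords, vel, mass, dt, gamma, temperature, n_steps,
                   output_stride, save_velocities, f);
}

// [[Rcpp::export]]
List cpp_run_rbf(NumericMatrix coords, NumericMatrix vel, NumericVector mass,
                 double dt, double gamma, double temperature, int n_steps,
                 int output_stride, bool save_velocities, IntegerVector types,
                 int n_types, NumericMatrix coef, NumericVector centers,
                 double width, double cutoff) {
  RbfFF f{types, n_types, coef, centers, width, cutoff};
  return run_baoab(coords, vel, mass, dt, gamma, temperature, n_steps,
                   output_stride, save_velocities, f);
}
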