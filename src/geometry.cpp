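#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Row-vector lattice convention throughout: cart = frac %*% lattice, so cell
// vectors are the rows of `lattice`.

static inline double det3(const double L[3][3]) {
  return L[0][0]*(L[1][1]*L[2][2]-L[1][2]*L[2][1])
       - L[0][1]*(L[1][0]*L[2][2]-L[1][2]*L[2][0])
       + L[0][2]*(L[1][0]*L[2][1]-L[1][1]*L[2][0]);
}

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1]*b[2]-a[2]*b[1];
  out[1] = a[2]*b[0]-a[0]*b[2];
  out[2] = a[0]*b[1]-a[1]*b[0];
}

// images needed per direction for pair displacements wrapped to [-0.5, 0.5):
// the perpendicular offset of image S is at least (|S| - 0.5) * width
static void image_ranges(const double L[3][3], double cutoff, int n[3]) {
  double V = std::fabs(det3(L));
  for (int i = 0; i < 3; ++i) {
    double cr[3];
    cross3(L[(i+1)%3], L[(i+2)%3], cr);
    double area = std::sqrt(cr[0]*cr[0]+cr[1]*cr[1]+cr[2]*cr[2]);
    double width = V / area;
    n[i] = (int)std::ceil(cutoff / width + 0.5);
  }
}

static inline double fcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return 0.5 * (std::cos(M_PI * r / rc) + 1.0);
}

static void copy_lattice(const NumericMatrix &lattice, double L[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k) L[i][k] = lattice(i, k);
}

// [[Rcpp::export]]
List cpp_neighbor_list(NumericMatrix lattice, NumericMatrix frac, double cutoff) {
  int nat = frac.nrow();
  double L[3][3];
  copy_lattice(lattice, L);
  int nimg[3];
  image_ranges(L, cutoff, nimg);
  std::vector<int> vi, vj, va, vb, vc;
  std::vector<double> vd, vx, vy, vz;
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < nat; ++i) {
    for (int j = 0; j < nat; ++j) {
      double df[3], sh[3];
      for (int k = 0; k < 3; ++k) {
        double d = frac(j,k) - frac(i,k);
        sh[k] = std::nearbyint(d);       // wrap displacement to [-0.5, 0.5]
        df[k] = d - sh[k];
      }
      for (int a = -nimg[0]; a <= nimg[0]; ++a)
      for (int b = -nimg[1]; b <= nimg[1]; ++b)
      for (int c = -nimg[2]; c <= nimg[2]; ++c) {
        // true image offset seen by the caller
        int ia = a - (int)sh[0], ib = b - (int)sh[1], ic = c - (int)sh[2];
        if (i == j && ia == 0 && ib == 0 && ic == 0) continue;
        double fx = df[0] + a, fy = df[1] + b, fz = df[2] + c;
        double dx = fx*L[0][0] + fy*L[1][0] + fz*L[2][0];
        double dy = fx*L[0][1] + fy*L[1][1] + fz*L[2][1];
        double dz = fx*L[0][2] + fy*L[1][2] + fz*L[2][2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 <= cut2) {
          vi.push_back(i+1); vj.push_back(j+1);
          va.push_back(ia); vb.push_back(ib); vc.push_back(ic);
          vd.push_back(std::sqrt(d2));
          vx.push_back(dx); vy.push_back(dy); vz.push_back(dz);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["ia"] = wrap(va), _["ib"] = wrap(vb), _["ic"] = wrap(vc),
                      _["d"] = wrap(vd),
                      _["dx"] = wrap(vx), _["dy"] = wrap(vy), _["dz"] = wrap(vz));
}

// Atom-centered symmetry functions: radial G2 and angular G4 (Behler cosine
// cutoff), with all periodic images inside `cutoff` included. spec codes are
// 1-based indices into the element alphabet shared with the parameter tables.
// [[Rcpp::export]]
NumericMatrix cpp_acsf(NumericMatrix lattice, NumericMatrix frac, IntegerVector spec,
                       double cutoff,
                       IntegerVector rad_el, NumericVector rad_eta, NumericVector rad_rs,
                       IntegerVector ang_e1, IntegerVector ang_e2,
                       NumericVector ang_eta, NumericVector ang_zeta, NumericVector ang_lambda) {
  int nat = frac.nrow();
  int nrad = rad_el.size(), nang = ang_e1.size();
  NumericMatrix G(nat, nrad + nang);
  double L[3][3];
  copy_lattice(lattice, L);
  int nimg[3];
  image_ranges(L, cutoff, nimg);
  double cut2 = cutoff * cutoff;

  std::vector<double> ndx, ndy, ndz, nd, nfc;
  std::vector<int> nel;
  for (int i = 0; i < nat; ++i) {
    ndx.clear(); ndy.clear(); ndz.clear(); nd.clear(); nfc.clear(); nel.clear();
    for (int j = 0; j < nat; ++j) {
      double df[3];
      for (int k = 0; k < 3; ++k) {
        double d = frac(j,k) - frac(i,k);
        df[k] = d - std::nearbyint(d);
      }
      for (int a = -nimg[0]; a <= nimg[0]; ++a)
      for (int b = -nimg[1]; b <= nimg[1]; ++b)
      for (int c = -nimg[2]; c <= nimg[2]; ++c) {
        double fx = df[0] + a, fy = df[1] + b, fz = df[2] + c;
        double dx = fx*L[0][0] + fy*L[1][0] + fz*L[2][0];
        double dy = fx*L[0][1] + fy*L[1][1] + fz*L[2][1];
        double dz = fx*L[0][2] + fy*L[1][2] + fz*L[2][2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 <= cut2 && d2 > 1e-16) {
          ndx.push_back(dx); ndy.push_back(dy); ndz.push_back(dz);
          double r = std::sqrt(d2);
          nd.push_back(r);
          nfc.push_back(fcut(r, cutoff));
          nel.push_back(spec[j]);
        }
      }
    }
    int nn = (int)nd.size();
    for (int p = 0; p < nrad; ++p) {
      double acc = 0.0;
      for (int m = 0; m < nn; ++m) {
        if (nel[m] != rad_el[p]) continue;
        double dr = nd[m] - rad_rs[p];
        acc += std::exp(-rad_eta[p] * dr * dr) * nfc[m];
      }
      G(i, p) = acc;
    }
    if (nang == 0) continue;
    for (int m = 0; m < nn; ++m) {
      for (int q = m + 1; q < nn; ++q) {
        double rjk2 = (ndx[m]-ndx[q])*(ndx[m]-ndx[q])
                    + (ndy[m]-ndy[q])*(ndy[m]-ndy[q])
                    + (ndz[m]-ndz[q])*(ndz[m]-ndz[q]);
        if (rjk2 >= cut2 || rjk2 < 1e-16) continue;
        double rjk = std::sqrt(rjk2);
        double cosq = (ndx[m]*ndx[q] + ndy[m]*ndy[q] + ndz[m]*ndz[q]) / (nd[m]*nd[q]);
        if (cosq > 1.0) cosq = 1.0;
        if (cosq < -1.0) cosq = -1.0;
        double fprod = nfc[m] * nfc[q] * fcut(rjk, cutoff);
        double r2sum = nd[m]*nd[m] + nd[q]*nd[q] + rjk2;
        int e1 = nel[m], e2 = nel[q];
        for (int p = 0; p < nang; ++p) {
          bool match = (e1 == ang_e1[p] && e2 == ang_e2[p]) ||
                       (e1 == ang_e2[p] && e2 == ang_e1[p]);
          if (!match) continue;
          double base = 1.0 + ang_lambda[p] * cosq;
          if (base <= 0.0) continue;
          G(i, nrad + p) += std::pow(2.0, 1.0 - ang_zeta[p])
            * std::pow(base, ang_zeta[p])
            * std::exp(-ang_eta[p] * r2sum) * fprod;
        }
      }
    }
  }
  return G;
}

struct PairParams {
  const double *eps, *sig, *delA, *delR0;
  int ne;
  double delW, coulk, cutoff, hardcore;
  double atm3b;   // Axilrod-Teller-style triple-dipole strength (target only)
  double oscA, oscL;  // oscillatory short-range term shared by both levels
};

// Smooth three-body (triple-dipole) energy over atom triplets: one vertex in
// the home cell, the other two drawn from its periodic neighborhood.
// Distances are clamped at 2 A so the term stays bounded under overlap.
static double three_body_energy(const double L[3][3], const double *frac, int nat,
                                const int *mol, double cutoff, double strength) {
  if (strength == 0.0) return 0.0;
  int nimg[3];
  image_ranges(L, cutoff, nimg);
  double cut2 = cutoff * cutoff;
  double E = 0.0;
  std::vector<double> nx, ny, nz, nr, nf;
  std::vector<bool> nintra;
  for (int i = 0; i < nat; ++i) {
    nx.clear(); ny.clear(); nz.clear(); nr.clear(); nf.clear(); nintra.clear();
    for (int j = 0; j < nat; ++j) {
      double df[3];
      for (int k = 0; k < 3; ++k) {
        double d = frac[3*j+k] - frac[3*i+k];
        df[k] = d - std::nearbyint(d);
      }
      for (int a = -nimg[0]; a <= nimg[0]; ++a)
      for (int b = -nimg[1]; b <= nimg[1]; ++b)
      for (int c = -nimg[2]; c <= nimg[2]; ++c) {
        if (a == 0 && b == 0 && c == 0 && i == j) continue;
        double fx = df[0] + a, fy = df[1] + b, fz = df[2] + c;
        double dx = fx*L[0][0] + fy*L[1][0] + fz*L[2][0];
        double dy = fx*L[0][1] + fy*L[1][1] + fz*L[2][1];
        double dz = fx*L[0][2] + fy*L[1][2] + fz*L[2][2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 <= cut2 && d2 > 1e-16) {
          double r = std::sqrt(d2);
          nx.push_back(dx); ny.push_back(dy); nz.push_back(dz);
          nr.push_back(r);
          nf.push_back(fcut(r, cutoff));
          // bonded (minimum-image same-molecule) partner of the center
          nintra.push_back(mol[j] == mol[i] && a == 0 && b == 0 && c == 0);
        }
      }
    }
    int nn = (int)nr.size();
    for (int m = 0; m < nn; ++m) {
      for (int q = m + 1; q < nn; ++q) {
        // rigid molecules: a triangle entirely inside one molecule is a
        // structure-independent constant, so it is excluded
        if (nintra[m] && nintra[q]) continue;
        double jx = nx[q]-nx[m], jy = ny[q]-ny[m], jz = nz[q]-nz[m];
        double rjk2 = jx*jx + jy*jy + jz*jz;
        if (rjk2 >= cut2 || rjk2 < 1e-16) continue;
        double rjk = std::sqrt(rjk2);
        double rij = nr[m], rik = nr[q];
        // angles of the triangle at the three vertices
        double ci = (nx[m]*nx[q] + ny[m]*ny[q] + nz[m]*nz[q]) / (rij * rik);
        double cj = (-nx[m]*jx - ny[m]*jy - nz[m]*jz) / (rij * rjk);
        double ck = (nx[q]*jx + ny[q]*jy + nz[q]*jz) / (rik * rjk);
        double a1 = rij < 2.0 ? 2.0 : rij;
        double a2 = rik < 2.0 ? 2.0 : rik;
        double a3 = rjk < 2.0 ? 2.0 : rjk;
        double denom = a1*a1*a1 * a2*a2*a2 * a3*a3*a3;
        E += strength * (1.0 + 3.0 * ci * cj * ck) / denom
           * nf[m] * nf[q] * fcut(rjk, cutoff);
      }
    }
  }
  // each triangle is seen from up to three home-cell vertices
  return E / 3.0;
}

// Intermolecular pairwise energy core. component: 0 baseline, 1 target,
// 2 delta only. Returns whole-cell energy; min intermolecular distance and
// overlap flag through pointers.
static double pair_energy_core(const double L[3][3], const double *frac, int nat,
                               const int *mol, const int *spec, const double *q,
                               const PairParams &P, int component,
                               double *mind_out, bool *overlap_out) {
  int nimg[3];
  image_ranges(L, P.cutoff, nimg);
  double cut2 = P.cutoff * P.cutoff;
  double E = 0.0, mind = HUGE_VAL;
  bool overlap = false;
  for (int i = 0; i < nat; ++i) {
    int ei = spec[i] - 1;
    for (int j = i; j < nat; ++j) {
      int ej = spec[j] - 1;
      bool same_mol = (mol[i] == mol[j]);
      double df[3];
      for (int k = 0; k < 3; ++k) {
        double d = frac[3*j+k] - frac[3*i+k];
        df[k] = d - std::nearbyint(d);
      }
      double w = (i == j) ? 0.5 : 1.0;
      for (int a = -nimg[0]; a <= nimg[0]; ++a)
      for (int b = -nimg[1]; b <= nimg[1]; ++b)
      for (int c = -nimg[2]; c <= nimg[2]; ++c) {
        // the minimum-image copy of a same-molecule pair is the bonded
        // (intramolecular) one; molecules are assumed smaller than half the
        // cell, so wrapping does not change which copy that is
        bool nearest = (a == 0 && b == 0 && c == 0);
        if (nearest && (same_mol || i == j)) continue;  // intramolecular / self
        double fx = df[0] + a, fy = df[1] + b, fz = df[2] + c;
        double dx = fx*L[0][0] + fy*L[1][0] + fz*L[2][0];
        double dy = fx*L[0][1] + fy*L[1][1] + fz*L[2][1];
        double dz = fx*L[0][2] + fy*L[1][2] + fz*L[2][2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 > cut2) continue;
        double r = std::sqrt(d2);
        if (r < mind) mind = r;
        if (r < P.hardcore) overlap = true;
        double reff = r < 0.5 ? 0.5 : r;  // keep the energy finite under overlap
        double fc = fcut(r, P.cutoff);
        double u = 0.0;
        if (component != 2) {
          double sr = P.sig[ei + P.ne*ej] / reff;
          double sr6 = sr*sr*sr; sr6 = sr6*sr6;
          u += 4.0 * P.eps[ei + P.ne*ej] * (sr6*sr6 - sr6)
             + P.coulk * q[i] * q[j] / reff
             + P.oscA * std::cos(2.0 * M_PI * reff / P.oscL);
        }
        if (component != 0) {
          double dr = reff - P.delR0[ei + P.ne*ej];
          u += P.delA[ei + P.ne*ej] * std::exp(-dr*dr / (2.0 * P.delW * P.delW));
        }
        E += w * u * fc;
      }
    }
  }
  if (component != 0 && P.atm3b != 0.0)
    E += three_body_energy(L, frac, nat, mol, P.cutoff, P.atm3b);
  *mind_out = mind;
  *overlap_out = overlap;
  return E;
}

// Minimum distance between atoms of different molecules (or different
// periodic copies of the same molecule), same convention as the energy core.
// Returns R_PosInf when nothing lies within `cutoff`.
// [[Rcpp::export]]
double cpp_min_intermol_dist(NumericMatrix lattice, NumericMatrix frac,
                             IntegerVector mol, double cutoff) {
  int nat = frac.nrow();
  double L[3][3];
  copy_lattice(lattice, L);
  int nimg[3];
  image_ranges(L, cutoff, nimg);
  double cut2 = cutoff * cutoff, mind2 = HUGE_VAL;
  for (int i = 0; i < nat; ++i) {
    for (int j = i; j < nat; ++j) {
      bool same_mol = (mol[i] == mol[j]);
      double df[3];
      for (int k = 0; k < 3; ++k) {
        double d = frac(j,k) - frac(i,k);
        df[k] = d - std::nearbyint(d);
      }
      for (int a = -nimg[0]; a <= nimg[0]; ++a)
      for (int b = -nimg[1]; b <= nimg[1]; ++b)
      for (int c = -nimg[2]; c <= nimg[2]; ++c) {
        if (a == 0 && b == 0 && c == 0 && (same_mol || i == j)) continue;
        double fx = df[0] + a, fy = df[1] + b, fz = df[2] + c;
        double dx = fx*L[0][0] + fy*L[1][0] + fz*L[2][0];
        double dy = fx*L[0][1] + fy*L[1][1] + fz*L[2][1];
        double dz = fx*L[0][2] + fy*L[1][2] + fz*L[2][2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < mind2 && d2 <= cut2) mind2 = d2;
      }
    }
  }
  return std::isfinite(mind2) ? std::sqrt(mind2) : R_PosInf;
}

// [[Rcpp::export]]
List cpp_pair_energy(NumericMatrix lattice, NumericMatrix frac, IntegerVector mol,
                     IntegerVector spec, NumericVector q, double cutoff,
                     NumericMatrix eps, NumericMatrix sig,
                     NumericMatrix delA, NumericMatrix delR0, double delW,
                     double atm3b, double oscA, double oscL,
                     double coulk, double hardcore, int component) {
  int nat = frac.nrow();
  double L[3][3];
  copy_lattice(lattice, L);
  std::vector<double> fr(3 * nat);
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) fr[3*i+k] = frac(i,k);
  PairParams P = { eps.begin(), sig.begin(), delA.begin(), delR0.begin(),
                   eps.nrow(), delW, coulk, cutoff, hardcore, atm3b,
                   oscA, oscL };
  double mind; bool overlap;
  double E = pair_energy_core(L, fr.data(), nat, mol.begin(), spec.begin(),
                              q.begin(), P, component, &mind, &overlap);
  return List::create(_["energy"] = E, _["min_dist"] = mind,
                      _["overlap"] = overlap);
}

// --- rigid packing objective -----------------------------------------------
// theta: a, b, c (A), alpha, beta, gamma (deg), rotvec1 (3),
//        then per molecule m >= 2: centroid_frac (3), rotvec (3).
// Rotation-vector increments act on reference orientations rot0 (3x3 per
// molecule, row-major). Returns baseline energy per molecule, or `bad` for
// an invalid cell.

static bool lattice_from_params(const double *cp, double L[3][3]) {
  double a = cp[0], b = cp[1], c = cp[2];
  double al = cp[3] * M_PI / 180, be = cp[4] * M_PI / 180, ga = cp[5] * M_PI / 180;
  if (a <= 0 || b <= 0 || c <= 0) return false;
  double ca = std::cos(al), cb = std::cos(be), cg = std::cos(ga), sg = std::sin(ga);
  double v2 = 1 - ca*ca - cb*cb - cg*cg + 2*ca*cb*cg;
  if (v2 <= 1e-10 || std::fabs(sg) < 1e-8) return false;
  L[0][0] = a;        L[0][1] = 0;               L[0][2] = 0;
  L[1][0] = b * cg;   L[1][1] = b * sg;          L[1][2] = 0;
  L[2][0] = c * cb;   L[2][1] = c * (ca - cb*cg) / sg;
  L[2][2] = c * std::sqrt(v2) / sg;
  return true;
}

static void rotvec_to_matrix(const double v[3], double R[3][3]) {
  double th = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  if (th < 1e-12) {
    for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) R[i][j] = (i == j);
    return;
  }
  double k[3] = { v[0]/th, v[1]/th, v[2]/th };
  double ct = std::cos(th), st = std::sin(th), omc = 1 - ct;
  R[0][0] = ct + k[0]*k[0]*omc;      R[0][1] = k[0]*k[1]*omc - k[2]*st;  R[0][2] = k[0]*k[2]*omc + k[1]*st;
  R[1][0] = k[1]*k[0]*omc + k[2]*st; R[1][1] = ct + k[1]*k[1]*omc;       R[1][2] = k[1]*k[2]*omc - k[0]*st;
  R[2][0] = k[2]*k[0]*omc - k[1]*st; R[2][1] = k[2]*k[1]*omc + k[0]*st;  R[2][2] = ct + k[2]*k[2]*omc;
}

static double pack_energy_one(const double *theta, int z,
                              const NumericMatrix &sites0,
                              const NumericMatrix &rot0,
                              const IntegerVector &site_spec,
                              const NumericVector &site_q,
                              const PairParams &P, double bad) {
  double L[3][3];
  if (!lattice_from_params(theta, L)) return bad;
  // inverse lattice for cart -> frac
  double det = det3(L);
  if (std::fabs(det) < 1e-10) return bad;
  double inv[3][3];
  inv[0][0] =  (L[1][1]*L[2][2]-L[1][2]*L[2][1])/det;
  inv[0][1] = -(L[0][1]*L[2][2]-L[0][2]*L[2][1])/det;
  inv[0][2] =  (L[0][1]*L[1][2]-L[0][2]*L[1][1])/det;
  inv[1][0] = -(L[1][0]*L[2][2]-L[1][2]*L[2][0])/det;
  inv[1][1] =  (L[0][0]*L[2][2]-L[0][2]*L[2][0])/det;
  inv[1][2] = -(L[0][0]*L[1][2]-L[0][2]*L[1][0])/det;
  inv[2][0] =  (L[1][0]*L[2][1]-L[1][1]*L[2][0])/det;
  inv[2][1] = -(L[0][0]*L[2][1]-L[0][1]*L[2][0])/det;
  inv[2][2] =  (L[0][0]*L[1][1]-L[0][1]*L[1][0])/det;

  int ns = sites0.nrow();
  int nat = ns * z;
  std::vector<double> frac(3 * nat);
  std::vector<int> mol(nat), spec(nat);
  std::vector<double> q(nat);
  for (int m = 0; m < z; ++m) {
    double rv[3], cen[3] = {0, 0, 0};
    if (m == 0) {
      rv[0] = theta[6]; rv[1] = theta[7]; rv[2] = theta[8];
    } else {
      int off = 9 + 6 * (m - 1);
      cen[0] = theta[off]; cen[1] = theta[off+1]; cen[2] = theta[off+2];
      rv[0] = theta[off+3]; rv[1] = theta[off+4]; rv[2] = theta[off+5];
    }
    double Rinc[3][3], R[3][3];
    rotvec_to_matrix(rv, Rinc);
    // R = Rinc %*% rot0_m
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        R[i][j] = 0;
        for (int k = 0; k < 3; ++k) R[i][j] += Rinc[i][k] * rot0(3*m + k, j);
      }
    double cenc[3];   // centroid in cartesian
    for (int k = 0; k < 3; ++k)
      cenc[k] = cen[0]*L[0][k] + cen[1]*L[1][k] + cen[2]*L[2][k];
    for (int s = 0; s < ns; ++s) {
      double cart[3];
      for (int k = 0; k < 3; ++k) {
        cart[k] = cenc[k];
        for (int d = 0; d < 3; ++d) cart[k] += R[k][d] * sites0(s, d);
      }
      int ia = m * ns + s;
      for (int k = 0; k < 3; ++k)
        frac[3*ia+k] = cart[0]*inv[0][k] + cart[1]*inv[1][k] + cart[2]*inv[2][k];
      mol[ia] = m + 1;
      spec[ia] = site_spec[s];
      q[ia] = site_q[s];
    }
  }
  double mind; bool overlap;
  double E = pair_energy_core(L, frac.data(), nat, mol.data(), spec.data(),
                              q.data(), P, 0, &mind, &overlap);
  return E / z;
}

// [[Rcpp::export]]
double cpp_pack_energy(NumericVector theta, int z, NumericMatrix sites0,
                       NumericMatrix rot0, IntegerVector site_spec,
                       NumericVector site_q, double cutoff,
                       NumericMatrix eps, NumericMatrix sig,
                       double coulk, double hardcore,
                       double oscA, double oscL) {
  NumericMatrix dummy(eps.nrow(), eps.ncol());
  PairParams P = { eps.begin(), sig.begin(), dummy.begin(), dummy.begin(),
                   eps.nrow(), 1.0, coulk, cutoff, hardcore, 0.0,
                   oscA, oscL };
  return pack_energy_one(theta.begin(), z, sites0, rot0, site_spec, site_q,
                         P, 1e8);
}

// central-difference gradient of the packing objective in one call
// [[Rcpp::export]]
NumericVector cpp_pack_grad(NumericVector theta, NumericVector h, int z,
                            NumericMatrix sites0, NumericMatrix rot0,
                            IntegerVector site_spec, NumericVector site_q,
                            double cutoff, NumericMatrix eps, NumericMatrix sig,
                            double coulk, double hardcore,
                            double oscA, double oscL) {
  NumericMatrix dummy(eps.nrow(), eps.ncol());
  PairParams P = { eps.begin(), sig.begin(), dummy.begin(), dummy.begin(),
                   eps.nrow(), 1.0, coulk, cutoff, hardcore, 0.0,
                   oscA, oscL };
  int n = theta.size();
  NumericVector g(n);
  std::vector<double> th(theta.begin(), theta.end());
  for (int p = 0; p < n; ++p) {
    double orig = th[p];
    th[p] = orig + h[p];
    double ep = pack_energy_one(th.data(), z, sites0, rot0, site_spec, site_q, P, 1e8);
    th[p] = orig - h[p];
    double em = pack_energy_one(th.data(), z, sites0, rot0, site_spec, site_q, P, 1e8);
    th[p] = orig;
    g[p] = (ep - em) / (2 * h[p]);
  }
  return g;
}
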