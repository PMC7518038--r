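// Pairwise molecular-mechanics energy with analytic gradients.
//
// Terms: Lennard-Jones 12-6 (geometric combining), screened Coulomb with a
// distance-dependent dielectric eps(r) = 4r, a pairwise Born-style
// desolvation penalty, a directional 10-12 hydrogen-bond term with a
// cos^2(angle) gate, ligand/receptor valence terms (harmonic bonds and
// angles, cosine torsions) and harmonic positional restraints. Nonbonded
// interactions are switched off smoothly between r_on and r_off.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COULOMB_K = 332.0636; // kcal*A/(mol*e^2)

// [[Rcpp::export]]
IntegerMatrix infer_bonds_cpp(NumericMatrix xyz, NumericVector covr,
                              double tol) {
  int n = xyz.nrow();
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double lim = covr[i] + covr[j] + tol;
      if (r > 0.4 && r < lim) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

// Build the nonbonded pair list (0-based) within `cutoff`, skipping excluded
// (1-2/1-3) pairs and tagging 1-4 pairs with `scale14`.
// [[Rcpp::export]]
List build_pairs_cpp(NumericMatrix xyz, double cutoff,
                     IntegerVector excl_i, IntegerVector excl_j,
                     IntegerVector s14_i, IntegerVector s14_j,
                     double scale14) {
  int n = xyz.nrow();
  std::set<long long> excl, s14;
  for (int k = 0; k < excl_i.size(); ++k) {
    int a = excl_i[k], b = excl_j[k];
    excl.insert((long long)std::min(a, b) * n + std::max(a, b));
  }
  for (int k = 0; k < s14_i.size(); ++k) {
    int a = s14_i[k], b = s14_j[k];
    s14.insert((long long)std::min(a, b) * n + std::max(a, b));
  }
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  std::vector<double> sc;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > c2) continue;
      long long key = (long long)i * n + j;
      if (excl.count(key)) continue;
      ii.push_back(i);
      jj.push_back(j);
      sc.push_back(s14.count(key) ? scale14 : 1.0);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["scale"] = wrap(sc));
}

struct Switch {
  double ron2, roff2, denom;
  Switch(double ron, double roff) {
    ron2 = ron * ron;
    roff2 = roff * roff;
    double d = roff2 - ron2;
    denom = d * d * d;
  }
  // value and d/dr2
  inline void eval(double r2, double &s, double &dsdr2) const {
    if (r2 <= ron2) {
      s = 1.0;
      dsdr2 = 0.0;
    } else if (r2 >= roff2) {
      s = 0.0;
      dsdr2 = 0.0;
    } else {
      double a = roff2 - r2;
      double b = roff2 + 2.0 * r2 - 3.0 * ron2;
      s = a * a * b / denom;
      dsdr2 = (-2.0 * a * b + 2.0 * a * a) / denom;
    }
  }
};

// [[Rcpp::export]]
List ff_eval_cpp(NumericMatrix xyz, List sys, bool want_grad) {
  int n = xyz.nrow();
  NumericVector q = sys["charge"], sig = sys["sigma"], eps = sys["eps"];
  IntegerVector pi = sys["pair_i"], pj = sys["pair_j"];
  NumericVector psc = sys["pair_scale"];
  IntegerVector bi = sys["bond_i"], bj = sys["bond_j"];
  NumericVector br0 = sys["bond_r0"], bk = sys["bond_k"];
  IntegerVector ai = sys["ang_i"], aj = sys["ang_j"], ak = sys["ang_k"];
  NumericVector ath0 = sys["ang_th0"], akf = sys["ang_kf"];
  IntegerVector ti = sys["tor_i"], tj = sys["tor_j"], tk = sys["tor_k"],
                tl = sys["tor_l"];
  NumericVector tV = sys["tor_V"], tn = sys["tor_n"], tg = sys["tor_phase"];
  IntegerVector hd = sys["hb_d"], hh = sys["hb_h"], ha = sys["hb_a"];
  NumericVector rk = sys["restraint_k"];
  NumericMatrix rref = sys["restraint_ref"];
  double ron = as<double>(sys["r_on"]);
  double roff = as<double>(sys["r_off"]);
  double solvK = as<double>(sys["solv_k"]);
  double solvS = as<double>(sys["solv_sigma"]);
  double hbEps = as<double>(sys["hb_eps"]);
  double hbR0 = as<double>(sys["hb_r0"]);

  Switch sw(ron, roff);
  NumericMatrix grad(want_grad ? n : 1, 3);
  double e_vdw = 0, e_elec = 0, e_solv = 0, e_hb = 0, e_bonded = 0, e_res = 0;
  double s2inv = 1.0 / (solvS * solvS);

  // nonbonded pairs
  for (int p = 0; p < pi.size(); ++p) {
    int i = pi[p], j = pj[p];
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 0.01) {
      stop("overlapping atoms (r < 0.1 A): pair %d, %d", i + 1, j + 1);
    }
    if (r2 >= sw.roff2) continue;
    double s, dsdr2;
    sw.eval(r2, s, dsdr2);
    double scale = psc[p];
    double sij = std::sqrt(sig[i] * sig[j]);
    double eij = std::sqrt(eps[i] * eps[j]);
    double sr2 = sij * sij / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    double elj = 4.0 * eij * (sr12 - sr6) * scale;
    // dlj/dr2
    double dlj = 4.0 * eij * (-6.0 * sr12 + 3.0 * sr6) / r2 * scale;
    double ec = COULOMB_K * q[i] * q[j] / (4.0 * r2) * scale;
    double dec = -ec / r2;
    double qq = q[i] * q[i] + q[j] * q[j];
    double es = solvK * qq * std::exp(-0.5 * r2 * s2inv);
    double des = es * (-0.5 * s2inv);
    e_vdw += elj * s;
    e_elec += ec * s;
    e_solv += es * s;
    if (want_grad) {
      double dtot = (dlj + dec + des) * s + (elj + ec + es) * dsdr2;
      double gx = 2.0 * dtot * dx, gy = 2.0 * dtot * dy, gz = 2.0 * dtot * dz;
      grad(i, 0) += gx; grad(i, 1) += gy; grad(i, 2) += gz;
      grad(j, 0) -= gx; grad(j, 1) -= gy; grad(j, 2) -= gz;
    }
  }

  // bonds
  for (int b = 0; b < bi.size(); ++b) {
    int i = bi[b], j = bj[b];
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - br0[b];
    e_bonded += bk[b] * dr * dr;
    if (want_grad && r > 1e-10) {
      double f = 2.0 * bk[b] * dr / r;
      grad(i, 0) += f * dx; grad(i, 1) += f * dy; grad(i, 2) += f * dz;
      grad(j, 0) -= f * dx; grad(j, 1) -= f * dy; grad(j, 2) -= f * dz;
    }
  }

  // angles
  for (int a = 0; a < ai.size(); ++a) {
    int i = ai[a], j = aj[a], k = ak[a];
    double ux = xyz(i, 0) - xyz(j, 0), uy = xyz(i, 1) - xyz(j, 1),
           uz = xyz(i, 2) - xyz(j, 2);
    double vx = xyz(k, 0) - xyz(j, 0), vy = xyz(k, 1) - xyz(j, 1),
           vz = xyz(k, 2) - xyz(j, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-10 || nv < 1e-10) continue;
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - ath0[a];
    e_bonded += akf[a] * dth * dth;
    if (want_grad) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double coef = 2.0 * akf[a] * dth;
      // dtheta/dri and /drk
      double gix = (ct * ux / nu - vx / nv) / (nu * st);
      double giy = (ct * uy / nu - vy / nv) / (nu * st);
      double giz = (ct * uz / nu - vz / nv) / (nu * st);
      double gkx = (ct * vx / nv - ux / nu) / (nv * st);
      double gky = (ct * vy / nv - uy / nu) / (nv * st);
      double gkz = (ct * vz / nv - uz / nu) / (nv * st);
      grad(i, 0) += coef * gix; grad(i, 1) += coef * giy; grad(i, 2) += coef * giz;
      grad(k, 0) += coef * gkx; grad(k, 1) += coef * gky; grad(k, 2) += coef * gkz;
      grad(j, 0) -= coef * (gix + gkx);
      grad(j, 1) -= coef * (giy + gky);
      grad(j, 2) -= coef * (giz + gkz);
    }
  }

  // torsions: E = V/2 (1 + cos(n*phi - gamma))
  for (int t = 0; t < ti.size(); ++t) {
    int i = ti[t], j = tj[t], k = tk[t], l = tl[t];
    double b1x = xyz(j, 0) - xyz(i, 0), b1y = xyz(j, 1) - xyz(i, 1),
           b1z = xyz(j, 2) - xyz(i, 2);
    double b2x = xyz(k, 0) - xyz(j, 0), b2y = xyz(k, 1) - xyz(j, 1),
           b2z = xyz(k, 2) - xyz(j, 2);
    double b3x = xyz(l, 0) - xyz(k, 0), b3y = xyz(l, 1) - xyz(k, 1),
           b3z = xyz(l, 2) - xyz(k, 2);
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
           n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
           n2z = b2x * b3y - b2y * b3x;
    double n1sq = n1x * n1x + n1y * n1y + n1z * n1z;
    double n2sq = n2x * n2x + n2y * n2y + n2z * n2z;
    double nb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (n1sq < 1e-12 || n2sq < 1e-12 || nb2 < 1e-10) continue;
    double mx = n1y * n2z - n1z * n2y, my = n1z * n2x - n1x * n2z,
           mz = n1x * n2y - n1y * n2x;
    double y = (mx * b2x + my * b2y + mz * b2z) / nb2;
    double x = n1x * n2x + n1y * n2y + n1z * n2z;
    double phi = std::atan2(y, x);
    double arg = tn[t] * phi - tg[t];
    e_bonded += 0.5 * tV[t] * (1.0 + std::cos(arg));
    if (want_grad) {
      double dEdphi = -0.5 * tV[t] * tn[t] * std::sin(arg);
      // Blondel & Karplus derivative: with F = ri-rj, G = rj-rk, H = rl-rk,
      // A = F x G = n1, B = H x G = n2 (for this sign convention of phi):
      // dphi/dri = -|G|/|A|^2 A; dphi/drl = |G|/|B|^2 B;
      // dphi/dG  = (F.G/(|A|^2|G|)) A - (H.G/(|B|^2|G|)) B
      double c1 = -nb2 / n1sq, c4 = nb2 / n2sq;
      double gix = c1 * n1x, giy = c1 * n1y, giz = c1 * n1z;
      double glx = c4 * n2x, gly = c4 * n2y, glz = c4 * n2z;
      double fg = b1x * b2x + b1y * b2y + b1z * b2z;      // F.G
      double hg = -(b3x * b2x + b3y * b2y + b3z * b2z);   // H.G
      double cA = fg / (n1sq * nb2), cB = hg / (n2sq * nb2);
      double gGx = cA * n1x - cB * n2x;
      double gGy = cA * n1y - cB * n2y;
      double gGz = cA * n1z - cB * n2z;
      double gjx = -gix + gGx, gjy = -giy + gGy, gjz = -giz + gGz;
      double gkx = -gGx - glx, gky = -gGy - gly, gkz = -gGz - glz;
      grad(i, 0) += dEdphi * gix; grad(i, 1) += dEdphi * giy; grad(i, 2) += dEdphi * giz;
      grad(j, 0) += dEdphi * gjx; grad(j, 1) += dEdphi * gjy; grad(j, 2) += dEdphi * gjz;
      grad(k, 0) += dEdphi * gkx; grad(k, 1) += dEdphi * gky; grad(k, 2) += dEdphi * gkz;
      grad(l, 0) += dEdphi * glx; grad(l, 1) += dEdphi * gly; grad(l, 2) += dEdphi * glz;
    }
  }

  // hydrogen bonds: 10-12 radial on the donor...acceptor heavy distance,
  // gated by cos^2 of the D-H...A angle (active when the angle exceeds 90).
  for (int hbi = 0; hbi < hd.size(); ++hbi) {
    int d = hd[hbi], h = hh[hbi], a = ha[hbi];
    double dx = xyz(d, 0) - xyz(a, 0), dy = xyz(d, 1) - xyz(a, 1),
           dz = xyz(d, 2) - xyz(a, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    if (r < 1e-6 || r > 6.0) continue;
    // angle at H between D and A
    double ux = xyz(d, 0) - xyz(h, 0), uy = xyz(d, 1) - xyz(h, 1),
           uz = xyz(d, 2) - xyz(h, 2);
    double vx = xyz(a, 0) - xyz(h, 0), vy = xyz(a, 1) - xyz(h, 1),
           vz = xyz(a, 2) - xyz(h, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-10 || nv < 1e-10) continue;
    double ca = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    ca = std::max(-1.0, std::min(1.0, ca));
    if (ca >= 0.0) continue; // angle below 90 degrees: no hydrogen bond
    double xr = hbR0 / r;
    double x10 = std::pow(xr, 10);
    double x12 = x10 * xr * xr;
    double rad = hbEps * (5.0 * x12 - 6.0 * x10);
    double gate = ca * ca;
    e_hb += rad * gate;
    if (want_grad) {
      double draddr = hbEps * (-60.0 * x12 + 60.0 * x10) / r;
      double fx = draddr * gate * dx / r, fy = draddr * gate * dy / r,
             fz = draddr * gate * dz / r;
      grad(d, 0) += fx; grad(d, 1) += fy; grad(d, 2) += fz;
      grad(a, 0) -= fx; grad(a, 1) -= fy; grad(a, 2) -= fz;
      // angular part: d(ca)/dx via the standard angle-gradient identities
      double coef = rad * 2.0 * ca;
      double st2 = 1.0 - ca * ca; // sin^2
      if (st2 < 1e-12) st2 = 1e-12;
      // d(cos)/dri = (v/nv - ca*u/nu)/nu  (center h)
      double gdx = (vx / nv - ca * ux / nu) / nu;
      double gdy = (vy / nv - ca * uy / nu) / nu;
      double gdz = (vz / nv - ca * uz / nu) / nu;
      double gax = (ux / nu - ca * vx / nv) / nv;
      double gay = (uy / nu - ca * vy / nv) / nv;
      double gaz = (uz / nu - ca * vz / nv) / nv;
      grad(d, 0) += coef * gdx; grad(d, 1) += coef * gdy; grad(d, 2) += coef * gdz;
      grad(a, 0) += coef * gax; grad(a, 1) += coef * gay; grad(a, 2) += coef * gaz;
      grad(h, 0) -= coef * (gdx + gax);
      grad(h, 1) -= coef * (gdy + gay);
      grad(h, 2) -= coef * (gdz + gaz);
    }
  }

  // positional restraints
  for (int i = 0; i < n; ++i) {
    if (rk[i] <= 0) continue;
    double dx = xyz(i, 0) - rref(i, 0);
    double dy = xyz(i, 1) - rref(i, 1);
    double dz = xyz(i, 2) - rref(i, 2);
    e_res += rk[i] * (dx * dx + dy * dy + dz * dz);
    if (want_grad) {
      grad(i, 0) += 2.0 * rk[i] * dx;
      grad(i, 1) += 2.0 * rk[i] * dy;
      grad(i, 2) += 2.0 * rk[i] * dz;
    }
  }

  double total = e_vdw + e_elec + e_solv + e_hb + e_bonded + e_res;
  List out = List::create(
      _["total"] = total,
      _["components"] = NumericVector::create(
          _["vdw"] = e_vdw, _["elec"] = e_elec, _["solv"] = e_solv,
          _["hbond"] = e_hb, _["bonded"] = e_bonded, _["restraint"] = e_res));
  if (want_grad) out["grad"] = grad;
  return out;
}

// Steric clash score used by torsion placement: sum over fragment x
// environment pairs of a truncated repulsive term ((0.89*(vi+vj)/r)^12,
// capped). Returns one score per rotation angle of the fragment about the
// given axis.
// [[Rcpp::export]]
NumericVector clash_scan_cpp(NumericMatrix frag, NumericVector fvdw,
                             NumericMatrix env, NumericVector evdw,
                             NumericVector origin, NumericVector axis,
                             NumericVector angles, double cap) {
  int nf = frag.nrow(), ne = env.nrow(), na = angles.size();
  NumericVector out(na);
  double ux = axis[0], uy = axis[1], uz = axis[2];
  double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nn; uy /= nn; uz /= nn;
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    double score = 0.0;
    for (int f = 0; f < nf; ++f) {
      // rotate fragment atom about axis through origin (Rodrigues)
      double px = frag(f, 0) - origin[0];
      double py = frag(f, 1) - origin[1];
      double pz = frag(f, 2) - origin[2];
      double dot = px * ux + py * uy + pz * uz;
      double cx = uy * pz - uz * py, cy = uz * px - ux * pz,
             cz = ux * py - uy * px;
      double rx = px * ct + cx * st + ux * dot * (1 - ct) + origin[0];
      double ry = py * ct + cy * st + uy * dot * (1 - ct) + origin[1];
      double rz = pz * ct + cz * st + uz * dot * (1 - ct) + origin[2];
      for (int e = 0; e < ne; ++e) {
        double dx = rx - env(e, 0), dy = ry - env(e, 1), dz = rz - env(e, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r0 = 0.89 * (fvdw[f] + evdw[e]);
        double rr = r0 * r0 / r2;
        double t = rr * rr * rr;
        t = t * t; // ^12
        if (t > cap) t = cap;
        if (t > 1e-6) score += t;
      }
    }
    out[a] = score;
  }
  return out;
}
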