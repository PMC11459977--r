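#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Conventions (documented in the package vignette):
//  - image arrays have dim c(nz, ny, nx); linear index l = iz + nz*(iy + ny*ix)
//  - voxel centres: x = ox + (ix-(nx-1)/2)*dx (dy = dx in-plane), z = oz + (iz-(nz-1)/2)*dz
//  - rotating frame at view angle theta (deg, CCW from +y detector position):
//      x' =  c*x + s*y ;  y' = -s*x + c*y ;  z' = z
//  - detector bins: transaxial it along x', axial ia along z';
//    bin centre x' = (it-(nbt-1)/2)*bin, z' = (ia-(nba-1)/2)*bin + axial_pos;
//    per-view linear bin b = ia + nba*it (matches views[v,,] vectorisation in R)

static const double DEG = M_PI / 180.0;

struct Hole {
  double x, y, z;      // position, rotating frame (mm)
  int shape;           // 0 = round, 1 = rectangular
  double w, h;         // diameter (round, w only) or width/height (mm)
  double tilt;         // about z' (deg)
  double acc;          // acceptance half-angle (deg)
};

struct DetGeom {
  int nbt, nba;
  double bin, axial_pos;
  double Rdet;          // face radius (mm)
  double T;             // crystal thickness (mm)
  double muc;           // crystal attenuation (mm^-1)
  double fwhm;          // intrinsic resolution FWHM (mm)
};

struct Cfg {
  bool psf, doi;
  double nsigma;
  int subsamp;
  double sampint;
  double minw;
};

static inline int floordiv(int a, int b) {
  int q = a / b, r = a % b;
  return (r != 0 && ((r < 0) != (b < 0))) ? q - 1 : q;
}

// crossings of the horizontal line z = zs with the polygon edges (even-odd);
// returns the number of crossings written into xs (sorted ascending)
static int scan_crossings(double zs, const std::vector<double>& px,
                          const std::vector<double>& pz, double* xs, int cap) {
  int n = 0;
  size_t M = px.size();
  for (size_t i = 0, j = M - 1; i < M; j = i++) {
    if ((pz[i] > zs) != (pz[j] > zs)) {
      double x = px[i] + (zs - pz[i]) * (px[j] - px[i]) / (pz[j] - pz[i]);
      if (n < cap) xs[n++] = x;
    }
  }
  // insertion sort (n is tiny)
  for (int a = 1; a < n; ++a) {
    double v = xs[a]; int b = a - 1;
    while (b >= 0 && xs[b] > v) { xs[b + 1] = xs[b]; --b; }
    xs[b + 1] = v;
  }
  return n - (n % 2);
}

// integrated Gaussian 1D kernel on a grid of pitch 1 (pixel units), truncated
static std::vector<double> gauss_kernel(double sigma_pix, double nsigma) {
  int K = (int)std::ceil(nsigma * sigma_pix);
  if (sigma_pix <= 0.0 || K < 1) return std::vector<double>(1, 1.0);
  std::vector<double> k(2 * K + 1);
  double s = 0.0, inv = 1.0 / (sigma_pix * std::sqrt(2.0));
  for (int i = -K; i <= K; ++i) {
    double v = 0.5 * (std::erf((i + 0.5) * inv) - std::erf((i - 0.5) * inv));
    k[i + K] = v; s += v;
  }
  for (double& v : k) v /= s;
  return k;
}

// footprint of one voxel (rotating-frame position v) through one hole,
// appended to `out` as (bin, weight) pairs sorted by bin (deduplicated)
static void hole_footprint(double vx, double vy, double vz,
                           const Hole& H, const DetGeom& D, const Cfg& C,
                           std::vector<std::pair<int, double> >& out) {
  double ax = -std::sin(H.tilt * DEG), ay = std::cos(H.tilt * DEG);
  double dx3 = H.x - vx, dy3 = H.y - vy, dz3 = H.z - vz;
  double r = std::sqrt(dx3 * dx3 + dy3 * dy3 + dz3 * dz3);
  if (r <= 1e-9) stop("voxel coincides with hole centre: undefined ray");
  double ux = dx3 / r, uy = dy3 / r, uz = dz3 / r;
  double cosinc = ux * ax + uy * ay;            // angle to (tilted) hole axis
  if (cosinc <= std::cos(H.acc * DEG)) return;  // outside acceptance cone
  if (uy <= 1e-9) return;                       // grazing / wrong side
  if (vy >= H.y) return;                        // voxel must be object-side

  // depth planes (P = detection plane radius, wk = interaction probability)
  static std::vector<double> P, wk;
  P.clear(); wk.clear();
  if (!C.doi) {
    P.push_back(D.Rdet + 0.5 * D.T); wk.push_back(1.0);
  } else if (D.T <= 0.0) {
    P.push_back(D.Rdet); wk.push_back(1.0);            // T -> 0 limit: face
  } else if (D.muc <= 0.0) {
    P.push_back(D.Rdet + 0.5 * D.T); wk.push_back(1.0); // fallback: mid-depth
  } else if (C.sampint >= D.T) {
    P.push_back(D.Rdet + 0.5 * D.T);
    wk.push_back(1.0 - std::exp(-D.muc * D.T / uy));
  } else {
    int ns = (int)std::ceil(D.T / C.sampint);
    for (int k = 0; k < ns; ++k) {
      double t0 = D.T * k / ns, t1 = D.T * (k + 1) / ns;
      P.push_back(D.Rdet + 0.5 * (t0 + t1));
      wk.push_back(std::exp(-D.muc * t0 / uy) - std::exp(-D.muc * t1 / uy));
    }
  }

  // aperture boundary (3D, rotating frame)
  double e1x = std::cos(H.tilt * DEG), e1y = std::sin(H.tilt * DEG);
  static std::vector<double> qx, qy, qz;
  qx.clear(); qy.clear(); qz.clear();
  if (H.shape == 0) {
    int M = 24;
    for (int m = 0; m < M; ++m) {
      double ph = 2.0 * M_PI * m / M, cr = 0.5 * H.w * std::cos(ph), sr = 0.5 * H.w * std::sin(ph);
      qx.push_back(H.x + cr * e1x); qy.push_back(H.y + cr * e1y); qz.push_back(H.z + sr);
    }
  } else {
    double sw = 0.5 * H.w, sh = 0.5 * H.h;
    double cs[4][2] = {{-sw, -sh}, {sw, -sh}, {sw, sh}, {-sw, sh}};
    for (int m = 0; m < 4; ++m) {
      qx.push_back(H.x + cs[m][0] * e1x); qy.push_back(H.y + cs[m][0] * e1y);
      qz.push_back(H.z + cs[m][1]);
    }
  }

  double fp = D.bin / C.subsamp;
  double x0 = -0.5 * D.nbt * D.bin;                 // fine-grid origin (left edge)
  double z0 = -0.5 * D.nba * D.bin + D.axial_pos;   // bottom edge

  size_t nd = P.size(), M = qx.size();

  // projection to plane P is affine per boundary point: precompute offsets
  static std::vector<double> inv, ofx, ofz, polx, polz;
  inv.resize(M); ofx.resize(M); ofz.resize(M);
  polx.resize(M); polz.resize(M);
  for (size_t m = 0; m < M; ++m) {
    double denom = qy[m] - vy;
    if (denom <= 1e-9) return;  // aperture edge not ahead of voxel
    inv[m] = 1.0 / denom; ofx[m] = qx[m] - vx; ofz[m] = qz[m] - vz;
  }

  // vertices trace line segments as P varies: the union bbox over depths is
  // the bbox of the polygons at the extreme planes
  double Pmin = P[0], Pmax = P[0];
  for (size_t k = 1; k < nd; ++k) {
    Pmin = std::min(Pmin, P[k]); Pmax = std::max(Pmax, P[k]);
  }
  int jt0 = INT_MAX, jt1 = INT_MIN, ja0 = INT_MAX, ja1 = INT_MIN;
  for (int e = 0; e < 2; ++e) {
    double Pe = e ? Pmax : Pmin;
    for (size_t m = 0; m < M; ++m) {
      double s = (Pe - vy) * inv[m];
      int jt = (int)std::floor((vx + s * ofx[m] - x0) / fp);
      int ja = (int)std::floor((vz + s * ofz[m] - z0) / fp);
      jt0 = std::min(jt0, jt - 1); jt1 = std::max(jt1, jt + 1);
      ja0 = std::min(ja0, ja - 1); ja1 = std::max(ja1, ja + 1);
    }
  }
  // guard against degenerate huge footprints
  int lim = 8 * std::max(D.nbt, D.nba) * C.subsamp;
  if (jt1 - jt0 > lim || ja1 - ja0 > lim) return;

  int K = 0;
  std::vector<double> kern(1, 1.0);
  if (C.psf && D.fwhm > 0.0) {
    double sig = D.fwhm / 2.354820045030949327 / fp;
    kern = gauss_kernel(sig, C.nsigma);
    K = ((int)kern.size() - 1) / 2;
  }
  jt0 -= K; jt1 += K; ja0 -= K; ja1 += K;
  int WT = jt1 - jt0 + 1, WA = ja1 - ja0 + 1;
  static std::vector<double> buf;
  buf.assign((size_t)WT * WA, 0.0);

  // rasterize each depth polygon by scanlines: exact interval coverage in x,
  // two subsample rows per fine pixel in z; normalise per depth to wk
  struct Iv { int ja; double xa, xb; };
  static std::vector<Iv> ivs;
  double xs[16];
  static const double off[4] = {0.125, 0.375, 0.625, 0.875};
  for (size_t k = 0; k < nd; ++k) {
    double s0 = (P[k] - vy);
    double bz0 = HUGE_VAL, bz1 = -HUGE_VAL;
    for (size_t m = 0; m < M; ++m) {
      double s = s0 * inv[m];
      polx[m] = vx + s * ofx[m];
      polz[m] = vz + s * ofz[m];
      bz0 = std::min(bz0, polz[m]); bz1 = std::max(bz1, polz[m]);
    }
    int a0 = (int)std::floor((bz0 - z0) / fp), a1 = (int)std::floor((bz1 - z0) / fp);
    ivs.clear();
    double tot = 0.0;
    for (int ja = a0; ja <= a1; ++ja) {
      for (int sr = 0; sr < 4; ++sr) {
        double zs = z0 + (ja + off[sr]) * fp;
        int nc = scan_crossings(zs, polx, polz, xs, 16);
        for (int c = 0; c + 1 < nc; c += 2) {
          Iv iv; iv.ja = ja; iv.xa = xs[c]; iv.xb = xs[c + 1];
          ivs.push_back(iv);
          tot += 0.25 * (iv.xb - iv.xa) / fp;
        }
      }
    }
    if (tot <= 0.0) {
      // footprint thinner than the sampling rows: deposit at the centroid
      double cx = 0.0, cz = 0.0;
      for (size_t m = 0; m < M; ++m) { cx += polx[m]; cz += polz[m]; }
      cx /= M; cz /= M;
      int jt = (int)std::floor((cx - x0) / fp), ja = (int)std::floor((cz - z0) / fp);
      if (jt >= jt0 && jt <= jt1 && ja >= ja0 && ja <= ja1)
        buf[(size_t)(jt - jt0) * WA + (ja - ja0)] += wk[k];
      continue;
    }
    double sc = 0.25 * wk[k] / (tot * fp);
    for (size_t q = 0; q < ivs.size(); ++q) {
      const Iv& iv = ivs[q];
      int t0 = (int)std::floor((iv.xa - x0) / fp);
      int t1 = (int)std::floor((iv.xb - x0) / fp);
      for (int jt = std::max(t0, jt0); jt <= std::min(t1, jt1); ++jt) {
        double lo = std::max(iv.xa, x0 + jt * fp);
        double hi = std::min(iv.xb, x0 + (jt + 1) * fp);
        if (hi > lo)
          buf[(size_t)(jt - jt0) * WA + (iv.ja - ja0)] += (hi - lo) * sc;
      }
    }
  }

  // PSF: separable convolution on the fine grid
  if (K > 0) {
    std::vector<double> tmp((size_t)WT * WA, 0.0);
    for (int i = 0; i < WT; ++i)          // along axial (contiguous)
      for (int j = 0; j < WA; ++j) {
        double v = buf[(size_t)i * WA + j];
        if (v == 0.0) continue;
        for (int d = -K; d <= K; ++d) {
          int jj = j + d;
          if (jj >= 0 && jj < WA) tmp[(size_t)i * WA + jj] += v * kern[d + K];
        }
      }
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int i = 0; i < WT; ++i)
      for (int j = 0; j < WA; ++j) {
        double v = tmp[(size_t)i * WA + j];
        if (v == 0.0) continue;
        for (int d = -K; d <= K; ++d) {
          int ii = i + d;
          if (ii >= 0 && ii < WT) buf[(size_t)ii * WA + j] += v * kern[d + K];
        }
      }
  }

  // geometric sensitivity: A * cos(theta) / (4 pi r^2)
  double A = (H.shape == 0) ? M_PI * 0.25 * H.w * H.w : H.w * H.h;
  double G = A * cosinc / (4.0 * M_PI * r * r);

  // downsample fine grid to detector bins (clip to detector here),
  // iterating bins so the emitted pairs are strictly ascending in bin
  int bt0 = floordiv(jt0, C.subsamp), bt1 = floordiv(jt1, C.subsamp);
  int ba0 = floordiv(ja0, C.subsamp), ba1 = floordiv(ja1, C.subsamp);
  for (int it = std::max(bt0, 0); it <= std::min(bt1, D.nbt - 1); ++it) {
    int fi0 = std::max(jt0, it * C.subsamp);
    int fi1 = std::min(jt1, it * C.subsamp + C.subsamp - 1);
    for (int ia = std::max(ba0, 0); ia <= std::min(ba1, D.nba - 1); ++ia) {
      int fj0 = std::max(ja0, ia * C.subsamp);
      int fj1 = std::min(ja1, ia * C.subsamp + C.subsamp - 1);
      double v = 0.0;
      for (int i = fi0; i <= fi1; ++i)
        for (int j = fj0; j <= fj1; ++j)
          v += buf[(size_t)(i - jt0) * WA + (j - ja0)];
      if (v > 0.0) out.push_back(std::make_pair(ia + D.nba * it, v * G));
    }
  }
}

// ---- Siddon-style exact ray traversal --------------------------------------

struct GridGeom {
  int nx, ny, nz;
  double dx, dz, ox, oy, oz;
  double xmin() const { return ox - 0.5 * nx * dx; }
  double ymin() const { return oy - 0.5 * ny * dx; }
  double zmin() const { return oz - 0.5 * nz * dz; }
};

// walk the segment p0 -> p1; cb(l, ix, iy, iz, len) for every voxel crossed
template <typename F>
static void traverse(const GridGeom& g,
                     double x0, double y0, double z0,
                     double x1, double y1, double z1, F cb) {
  double d[3] = {x1 - x0, y1 - y0, z1 - z0};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return;
  double p0[3] = {x0, y0, z0};
  double gmin[3] = {g.xmin(), g.ymin(), g.zmin()};
  double sp[3] = {g.dx, g.dx, g.dz};
  int n[3] = {g.nx, g.ny, g.nz};

  // clip [t0,t1] (param in [0,1]) to the grid box
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    double lo = gmin[a], hi = gmin[a] + n[a] * sp[a];
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] <= lo || p0[a] >= hi) return;
    } else {
      double ta = (lo - p0[a]) / d[a], tb = (hi - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return;

  // initial voxel at entry (nudged inwards)
  double te = t0 + 1e-12 * (t1 - t0);
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    idx[a] = (int)std::floor((p0[a] + te * d[a] - gmin[a]) / sp[a]);
    if (idx[a] < 0) idx[a] = 0;
    if (idx[a] >= n[a]) idx[a] = n[a] - 1;
  }
  int step[3];
  double tnext[3], tdelta[3];
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 1e-12) {
      step[a] = 1;
      tnext[a] = ((gmin[a] + (idx[a] + 1) * sp[a]) - p0[a]) / d[a];
      tdelta[a] = sp[a] / d[a];
    } else if (d[a] < -1e-12) {
      step[a] = -1;
      tnext[a] = ((gmin[a] + idx[a] * sp[a]) - p0[a]) / d[a];
      tdelta[a] = -sp[a] / d[a];
    } else {
      step[a] = 0; tnext[a] = 2.0; tdelta[a] = 2.0;
    }
  }
  double t = t0;
  int guard = 3 * (n[0] + n[1] + n[2]) + 6;
  while (t < t1 && guard-- > 0) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double tstop = std::min(tnext[a], t1);
    double len = (tstop - t) * L;
    if (len > 0.0) cb(idx[0], idx[1], idx[2], len);
    t = tstop;
    if (tnext[a] >= t1) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= n[a]) break;
    tnext[a] += tdelta[a];
  }
}

static double line_integral(const double* mu, const GridGeom& g,
                            double x0, double y0, double z0,
                            double x1, double y1, double z1) {
  double s = 0.0;
  traverse(g, x0, y0, z0, x1, y1, z1,
           [&](int ix, int iy, int iz, double len) {
             s += mu[iz + (size_t)g.nz * (iy + (size_t)g.ny * ix)] * len;
           });
  return s;
}

// ---- exported entry points -------------------------------------------------

static std::vector<Hole> unpack_holes(const NumericMatrix& holes) {
  std::vector<Hole> hs(holes.nrow());
  for (int i = 0; i < holes.nrow(); ++i) {
    hs[i].x = holes(i, 0); hs[i].y = holes(i, 1); hs[i].z = holes(i, 2);
    hs[i].shape = (int)holes(i, 3);
    hs[i].w = holes(i, 4); hs[i].h = holes(i, 5);
    hs[i].tilt = holes(i, 6); hs[i].acc = holes(i, 7);
  }
  return hs;
}

// [[Rcpp::export]]
List cpp_view_matrix(double angle_deg,
                     int nx, int ny, int nz, double dx, double dz,
                     double ox, double oy, double oz,
                     int nbt, int nba, double bin, double axial_pos,
                     double det_radius, double crystal_T, double mu_crystal,
                     double fwhm,
                     NumericMatrix holes,
                     bool psf, bool doi, int att_mode,
                     double n_sigma, int subsamp, double samp_int,
                     double min_weight,
                     LogicalVector mask, NumericVector atten) {
  DetGeom D; D.nbt = nbt; D.nba = nba; D.bin = bin; D.axial_pos = axial_pos;
  D.Rdet = det_radius; D.T = crystal_T; D.muc = mu_crystal; D.fwhm = fwhm;
  Cfg C; C.psf = psf; C.doi = doi; C.nsigma = n_sigma; C.subsamp = subsamp;
  C.sampint = samp_int; C.minw = min_weight;
  std::vector<Hole> hs = unpack_holes(holes);
  GridGeom g; g.nx = nx; g.ny = ny; g.nz = nz; g.dx = dx; g.dz = dz;
  g.ox = ox; g.oy = oy; g.oz = oz;

  double th = angle_deg * DEG, c = std::cos(th), s = std::sin(th);
  const double* mu = (atten.size() > 0) ? REAL(atten) : (double*)NULL;

  std::vector<int> oi, oj;
  std::vector<double> ow;
  std::vector<std::pair<int, double> > hout, acc, merged;
  bool single = hs.size() == 1;

  for (int ix = 0; ix < nx; ++ix) {
    double x = g.ox + (ix - 0.5 * (nx - 1)) * dx;
    for (int iy = 0; iy < ny; ++iy) {
      double y = g.oy + (iy - 0.5 * (ny - 1)) * dx;
      double vx = c * x + s * y, vy = -s * x + c * y;
      for (int iz = 0; iz < nz; ++iz) {
        size_t l = iz + (size_t)nz * (iy + (size_t)ny * ix);
        if (!mask[l]) continue;
        double vz = g.oz + (iz - 0.5 * (nz - 1)) * dz;
        acc.clear();
        for (size_t hi = 0; hi < hs.size(); ++hi) {
          hout.clear();
          hole_footprint(vx, vy, vz, hs[hi], D, C, hout);
          if (hout.empty()) continue;
          if (att_mode == 1 && mu) {
            // simple: one factor along voxel -> hole centre (fixed frame)
            double hxf = c * hs[hi].x - s * hs[hi].y;
            double hyf = s * hs[hi].x + c * hs[hi].y;
            double f = std::exp(-line_integral(mu, g, x, y, vz, hxf, hyf, hs[hi].z));
            for (size_t q = 0; q < hout.size(); ++q) hout[q].second *= f;
          } else if (att_mode == 2 && mu) {
            // full: per-bin factor along voxel -> bin centre
            double P = doi ? det_radius : det_radius + 0.5 * crystal_T;
            for (size_t q = 0; q < hout.size(); ++q) {
              int b = hout[q].first, bt = b / nba, ba = b % nba;
              double bxp = (bt - 0.5 * (nbt - 1)) * bin;
              double bzp = (ba - 0.5 * (nba - 1)) * bin + axial_pos;
              double bx = c * bxp - s * P, by = s * bxp + c * P;
              hout[q].second *=
                std::exp(-line_integral(mu, g, x, y, vz, bx, by, bzp));
            }
          }
          if (single) {
            acc.swap(hout);
          } else {
            // merge two bin-sorted lists
            merged.clear();
            size_t a = 0, b = 0;
            while (a < acc.size() || b < hout.size()) {
              if (b >= hout.size() ||
                  (a < acc.size() && acc[a].first < hout[b].first))
                merged.push_back(acc[a++]);
              else if (a >= acc.size() || hout[b].first < acc[a].first)
                merged.push_back(hout[b++]);
              else {
                merged.push_back(std::make_pair(acc[a].first,
                                                acc[a].second + hout[b].second));
                ++a; ++b;
              }
            }
            acc.swap(merged);
          }
        }
        for (size_t q = 0; q < acc.size(); ++q) {
          double w = acc[q].second;
          if (w > C.minw && w > 0.0 && R_finite(w)) {
            oi.push_back(acc[q].first + 1);
            oj.push_back((int)l + 1);
            ow.push_back(w);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["x"] = wrap(ow));
}

// footprint of a single point (rotating-frame coordinates), all corrections
// except object attenuation
// [[Rcpp::export]]
List cpp_point_footprint(double vx, double vy, double vz,
                         NumericMatrix holes,
                         int nbt, int nba, double bin, double axial_pos,
                         double det_radius, double crystal_T, double mu_crystal,
                         double fwhm,
                         bool psf, bool doi,
                         double n_sigma, int subsamp, double samp_int) {
  DetGeom D; D.nbt = nbt; D.nba = nba; D.bin = bin; D.axial_pos = axial_pos;
  D.Rdet = det_radius; D.T = crystal_T; D.muc = mu_crystal; D.fwhm = fwhm;
  Cfg C; C.psf = psf; C.doi = doi; C.nsigma = n_sigma; C.subsamp = subsamp;
  C.sampint = samp_int; C.minw = 0.0;
  std::vector<Hole> hs = unpack_holes(holes);
  std::map<int, double> acc;
  std::vector<std::pair<int, double> > hout;
  for (size_t hi = 0; hi < hs.size(); ++hi) {
    hout.clear();
    hole_footprint(vx, vy, vz, hs[hi], D, C, hout);
    for (size_t q = 0; q < hout.size(); ++q)
      acc[hout[q].first] += hout[q].second;
  }
  int n = (int)acc.size();
  IntegerVector bi(n), bt(n), ba(n);
  NumericVector w(n);
  int k = 0;
  for (std::map<int, double>::iterator it = acc.begin(); it != acc.end(); ++it, ++k) {
    bi[k] = it->first + 1;
    bt[k] = it->first / nba + 1;
    ba[k] = it->first % nba + 1;
    w[k] = it->second;
  }
  return List::create(_["bin"] = bi, _["it"] = bt, _["ia"] = ba, _["weight"] = w);
}

// [[Rcpp::export]]
NumericMatrix cpp_trace_ray(NumericVector p0, NumericVector p1,
                            int nx, int ny, int nz, double dx, double dz,
                            double ox, double oy, double oz) {
  GridGeom g; g.nx = nx; g.ny = ny; g.nz = nz; g.dx = dx; g.dz = dz;
  g.ox = ox; g.oy = oy; g.oz = oz;
  std::vector<int> vix, viy, viz;
  std::vector<double> vl;
  traverse(g, p0[0], p0[1], p0[2], p1[0], p1[1], p1[2],
           [&](int ix, int iy, int iz, double len) {
             vix.push_back(ix + 1); viy.push_back(iy + 1); viz.push_back(iz + 1);
             vl.push_back(len);
           });
  NumericMatrix out((int)vl.size(), 4);
  for (int i = 0; i < (int)vl.size(); ++i) {
    out(i, 0) = viz[i]; out(i, 1) = viy[i]; out(i, 2) = vix[i]; out(i, 3) = vl[i];
  }
  colnames(out) = CharacterVector::create("iz", "iy", "ix", "length");
  return out;
}

// [[Rcpp::export]]
double cpp_line_integral(NumericVector mu, NumericVector p0, NumericVector p1,
                         int nx, int ny, int nz, double dx, double dz,
                         double ox, double oy, double oz) {
  GridGeom g; g.nx = nx; g.ny = ny; g.nz = nz; g.dx = dx; g.dz = dz;
  g.ox = ox; g.oy = oy; g.oz = oz;
  return line_integral(REAL(mu), g, p0[0], p0[1], p0[2], p1[0], p1[1], p1[2]);
}

// 3x3x3 median filter (truncated neighbourhood at the volume faces)
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector x, int nz, int ny, int nx) {
  NumericVector out((R_xlen_t)nz * ny * nx);
  std::vector<double> nb; nb.reserve(27);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        nb.clear();
        for (int a = std::max(0, ix - 1); a <= std::min(nx - 1, ix + 1); ++a)
          for (int b = std::max(0, iy - 1); b <= std::min(ny - 1, iy + 1); ++b)
            for (int cc = std::max(0, iz - 1); cc <= std::min(nz - 1, iz + 1); ++cc)
              nb.push_back(x[cc + (size_t)nz * (b + (size_t)ny * a)]);
        size_t n = nb.size(), mid = n / 2;
        std::nth_element(nb.begin(), nb.begin() + mid, nb.end());
        double med = nb[mid];
        if (n % 2 == 0) {
          std::nth_element(nb.begin(), nb.begin() + mid - 1, nb.begin() + mid);
          med = 0.5 * (med + nb[mid - 1]);
        }
        out[iz + (size_t)nz * (iy + (size_t)ny * ix)] = med;
      }
  return out;
}

// quadratic-prior gradient and curvature, 26-neighbourhood, weights 1/distance
// R(x) = 1/4 * sum_j sum_{k in N_j} w_jk (x_j - x_k)^2  (each pair counted twice)
// [[Rcpp::export]]
List cpp_quad_prior(NumericVector x, int nz, int ny, int nx) {
  NumericVector grad((R_xlen_t)nz * ny * nx), curv((R_xlen_t)nz * ny * nx);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        size_t l = iz + (size_t)nz * (iy + (size_t)ny * ix);
        double gsum = 0.0, csum = 0.0, xc = x[l];
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int cc = -1; cc <= 1; ++cc) {
              if (!a && !b && !cc) continue;
              int jx = ix + a, jy = iy + b, jz = iz + cc;
              if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
                continue;
              double w = 1.0 / std::sqrt((double)(a * a + b * b + cc * cc));
              gsum += w * (xc - x[jz + (size_t)nz * (jy + (size_t)ny * jx)]);
              csum += 2.0 * w;
            }
        grad[l] = gsum; curv[l] = csum;
      }
  return List::create(_["grad"] = grad, _["curv"] = curv);
}
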