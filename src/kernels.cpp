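// Low-level geometry kernels: Gauss linking charges between straight
// segments (closed-form solid-angle expression), writhe, segment-segment
// distances, contribution-matrix band labelling, and the topology-preserving
// Monte Carlo relaxer.  All coordinates are in nm.

#include <Rcpp.h>
#include <functional>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline void sub3(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Gauss linking charge of two straight segments p1->p2 and q1->q2:
// the signed solid angle of the quadrilateral spanned by the four
// end-to-end vectors, divided by 4*pi (Klenin & Langowski spherical-excess
// form).  Coplanar / degenerate configurations contribute 0.
static double pair_charge(const double* p1, const double* p2,
                          const double* q1, const double* q2) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  sub3(p2, p1, r12); sub3(q2, q1, r34);
  sub3(q1, p1, r13); sub3(q2, p1, r14);
  sub3(q1, p2, r23); sub3(q2, p2, r24);

  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1); cross3(r14, r24, n2);
  cross3(r24, r23, n3); cross3(r23, r13, n4);
  const double eps = 1e-12;
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < eps || l2 < eps || l3 < eps || l4 < eps) return 0.0;
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }
  double omega = std::asin(clamp1(dot3(n1, n2))) +
                 std::asin(clamp1(dot3(n2, n3))) +
                 std::asin(clamp1(dot3(n3, n4))) +
                 std::asin(clamp1(dot3(n4, n1)));
  double cr[3];
  cross3(r34, r12, cr);
  double s = dot3(cr, r13);
  double sgn = (s > 0) - (s < 0);
  return omega * sgn / (4.0 * M_PI);
}

// [[Rcpp::export]]
double gauss_pair_charge_cpp(NumericVector p1, NumericVector p2,
                             NumericVector q1, NumericVector q2) {
  double a[3] = { p1[0], p1[1], p1[2] }, b[3] = { p2[0], p2[1], p2[2] };
  double c[3] = { q1[0], q1[1], q1[2] }, d[3] = { q2[0], q2[1], q2[2] };
  return pair_charge(a, b, c, d);
}

// Segment start/end accessor for a curve stored as an n x 3 matrix.
// Closed curves have n segments (last wraps to first), open curves n-1.
struct Segs {
  const double* x; const double* y; const double* z;
  int n; bool closed;
  Segs(const NumericMatrix& P, bool cl)
    : x(&P(0, 0)), y(&P(0, 1)), z(&P(0, 2)), n(P.nrow()), closed(cl) {}
  int nseg() const { return closed ? n : n - 1; }
  void get(int i, double* a, double* b) const {
    int j = (i + 1) % n;
    a[0] = x[i]; a[1] = y[i]; a[2] = z[i];
    b[0] = x[j]; b[1] = y[j]; b[2] = z[j];
  }
};

// [[Rcpp::export]]
NumericMatrix gauss_matrix_cpp(NumericMatrix A, bool closedA,
                               NumericMatrix B, bool closedB) {
  Segs sa(A, closedA), sb(B, closedB);
  int na = sa.nseg(), nb = sb.nseg();
  NumericMatrix M(na, nb);
  double a1[3], a2[3], b1[3], b2[3];
  for (int i = 0; i < na; ++i) {
    sa.get(i, a1, a2);
    for (int j = 0; j < nb; ++j) {
      sb.get(j, b1, b2);
      M(i, j) = pair_charge(a1, a2, b1, b2);
    }
  }
  return M;
}

// Block sums of the contribution matrix without materializing it.
// row_breaks / col_breaks are 0-based segment indices marking the starts of
// blocks (first element must be 0).
// [[Rcpp::export]]
NumericMatrix gauss_block_sums_cpp(NumericMatrix A, bool closedA,
                                   NumericMatrix B, bool closedB,
                                   IntegerVector row_breaks,
                                   IntegerVector col_breaks) {
  Segs sa(A, closedA), sb(B, closedB);
  int na = sa.nseg(), nb = sb.nseg();
  int nrb = row_breaks.size(), ncb = col_breaks.size();
  std::vector<int> rblk(na), cblk(nb);
  for (int i = 0; i < na; ++i) {
    int b = 0;
    while (b + 1 < nrb && i >= row_breaks[b + 1]) ++b;
    rblk[i] = b;
  }
  for (int j = 0; j < nb; ++j) {
    int b = 0;
    while (b + 1 < ncb && j >= col_breaks[b + 1]) ++b;
    cblk[j] = b;
  }
  NumericMatrix S(nrb, ncb);
  double a1[3], a2[3], b1[3], b2[3];
  for (int i = 0; i < na; ++i) {
    sa.get(i, a1, a2);
    int ri = rblk[i];
    for (int j = 0; j < nb; ++j) {
      sb.get(j, b1, b2);
      S(ri, cblk[j]) += pair_charge(a1, a2, b1, b2);
    }
  }
  return S;
}

// Writhe of a polygonal curve, always treated as closed (open inputs are
// closed by the implicit last-to-first segment at the R level).
// [[Rcpp::export]]
double writhe_cpp(NumericMatrix P) {
  Segs s(P, true);
  int n = s.nseg();
  double a1[3], a2[3], b1[3], b2[3];
  double wr = 0.0;
  for (int i = 0; i < n; ++i) {
    s.get(i, a1, a2);
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through closure
      s.get(j, b1, b2);
      wr += 2.0 * pair_charge(a1, a2, b1, b2);
    }
  }
  return wr;
}

// Minimum distance between segments p1->p2 and q1->q2 (clamped to the
// segments; parallel and degenerate cases fall back to point-segment
// distances).
static double seg_seg_dist(const double* p1, const double* p2,
                           const double* q1, const double* q2) {
  double d1[3], d2[3], r[3];
  sub3(p2, p1, d1); sub3(q2, q1, d2); sub3(p1, q1, r);
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double s = 0.0, t = 0.0;
  const double eps = 1e-12;
  if (a <= eps && e <= eps) {
    // both degenerate: point-point
  } else if (a <= eps) {
    t = f / e; t = t < 0 ? 0 : (t > 1 ? 1 : t);
  } else {
    double c = dot3(d1, r);
    if (e <= eps) {
      s = -c / a; s = s < 0 ? 0 : (s > 1 ? 1 : s);
    } else {
      double b = dot3(d1, d2);
      double denom = a * e - b * b;
      if (denom > eps) {
        s = (b * f - c * e) / denom;
        s = s < 0 ? 0 : (s > 1 ? 1 : s);
      } else {
        s = 0.0;  // parallel
      }
      t = (b * s + f) / e;
      if (t < 0) {
        t = 0; s = -c / a; s = s < 0 ? 0 : (s > 1 ? 1 : s);
      } else if (t > 1) {
        t = 1; s = (b - c) / a; s = s < 0 ? 0 : (s > 1 ? 1 : s);
      }
    }
  }
  double cp[3], cq[3];
  for (int k = 0; k < 3; ++k) {
    cp[k] = p1[k] + s * d1[k];
    cq[k] = q1[k] + t * d2[k];
  }
  double d[3];
  sub3(cp, cq, d);
  return norm3(d);
}

// [[Rcpp::export]]
double seg_dist_cpp(NumericVector p1, NumericVector p2,
                    NumericVector q1, NumericVector q2) {
  double a[3] = { p1[0], p1[1], p1[2] }, b[3] = { p2[0], p2[1], p2[2] };
  double c[3] = { q1[0], q1[1], q1[2] }, d[3] = { q2[0], q2[1], q2[2] };
  return seg_seg_dist(a, b, c, d);
}

// Segment-segment distance landscape between two polylines.
// [[Rcpp::export]]
NumericMatrix seg_dist_matrix_cpp(NumericMatrix A, bool closedA,
                                  NumericMatrix B, bool closedB) {
  Segs sa(A, closedA), sb(B, closedB);
  int na = sa.nseg(), nb = sb.nseg();
  NumericMatrix D(na, nb);
  double a1[3], a2[3], b1[3], b2[3];
  for (int i = 0; i < na; ++i) {
    sa.get(i, a1, a2);
    for (int j = 0; j < nb; ++j) {
      sb.get(j, b1, b2);
      D(i, j) = seg_seg_dist(a1, a2, b1, b2);
    }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Monte Carlo relaxer
// ---------------------------------------------------------------------------

struct Grid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> cells;
  static int64_t key(int ix, int iy, int iz) {
    return ((int64_t)(ix + 1048576) << 42) |
           ((int64_t)(iy + 1048576) << 21) |
           (int64_t)(iz + 1048576);
  }
  int64_t keyof(const double* p) const {
    return key((int)std::floor(p[0] / cell), (int)std::floor(p[1] / cell),
               (int)std::floor(p[2] / cell));
  }
  void insert(int idx, const double* p) { cells[keyof(p)].push_back(idx); }
  void remove(int idx, const double* p) {
    auto it = cells.find(keyof(p));
    if (it == cells.end()) return;
    auto& v = it->second;
    for (size_t k = 0; k < v.size(); ++k) {
      if (v[k] == idx) { v[k] = v.back(); v.pop_back(); break; }
    }
  }
};

struct MCSys {
  std::vector<double> P;          // 3*m coords
  int m;
  std::vector<int> sid;           // strand id 0..3 (0 A, 1 B, 2 new1, 3 new2)
  std::vector<int> rix;           // parental ring index
  int n_par, n_unrep;
  bool is_ri;
  double hardcore;
  const double* pt(int i) const { return &P[3 * i]; }
  double* pt(int i) { return &P[3 * i]; }

  int strand_len(int s) const {
    return (s <= 1) ? n_par : (n_par - n_unrep);
  }
  bool strand_closed(int s) const { return s <= 1; }

  // per-pair hard-core threshold: 0 for covalent/contour neighbours, a
  // reduced core inside the congested fork junction zones, the full core
  // elsewhere
  double pair_hardcore(int p, int q) const {
    int sp = sid[p], sq = sid[q];
    int rp = rix[p], rq = rix[q];
    if (sp == sq) {
      int d = std::abs(rp - rq);
      if (strand_closed(sp)) d = std::min(d, n_par - d);
      return d <= 3 ? 0.0 : hardcore;
    }
    auto did = [&](int s, int r) {
      if (s == 0) return (r < n_unrep || !is_ri) ? 0 : 1;
      if (s == 1) return (r < n_unrep || !is_ri) ? 0 : 2;
      return s == 2 ? 1 : 2;
    };
    int dp = did(sp, rp), dq = did(sq, rq);
    if (dp == dq) {
      // paired strands of one duplex: native helical geometry keeps all
      // cross-strand pairs at >= 1.5 nm, so a reduced 1.2 nm core blocks
      // strand passage without rejecting the native structure
      double core = hardcore < 1.2 ? hardcore : 1.2;
      return std::abs(rp - rq) <= 6 ? core : hardcore;
    }
    if (!is_ri) return hardcore;
    auto near_fork1 = [&](int r) {
      return r >= n_unrep - 13 && r <= n_unrep + 12;
    };
    auto near_fork2 = [&](int r) { return r >= n_par - 13 || r <= 12; };
    if ((near_fork1(rp) && near_fork1(rq)) ||
        (near_fork2(rp) && near_fork2(rq)))
      return hardcore < 0.9 ? hardcore : 0.9;
    return hardcore;
  }
};

static void rotate_about(const double* axis_p, const double* axis_d,
                         double angle, const double* in, double* out) {
  // Rodrigues rotation of point `in` about the line through axis_p along
  // unit vector axis_d.
  double v[3];
  sub3(in, axis_p, v);
  double c = std::cos(angle), s = std::sin(angle);
  double kd = dot3(axis_d, v);
  double cr[3];
  cross3(axis_d, v, cr);
  for (int k = 0; k < 3; ++k)
    out[k] = axis_p[k] + v[k] * c + cr[k] * s + axis_d[k] * kd * (1 - c);
}

// [[Rcpp::export]]
List mc_relax_cpp(NumericMatrix P0, IntegerVector strand_id,
                  IntegerVector ring_index, int n_parental, int n_unrep,
                  bool is_ri, bool forks_free, int n_moves,
                  double max_angle, int min_block, int max_block,
                  double hardcore, double bond_slack, int n_frames,
                  double fork_move_prob = 0.25) {
  MCSys S;
  S.m = P0.nrow();
  S.P.resize(3 * S.m);
  for (int i = 0; i < S.m; ++i)
    for (int k = 0; k < 3; ++k) S.P[3 * i + k] = P0(i, k);
  S.sid.assign(strand_id.begin(), strand_id.end());
  S.rix.assign(ring_index.begin(), ring_index.end());
  S.n_par = n_parental; S.n_unrep = n_unrep;
  S.is_ri = is_ri; S.hardcore = hardcore;

  // site membership: points that share a parental ring index move together
  std::vector<std::vector<int>> site(n_parental);
  for (int i = 0; i < S.m; ++i) site[S.rix[i]].push_back(i);
  std::vector<double> cent(3 * n_parental);
  auto update_centroid = [&](int r) {
    double c[3] = { 0, 0, 0 };
    for (int idx : site[r])
      for (int k = 0; k < 3; ++k) c[k] += S.P[3 * idx + k];
    for (int k = 0; k < 3; ++k) cent[3 * r + k] = c[k] / site[r].size();
  };
  for (int r = 0; r < n_parental; ++r) update_centroid(r);

  // intra-strand bonds (consecutive points of each strand, wrap if closed)
  std::vector<std::pair<int, int>> bonds;
  {
    std::vector<std::vector<int>> by_strand(4);
    for (int i = 0; i < S.m; ++i) by_strand[S.sid[i]].push_back(i);
    for (int s = 0; s < 4; ++s) {
      auto& v = by_strand[s];
      if (v.empty()) continue;
      for (size_t k = 0; k + 1 < v.size(); ++k)
        bonds.push_back({ v[k], v[k + 1] });
      if (S.strand_closed(s)) bonds.push_back({ v.back(), v.front() });
    }
  }
  std::vector<double> bond_len0(bonds.size());
  auto blen = [&](size_t b) {
    double d[3];
    sub3(S.pt(bonds[b].first), S.pt(bonds[b].second), d);
    return norm3(d);
  };
  for (size_t b = 0; b < bonds.size(); ++b) bond_len0[b] = blen(b);

  // virtual guard points subdividing long bonds (fork junction chords):
  // derived positions on the chord, kept in the grid so nothing can pass
  // through the junction gaps
  struct VBond { int e1, e2; std::vector<int> vidx; std::vector<double> frac; };
  std::vector<VBond> vbonds;
  std::vector<int> vb_of_point(S.m, -1);  // endpoint -> vbond index
  {
    int next_idx = S.m;
    std::vector<double> extraP;
    std::vector<int> extraSid, extraRix;
    for (size_t b = 0; b < bonds.size(); ++b) {
      if (bond_len0[b] <= 1.2) continue;
      VBond vb;
      vb.e1 = bonds[b].first; vb.e2 = bonds[b].second;
      int k = (int)std::floor(bond_len0[b] / 0.7);
      for (int j = 1; j <= k; ++j) {
        double f = (double)j / (k + 1);
        vb.frac.push_back(f);
        vb.vidx.push_back(next_idx++);
        for (int c = 0; c < 3; ++c)
          extraP.push_back((1 - f) * S.P[3 * vb.e1 + c] +
                           f * S.P[3 * vb.e2 + c]);
        extraSid.push_back(S.sid[vb.e1]);
        extraRix.push_back(f < 0.5 ? S.rix[vb.e1] : S.rix[vb.e2]);
      }
      vb_of_point[vb.e1] = (int)vbonds.size();
      vb_of_point[vb.e2] = (int)vbonds.size();
      vbonds.push_back(vb);
    }
    if (!extraP.empty()) {
      S.P.insert(S.P.end(), extraP.begin(), extraP.end());
      S.sid.insert(S.sid.end(), extraSid.begin(), extraSid.end());
      S.rix.insert(S.rix.end(), extraRix.begin(), extraRix.end());
      S.m = (int)S.P.size() / 3;
    }
  }
  int m_real = P0.nrow();

  // anchored ring sites (fork windows) when forks are fixed
  std::vector<char> anchored(n_parental, 0);
  if (is_ri && !forks_free) {
    for (int r = 0; r < n_parental; ++r) {
      bool f1 = r >= n_unrep - 3 && r <= n_unrep + 2;
      bool f2 = r >= n_parental - 3 || r <= 2;
      if (f1 || f2) anchored[r] = 1;
    }
  }

  Grid grid;
  grid.cell = hardcore;
  for (int i = 0; i < S.m; ++i) grid.insert(i, S.pt(i));

  RNGScope rng;
  std::vector<int> moved;            // moved point indices
  std::vector<double> newpos;        // proposed coords
  std::vector<char> is_moved(S.m, 0);
  int accepted = 0;
  List frames(n_frames);
  int frame_at = 0;

  auto clash = [&](const double* p, int self) {
    int ix = (int)std::floor(p[0] / grid.cell);
    int iy = (int)std::floor(p[1] / grid.cell);
    int iz = (int)std::floor(p[2] / grid.cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.cells.find(Grid::key(ix + dx, iy + dy, iz + dz));
          if (it == grid.cells.end()) continue;
          for (int q : it->second) {
            if (is_moved[q]) continue;  // static points only
            double d[3];
            sub3(p, S.pt(q), d);
            double dd = dot3(d, d);
            if (dd < hardcore * hardcore) {
              double thr = S.pair_hardcore(self, q);
              if (dd < thr * thr) return true;
            }
          }
        }
    return false;
  };

  for (int mv = 0; mv < n_moves; ++mv) {
    bool fork_move = is_ri && forks_free && unif_rand() < fork_move_prob;
    double axis_p[3], axis_d[3];
    moved.clear();

    if (!fork_move) {
      int i = (int)(unif_rand() * n_parental) % n_parental;
      int L = min_block +
              (int)(unif_rand() * (max_block - min_block + 1));
      if (L >= n_parental - 2) L = n_parental - 3;
      int j = (i + L) % n_parental;
      bool bad = false;
      for (int k = 1; k < L; ++k) {
        int r = (i + k) % n_parental;
        if (anchored[r]) { bad = true; break; }
        for (int idx : site[r]) moved.push_back(idx);
      }
      if (bad || moved.empty()) continue;
      for (int k = 0; k < 3; ++k) {
        axis_p[k] = cent[3 * i + k];
        axis_d[k] = cent[3 * j + k] - cent[3 * i + k];
      }
    } else {
      // fork-twist: rotate a terminal block next to a fork about the local
      // chain tangent, transferring twist across the fork junction
      int f = unif_rand() < 0.5 ? 1 : 2;
      bool unrep_side = unif_rand() < 0.5;
      int L = min_block +
              (int)(unif_rand() * (max_block - min_block + 1));
      int lo, hi, anchor, anchor2;  // ring range [lo, hi] inclusive
      if (f == 1) {                 // fork between n_unrep-1 and n_unrep
        if (unrep_side) {
          lo = n_unrep - L; hi = n_unrep - 1;
          anchor = lo - 1; anchor2 = lo - 2;
        } else {
          lo = n_unrep; hi = n_unrep + L - 1;
          anchor = hi + 1; anchor2 = hi + 2;
        }
      } else {                      // fork between n_parental-1 and 0
        if (unrep_side) {
          lo = 0; hi = L - 1;
          anchor = hi + 1; anchor2 = hi + 2;
        } else {
          lo = n_parental - L; hi = n_parental - 1;
          anchor = lo - 1; anchor2 = lo - 2;
        }
      }
      if (lo < 0 || hi >= n_parental || anchor < 0 ||
          anchor >= n_parental || anchor2 < 0 || anchor2 >= n_parental)
        continue;
      // block must stay on one side of its fork
      if (unrep_side && (lo < 0 || hi >= n_unrep)) continue;
      if (!unrep_side && lo < n_unrep) continue;
      for (int r = lo; r <= hi; ++r)
        for (int idx : site[r]) moved.push_back(idx);
      for (int k = 0; k < 3; ++k) {
        axis_p[k] = cent[3 * anchor + k];
        axis_d[k] = cent[3 * anchor + k] - cent[3 * anchor2 + k];
      }
    }

    double dl = norm3(axis_d);
    if (dl < 1e-9) continue;
    for (int k = 0; k < 3; ++k) axis_d[k] /= dl;
    double theta = (2.0 * unif_rand() - 1.0) * max_angle;

    // lever arm -> number of interpolation checkpoints
    double rmax = 0.0;
    for (int idx : moved) {
      double v[3];
      sub3(S.pt(idx), axis_p, v);
      double kd = dot3(axis_d, v);
      double per2 = dot3(v, v) - kd * kd;
      if (per2 > rmax) rmax = per2;
    }
    rmax = std::sqrt(std::max(0.0, rmax));
    int steps = std::max(1, (int)std::ceil(rmax * std::fabs(theta) / 0.6));
    if (steps > 24) continue;  // overly large sweep: skip cheaply

    for (int idx : moved) is_moved[idx] = 1;
    // junction chords with a moving endpoint: their derived guard points
    // move too and must be re-checked at every interpolation step
    std::vector<int> vb_active;
    for (size_t vb = 0; vb < vbonds.size(); ++vb) {
      if (is_moved[vbonds[vb].e1] || is_moved[vbonds[vb].e2]) {
        vb_active.push_back((int)vb);
        for (int vi : vbonds[vb].vidx) is_moved[vi] = 1;
      }
    }
    bool ok = true;
    newpos.assign(3 * moved.size(), 0.0);
    std::vector<double> vpos;   // proposed guard-point positions
    std::vector<int> vids;
    for (int st = 1; st <= steps && ok; ++st) {
      double ang = theta * st / steps;
      for (size_t k = 0; k < moved.size(); ++k) {
        double out[3];
        rotate_about(axis_p, axis_d, ang, S.pt(moved[k]), out);
        for (int c = 0; c < 3; ++c) newpos[3 * k + c] = out[c];
        if (clash(out, moved[k])) { ok = false; break; }
      }
      // junction chords deform (one endpoint may be static), so their
      // guard points must also be checked against the moving block and
      // against the other active chords, not only against static points
      vpos.clear(); vids.clear();
      for (int vb : vb_active) {
        if (!ok) break;
        const VBond& B = vbonds[vb];
        double e1[3], e2[3];
        if (is_moved[B.e1])
          rotate_about(axis_p, axis_d, ang, S.pt(B.e1), e1);
        else for (int c = 0; c < 3; ++c) e1[c] = S.pt(B.e1)[c];
        if (is_moved[B.e2])
          rotate_about(axis_p, axis_d, ang, S.pt(B.e2), e2);
        else for (int c = 0; c < 3; ++c) e2[c] = S.pt(B.e2)[c];
        for (size_t j = 0; j < B.vidx.size() && ok; ++j) {
          double f = B.frac[j], pos[3];
          for (int c = 0; c < 3; ++c)
            pos[c] = (1 - f) * e1[c] + f * e2[c];
          if (clash(pos, B.vidx[j])) { ok = false; break; }
          for (size_t k = 0; k < moved.size(); ++k) {
            double d[3] = { pos[0] - newpos[3 * k], pos[1] - newpos[3 * k + 1],
                            pos[2] - newpos[3 * k + 2] };
            double thr = S.pair_hardcore(B.vidx[j], moved[k]);
            if (dot3(d, d) < thr * thr) { ok = false; break; }
          }
          for (size_t v = 0; v < vids.size() && ok; ++v) {
            double d[3] = { pos[0] - vpos[3 * v], pos[1] - vpos[3 * v + 1],
                            pos[2] - vpos[3 * v + 2] };
            double thr = S.pair_hardcore(B.vidx[j], vids[v]);
            if (dot3(d, d) < thr * thr) ok = false;
          }
          vpos.push_back(pos[0]); vpos.push_back(pos[1]);
          vpos.push_back(pos[2]);
          vids.push_back(B.vidx[j]);
        }
      }
    }

    if (ok) {
      // boundary-bond guard: apply proposal, check, roll back on failure
      std::vector<double> oldpos(3 * moved.size());
      for (size_t k = 0; k < moved.size(); ++k)
        for (int c = 0; c < 3; ++c) oldpos[3 * k + c] = S.P[3 * moved[k] + c];
      for (size_t k = 0; k < moved.size(); ++k)
        for (int c = 0; c < 3; ++c) S.P[3 * moved[k] + c] = newpos[3 * k + c];
      for (size_t b = 0; b < bonds.size() && ok; ++b) {
        if (is_moved[bonds[b].first] == is_moved[bonds[b].second]) continue;
        if (std::fabs(blen(b) - bond_len0[b]) > bond_slack) ok = false;
      }
      if (!ok) {
        for (size_t k = 0; k < moved.size(); ++k)
          for (int c = 0; c < 3; ++c)
            S.P[3 * moved[k] + c] = oldpos[3 * k + c];
      } else {
        // grid update: re-key moved points and the derived guard points
        for (size_t k = 0; k < moved.size(); ++k) {
          grid.remove(moved[k], &oldpos[3 * k]);
          grid.insert(moved[k], S.pt(moved[k]));
        }
        for (int vb : vb_active) {
          const VBond& B = vbonds[vb];
          for (size_t j = 0; j < B.vidx.size(); ++j) {
            int vi = B.vidx[j];
            double f = B.frac[j];
            grid.remove(vi, S.pt(vi));
            for (int c = 0; c < 3; ++c)
              S.P[3 * vi + c] = (1 - f) * S.P[3 * B.e1 + c] +
                                f * S.P[3 * B.e2 + c];
            grid.insert(vi, S.pt(vi));
          }
        }
        std::vector<char> site_touch(n_parental, 0);
        for (int idx : moved) site_touch[S.rix[idx]] = 1;
        for (int r = 0; r < n_parental; ++r)
          if (site_touch[r]) update_centroid(r);
        ++accepted;
      }
    }
    for (int idx : moved) is_moved[idx] = 0;
    for (int vb : vb_active)
      for (int vi : vbonds[vb].vidx) is_moved[vi] = 0;

    if (n_frames > 0 &&
        (mv + 1) % std::max(1, n_moves / n_frames) == 0 &&
        frame_at < n_frames) {
      NumericMatrix F(m_real, 3);
      for (int i = 0; i < m_real; ++i)
        for (int k = 0; k < 3; ++k) F(i, k) = S.P[3 * i + k];
      frames[frame_at++] = F;
    }
  }

  NumericMatrix Pout(m_real, 3);
  for (int i = 0; i < m_real; ++i)
    for (int k = 0; k < 3; ++k) Pout(i, k) = S.P[3 * i + k];
  return List::create(_["points"] = Pout, _["frames"] = frames,
                      _["n_frames_filled"] = frame_at,
                      _["acceptance"] = (double)accepted / n_moves);
}
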