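// Stochastic simulators for nucleotide-coupled subunit shuffling of hexamers.
//
// Monomer nucleotide states: 0 = T (ATP-bound), 1 = D (ADP-bound),
// 2 = N (AMP-PNP-bound).  Per-monomer reactions: T -> D at rate kh
// (hydrolysis); D (and optionally N) -> exchange at rate ke, installing T with
// probability w_atp and N otherwise.  Reverse reactions are ignored.
// A hexamer with >= 2 ADP-bound monomers is a competent-state (CS) hexamer
// and can exchange subunits; hexamers with < 2 ADP are ground state (GS).
//
// Two couplings of shuffling to the nucleotide kinetics are provided:
//  * fast-equilibrium: at fixed synchronisation intervals dt, all subunits of
//    all current CS-hexamers are pooled and repartitioned uniformly at random
//    (the stationary outcome of fast dissociation/re-association);
//  * explicit: event-driven (Gillespie) dynamics in which CS-hexamers
//    dissociate at rate kdcs into two contiguous arcs and complementary-size
//    free oligomers re-associate at rate krcs per pair.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

inline int ipick(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// membership lists with O(1) removal
struct SlotList {
  std::vector<int> items;
  std::vector<int> pos; // pos[slot] = index in items, or -1
  void init(int nslots) { items.clear(); pos.assign(nslots, -1); }
  void add(int s) { pos[s] = items.size(); items.push_back(s); }
  void remove(int s) {
    int p = pos[s];
    int last = items.back();
    items[p] = last;
    pos[last] = p;
    items.pop_back();
    pos[s] = -1;
  }
  bool has(int s) const { return pos[s] >= 0; }
  int size() const { return (int)items.size(); }
};

} // namespace

// Fast-equilibrium simulator (tau-leaping on the per-monomer reactions with
// step dt equal to the shuffling synchronisation interval).
// [[Rcpp::export(name = ".sim_fast_eq_cpp")]]
List sim_fast_eq_cpp(int n_hex, int n_tagged, double kh, double ke,
                     NumericVector t_grid, double dt, double w_atp,
                     bool exchange_n, double init_d_prob, double init_n_prob,
                     bool shuffle_on) {
  const int nslots = 6 * n_hex;
  std::vector<int> st(nslots, 0);   // nucleotide state per slot
  std::vector<int> tg(nslots, 0);   // tag flag per slot
  std::vector<int> dcnt(n_hex, 0);  // ADP count per hexamer
  SlotList listT, listX;            // T monomers; exchange-eligible monomers
  SlotList listCS;                  // hexamers with >= 2 ADP
  listT.init(nslots);
  listX.init(nslots);
  listCS.init(n_hex);

  for (int h = 0; h < n_hex; ++h) {
    for (int i = 0; i < 6; ++i) {
      int s = 6 * h + i;
      tg[s] = (h >= n_hex - n_tagged) ? 1 : 0;
      double u = (init_d_prob > 0.0 || init_n_prob > 0.0) ? unif_rand() : 1.0;
      if (u < init_d_prob) {
        st[s] = 1;
        dcnt[h]++;
        listX.add(s);
      } else if (u < init_d_prob + init_n_prob) {
        st[s] = 2;
        if (exchange_n) listX.add(s);
      } else {
        listT.add(s);
      }
    }
    if (dcnt[h] >= 2) listCS.add(h);
  }

  const int n_rec = t_grid.size();
  IntegerMatrix pk(n_rec, 7), dh(n_rec, 7), nuc_tot(n_rec, 3);
  IntegerMatrix jk(n_rec, 49); // j-major: column j*7 + k
  const double pT = -expm1(-kh * dt);
  const double pX = -expm1(-ke * dt);

  std::vector<int> cs;
  std::vector<int> pool_st, pool_tg, slots;

  int rec = 0;
  double t = 0.0;
  const double t_end = t_grid[n_rec - 1];
  long step = 0;

  auto record = [&](int r) {
    for (int h = 0; h < n_hex; ++h) {
      int kt = 0, jt = 0;
      for (int i = 0; i < 6; ++i) {
        int s = 6 * h + i;
        kt += tg[s];
        jt += (st[s] == 0);
      }
      pk(r, kt)++;
      dh(r, dcnt[h])++;
      jk(r, jt * 7 + kt)++;
    }
    for (int s = 0; s < nslots; ++s) nuc_tot(r, st[s])++;
  };

  while (rec < n_rec && t_grid[rec] <= 1e-12) record(rec++);

  while (rec < n_rec) {
    // hydrolysis events
    int nT = listT.size();
    if (nT > 0 && pT > 0) {
      int kev = (int)R::rbinom(nT, pT);
      for (int e = 0; e < kev && listT.size() > 0; ++e) {
        int s = listT.items[ipick(listT.size())];
        listT.remove(s);
        st[s] = 1;
        int h = s / 6;
        if (++dcnt[h] == 2) listCS.add(h);
        listX.add(s);
      }
    }
    // exchange events
    int nX = listX.size();
    if (nX > 0 && pX > 0) {
      int kev = (int)R::rbinom(nX, pX);
      for (int e = 0; e < kev && listX.size() > 0; ++e) {
        int s = listX.items[ipick(listX.size())];
        listX.remove(s);
        if (st[s] == 1) {
          int h = s / 6;
          if (--dcnt[h] == 1 && listCS.has(h)) listCS.remove(h);
        }
        if (w_atp >= 1.0 || unif_rand() < w_atp) {
          st[s] = 0;
          listT.add(s);
        } else {
          st[s] = 2;
          if (exchange_n) listX.add(s);
        }
      }
    }
    // fast-equilibrium shuffling of the CS pool
    if (shuffle_on) {
      cs.assign(listCS.items.begin(), listCS.items.end());
      int m = (int)cs.size();
      if (m >= 2) {
        slots.clear();
        pool_st.clear();
        pool_tg.clear();
        for (int ci = 0; ci < m; ++ci)
          for (int i = 0; i < 6; ++i) {
            int s = 6 * cs[ci] + i;
            slots.push_back(s);
            pool_st.push_back(st[s]);
            pool_tg.push_back(tg[s]);
          }
        // joint Fisher-Yates shuffle of (state, tag) pairs
        for (int i = (int)pool_st.size() - 1; i > 0; --i) {
          int j = ipick(i + 1);
          std::swap(pool_st[i], pool_st[j]);
          std::swap(pool_tg[i], pool_tg[j]);
        }
        for (size_t q = 0; q < slots.size(); ++q) {
          int s = slots[q];
          int olds = st[s], news = pool_st[q];
          tg[s] = pool_tg[q];
          if (olds != news) {
            // update membership lists
            if (olds == 0) listT.remove(s);
            else if (listX.has(s)) listX.remove(s);
            if (news == 0) listT.add(s);
            else if (news == 1 || exchange_n) listX.add(s);
            st[s] = news;
          }
        }
        for (int ci = 0; ci < m; ++ci) {
          int h = cs[ci], d = 0;
          for (int i = 0; i < 6; ++i) d += (st[6 * h + i] == 1);
          dcnt[h] = d;
          if (d >= 2 && !listCS.has(h)) listCS.add(h);
          if (d < 2 && listCS.has(h)) listCS.remove(h);
        }
      }
    }
    t += dt;
    ++step;
    while (rec < n_rec && t >= t_grid[rec] - 1e-12) record(rec++);
    if (t > t_end + dt) break; // safety
    if (step % 16384 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix nuc_fin(n_hex, 6), tag_fin(n_hex, 6);
  for (int h = 0; h < n_hex; ++h)
    for (int i = 0; i < 6; ++i) {
      nuc_fin(h, i) = st[6 * h + i];
      tag_fin(h, i) = tg[6 * h + i];
    }

  return List::create(_["pk_counts"] = pk, _["d_hist"] = dh,
                      _["jk_counts"] = jk, _["nuc_totals"] = nuc_tot,
                      _["nuc_final"] = nuc_fin, _["tag_final"] = tag_fin,
                      _["n_steps"] = (double)step, _["dt"] = dt);
}

namespace {

struct Unit {
  int size;
  int st[6];
  int tg[6];
};

} // namespace

// Explicit-rate simulator: Gillespie over per-monomer reactions plus
// CS-hexamer dissociation (kdcs) and complementary oligomer association
// (krcs per complementary pair).  cut_rule: 0 = uniform over the 15 unordered
// interface pairs; 1 = uniform over pairs of ADP-weakened interfaces
// (interface i, between ring positions i and i+1, is weakened when the
// monomer at position i is ADP-bound).
// [[Rcpp::export(name = ".sim_explicit_cpp")]]
List sim_explicit_cpp(int n_hex, int n_tagged, double kh, double ke,
                      NumericVector t_grid, double kdcs, double krcs,
                      double w_atp, bool exchange_n, double init_d_prob,
                      double init_n_prob, int cut_rule) {
  std::vector<Unit> hexes, oligs;
  hexes.reserve(n_hex);
  long nT = 0, nX = 0, nCS = 0;
  long scnt[6] = {0, 0, 0, 0, 0, 0}; // oligomer counts by size (index 1..5)

  auto dof = [](const Unit &u) {
    int d = 0;
    for (int i = 0; i < u.size; ++i) d += (u.st[i] == 1);
    return d;
  };

  for (int h = 0; h < n_hex; ++h) {
    Unit u;
    u.size = 6;
    for (int i = 0; i < 6; ++i) {
      u.tg[i] = (h >= n_hex - n_tagged) ? 1 : 0;
      double r = (init_d_prob > 0.0 || init_n_prob > 0.0) ? unif_rand() : 1.0;
      if (r < init_d_prob) {
        u.st[i] = 1;
        nX++;
      } else if (r < init_d_prob + init_n_prob) {
        u.st[i] = 2;
        if (exchange_n) nX++;
      } else {
        u.st[i] = 0;
        nT++;
      }
    }
    if (dof(u) >= 2) nCS++;
    hexes.push_back(u);
  }

  const int n_rec = t_grid.size();
  IntegerMatrix pk(n_rec, 7), dh(n_rec, 7), nuc_tot(n_rec, 3);
  IntegerMatrix olig_sizes(n_rec, 5);
  IntegerVector n_hex_rec(n_rec), free_sub(n_rec), tag_tot(n_rec);

  auto record = [&](int r) {
    for (size_t h = 0; h < hexes.size(); ++h) {
      int kt = 0;
      for (int i = 0; i < 6; ++i) kt += hexes[h].tg[i];
      pk(r, kt)++;
      dh(r, dof(hexes[h]))++;
    }
    long tagc = 0;
    for (size_t h = 0; h < hexes.size(); ++h)
      for (int i = 0; i < 6; ++i) {
        nuc_tot(r, hexes[h].st[i])++;
        tagc += hexes[h].tg[i];
      }
    long fs = 0;
    for (size_t o = 0; o < oligs.size(); ++o) {
      olig_sizes(r, oligs[o].size - 1)++;
      fs += oligs[o].size;
      for (int i = 0; i < oligs[o].size; ++i) {
        nuc_tot(r, oligs[o].st[i])++;
        tagc += oligs[o].tg[i];
      }
    }
    n_hex_rec[r] = (int)hexes.size();
    free_sub[r] = (int)fs;
    tag_tot[r] = (int)tagc;
  };

  int rec = 0;
  double t = 0.0;
  const double t_end = t_grid[n_rec - 1];
  while (rec < n_rec && t_grid[rec] <= 1e-12) record(rec++);
  long n_events = 0;

  // locate the r-th monomer with a given property across hexes then oligs
  enum Prop { P_T, P_X };
  auto apply_monomer = [&](Prop p, long r, bool &was_hex_cs_change) {
    was_hex_cs_change = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<Unit> &v = (pass == 0) ? hexes : oligs;
      for (size_t uidx = 0; uidx < v.size(); ++uidx) {
        Unit &u = v[uidx];
        for (int i = 0; i < u.size; ++i) {
          bool match = (p == P_T) ? (u.st[i] == 0)
                                  : (u.st[i] == 1 || (exchange_n && u.st[i] == 2));
          if (!match) continue;
          if (r-- > 0) continue;
          int d0 = dof(u);
          if (p == P_T) { // hydrolysis T -> D
            u.st[i] = 1;
            nT--;
            nX++;
          } else { // exchange
            if (u.st[i] == 1) { /* leaving D */ }
            bool to_T = (w_atp >= 1.0 || unif_rand() < w_atp);
            int olds = u.st[i];
            u.st[i] = to_T ? 0 : 2;
            nX--;
            if (to_T) nT++;
            else if (exchange_n) nX++;
            (void)olds;
          }
          if (pass == 0) {
            int d1 = dof(u);
            if (d0 < 2 && d1 >= 2) nCS++;
            if (d0 >= 2 && d1 < 2) nCS--;
          }
          return;
        }
      }
    }
  };

  while (rec < n_rec) {
    double aH = kh * nT;
    double aX = ke * nX;
    double aD = kdcs * nCS;
    double aA = krcs * ((double)scnt[1] * scnt[5] + (double)scnt[2] * scnt[4] +
                        (double)scnt[3] * (scnt[3] - 1) / 2.0);
    double atot = aH + aX + aD + aA;
    if (atot <= 0) { t = t_end; }
    else t += R::exp_rand() / atot;
    while (rec < n_rec && t >= t_grid[rec] - 1e-12) record(rec++);
    if (rec >= n_rec) break;
    if (atot <= 0) break;

    double u = unif_rand() * atot;
    bool dummy;
    if (u < aH) {
      apply_monomer(P_T, (long)(unif_rand() * nT), dummy);
    } else if (u < aH + aX) {
      apply_monomer(P_X, (long)(unif_rand() * nX), dummy);
    } else if (u < aH + aX + aD) {
      // dissociation of a CS hexamer into two arcs
      long r = (long)(unif_rand() * nCS);
      size_t hi = 0;
      for (; hi < hexes.size(); ++hi)
        if (dof(hexes[hi]) >= 2 && r-- == 0) break;
      Unit hx = hexes[hi];
      hexes[hi] = hexes.back();
      hexes.pop_back();
      nCS--;
      int a = 0, b = 0;
      if (cut_rule == 1) {
        int loose[6], nl = 0;
        for (int i = 0; i < 6; ++i)
          if (hx.st[i] == 1) loose[nl++] = i;
        int i1 = ipick(nl), i2 = ipick(nl - 1);
        if (i2 >= i1) i2++;
        a = loose[i1] < loose[i2] ? loose[i1] : loose[i2];
        b = loose[i1] < loose[i2] ? loose[i2] : loose[i1];
      } else {
        a = ipick(6);
        b = ipick(5);
        if (b >= a) b++;
        if (a > b) std::swap(a, b);
      }
      // arcs: positions a+1..b and b+1..a (mod 6)
      Unit o1, o2;
      o1.size = b - a;
      for (int i = 0; i < o1.size; ++i) {
        int p = (a + 1 + i) % 6;
        o1.st[i] = hx.st[p];
        o1.tg[i] = hx.tg[p];
      }
      o2.size = 6 - o1.size;
      for (int i = 0; i < o2.size; ++i) {
        int p = (b + 1 + i) % 6;
        o2.st[i] = hx.st[p];
        o2.tg[i] = hx.tg[p];
      }
      oligs.push_back(o1);
      oligs.push_back(o2);
      scnt[o1.size]++;
      scnt[o2.size]++;
    } else {
      // association of a complementary oligomer pair
      double w15 = (double)scnt[1] * scnt[5];
      double w24 = (double)scnt[2] * scnt[4];
      double v = unif_rand() * (w15 + w24 + (double)scnt[3] * (scnt[3] - 1) / 2.0);
      int s1, s2;
      if (v < w15) { s1 = 1; s2 = 5; }
      else if (v < w15 + w24) { s1 = 2; s2 = 4; }
      else { s1 = 3; s2 = 3; }
      long r1 = (long)(unif_rand() * scnt[s1]);
      long r2 = (long)(unif_rand() * (s1 == s2 ? scnt[s2] - 1 : scnt[s2]));
      size_t i1 = SIZE_MAX, i2 = SIZE_MAX;
      long c = 0;
      for (size_t o = 0; o < oligs.size() && i1 == SIZE_MAX; ++o)
        if (oligs[o].size == s1 && c++ == r1) i1 = o;
      c = 0;
      for (size_t o = 0; o < oligs.size() && i2 == SIZE_MAX; ++o) {
        if (oligs[o].size != s2 || o == i1) continue;
        if (c++ == r2) i2 = o;
      }
      if (i1 == SIZE_MAX || i2 == SIZE_MAX) continue; // should not happen
      Unit nu;
      nu.size = 6;
      const Unit &A = oligs[i1], &B = oligs[i2];
      for (int i = 0; i < A.size; ++i) { nu.st[i] = A.st[i]; nu.tg[i] = A.tg[i]; }
      for (int i = 0; i < B.size; ++i) {
        nu.st[A.size + i] = B.st[i];
        nu.tg[A.size + i] = B.tg[i];
      }
      scnt[s1]--;
      scnt[s2]--;
      size_t hi2 = std::max(i1, i2), lo = std::min(i1, i2);
      oligs[hi2] = oligs.back();
      oligs.pop_back();
      oligs[lo] = oligs.back();
      oligs.pop_back();
      hexes.push_back(nu);
      if (dof(nu) >= 2) nCS++;
    }
    if (++n_events % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["pk_counts"] = pk, _["d_hist"] = dh,
                      _["nuc_totals"] = nuc_tot, _["n_hexamers"] = n_hex_rec,
                      _["free_subunits"] = free_sub, _["olig_sizes"] = olig_sizes,
                      _["tag_totals"] = tag_tot, _["n_events"] = (double)n_events);
}
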