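// Metropolis Monte Carlo engine for two apposing membranes on a periodic
// square lattice: a continuous separation field l_i per apposing patch pair,
// single-occupancy protein placements on each membrane, and three move types
// (separation shift, single-protein hop, apposing-pair hop).
//
// All energies are dimensionless in units of kBT. Time is measured in MC
// steps t0; one step = nx*ny separation attempts, N protein attempts and M
// pair attempts, where N is the total protein number and M the number of
// apposing cognate pairs frozen at the start of the pair substep.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// xoshiro256++ PRNG (deterministic across platforms, unlike std:: engines)

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in [0, n), n small
  int below(int n) {
    return (int)((unsigned __int128)next() * (uint64_t)n >> 64);
  }
};

// ---------------------------------------------------------------------------

// species codes: membrane 1: 0 empty, 1 TCR, 2 LFA-1
//                membrane 2: 0 empty, 1 self-pMHC, 2 foreign-pMHC, 3 ICAM-1
// complex kinds: 0 TCR/self-pMHC, 1 TCR/foreign-pMHC, 2 LFA-1/ICAM-1
static const int SP_TCR = 1, SP_LFA = 2;
static const int SP_SMHC = 1, SP_FMHC = 2, SP_ICAM = 3;

static inline int kind_of(int s1, int s2) {
  if (s1 == SP_TCR) {
    if (s2 == SP_SMHC) return 0;
    if (s2 == SP_FMHC) return 1;
  } else if (s1 == SP_LFA && s2 == SP_ICAM) {
    return 2;
  }
  return -1;
}

struct Outcome {
  int type;          // 1 separation, 2 protein, 3 pair
  int pos, tgt;      // linear patch indices (-1 if n/a)
  double dE;
  double dl;         // separation proposal only
  bool accepted, excluded;
  int reason;        // 0 metropolis path, 1 target occupied, 2 floor, 3 no-op
  int mover_mem, mover_sp;
  int formed, broken; // complex kinds, -1 none
};

struct Engine {
  int nx, ny, n;
  // parameters
  double coef;             // kappa / (2 a^2)
  double a;                // patch size, nm
  double rest[3], hw[3];   // binding window centre/half-width per kind, nm
  double U[3];             // binding energies, kBT
  double sep_hw;           // separation move half-width, nm
  double contact_thr;      // close-contact threshold, nm
  double win_lo, win_hi;   // TCR/pMHC window, for patch counting

  std::vector<double> l;
  std::vector<int> occ1, occ2;
  std::vector<int> nb;               // 4 neighbours per site
  std::vector<int> pkind;            // apposing cognate pair kind or -1
  std::vector<int> pairs, pair_idx;  // pair position list + backmap
  std::vector<int> bond_kind;        // -1 or kind
  std::vector<double> bond_start;
  long long nbond[3];

  std::vector<int> prot_mem, prot_pos; // one entry per protein
  std::vector<int> slot1, slot2;       // site -> protein index or -1

  double step;
  Xoshiro rng;

  double attempts[3], accepts[3], excluded_count;
  double bind_count[3], unbind_count[3];

  std::vector<double> rec_bind, rec_unbind;
  std::vector<int> rec_kind;

  Outcome out;

  // -- setup ----------------------------------------------------------------

  void build_neighbors() {
    nb.assign(4 * n, 0);
    for (int c = 0; c < ny; ++c) {
      for (int r = 0; r < nx; ++r) {
        int pos = r + c * nx;
        int rm = (r == 0) ? nx - 1 : r - 1;
        int rp = (r == nx - 1) ? 0 : r + 1;
        int cm = (c == 0) ? ny - 1 : c - 1;
        int cp = (c == ny - 1) ? 0 : c + 1;
        nb[4 * pos + 0] = rm + c * nx;
        nb[4 * pos + 1] = rp + c * nx;
        nb[4 * pos + 2] = r + cm * nx;
        nb[4 * pos + 3] = r + cp * nx;
      }
    }
  }

  bool inwin(double x, int k) const {
    return x >= rest[k] - hw[k] && x <= rest[k] + hw[k];
  }

  double lap(int pos) const {
    const int* b = &nb[4 * pos];
    return l[b[0]] + l[b[1]] + l[b[2]] + l[b[3]] - 4.0 * l[pos];
  }

  void add_pair(int pos, int k) {
    pkind[pos] = k;
    pair_idx[pos] = (int)pairs.size();
    pairs.push_back(pos);
  }

  void remove_pair(int pos) {
    int idx = pair_idx[pos];
    int last = pairs.back();
    pairs[idx] = last;
    pair_idx[last] = idx;
    pairs.pop_back();
    pair_idx[pos] = -1;
    pkind[pos] = -1;
  }

  // refresh the apposing-pair bookkeeping at a site after occupancy changed
  void refresh_pair(int pos) {
    int k = kind_of(occ1[pos], occ2[pos]);
    if (k == pkind[pos]) return;
    if (pkind[pos] >= 0) remove_pair(pos);
    if (k >= 0) add_pair(pos, k);
  }

  void do_bind(int pos, int k) {
    bond_kind[pos] = k;
    bond_start[pos] = step;
    ++nbond[k];
    bind_count[k] += 1.0;
  }

  void do_unbind(int pos) {
    int k = bond_kind[pos];
    rec_bind.push_back(bond_start[pos]);
    rec_unbind.push_back(step);
    rec_kind.push_back(k);
    bond_kind[pos] = -1;
    --nbond[k];
    unbind_count[k] += 1.0;
  }

  // -- energies -------------------------------------------------------------

  // bending-energy change for shifting l[pos] by d; exact also on
  // degenerate lattices where wrapped neighbours repeat
  double delta_bend(int pos, double d) {
    if (nx >= 3 && ny >= 3) {
      // nondegenerate: the centre Laplacian changes by -4d, each of the
      // four distinct neighbours' by +d, giving a closed form
      const int* b = &nb[4 * pos];
      double lap0 = lap(pos);
      double S = lap(b[0]) + lap(b[1]) + lap(b[2]) + lap(b[3]);
      return coef * (2.0 * d * (S - 4.0 * lap0) + 20.0 * d * d);
    }
    int aff[5];
    int na = 0;
    aff[na++] = pos;
    for (int k = 0; k < 4; ++k) {
      int s = nb[4 * pos + k];
      bool seen = false;
      for (int j = 0; j < na; ++j)
        if (aff[j] == s) { seen = true; break; }
      if (!seen) aff[na++] = s;
    }
    double dE = 0.0;
    for (int j = 0; j < na; ++j) {
      int s = aff[j];
      double lb = lap(s);
      int cnt = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[4 * s + k] == pos) ++cnt;
      double dlap = d * cnt - (s == pos ? 4.0 * d : 0.0);
      double la = lb + dlap;
      dE += la * la - lb * lb;
    }
    return coef * dE;
  }

  double bending_energy() const {
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = lap(i);
      e += x * x;
    }
    return coef * e;
  }

  double binding_energy() const {
    return -(U[0] * nbond[0] + U[1] * nbond[1] + U[2] * nbond[2]);
  }

  bool metropolis(double dE) {
    if (dE <= 0.0) return true;
    return rng.unif() < std::exp(-dE);
  }

  // -- moves ----------------------------------------------------------------

  void reset_out(int type) {
    out.type = type;
    out.pos = out.tgt = -1;
    out.dE = 0.0;
    out.dl = 0.0;
    out.accepted = out.excluded = false;
    out.reason = 0;
    out.mover_mem = 0;
    out.mover_sp = 0;
    out.formed = out.broken = -1;
  }

  void attempt_separation() {
    reset_out(1);
    attempts[0] += 1.0;
    int pos = rng.below(n);
    double d = (rng.unif() * 2.0 - 1.0) * sep_hw;
    out.pos = pos;
    out.dl = d;
    double newl = l[pos] + d;
    if (newl < 0.0) { out.reason = 2; return; } // hard impenetrability
    double dE = delta_bend(pos, d);
    int k = pkind[pos];
    int formed = -1, broken = -1;
    if (k >= 0) {
      bool b0 = inwin(l[pos], k), b1 = inwin(newl, k);
      if (b0 && !b1) { dE += U[k]; broken = k; }
      else if (!b0 && b1) { dE -= U[k]; formed = k; }
    }
    out.dE = dE;
    if (!metropolis(dE)) return;
    l[pos] = newl;
    out.accepted = true;
    accepts[0] += 1.0;
    if (broken >= 0) { do_unbind(pos); out.broken = broken; }
    if (formed >= 0) { do_bind(pos, formed); out.formed = formed; }
  }

  void attempt_protein() {
    reset_out(2);
    attempts[1] += 1.0;
    int N = (int)prot_mem.size();
    if (N == 0) { out.reason = 3; return; }
    int p = rng.below(N);
    int mem = prot_mem[p];
    int pos = prot_pos[p];
    int dir = rng.below(4);
    int tgt = nb[4 * pos + dir];
    out.pos = pos;
    out.tgt = tgt;
    out.mover_mem = mem;
    std::vector<int>& occA = (mem == 1) ? occ1 : occ2;
    std::vector<int>& slotA = (mem == 1) ? slot1 : slot2;
    const std::vector<int>& occB = (mem == 1) ? occ2 : occ1;
    int sp = occA[pos];
    out.mover_sp = sp;
    if (occA[tgt] != 0) { out.reason = 1; return; }
    bool bound_before = bond_kind[pos] >= 0;
    int k2 = (mem == 1) ? kind_of(sp, occB[tgt]) : kind_of(occB[tgt], sp);
    bool would_form = (k2 >= 0) && inwin(l[tgt], k2);
    if (bound_before && would_form) {
      // a bound protein may not hop directly into a new complex
      out.excluded = true;
      excluded_count += 1.0;
      return;
    }
    double dE = 0.0;
    if (bound_before) dE += U[bond_kind[pos]];
    if (would_form) dE -= U[k2];
    out.dE = dE;
    if (!metropolis(dE)) return;
    if (bound_before) { out.broken = bond_kind[pos]; do_unbind(pos); }
    occA[pos] = 0;
    occA[tgt] = sp;
    slotA[tgt] = p;
    slotA[pos] = -1;
    prot_pos[p] = tgt;
    refresh_pair(pos);
    refresh_pair(tgt);
    if (would_form) { do_bind(tgt, k2); out.formed = k2; }
    out.accepted = true;
    accepts[1] += 1.0;
  }

  void attempt_pair() {
    reset_out(3);
    attempts[2] += 1.0;
    if (pairs.empty()) { out.reason = 3; return; }
    int pos = pairs[rng.below((int)pairs.size())];
    int k = pkind[pos];
    int dir = rng.below(4);
    int tgt = nb[4 * pos + dir];
    out.pos = pos;
    out.tgt = tgt;
    if (occ1[tgt] != 0 || occ2[tgt] != 0) { out.reason = 1; return; }
    bool b0 = bond_kind[pos] >= 0;
    bool b1 = inwin(l[tgt], k);
    double dE = (b0 ? U[k] : 0.0) - (b1 ? U[k] : 0.0);
    out.dE = dE;
    if (!metropolis(dE)) return;
    int p1 = slot1[pos], p2 = slot2[pos];
    occ1[tgt] = occ1[pos];
    occ2[tgt] = occ2[pos];
    occ1[pos] = occ2[pos] = 0;
    slot1[tgt] = p1;
    slot2[tgt] = p2;
    slot1[pos] = slot2[pos] = -1;
    prot_pos[p1] = tgt;
    prot_pos[p2] = tgt;
    if (b0 && b1) {
      // bound complex diffuses: bond identity (and dwell clock) carries over
      bond_kind[tgt] = k;
      bond_start[tgt] = bond_start[pos];
      bond_kind[pos] = -1;
    } else if (b0) {
      do_unbind(pos);
      out.broken = k;
    }
    refresh_pair(pos);
    refresh_pair(tgt);
    if (!b0 && b1) {
      do_bind(tgt, k);
      out.formed = k;
    }
    out.accepted = true;
    accepts[2] += 1.0;
  }

  void mc_step() {
    for (int t = 0; t < n; ++t) attempt_separation();
    int N = (int)prot_mem.size();
    for (int t = 0; t < N; ++t) attempt_protein();
    int M0 = (int)pairs.size(); // frozen at substep start
    for (int t = 0; t < M0; ++t) attempt_pair();
    step += 1.0;
  }

  // -- observables ----------------------------------------------------------

  void sample_row(double* row) const {
    int ncontact = 0, nwindow = 0;
    double minl = l[0];
    for (int i = 0; i < n; ++i) {
      double x = l[i];
      if (x < contact_thr) ++ncontact;
      if (x >= win_lo && x <= win_hi) ++nwindow;
      if (x < minl) minl = x;
    }
    row[0] = step;
    row[1] = (double)nbond[0];
    row[2] = (double)nbond[1];
    row[3] = (double)nbond[2];
    row[4] = (double)ncontact;
    row[5] = (double)nwindow;
    row[6] = minl;
    row[7] = bending_energy();
    row[8] = binding_energy();
  }
};

// ---------------------------------------------------------------------------
// R interface

static Engine* get(SEXP xp) {
  XPtr<Engine> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP sim_create(NumericMatrix l, IntegerMatrix occ1, IntegerMatrix occ2,
                List par, double seed, double step0) {
  XPtr<Engine> xp(new Engine(), true);
  Engine* e = xp.get();
  e->nx = l.nrow();
  e->ny = l.ncol();
  e->n = e->nx * e->ny;
  if (occ1.nrow() != e->nx || occ1.ncol() != e->ny ||
      occ2.nrow() != e->nx || occ2.ncol() != e->ny)
    stop("occupancy matrices must match the separation field dimensions");

  double a = as<double>(par["patch_size"]);
  double kappa = as<double>(par["kappa"]);
  e->a = a;
  e->coef = kappa / (2.0 * a * a);
  e->rest[0] = e->rest[1] = as<double>(par["tcr_rest"]);
  e->hw[0] = e->hw[1] = as<double>(par["tcr_halfwidth"]);
  e->rest[2] = as<double>(par["lfa_rest"]);
  e->hw[2] = as<double>(par["lfa_halfwidth"]);
  e->U[0] = as<double>(par["u_self"]);
  e->U[1] = as<double>(par["u_foreign"]);
  e->U[2] = as<double>(par["u_li"]);
  e->sep_hw = as<double>(par["sep_halfwidth"]);
  e->contact_thr = as<double>(par["contact_threshold"]);
  e->win_lo = e->rest[0] - e->hw[0];
  e->win_hi = e->rest[0] + e->hw[0];

  e->l.assign(l.begin(), l.end());
  e->occ1.assign(occ1.begin(), occ1.end());
  e->occ2.assign(occ2.begin(), occ2.end());
  for (int i = 0; i < e->n; ++i)
    if (e->l[i] < 0.0) stop("separation field must be non-negative");

  e->build_neighbors();
  e->pkind.assign(e->n, -1);
  e->pair_idx.assign(e->n, -1);
  e->bond_kind.assign(e->n, -1);
  e->bond_start.assign(e->n, 0.0);
  e->slot1.assign(e->n, -1);
  e->slot2.assign(e->n, -1);
  e->nbond[0] = e->nbond[1] = e->nbond[2] = 0;
  e->step = step0;
  e->rng.seed((uint64_t)seed);
  for (int k = 0; k < 3; ++k) {
    e->attempts[k] = e->accepts[k] = 0.0;
    e->bind_count[k] = e->unbind_count[k] = 0.0;
  }
  e->excluded_count = 0.0;

  // protein lists in deterministic scan order (membrane 1 first)
  for (int i = 0; i < e->n; ++i) {
    if (e->occ1[i] != 0) {
      e->slot1[i] = (int)e->prot_mem.size();
      e->prot_mem.push_back(1);
      e->prot_pos.push_back(i);
    }
  }
  for (int i = 0; i < e->n; ++i) {
    if (e->occ2[i] != 0) {
      e->slot2[i] = (int)e->prot_mem.size();
      e->prot_mem.push_back(2);
      e->prot_pos.push_back(i);
    }
  }
  // apposing pairs and initial bonds derived from the configuration
  for (int i = 0; i < e->n; ++i) {
    int k = kind_of(e->occ1[i], e->occ2[i]);
    if (k >= 0) {
      e->add_pair(i, k);
      if (e->inwin(e->l[i], k)) {
        e->bond_kind[i] = k;
        e->bond_start[i] = step0;
        ++e->nbond[k];
      }
    }
  }
  return xp;
}

// [[Rcpp::export]]
NumericMatrix sim_run(SEXP xp, double n_steps, double sample_every) {
  Engine* e = get(xp);
  long long ns = (long long)n_steps;
  long long se = (long long)sample_every;
  std::vector<double> rows;
  for (long long t = 0; t < ns; ++t) {
    e->mc_step();
    if (se > 0 && ((long long)e->step) % se == 0) {
      double row[9];
      e->sample_row(row);
      rows.insert(rows.end(), row, row + 9);
    }
    if (t % 16384 == 0) Rcpp::checkUserInterrupt();
  }
  int nr = (int)(rows.size() / 9);
  NumericMatrix m(nr, 9);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 9; ++j) m(i, j) = rows[(size_t)i * 9 + j];
  return m;
}

// [[Rcpp::export]]
double sim_run_until_unbind(SEXP xp, double max_steps, double target_events) {
  Engine* e = get(xp);
  double base = e->unbind_count[0] + e->unbind_count[1];
  long long ms = (long long)max_steps;
  long long t = 0;
  for (; t < ms; ++t) {
    e->mc_step();
    if (e->unbind_count[0] + e->unbind_count[1] - base >= target_events) {
      ++t;
      break;
    }
    if (t % 16384 == 0) Rcpp::checkUserInterrupt();
  }
  return (double)t;
}

// [[Rcpp::export]]
List sim_attempt(SEXP xp, int type) {
  Engine* e = get(xp);
  if (type == 1) e->attempt_separation();
  else if (type == 2) e->attempt_protein();
  else if (type == 3) e->attempt_pair();
  else stop("move type must be 1, 2 or 3");
  const Outcome& o = e->out;
  int nx = e->nx;
  auto rc = [nx](int pos) {
    if (pos < 0) return IntegerVector::create(NA_INTEGER, NA_INTEGER);
    return IntegerVector::create(pos % nx + 1, pos / nx + 1);
  };
  return List::create(
      _["type"] = o.type, _["pos"] = rc(o.pos), _["target"] = rc(o.tgt),
      _["dE"] = o.dE, _["dl"] = o.dl, _["accepted"] = o.accepted,
      _["excluded"] = o.excluded, _["reason"] = o.reason,
      _["mover_membrane"] = o.mover_mem, _["mover_species"] = o.mover_sp,
      _["formed"] = o.formed, _["broken"] = o.broken);
}

// [[Rcpp::export]]
void sim_step(SEXP xp, double n_steps) {
  Engine* e = get(xp);
  long long ns = (long long)n_steps;
  for (long long t = 0; t < ns; ++t) e->mc_step();
}

// [[Rcpp::export]]
List sim_state(SEXP xp) {
  Engine* e = get(xp);
  NumericMatrix l(e->nx, e->ny);
  IntegerMatrix o1(e->nx, e->ny), o2(e->nx, e->ny);
  std::copy(e->l.begin(), e->l.end(), l.begin());
  std::copy(e->occ1.begin(), e->occ1.end(), o1.begin());
  std::copy(e->occ2.begin(), e->occ2.end(), o2.begin());
  return List::create(_["l"] = l, _["occ1"] = o1, _["occ2"] = o2,
                      _["step"] = e->step);
}

// [[Rcpp::export]]
List sim_counters(SEXP xp) {
  Engine* e = get(xp);
  return List::create(
      _["attempts"] = NumericVector::create(e->attempts[0], e->attempts[1],
                                            e->attempts[2]),
      _["accepts"] = NumericVector::create(e->accepts[0], e->accepts[1],
                                           e->accepts[2]),
      _["excluded"] = e->excluded_count,
      _["bind_events"] = NumericVector::create(e->bind_count[0],
                                               e->bind_count[1],
                                               e->bind_count[2]),
      _["unbind_events"] = NumericVector::create(e->unbind_count[0],
                                                 e->unbind_count[1],
                                                 e->unbind_count[2]),
      _["n_pairs"] = (int)e->pairs.size(),
      _["n_proteins"] = (int)e->prot_mem.size(),
      _["step"] = e->step);
}

// [[Rcpp::export]]
IntegerVector sim_bond_counts(SEXP xp) {
  Engine* e = get(xp);
  return IntegerVector::create((int)e->nbond[0], (int)e->nbond[1],
                               (int)e->nbond[2]);
}

// [[Rcpp::export]]
IntegerMatrix sim_bond_map(SEXP xp) {
  Engine* e = get(xp);
  IntegerMatrix m(e->nx, e->ny);
  std::copy(e->bond_kind.begin(), e->bond_kind.end(), m.begin());
  return m;
}

// [[Rcpp::export]]
List sim_bond_records(SEXP xp) {
  Engine* e = get(xp);
  // completed bonds, then bonds still alive (right-censored, unbind = NA)
  size_t nc = e->rec_bind.size();
  size_t nalive = 0;
  for (int i = 0; i < e->n; ++i)
    if (e->bond_kind[i] >= 0) ++nalive;
  NumericVector bind(nc + nalive), unbind(nc + nalive);
  IntegerVector kind(nc + nalive);
  for (size_t i = 0; i < nc; ++i) {
    bind[i] = e->rec_bind[i];
    unbind[i] = e->rec_unbind[i];
    kind[i] = e->rec_kind[i];
  }
  size_t j = nc;
  for (int i = 0; i < e->n; ++i) {
    if (e->bond_kind[i] >= 0) {
      bind[j] = e->bond_start[i];
      unbind[j] = NA_REAL;
      kind[j] = e->bond_kind[i];
      ++j;
    }
  }
  return List::create(_["bind"] = bind, _["unbind"] = unbind,
                      _["kind"] = kind);
}

// [[Rcpp::export]]
List sim_energy(SEXP xp) {
  Engine* e = get(xp);
  double eb = e->bending_energy(), ei = e->binding_energy();
  return List::create(_["e_bend"] = eb, _["e_bind"] = ei,
                      _["e_total"] = eb + ei);
}
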