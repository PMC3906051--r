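// Compiled core of the cultural-evolution agent-based model.
//
// The world is a bounded W x H grid; each square carries per-type resource
// stocks that are reset to the configured level at the start of every time
// step (resources are a renewable per-step flow).  At most one group occupies
// a square.  Individuals belong to exactly one group, hold an ordered prefix
// of subsistence traits (trait i enables extraction of resource i) with
// integer skill values, and carry an energy store bounded by the cap.
//
// Per-step schedule (see sim_step() on the R side for the contract):
//   1. replenish resource stocks
//   2. shuffle individual processing order
//   3. per individual: metabolize, forage, death check
//   4. per survivor, same order: learning / invention if under pressure,
//      then partner search / reproduction if eligible
//   5. per group: fission or migration under pressure
//   6. record observables
//
// All randomness is drawn from R's RNG stream so a run is fully determined
// by (config, seed) set on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const int MAXT = 16; // hard bound on n_resource_types (default 10)

struct Cfg {
  int W, H, NT;
  double level, seldiff, basic;
  int max_skill;
  double copy_err;
  double inv_cost, learn_cost;
  int radius; // 1 = within group, 2 = Moore neighbourhood
  double cap, req;
  int min_repro_age;
  double erep, transfer;
  int max_age;
  int fiss_min;
  double fiss_frac;
  bool forage_to_req; // false = fill storage to the cap
};

struct Ind {
  double id;
  int sex;   // 0 = female, 1 = male
  int age;
  int grp;   // index into World::grps
  int pos;   // position within the group's member list
  int k;     // number of traits held (prefix 1..k)
  int16_t sk[MAXT];
  double energy, intake;
  bool pressure, alive, paired;
};

struct Grp {
  int id, sq;
  bool alive;
  std::vector<int> members;      // indices into World::inds
  int cnt[MAXT + 1];             // cnt[j] = members holding at least j traits
  int16_t maxv[MAXT];            // per-trait max skill among members (0 = none)
  std::vector<int> elig[2];      // reproduction candidates by sex (lazy)
};

static inline int runif_int(int n) {
  int j = (int)(unif_rand() * n);
  if (j >= n) j = n - 1;
  if (j < 0) j = 0;
  return j;
}

// 5% copy error: with prob p the copied value shifts one unit up or down
// (equal odds), clamped to [1, max_skill].
static inline int copy_err_val(int v, double p, int maxs) {
  if (p > 0.0 && unif_rand() < p) {
    v += (unif_rand() < 0.5) ? -1 : 1;
    if (v < 1) v = 1;
    if (v > maxs) v = maxs;
  }
  return v;
}

// Greedy foraging: traits in descending order of extraction rate (ties by
// trait index), each contributing min(rate, stock, storage headroom).
static double forage_core(int k, const int16_t* sk, double& energy, double* st,
                          const Cfg& c) {
  int ord[MAXT];
  for (int i = 0; i < k; ++i) ord[i] = i;
  for (int i = 1; i < k; ++i) { // stable insertion sort, higher skill first
    int o = ord[i], j = i - 1;
    while (j >= 0 && sk[ord[j]] < sk[o]) { ord[j + 1] = ord[j]; --j; }
    ord[j + 1] = o;
  }
  double intake = 0.0;
  for (int i = 0; i < k; ++i) {
    double head = c.cap - energy;
    if (head <= 1e-12) break;
    if (c.forage_to_req && intake >= c.req - 1e-12) break;
    int t = ord[i];
    double rate = c.basic + c.seldiff * (sk[t] - 1);
    double take = std::min(rate, st[t]);
    if (take > head) take = head;
    if (take <= 0) continue;
    st[t] -= take;
    energy += take;
    intake += take;
  }
  return intake;
}

struct World {
  Cfg c;
  int nsq;
  std::vector<double> stocks; // nsq * NT, square-major
  std::vector<int> occ;       // group index occupying square, -1 if empty
  std::vector<Grp> grps;
  std::vector<Ind> inds;
  std::vector<int> freeslots;
  double next_id;
  int next_gid;
  int stepno;
  std::vector<double> ev_step, ev_gid, ev_trait, ev_ind;

  std::vector<int> nbrs(int sq) const {
    std::vector<int> out;
    int col = sq % c.W, row = sq / c.W;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int rr = row + dr, cc = col + dc;
        if (rr < 0 || rr >= c.H || cc < 0 || cc >= c.W) continue;
        out.push_back(rr * c.W + cc);
      }
    return out;
  }

  double sq_total(int sq) const {
    double s = 0;
    for (int t = 0; t < c.NT; ++t) s += stocks[(size_t)sq * c.NT + t];
    return s;
  }

  // Candidate groups for learning and partner search: own group, plus
  // occupied Moore-neighbour squares when interaction radius is 2.
  int cand_groups(int gi, int* out) const {
    int n = 0;
    out[n++] = gi;
    if (c.radius == 2) {
      for (int s : nbrs(grps[gi].sq)) {
        int o = occ[s];
        if (o >= 0) out[n++] = o;
      }
    }
    return n;
  }

  void add_member(int gi, int ii) {
    Grp& G = grps[gi];
    Ind& a = inds[ii];
    a.grp = gi;
    a.pos = (int)G.members.size();
    G.members.push_back(ii);
    for (int j = 1; j <= a.k; ++j) G.cnt[j] += 1;
    for (int t = 0; t < a.k; ++t)
      if (a.sk[t] > G.maxv[t]) G.maxv[t] = a.sk[t];
  }

  void remove_member(int ii) { // O(1) swap-remove; aggregates left stale
    Ind& a = inds[ii];
    Grp& G = grps[a.grp];
    int last = G.members.back();
    G.members[a.pos] = last;
    inds[last].pos = a.pos;
    G.members.pop_back();
  }

  void rebuild_groups() {
    for (auto& G : grps) {
      if (!G.alive) continue;
      if (G.members.empty()) {
        G.alive = false;
        occ[G.sq] = -1;
        continue;
      }
      std::fill(G.cnt, G.cnt + MAXT + 1, 0);
      std::fill(G.maxv, G.maxv + MAXT, (int16_t)0);
      G.elig[0].clear();
      G.elig[1].clear();
      for (int m : G.members) {
        Ind& a = inds[m];
        for (int j = 1; j <= a.k; ++j) G.cnt[j] += 1;
        for (int t = 0; t < a.k; ++t)
          if (a.sk[t] > G.maxv[t]) G.maxv[t] = a.sk[t];
        if (a.age >= c.min_repro_age && a.energy >= c.erep)
          G.elig[a.sex].push_back(m);
      }
    }
  }

  // One social-learning attempt over the candidate pool (own group, plus
  // Moore-neighbour groups at radius 2).  Preference order: (a) acquire trait
  // k+1, copying a uniformly chosen model that holds it; else (b) improve a
  // uniformly chosen owned trait for which some model is strictly better,
  // copying the value of a uniformly chosen model holding that trait.  Both
  // routes pass through the copy error.  Value transmission in (b) is
  // frequency-proportional: a skill variant spreads only as often as its
  // carriers are sampled, so skill escalation is driven by selection on
  // carriers rather than by the learning rule itself.
  bool try_learn(int ii) {
    Ind& a = inds[ii];
    if (a.energy <= c.learn_cost) return false;
    int cg[9];
    int ng = cand_groups(a.grp, cg);
    int kk = a.k;
    if (kk < c.NT) { // (a) acquire the next trait from any holder
      int total = 0;
      for (int g = 0; g < ng; ++g) total += grps[cg[g]].cnt[kk + 1];
      if (total > 0) {
        int r = runif_int(total), gi = -1;
        for (int g = 0; g < ng; ++g) {
          int cc = grps[cg[g]].cnt[kk + 1];
          if (r < cc) { gi = cg[g]; break; }
          r -= cc;
        }
        Grp& G = grps[gi];
        int m;
        do {
          m = G.members[runif_int((int)G.members.size())];
        } while (inds[m].k < kk + 1);
        int v = copy_err_val(inds[m].sk[kk], c.copy_err, c.max_skill);
        a.sk[kk] = (int16_t)v;
        a.k = kk + 1;
        Grp& own = grps[a.grp];
        own.cnt[a.k] += 1;
        if (v > own.maxv[kk]) own.maxv[kk] = (int16_t)v;
        a.energy = std::max(0.0, a.energy - c.learn_cost);
        return true;
      }
    }
    int elig_t[MAXT], nelig = 0; // (b) traits with a strictly better model
    for (int t = 0; t < kk; ++t) {
      int best = 0;
      for (int g = 0; g < ng; ++g)
        best = std::max(best, (int)grps[cg[g]].maxv[t]);
      if (best > a.sk[t]) elig_t[nelig++] = t;
    }
    if (!nelig) return false;
    int t = elig_t[runif_int(nelig)];
    int total = -1; // holders of trait t other than the learner itself
    for (int g = 0; g < ng; ++g) total += grps[cg[g]].cnt[t + 1];
    if (total <= 0) return false; // unreachable: a strictly better model exists
    int r = runif_int(total), gi = -1;
    for (int g = 0; g < ng; ++g) {
      int cc = grps[cg[g]].cnt[t + 1] - (cg[g] == a.grp ? 1 : 0);
      if (r < cc) { gi = cg[g]; break; }
      r -= cc;
    }
    Grp& G = grps[gi];
    int m;
    do {
      m = G.members[runif_int((int)G.members.size())];
    } while (inds[m].k < t + 1 || m == ii);
    int v = copy_err_val(inds[m].sk[t], c.copy_err, c.max_skill);
    a.sk[t] = (int16_t)v;
    Grp& own = grps[a.grp];
    if (v > own.maxv[t]) own.maxv[t] = (int16_t)v;
    a.energy = std::max(0.0, a.energy - c.learn_cost);
    return true;
  }

  // Invention gate: mastery (max skill) of the last owned trait, a free slot
  // in the trait list, and energy strictly above the innovation cost.
  void try_invent(int ii) {
    Ind& a = inds[ii];
    if (a.k < 1 || a.k >= c.NT) return;
    if (a.sk[a.k - 1] != c.max_skill) return;
    if (!(a.energy > c.inv_cost)) return;
    a.sk[a.k] = 1;
    a.k += 1;
    a.energy -= c.inv_cost;
    Grp& own = grps[a.grp];
    own.cnt[a.k] += 1;
    if (own.maxv[a.k - 1] < 1) own.maxv[a.k - 1] = 1;
    ev_step.push_back(stepno);
    ev_gid.push_back(own.id);
    ev_trait.push_back(a.k);
    ev_ind.push_back(a.id);
  }

  // Uniform draw among currently eligible opposite-sex candidates, with lazy
  // removal of entries invalidated since the lists were built (energy can
  // only fall, and pairing is permanent, within the phase).
  int find_partner(int ii) {
    Ind& a = inds[ii];
    int cg[9];
    int ng = cand_groups(a.grp, cg);
    int os = 1 - a.sex;
    while (true) {
      int total = 0;
      for (int g = 0; g < ng; ++g) total += (int)grps[cg[g]].elig[os].size();
      if (total == 0) return -1;
      int r = runif_int(total);
      for (int g = 0; g < ng; ++g) {
        std::vector<int>& L = grps[cg[g]].elig[os];
        if (r < (int)L.size()) {
          int m = L[r];
          if (!inds[m].paired && inds[m].energy >= c.erep) return m;
          L[r] = L.back();
          L.pop_back();
          break;
        }
        r -= (int)L.size();
      }
    }
  }

  int new_slot() {
    if (!freeslots.empty()) {
      int s = freeslots.back();
      freeslots.pop_back();
      return s;
    }
    inds.push_back(Ind());
    return (int)inds.size() - 1;
  }

  void reproduce(int ai, int bi) {
    int mo = (inds[ai].sex == 0) ? ai : bi;
    int fa = (inds[ai].sex == 0) ? bi : ai;
    int kc = std::min(inds[mo].k, inds[fa].k);
    int16_t cs[MAXT];
    for (int t = 0; t < kc; ++t) {
      const Ind& src = (unif_rand() < 0.5) ? inds[mo] : inds[fa];
      cs[t] = (int16_t)copy_err_val(src.sk[t], c.copy_err, c.max_skill);
    }
    int mg = inds[mo].grp;
    inds[ai].energy = std::max(0.0, inds[ai].energy - c.transfer);
    inds[bi].energy = std::max(0.0, inds[bi].energy - c.transfer);
    inds[ai].paired = inds[bi].paired = true;
    int s = new_slot(); // may reallocate inds; parents fully updated above
    Ind& ch = inds[s];
    ch.id = next_id;
    next_id += 1;
    ch.sex = runif_int(2);
    ch.age = 0;
    ch.energy = 2 * c.transfer;
    ch.k = kc;
    for (int t = 0; t < kc; ++t) ch.sk[t] = cs[t];
    ch.intake = 0;
    ch.pressure = false;
    ch.alive = true;
    ch.paired = false;
    add_member(mg, s);
  }

  int pick_best_square(const std::vector<int>& sqs) {
    double best = -1;
    std::vector<int> top;
    for (int s : sqs) {
      double v = sq_total(s);
      if (v > best + 1e-9) {
        best = v;
        top.clear();
        top.push_back(s);
      } else if (v > best - 1e-9) {
        top.push_back(s);
      }
    }
    return top[runif_int((int)top.size())];
  }

  // Group response to pressure: fission to an empty neighbour square if the
  // group is large enough, else migrate wholesale to a richer empty square.
  void fission_or_migrate(int gi) {
    if (!grps[gi].alive) return;
    int size = (int)grps[gi].members.size();
    if (size == 0) return;
    int np = 0;
    for (int m : grps[gi].members)
      if (inds[m].pressure) ++np;
    if ((double)np / size <= c.fiss_frac) return;
    int cursq = grps[gi].sq;
    std::vector<int> unocc;
    for (int s : nbrs(cursq))
      if (occ[s] < 0) unocc.push_back(s);
    if (size >= c.fiss_min && !unocc.empty()) {
      int target = pick_best_square(unocc);
      int nhalf = size / 2;
      std::vector<int> pool = grps[gi].members;
      for (int i = 0; i < nhalf; ++i) { // partial Fisher-Yates
        int j = i + runif_int((int)pool.size() - i);
        std::swap(pool[i], pool[j]);
      }
      Grp NG;
      NG.id = next_gid++;
      NG.sq = target;
      NG.alive = true;
      std::fill(NG.cnt, NG.cnt + MAXT + 1, 0);
      std::fill(NG.maxv, NG.maxv + MAXT, (int16_t)0);
      grps.push_back(NG);
      int newgi = (int)grps.size() - 1;
      occ[target] = newgi;
      for (int i = 0; i < nhalf; ++i) {
        int m = pool[i];
        remove_member(m);
        add_member(newgi, m);
      }
    } else {
      double cur = sq_total(cursq);
      std::vector<int> better;
      for (int s : unocc)
        if (sq_total(s) > cur + 1e-9) better.push_back(s);
      if (better.empty()) return;
      int target = pick_best_square(better);
      occ[cursq] = -1;
      grps[gi].sq = target;
      occ[target] = gi;
    }
  }

  // Executes one step; fills the 6 observables (step, pop, mean group size,
  // mean traits per individual, competition, group count).
  int do_step(double* row) {
    stepno += 1;
    std::fill(stocks.begin(), stocks.end(), c.level);
    std::vector<int> order;
    order.reserve(inds.size());
    for (int i = 0; i < (int)inds.size(); ++i)
      if (inds[i].alive) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int i : order) {
      Ind& a = inds[i];
      a.paired = false;
      a.age += 1;
      a.energy = std::max(0.0, a.energy - c.req);
      double* st = &stocks[(size_t)grps[a.grp].sq * c.NT];
      a.intake = forage_core(a.k, a.sk, a.energy, st, c);
      a.pressure = a.intake < c.req - 1e-9;
      if (a.energy <= 1e-12 || a.age > c.max_age) {
        remove_member(i);
        a.alive = false;
        freeslots.push_back(i);
      }
    }
    std::vector<int> order2;
    order2.reserve(order.size());
    for (int i : order)
      if (inds[i].alive) order2.push_back(i);
    rebuild_groups();
    for (int i : order2) {
      if (inds[i].pressure) {
        bool learned = try_learn(i);
        if (!learned) try_invent(i);
      }
      Ind& a = inds[i];
      if (!a.paired && a.age >= c.min_repro_age && a.energy >= c.erep) {
        int p = find_partner(i);
        if (p >= 0) reproduce(i, p); // may invalidate references into inds
      }
    }
    int ngr = (int)grps.size(); // groups created below are not re-evaluated
    for (int gi = 0; gi < ngr; ++gi) fission_or_migrate(gi);
    int pop = 0, np = 0, ngroups = 0;
    double ksum = 0;
    for (auto& a : inds)
      if (a.alive) {
        ++pop;
        ksum += a.k;
        if (a.pressure) ++np;
      }
    for (auto& G : grps)
      if (G.alive) ++ngroups;
    row[0] = stepno;
    row[1] = pop;
    row[2] = ngroups > 0 ? (double)pop / ngroups : NA_REAL;
    row[3] = pop > 0 ? ksum / pop : NA_REAL;
    row[4] = pop > 0 ? (double)np / pop : NA_REAL;
    row[5] = ngroups;
    return pop;
  }
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.W = as<int>(cfg["grid_width"]);
  c.H = as<int>(cfg["grid_height"]);
  c.NT = as<int>(cfg["n_resource_types"]);
  if (c.NT < 1 || c.NT > MAXT) stop("n_resource_types out of supported range");
  c.level = as<double>(cfg["resource_level"]);
  c.seldiff = as<double>(cfg["selection_differential"]);
  c.basic = as<double>(cfg["basic_rate"]);
  c.max_skill = as<int>(cfg["max_skill"]);
  c.copy_err = as<double>(cfg["copy_error_prob"]);
  c.inv_cost = as<double>(cfg["innovation_cost"]);
  c.learn_cost = as<double>(cfg["learning_cost"]);
  c.radius = as<int>(cfg["interaction_radius"]);
  c.cap = as<double>(cfg["energy_cap"]);
  c.req = as<double>(cfg["step_requirement"]);
  c.min_repro_age = as<int>(cfg["min_repro_age"]);
  c.erep = as<double>(cfg["repro_energy_threshold"]);
  c.transfer = as<double>(cfg["birth_energy_transfer"]);
  c.max_age = as<int>(cfg["max_age"]);
  c.fiss_min = as<int>(cfg["fission_min_size"]);
  c.fiss_frac = as<double>(cfg["pressure_fission_fraction"]);
  c.forage_to_req = as<std::string>(cfg["forage_mode"]) == "to_requirement";
  return c;
}

// [[Rcpp::export]]
List cpp_run(List state, List cfg, int n_steps) {
  World w;
  w.c = parse_cfg(cfg);
  const Cfg& c = w.c;
  w.nsq = c.W * c.H;
  NumericMatrix stocks_in = state["stocks"];
  if (stocks_in.nrow() != w.nsq || stocks_in.ncol() != c.NT)
    stop("stocks matrix does not match grid dimensions");
  w.stocks.assign(w.nsq * (size_t)c.NT, 0.0);
  for (int s = 0; s < w.nsq; ++s)
    for (int t = 0; t < c.NT; ++t)
      w.stocks[(size_t)s * c.NT + t] = stocks_in(s, t);
  w.occ.assign(w.nsq, -1);
  List groups = state["groups"];
  IntegerVector gid = groups["id"], gcol = groups["col"], grow = groups["row"];
  std::unordered_map<int, int> gmap;
  for (int g = 0; g < gid.size(); ++g) {
    Grp G;
    G.id = gid[g];
    G.sq = grow[g] * c.W + gcol[g];
    if (G.sq < 0 || G.sq >= w.nsq) stop("group square off grid");
    G.alive = true;
    std::fill(G.cnt, G.cnt + MAXT + 1, 0);
    std::fill(G.maxv, G.maxv + MAXT, (int16_t)0);
    if (w.occ[G.sq] != -1) stop("two groups on one square");
    w.occ[G.sq] = g;
    gmap[G.id] = g;
    w.grps.push_back(G);
  }
  List ind = state["individuals"];
  NumericVector iid = ind["id"];
  IntegerVector isex = ind["sex"], iage = ind["age"], igrp = ind["group_id"];
  NumericVector ien = ind["energy"], iin = ind["intake"];
  LogicalVector ipr = ind["under_pressure"];
  IntegerMatrix sk = state["skills"];
  int n = iid.size();
  if (sk.nrow() != n || sk.ncol() != c.NT) stop("skills matrix shape mismatch");
  for (int i = 0; i < n; ++i) {
    Ind a;
    a.id = iid[i];
    a.sex = isex[i];
    a.age = iage[i];
    a.energy = ien[i];
    a.intake = iin[i];
    a.pressure = ipr[i] == TRUE;
    a.alive = true;
    a.paired = false;
    a.k = 0;
    for (int t = 0; t < c.NT; ++t) {
      int v = sk(i, t);
      if (v > 0) {
        if (t != a.k) stop("trait list is not a prefix");
        a.sk[t] = (int16_t)v;
        a.k = t + 1;
      } else {
        a.sk[t] = 0;
      }
    }
    if (a.k < 1) stop("individual holds no traits");
    auto it = gmap.find(igrp[i]);
    if (it == gmap.end()) stop("individual references unknown group");
    w.inds.push_back(a);
    w.add_member(it->second, (int)w.inds.size() - 1);
  }
  w.next_id = as<double>(state["next_ind_id"]);
  w.next_gid = as<int>(state["next_group_id"]);
  w.stepno = as<int>(state["step"]);

  NumericMatrix ts(n_steps, 6);
  int done = 0;
  bool extinct = false;
  double row[6];
  for (int s = 0; s < n_steps; ++s) {
    int pop = w.do_step(row);
    for (int j = 0; j < 6; ++j) ts(s, j) = row[j];
    done = s + 1;
    if (pop == 0) {
      extinct = true;
      break;
    }
  }
  NumericMatrix ts_out(done, 6);
  for (int s = 0; s < done; ++s)
    for (int j = 0; j < 6; ++j) ts_out(s, j) = ts(s, j);

  // marshal state back (alive individuals sorted by id, groups by creation)
  std::vector<int> alive;
  for (int i = 0; i < (int)w.inds.size(); ++i)
    if (w.inds[i].alive) alive.push_back(i);
  std::sort(alive.begin(), alive.end(), [&](int a, int b) {
    return w.inds[a].id < w.inds[b].id;
  });
  int na = (int)alive.size();
  NumericVector oid(na), oen(na), oin(na);
  IntegerVector osex(na), oage(na), ogrp(na);
  LogicalVector opr(na);
  IntegerMatrix osk(na, c.NT);
  for (int j = 0; j < na; ++j) {
    const Ind& a = w.inds[alive[j]];
    oid[j] = a.id;
    osex[j] = a.sex;
    oage[j] = a.age;
    oen[j] = a.energy;
    oin[j] = a.intake;
    opr[j] = a.pressure;
    ogrp[j] = w.grps[a.grp].id;
    for (int t = 0; t < c.NT; ++t) osk(j, t) = (t < a.k) ? a.sk[t] : 0;
  }
  std::vector<int> galive;
  for (int g = 0; g < (int)w.grps.size(); ++g)
    if (w.grps[g].alive) galive.push_back(g);
  int ngv = (int)galive.size();
  IntegerVector ogid(ngv), ocol(ngv), orow(ngv);
  for (int j = 0; j < ngv; ++j) {
    const Grp& G = w.grps[galive[j]];
    ogid[j] = G.id;
    ocol[j] = G.sq % c.W;
    orow[j] = G.sq / c.W;
  }
  IntegerVector sqg(w.nsq, NA_INTEGER);
  for (int s = 0; s < w.nsq; ++s)
    if (w.occ[s] >= 0) sqg[s] = w.grps[w.occ[s]].id;
  NumericMatrix ost(w.nsq, c.NT);
  for (int s = 0; s < w.nsq; ++s)
    for (int t = 0; t < c.NT; ++t) ost(s, t) = w.stocks[(size_t)s * c.NT + t];

  int nev = (int)w.ev_step.size();
  NumericMatrix ev(nev, 4);
  for (int e = 0; e < nev; ++e) {
    ev(e, 0) = w.ev_step[e];
    ev(e, 1) = w.ev_gid[e];
    ev(e, 2) = w.ev_trait[e];
    ev(e, 3) = w.ev_ind[e];
  }

  List out_state = List::create(
      _["step"] = w.stepno, _["stocks"] = ost, _["square_group"] = sqg,
      _["groups"] = List::create(_["id"] = ogid, _["col"] = ocol,
                                 _["row"] = orow),
      _["individuals"] = List::create(
          _["id"] = oid, _["sex"] = osex, _["age"] = oage, _["energy"] = oen,
          _["group_id"] = ogrp, _["intake"] = oin, _["under_pressure"] = opr),
      _["skills"] = osk, _["next_ind_id"] = w.next_id,
      _["next_group_id"] = w.next_gid);
  return List::create(_["state"] = out_state, _["timeseries"] = ts_out,
                      _["events"] = ev, _["extinct"] = extinct);
}

// ---- granular model primitives shared with the engine ----------------------

// [[Rcpp::export]]
IntegerVector cpp_copy_with_error(IntegerVector values, double error_prob,
                                  int max_skill) {
  int n = values.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = copy_err_val(values[i], error_prob, max_skill);
  return out;
}

// [[Rcpp::export]]
List cpp_forage(IntegerVector skills, double energy, NumericVector stocks,
                double basic_rate, double selection_differential,
                double energy_cap, double step_requirement,
                bool to_requirement) {
  int k = skills.size();
  if (k > MAXT) stop("too many traits");
  if (stocks.size() < k) stop("fewer stocks than traits");
  Cfg c;
  c.basic = basic_rate;
  c.seldiff = selection_differential;
  c.cap = energy_cap;
  c.req = step_requirement;
  c.forage_to_req = to_requirement;
  int16_t sk[MAXT];
  for (int i = 0; i < k; ++i) sk[i] = (int16_t)skills[i];
  std::vector<double> st(stocks.begin(), stocks.end());
  double e = energy;
  double intake = forage_core(k, sk, e, st.data(), c);
  return List::create(
      _["energy"] = e, _["stocks"] = NumericVector(st.begin(), st.end()),
      _["intake"] = intake,
      _["under_pressure"] = intake < step_requirement - 1e-9);
}

// [[Rcpp::export]]
IntegerVector cpp_vertical_transmission(IntegerVector mother,
                                        IntegerVector father,
                                        double error_prob, int max_skill) {
  int k = std::min(mother.size(), father.size());
  IntegerVector out(k);
  for (int t = 0; t < k; ++t) {
    int v = (unif_rand() < 0.5) ? mother[t] : father[t];
    out[t] = copy_err_val(v, error_prob, max_skill);
  }
  return out;
}

// Direct (explicit-candidate-list) form of the social-learning rule, used by
// the R-level operation; the engine applies the same rule through per-group
// aggregates.
// [[Rcpp::export]]
List cpp_social_learn(IntegerVector learner_skills, double learner_energy,
                      IntegerMatrix model_skills, double error_prob,
                      int max_skill, double learning_cost,
                      int n_resource_types) {
  int kk = learner_skills.size();
  IntegerVector out = clone(learner_skills);
  if (learner_energy <= learning_cost)
    return List::create(_["skills"] = out, _["energy"] = learner_energy,
                        _["learned"] = false);
  int nm = model_skills.nrow();
  std::vector<int> mk(nm, 0);
  for (int m = 0; m < nm; ++m) {
    int k = 0;
    while (k < model_skills.ncol() && model_skills(m, k) > 0) ++k;
    mk[m] = k;
  }
  if (kk < n_resource_types) { // (a) acquire the next trait from any holder
    std::vector<int> holders;
    for (int m = 0; m < nm; ++m)
      if (mk[m] >= kk + 1) holders.push_back(m);
    if (!holders.empty()) {
      int m = holders[runif_int((int)holders.size())];
      int v = copy_err_val(model_skills(m, kk), error_prob, max_skill);
      IntegerVector grown(kk + 1);
      for (int t = 0; t < kk; ++t) grown[t] = out[t];
      grown[kk] = v;
      return List::create(
          _["skills"] = grown,
          _["energy"] = std::max(0.0, learner_energy - learning_cost),
          _["learned"] = true);
    }
  }
  std::vector<int> elig_t; // (b) traits for which some model is strictly better
  for (int t = 0; t < kk; ++t) {
    int best = 0;
    for (int m = 0; m < nm; ++m)
      if (mk[m] > t) best = std::max(best, (int)model_skills(m, t));
    if (best > out[t]) elig_t.push_back(t);
  }
  if (elig_t.empty())
    return List::create(_["skills"] = out, _["energy"] = learner_energy,
                        _["learned"] = false);
  int t = elig_t[runif_int((int)elig_t.size())];
  std::vector<int> holders;
  for (int m = 0; m < nm; ++m)
    if (mk[m] > t) holders.push_back(m);
  int m = holders[runif_int((int)holders.size())];
  out[t] = copy_err_val(model_skills(m, t), error_prob, max_skill);
  return List::create(
      _["skills"] = out,
      _["energy"] = std::max(0.0, learner_energy - learning_cost),
      _["learned"] = true);
}
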