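// Exact event-driven (Gillespie) core of the Golgi self-organisation model.
//
// State: a set of compartments, each an integer triple of (cis, medial,
// trans) patch counts plus a passive cargo count. Elementary events:
//   injection        new pure cis vesicle at rate j
//   fusion           pair (a,b) at rate sum_i phi_i(a) phi_i(b)
//   boundary fusion  ER at alpha_er * phi_cis, TGN at alpha_tgn * phi_trans
//   budding          per identity present: kb * n (saturated) or kb * n_i
//                    (linear); only compartments of size >= 2
//   conversion       per patch: cis->medial and medial->trans at rate km
//
// Class propensities are maintained incrementally through the aggregates
//   S_i = sum_a phi_i(a),  Q_i = sum_a phi_i(a)^2,
// so the total pair-fusion propensity is sum_i (S_i^2 - Q_i)/2 without an
// O(M^2) pass. Aggregates are refreshed from scratch periodically to keep
// floating-point drift below the sampling noise. Sampling a concrete event
// within a class is a single O(M) scan.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const double REFRESH_EVERY = 65536;  // events between aggregate rebuilds

struct Params {
  double j, kb, km, alpha_er, alpha_tgn;
  bool fusion_on, linear_budding;
  double t_max, t_burn, sample_dt, snapshot_dt;
  int cargo_mode;  // 0 none, 1 pulse, 2 continuous
  double cargo_time, cargo_frac;
  int cargo_n;
  bool record_events, check;
  uint32_t seed;
};

Params read_params(const List& p) {
  Params q;
  q.j = as<double>(p["j"]);
  q.kb = as<double>(p["kb"]);
  q.km = as<double>(p["km"]);
  q.alpha_er = as<double>(p["alpha_er"]);
  q.alpha_tgn = as<double>(p["alpha_tgn"]);
  q.fusion_on = as<int>(p["fusion_on"]) != 0;
  q.linear_budding = as<int>(p["budding_linear"]) != 0;
  q.t_max = as<double>(p["t_max"]);
  q.t_burn = as<double>(p["t_burn"]);
  q.sample_dt = as<double>(p["sample_dt"]);
  q.snapshot_dt = as<double>(p["snapshot_dt"]);
  q.cargo_mode = as<int>(p["cargo_mode_code"]);
  q.cargo_time = as<double>(p["cargo_time"]);
  q.cargo_frac = as<double>(p["cargo_frac"]);
  q.cargo_n = as<int>(p["cargo_n"]);
  q.record_events = as<int>(p["record_events"]) != 0;
  q.check = as<int>(p["check"]) != 0;
  q.seed = static_cast<uint32_t>(as<int>(p["seed"]));
  return q;
}

// event kinds (also the integer codes in the event log)
enum Kind {
  INJECTION = 0, FUSION = 1, EXIT_ER = 2, EXIT_TGN = 3,
  BUDDING = 4, CONV_CM = 5, CONV_MT = 6
};

struct Event {
  int kind = -1;
  int a = -1, b = -1;   // compartment slots
  int identity = -1;    // budding identity (0 cis, 1 medial, 2 trans)
};

struct Engine {
  Params P;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  // compartment storage (parallel arrays, swap-remove on deletion)
  std::vector<int64_t> id;
  std::vector<int> nc, nm, nt, cargo;
  std::vector<char> has_origin;       // set on budded vesicles until they grow
  std::vector<int64_t> origin_id;
  std::vector<double> ophi_c, ophi_m, ophi_t;  // donor composition at budding

  int64_t next_id = 1;
  double t = 0.0;

  // aggregates
  double S[3] = {0, 0, 0}, Q[3] = {0, 0, 0};
  int64_t V[3] = {0, 0, 0};  // size-1 vesicle counts per identity
  double bud_total = 0.0;
  int64_t tot[3] = {0, 0, 0};
  int64_t cargo_total = 0;

  // counters
  int64_t injected_patches = 0, init_patches = 0;
  int64_t exited_er = 0, exited_tgn = 0;
  int64_t cargo_injected = 0, cargo_exited_er = 0, cargo_exited_tgn = 0;
  int pulse_left = 0;
  int64_t n_events = 0;
  int64_t kind_counts[7] = {0, 0, 0, 0, 0, 0, 0};
  double events_since_refresh = 0;

  // recorders
  std::vector<double> ser_t;
  std::vector<int> ser_m;
  std::vector<double> ser_n, ser_nc, ser_nm, ser_nt, ser_cargo, ser_cexit;
  std::vector<double> snap_t;
  std::vector<double> snap_id;
  std::vector<int> snap_nc, snap_nm, snap_nt, snap_cargo;
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_identity, ev_moved;
  std::vector<double> ev_id1, ev_id2;
  std::vector<double> tr_t, tr_did, tr_aid;
  std::vector<int> tr_identity, tr_cargo, tr_back, tr_boundary;
  std::vector<double> tr_dpc, tr_dpm, tr_dpt, tr_apc, tr_apm, tr_apt;

  explicit Engine(const Params& p) : P(p), rng(p.seed) {}

  int M() const { return static_cast<int>(nc.size()); }
  int size_of(int k) const { return nc[k] + nm[k] + nt[k]; }

  double comp_bud(int k) const {
    int n = size_of(k);
    if (n < 2) return 0.0;
    if (P.linear_budding) return P.kb * n;
    int present = (nc[k] > 0) + (nm[k] > 0) + (nt[k] > 0);
    return P.kb * n * present;
  }

  void add_contrib(int k, int sign) {
    double n = size_of(k);
    double pc = nc[k] / n, pm = nm[k] / n, pt = nt[k] / n;
    S[0] += sign * pc; S[1] += sign * pm; S[2] += sign * pt;
    Q[0] += sign * pc * pc; Q[1] += sign * pm * pm; Q[2] += sign * pt * pt;
    if (n == 1) V[nc[k] > 0 ? 0 : (nm[k] > 0 ? 1 : 2)] += sign;
    bud_total += sign * comp_bud(k);
    tot[0] += sign * nc[k]; tot[1] += sign * nm[k]; tot[2] += sign * nt[k];
    cargo_total += sign * cargo[k];
  }

  void refresh_aggregates() {
    S[0] = S[1] = S[2] = Q[0] = Q[1] = Q[2] = 0.0;
    V[0] = V[1] = V[2] = 0;
    bud_total = 0.0;
    tot[0] = tot[1] = tot[2] = 0;
    cargo_total = 0;
    for (int k = 0; k < M(); ++k) add_contrib(k, +1);
    events_since_refresh = 0;
  }

  void push_comp(int64_t cid, int c, int m2, int t2, int cg, bool origin,
                 int64_t oid, double opc, double opm, double opt) {
    id.push_back(cid);
    nc.push_back(c); nm.push_back(m2); nt.push_back(t2); cargo.push_back(cg);
    has_origin.push_back(origin ? 1 : 0);
    origin_id.push_back(oid);
    ophi_c.push_back(opc); ophi_m.push_back(opm); ophi_t.push_back(opt);
    add_contrib(M() - 1, +1);
  }

  void remove_comp(int k) {  // assumes contribution already removed
    int last = M() - 1;
    if (k != last) {
      id[k] = id[last]; nc[k] = nc[last]; nm[k] = nm[last]; nt[k] = nt[last];
      cargo[k] = cargo[last];
      has_origin[k] = has_origin[last]; origin_id[k] = origin_id[last];
      ophi_c[k] = ophi_c[last]; ophi_m[k] = ophi_m[last]; ophi_t[k] = ophi_t[last];
    }
    id.pop_back(); nc.pop_back(); nm.pop_back(); nt.pop_back(); cargo.pop_back();
    has_origin.pop_back(); origin_id.pop_back();
    ophi_c.pop_back(); ophi_m.pop_back(); ophi_t.pop_back();
  }

  // channel weight of identity i: all unordered pairs (fusion on), or only
  // pairs involving at least one vesicle (inter-compartment fusion off)
  double fusion_channel_weight(int i) const {
    if (P.fusion_on) return std::max(0.0, 0.5 * (S[i] * S[i] - Q[i]));
    double v = static_cast<double>(V[i]);
    double w = S[i] - v;  // summed phi_i of size >= 2 compartments
    return 0.5 * v * (v - 1.0) + v * std::max(0.0, w);
  }

  double fusion_propensity() const {
    return fusion_channel_weight(0) + fusion_channel_weight(1) +
           fusion_channel_weight(2);
  }

  double class_propensities(double* a) const {
    a[0] = P.j;                       // injection
    a[1] = fusion_propensity();       // pair fusion
    a[2] = P.alpha_er * S[0];         // ER exit
    a[3] = P.alpha_tgn * S[2];        // TGN exit
    a[4] = bud_total;                 // budding
    a[5] = P.km * static_cast<double>(tot[0]);  // cis -> medial
    a[6] = P.km * static_cast<double>(tot[1]);  // medial -> trans
    double tot_a = 0;
    for (int i = 0; i < 7; ++i) tot_a += a[i];
    return tot_a;
  }

  double phi(int k, int i) const {
    double n = size_of(k);
    return (i == 0 ? nc[k] : (i == 1 ? nm[k] : nt[k])) / n;
  }

  // sample a compartment with probability proportional to phi_i
  int sample_by_phi(int i, double total) {
    for (;;) {
      double target = unif(rng) * total, acc = 0.0;
      for (int k = 0; k < M(); ++k) {
        acc += phi(k, i);
        if (acc >= target) return k;
      }
      // fell through by rounding: retry with a fresh total
      total = 0.0;
      for (int k = 0; k < M(); ++k) total += phi(k, i);
      if (total <= 0) stop("internal error: empty phi channel");
    }
  }

  int sample_by_count(int i, double total) {
    for (;;) {
      double target = unif(rng) * total, acc = 0.0;
      for (int k = 0; k < M(); ++k) {
        acc += (i == 0 ? nc[k] : nm[k]);
        if (acc >= target) return k;
      }
      total = 0.0;
      for (int k = 0; k < M(); ++k) total += (i == 0 ? nc[k] : nm[k]);
      if (total <= 0) stop("internal error: empty count channel");
    }
  }

  int sample_vesicle(int i) {  // uniform among size-1 vesicles of identity i
    for (;;) {
      int target = static_cast<int>(unif(rng) * V[i]), seen = 0;
      for (int k = 0; k < M(); ++k) {
        if (size_of(k) == 1 && phi(k, i) == 1.0) {
          if (seen == target) return k;
          ++seen;
        }
      }
      refresh_aggregates();
      if (V[i] <= 0) stop("internal error: empty vesicle channel");
    }
  }

  int sample_big_by_phi(int i, double total) {  // size >= 2, weight phi_i
    for (;;) {
      double target = unif(rng) * total, acc = 0.0;
      for (int k = 0; k < M(); ++k) {
        if (size_of(k) < 2) continue;
        acc += phi(k, i);
        if (acc >= target) return k;
      }
      total = 0.0;
      for (int k = 0; k < M(); ++k)
        if (size_of(k) >= 2) total += phi(k, i);
      if (total <= 0) stop("internal error: empty non-vesicle channel");
    }
  }

  Event select_event() {
    double a[7];
    double tot_a = class_propensities(a);
    if (tot_a <= 0) stop("internal error: event selected at zero propensity");
    Event ev;
    double r = unif(rng) * tot_a;
    if (r < a[0]) { ev.kind = INJECTION; return ev; }
    r -= a[0];
    if (r < a[1]) {  // pair fusion: identity channel, then the pair
      double w[3];
      double wt = 0;
      for (int i = 0; i < 3; ++i) {
        w[i] = fusion_channel_weight(i);
        wt += w[i];
      }
      double rr = unif(rng) * wt;
      int ch = 0;
      while (ch < 2 && rr >= w[ch]) { rr -= w[ch]; ++ch; }
      ev.kind = FUSION;
      if (P.fusion_on) {
        for (int attempt = 0; ; ++attempt) {
          ev.a = sample_by_phi(ch, S[ch]);
          ev.b = sample_by_phi(ch, S[ch]);
          if (ev.a != ev.b) break;
          if (attempt > 10000) {
            // channel weight is numerically spurious; rebuild and redraw
            refresh_aggregates();
            return select_event();
          }
        }
      } else {
        // only pairs with at least one vesicle: split vesicle-vesicle vs
        // vesicle-(size >= 2) by their exact weights
        double v = static_cast<double>(V[ch]);
        double w_big = std::max(0.0, S[ch] - v);
        double w_vv = 0.5 * v * (v - 1.0);
        double w_vb = v * w_big;
        if (unif(rng) * (w_vv + w_vb) < w_vv) {
          ev.a = sample_vesicle(ch);
          do { ev.b = sample_vesicle(ch); } while (ev.b == ev.a);
        } else {
          ev.a = sample_vesicle(ch);
          ev.b = sample_big_by_phi(ch, w_big);
        }
      }
      return ev;
    }
    r -= a[1];
    if (r < a[2]) {
      ev.kind = EXIT_ER;
      ev.a = sample_by_phi(0, S[0]);
      return ev;
    }
    r -= a[2];
    if (r < a[3]) {
      ev.kind = EXIT_TGN;
      ev.a = sample_by_phi(2, S[2]);
      return ev;
    }
    r -= a[3];
    if (r < a[4]) {  // budding: scan compartments by their budding rate
      ev.kind = BUDDING;
      for (;;) {
        double target = unif(rng) * bud_total, acc = 0.0;
        int kfound = -1;
        for (int k = 0; k < M(); ++k) {
          acc += comp_bud(k);
          if (acc >= target) { kfound = k; break; }
        }
        if (kfound < 0) { refresh_aggregates(); continue; }
        ev.a = kfound;
        break;
      }
      // identity within the compartment
      int k = ev.a;
      if (P.linear_budding) {
        double n = size_of(k);
        double rr = unif(rng) * n;
        ev.identity = (rr < nc[k]) ? 0 : (rr < nc[k] + nm[k] ? 1 : 2);
      } else {
        int present[3], np = 0;
        if (nc[k] > 0) present[np++] = 0;
        if (nm[k] > 0) present[np++] = 1;
        if (nt[k] > 0) present[np++] = 2;
        ev.identity = present[static_cast<int>(unif(rng) * np) % np];
      }
      return ev;
    }
    r -= a[4];
    if (r < a[5]) {
      ev.kind = CONV_CM;
      ev.a = sample_by_count(0, static_cast<double>(tot[0]));
      return ev;
    }
    ev.kind = CONV_MT;
    ev.a = sample_by_count(1, static_cast<double>(tot[1]));
    return ev;
  }

  void record_transport(int k, double apc, double apm, double apt,
                        int64_t acceptor, int back, int boundary) {
    if (!has_origin[k] || cargo[k] < 1) return;
    tr_t.push_back(t);
    int ident = nc[k] > 0 ? 0 : (nm[k] > 0 ? 1 : 2);
    tr_identity.push_back(ident);
    tr_did.push_back(static_cast<double>(origin_id[k]));
    tr_aid.push_back(static_cast<double>(acceptor));
    tr_dpc.push_back(ophi_c[k]); tr_dpm.push_back(ophi_m[k]); tr_dpt.push_back(ophi_t[k]);
    tr_apc.push_back(apc); tr_apm.push_back(apm); tr_apt.push_back(apt);
    tr_cargo.push_back(cargo[k]);
    tr_back.push_back(back);
    tr_boundary.push_back(boundary);
  }

  void log_event(int kind, int identity, int64_t id1, int64_t id2, int moved) {
    if (!P.record_events) return;
    ev_t.push_back(t);
    ev_kind.push_back(kind);
    ev_identity.push_back(identity);
    ev_id1.push_back(static_cast<double>(id1));
    ev_id2.push_back(static_cast<double>(id2));
    ev_moved.push_back(moved);
  }

  void execute(const Event& ev) {
    switch (ev.kind) {
      case INJECTION: {
        int cg = 0;
        if (P.cargo_mode == 1 && t >= P.cargo_time && pulse_left > 0) {
          cg = 1; --pulse_left;
        } else if (P.cargo_mode == 2 && t >= P.cargo_time &&
                   unif(rng) < P.cargo_frac) {
          cg = 1;
        }
        push_comp(next_id, 1, 0, 0, cg, false, -1, 0, 0, 0);
        ++injected_patches;
        cargo_injected += cg;
        log_event(INJECTION, 0, next_id, -1, cg);
        ++next_id;
        break;
      }
      case FUSION: {
        int a = ev.a, b = ev.b;
        double na = size_of(a), nb = size_of(b);
        record_transport(a, nc[b] / nb, nm[b] / nb, nt[b] / nb, id[b],
                         origin_id[a] == id[b] ? 1 : 0, 0);
        record_transport(b, nc[a] / na, nm[a] / na, nt[a] / na, id[a],
                         origin_id[b] == id[a] ? 1 : 0, 0);
        log_event(FUSION, -1, id[a], id[b], cargo[b]);
        add_contrib(a, -1);
        add_contrib(b, -1);
        nc[a] += nc[b]; nm[a] += nm[b]; nt[a] += nt[b]; cargo[a] += cargo[b];
        has_origin[a] = 0;
        add_contrib(a, +1);
        remove_comp(b);
        break;
      }
      case EXIT_ER:
      case EXIT_TGN: {
        int a = ev.a;
        bool er = ev.kind == EXIT_ER;
        record_transport(a, er ? 1.0 : 0.0, 0.0, er ? 0.0 : 1.0,
                         er ? -1 : -2, 0, er ? 1 : 2);
        log_event(ev.kind, -1, id[a], -1, cargo[a]);
        if (er) { exited_er += size_of(a); cargo_exited_er += cargo[a]; }
        else { exited_tgn += size_of(a); cargo_exited_tgn += cargo[a]; }
        add_contrib(a, -1);
        remove_comp(a);
        break;
      }
      case BUDDING: {
        int a = ev.a, i = ev.identity;
        double n = size_of(a);
        double opc = nc[a] / n, opm = nm[a] / n, opt = nt[a] / n;
        int moved = 0;
        if (cargo[a] > 0) {
          std::binomial_distribution<int> bin(cargo[a], 1.0 / n);
          moved = bin(rng);
        }
        add_contrib(a, -1);
        if (i == 0) --nc[a]; else if (i == 1) --nm[a]; else --nt[a];
        cargo[a] -= moved;
        add_contrib(a, +1);
        push_comp(next_id, i == 0 ? 1 : 0, i == 1 ? 1 : 0, i == 2 ? 1 : 0,
                  moved, true, id[a], opc, opm, opt);
        log_event(BUDDING, i, id[a], next_id, moved);
        ++next_id;
        break;
      }
      case CONV_CM: {
        int a = ev.a;
        add_contrib(a, -1);
        --nc[a]; ++nm[a];
        add_contrib(a, +1);
        log_event(CONV_CM, 0, id[a], -1, 0);
        break;
      }
      case CONV_MT: {
        int a = ev.a;
        add_contrib(a, -1);
        --nm[a]; ++nt[a];
        add_contrib(a, +1);
        log_event(CONV_MT, 1, id[a], -1, 0);
        break;
      }
    }
    ++n_events;
    ++kind_counts[ev.kind];
    if ((events_since_refresh += 1) >= REFRESH_EVERY) refresh_aggregates();
    if (P.check) verify();
  }

  void verify() {
    int64_t sc = 0, sm = 0, st = 0, scg = 0;
    for (int k = 0; k < M(); ++k) {
      int n = size_of(k);
      if (n < 1) stop("invariant violated: compartment of size 0");
      if (has_origin[k]) {
        if (n != 1) stop("invariant violated: grown compartment kept its vesicle origin tag");
        if ((nc[k] > 0) + (nm[k] > 0) + (nt[k] > 0) != 1)
          stop("invariant violated: budded vesicle is not pure");
      }
      sc += nc[k]; sm += nm[k]; st += nt[k]; scg += cargo[k];
    }
    if (sc != tot[0] || sm != tot[1] || st != tot[2])
      stop("invariant violated: cached species totals disagree with recount");
    if (sc + sm + st != init_patches + injected_patches - exited_er - exited_tgn)
      stop("invariant violated: patch conservation");
    if (scg != cargo_injected - cargo_exited_er - cargo_exited_tgn)
      stop("invariant violated: cargo conservation");
  }

  void record_series_at(double ts) {
    ser_t.push_back(ts);
    ser_m.push_back(M());
    ser_n.push_back(static_cast<double>(tot[0] + tot[1] + tot[2]));
    ser_nc.push_back(static_cast<double>(tot[0]));
    ser_nm.push_back(static_cast<double>(tot[1]));
    ser_nt.push_back(static_cast<double>(tot[2]));
    ser_cargo.push_back(static_cast<double>(cargo_total));
    ser_cexit.push_back(static_cast<double>(cargo_exited_er + cargo_exited_tgn));
  }

  void record_snapshot_at(double ts) {
    for (int k = 0; k < M(); ++k) {
      snap_t.push_back(ts);
      snap_id.push_back(static_cast<double>(id[k]));
      snap_nc.push_back(nc[k]); snap_nm.push_back(nm[k]);
      snap_nt.push_back(nt[k]); snap_cargo.push_back(cargo[k]);
    }
  }

  void run() {
    if (P.cargo_mode == 1) pulse_left = P.cargo_n;
    double next_sample = 0.0, next_snap = 0.0;
    for (;;) {
      Rcpp::checkUserInterrupt();
      double a[7];
      double tot_a = class_propensities(a);
      double t_next;
      if (tot_a <= 0) {
        t_next = P.t_max;  // frozen system: nothing can fire
      } else {
        double u = unif(rng);
        t_next = t + (-std::log(1.0 - u) / tot_a);
      }
      while (next_sample <= t_next && next_sample <= P.t_max + 1e-12) {
        record_series_at(next_sample);
        next_sample += P.sample_dt;
      }
      while (next_snap <= t_next && next_snap <= P.t_max + 1e-12) {
        record_snapshot_at(next_snap);
        next_snap += P.snapshot_dt;
      }
      if (t_next >= P.t_max || tot_a <= 0) { t = P.t_max; break; }
      t = t_next;
      Event ev = select_event();
      execute(ev);
    }
  }
};

void init_from_df(Engine& eng, const DataFrame& comps) {
  if (comps.nrow() == 0) return;
  IntegerVector nc = comps["n_cis"], nm = comps["n_medial"], nt = comps["n_trans"];
  IntegerVector cg = comps.containsElementNamed("cargo")
                       ? IntegerVector(comps["cargo"])
                       : IntegerVector(comps.nrow(), 0);
  for (int k = 0; k < comps.nrow(); ++k) {
    if (nc[k] + nm[k] + nt[k] < 1) stop("initial compartment of size 0");
    eng.push_comp(eng.next_id++, nc[k], nm[k], nt[k], cg[k], false, -1, 0, 0, 0);
    eng.init_patches += nc[k] + nm[k] + nt[k];
    eng.cargo_injected += cg[k];  // book initial cargo as injected
  }
}

CharacterVector kind_labels(const std::vector<int>& kinds) {
  static const char* lab[7] = {"injection", "fusion", "boundary_fusion_er",
                               "boundary_fusion_tgn", "budding",
                               "conversion_cis_medial", "conversion_medial_trans"};
  CharacterVector out(kinds.size());
  for (size_t i = 0; i < kinds.size(); ++i) out[i] = lab[kinds[i]];
  return out;
}

CharacterVector identity_labels(const std::vector<int>& ids) {
  static const char* lab[3] = {"cis", "medial", "trans"};
  CharacterVector out(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) {
    if (ids[i] >= 0) out[i] = lab[ids[i]]; else out[i] = NA_STRING;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List params, DataFrame init) {
  Params P = read_params(params);
  Engine eng(P);
  init_from_df(eng, init);
  eng.run();

  DataFrame series = DataFrame::create(
    _["time"] = eng.ser_t, _["n_compartments"] = eng.ser_m,
    _["n_total"] = eng.ser_n, _["n_cis"] = eng.ser_nc,
    _["n_medial"] = eng.ser_nm, _["n_trans"] = eng.ser_nt,
    _["cargo_in_system"] = eng.ser_cargo, _["cargo_exited"] = eng.ser_cexit);

  DataFrame snapshots = DataFrame::create(
    _["time"] = eng.snap_t, _["id"] = eng.snap_id,
    _["n_cis"] = eng.snap_nc, _["n_medial"] = eng.snap_nm,
    _["n_trans"] = eng.snap_nt, _["cargo"] = eng.snap_cargo);

  DataFrame transport = DataFrame::create(
    _["time"] = eng.tr_t, _["identity"] = identity_labels(eng.tr_identity),
    _["donor_id"] = eng.tr_did, _["acceptor_id"] = eng.tr_aid,
    _["donor_phi_cis"] = eng.tr_dpc, _["donor_phi_medial"] = eng.tr_dpm,
    _["donor_phi_trans"] = eng.tr_dpt,
    _["acceptor_phi_cis"] = eng.tr_apc, _["acceptor_phi_medial"] = eng.tr_apm,
    _["acceptor_phi_trans"] = eng.tr_apt,
    _["cargo"] = eng.tr_cargo,
    _["back_fusion"] = LogicalVector(eng.tr_back.begin(), eng.tr_back.end()),
    _["to_boundary"] = eng.tr_boundary);

  DataFrame events;
  if (P.record_events) {
    events = DataFrame::create(
      _["time"] = eng.ev_t, _["kind"] = kind_labels(eng.ev_kind),
      _["identity"] = identity_labels(eng.ev_identity),
      _["id1"] = eng.ev_id1, _["id2"] = eng.ev_id2,
      _["cargo_moved"] = eng.ev_moved);
  }

  DataFrame final_state = DataFrame::create(
    _["id"] = std::vector<double>(eng.id.begin(), eng.id.end()),
    _["n_cis"] = eng.nc, _["n_medial"] = eng.nm, _["n_trans"] = eng.nt,
    _["cargo"] = eng.cargo);

  NumericVector counters = NumericVector::create(
    _["injected_patches"] = static_cast<double>(eng.injected_patches),
    _["initial_patches"] = static_cast<double>(eng.init_patches),
    _["exited_er"] = static_cast<double>(eng.exited_er),
    _["exited_tgn"] = static_cast<double>(eng.exited_tgn),
    _["cargo_injected"] = static_cast<double>(eng.cargo_injected),
    _["cargo_exited_er"] = static_cast<double>(eng.cargo_exited_er),
    _["cargo_exited_tgn"] = static_cast<double>(eng.cargo_exited_tgn),
    _["n_events"] = static_cast<double>(eng.n_events));

  NumericVector by_kind(7);
  for (int i = 0; i < 7; ++i) by_kind[i] = static_cast<double>(eng.kind_counts[i]);
  by_kind.names() = CharacterVector::create(
    "injection", "fusion", "boundary_fusion_er", "boundary_fusion_tgn",
    "budding", "conversion_cis_medial", "conversion_medial_trans");

  return List::create(
    _["series"] = series, _["snapshots"] = snapshots,
    _["transport"] = transport, _["events"] = events,
    _["final_state"] = final_state, _["counters"] = counters,
    _["events_by_kind"] = by_kind);
}

// Class-level propensities of a frozen state, computed by the engine's own
// bookkeeping (used to cross-check against the interpreted enumeration).
// [[Rcpp::export]]
NumericVector cpp_class_propensities(List params, DataFrame comps) {
  Params P = read_params(params);
  Engine eng(P);
  init_from_df(eng, comps);
  double a[7];
  double tot = eng.class_propensities(a);
  NumericVector out = NumericVector::create(
    _["injection"] = a[0], _["fusion"] = a[1],
    _["boundary_fusion_er"] = a[2], _["boundary_fusion_tgn"] = a[3],
    _["budding"] = a[4], _["conversion_cis_medial"] = a[5],
    _["conversion_medial_trans"] = a[6], _["total"] = tot);
  return out;
}

// Repeatedly sample (waiting time, event) from one frozen state without
// executing anything, through the production selection code path.
// [[Rcpp::export]]
DataFrame cpp_frozen_draws(List params, DataFrame comps, int n_draws) {
  Params P = read_params(params);
  Engine eng(P);
  init_from_df(eng, comps);
  double a[7];
  double tot = eng.class_propensities(a);
  if (tot <= 0) stop("frozen state has zero total propensity");
  std::vector<double> dt(n_draws);
  std::vector<int> kind(n_draws), slot_a(n_draws), slot_b(n_draws),
      identity(n_draws);
  for (int i = 0; i < n_draws; ++i) {
    double u = eng.unif(eng.rng);
    dt[i] = -std::log(1.0 - u) / tot;
    Event ev = eng.select_event();
    kind[i] = ev.kind;
    slot_a[i] = ev.a + 1;  // 1-based row index into `comps`, 0 -> NA side
    slot_b[i] = ev.b + 1;
    identity[i] = ev.identity;
  }
  return DataFrame::create(
    _["dt"] = dt, _["kind"] = kind_labels(kind),
    _["a"] = slot_a, _["b"] = slot_b,
    _["identity"] = identity_labels(identity));
}
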