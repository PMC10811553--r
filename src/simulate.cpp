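#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven propagation through the dual-pathway AV-node network.
//
// Topology: two chains of m nodes (fast pathway = nodes 0..m-1, slow pathway =
// nodes m..2m-1; node 0 and node m are the atrial entry nodes), the two chain
// ends (m-1 and 2m-1) mutually connected, and both chain ends feeding the
// coupling node (index 2m). Chain-internal edges are bidirectional, so
// retrograde travel is possible; the coupling node does not re-emit.
//
// Node update per incoming impulse n at arrival time t:
//   tdia = t - (t_last + R_last)          (diastolic interval)
//   tdia < 0            -> impulse blocked, state unchanged
//   never activated     -> fully recovered limit: R = Rmin + dR, D = Dmin
//   otherwise           -> R = Rmin + dR * (1 - exp(-tdia/tauR))
//                          D = Dmin + dD * exp(-tdia/tauD)
// On activation the node transmits to all neighbours with delay D and becomes
// refractory for R. The coupling node has fixed R and D; its activations plus
// the fixed delay are the ventricular beat times.

struct Event {
  double t;
  int node;
  long long seq;
  int from; // sending node index, -1 for an atrial impulse
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.node != b.node) return a.node > b.node;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export(name = ".simulate_avn_cpp")]]
List simulate_avn_cpp(NumericVector arrivals,
                      NumericVector theta,
                      double coupling_rp,
                      double coupling_cd,
                      int nodes_per_pathway,
                      bool log_activations) {
  if (theta.size() != 12) stop("theta must have 12 elements");
  const int m = nodes_per_pathway;
  if (m < 1) stop("nodes_per_pathway must be >= 1");
  const int n_nodes = 2 * m + 1;
  const int cpl = 2 * m;

  // canonical order: fp_rmin, fp_dr, fp_taur, fp_dmin, fp_dd, fp_taud, then SP
  const double fp_rmin = theta[0], fp_dr = theta[1], fp_taur = theta[2];
  const double fp_dmin = theta[3], fp_dd = theta[4], fp_taud = theta[5];
  const double sp_rmin = theta[6], sp_dr = theta[7], sp_taur = theta[8];
  const double sp_dmin = theta[9], sp_dd = theta[10], sp_taud = theta[11];

  std::vector<double> last_act(n_nodes, R_NegInf);
  std::vector<double> last_rp(n_nodes, 0.0);
  // end of the current refractory interval; monotone non-decreasing per
  // node, so an arrival strictly before it can never conduct and need not
  // be queued at all
  std::vector<double> refr_end(n_nodes, R_NegInf);
  std::vector<bool> ever(n_nodes, false);

  // The heap holds only in-flight conduction events; atrial arrivals are
  // streamed from the (sorted) input so heap operations stay shallow.
  // Ordering is identical to pushing everything up front: arrivals carry
  // sequence numbers 0..2n-1 (node-0 delivery before node-m delivery),
  // internal events 2n and up, and events are processed by
  // (time, node index, sequence).
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  const R_xlen_t n_arr = arrivals.size();
  R_xlen_t ai = 0;   // next arrival to deliver
  int phase = 0;     // 0: deliver to FP entry, 1: to SP entry
  long long seq = 2 * static_cast<long long>(n_arr);
  const double last_arrival = n_arr ? arrivals[n_arr - 1] : 0.0;
  // let the last impulses finish crossing the network, but bound any
  // self-sustained retrograde loop that outlives the atrial train
  const double t_cap = last_arrival + 10000.0;

  std::vector<double> beats;
  std::vector<int> beat_src; // 1 = FP, 2 = SP
  beats.reserve(arrivals.size() / 2);
  beat_src.reserve(arrivals.size() / 2);
  std::vector<int> log_node;
  std::vector<double> log_t, log_tdia, log_r, log_d;

  std::vector<int> nbr;
  nbr.reserve(4);

  while (!q.empty() || ai < n_arr) {
    Event ev;
    bool from_stream = false;
    if (ai < n_arr) {
      const double ta = arrivals[ai];
      const int na = phase == 0 ? 0 : m;
      const long long sa = 2 * static_cast<long long>(ai) + phase;
      if (q.empty()) {
        from_stream = true;
      } else {
        const Event& top = q.top();
        from_stream = (ta < top.t) ||
          (ta == top.t && (na < top.node ||
                           (na == top.node && sa < top.seq)));
      }
      if (from_stream) {
        ev = Event{ta, na, sa, -1};
        if (phase == 0) phase = 1; else { phase = 0; ++ai; }
      }
    }
    if (!from_stream) {
      ev = q.top();
      q.pop();
    }
    const int nd = ev.node;
    const double t = ev.t;
    if (t > t_cap) continue; // retrograde echoes beyond the atrial train

    const bool is_cpl = (nd == cpl);
    double tdia;
    if (!ever[nd]) {
      tdia = R_PosInf;
    } else {
      tdia = t - (last_act[nd] + last_rp[nd]);
      if (tdia < 0) continue; // refractory: blocked, state untouched
    }

    double R, D;
    if (is_cpl) {
      R = coupling_rp;
      D = coupling_cd;
    } else {
      const bool fp = nd < m;
      const double rmin = fp ? fp_rmin : sp_rmin;
      const double dr = fp ? fp_dr : sp_dr;
      const double taur = fp ? fp_taur : sp_taur;
      const double dmin = fp ? fp_dmin : sp_dmin;
      const double dd = fp ? fp_dd : sp_dd;
      const double taud = fp ? fp_taud : sp_taud;
      if (!std::isfinite(tdia)) {
        R = rmin + dr;
        D = dmin;
      } else {
        R = rmin + dr * (1.0 - std::exp(-tdia / taur));
        D = dmin + dd * std::exp(-tdia / taud);
      }
    }

    last_act[nd] = t;
    last_rp[nd] = R;
    refr_end[nd] = t + R;
    ever[nd] = true;

    if (is_cpl) {
      beats.push_back(t + D);
      // source pathway: chain of the presynaptic node
      beat_src.push_back(ev.from >= 0 && ev.from < m ? 1 : 2);
      continue; // terminal: ventricles, no re-emission
    }

    if (log_activations) {
      log_node.push_back(nd + 1);
      log_t.push_back(t);
      log_tdia.push_back(tdia);
      log_r.push_back(R);
      log_d.push_back(D);
    }

    nbr.clear();
    const int chain_lo = nd < m ? 0 : m;
    const int chain_hi = chain_lo + m - 1;
    if (nd > chain_lo) nbr.push_back(nd - 1);
    if (nd < chain_hi) nbr.push_back(nd + 1);
    if (nd == chain_hi) {
      nbr.push_back(nd < m ? 2 * m - 1 : m - 1); // opposite chain end
      nbr.push_back(cpl);
    }
    for (size_t k = 0; k < nbr.size(); ++k)
      if (t + D >= refr_end[nbr[k]]) // else provably blocked on arrival
        q.push(Event{t + D, nbr[k], seq++, nd});
  }

  int n_fp = 0, n_sp = 0;
  for (size_t i = 0; i < beat_src.size(); ++i)
    (beat_src[i] == 1 ? n_fp : n_sp)++;

  NumericVector bt(beats.begin(), beats.end());
  NumericVector rr(beats.size() > 1 ? beats.size() - 1 : 0);
  for (R_xlen_t i = 1; i < bt.size(); ++i) rr[i - 1] = bt[i] - bt[i - 1];

  List out = List::create(
      _["beat_times"] = bt,
      _["rr"] = rr,
      _["beat_source"] = IntegerVector(beat_src.begin(), beat_src.end()),
      _["n_fp"] = n_fp,
      _["n_sp"] = n_sp);
  if (log_activations) {
    out["log"] = DataFrame::create(
        _["node"] = IntegerVector(log_node.begin(), log_node.end()),
        _["time"] = NumericVector(log_t.begin(), log_t.end()),
        _["tdia"] = NumericVector(log_tdia.begin(), log_tdia.end()),
        _["R"] = NumericVector(log_r.begin(), log_r.end()),
        _["D"] = NumericVector(log_d.begin(), log_d.end()));
  }
  return out;
}
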