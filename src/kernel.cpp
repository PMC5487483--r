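// Simulation kernel: rank-local network build, neuron update, spike delivery.
//
// The kernel mirrors the data structures of a distributed spiking-network
// simulator: neurons are assigned to (rank, thread) slots round-robin by GID,
// synapses live on the thread of their postsynaptic neuron in a per-thread
// sparse table keyed by source GID (CSR layout, sorted by source then synapse
// type), and spikes travel through flat marker-structured buffers handled on
// the R side. Only the per-event hot paths live here.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

#include "rng.h"

using namespace Rcpp;
using dryspike::rng_t;

namespace {

struct LifPar {
  double decay;    // exp(-h / tau_m)
  double theta;    // threshold (mV)
  double v_reset;  // reset potential (mV)
  int t_ref;       // refractory period in h-steps
};

// One h-step of exact-propagator leaky integrate-and-fire with delta-current
// input lumped at the step boundary. Returns true if the neuron spiked.
// During refractoriness the membrane is clamped and inputs are discarded.
inline bool lif_step(double &V, int &refr, double inp, const LifPar &P) {
  if (refr > 0) {
    --refr;
    V = P.v_reset;
    return false;
  }
  V = V * P.decay + inp;
  if (V >= P.theta) {
    V = P.v_reset;
    refr = P.t_ref;
    return true;
  }
  return false;
}

struct StdpPar {
  double lambda, alpha, mu, tau_plus, tau_minus, w_max;
  double wfac; // precomputed w_max^(1 - mu)
};

// Delivery-time update of a pair-based STDP synapse (all-to-all pairing via
// exponential traces). Replays the target's archived post-spike times in
// (t_last, t_pre]: each applies potentiation using the presynaptic trace
// Kplus evolved to the post time (which excludes the pre arriving now, so a
// simultaneous pre/post pairing contributes nothing). The spike is then
// delivered with the post-potentiation weight, after which depression is
// applied against the decayed sum of archived posts strictly before t_pre.
// Returns the delivered weight.
inline double stdp_pre(double &w, double &kp, double &tl, double t_pre,
                       const double *posts, size_t n_posts, double km,
                       const StdpPar &P) {
  // potentiation window (tl, t_pre]: archive is ascending, so skip to the
  // first post after tl
  const double *it = std::upper_bound(posts, posts + n_posts, tl);
  for (; it != posts + n_posts && *it <= t_pre; ++it) {
    const double kp_at = kp * std::exp(-(*it - tl) / P.tau_plus);
    w += P.lambda * P.wfac * std::pow(w, P.mu) * kp_at;
    if (w > P.w_max) w = P.w_max;
  }
  const double w_deliver = w;
  w -= P.lambda * P.alpha * w * km;
  if (w < 0.0) w = 0.0;
  kp = kp * std::exp(-(t_pre - tl) / P.tau_plus) + 1.0;
  tl = t_pre;
  return w_deliver;
}

// Decayed sum of all post spikes before t (the depression trace Kminus),
// by direct summation over an ascending archive. The kernel instead keeps
// this trace incrementally per neuron; the two agree to rounding order.
inline double kminus_from_archive(const double *posts, size_t n, double t,
                                  double tau_minus) {
  double km = 0.0;
  for (size_t i = 0; i < n && posts[i] < t; ++i)
    km += std::exp(-(t - posts[i]) / tau_minus);
  return km;
}

// Synapse types: 0 = static excitatory, 1 = static inhibitory, 2 = plastic
// excitatory (STDP).
struct ThreadConn {
  std::vector<int> keys;        // sorted unique source GIDs
  std::vector<int64_t> offs;    // CSR offsets, size keys.size() + 1
  std::vector<int> tgt;         // rank-local target neuron index
  std::vector<uint8_t> type;
  std::vector<int> plidx;       // index into plastic arrays, -1 for static
  std::vector<double> pl_w, pl_kp, pl_tl;
};

struct RankNet {
  int rank;
  std::vector<int> gids;                  // local neurons, ascending
  std::vector<std::vector<int> > by_thread; // local indices per thread
  std::vector<double> V;
  std::vector<int> refr;
  std::vector<double> ring;               // n_local * L, row-major
  std::vector<std::vector<double> > archive; // post-spike times per neuron
  std::vector<double> km_val, km_t;          // incremental Kminus trace
  long long spike_counter = 0;
  std::vector<ThreadConn> conn;           // one per thread
};

struct Net {
  int M, T, H, L, N, Nexc, Ke, Ki, delay_steps;
  double h, Je, Ji, Jext, dc, lambda_drive;
  bool plastic_ee, record_events, ring_topology, autapses, multapses;
  LifPar lif;
  StdpPar stdp;
  double w_init;
  long long cycle = 0;
  std::vector<int> rank_slot;             // rank -> index in nets, -1 if absent
  std::vector<RankNet> nets;
  std::vector<rng_t> vp_rng;              // one stream per virtual process
  // event log (test instrumentation)
  std::vector<int> ev_src, ev_tgt;
  std::vector<double> ev_step, ev_w;
};

inline int thread_of(int gid, int M, int T) { return (gid % (M * T)) / M; }

void build_rank(Net &net, int rank) {
  RankNet rn;
  rn.rank = rank;
  const int M = net.M, T = net.T;
  for (int g = (rank == 0 ? M : rank); g <= net.N; g += M) rn.gids.push_back(g);
  const size_t n = rn.gids.size();
  rn.by_thread.assign(T, std::vector<int>());
  for (size_t i = 0; i < n; ++i)
    rn.by_thread[thread_of(rn.gids[i], M, T)].push_back((int)i);
  rn.V.assign(n, net.lif.v_reset);
  rn.refr.assign(n, 0);
  rn.ring.assign(n * (size_t)net.L, 0.0);
  rn.archive.assign(n, std::vector<double>());
  rn.km_val.assign(n, 0.0);
  rn.km_t.assign(n, 0.0);
  rn.conn.resize(T);

  for (int t = 0; t < T; ++t) {
    const int vp = rank + M * t;
    rng_t &rng = net.vp_rng[vp];
    std::vector<int> src;
    std::vector<int> tgt;
    std::vector<uint8_t> typ;
    const std::vector<int> &targets = rn.by_thread[t];
    if (net.ring_topology) {
      for (size_t k = 0; k < targets.size(); ++k) {
        const int li = targets[k];
        const int g = rn.gids[li];
        const int s = (g == 1) ? net.N : g - 1;
        src.push_back(s);
        tgt.push_back(li);
        const bool pl = net.plastic_ee && s <= net.Nexc && g <= net.Nexc;
        typ.push_back(pl ? 2 : (s <= net.Nexc ? 0 : 1));
      }
    } else {
      src.reserve(targets.size() * (size_t)(net.Ke + net.Ki));
      tgt.reserve(src.capacity());
      typ.reserve(src.capacity());
      std::vector<int> drawn; // per-target draws, for multapse rejection
      for (size_t k = 0; k < targets.size(); ++k) {
        const int li = targets[k];
        const int g = rn.gids[li];
        const bool tgt_exc = g <= net.Nexc;
        drawn.clear();
        for (int j = 0; j < net.Ke; ++j) {
          int s;
          bool again;
          do {
            s = 1 + (int)dryspike::draw_bounded(rng, (uint64_t)net.Nexc);
            again = (!net.autapses && s == g);
            if (!again && !net.multapses)
              again = std::find(drawn.begin(), drawn.end(), s) != drawn.end();
          } while (again);
          if (!net.multapses) drawn.push_back(s);
          src.push_back(s);
          tgt.push_back(li);
          typ.push_back((net.plastic_ee && tgt_exc) ? 2 : 0);
        }
        const int Ninh = net.N - net.Nexc;
        drawn.clear();
        for (int j = 0; j < net.Ki; ++j) {
          int s;
          bool again;
          do {
            s = net.Nexc + 1 + (int)dryspike::draw_bounded(rng, (uint64_t)Ninh);
            again = (!net.autapses && s == g);
            if (!again && !net.multapses)
              again = std::find(drawn.begin(), drawn.end(), s) != drawn.end();
          } while (again);
          if (!net.multapses) drawn.push_back(s);
          src.push_back(s);
          tgt.push_back(li);
          typ.push_back(1);
        }
      }
    }
    // CSR grouped by source GID, synapses within a Connector sorted by type;
    // insertion order (ascending target) preserved within (source, type).
    const size_t ns = src.size();
    std::vector<uint64_t> keyed(ns);
    for (size_t i = 0; i < ns; ++i)
      keyed[i] = ((uint64_t)src[i] << 33) | ((uint64_t)typ[i] << 31) |
                 (uint64_t)i;
    std::sort(keyed.begin(), keyed.end());
    ThreadConn &tc = rn.conn[t];
    tc.tgt.resize(ns);
    tc.type.resize(ns);
    tc.plidx.assign(ns, -1);
    int prev_src = -1;
    int npl = 0;
    for (size_t i = 0; i < ns; ++i) {
      const size_t orig = (size_t)(keyed[i] & 0x7FFFFFFFULL);
      const int s = (int)(keyed[i] >> 33);
      if (s != prev_src) {
        tc.keys.push_back(s);
        tc.offs.push_back((int64_t)i);
        prev_src = s;
      }
      tc.tgt[i] = tgt[orig];
      tc.type[i] = typ[orig];
      if (typ[orig] == 2) tc.plidx[i] = npl++;
    }
    tc.offs.push_back((int64_t)ns);
    tc.pl_w.assign(npl, net.w_init);
    tc.pl_kp.assign(npl, 0.0);
    tc.pl_tl.assign(npl, -std::numeric_limits<double>::infinity());
  }
  net.nets.push_back(std::move(rn));
  net.rank_slot[rank] = (int)net.nets.size() - 1;
}

inline RankNet &get_rank(Net &net, int rank) {
  if (rank < 0 || rank >= net.M || net.rank_slot[rank] < 0)
    stop("rank %d is not built on this process", rank);
  return net.nets[net.rank_slot[rank]];
}

} // namespace

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(List par, int M, int T, IntegerVector ranks,
                bool record_events) {
  Net *net = new Net();
  net->M = M;
  net->T = T;
  net->N = as<int>(par["N"]);
  net->Nexc = as<int>(par["N_exc"]);
  net->Ke = as<int>(par["K_exc"]);
  net->Ki = as<int>(par["K_inh"]);
  net->H = as<int>(par["H"]);
  net->delay_steps = as<int>(par["delay_steps"]);
  net->L = net->H + net->delay_steps;
  net->h = as<double>(par["h"]);
  net->Je = as<double>(par["J_exc"]);
  net->Ji = as<double>(par["J_inh"]);
  net->Jext = as<double>(par["J_ext"]);
  net->dc = as<double>(par["dc_mv"]);
  net->lambda_drive =
      as<double>(par["eta"]) * as<double>(par["drive_rate_hz"]) * net->h / 1000.0;
  net->plastic_ee = as<bool>(par["plastic_ee"]);
  net->ring_topology = as<std::string>(par["connectivity"]) == "ring";
  net->autapses = as<bool>(par["autapses"]);
  net->multapses = as<bool>(par["multapses"]);
  net->record_events = record_events;
  net->lif.decay = std::exp(-net->h / as<double>(par["tau_m"]));
  net->lif.theta = as<double>(par["theta"]);
  net->lif.v_reset = as<double>(par["v_reset"]);
  net->lif.t_ref = as<int>(par["t_ref_steps"]);
  List sp = par["stdp"];
  net->stdp.lambda = as<double>(sp["lambda"]);
  net->stdp.alpha = as<double>(sp["alpha"]);
  net->stdp.mu = as<double>(sp["mu"]);
  net->stdp.tau_plus = as<double>(sp["tau_plus"]);
  net->stdp.tau_minus = as<double>(sp["tau_minus"]);
  net->stdp.w_max = as<double>(sp["w_max"]);
  net->stdp.wfac = std::pow(net->stdp.w_max, 1.0 - net->stdp.mu);
  net->w_init = as<double>(sp["w_init"]);

  const uint64_t master = (uint64_t)as<double>(par["seed"]);
  net->vp_rng.reserve((size_t)M * T);
  for (int vp = 0; vp < M * T; ++vp)
    net->vp_rng.push_back(dryspike::make_stream(master, (uint64_t)vp));

  net->rank_slot.assign(M, -1);
  for (int i = 0; i < ranks.size(); ++i) build_rank(*net, ranks[i]);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export(name = ".net_update")]]
IntegerMatrix net_update(SEXP p, int rank) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  const int H = net->H, L = net->L;
  const long long base = net->cycle * H;
  std::vector<int> sp_gid, sp_step;
  for (int t = 0; t < net->T; ++t) {
    const int vp = rank + net->M * t;
    rng_t &rng = net->vp_rng[vp];
    const std::vector<int> &idx = rn.by_thread[t];
    for (size_t k = 0; k < idx.size(); ++k) {
      const int i = idx[k];
      double *ring = &rn.ring[(size_t)i * L];
      for (int s = 0; s < H; ++s) {
        // drive drawn unconditionally so stream consumption is state-free
        const int nk = dryspike::draw_poisson(rng, net->lambda_drive);
        const long long gs = base + s;
        const int slot = (int)(gs % L);
        const double inp = ring[slot] + nk * net->Jext + net->dc;
        ring[slot] = 0.0;
        if (lif_step(rn.V[i], rn.refr[i], inp, net->lif)) {
          sp_gid.push_back(rn.gids[i]);
          sp_step.push_back(s);
          const double ts = (gs + 1) * net->h;
          rn.archive[i].push_back(ts);
          rn.km_val[i] = rn.km_val[i] *
              std::exp(-(ts - rn.km_t[i]) / net->stdp.tau_minus) + 1.0;
          rn.km_t[i] = ts;
          ++rn.spike_counter;
        }
      }
    }
  }
  IntegerMatrix out((int)sp_gid.size(), 2);
  for (size_t i = 0; i < sp_gid.size(); ++i) {
    out(i, 0) = sp_gid[i];
    out(i, 1) = sp_step[i];
  }
  colnames(out) = CharacterVector::create("gid", "step");
  return out;
}

// [[Rcpp::export(name = ".net_deliver")]]
double net_deliver(SEXP p, int rank, IntegerVector buf, int capacity,
                   bool check) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  const int M = net->M, T = net->T, H = net->H, L = net->L;
  if (buf.size() != (R_xlen_t)M * capacity)
    stop("global buffer length %d does not match %d ranks x capacity %d",
         (int)buf.size(), M, capacity);
  if (net->cycle < 1) stop("no previous cycle to deliver from");
  const long long emit_base = (net->cycle - 1) * H;
  double events = 0.0;
  for (int r = 0; r < M; ++r) {
    const int *sec = buf.begin() + (R_xlen_t)r * capacity;
    int part = 0;
    for (int pos = 0; pos < capacity; ++pos) {
      const int v = sec[pos];
      if (v == -1) { ++part; continue; }   // marker: next (h-step, thread) part
      if (v == -2) continue;               // padding
      if (v < 1) stop("invalid buffer entry %d", v);
      if (part >= H * T)
        stop("buffer entry after final marker in section of rank %d", r);
      const int step = part / T;
      const int pthr = part % T;
      if (check) {
        if (v % M != r || thread_of(v, M, T) != pthr)
          stop("buffer integrity violation: GID %d in part (rank %d, thread %d)",
               v, r, pthr);
      }
      const long long arr = emit_base + step + net->delay_steps;
      const int slot = (int)(arr % L);
      const double t_pre = (arr + 1) * net->h;
      for (int th = 0; th < T; ++th) {
        ThreadConn &tc = rn.conn[th];
        std::vector<int>::const_iterator it =
            std::lower_bound(tc.keys.begin(), tc.keys.end(), v);
        if (it == tc.keys.end() || *it != v) continue;
        const size_t ki = (size_t)(it - tc.keys.begin());
        for (int64_t j = tc.offs[ki]; j < tc.offs[ki + 1]; ++j) {
          const int tg = tc.tgt[j];
          double w;
          if (tc.type[j] == 0) w = net->Je;
          else if (tc.type[j] == 1) w = net->Ji;
          else {
            const int pi = tc.plidx[j];
            const std::vector<double> &A = rn.archive[tg];
            // all archived posts precede t_pre (delivery runs before the
            // update of the cycle), so the cached trace is Kminus(t_pre)
            const double km = rn.km_val[tg] *
                std::exp(-(t_pre - rn.km_t[tg]) / net->stdp.tau_minus);
            w = stdp_pre(tc.pl_w[pi], tc.pl_kp[pi], tc.pl_tl[pi], t_pre,
                         A.empty() ? NULL : &A[0], A.size(), km, net->stdp);
          }
          rn.ring[(size_t)tg * L + slot] += w;
          events += 1.0;
          if (net->record_events) {
            net->ev_src.push_back(v);
            net->ev_tgt.push_back(rn.gids[tg]);
            net->ev_step.push_back((double)arr);
            net->ev_w.push_back(w);
          }
        }
      }
    }
  }
  return events;
}

// [[Rcpp::export(name = ".net_advance_cycle")]]
void net_advance_cycle(SEXP p) {
  XPtr<Net> net(p);
  net->cycle += 1;
}

// [[Rcpp::export(name = ".net_info")]]
List net_info(SEXP p) {
  XPtr<Net> net(p);
  IntegerVector built;
  for (int r = 0; r < net->M; ++r)
    if (net->rank_slot[r] >= 0) built.push_back(r);
  return List::create(
      _["M"] = net->M, _["T"] = net->T, _["N"] = net->N,
      _["N_exc"] = net->Nexc, _["H"] = net->H, _["L"] = net->L,
      _["delay_steps"] = net->delay_steps, _["cycle"] = (double)net->cycle,
      _["built_ranks"] = built);
}

// [[Rcpp::export(name = ".net_counters")]]
List net_counters(SEXP p) {
  XPtr<Net> net(p);
  List out;
  for (int r = 0; r < net->M; ++r) {
    if (net->rank_slot[r] < 0) continue;
    RankNet &rn = net->nets[net->rank_slot[r]];
    out.push_back(List::create(_["rank"] = r,
                               _["n_local"] = (int)rn.gids.size(),
                               _["local_spike_counter"] =
                                   (double)rn.spike_counter));
  }
  return out;
}

// [[Rcpp::export(name = ".net_local_gids")]]
IntegerVector net_local_gids(SEXP p, int rank) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  return wrap(rn.gids);
}

// [[Rcpp::export(name = ".net_state")]]
List net_state(SEXP p, int rank) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  return List::create(_["gid"] = wrap(rn.gids), _["V_m"] = wrap(rn.V),
                      _["refractory_steps_left"] = wrap(rn.refr));
}

// [[Rcpp::export(name = ".net_connections")]]
DataFrame net_connections(SEXP p, int rank) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  size_t ns = 0;
  for (int t = 0; t < net->T; ++t) ns += rn.conn[t].tgt.size();
  IntegerVector src((int)ns), tgt((int)ns), thr((int)ns), typ((int)ns);
  NumericVector w((int)ns);
  int o = 0;
  for (int t = 0; t < net->T; ++t) {
    ThreadConn &tc = rn.conn[t];
    for (size_t ki = 0; ki + 1 < tc.offs.size(); ++ki) {
      for (int64_t j = tc.offs[ki]; j < tc.offs[ki + 1]; ++j) {
        src[o] = tc.keys[ki];
        tgt[o] = rn.gids[tc.tgt[j]];
        thr[o] = t;
        typ[o] = tc.type[j];
        w[o] = tc.type[j] == 0 ? net->Je
             : tc.type[j] == 1 ? net->Ji : tc.pl_w[tc.plidx[j]];
        ++o;
      }
    }
  }
  return DataFrame::create(_["source"] = src, _["target"] = tgt,
                           _["thread"] = thr, _["type"] = typ,
                           _["weight"] = w,
                           _["delay_steps"] =
                               IntegerVector((int)ns, net->delay_steps));
}

// [[Rcpp::export(name = ".net_report")]]
List net_report(SEXP p, int rank) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  double n_exc = 0, n_inh = 0, n_pl = 0, entries = 0;
  for (int t = 0; t < net->T; ++t) {
    ThreadConn &tc = rn.conn[t];
    entries += (double)tc.keys.size();
    for (size_t j = 0; j < tc.type.size(); ++j) {
      if (tc.type[j] == 0) ++n_exc;
      else if (tc.type[j] == 1) ++n_inh;
      else ++n_pl;
    }
  }
  return List::create(
      _["n_neurons"] = (int)rn.gids.size(),
      _["n_synapses"] = n_exc + n_inh + n_pl,
      _["n_static_exc"] = n_exc, _["n_static_inh"] = n_inh,
      _["n_plastic"] = n_pl, _["n_sparse_entries"] = entries,
      _["n_connectors"] = entries,
      _["ring_slots"] = (double)rn.ring.size());
}

// [[Rcpp::export(name = ".net_plastic_weights")]]
NumericVector net_plastic_weights(SEXP p, int rank) {
  XPtr<Net> net(p);
  RankNet &rn = get_rank(*net, rank);
  std::vector<double> w;
  for (int t = 0; t < net->T; ++t)
    w.insert(w.end(), rn.conn[t].pl_w.begin(), rn.conn[t].pl_w.end());
  return wrap(w);
}

// [[Rcpp::export(name = ".net_event_log")]]
DataFrame net_event_log(SEXP p) {
  XPtr<Net> net(p);
  return DataFrame::create(_["source"] = wrap(net->ev_src),
                           _["target"] = wrap(net->ev_tgt),
                           _["arrival_step"] = wrap(net->ev_step),
                           _["weight"] = wrap(net->ev_w));
}

// [[Rcpp::export(name = ".net_clear_event_log")]]
void net_clear_event_log(SEXP p) {
  XPtr<Net> net(p);
  net->ev_src.clear();
  net->ev_tgt.clear();
  net->ev_step.clear();
  net->ev_w.clear();
}

// ---------------------------------------------------------------------------
// Stand-alone surface operations (single neuron / synapse / RNG stream)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".lif_update")]]
List lif_update_cpp(double V, int refr, NumericVector ring,
                    NumericVector drive, double tau_m, double theta,
                    double v_reset, int t_ref_steps, double h) {
  if (drive.size() != ring.size())
    stop("ring and drive must have one slot per step");
  LifPar P;
  P.decay = std::exp(-h / tau_m);
  P.theta = theta;
  P.v_reset = v_reset;
  P.t_ref = t_ref_steps;
  NumericVector ring_out = clone(ring);
  std::vector<int> offsets;
  for (int s = 0; s < ring.size(); ++s) {
    const double inp = ring_out[s] + drive[s];
    ring_out[s] = 0.0;
    if (lif_step(V, refr, inp, P)) offsets.push_back(s);
  }
  return List::create(_["V_m"] = V, _["refractory_steps_left"] = refr,
                      _["input_ring"] = ring_out,
                      _["spike_offsets"] = wrap(offsets));
}

// [[Rcpp::export(name = ".stdp_apply_pre")]]
List stdp_apply_pre_cpp(double weight, double Kplus, double last_update_time,
                        double pre_time, NumericVector post_times,
                        double lambda, double alpha, double mu,
                        double tau_plus, double tau_minus, double w_max) {
  StdpPar P;
  P.lambda = lambda;
  P.alpha = alpha;
  P.mu = mu;
  P.tau_plus = tau_plus;
  P.tau_minus = tau_minus;
  P.w_max = w_max;
  P.wfac = std::pow(w_max, 1.0 - mu);
  double w = weight, kp = Kplus, tl = last_update_time;
  const double *posts = post_times.size() ? &post_times[0] : NULL;
  const double km = kminus_from_archive(posts, (size_t)post_times.size(),
                                        pre_time, tau_minus);
  const double wd = stdp_pre(w, kp, tl, pre_time, posts,
                             (size_t)post_times.size(), km, P);
  return List::create(_["weight"] = w, _["Kplus"] = kp,
                      _["last_update_time"] = tl,
                      _["delivered_weight"] = wd);
}

// [[Rcpp::export(name = ".rng_stream")]]
SEXP rng_stream_cpp(double seed, double key) {
  rng_t *g = new rng_t(dryspike::make_stream((uint64_t)seed, (uint64_t)key));
  return XPtr<rng_t>(g, true);
}

// [[Rcpp::export(name = ".rng_poisson")]]
IntegerVector rng_poisson_cpp(SEXP p, double lambda, int n) {
  XPtr<rng_t> g(p);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dryspike::draw_poisson(*g, lambda);
  return out;
}

// [[Rcpp::export(name = ".rng_bounded")]]
IntegerVector rng_bounded_cpp(SEXP p, IntegerVector bounds) {
  XPtr<rng_t> g(p);
  IntegerVector out(bounds.size());
  for (int i = 0; i < bounds.size(); ++i)
    out[i] = (int)dryspike::draw_bounded(*g, (uint64_t)bounds[i]);
  return out;
}

// [[Rcpp::export(name = ".rng_unif")]]
NumericVector rng_unif_cpp(SEXP p, int n) {
  XPtr<rng_t> g(p);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dryspike::draw_unif(*g);
  return out;
}
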