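#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Synchronous threshold-logic update kernel.
//
// A network is passed in compiled (CSR-like) form:
//   kind      : 0 = dynamic, 1 = constant-one, 2 = external input
//   thr       : activation threshold per node (dynamic nodes)
//   act_ptr / act_idx : incoming activator lists, 0-based CSR
//   inh_ptr / inh_idx : incoming inhibitor lists, 0-based CSR
//   in_nodes  : node indices (0-based) of external inputs, aligned with
//   in_period / in_phase : their periodic spike streams
//               (bit at step t is 1 iff (t - phase) mod period == 0)

static inline int input_bit(int t, int period, int phase) {
  int r = (t - phase) % period;
  if (r < 0) r += period;
  return r == 0 ? 1 : 0;
}

static void step_state(const std::vector<int> &cur, std::vector<int> &nxt,
                       int t_next,
                       const IntegerVector &kind, const IntegerVector &thr,
                       const IntegerVector &act_ptr, const IntegerVector &act_idx,
                       const IntegerVector &inh_ptr, const IntegerVector &inh_idx,
                       const IntegerVector &in_nodes,
                       const IntegerVector &in_period,
                       const IntegerVector &in_phase) {
  int n = cur.size();
  for (int i = 0; i < n; ++i) {
    if (kind[i] == 1) { nxt[i] = 1; continue; }
    if (kind[i] == 2) { nxt[i] = 0; continue; } // filled below
    int off = 0;
    for (int e = inh_ptr[i]; e < inh_ptr[i + 1]; ++e) {
      if (cur[inh_idx[e]]) { off = 1; break; }
    }
    if (off) { nxt[i] = 0; continue; }
    int cnt = 0, need = thr[i];
    for (int e = act_ptr[i]; e < act_ptr[i + 1]; ++e) {
      if (cur[act_idx[e]] && ++cnt >= need) break;
    }
    nxt[i] = (cnt >= need) ? 1 : 0;
  }
  for (int j = 0; j < in_nodes.size(); ++j)
    nxt[in_nodes[j]] = input_bit(t_next, in_period[j], in_phase[j]);
}

// Simulate `steps` synchronous updates from `init` (taken as step 0) and
// record the listed nodes; returns a (steps+1) x length(record) matrix.
// [[Rcpp::export(name = ".sim_kernel")]]
IntegerMatrix sim_kernel(IntegerVector kind, IntegerVector thr,
                         IntegerVector act_ptr, IntegerVector act_idx,
                         IntegerVector inh_ptr, IntegerVector inh_idx,
                         IntegerVector in_nodes, IntegerVector in_period,
                         IntegerVector in_phase,
                         IntegerVector init, int steps,
                         IntegerVector record) {
  int n = kind.size(), nr = record.size();
  std::vector<int> cur(init.begin(), init.end()), nxt(n);
  IntegerMatrix out(steps + 1, nr);
  for (int j = 0; j < nr; ++j) out(0, j) = cur[record[j]];
  for (int t = 1; t <= steps; ++t) {
    step_state(cur, nxt, t, kind, thr, act_ptr, act_idx, inh_ptr, inh_idx,
               in_nodes, in_period, in_phase);
    cur.swap(nxt);
    for (int j = 0; j < nr; ++j) out(t, j) = cur[record[j]];
  }
  return out;
}

// Pack a bit state into bytes for hashing.
static std::string pack_state(const std::vector<int> &s, int phase_mod) {
  std::string key((s.size() + 7) / 8 + 4, '\0');
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i]) key[i >> 3] |= (1 << (i & 7));
  size_t b = (s.size() + 7) / 8;
  for (int j = 0; j < 4; ++j) key[b + j] = (phase_mod >> (8 * j)) & 0xff;
  return key;
}

// Exact cycle detection: iterate until the augmented state (node bits plus
// the input phase counter t mod lcm) repeats. Returns transient length,
// cycle length and the cycle's states (cycle_length x n matrix), or an
// empty list element if `cap` is exceeded.
// [[Rcpp::export(name = ".cycle_kernel")]]
List cycle_kernel(IntegerVector kind, IntegerVector thr,
                  IntegerVector act_ptr, IntegerVector act_idx,
                  IntegerVector inh_ptr, IntegerVector inh_idx,
                  IntegerVector in_nodes, IntegerVector in_period,
                  IntegerVector in_phase,
                  IntegerVector init, int lcm_period, int cap) {
  int n = kind.size();
  std::vector<int> cur(init.begin(), init.end()), nxt(n);
  std::unordered_map<std::string, int> seen;
  std::vector<std::string> states;
  states.reserve(256);
  int first = -1, t = 0;
  for (;; ++t) {
    std::string key = pack_state(cur, lcm_period > 0 ? t % lcm_period : 0);
    auto hit = seen.find(key);
    if (hit != seen.end()) { first = hit->second; break; }
    seen.emplace(std::move(key), t);
    states.push_back(pack_state(cur, 0));
    if (t >= cap)
      return List::create(_["found"] = false, _["steps"] = t);
    step_state(cur, nxt, t + 1, kind, thr, act_ptr, act_idx, inh_ptr, inh_idx,
               in_nodes, in_period, in_phase);
    cur.swap(nxt);
  }
  int clen = t - first;
  IntegerMatrix cyc(clen, n);
  for (int r = 0; r < clen; ++r) {
    const std::string &key = states[first + r];
    for (int i = 0; i < n; ++i)
      cyc(r, i) = (key[i >> 3] >> (i & 7)) & 1;
  }
  return List::create(_["found"] = true, _["transient"] = first,
                      _["cycle_length"] = clen, _["cycle"] = cyc);
}
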