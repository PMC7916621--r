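// Synchronous Boolean network core: state stepping, attractor search from
// sampled starts (with memoized state -> attractor lookup), and exact
// fixed-point enumeration by backtracking with three-valued propagation.
//
// States are encoded as 64-bit words, bit i = node i in network order.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Net {
  int n;                               // number of nodes
  std::vector<std::vector<int>> regs;  // 0-based regulator indices
  std::vector<std::vector<uint8_t>> tts;

  explicit Net(const List& reg_list, const List& tt_list) {
    n = reg_list.size();
    regs.resize(n);
    tts.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector r = reg_list[i];
      IntegerVector t = tt_list[i];
      regs[i].assign(r.begin(), r.end());
      tts[i].assign(t.begin(), t.end());
    }
  }

  uint64_t step(uint64_t s) const {
    uint64_t ns = 0;
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& r = regs[i];
      size_t idx = 0;
      for (size_t j = 0; j < r.size(); ++j) {
        idx |= ((s >> r[j]) & 1ULL) << j;
      }
      ns |= (uint64_t)tts[i][idx] << i;
    }
    return ns;
  }
};

uint64_t encode_row(const IntegerMatrix& m, int row) {
  uint64_t s = 0;
  for (int j = 0; j < m.ncol(); ++j) {
    if (m(row, j)) s |= 1ULL << j;
  }
  return s;
}

IntegerMatrix decode_states(const std::vector<uint64_t>& states, int n) {
  IntegerMatrix out(states.size(), n);
  for (size_t i = 0; i < states.size(); ++i) {
    for (int j = 0; j < n; ++j) out(i, j) = (states[i] >> j) & 1ULL;
  }
  return out;
}

// Project a state onto a node subset (bits renumbered by subset order).
uint64_t project(uint64_t s, const std::vector<int>& keep) {
  uint64_t p = 0;
  for (size_t j = 0; j < keep.size(); ++j) {
    p |= ((s >> keep[j]) & 1ULL) << j;
  }
  return p;
}

// Canonical key of a cycle: the lexicographically least rotation of its
// projected encodings. Registers carry redundant phase information, so the
// projection prevents double-counting attractors that differ only there.
std::vector<uint64_t> cycle_key(const std::vector<uint64_t>& cyc,
                                const std::vector<int>& keep,
                                int* rot_out) {
  size_t L = cyc.size();
  std::vector<uint64_t> proj(L);
  for (size_t i = 0; i < L; ++i) proj[i] = project(cyc[i], keep);
  size_t best = 0;
  for (size_t r = 1; r < L; ++r) {
    for (size_t i = 0; i < L; ++i) {
      uint64_t a = proj[(r + i) % L], b = proj[(best + i) % L];
      if (a < b) { best = r; break; }
      if (a > b) break;
    }
  }
  std::vector<uint64_t> key(L);
  for (size_t i = 0; i < L; ++i) key[i] = proj[(best + i) % L];
  if (rot_out) *rot_out = (int)best;
  return key;
}

}  // namespace

// Simulate a single trajectory until the first repeated state or max_steps.
// Returns states (rows = time 0..T), transient length, cycle length and a
// resolved flag.
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List reg_list, List tt_list, IntegerVector init,
                  int max_steps) {
  Net net(reg_list, tt_list);
  uint64_t s = 0;
  for (int j = 0; j < init.size(); ++j) {
    if (init[j]) s |= 1ULL << j;
  }
  std::vector<uint64_t> path;
  std::unordered_map<uint64_t, int> pos;
  path.push_back(s);
  pos[s] = 0;
  int transient = -1, cycle_len = -1;
  bool resolved = false;
  for (int t = 0; t < max_steps; ++t) {
    s = net.step(s);
    auto it = pos.find(s);
    if (it != pos.end()) {
      transient = it->second;
      cycle_len = (int)path.size() - it->second;
      resolved = true;
      path.push_back(s);  // keep the closing state for inspection
      break;
    }
    pos[s] = (int)path.size();
    path.push_back(s);
  }
  return List::create(
      _["states"] = decode_states(path, net.n),
      _["transient"] = transient,
      _["cycle_length"] = cycle_len,
      _["resolved"] = resolved);
}

// Attractor search from a matrix of start states (rows). Trajectories are
// memoized: any state whose attractor is already known terminates the walk.
// Attractors are deduplicated by the canonical key of their cycle projected
// onto `bio` (0-based biological node indices) and returned sorted by key.
// [[Rcpp::export(name = ".cpp_attractors")]]
List cpp_attractors(List reg_list, List tt_list, IntegerMatrix starts,
                    IntegerVector bio, int max_steps) {
  Net net(reg_list, tt_list);
  std::vector<int> keep(bio.begin(), bio.end());

  std::unordered_map<uint64_t, int> state2attr;  // resolved state -> attractor
  std::map<std::vector<uint64_t>, int> key2attr;
  std::vector<std::vector<uint64_t>> cycles;     // full-state cycles, rotated
  std::vector<int> basin;
  int n_starts = starts.nrow();
  IntegerVector assignment(n_starts);
  int unresolved = 0;

  for (int r = 0; r < n_starts; ++r) {
    uint64_t s = encode_row(starts, r);
    std::vector<uint64_t> path;
    std::unordered_map<uint64_t, int> pos;
    int attr = -1;
    for (int t = 0; t <= max_steps; ++t) {
      auto known = state2attr.find(s);
      if (known != state2attr.end()) { attr = known->second; break; }
      auto seen = pos.find(s);
      if (seen != pos.end()) {
        // new cycle: states path[seen->second .. end)
        std::vector<uint64_t> cyc(path.begin() + seen->second, path.end());
        int rot = 0;
        std::vector<uint64_t> key = cycle_key(cyc, keep, &rot);
        auto kit = key2attr.find(key);
        if (kit != key2attr.end()) {
          attr = kit->second;
        } else {
          attr = (int)cycles.size();
          std::vector<uint64_t> rotated(cyc.size());
          for (size_t i = 0; i < cyc.size(); ++i) {
            rotated[i] = cyc[(rot + i) % cyc.size()];
          }
          cycles.push_back(rotated);
          basin.push_back(0);
          key2attr[key] = attr;
        }
        break;
      }
      pos[s] = (int)path.size();
      path.push_back(s);
      s = net.step(s);
    }
    if (attr < 0) {
      ++unresolved;
      assignment[r] = NA_INTEGER;
      continue;
    }
    for (uint64_t st : path) state2attr[st] = attr;
    state2attr[s] = attr;
    basin[attr] += 1;
    assignment[r] = attr + 1;  // 1-based for R
  }

  // deterministic order: sort attractors by canonical key
  std::vector<int> order;
  for (auto& kv : key2attr) order.push_back(kv.second);
  std::vector<int> rank(cycles.size());
  for (size_t i = 0; i < order.size(); ++i) rank[order[i]] = (int)i;

  List attr_states(cycles.size());
  IntegerVector basin_out(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i) {
    attr_states[rank[i]] = decode_states(cycles[i], net.n);
    basin_out[rank[i]] = basin[i];
  }
  for (int r = 0; r < n_starts; ++r) {
    if (assignment[r] != NA_INTEGER) {
      assignment[r] = rank[assignment[r] - 1] + 1;
    }
  }

  return List::create(
      _["cycles"] = attr_states,
      _["basin"] = basin_out,
      _["assignment"] = assignment,
      _["n_unresolved"] = unresolved);
}

namespace {

// Three-valued evaluation over a truth table: returns 0, 1, or -1 (unknown)
// given a partial assignment of the regulators.
int eval_partial(const Net& net, int i, const std::vector<int8_t>& vals) {
  const std::vector<int>& r = net.regs[i];
  std::vector<int> free_idx;
  size_t base = 0;
  for (size_t j = 0; j < r.size(); ++j) {
    int8_t v = vals[r[j]];
    if (v < 0) free_idx.push_back((int)j);
    else base |= (size_t)v << j;
  }
  int out = -2;
  size_t m = free_idx.size();
  for (size_t c = 0; c < (1ULL << m); ++c) {
    size_t idx = base;
    for (size_t b = 0; b < m; ++b) {
      idx |= ((c >> b) & 1ULL) << free_idx[b];
    }
    int v = net.tts[i][idx];
    if (out == -2) out = v;
    else if (out != v) return -1;
  }
  return out;
}

bool propagate(const Net& net, std::vector<int8_t>& vals) {
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < net.n; ++i) {
      int v = eval_partial(net, i, vals);
      if (v < 0) continue;
      if (vals[i] < 0) {
        vals[i] = (int8_t)v;  // fixed point forces x_i = f_i(x)
        changed = true;
      } else if (vals[i] != v) {
        return false;  // contradiction
      }
    }
  }
  return true;
}

void search_fp(const Net& net, std::vector<int8_t> vals,
               std::vector<uint64_t>& found) {
  if (!propagate(net, vals)) return;
  int branch = -1;
  for (int i = 0; i < net.n; ++i) {
    if (vals[i] < 0) { branch = i; break; }
  }
  if (branch < 0) {
    uint64_t s = 0;
    for (int i = 0; i < net.n; ++i) {
      if (vals[i]) s |= 1ULL << i;
    }
    if (net.step(s) == s) found.push_back(s);
    return;
  }
  for (int v = 0; v <= 1; ++v) {
    std::vector<int8_t> next = vals;
    next[branch] = (int8_t)v;
    search_fp(net, next, found);
  }
}

}  // namespace

// Exact fixed-point enumeration (complete). Returns a matrix of fixed
// points, rows ordered by state encoding.
// [[Rcpp::export(name = ".cpp_fixed_points")]]
IntegerMatrix cpp_fixed_points(List reg_list, List tt_list) {
  Net net(reg_list, tt_list);
  std::vector<int8_t> vals(net.n, -1);
  std::vector<uint64_t> found;
  search_fp(net, vals, found);
  std::sort(found.begin(), found.end());
  found.erase(std::unique(found.begin(), found.end()), found.end());
  return decode_states(found, net.n);
}
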