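// Synchronous stochastic simulation engine.
//
// Models arrive pre-compiled from R as a postfix bytecode over a boolean
// stack: leaves read a node level (subject to per-occurrence dosage
// sampling), internal ops are NOT / AND(n) / OR(n). Each rule carries its
// target node and level; per node, rules are evaluated in descending level
// order and the first satisfied rule sets the proposed level (0 if none),
// after which the outcome-level dosage reset is applied to dosed targets.
//
// RNG: counter-based substreams. Draws at (replicate r, step t) come from a
// splitmix64 stream whose state is a mix of (seed, r, t), so replicates are
// order-independent and a replicate's trajectory depends only on (seed, r).

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const int OP_GE = 0, OP_EQ = 1, OP_NOT = 2, OP_AND = 3, OP_OR = 4;

inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  void seed_at(uint64_t seed, uint64_t rep, uint64_t step) {
    state = mix64(mix64(seed + 0x9E3779B97F4A7C15ULL * (rep + 1)) +
                  0xD1B54A32D192ED03ULL * (step + 1));
  }
  double unif() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = mix64(state);
    return (z >> 11) * (1.0 / 9007199254740992.0);  // 53-bit mantissa
  }
};

struct Compiled {
  int n_nodes;
  std::vector<int> code;        // flat instructions, 3 ints each: op,a,b
  std::vector<int> rule_target; // per rule
  std::vector<int> rule_level;
  std::vector<int> rule_code_start;  // instruction index
  std::vector<int> rule_code_len;
  std::vector<int> node_rule_start;  // per node, into rule arrays
  std::vector<int> node_rule_count;
  std::vector<int> sig_start;  // 3 signatures
  std::vector<int> sig_len;
  std::vector<double> dose;    // per node, 1 = undosed
  int cyt, mass, cyt_level;
  bool require_mass_return;
};

// Evaluate instructions [start, start+len) against `state`.
// When sampling == true, leaf reads of dosed nodes with positive state are
// independently reset to 0 with probability 1 - d.
inline bool eval_code(const Compiled& cm, const std::vector<int>& state,
                      int start, int len, bool sampling, Rng& rng,
                      std::vector<char>& stack) {
  stack.clear();
  const int* code = cm.code.data();
  for (int i = start; i < start + len; ++i) {
    int op = code[3 * i], a = code[3 * i + 1], b = code[3 * i + 2];
    switch (op) {
      case OP_GE:
      case OP_EQ: {
        int v = state[a];
        if (sampling && v > 0 && cm.dose[a] < 1.0) {
          if (rng.unif() >= cm.dose[a]) v = 0;
        }
        stack.push_back(op == OP_GE ? (v >= b) : (v == b));
        break;
      }
      case OP_NOT:
        stack.back() = !stack.back();
        break;
      case OP_AND: {
        bool r = true;
        for (int k = 0; k < a; ++k) { r = r && stack.back(); stack.pop_back(); }
        stack.push_back(r);
        break;
      }
      case OP_OR: {
        bool r = false;
        for (int k = 0; k < a; ++k) { r = r || stack.back(); stack.pop_back(); }
        stack.push_back(r);
        break;
      }
    }
  }
  return stack.back();
}

Compiled unpack(const List& cmodel, const NumericVector& dose,
                bool require_mass_return) {
  Compiled cm;
  cm.n_nodes = as<int>(cmodel["n_nodes"]);
  cm.code = as<std::vector<int>>(cmodel["code"]);
  cm.rule_target = as<std::vector<int>>(cmodel["rule_target"]);
  cm.rule_level = as<std::vector<int>>(cmodel["rule_level"]);
  cm.rule_code_start = as<std::vector<int>>(cmodel["rule_code_start"]);
  cm.rule_code_len = as<std::vector<int>>(cmodel["rule_code_len"]);
  cm.node_rule_start = as<std::vector<int>>(cmodel["node_rule_start"]);
  cm.node_rule_count = as<std::vector<int>>(cmodel["node_rule_count"]);
  cm.sig_start = as<std::vector<int>>(cmodel["sig_start"]);
  cm.sig_len = as<std::vector<int>>(cmodel["sig_len"]);
  cm.dose = as<std::vector<double>>(dose);
  cm.cyt = as<int>(cmodel["cyt"]);
  cm.mass = as<int>(cmodel["mass"]);
  cm.cyt_level = as<int>(cmodel["cyt_level"]);
  cm.require_mass_return = require_mass_return;
  return cm;
}

inline void step_once(const Compiled& cm, const std::vector<int>& state,
                      std::vector<int>& next, bool sampling, Rng& rng,
                      std::vector<char>& stack) {
  for (int v = 0; v < cm.n_nodes; ++v) {
    int proposed = 0;
    int rs = cm.node_rule_start[v], rc = cm.node_rule_count[v];
    for (int r = rs; r < rs + rc; ++r) {
      if (eval_code(cm, state, cm.rule_code_start[r], cm.rule_code_len[r],
                    sampling, rng, stack)) {
        proposed = cm.rule_level[r];
        break;
      }
    }
    if (proposed > 0 && cm.dose[v] < 1.0) {
      if (cm.dose[v] <= 0.0 || rng.unif() >= cm.dose[v]) proposed = 0;
    }
    next[v] = proposed;
  }
}

}  // namespace

// [[Rcpp::export(name = ".engine_simulate")]]
List engine_simulate(List cmodel, NumericVector dose, IntegerVector start,
                     int n_steps, int n_reps, double seed,
                     bool record_trajectory, bool require_mass_return,
                     int rep_offset) {
  Compiled cm = unpack(cmodel, dose, require_mass_return);
  bool sampling = false;
  for (double d : cm.dose) if (d < 1.0) sampling = true;

  IntegerMatrix phase_counts(n_reps, 4);  // G1, S_G2, M, unclassified
  IntegerVector events(n_reps);
  NumericVector period_sum(n_reps);
  IntegerVector period_count(n_reps);
  int conflicts = 0;
  IntegerMatrix traj;
  if (record_trajectory) traj = IntegerMatrix(n_steps + 1, cm.n_nodes);

  std::vector<int> state(cm.n_nodes), next(cm.n_nodes);
  std::vector<char> stack;
  stack.reserve(64);
  Rng rng;
  uint64_t useed = (uint64_t)(int64_t)seed;

  for (int rep = 0; rep < n_reps; ++rep) {
    for (int v = 0; v < cm.n_nodes; ++v) state[v] = start[v];
    if (record_trajectory && rep == 0)
      for (int v = 0; v < cm.n_nodes; ++v) traj(0, v) = state[v];

    int run_len = 0;          // current cytokinesis run length
    int pending = 0;          // completed runs awaiting mass return
    int last_end = 0;         // step closing the previous cycle
    for (int t = 1; t <= n_steps; ++t) {
      rng.seed_at(useed, (uint64_t)(rep + rep_offset), (uint64_t)t);
      step_once(cm, state, next, sampling, rng, stack);
      state.swap(next);
      if (record_trajectory && rep == 0)
        for (int v = 0; v < cm.n_nodes; ++v) traj(t, v) = state[v];

      // phase classification (observational: no dosage sampling)
      int matched = -1, n_match = 0;
      for (int s = 0; s < 3; ++s) {
        if (eval_code(cm, state, cm.sig_start[s], cm.sig_len[s], false, rng,
                      stack)) {
          matched = s;
          ++n_match;
        }
      }
      if (n_match > 1) ++conflicts;
      phase_counts(rep, n_match == 1 ? matched : 3) += 1;

      // cytokinesis-run and cycle-event detection
      if (state[cm.cyt] == cm.cyt_level) {
        ++run_len;
      } else {
        if (run_len > 2) {
          if (cm.require_mass_return) {
            ++pending;
          } else {
            events[rep] += 1;
            period_sum[rep] += t - last_end;
            period_count[rep] += 1;
            last_end = t;
          }
        }
        run_len = 0;
      }
      if (pending > 0 && state[cm.mass] == 1) {
        events[rep] += pending;
        period_sum[rep] += t - last_end;
        period_count[rep] += 1;
        last_end = t;
        pending = 0;
      }
    }
    // runs/pending cycles truncated by the trajectory end are discarded
  }

  List out = List::create(
      _["phase_counts"] = phase_counts, _["events"] = events,
      _["period_sum"] = period_sum, _["period_count"] = period_count,
      _["signature_conflicts"] = conflicts);
  if (record_trajectory) out["trajectory"] = traj;
  return out;
}
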