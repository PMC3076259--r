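#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Serial structured coalescent engine.
//
// Time runs backward from the present in units of generations.  Lineages
// live in at most two demes; within a deme of (haploid) size N the waiting
// time to the next coalescence among k lineages is exponential with rate
// k(k-1)/(2N) per generation.  Piecewise-constant epochs restart the clock
// at their boundaries; the exponential-growth epoch of the expansion model
// uses the exact inverse of the integrated rate.

namespace {

// ---- RNG: xoshiro256** seeded through splitmix64 -------------------------
// Fully self-contained so that (seed, stream) -> genealogy is reproducible
// bit-for-bit across platforms.  Each replicate gets its own stream.

inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class Xoshiro {
 public:
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed;
    uint64_t mixed = splitmix64_next(x);
    x = mixed ^ (0x9E3779B97F4A7C15ULL * (stream + 1ULL));
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64_next(x);
    if (!(s_[0] | s_[1] | s_[2] | s_[3])) s_[0] = 1;
  }
  uint64_t next() {
    const uint64_t result = rotl(s_[1] * 5, 7) * 9;
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }
  // uniform on (0, 1), never exactly 0 or 1
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double expo() { return -std::log(unif()); }
  int randint(int n) {  // uniform on 0..n-1 (n modest, double has spare bits)
    int v = (int)(unif() * n);
    return v >= n ? n - 1 : v;
  }

 private:
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t s_[4];
};

// ---- configuration -------------------------------------------------------

struct Cfg {
  int variant;  // 0 constant, 1 expansion, 2 isolation-admixture
  double ne;
  double ne_present, ne_initial, t_growth, r_growth;
  double admix_c, t_split, t_bottle, t_join, bfac;
  bool prop_nw;
  int n_modern, n_ancient;
  double t_anc;
};

Cfg parse_cfg(const List &cfg) {
  Cfg c;
  c.variant = as<int>(cfg["variant"]);
  c.ne = as<double>(cfg["ne"]);
  c.ne_present = as<double>(cfg["ne_present"]);
  c.ne_initial = as<double>(cfg["ne_initial"]);
  c.t_growth = as<double>(cfg["t_growth"]);
  c.r_growth = (c.variant == 1 && c.t_growth > 0)
                   ? std::log(c.ne_present / c.ne_initial) / c.t_growth
                   : 0.0;
  c.admix_c = as<double>(cfg["c"]);
  c.t_split = as<double>(cfg["t_split"]);
  c.t_bottle = as<double>(cfg["t_bottle"]);
  c.t_join = as<double>(cfg["t_join"]);
  c.bfac = as<double>(cfg["bottleneck_factor"]);
  c.prop_nw = as<bool>(cfg["proportional_nw"]);
  c.n_modern = as<int>(cfg["n_modern"]);
  c.n_ancient = as<int>(cfg["n_ancient"]);
  c.t_anc = as<double>(cfg["t_anc"]);
  return c;
}

// ---- engine --------------------------------------------------------------

struct Lineage {
  int anc;      // number of ancient tips subtended
  uint8_t mod;  // subtends at least one modern tip
  int node;     // node id (tips 1..n, internals n+1.. in creation order)
};

struct TreeOut {
  std::vector<int> parent, child;  // two edges per coalescence
  std::vector<double> itime;       // internal node times, creation order
  std::vector<int> ideme;          // deme in which each coalescence happened
};

class Engine {
 public:
  Engine(const Cfg &cg, uint64_t seed, uint64_t stream)
      : cg_(cg), rng_(seed, stream) {}

  // statistic = 0 (single): the largest clade of ancient tips containing no
  //   modern tip.  statistic = 1 (pooled): the total number of ancient tips
  //   in maximal modern-exclusive clades of size >= 2 (ancients that
  //   coalesce with other ancients before any modern-descended lineage).
  // kthr > 0 and no tree: return the >=kthr indicator with exact early exit.
  // kthr == 0 and no tree: return the exact statistic value.
  // tree != nullptr: simulate the complete genealogy to the MRCA.
  int run(int kthr, int statistic, TreeOut *tree) {
    pop_[0].clear();
    pop_[1].clear();
    pop_[0].reserve((size_t)cg_.n_modern + cg_.n_ancient);
    for (int i = 0; i < cg_.n_modern; ++i) pop_[0].push_back({0, 1, i + 1});
    bool anc_added = (cg_.n_ancient == 0);
    best_ = 0;
    pure_total_ = 0;
    pooled_done_ = 0;
    pure_ge2_ = 0;
    next_node_ = cg_.n_modern + cg_.n_ancient + 1;

    // boundary events: 0 add ancient sample, 1 split, 2 join, 3 size change
    std::vector<std::pair<double, int> > ev;
    if (!anc_added) ev.push_back(std::make_pair(cg_.t_anc, 0));
    if (cg_.variant == 1) ev.push_back(std::make_pair(cg_.t_growth, 3));
    if (cg_.variant == 2) {
      ev.push_back(std::make_pair(cg_.t_split, 1));
      ev.push_back(std::make_pair(cg_.t_bottle, 3));
      ev.push_back(std::make_pair(cg_.t_join, 2));
    }
    std::sort(ev.begin(), ev.end());
    size_t ei = 0;
    double t = 0.0;
    const double INF = std::numeric_limits<double>::infinity();

    for (;;) {
      while (ei < ev.size() && ev[ei].first <= t) {
        apply_event(ev[ei].second, &anc_added);
        ++ei;
      }
      if (!tree && anc_added) {
        if (kthr > 0) {
          // lower / upper bounds on the final statistic are exact exits
          int lo = (statistic == 0) ? best_ : pooled_done_ + pure_ge2_;
          int hi = (statistic == 0) ? best_ : pooled_done_ + pure_total_;
          if (statistic == 0) hi = pure_total_ > best_ ? pure_total_ : best_;
          if (lo >= kthr) return 1;
          if (hi < kthr) return 0;
        } else if (pure_total_ == 0) {
          // no ancient-exclusive lineage left; the statistic is final
          return (statistic == 0) ? best_ : pooled_done_;
        }
      }
      size_t ntot = pop_[0].size() + pop_[1].size();
      if (ntot <= 1 && ei >= ev.size()) break;
      double tb = (ei < ev.size()) ? ev[ei].first : INF;
      double w0 = wait_time(0, t);
      double w1 = wait_time(1, t);
      int d = (w0 <= w1) ? 0 : 1;
      double w = std::min(w0, w1);
      if (t + w < tb) {
        t += w;
        coalesce(d, t, tree);
      } else if (tb < INF) {
        t = tb;
      } else {
        break;  // lone lineages only; nothing left to happen
      }
    }
    // a never-absorbed ancient-exclusive lineage (no modern tips sampled)
    for (int d = 0; d < 2; ++d)
      for (size_t i = 0; i < pop_[d].size(); ++i)
        if (!pop_[d][i].mod && pop_[d][i].anc >= 2)
          pooled_done_ += pop_[d][i].anc;
    int value = (statistic == 0) ? best_ : pooled_done_;
    if (kthr > 0 && !tree) return value >= kthr ? 1 : 0;
    return value;
  }

 private:
  Cfg cg_;
  Xoshiro rng_;
  std::vector<Lineage> pop_[2];
  int best_, pure_total_, pooled_done_, pure_ge2_, next_node_;

  double deme_size(int d, double t) const {
    switch (cg_.variant) {
      case 0:
        return cg_.ne;
      case 1:
        return (t < cg_.t_growth)
                   ? cg_.ne_present * std::exp(-cg_.r_growth * t)
                   : cg_.ne_initial;
      default: {
        if (d == 0) return cg_.ne;  // merged / Old World / ancestral
        double nw = cg_.prop_nw ? cg_.admix_c * cg_.ne : cg_.ne;
        return (t >= cg_.t_bottle) ? nw / cg_.bfac : nw;
      }
    }
  }

  double wait_time(int d, double t) {
    size_t k = pop_[d].size();
    if (k < 2) return std::numeric_limits<double>::infinity();
    double kk = 0.5 * (double)k * (double)(k - 1);
    double e = rng_.expo();
    if (cg_.variant == 1 && t < cg_.t_growth && cg_.r_growth != 0.0) {
      // N(s) = ne_present * exp(-r s): invert the integrated rate exactly
      double r = cg_.r_growth;
      double a = std::exp(r * t) + e * cg_.ne_present * r / kk;
      return std::log(a) / r - t;
    }
    return e * deme_size(d, t) / kk;
  }

  void apply_event(int type, bool *anc_added) {
    if (type == 0) {  // ancient sampling horizon
      int d = (cg_.variant == 2) ? 1 : 0;
      int tip0 = cg_.n_modern;
      for (int i = 0; i < cg_.n_ancient; ++i)
        pop_[d].push_back({1, 0, tip0 + i + 1});
      pure_total_ = cg_.n_ancient;
      if (cg_.n_ancient > 0 && best_ < 1) best_ = 1;
      *anc_added = true;
    } else if (type == 1) {  // Bernoulli(c) assignment to the New World deme
      std::vector<Lineage> keep;
      keep.reserve(pop_[0].size());
      for (size_t i = 0; i < pop_[0].size(); ++i) {
        if (rng_.unif() < cg_.admix_c)
          pop_[1].push_back(pop_[0][i]);
        else
          keep.push_back(pop_[0][i]);
      }
      pop_[0].swap(keep);
    } else if (type == 2) {  // demes merge into the ancestral population
      for (size_t i = 0; i < pop_[1].size(); ++i) pop_[0].push_back(pop_[1][i]);
      pop_[1].clear();
    }
    // type 3 (pure size change) needs no state change: boundaries only
    // truncate the exponential clocks, deme_size() reads the new size.
  }

  void coalesce(int d, double t, TreeOut *tree) {
    int k = (int)pop_[d].size();
    int i = rng_.randint(k);
    int j = rng_.randint(k - 1);
    if (j >= i) ++j;
    Lineage A = pop_[d][i];
    Lineage B = pop_[d][j];
    Lineage m;
    m.anc = A.anc + B.anc;
    m.mod = (uint8_t)(A.mod | B.mod);
    m.node = next_node_++;
    bool pa = (!A.mod && A.anc > 0), pb = (!B.mod && B.anc > 0);
    if (pa && pb) {
      if (m.anc > best_) best_ = m.anc;
      // merged pure clade always has size >= 2
      pure_ge2_ += m.anc - (A.anc >= 2 ? A.anc : 0) - (B.anc >= 2 ? B.anc : 0);
    } else if (pa) {
      pure_total_ -= A.anc;
      if (A.anc >= 2) {
        pure_ge2_ -= A.anc;
        pooled_done_ += A.anc;  // maximal exclusive clade, now absorbed
      }
    } else if (pb) {
      pure_total_ -= B.anc;
      if (B.anc >= 2) {
        pure_ge2_ -= B.anc;
        pooled_done_ += B.anc;
      }
    }
    if (tree) {
      tree->parent.push_back(m.node);
      tree->child.push_back(A.node);
      tree->parent.push_back(m.node);
      tree->child.push_back(B.node);
      tree->itime.push_back(t);
      tree->ideme.push_back(d);
    }
    pop_[d][i] = m;
    pop_[d][j] = pop_[d].back();
    pop_[d].pop_back();
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector sim_stat_batch_cpp(List cfg, int reps, double seed,
                                 double stream_offset, int k, int statistic) {
  Cfg c = parse_cfg(cfg);
  IntegerVector out(reps);
  for (int i = 0; i < reps; ++i) {
    Engine e(c, (uint64_t)seed, (uint64_t)(stream_offset + i));
    out[i] = e.run(k, statistic, 0);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List sim_genealogy_cpp(List cfg, double seed, double stream) {
  Cfg c = parse_cfg(cfg);
  Engine e(c, (uint64_t)seed, (uint64_t)stream);
  TreeOut tr;
  e.run(0, 0, &tr);
  return List::create(_["parent"] = wrap(tr.parent),
                      _["child"] = wrap(tr.child),
                      _["node_time"] = wrap(tr.itime),
                      _["node_deme"] = wrap(tr.ideme));
}
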