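// Seed-and-verify bisulfite alignment in the three-letter reduced alphabet.
//
// The genome is reduced twice (C->T for reads originating from the top
// strand and its PCR complement, G->A for the bottom strand pair) and a
// k-mer seed table is built over both reductions. Each read is tested in
// up to four strand configurations:
//   0 = OT    : CT(read)           vs CT(genome)
//   1 = CTOT  : CT(revcomp(read))  vs CT(genome)
//   2 = CTOB  : GA(read)           vs GA(genome)
//   3 = OB    : GA(revcomp(read))  vs GA(genome)
// The reported hit is the unique minimal-mismatch placement; ties are kept
// but flagged non-unique so callers can discard them.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static std::string reduce_ct(std::string s) {
  for (auto& c : s) if (c == 'C') c = 'T';
  return s;
}

static std::string reduce_ga(std::string s) {
  for (auto& c : s) if (c == 'G') c = 'A';
  return s;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int> > table;

  void build(const std::string& g, int k_) {
    k = k_;
    table.clear();
    if ((int)g.size() < k) return;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t h = 0;
    int run = 0;
    table.reserve(g.size());
    for (int i = 0; i < (int)g.size(); ++i) {
      int c = base_code(g[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) table[h].push_back(i - k + 1);
    }
  }

  const std::vector<int>* lookup(const std::string& s, int off) const {
    uint64_t h = 0;
    for (int i = 0; i < k; ++i) {
      int c = base_code(s[off + i]);
      if (c < 0) return nullptr;
      h = (h << 2) | (uint64_t)c;
    }
    auto it = table.find(h);
    return (it == table.end()) ? nullptr : &it->second;
  }
};

// count mismatches of read placed at pos, aborting once count exceeds bound
static int verify(const std::string& g, const std::string& read, int pos,
                  int bound) {
  int mm = 0;
  const int n = (int)read.size();
  for (int i = 0; i < n; ++i) {
    if (g[pos + i] != read[i]) {
      if (++mm > bound) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_align_bisulfite(std::string genome, CharacterVector reads,
                         bool non_directional, double max_mismatch_rate,
                         int k) {
  const std::string g_ct = reduce_ct(genome);
  const std::string g_ga = reduce_ga(genome);
  SeedIndex idx_ct, idx_ga;
  idx_ct.build(g_ct, k);
  idx_ga.build(g_ga, k);
  const int glen = (int)genome.size();
  const int nreads = reads.size();

  IntegerVector out_pos(nreads, -1);
  IntegerVector out_cfg(nreads, -1);
  IntegerVector out_mm(nreads, NA_INTEGER);
  LogicalVector out_unique(nreads, false);

  std::vector<int> cfg_set;
  if (non_directional) cfg_set = {0, 1, 2, 3};
  else cfg_set = {0, 3};

  std::vector<int> cands;
  for (int r = 0; r < nreads; ++r) {
    const std::string raw = as<std::string>(reads[r]);
    const int len = (int)raw.size();
    if (len < k) continue;
    const std::string rc = revcomp_str(raw);
    const int max_mm = (int)std::floor(max_mismatch_rate * len);

    int best_mm = max_mm + 1, best_pos = -1, best_cfg = -1, best_count = 0;
    for (int cfg : cfg_set) {
      const std::string var =
        (cfg == 0) ? reduce_ct(raw) :
        (cfg == 1) ? reduce_ct(rc)  :
        (cfg == 2) ? reduce_ga(raw) : reduce_ga(rc);
      const SeedIndex& idx = (cfg <= 1) ? idx_ct : idx_ga;
      const std::string& gred = (cfg <= 1) ? g_ct : g_ga;

      cands.clear();
      int offs[3] = {0, (len - k) / 2, len - k};
      for (int s = 0; s < 3; ++s) {
        if (s > 0 && offs[s] == offs[s - 1]) continue;
        const std::vector<int>* hits = idx.lookup(var, offs[s]);
        if (!hits) continue;
        for (int h : *hits) {
          int p = h - offs[s];
          if (p >= 0 && p + len <= glen) cands.push_back(p);
        }
      }
      std::sort(cands.begin(), cands.end());
      // run-length collapse; verify high-multiplicity candidates first so
      // the mismatch bound tightens before the long tail of similar copies
      std::vector<std::pair<int, int> > uniq; // (pos, n_seeds)
      uniq.reserve(cands.size());
      for (size_t i = 0; i < cands.size();) {
        size_t j = i;
        while (j < cands.size() && cands[j] == cands[i]) ++j;
        uniq.push_back(std::make_pair(cands[i], (int)(j - i)));
        i = j;
      }
      int max_cnt = 0;
      for (auto& u : uniq) max_cnt = std::max(max_cnt, u.second);
      for (int cthr = max_cnt; cthr >= 1; --cthr) {
        for (auto& u : uniq) {
          if (u.second != cthr) continue;
          const int p = u.first;
          int bound = std::min(max_mm, best_mm);
          int mm = verify(gred, var, p, bound);
          if (mm > bound) continue;
          if (mm < best_mm) {
            best_mm = mm; best_pos = p; best_cfg = cfg; best_count = 1;
          } else if (mm == best_mm && p != best_pos) {
            // uniqueness is per location: the same position reached in two
            // strand configurations (an unconverted read) is one alignment
            ++best_count;
          }
        }
      }
    }
    if (best_mm <= max_mm) {
      out_pos[r] = best_pos;
      out_cfg[r] = best_cfg;
      out_mm[r] = best_mm;
      out_unique[r] = (best_count == 1);
    }
  }
  return List::create(_["start"] = out_pos, _["config"] = out_cfg,
                      _["mismatches"] = out_mm, _["unique"] = out_unique);
}

// [[Rcpp::export]]
List cpp_extract_calls(std::string genome, CharacterVector reads,
                       IntegerVector start, IntegerVector config) {
  const int glen = (int)genome.size();
  const int n = reads.size();
  std::vector<int> o_read, o_pos, o_context;
  std::vector<int> o_meth;
  o_read.reserve(n * 16);
  o_pos.reserve(n * 16);
  o_context.reserve(n * 16);
  o_meth.reserve(n * 16);

  for (int r = 0; r < n; ++r) {
    const int pos = start[r];
    const int cfg = config[r];
    if (pos < 0 || cfg < 0) continue;
    std::string oriented = as<std::string>(reads[r]);
    if (cfg == 1 || cfg == 3) oriented = revcomp_str(oriented);
    const int len = (int)oriented.size();
    if (pos + len > glen) stop("alignment extends beyond reference bounds");
    const bool top = (cfg <= 1);

    for (int i = 0; i < len; ++i) {
      const int p = pos + i;
      if (top) {
        if (genome[p] != 'C') continue;
        int context;
        if (p + 1 < glen && genome[p + 1] == 'G') context = 1;
        else if (p + 2 < glen && genome[p + 2] == 'G') context = 2;
        else context = 3;
        const char b = oriented[i];
        int meth;
        if (b == 'C') meth = 1;
        else if (b == 'T') meth = 0;
        else continue;
        o_read.push_back(r + 1);
        o_pos.push_back(p);
        o_context.push_back(context);
        o_meth.push_back(meth);
      } else {
        if (genome[p] != 'G') continue;
        int context, report;
        if (p - 1 >= 0 && genome[p - 1] == 'C') { context = 1; report = p - 1; }
        else if (p - 2 >= 0 && genome[p - 2] == 'C') { context = 2; report = p; }
        else { context = 3; report = p; }
        const char b = oriented[i];
        int meth;
        if (b == 'G') meth = 1;
        else if (b == 'A') meth = 0;
        else continue;
        o_read.push_back(r + 1);
        o_pos.push_back(report);
        o_context.push_back(context);
        o_meth.push_back(meth);
      }
    }
  }
  return List::create(_["read_index"] = wrap(o_read), _["pos"] = wrap(o_pos),
                      _["context"] = wrap(o_context), _["meth"] = wrap(o_meth));
}
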