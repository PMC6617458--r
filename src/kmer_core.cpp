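#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Standard genetic code, codon index = 16*b1 + 4*b2 + b3 with T=0,C=1,A=2,G=3.
static const char CODE[] =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline int base_idx(char c) {
  switch (c) {
    case 'T': case 't': case 'U': case 'u': return 0;
    case 'C': case 'c': return 1;
    case 'A': case 'a': return 2;
    case 'G': case 'g': return 3;
    default: return -1; // ambiguity code -> unknown residue
  }
}

static inline bool is_iupac(char c) {
  switch (c) {
    case 'A': case 'C': case 'G': case 'T': case 'U': case 'N':
    case 'R': case 'Y': case 'S': case 'W': case 'K': case 'M':
    case 'B': case 'D': case 'H': case 'V':
    case 'a': case 'c': case 'g': case 't': case 'u': case 'n':
    case 'r': case 'y': case 's': case 'w': case 'k': case 'm':
    case 'b': case 'd': case 'h': case 'v':
      return true;
    default: return false;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': case 'U': case 'u': return 'A';
    case 'N': case 'n': return 'N';
    case 'R': case 'r': return 'Y';
    case 'Y': case 'y': return 'R';
    case 'S': case 's': return 'S';
    case 'W': case 'w': return 'W';
    case 'K': case 'k': return 'M';
    case 'M': case 'm': return 'K';
    case 'B': case 'b': return 'V';
    case 'V': case 'v': return 'B';
    case 'D': case 'd': return 'H';
    case 'H': case 'h': return 'D';
    default: return 'N';
  }
}

static std::string translate_frame(const std::string& s, size_t start) {
  std::string out;
  if (s.size() < start + 3) return out;
  size_t n_codons = (s.size() - start) / 3;
  out.reserve(n_codons);
  for (size_t i = 0; i < n_codons; ++i) {
    int a = base_idx(s[start + 3 * i]);
    int b = base_idx(s[start + 3 * i + 1]);
    int c = base_idx(s[start + 3 * i + 2]);
    if (a < 0 || b < 0 || c < 0) out.push_back('X');
    else out.push_back(CODE[16 * a + 4 * b + c]);
  }
  return out;
}

static std::string revcomp_one(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

static void check_iupac(const std::string& s) {
  for (size_t i = 0; i < s.size(); ++i)
    if (!is_iupac(s[i]))
      stop("invalid nucleotide character '%s' at position %d",
           std::string(1, s[i]).c_str(), (int)(i + 1));
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector dna) {
  CharacterVector out(dna.size());
  for (R_xlen_t i = 0; i < dna.size(); ++i) {
    std::string s = as<std::string>(dna[i]);
    check_iupac(s);
    out[i] = revcomp_one(s);
  }
  return out;
}

// Six frames: +1,+2,+3 on the forward strand then -1,-2,-3 on the
// reverse complement.
static std::vector<std::string> six_frames(const std::string& s) {
  std::vector<std::string> fr(6);
  fr[0] = translate_frame(s, 0);
  fr[1] = translate_frame(s, 1);
  fr[2] = translate_frame(s, 2);
  std::string rc = revcomp_one(s);
  fr[3] = translate_frame(rc, 0);
  fr[4] = translate_frame(rc, 1);
  fr[5] = translate_frame(rc, 2);
  return fr;
}

// [[Rcpp::export(name = ".six_frame_cpp")]]
CharacterVector six_frame_cpp(std::string dna) {
  check_iupac(dna);
  std::vector<std::string> fr = six_frames(dna);
  return wrap(fr);
}

static inline bool std_aa(char c) {
  switch (c) {
    case 'A': case 'C': case 'D': case 'E': case 'F': case 'G': case 'H':
    case 'I': case 'K': case 'L': case 'M': case 'N': case 'P': case 'Q':
    case 'R': case 'S': case 'T': case 'V': case 'W': case 'Y':
      return true;
    default: return false; // '*', 'X', B J O U Z break windows
  }
}

// depth of each node given 1-based parent index vector; root has parent==self
static std::vector<int> node_depths(const IntegerVector& parent) {
  int n = parent.size();
  std::vector<int> depth(n, -1);
  for (int i = 0; i < n; ++i) {
    if (depth[i] >= 0) continue;
    std::vector<int> chain;
    int u = i;
    while (depth[u] < 0 && parent[u] - 1 != u) {
      chain.push_back(u);
      u = parent[u] - 1;
    }
    int d = (depth[u] >= 0) ? depth[u] : 0;
    for (int j = (int)chain.size() - 1; j >= 0; --j) depth[chain[j]] = ++d;
  }
  return depth;
}

static int lca_pair(int a, int b, const IntegerVector& parent,
                    const std::vector<int>& depth) {
  while (depth[a] > depth[b]) a = parent[a] - 1;
  while (depth[b] > depth[a]) b = parent[b] - 1;
  while (a != b) { a = parent[a] - 1; b = parent[b] - 1; }
  return a;
}

// Build k-mer -> LCA(node index) map over reference proteins.
// prot: peptide sequences; node_idx: 1-based tree positions per protein.
// [[Rcpp::export(name = ".build_index_cpp")]]
List build_index_cpp(CharacterVector prot, IntegerVector node_idx,
                     IntegerVector parent, int k) {
  std::vector<int> depth = node_depths(parent);
  std::unordered_map<std::string, int> idx; // value: 0-based node position
  for (R_xlen_t p = 0; p < prot.size(); ++p) {
    std::string s = as<std::string>(prot[p]);
    int v = node_idx[p] - 1;
    if ((int)s.size() < k) continue;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j)
        if (!std_aa(s[i + j])) { ok = false; break; }
      if (!ok) continue;
      std::string key = s.substr(i, k);
      std::unordered_map<std::string, int>::iterator it = idx.find(key);
      if (it == idx.end()) idx[key] = v;
      else it->second = lca_pair(it->second, v, parent, depth);
    }
  }
  CharacterVector keys(idx.size());
  IntegerVector vals(idx.size());
  R_xlen_t i = 0;
  for (std::unordered_map<std::string, int>::iterator it = idx.begin();
       it != idx.end(); ++it, ++i) {
    keys[i] = it->first;
    vals[i] = it->second + 1;
  }
  return List::create(_["kmer"] = keys, _["node_idx"] = vals);
}

// Offsets (1-based) and node indices of index hits over one peptide.
// [[Rcpp::export(name = ".query_kmers_cpp")]]
List query_kmers_cpp(std::string peptide, CharacterVector keys,
                     IntegerVector vals, int k) {
  std::unordered_map<std::string, int> idx;
  idx.reserve(keys.size() * 2 + 1);
  for (R_xlen_t i = 0; i < keys.size(); ++i)
    idx[as<std::string>(keys[i])] = vals[i];
  std::vector<int> off, hit;
  if ((int)peptide.size() >= k) {
    for (size_t i = 0; i + k <= peptide.size(); ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j)
        if (!std_aa(peptide[i + j])) { ok = false; break; }
      if (!ok) continue;
      std::unordered_map<std::string, int>::iterator it =
        idx.find(peptide.substr(i, k));
      if (it != idx.end()) { off.push_back((int)i + 1); hit.push_back(it->second); }
    }
  }
  return List::create(_["offset"] = wrap(off), _["node_idx"] = wrap(hit));
}

// Descent consensus: drop root hits; climb-accumulate subtree weights; from
// the root repeatedly move to the child holding >= f of the current weight.
static int consensus_nodes(const std::vector<int>& hits,
                           const IntegerVector& parent, int root0, double f) {
  std::unordered_map<int, double> w;      // subtree weight per node
  std::unordered_map<int, int> par_of;    // parent links restricted to hit paths
  double total = 0.0;
  for (size_t i = 0; i < hits.size(); ++i) {
    int u = hits[i];
    if (u == root0) continue; // filtered
    total += 1.0;
    int v = u;
    while (true) {
      w[v] += 1.0;
      int pv = parent[v] - 1;
      par_of[v] = pv;
      if (pv == v) break;
      v = pv;
    }
  }
  if (total <= 0.0) return -1; // unclassified
  int cur = root0;
  while (true) {
    double wcur = (cur == root0) ? total : w[cur];
    int next = -1;
    for (std::unordered_map<int, double>::iterator it = w.begin();
         it != w.end(); ++it) {
      if (it->first == cur) continue;
      std::unordered_map<int, int>::iterator p = par_of.find(it->first);
      if (p == par_of.end() || p->second != cur) continue;
      if (it->second >= f * wcur - 1e-12) { next = it->first; break; }
    }
    if (next < 0) return cur;
    cur = next;
  }
}

// [[Rcpp::export(name = ".consensus_cpp")]]
int consensus_cpp(IntegerVector hit_idx, IntegerVector parent, int root_idx,
                  double f) {
  std::vector<int> hits(hit_idx.begin(), hit_idx.end());
  for (size_t i = 0; i < hits.size(); ++i) hits[i] -= 1;
  int res = consensus_nodes(hits, parent, root_idx - 1, f);
  return res < 0 ? NA_INTEGER : res + 1;
}

// amino-acid code 0..19, -1 for stops/non-standard residues
static inline int aa_code(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    default: return -1;
  }
}

// pack a k-window (k <= 12) into a 5-bit-per-residue integer key
static inline bool pack_window(const char* p, int k, uint64_t& key) {
  uint64_t acc = 0;
  for (int j = 0; j < k; ++j) {
    int c = aa_code(p[j]);
    if (c < 0) return false;
    acc = (acc << 5) | (uint64_t)c;
  }
  key = acc;
  return true;
}

// Classify many reads: translate six frames, pool index hits, consensus.
// [[Rcpp::export(name = ".classify_reads_cpp")]]
List classify_reads_cpp(CharacterVector reads, CharacterVector keys,
                        IntegerVector vals, IntegerVector parent,
                        int root_idx, double f, int k) {
  if (k > 12) stop("packed classification supports k <= 12");
  std::unordered_map<uint64_t, int> idx;
  idx.reserve(keys.size() * 2 + 1);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    const char* s = CHAR(STRING_ELT(keys, i));
    uint64_t key;
    if (pack_window(s, k, key)) idx[key] = vals[i] - 1;
  }
  int root0 = root_idx - 1;
  R_xlen_t n = reads.size();
  IntegerVector out_idx(n), n_hits(n), n_windows(n);
  std::vector<int> hits;
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(reads[r]);
    check_iupac(s);
    std::vector<std::string> fr = six_frames(s);
    hits.clear();
    int nw = 0;
    for (int fi = 0; fi < 6; ++fi) {
      const std::string& pep = fr[fi];
      if ((int)pep.size() < k) continue;
      const char* p = pep.c_str();
      for (size_t i = 0; i + k <= pep.size(); ++i) {
        uint64_t key;
        if (!pack_window(p + i, k, key)) continue;
        ++nw;
        std::unordered_map<uint64_t, int>::iterator it = idx.find(key);
        if (it != idx.end()) hits.push_back(it->second);
      }
    }
    n_windows[r] = nw;
    n_hits[r] = (int)hits.size();
    int res;
    if (hits.empty()) res = -1;
    else {
      // fast path: unanimous non-root hits need no descent bookkeeping
      bool same = true;
      for (size_t i = 1; i < hits.size(); ++i)
        if (hits[i] != hits[0]) { same = false; break; }
      if (same) res = (hits[0] == root0) ? -1 : hits[0];
      else res = consensus_nodes(hits, parent, root0, f);
    }
    out_idx[r] = res < 0 ? NA_INTEGER : res + 1;
  }
  return List::create(_["node_idx"] = out_idx, _["n_hits"] = n_hits,
                      _["n_windows"] = n_windows);
}
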