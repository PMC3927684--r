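#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <fstream>
#include <cstdio>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Watson-Crick complement; 0 marks an invalid base.
static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;
  }
}

static std::string revcomp_str(const std::string& s) {
  const size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = comp(s[n - 1 - i]);
    if (c == 0) stop("non-ACGT character '%s' in sequence", std::string(1, s[n - 1 - i]));
    out[i] = c;
  }
  return out;
}

// true iff the reverse complement of s[0..k) is strictly smaller (byte order,
// which on {A,C,G,T} equals the A<C<G<T lexicographic order).
static inline bool rc_is_smaller(const char* s, int k) {
  for (int i = 0; i < k; ++i) {
    char rc = comp(s[k - 1 - i]);
    if (rc < s[i]) return true;
    if (rc > s[i]) return false;
  }
  return false;
}

static inline std::string canonical_window(const char* s, int k) {
  if (rc_is_smaller(s, k)) {
    std::string out(k, 'N');
    for (int i = 0; i < k; ++i) out[i] = comp(s[k - 1 - i]);
    return out;
  }
  return std::string(s, s + k);
}

static void check_acgt(const std::string& s) {
  for (char c : s)
    if (comp(c) == 0) stop("non-ACGT character '%s' in sequence", std::string(1, c));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    if (s.empty()) stop("empty sequence");
    out[i] = revcomp_str(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    if (s.empty()) stop("empty sequence");
    check_acgt(s);
    out[i] = canonical_window(s.data(), (int) s.size());
  }
  return out;
}

typedef std::unordered_map<std::string, int64_t> count_map;

static List map_to_sorted_list(count_map& counts, double total_tokens) {
  std::vector<const std::string*> keys;
  keys.reserve(counts.size());
  for (count_map::const_iterator it = counts.begin(); it != counts.end(); ++it)
    keys.push_back(&it->first);
  std::sort(keys.begin(), keys.end(),
            [](const std::string* a, const std::string* b) { return *a < *b; });
  R_xlen_t m = (R_xlen_t) keys.size();
  CharacterVector kmer(m);
  NumericVector cnt(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmer[i] = *keys[i];
    cnt[i] = (double) counts[*keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = cnt,
                      _["total_tokens"] = total_tokens);
}

// [[Rcpp::export]]
List cpp_count_kmers_mem(CharacterVector parts, int k) {
  if (k < 1) stop("k must be >= 1");
  count_map counts;
  double total = 0;
  for (R_xlen_t p = 0; p < parts.size(); ++p) {
    std::string s = as<std::string>(parts[p]);
    check_acgt(s);
    if ((int) s.size() < k) continue;
    const char* cs = s.data();
    int nw = (int) s.size() - k + 1;
    for (int i = 0; i < nw; ++i) {
      ++counts[canonical_window(cs + i, k)];
      ++total;
    }
  }
  return map_to_sorted_list(counts, total);
}

// FNV-1a: deterministic across platforms, unlike std::hash.
static inline uint64_t fnv1a(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char) s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

// Two-pass disk-bucketed counting: tokens are spilled to per-bucket text
// files keyed by a hash of the canonical k-mer, then each bucket is counted
// independently (bounded memory: one bucket's distinct types at a time).
// [[Rcpp::export]]
List cpp_count_kmers_disk(CharacterVector parts, int k, int n_buckets,
                          std::string workdir) {
  if (k < 1) stop("k must be >= 1");
  if (n_buckets < 1) stop("n_buckets must be >= 1");
  std::vector<std::string> paths(n_buckets);
  std::vector<std::ofstream> outs(n_buckets);
  for (int b = 0; b < n_buckets; ++b) {
    paths[b] = workdir + "/bucket_" + std::to_string(b) + ".tokens";
    outs[b].open(paths[b].c_str(), std::ios::out | std::ios::trunc);
    if (!outs[b].is_open()) stop("cannot open spill file in '%s'", workdir);
  }
  double total = 0;
  for (R_xlen_t p = 0; p < parts.size(); ++p) {
    std::string s = as<std::string>(parts[p]);
    check_acgt(s);
    if ((int) s.size() < k) continue;
    const char* cs = s.data();
    int nw = (int) s.size() - k + 1;
    for (int i = 0; i < nw; ++i) {
      std::string can = canonical_window(cs + i, k);
      std::ofstream& o = outs[fnv1a(can) % (uint64_t) n_buckets];
      o << can << '\n';
      if (!o) stop("write failure on spill file (disk full?)");
      ++total;
    }
  }
  for (int b = 0; b < n_buckets; ++b) outs[b].close();

  std::vector<std::string> all_keys;
  std::vector<int64_t> all_counts;
  for (int b = 0; b < n_buckets; ++b) {
    count_map counts;
    std::ifstream in(paths[b].c_str());
    std::string line;
    while (std::getline(in, line))
      if (!line.empty()) ++counts[line];
    in.close();
    std::remove(paths[b].c_str());
    for (count_map::const_iterator it = counts.begin(); it != counts.end(); ++it) {
      all_keys.push_back(it->first);
      all_counts.push_back(it->second);
    }
  }
  // buckets hold disjoint key sets; a global sort restores canonical order
  std::vector<size_t> idx(all_keys.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    return all_keys[a] < all_keys[b];
  });
  R_xlen_t m = (R_xlen_t) idx.size();
  CharacterVector kmer(m);
  NumericVector cnt(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmer[i] = all_keys[idx[i]];
    cnt[i] = (double) all_counts[idx[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = cnt,
                      _["total_tokens"] = total);
}

// Scan partitions for windows whose canonical form is in `members`; report
// genome coordinates (partition start offset + window offset, 0-based).
// [[Rcpp::export]]
List cpp_locate(CharacterVector parts, CharacterVector chroms,
                NumericVector part_starts, int k, CharacterVector members) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_set<std::string> want;
  for (R_xlen_t i = 0; i < members.size(); ++i)
    want.insert(as<std::string>(members[i]));
  std::vector<int> hit_part;
  std::vector<double> hit_pos;
  std::vector<std::string> hit_kmer;
  for (R_xlen_t p = 0; p < parts.size(); ++p) {
    std::string s = as<std::string>(parts[p]);
    check_acgt(s);
    if ((int) s.size() < k) continue;
    const char* cs = s.data();
    int nw = (int) s.size() - k + 1;
    for (int i = 0; i < nw; ++i) {
      std::string can = canonical_window(cs + i, k);
      if (want.count(can)) {
        hit_part.push_back((int) p);
        hit_pos.push_back(part_starts[p] + i);
        hit_kmer.push_back(can);
      }
    }
  }
  R_xlen_t m = (R_xlen_t) hit_part.size();
  CharacterVector chrom(m), kmer(m);
  NumericVector pos(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    chrom[i] = chroms[hit_part[i]];
    pos[i] = hit_pos[i];
    kmer[i] = hit_kmer[i];
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos, _["kmer"] = kmer);
}
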