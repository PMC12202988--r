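// Core k-mer machinery: 2-bit packed canonical encoding (A=0,C=1,G=2,T=3),
// an invertible 64-bit mixer, hash-based counting, middle-base pair search,
// support-length extension and sketch counting. Codes cross the R boundary
// as doubles, exact for k <= 25 (2k bits < 53).
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// encode uppercase ACGT string; returns false on ambiguous base
static bool encode_kmer(const char* s, int k, uint64_t& code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t canon_code(uint64_t code, int k) {
  uint64_t rc = revcomp_code(code, k);
  return code < rc ? code : rc;
}

// ---- invertible 64-bit hash (murmur3 finalizer; inverses derived at runtime)

static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 33;
  x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33;
  x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}

// multiplicative inverse of odd a mod 2^64 (Newton iteration)
static uint64_t inv64(uint64_t a) {
  uint64_t x = a; // 3 bits correct
  for (int i = 0; i < 6; ++i) x *= 2ULL - a * x;
  return x;
}

static inline uint64_t unmix64(uint64_t x) {
  static const uint64_t inv1 = inv64(0xc4ceb9fe1a85ec53ULL);
  static const uint64_t inv2 = inv64(0xff51afd7ed558ccdULL);
  x ^= x >> 33;
  x *= inv1;
  x ^= x >> 33;
  x *= inv2;
  x ^= x >> 33;
  return x;
}

static std::string u64_to_hex(uint64_t x) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

static uint64_t hex_to_u64(const std::string& s) {
  uint64_t x = 0;
  for (char c : s) {
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else break;
    x = (x << 4) | (uint64_t)d;
  }
  return x;
}

// [[Rcpp::export]]
CharacterVector cpp_hash_hex(CharacterVector hex) {
  int n = hex.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = u64_to_hex(mix64(hex_to_u64(as<std::string>(hex[i]))));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_unhash_hex(CharacterVector hex) {
  int n = hex.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = u64_to_hex(unmix64(hex_to_u64(as<std::string>(hex[i]))));
  return out;
}

// hash the integers 0..n-1, returned as hex (distinctness checks)
// [[Rcpp::export]]
CharacterVector cpp_hash_range(int n) {
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = u64_to_hex(mix64((uint64_t)i));
  return out;
}

// ---- canonicalization exposed to R

// [[Rcpp::export]]
List cpp_canonical(CharacterVector seqs, int k) {
  int n = seqs.size();
  NumericVector code(n);
  CharacterVector kmer(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    uint64_t c;
    if ((int)LENGTH(STRING_ELT(seqs, i)) != k || !encode_kmer(s, k, c)) {
      ok[i] = false; code[i] = NA_REAL; kmer[i] = NA_STRING;
      continue;
    }
    uint64_t cc = canon_code(c, k);
    ok[i] = true;
    code[i] = (double)cc;
    kmer[i] = decode_kmer(cc, k);
  }
  return List::create(_["code"] = code, _["kmer"] = kmer, _["ok"] = ok);
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int k) {
  int n = codes.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = decode_kmer((uint64_t)codes[i], k);
  return out;
}

// ---- counting

struct KCounter {
  std::unordered_map<uint64_t, uint32_t> tab;
  double n_windows = 0;
  int k;
  explicit KCounter(int k_) : k(k_) { tab.reserve(1 << 20); }
  void add_seq(const char* s, int len) {
    if (len < k) return;
    uint64_t code = 0;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    int run = 0; // valid bases accumulated
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        ++tab[canon_code(code, k)];
        n_windows += 1;
      }
    }
  }
};

// external-pointer-free: accumulate over possibly multiple calls via R side
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  KCounter kc(k);
  for (int i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    if (el == NA_STRING) stop("malformed record at index %d (NA sequence)", i + 1);
    kc.add_seq(CHAR(el), LENGTH(el));
  }
  size_t n = kc.tab.size();
  std::vector<std::pair<uint64_t, uint32_t> > v(kc.tab.begin(), kc.tab.end());
  std::sort(v.begin(), v.end());
  NumericVector code(n);
  IntegerVector count(n);
  for (size_t i = 0; i < n; ++i) {
    code[i] = (double)v[i].first;
    count[i] = (int)v[i].second;
  }
  return List::create(_["code"] = code, _["count"] = count,
                      _["n_windows"] = kc.n_windows);
}

// merge two sorted (code, count) tables
// [[Rcpp::export]]
List cpp_merge_tables(NumericVector c1, IntegerVector n1,
                      NumericVector c2, IntegerVector n2) {
  size_t i = 0, j = 0, a = c1.size(), b = c2.size();
  std::vector<double> code; code.reserve(a + b);
  std::vector<int> cnt; cnt.reserve(a + b);
  while (i < a || j < b) {
    if (j >= b || (i < a && c1[i] < c2[j])) { code.push_back(c1[i]); cnt.push_back(n1[i]); ++i; }
    else if (i >= a || c2[j] < c1[i])       { code.push_back(c2[j]); cnt.push_back(n2[j]); ++j; }
    else { code.push_back(c1[i]); cnt.push_back(n1[i] + n2[j]); ++i; ++j; }
  }
  return List::create(_["code"] = wrap(code), _["count"] = wrap(cnt));
}

// ---- candidate pair search (middle-base difference, orientation-aware)

static inline bool in_sorted(const NumericVector& codes, double x) {
  return std::binary_search(codes.begin(), codes.end(), x);
}

// [[Rcpp::export]]
DataFrame cpp_find_pairs(NumericVector codes, int k) {
  // codes: sorted canonical codes of the heterozygous set
  int mid = (k - 1) / 2;
  std::vector<double> codeA, codeB;
  std::vector<std::string> orA, orB;
  int n = codes.size();
  for (int i = 0; i < n; ++i) {
    uint64_t a = (uint64_t)codes[i];
    std::string s = decode_kmer(a, k); // canonical string (<= its revcomp)
    int mb = base2bits(s[mid]);
    for (int b = 0; b < 4; ++b) {
      if (b == mb) continue;
      std::string t = s;
      t[mid] = BITS2BASE[b];
      uint64_t tc;
      encode_kmer(t.c_str(), k, tc);
      uint64_t cc = canon_code(tc, k);
      if ((double)cc <= (double)a) continue;  // dedup: record once, from smaller code
      if (!in_sorted(codes, (double)cc)) continue;
      codeA.push_back((double)a);
      codeB.push_back((double)cc);
      orA.push_back(s);
      orB.push_back(t);
    }
  }
  return DataFrame::create(_["codeA"] = wrap(codeA), _["codeB"] = wrap(codeB),
                           _["orientedA"] = wrap(orA), _["orientedB"] = wrap(orB),
                           _["stringsAsFactors"] = false);
}

// ---- support-length extension

// [[Rcpp::export]]
List cpp_support(CharacterVector orientedA, CharacterVector orientedB,
                 NumericVector hetCodes, int k) {
  int mid = (k - 1) / 2, n = orientedA.size();
  IntegerVector support(n);
  CharacterVector ctxA(n), ctxB(n);
  for (int p = 0; p < n; ++p) {
    std::string RA = as<std::string>(orientedA[p]);
    std::string RB = as<std::string>(orientedB[p]);
    int left = 0, right = 0;
    // extend right: drop first base of last window, append candidate
    while (right < mid) {
      int nok = 0; char keep = 'A';
      for (int b = 0; b < 4; ++b) {
        std::string wA = RA.substr(RA.size() - (k - 1)) + BITS2BASE[b];
        std::string wB = RB.substr(RB.size() - (k - 1)) + BITS2BASE[b];
        uint64_t ca, cb;
        encode_kmer(wA.c_str(), k, ca);
        encode_kmer(wB.c_str(), k, cb);
        if (in_sorted(hetCodes, (double)canon_code(ca, k)) &&
            in_sorted(hetCodes, (double)canon_code(cb, k))) {
          ++nok; keep = BITS2BASE[b];
        }
      }
      if (nok != 1) break;  // no extension, or ambiguous -> stop
      RA.push_back(keep); RB.push_back(keep); ++right;
    }
    while (left < mid) {
      int nok = 0; char keep = 'A';
      for (int b = 0; b < 4; ++b) {
        std::string wA = std::string(1, BITS2BASE[b]) + RA.substr(0, k - 1);
        std::string wB = std::string(1, BITS2BASE[b]) + RB.substr(0, k - 1);
        uint64_t ca, cb;
        encode_kmer(wA.c_str(), k, ca);
        encode_kmer(wB.c_str(), k, cb);
        if (in_sorted(hetCodes, (double)canon_code(ca, k)) &&
            in_sorted(hetCodes, (double)canon_code(cb, k))) {
          ++nok; keep = BITS2BASE[b];
        }
      }
      if (nok != 1) break;
      RA.insert(RA.begin(), keep); RB.insert(RB.begin(), keep); ++left;
    }
    support[p] = 1 + left + right;
    ctxA[p] = RA;
    ctxB[p] = RB;
  }
  return List::create(_["support"] = support, _["ctxA"] = ctxA, _["ctxB"] = ctxB);
}

// ---- counting a sample against a sketch index

// codes must be sorted; returns per-code hit increments for this batch
// [[Rcpp::export]]
List cpp_count_against(CharacterVector seqs, NumericVector codes, int k) {
  int m = codes.size();
  IntegerVector hits(m);
  double n_windows = 0, n_bases = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (int i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    if (el == NA_STRING) continue;
    const char* s = CHAR(el);
    int len = LENGTH(el);
    n_bases += len;
    uint64_t code = 0;
    int run = 0;
    for (int j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        n_windows += 1;
        double cc = (double)canon_code(code, k);
        NumericVector::iterator it =
          std::lower_bound(codes.begin(), codes.end(), cc);
        if (it != codes.end() && *it == cc) ++hits[it - codes.begin()];
      }
    }
  }
  return List::create(_["hits"] = hits, _["n_windows"] = n_windows,
                      _["n_bases"] = n_bases);
}

// ---- read simulation (uses R's RNG; deterministic under set.seed)

// [[Rcpp::export]]
CharacterVector cpp_sim_reads(std::string hap1, std::string hap2, int n_reads,
                              int read_len, double error_rate) {
  RNGScope scope;
  CharacterVector out(n_reads);
  int L1 = hap1.size(), L2 = hap2.size();
  std::string read(read_len, 'A');
  for (int i = 0; i < n_reads; ++i) {
    bool h2 = unif_rand() < 0.5;
    const std::string& hap = h2 ? hap2 : hap1;
    int L = h2 ? L2 : L1;
    int start = (int)(unif_rand() * (L - read_len + 1));
    if (start > L - read_len) start = L - read_len;
    read.assign(hap, start, read_len);
    if (error_rate > 0) {
      for (int j = 0; j < read_len; ++j) {
        if (unif_rand() < error_rate) {
          int b = base2bits(read[j]);
          int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
          read[j] = BITS2BASE[nb];
        }
      }
    }
    if (unif_rand() < 0.5) { // minus strand
      std::string rc(read_len, 'A');
      for (int j = 0; j < read_len; ++j) {
        int b = base2bits(read[read_len - 1 - j]);
        rc[j] = BITS2BASE[3 - b];
      }
      out[i] = rc;
    } else {
      out[i] = read;
    }
  }
  return out;
}

// random genome string under R RNG
// [[Rcpp::export]]
std::string cpp_random_genome(int len) {
  RNGScope scope;
  std::string g(len, 'A');
  for (int i = 0; i < len; ++i) g[i] = BITS2BASE[(int)(unif_rand() * 4) & 3];
  return g;
}
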