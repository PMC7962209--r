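#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Portable seedable RNG: splitmix64 expands the user seed into the state of
// xoshiro256++ (Blackman & Vigna).  Pure 64-bit integer arithmetic, so the
// shuffled space is byte-identical across platforms and compilers.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // unbiased draw in [0, bound) by rejection on the modulo threshold
  uint64_t bounded(uint64_t bound) {
    const uint64_t threshold = (0ULL - bound) % bound;
    for (;;) {
      uint64_t r = next();
      if (r >= threshold) return r % bound;
    }
  }
};

// Fisher-Yates with descending index: perm[d] is the shuffled rank of
// dimension d (the inverse of the shuffled identity array).
// [[Rcpp::export]]
IntegerVector fisher_yates_ranks(double n_, int seed) {
  const int64_t n = (int64_t)n_;
  if (n < 1) stop("n must be >= 1");
  std::vector<int> v((size_t)n);
  for (int64_t i = 0; i < n; ++i) v[(size_t)i] = (int)i;
  Xoshiro256pp rng((uint64_t)(uint32_t)seed);
  for (int64_t i = n - 1; i > 0; --i) {
    uint64_t j = rng.bounded((uint64_t)i + 1);
    std::swap(v[(size_t)i], v[(size_t)j]);
  }
  // invert: v[pos] = dimension at shuffled position pos
  IntegerVector ranks((R_xlen_t)n);
  int *rp = INTEGER(ranks);
  for (int64_t pos = 0; pos < n; ++pos) rp[v[(size_t)pos]] = (int)pos;
  return ranks;
}

// FNV-1a over the rank table plus (w, a); hex string used as the space
// fingerprint so incompatible sketches are refused loudly.
// [[Rcpp::export]]
std::string space_checksum(IntegerVector perm, int w, int a) {
  uint64_t h = 0xCBF29CE484222325ULL;
  const uint64_t prime = 0x100000001B3ULL;
  auto mix = [&](uint64_t x) {
    for (int b = 0; b < 8; ++b) {
      h ^= (x >> (8 * b)) & 0xFF;
      h *= prime;
    }
  };
  mix((uint64_t)w);
  mix((uint64_t)a);
  const int *p = INTEGER(perm);
  for (R_xlen_t i = 0; i < perm.size(); ++i) mix((uint64_t)(uint32_t)p[i]);
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// ---------------------------------------------------------------------------
// k-mer scanning.  Windows are packed 2 bits per base (A=0,C=1,G=2,T=3) with
// the first base in the most significant position, so numeric order of packed
// words equals lexicographic order of the k-mers.  Any non-ACGT character
// breaks the current window run.
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct PatternInfo {
  int k, w;
  bool contiguous;      // all 1s form one run [s1, e1)
  int s1, e1;           // run bounds when contiguous
  std::vector<int> sel; // positions of 1s
  std::vector<int> unsel;
};

static PatternInfo parse_pattern(const std::string &pat) {
  PatternInfo pi;
  pi.k = (int)pat.size();
  pi.w = 0;
  pi.s1 = -1;
  pi.e1 = -1;
  for (int i = 0; i < pi.k; ++i) {
    if (pat[i] == '1') {
      pi.sel.push_back(i);
      ++pi.w;
    } else if (pat[i] == '0') {
      pi.unsel.push_back(i);
    } else {
      stop("selection pattern must contain only '0' and '1'");
    }
  }
  pi.contiguous = false;
  if (pi.w > 0) {
    pi.s1 = pi.sel.front();
    pi.e1 = pi.sel.back() + 1;
    pi.contiguous = (pi.e1 - pi.s1 == pi.w);
  }
  return pi;
}

// split packed k-mer word into (dim = selected substring, p0 = unselected)
static inline void split_word(uint64_t word, const PatternInfo &pi,
                              uint64_t &dim, uint64_t &p0) {
  const int k = pi.k;
  if (pi.contiguous) {
    const int tail = k - pi.e1;                   // bases after the 1-run
    const uint64_t wmask = (pi.w == 32) ? ~0ULL : ((1ULL << (2 * pi.w)) - 1);
    dim = (word >> (2 * tail)) & wmask;
    const uint64_t hi = word >> (2 * (k - pi.s1));
    const uint64_t lomask = (tail == 0) ? 0ULL : ((1ULL << (2 * tail)) - 1);
    p0 = (hi << (2 * tail)) | (word & lomask);
  } else if (pi.w == 0) {
    dim = 0;
    p0 = word;
  } else {
    dim = 0;
    for (int i : pi.sel) dim = (dim << 2) | ((word >> (2 * (k - 1 - i))) & 3ULL);
    p0 = 0;
    for (int i : pi.unsel) p0 = (p0 << 2) | ((word >> (2 * (k - 1 - i))) & 3ULL);
  }
}

template <typename EMIT>
static double scan_sequences(CharacterVector seqs, const PatternInfo &pi,
                             bool canonical, EMIT emit) {
  const int k = pi.k;
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  double total = 0;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *s = CHAR(STRING_ELT(seqs, si));
    uint64_t fw = 0, rw = 0;
    int run = 0;
    for (const char *p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) {
        run = 0;
        fw = rw = 0;
        continue;
      }
      fw = ((fw << 2) | (uint64_t)c) & kmask;
      rw = (rw >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        total += 1;
        uint64_t word = (canonical && rw < fw) ? rw : fw;
        emit(word);
      }
    }
  }
  return total;
}

static NumericVector sorted_codes(std::vector<uint64_t> &v) {
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  NumericVector out((R_xlen_t)v.size());
  for (size_t i = 0; i < v.size(); ++i) out[(R_xlen_t)i] = (double)v[i];
  return out;
}

// Sketch: keep k-mers whose selected substring falls in the chosen subspace,
// recode as p0(K) concatenated with the in-subspace rank of p1(K).
// Occurrence counts are kept only for selected k-mers (memory ~ sketch size).
// [[Rcpp::export]]
List sketch_codes(CharacterVector seqs, std::string pattern, IntegerVector perm,
                  int a, int chosen, int min_occ, bool canonical) {
  PatternInfo pi = parse_pattern(pattern);
  if (pi.k > 26) stop("k-mer length above 26 is not supported (code width)");
  if (a > pi.w) stop("partition exponent a must not exceed the pattern weight");
  if ((double)perm.size() != std::pow(4.0, pi.w))
    stop("rank table size does not match the pattern weight");
  const int rb = 2 * (pi.w - a); // rank bits
  const uint64_t rmask = (rb == 0) ? 0ULL : ((1ULL << rb) - 1);
  const int *pp = INTEGER(perm);
  std::vector<uint64_t> keep;
  std::unordered_map<uint64_t, uint32_t> counts;
  const bool filter = min_occ > 1;
  double total = scan_sequences(seqs, pi, canonical, [&](uint64_t word) {
    uint64_t dim, p0;
    split_word(word, pi, dim, p0);
    uint64_t pos = (uint64_t)(uint32_t)pp[dim];
    if ((int)(pos >> rb) != chosen) return;
    uint64_t code = (p0 << rb) | (pos & rmask);
    if (filter) {
      ++counts[code];
    } else {
      keep.push_back(code);
    }
  });
  if (filter) {
    for (auto &kv : counts)
      if (kv.second >= (uint32_t)min_occ) keep.push_back(kv.first);
  }
  return List::create(_["codes"] = sorted_codes(keep), _["kmer_total"] = total);
}

// Decomposition: every k-mer lands in exactly one of the N = 4^a subspaces.
// Keyed on the full recoded k-mer (p0, dim) so occurrence filtering stays
// per distinct k-mer.
// [[Rcpp::export]]
List decompose_codes(CharacterVector seqs, std::string pattern,
                     IntegerVector perm, int a, int min_occ, bool canonical) {
  PatternInfo pi = parse_pattern(pattern);
  if (pi.k > 26) stop("k-mer length above 26 is not supported (code width)");
  if (a > pi.w) stop("partition exponent a must not exceed the pattern weight");
  if (a > 10) stop("decomposition with more than 4^10 components is not supported");
  const int N = 1 << (2 * a);
  const int rb = 2 * (pi.w - a);
  const uint64_t rmask = (rb == 0) ? 0ULL : ((1ULL << rb) - 1);
  const int *pp = INTEGER(perm);
  std::unordered_map<uint64_t, uint32_t> counts;
  double total = scan_sequences(seqs, pi, canonical, [&](uint64_t word) {
    uint64_t dim, p0;
    split_word(word, pi, dim, p0);
    uint64_t key = (p0 << (2 * pi.w)) | dim;
    ++counts[key];
  });
  const uint64_t dmask = (pi.w == 0) ? 0ULL : ((1ULL << (2 * pi.w)) - 1);
  std::vector<std::vector<uint64_t>> comp((size_t)N);
  for (auto &kv : counts) {
    if (kv.second < (uint32_t)min_occ) continue;
    uint64_t dim = kv.first & dmask;
    uint64_t p0 = kv.first >> (2 * pi.w);
    uint64_t pos = (uint64_t)(uint32_t)pp[dim];
    int ci = (int)(pos >> rb);
    comp[(size_t)ci].push_back((p0 << rb) | (pos & rmask));
  }
  List out((R_xlen_t)N);
  for (int i = 0; i < N; ++i) out[i] = sorted_codes(comp[(size_t)i]);
  return List::create(_["components"] = out, _["kmer_total"] = total);
}
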