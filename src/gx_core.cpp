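// Core routines for the gxscreen contamination screen:
//  - locality-sensitive h-mer hashing (wobble drop + 1-bit alphabet + minword)
//  - 9-byte index node packing / 2-bit sequence packing
//  - pass-1 seed collection, diagonal noise filter and ungapped runs
//  - pass-2 seed-and-extend alignment with greedy gapped extension
//  - rolling hexamer Shannon entropy for low-complexity masking
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <array>
#include <algorithm>
#include <memory>
#include <cmath>
using namespace Rcpp;

// Fixed 64-bit finalizer (splitmix64); the mixing hash behind every h-mer key.
// The constants are pinned so databases are reproducible across platforms.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return z;
}

static inline int bcode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline int retained_bits(int k) { return k - k / 3; }

// Canonical h-mer key for the k-long window starting at `pos` (0-based).
// Wobble positions (i %% 3 == 2 on each strand's own 5'->3' reading) are
// dropped; retained bases are encoded 1 bit each (A,G -> 0; C,T -> 1); both
// strand encodings are hashed and the lesser hash is the key. Ties and
// forward-minimizing windows get orient = +1.
static inline bool hmer_at(const char* s, long pos, int k,
                           double& key, int& orient,
                           uint64_t* packed_fwd = nullptr,
                           uint64_t* packed_rc = nullptr) {
  uint64_t fwd = 0, rc = 0;
  for (int i = 0; i < k; ++i) {
    if (i % 3 == 2) continue;
    int c = bcode(s[pos + i]);
    if (c < 0) return false;
    fwd = (fwd << 1) | (uint64_t)(c == 1 || c == 3);
  }
  for (int j = 0; j < k; ++j) {
    if (j % 3 == 2) continue;
    int c = bcode(s[pos + k - 1 - j]);
    if (c < 0) return false;
    // complement flips purine <-> pyrimidine, so the bit flips
    rc = (rc << 1) | (uint64_t)(!(c == 1 || c == 3));
  }
  int bits = retained_bits(k);
  uint64_t mask = (1ULL << bits) - 1;
  uint64_t hf = mix64(fwd) & mask, hr = mix64(rc) & mask;
  if (hf <= hr) { key = (double)hf; orient = 1; }
  else          { key = (double)hr; orient = -1; }
  if (packed_fwd) *packed_fwd = fwd;
  if (packed_rc)  *packed_rc = rc;
  return true;
}

// [[Rcpp::export]]
List cpp_hmer_key(std::string window) {
  int k = (int)window.size();
  double key; int orient; uint64_t pf, pr;
  if (!hmer_at(window.c_str(), 0, k, key, orient, &pf, &pr))
    stop("window contains non-ACGT bases");
  return List::create(_["key"] = key, _["orient"] = orient,
                      _["packed_fwd"] = (double)pf, _["packed_rc"] = (double)pr,
                      _["bits"] = retained_bits(k));
}

// Windows at starts 0, stride, 2*stride, ... with start + k <= length.
// skip: optional logical per base; a window is skipped for seeding when at
// least half of its bases are flagged.
// [[Rcpp::export]]
DataFrame cpp_extract_hmers(std::string seq, int stride, int k,
                            Nullable<LogicalVector> skip = R_NilValue) {
  long n = (long)seq.size();
  std::vector<int> pos_out; std::vector<double> key_out; std::vector<int> ori_out;
  std::vector<long> cum;
  bool have_skip = skip.isNotNull();
  if (have_skip) {
    LogicalVector sk(skip);
    cum.assign(n + 1, 0);
    for (long i = 0; i < n; ++i) cum[i + 1] = cum[i] + (sk[i] == TRUE ? 1 : 0);
  }
  const char* s = seq.c_str();
  for (long p = 0; p + k <= n; p += stride) {
    if (have_skip && 2 * (cum[p + k] - cum[p]) >= k) continue;
    double key; int orient;
    if (!hmer_at(s, p, k, key, orient)) continue;
    pos_out.push_back((int)p); key_out.push_back(key); ori_out.push_back(orient);
  }
  return DataFrame::create(_["pos"] = pos_out, _["key"] = key_out,
                           _["orient"] = ori_out);
}

// Replace non-ACGT bases with pseudorandom bases seeded by (sequence id,
// position), so rebuilds are bit-reproducible. Returns the filled sequence
// (uppercased) and the 1-based positions that were filled.
// [[Rcpp::export]]
List cpp_fill_ambiguous(std::string id, std::string seq) {
  uint64_t h = 1469598103934665603ULL; // FNV-1a over the id
  for (char c : id) { h ^= (uint64_t)(unsigned char)c; h *= 1099511628211ULL; }
  static const char* B = "ACGT";
  std::vector<int> fill;
  for (long i = 0; i < (long)seq.size(); ++i) {
    int c = bcode(seq[i]);
    if (c < 0) {
      uint64_t x = mix64(h + 0x9E3779B97F4A7C15ULL * (uint64_t)(i + 1));
      seq[i] = B[x & 3ULL];
      fill.push_back((int)i + 1);
    } else {
      seq[i] = B[c];
    }
  }
  return List::create(_["seq"] = seq, _["fill"] = wrap(fill));
}

// ---- 2-bit sequence packing (.gxs role) ------------------------------------

// [[Rcpp::export]]
RawVector cpp_pack2bit(std::string seq) {
  long n = (long)seq.size();
  RawVector out((n + 3) / 4);
  for (long i = 0; i < n; ++i) {
    int c = bcode(seq[i]);
    if (c < 0) stop("cannot 2-bit pack non-ACGT base at position %ld", i + 1);
    out[i / 4] |= (Rbyte)(c << (2 * (i % 4)));
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_unpack2bit(RawVector packed, double len) {
  static const char* B = "ACGT";
  long n = (long)len;
  std::string out(n, 'A');
  for (long i = 0; i < n; ++i)
    out[i] = B[(packed[i / 4] >> (2 * (i % 4))) & 3];
  return out;
}

// ---- 9-byte node packing (.gxi role) ---------------------------------------
// node = (1-byte lower subkey, 4-byte subject ordinal (0-based, LE),
//         4-byte signed position, sign = orientation, |pos| = start + 1)

// [[Rcpp::export]]
RawVector cpp_pack_nodes(NumericVector key, IntegerVector ord, IntegerVector pos) {
  R_xlen_t n = key.size();
  RawVector out(9 * n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t k = (uint64_t)key[i];
    uint32_t o = (uint32_t)(ord[i] - 1);
    int32_t p = (int32_t)pos[i];
    Rbyte* b = &out[9 * i];
    b[0] = (Rbyte)(k & 0xFF);
    std::memcpy(b + 1, &o, 4);
    std::memcpy(b + 5, &p, 4);
  }
  return out;
}

// bucketUpper/bucketStart describe the sorted non-empty buckets; bucketStart is
// the 0-based index of each bucket's first node. Full keys are reconstructed as
// upper * 256 + lower.
// [[Rcpp::export]]
List cpp_unpack_nodes(RawVector raw, NumericVector bucketUpper,
                      NumericVector bucketStart) {
  R_xlen_t n = raw.size() / 9;
  NumericVector key(n); IntegerVector ord(n), pos(n);
  R_xlen_t nb = bucketUpper.size();
  for (R_xlen_t b = 0; b < nb; ++b) {
    R_xlen_t from = (R_xlen_t)bucketStart[b];
    R_xlen_t to = (b + 1 < nb) ? (R_xlen_t)bucketStart[b + 1] : n;
    for (R_xlen_t i = from; i < to; ++i) {
      const Rbyte* bp = &raw[9 * i];
      uint32_t o; int32_t p;
      std::memcpy(&o, bp + 1, 4);
      std::memcpy(&p, bp + 5, 4);
      key[i] = bucketUpper[b] * 256.0 + (double)bp[0];
      ord[i] = (int)o + 1;
      pos[i] = p;
    }
  }
  return List::create(_["key"] = key, _["ordinal"] = ord, _["pos"] = pos);
}

// ---- hexamer entropy (low-complexity masking) ------------------------------

// Shannon entropy (bits) of the hexamer distribution in each window of
// `window` bp, step 1. Sequences shorter than the window yield one entropy
// for the full sequence when it holds at least one hexamer.
// [[Rcpp::export]]
NumericVector cpp_entropy_windows(std::string seq, int window = 50) {
  long n = (long)seq.size();
  if (n < 6) return NumericVector(0);
  long w = std::min((long)window, n);
  long nwin = n - w + 1;
  long nhex_full = w - 5;
  // hexamer codes per start
  std::vector<int> code(n - 5, -1);
  for (long i = 0; i + 6 <= n; ++i) {
    int v = 0; bool ok = true;
    for (int j = 0; j < 6; ++j) {
      int c = bcode(seq[i + j]);
      if (c < 0) { ok = false; break; }
      v = (v << 2) | c;
    }
    code[i] = ok ? v : -1;
  }
  std::vector<double> xlx(nhex_full + 2, 0.0);
  for (long c = 2; c < (long)xlx.size(); ++c) xlx[c] = c * std::log2((double)c);
  std::vector<int> cnt(4096, 0);
  NumericVector out(nwin);
  double S = 0.0; long nh = 0;
  auto add = [&](int cd) {
    if (cd < 0) return;
    S -= xlx[cnt[cd]]; ++cnt[cd]; S += xlx[cnt[cd]]; ++nh;
  };
  auto rem = [&](int cd) {
    if (cd < 0) return;
    S -= xlx[cnt[cd]]; --cnt[cd]; S += xlx[cnt[cd]]; --nh;
  };
  for (long i = 0; i < nhex_full; ++i) add(code[i]);
  for (long p = 0; p < nwin; ++p) {
    out[p] = (nh > 0) ? std::log2((double)nh) - S / nh : 0.0;
    if (p + 1 < nwin) { rem(code[p]); add(code[p + w - 5]); }
  }
  return out;
}

// ---- alignment machinery ---------------------------------------------------

namespace {

struct StrandCache {
  // lazily materialized per-(ordinal, strand) subject strings and fill masks
  const CharacterVector& seqs;
  const List& fills;
  std::vector<std::unique_ptr<std::string>> fwd, rev;
  std::vector<std::unique_ptr<std::vector<uint8_t>>> ffwd, frev;
  StrandCache(const CharacterVector& s, const List& f)
    : seqs(s), fills(f), fwd(s.size()), rev(s.size()),
      ffwd(s.size()), frev(s.size()) {}
  const std::string& get(int ord0, int rel) {
    if (rel == 1) {
      if (!fwd[ord0]) fwd[ord0].reset(new std::string(as<std::string>(seqs[ord0])));
      return *fwd[ord0];
    }
    if (!rev[ord0]) {
      const std::string& f = get(ord0, 1);
      std::string r(f.rbegin(), f.rend());
      for (auto& c : r) {
        switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        }
      }
      rev[ord0].reset(new std::string(std::move(r)));
    }
    return *rev[ord0];
  }
  const std::vector<uint8_t>& fill(int ord0, int rel) {
    if (rel == 1) {
      if (!ffwd[ord0]) {
        long n = (long)get(ord0, 1).size();
        auto v = new std::vector<uint8_t>(n, 0);
        IntegerVector fp = fills[ord0];
        for (int p : fp) (*v)[p - 1] = 1;
        ffwd[ord0].reset(v);
      }
      return *ffwd[ord0];
    }
    if (!frev[ord0]) {
      const std::vector<uint8_t>& f = fill(ord0, 1);
      frev[ord0].reset(new std::vector<uint8_t>(f.rbegin(), f.rend()));
    }
    return *frev[ord0];
  }
};

struct Seed { int ord; int rel; int q; int s; };

static inline bool match_at(const char* Q, const uint8_t* FQ,
                            const char* S, const uint8_t* FS,
                            long q, long s) {
  // pseudorandom-filled bases never count as identity
  return Q[q] == S[s] && !FQ[q] && !FS[s];
}

// Extension ends are only advanced on exact runs of at least TRIM_RUN bp,
// so a handful of chance matches past a true homology boundary (e.g. a
// chimera junction) cannot drag the alignment end across it.
static const int TRIM_RUN = 5;

// X-drop ungapped extension to the right starting at (q0, s0); returns the
// number of columns kept (ends on the last scoring maximum reached inside
// an exact run of TRIM_RUN or more).
static int xdrop_right(const char* Q, const uint8_t* FQ, long qlen,
                       const char* S, const uint8_t* FS, long slen,
                       long q0, long s0, int xdrop) {
  int sc = 0, best = 0, bestLen = 0, run = 0;
  long i = 0;
  bool boundary = true;
  while (q0 + i < qlen && s0 + i < slen) {
    if (match_at(Q, FQ, S, FS, q0 + i, s0 + i)) { ++sc; ++run; }
    else { sc -= 3; run = 0; }
    if (sc > best && run >= TRIM_RUN) { best = sc; bestLen = (int)(i + 1); }
    if (best - sc > xdrop) { boundary = false; break; }
    ++i;
  }
  // a run cut short by the sequence boundary is real homology, not junction
  // overrun: keep it even below TRIM_RUN
  if (boundary && run > 0 && sc > best) bestLen = (int)i;
  return bestLen;
}

static int xdrop_left(const char* Q, const uint8_t* FQ,
                      const char* S, const uint8_t* FS,
                      long q0, long s0, int xdrop) {
  // extends from just before (q0, s0)
  int sc = 0, best = 0, bestLen = 0, run = 0;
  long i = 1;
  bool boundary = true;
  while (q0 - i >= 0 && s0 - i >= 0) {
    if (match_at(Q, FQ, S, FS, q0 - i, s0 - i)) { ++sc; ++run; }
    else { sc -= 3; run = 0; }
    if (sc > best && run >= TRIM_RUN) { best = sc; bestLen = (int)i; }
    if (best - sc > xdrop) { boundary = false; break; }
    ++i;
  }
  if (boundary && run > 0 && sc > best) bestLen = (int)(i - 1);
  return bestLen;
}

static int run_fwd(const char* Q, const uint8_t* FQ, long qlen,
                   const char* S, const uint8_t* FS, long slen,
                   long q, long s, int cap) {
  int L = 0;
  while (q + L < qlen && s + L < slen && L < cap &&
         match_at(Q, FQ, S, FS, q + L, s + L)) ++L;
  return L;
}

static int run_back(const char* Q, const uint8_t* FQ,
                    const char* S, const uint8_t* FS,
                    long q, long s, int cap) {
  // exact run ending at (q, s) inclusive, walking backwards
  int L = 0;
  while (q - L >= 0 && s - L >= 0 && L < cap &&
         match_at(Q, FQ, S, FS, q - L, s - L)) ++L;
  return L;
}

struct Block { long q, s, len; };

// maximal runs of 100%-identity columns across the blocks of an alignment
static void identity_segments(const char* Q, const uint8_t* FQ,
                              const char* S, const uint8_t* FS,
                              const std::vector<Block>& blocks,
                              std::vector<int>& segs, long& matches) {
  segs.clear(); matches = 0;
  for (const Block& b : blocks) {
    int cur = 0;
    for (long i = 0; i < b.len; ++i) {
      if (match_at(Q, FQ, S, FS, b.q + i, b.s + i)) { ++cur; ++matches; }
      else if (cur > 0) { segs.push_back(cur); cur = 0; }
    }
    if (cur > 0) segs.push_back(cur);
  }
}

static double l2_score(const std::vector<int>& segs) {
  double ss = 0;
  for (int l : segs) ss += (double)l * l;
  return std::sqrt(ss);
}

struct ExtendParams { int xdrop, gapSearch, minSeg; };

// Greedy gapped extension: anchor on the longest exact run inside the seed
// window, X-drop extend, then repeatedly take the indel (or mismatch skip)
// within +/- gapSearch of the alignment end that yields the longest exact
// continuation run, while that run stays significant (>= minSeg).
static bool extend_seed(const char* Q, const uint8_t* FQ, long qlen,
                        const char* S, const uint8_t* FS, long slen,
                        long q0, long s0, int k, const ExtendParams& P,
                        std::vector<Block>& blocks) {
  // anchor
  int bestL = 0; long bestQ = q0;
  {
    int cur = 0;
    for (int i = 0; i < k && q0 + i < qlen && s0 + i < slen; ++i) {
      if (match_at(Q, FQ, S, FS, q0 + i, s0 + i)) {
        ++cur;
        if (cur > bestL) { bestL = cur; bestQ = q0 + i - cur + 1; }
      } else cur = 0;
    }
  }
  if (bestL < P.minSeg) return false;
  long d = s0 - q0;
  blocks.assign(1, Block{bestQ, bestQ + d, bestL});
  // ungapped X-drop both ways on the anchor diagonal
  {
    Block& b = blocks.back();
    int e = xdrop_right(Q, FQ, qlen, S, FS, slen, b.q + b.len, b.s + b.len, P.xdrop);
    b.len += e;
    int l = xdrop_left(Q, FQ, S, FS, b.q, b.s, P.xdrop);
    b.q -= l; b.s -= l; b.len += l;
  }
  // gapped to the right
  for (int iter = 0; iter < 500; ++iter) {
    Block& last = blocks.back();
    long qe = last.q + last.len, se = last.s + last.len;
    int bL = 0, bA = 0, bB = 0;
    for (int a = 0; a <= P.gapSearch; ++a) {
      for (int bb = 0; bb <= P.gapSearch; ++bb) {
        if (a == 0 && bb == 0) continue;
        if (qe + a >= qlen || se + bb >= slen) continue;
        int L = run_fwd(Q, FQ, qlen, S, FS, slen, qe + a, se + bb, 256);
        if (L > bL || (L == bL && L > 0 &&
            (a + bb < bA + bB || (a + bb == bA + bB && a < bA)))) {
          bL = L; bA = a; bB = bb;
        }
      }
    }
    if (bL < P.minSeg) break;
    int e = xdrop_right(Q, FQ, qlen, S, FS, slen,
                        qe + bA + bL, se + bB + bL, P.xdrop);
    if (bA == bB) {
      last.len += bA + bL + e; // same diagonal: mismatch skip, no indel
    } else {
      blocks.push_back(Block{qe + bA, se + bB, (long)(bL + e)});
    }
  }
  // gapped to the left
  for (int iter = 0; iter < 500; ++iter) {
    Block& first = blocks.front();
    long qs = first.q, ss = first.s;
    int bL = 0, bA = 0, bB = 0;
    for (int a = 0; a <= P.gapSearch; ++a) {
      for (int bb = 0; bb <= P.gapSearch; ++bb) {
        if (a == 0 && bb == 0) continue;
        if (qs - a - 1 < 0 || ss - bb - 1 < 0) continue;
        int L = run_back(Q, FQ, S, FS, qs - a - 1, ss - bb - 1, 256);
        if (L > bL || (L == bL && L > 0 &&
            (a + bb < bA + bB || (a + bb == bA + bB && a < bA)))) {
          bL = L; bA = a; bB = bb;
        }
      }
    }
    if (bL < P.minSeg) break;
    long nq = qs - bA - bL, ns = ss - bB - bL;
    int e = xdrop_left(Q, FQ, S, FS, nq, ns, P.xdrop);
    nq -= e; ns -= e;
    if (bA == bB) {
      long grow = qs - nq;
      first.q = nq; first.s = ns; first.len += grow;
    } else {
      // new block spans [nq, qs - bA) on the query (run + left extension)
      blocks.insert(blocks.begin(), Block{nq, ns, (qs - bA) - nq});
    }
  }
  return true;
}

static std::vector<uint8_t> mask_from_positions(const IntegerVector& pos, long n) {
  std::vector<uint8_t> m(n, 0);
  for (int p : pos) if (p >= 1 && p <= n) m[p - 1] = 1;
  return m;
}

} // namespace

// ---- pass 1 ----------------------------------------------------------------

// Seeds from database lookups of every query h-mer (stride `qstride`), noise
// filter (a close neighbor within diagWin on the diagonal and antidiagWin on
// the antidiagonal), same-diagonal merge into ungapped runs, X-drop run
// extension, and per-taxon best-overlap filtering.
// [[Rcpp::export]]
List cpp_pass1(std::string query,
               IntegerVector qSkip, IntegerVector qFill,
               NumericVector nodeKey, IntegerVector nodeOrd, IntegerVector nodePos,
               CharacterVector subjSeqs, List subjFill,
               IntegerVector subjTax, LogicalVector subjKeep,
               int k, int qstride,
               int diagWin, int antidiagWin, int mergeGap,
               int xdrop, int maxBucket, double maxSeeds) {
  long qlen = (long)query.size();
  const char* Q = query.c_str();
  std::vector<uint8_t> fq = mask_from_positions(qFill, qlen);
  // seeding skip mask prefix sums (mask + fill)
  std::vector<long> cum(qlen + 1, 0);
  {
    std::vector<uint8_t> sk = mask_from_positions(qSkip, qlen);
    for (long i = 0; i < qlen; ++i)
      cum[i + 1] = cum[i] + (sk[i] || fq[i] ? 1 : 0);
  }
  int nsub = subjSeqs.size();
  std::vector<long> slen(nsub);
  for (int i = 0; i < nsub; ++i) slen[i] = (long)LENGTH(STRING_ELT(subjSeqs, i));

  const double* kb = REAL(nodeKey);
  R_xlen_t nn = nodeKey.size();

  std::vector<Seed> seeds;
  bool capped = false;
  for (long p = 0; p + k <= qlen && !capped; p += qstride) {
    if (2 * (cum[p + k] - cum[p]) >= k) continue;
    double key; int qo;
    if (!hmer_at(Q, p, k, key, qo)) continue;
    const double* lo = std::lower_bound(kb, kb + nn, key);
    const double* hi = std::upper_bound(lo, kb + nn, key);
    if (hi - lo > maxBucket) continue;
    for (const double* it = lo; it != hi; ++it) {
      R_xlen_t idx = it - kb;
      int ord = nodeOrd[idx];
      if (!subjKeep[ord - 1]) continue;
      int p1 = nodePos[idx];
      int so = p1 >= 0 ? 1 : -1;
      long sstart = std::labs((long)p1) - 1;
      int rel = qo * so;
      long sf = (rel == 1) ? sstart : slen[ord - 1] - k - sstart;
      seeds.push_back(Seed{ord, rel, (int)p, (int)sf});
      if ((double)seeds.size() >= maxSeeds) { capped = true; break; }
    }
  }

  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.ord != b.ord) return a.ord < b.ord;
    if (a.rel != b.rel) return a.rel < b.rel;
    long da = (long)a.q - a.s, db = (long)b.q - b.s;
    if (da != db) return da < db;
    return a.q < b.q;
  });

  // noise filter within each (ordinal, strand) group
  std::vector<char> keep(seeds.size(), 0);
  size_t g0 = 0;
  while (g0 < seeds.size()) {
    size_t g1 = g0;
    while (g1 < seeds.size() && seeds[g1].ord == seeds[g0].ord &&
           seeds[g1].rel == seeds[g0].rel) ++g1;
    size_t j0 = g0;
    for (size_t i = g0; i < g1; ++i) {
      long di = (long)seeds[i].q - seeds[i].s;
      long ai = (long)seeds[i].q + seeds[i].s;
      while (j0 < g1 && di - ((long)seeds[j0].q - seeds[j0].s) > diagWin) ++j0;
      for (size_t j = j0; j < g1; ++j) {
        long dj = (long)seeds[j].q - seeds[j].s;
        if (dj - di > diagWin) break;
        if (j == i) continue;
        long aj = (long)seeds[j].q + seeds[j].s;
        if (std::labs(aj - ai) <= antidiagWin) { keep[i] = 1; break; }
      }
    }
    g0 = g1;
  }

  StrandCache cache(subjSeqs, subjFill);

  // merge surviving same-diagonal seeds within mergeGap into runs
  struct Run {
    int ord, rel, tax; long qs, qe, d; double score; int nseg; long len;
    std::vector<int> segs;
  };
  std::vector<Run> runs;
  size_t i = 0;
  while (i < seeds.size()) {
    if (!keep[i]) { ++i; continue; }
    size_t j = i;
    long d = (long)seeds[i].q - seeds[i].s;
    size_t last = i;
    while (j + 1 < seeds.size()) {
      const Seed& nx = seeds[j + 1];
      if (!keep[j + 1]) { ++j; continue; }
      if (nx.ord != seeds[i].ord || nx.rel != seeds[i].rel ||
          ((long)nx.q - nx.s) != d || nx.q - seeds[last].q > mergeGap) break;
      last = j + 1; ++j;
    }
    Run r;
    r.ord = seeds[i].ord; r.rel = seeds[i].rel;
    r.tax = subjTax[r.ord - 1]; r.d = d;
    r.qs = seeds[i].q; r.qe = (long)seeds[last].q + k;
    // extend on the diagonal, then collect identity segments
    const std::string& S = cache.get(r.ord - 1, r.rel);
    const std::vector<uint8_t>& fs = cache.fill(r.ord - 1, r.rel);
    long sl = (long)S.size();
    int er = xdrop_right(Q, fq.data(), qlen, S.c_str(), fs.data(), sl,
                         r.qe, r.qe - d, xdrop);
    int el = xdrop_left(Q, fq.data(), S.c_str(), fs.data(), r.qs, r.qs - d, xdrop);
    r.qs -= el; r.qe += er;
    std::vector<Block> blocks{Block{r.qs, r.qs - d, r.qe - r.qs}};
    long matches;
    identity_segments(Q, fq.data(), S.c_str(), fs.data(), blocks, r.segs, matches);
    r.score = l2_score(r.segs);
    r.nseg = (int)r.segs.size();
    r.len = r.qe - r.qs;
    runs.push_back(std::move(r));
    i = j + 1;
  }

  // per-taxon best-overlap filter on query coordinates (greedy by score)
  std::vector<size_t> order(runs.size());
  for (size_t t = 0; t < order.size(); ++t) order[t] = t;
  std::sort(order.begin(), order.end(), [&](size_t a, size_t b) {
    if (runs[a].tax != runs[b].tax) return runs[a].tax < runs[b].tax;
    if (runs[a].score != runs[b].score) return runs[a].score > runs[b].score;
    if (runs[a].qs != runs[b].qs) return runs[a].qs < runs[b].qs;
    return runs[a].ord < runs[b].ord;
  });
  std::vector<char> rkeep(runs.size(), 0);
  std::vector<std::pair<long, long>> taken;
  int curTax = -2147483647;
  for (size_t oi : order) {
    const Run& r = runs[oi];
    if (r.tax != curTax) { taken.clear(); curTax = r.tax; }
    bool ov = false;
    for (auto& t : taken)
      if (r.qs < t.second && t.first < r.qe) { ov = true; break; }
    if (!ov) { rkeep[oi] = 1; taken.push_back({r.qs, r.qe}); }
  }

  std::vector<int> o_ord, o_tax, o_rel, o_qs, o_qe, o_ss, o_se, o_nseg, o_len;
  std::vector<double> o_score;
  R_xlen_t nKept = 0;
  for (size_t t = 0; t < runs.size(); ++t) if (rkeep[t]) ++nKept;
  List segList(nKept);   // assigned in place so every element stays protected
  R_xlen_t si = 0;
  for (size_t t = 0; t < runs.size(); ++t) {
    if (!rkeep[t]) continue;
    const Run& r = runs[t];
    long sfs = r.qs - r.d, sfe = r.qe - r.d;
    long sl = slen[r.ord - 1];
    long ssF = (r.rel == 1) ? sfs : sl - sfe;
    long seF = (r.rel == 1) ? sfe : sl - sfs;
    o_ord.push_back(r.ord); o_tax.push_back(r.tax); o_rel.push_back(r.rel);
    o_qs.push_back((int)r.qs); o_qe.push_back((int)r.qe);
    o_ss.push_back((int)ssF); o_se.push_back((int)seF);
    o_score.push_back(r.score); o_nseg.push_back(r.nseg);
    o_len.push_back((int)r.len);
    segList[si++] = wrap(r.segs);
  }
  DataFrame df = DataFrame::create(
    _["ordinal"] = o_ord, _["taxid"] = o_tax, _["strand"] = o_rel,
    _["qstart"] = o_qs, _["qend"] = o_qe,
    _["sstart"] = o_ss, _["send"] = o_se,
    _["len"] = o_len, _["score"] = o_score, _["nseg"] = o_nseg);
  return List::create(_["runs"] = df, _["segments"] = segList,
                      _["n_seeds"] = (double)seeds.size(),
                      _["capped"] = capped);
}

// ---- pass 2 ----------------------------------------------------------------

// The query is indexed with small h-mers (k2-bp windows, 20-bit keys);
// subject neighborhoods around pass-1 loci are scanned against that index and
// seeds are extended (ungapped, then gapped).
// [[Rcpp::export]]
List cpp_pass2(std::string query,
               IntegerVector qSkip, IntegerVector qFill,
               CharacterVector subjSeqs, List subjFill, IntegerVector subjTax,
               IntegerVector selOrd,
               IntegerVector runOrd, IntegerVector runSstart, IntegerVector runSend,
               int k2, int neighborhood, int xdrop, int gapSearch, int minSeg,
               int minMatches, int maxBucket2) {
  long qlen = (long)query.size();
  const char* Q = query.c_str();
  std::vector<uint8_t> fq = mask_from_positions(qFill, qlen);
  ExtendParams P{xdrop, gapSearch, minSeg};

  // query index over canonical k2-mers
  struct QEntry { double key; int pos; int ori; };
  std::vector<QEntry> qidx;
  {
    std::vector<long> cum(qlen + 1, 0);
    std::vector<uint8_t> sk = mask_from_positions(qSkip, qlen);
    for (long i = 0; i < qlen; ++i)
      cum[i + 1] = cum[i] + (sk[i] || fq[i] ? 1 : 0);
    for (long p = 0; p + k2 <= qlen; ++p) {
      if (2 * (cum[p + k2] - cum[p]) >= k2) continue;
      double key; int ori;
      if (!hmer_at(Q, p, k2, key, ori)) continue;
      qidx.push_back(QEntry{key, (int)p, ori});
    }
    std::sort(qidx.begin(), qidx.end(), [](const QEntry& a, const QEntry& b) {
      if (a.key != b.key) return a.key < b.key;
      return a.pos < b.pos;
    });
  }

  StrandCache cache(subjSeqs, subjFill);

  struct Hit {
    int ord, tax, rel; long qs, qe, sfs, sfe, dmin, dmax, matches;
    double score; std::vector<int> segs;
  };
  std::vector<Hit> hits;

  for (int ord : selOrd) {
    const std::string& SF = cache.get(ord - 1, 1);
    long sl = (long)SF.size();
    long W = std::min((long)neighborhood, 2 * qlen);
    // merged neighborhoods around this subject's pass-1 loci
    std::vector<std::pair<long, long>> iv;
    for (R_xlen_t r = 0; r < runOrd.size(); ++r) {
      if (runOrd[r] != ord) continue;
      long a = std::max(0L, (long)runSstart[r] - W);
      long b = std::min(sl, (long)runSend[r] + W);
      if (b - a >= k2) iv.push_back({a, b});
    }
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    std::vector<std::pair<long, long>> merged;
    for (auto& p : iv) {
      if (!merged.empty() && p.first <= merged.back().second)
        merged.back().second = std::max(merged.back().second, p.second);
      else merged.push_back(p);
    }
    const std::vector<uint8_t>& fsF = cache.fill(ord - 1, 1);
    size_t hit0 = hits.size();
    for (auto& seg : merged) {
      for (long t = seg.first; t + k2 <= seg.second; ++t) {
        double key; int so;
        if (!hmer_at(SF.c_str(), t, k2, key, so)) continue;
        // binary search the query index
        auto lo = std::lower_bound(qidx.begin(), qidx.end(), key,
          [](const QEntry& e, double k) { return e.key < k; });
        auto hi = lo;
        while (hi != qidx.end() && hi->key == key) ++hi;
        if (hi - lo > maxBucket2) continue;
        for (auto it = lo; it != hi; ++it) {
          int rel = it->ori * so;
          long sf = (rel == 1) ? t : sl - k2 - t;
          long qp = it->pos;
          bool covered = false;
          for (size_t h = hit0; h < hits.size(); ++h) {
            const Hit& H = hits[h];
            if (H.rel != rel) continue;
            if (qp >= H.qs && qp < H.qe && sf >= H.sfs && sf < H.sfe &&
                qp - sf >= H.dmin - 30 && qp - sf <= H.dmax + 30) {
              covered = true; break;
            }
          }
          if (covered) continue;
          const std::string& S = cache.get(ord - 1, rel);
          const std::vector<uint8_t>& fs = (rel == 1) ? fsF : cache.fill(ord - 1, -1);
          std::vector<Block> blocks;
          if (!extend_seed(Q, fq.data(), qlen, S.c_str(), fs.data(), sl,
                           qp, sf, k2, P, blocks)) continue;
          std::vector<int> segs; long matches;
          identity_segments(Q, fq.data(), S.c_str(), fs.data(), blocks,
                            segs, matches);
          if (matches < minMatches) continue;
          Hit H;
          H.ord = ord; H.tax = subjTax[ord - 1]; H.rel = rel;
          H.qs = blocks.front().q;
          H.qe = blocks.back().q + blocks.back().len;
          H.sfs = blocks.front().s;
          H.sfe = blocks.back().s + blocks.back().len;
          H.dmin = H.dmax = blocks.front().q - blocks.front().s;
          for (auto& b : blocks) {
            long d = b.q - b.s;
            H.dmin = std::min(H.dmin, d); H.dmax = std::max(H.dmax, d);
          }
          H.matches = matches; H.score = l2_score(segs);
          H.segs = std::move(segs);
          hits.push_back(std::move(H));
        }
      }
    }
  }

  std::vector<int> o_ord, o_tax, o_rel, o_qs, o_qe, o_ss, o_se, o_nseg;
  std::vector<double> o_score, o_match;
  List segList(hits.size());  // assigned in place so elements stay protected
  R_xlen_t si = 0;
  for (const Hit& H : hits) {
    long sl = (long)LENGTH(STRING_ELT(subjSeqs, H.ord - 1));
    long ssF = (H.rel == 1) ? H.sfs : sl - H.sfe;
    long seF = (H.rel == 1) ? H.sfe : sl - H.sfs;
    o_ord.push_back(H.ord); o_tax.push_back(H.tax); o_rel.push_back(H.rel);
    o_qs.push_back((int)H.qs); o_qe.push_back((int)H.qe);
    o_ss.push_back((int)ssF); o_se.push_back((int)seF);
    o_score.push_back(H.score); o_match.push_back((double)H.matches);
    o_nseg.push_back((int)H.segs.size());
    segList[si++] = wrap(H.segs);
  }
  DataFrame df = DataFrame::create(
    _["ordinal"] = o_ord, _["taxid"] = o_tax, _["strand"] = o_rel,
    _["qstart"] = o_qs, _["qend"] = o_qe,
    _["sstart"] = o_ss, _["send"] = o_se,
    _["matches"] = o_match, _["score"] = o_score, _["nseg"] = o_nseg);
  return List::create(_["hits"] = df, _["segments"] = segList);
}
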