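// Bit-level core: 2-bit k-mer packing, seedable invertible base hash,
// SimHash majority voting, minimizer/strobemer seeding, co-linear chaining DP.
// Hash values cross the R boundary as fixed-width lowercase hex strings
// because R has no native 64-bit integer type.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <cstdlib>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t bit_mask(int b) {
  return b >= 64 ? ~0ULL : ((1ULL << b) - 1ULL);
}

// splitmix64-style finalizer: invertible (bijective on 64 bits), avalanche-quality.
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

static inline uint64_t base_hash_u64(uint64_t code, uint64_t seed, int b) {
  uint64_t h = mix64(code ^ (seed * 0x9e3779b97f4a7c15ULL + 0x2545f4914f6cdd1dULL));
  return h & bit_mask(b);
}

static std::string to_hex(uint64_t x, int b) {
  static const char* digits = "0123456789abcdef";
  int width = (b + 3) / 4;
  std::string s(width, '0');
  for (int i = width - 1; i >= 0; --i) { s[i] = digits[x & 0xfULL]; x >>= 4; }
  return s;
}

static uint64_t from_hex(const std::string& s) {
  uint64_t x = 0;
  for (char c : s) {
    int v;
    if (c >= '0' && c <= '9') v = c - '0';
    else if (c >= 'a' && c <= 'f') v = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') v = c - 'A' + 10;
    else stop("invalid hex digit in hash value: '%s'", s.c_str());
    x = (x << 4) | (uint64_t)v;
  }
  return x;
}

static uint64_t simhash_u64(const std::vector<uint64_t>& items, int b) {
  std::vector<int> cnt(b, 0);
  for (uint64_t it : items)
    for (int t = 0; t < b; ++t)
      cnt[t] += ((it >> t) & 1ULL) ? 1 : -1;
  uint64_t h = 0;
  for (int t = 0; t < b; ++t)
    if (cnt[t] > 0) h |= (1ULL << t);
  return h;
}

// [[Rcpp::export]]
CharacterVector cpp_base_hash(NumericVector codes, int b, double hash_seed) {
  uint64_t seed = (uint64_t)hash_seed;
  int n = codes.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t c = (uint64_t)codes[i];
    out[i] = to_hex(base_hash_u64(c, seed, b), b);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_counter_vector(CharacterVector items, int b) {
  IntegerVector cnt(b);
  uint64_t mask = bit_mask(b);
  for (int i = 0; i < items.size(); ++i) {
    uint64_t x = from_hex(as<std::string>(items[i]));
    if (x & ~mask) stop("item overflow");
    for (int t = 0; t < b; ++t)
      cnt[t] += ((x >> t) & 1ULL) ? 1 : -1;
  }
  return cnt;
}

// [[Rcpp::export]]
String cpp_simhash(CharacterVector items, int b) {
  if (items.size() == 0) stop("empty set");
  uint64_t mask = bit_mask(b);
  std::vector<uint64_t> v(items.size());
  for (int i = 0; i < items.size(); ++i) {
    v[i] = from_hex(as<std::string>(items[i]));
    if (v[i] & ~mask) stop("item overflow");
  }
  return to_hex(simhash_u64(v, b), b);
}

// ---- seeding ----------------------------------------------------------------

struct WordRec {
  int pos;
  uint64_t code;   // canonical code
  char strand;     // '+' or '-'
  uint64_t val;    // selection value (and seed hash for baseline/blend_i)
  bool valid;
};

// Compute per-position canonical words of length wl with selection values.
// mode: 0 = baseline (val = base_hash), 1 = blend_i (val = simhash of n
// sub-k'-mer base hashes read on the canonical orientation), 2 = strobe
// component (same val as baseline; used by blend_s).
static std::vector<WordRec> scan_words(const std::string& seq, int wl, int mode,
                                       int n_items, int b, uint64_t seed) {
  int m = (int)seq.size();
  std::vector<WordRec> words;
  if (m < wl) return words;
  int P = m - wl + 1;
  words.resize(P);
  uint64_t mask = bit_mask(2 * wl);
  uint64_t cf = 0, cr = 0;
  int run = 0; // length of current run of unambiguous bases ending here
  int kp = wl - n_items + 1; // sub-k-mer length for blend_i
  uint64_t kpmask = bit_mask(2 * kp);
  std::vector<uint64_t> items((size_t)std::max(n_items, 1));
  for (int i = 0; i < m; ++i) {
    int c = base2code(seq[i]);
    if (c < 0) { run = 0; cf = 0; cr = 0; }
    else {
      cf = ((cf << 2) | (uint64_t)c) & mask;
      cr = (cr >> 2) | ((uint64_t)(3 - c) << (2 * (wl - 1)));
      ++run;
    }
    int p = i - wl + 1;
    if (p < 0) continue;
    WordRec& wr = words[p];
    wr.pos = p;
    if (run < wl) { wr.valid = false; continue; }
    uint64_t code; char strand;
    if (cf < cr) { code = cf; strand = '+'; }
    else if (cr < cf) { code = cr; strand = '-'; }
    else { wr.valid = false; continue; } // palindromic: strand ambiguous, skip
    wr.code = code; wr.strand = strand;
    if (mode == 1) {
      for (int j = 0; j < n_items; ++j) {
        uint64_t sub = (code >> (2 * (wl - kp - j))) & kpmask;
        items[j] = base_hash_u64(sub, seed, b);
      }
      wr.val = simhash_u64(items, b);
    } else {
      wr.val = base_hash_u64(code, seed, b);
    }
    wr.valid = true;
  }
  return words;
}

// Minimizer selection: leftmost minimum per window of w consecutive word
// positions; consecutive windows sharing a minimum emit it once. Windows with
// no valid word emit nothing. If fewer than w word positions exist the whole
// word list is treated as a single window.
static std::vector<int> select_minimizers(const std::vector<WordRec>& words, int w) {
  std::vector<int> sel;
  int P = (int)words.size();
  if (P == 0) return sel;
  int nwin = P >= w ? P - w + 1 : 1;
  int wsz = P >= w ? w : P;
  int last = -1;
  for (int p0 = 0; p0 < nwin; ++p0) {
    int best = -1;
    for (int j = p0; j < p0 + wsz; ++j) {
      if (!words[j].valid) continue;
      if (best < 0 || words[j].val < words[best].val) best = j;
    }
    if (best >= 0 && best != last) { sel.push_back(best); last = best; }
  }
  return sel;
}

// [[Rcpp::export]]
DataFrame cpp_seed_stream(std::string seq, std::string mode, int word_len,
                          int w, int n_items, int b, double hash_seed) {
  uint64_t seed = (uint64_t)hash_seed;
  if (word_len < 1 || word_len > 31) stop("word length must be in 1..31");
  int imode = (mode == "baseline") ? 0 : (mode == "blend_i") ? 1 : 2;
  std::vector<WordRec> words = scan_words(seq, word_len, imode, n_items, b, seed);
  std::vector<int> sel = select_minimizers(words, w);
  std::vector<int> starts, spans;
  std::vector<std::string> strands, hashes;
  if (imode != 2) {
    for (int j : sel) {
      const WordRec& wr = words[j];
      starts.push_back(wr.pos);
      spans.push_back(word_len);
      strands.push_back(std::string(1, wr.strand));
      hashes.push_back(to_hex(wr.val, b));
    }
  } else {
    // blend_s: each minimizer starts a seed linking the next n-1 minimizers
    // that share its orientation (opposite-strand minimizers are passed
    // over when forming the run, keeping seed strands well defined); a run
    // with too few same-strand successors is broken and emits nothing.
    int M = (int)sel.size();
    std::vector<uint64_t> items(n_items);
    for (int i = 0; i + n_items <= M; ++i) {
      char s0 = words[sel[i]].strand;
      int got = 0, last = -1;
      for (int j = i; j < M && got < n_items; ++j) {
        if (words[sel[j]].strand != s0) continue;
        items[got++] = words[sel[j]].val;
        last = j;
      }
      if (got < n_items) continue; // broken run
      int st = words[sel[i]].pos;
      int en = words[sel[last]].pos + word_len;
      starts.push_back(st);
      spans.push_back(en - st);
      strands.push_back(std::string(1, s0));
      hashes.push_back(to_hex(simhash_u64(items, b), b));
    }
  }
  return DataFrame::create(_["start"] = starts, _["span"] = spans,
                           _["strand"] = strands, _["hash"] = hashes,
                           _["stringsAsFactors"] = false);
}

// Hash standalone words under a scheme, without minimizer selection.
// Used by the uplift experiment; canonicalize=false hashes the forward
// orientation as written. Returns NA for unpackable (or, when canonicalizing,
// palindromic) words.
// [[Rcpp::export]]
CharacterVector cpp_hash_words(CharacterVector words, std::string mode,
                               int n_items, int b, double hash_seed,
                               bool canonicalize) {
  uint64_t seed = (uint64_t)hash_seed;
  int nw = words.size();
  CharacterVector out(nw);
  std::vector<uint64_t> items((size_t)std::max(n_items, 1));
  for (int i = 0; i < nw; ++i) {
    std::string wstr = as<std::string>(words[i]);
    int wl = (int)wstr.size();
    if (wl < 1 || wl > 31) stop("word length must be in 1..31");
    uint64_t mask = bit_mask(2 * wl);
    uint64_t cf = 0, cr = 0;
    bool ok = true;
    for (int j = 0; j < wl; ++j) {
      int c = base2code(wstr[j]);
      if (c < 0) { ok = false; break; }
      cf = ((cf << 2) | (uint64_t)c) & mask;
      cr = (cr >> 2) | ((uint64_t)(3 - c) << (2 * (wl - 1)));
    }
    if (!ok) { out[i] = NA_STRING; continue; }
    uint64_t code = cf;
    if (canonicalize) {
      if (cr < cf) code = cr;
      else if (cr == cf) { out[i] = NA_STRING; continue; }
    }
    if (mode == "blend_i") {
      int kp = wl - n_items + 1;
      if (kp < 1) stop("neighbor count too large for seed length");
      uint64_t kpmask = bit_mask(2 * kp);
      for (int j = 0; j < n_items; ++j)
        items[j] = base_hash_u64((code >> (2 * (wl - kp - j))) & kpmask, seed, b);
      out[i] = to_hex(simhash_u64(items, b), b);
    } else {
      out[i] = to_hex(base_hash_u64(code, seed, b), b);
    }
  }
  return out;
}

// ---- chaining ---------------------------------------------------------------

// Co-linear chaining DP over one (target, strand-pair) anchor group.
// Anchors must arrive sorted by (t, q). Transitions require strictly
// increasing q and t with both deltas <= max_gap; gap cost |dq - dt|.
// Best-score-first extraction with anchor consumption; chains scoring below
// min_score stop extraction, chains with fewer than min_anchors are dropped
// (their anchors stay consumed).
// Returns: chain_id per anchor (0 = unassigned), and per-chain scores.
// [[Rcpp::export]]
List cpp_chain(IntegerVector q, IntegerVector t, IntegerVector span,
               int max_gap, int min_score, int min_anchors) {
  int m = q.size();
  IntegerVector assign(m, 0);
  std::vector<int> scores;
  if (m == 0)
    return List::create(_["chain"] = assign, _["score"] = IntegerVector(0));
  std::vector<bool> used(m, false);
  std::vector<int> f(m), pre(m);
  int next_id = 1;
  for (;;) {
    int best = -1;
    for (int i = 0; i < m; ++i) {
      if (used[i]) continue;
      f[i] = span[i]; pre[i] = -1;
      for (int j = 0; j < i; ++j) {
        if (used[j]) continue;
        int dq = q[i] - q[j], dt = t[i] - t[j];
        if (dq <= 0 || dt <= 0 || dq > max_gap || dt > max_gap) continue;
        int s = f[j] + span[i] - std::abs(dq - dt);
        if (s > f[i]) { f[i] = s; pre[i] = j; }
      }
      if (best < 0 || f[i] > f[best]) best = i;
    }
    if (best < 0 || f[best] < min_score) break;
    int cnt = 0;
    for (int i = best; i >= 0; i = pre[i]) { used[i] = true; ++cnt; }
    if (cnt >= min_anchors) {
      for (int i = best; i >= 0; i = pre[i]) assign[i] = next_id;
      scores.push_back(f[best]);
      ++next_id;
    }
  }
  return List::create(_["chain"] = assign, _["score"] = wrap(scores));
}
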