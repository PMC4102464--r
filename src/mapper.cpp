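// Hash-seeded short-read mapper over an IUPAC-ambiguity-aware reference.
// Primary seeding uses exact h-mers (reference ambiguity codes expanded at
// index time). Reads whose best seeded placement still carries >= 2
// mismatches are re-examined through disjoint rescue chunks (pigeonhole:
// with max_mismatch mismatches one of max_mismatch+1 disjoint chunks must be
// mismatch-free), so the returned minimal-mismatch placement set equals an
// exhaustive all-positions scan.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline uint8_t iupac_bits(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    default: return 0;  // n/N: matches nothing
  }
}

static inline int popcount4(uint8_t b) {
  return ((b & 1) != 0) + ((b & 2) != 0) + ((b & 4) != 0) + ((b & 8) != 0);
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > WordMap;

struct HashIndex {
  std::vector<std::string> names;
  std::vector<std::vector<uint8_t> > bits;
  int h;
  int rescue_w;
  int max_ambig;
  long n_positions_h;  // distinct reference positions indexed at width h
  WordMap idx_h, idx_r;
};

// enumerate all concrete ACGT words compatible with the reference window and
// insert them keyed by 2-bit packed code
static void index_window(WordMap &idx, const std::vector<uint8_t> &B,
                         uint64_t val, long p, int w) {
  std::vector<uint64_t> keys;
  keys.push_back(0);
  for (int k = 0; k < w; ++k) {
    uint8_t b = B[p + k];
    std::vector<uint64_t> nxt;
    nxt.reserve(keys.size() * popcount4(b));
    for (int c = 0; c < 4; ++c) {
      if (!(b & (1 << c))) continue;
      for (size_t t = 0; t < keys.size(); ++t)
        nxt.push_back((keys[t] << 2) | (uint64_t)c);
    }
    keys.swap(nxt);
  }
  for (size_t t = 0; t < keys.size(); ++t) idx[keys[t]].push_back(val);
}

static void build_width(HashIndex &H, WordMap &idx, int w, long *count) {
  for (size_t g = 0; g < H.bits.size(); ++g) {
    const std::vector<uint8_t> &B = H.bits[g];
    for (long p = 0; p + w <= (long)B.size(); ++p) {
      int nambig = 0;
      bool ok = true;
      for (int k = 0; k < w; ++k) {
        uint8_t b = B[p + k];
        if (b == 0) { ok = false; break; }
        if (popcount4(b) > 1) ++nambig;
      }
      if (!ok || nambig > H.max_ambig) continue;
      if (count) ++(*count);
      index_window(idx, B, ((uint64_t)g << 32) | (uint64_t)p, p, w);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int h,
                     int rescue_w, int max_ambig) {
  if (h < 8 || h > 31) stop("hash length must be in [8, 31]");
  if (rescue_w < 0 || rescue_w > h) stop("invalid rescue width");
  HashIndex *H = new HashIndex();
  H->h = h;
  H->rescue_w = rescue_w;
  H->max_ambig = max_ambig;
  H->n_positions_h = 0;
  int n = seqs.size();
  H->names.resize(n);
  H->bits.resize(n);
  for (int g = 0; g < n; ++g) {
    H->names[g] = as<std::string>(names[g]);
    std::string s = as<std::string>(seqs[g]);
    H->bits[g].resize(s.size());
    for (size_t i = 0; i < s.size(); ++i) H->bits[g][i] = iupac_bits(s[i]);
  }
  build_width(*H, H->idx_h, h, &H->n_positions_h);
  if (rescue_w > 0 && rescue_w != h) build_width(*H, H->idx_r, rescue_w, NULL);
  XPtr<HashIndex> ptr(H, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<HashIndex> H(xp);
  IntegerVector lens(H->names.size());
  for (size_t g = 0; g < H->bits.size(); ++g) lens[g] = (int)H->bits[g].size();
  return List::create(_["h"] = H->h, _["rescue_w"] = H->rescue_w,
                      _["n_positions"] = (double)H->n_positions_h,
                      _["n_genes"] = (int)H->names.size(),
                      _["gene_names"] = wrap(H->names),
                      _["gene_lengths"] = lens);
}

// Lookup an exact ACGT word of the index's hash length; returns compatible
// reference placements (1-based gene index, 0-based offset).
// [[Rcpp::export]]
List cpp_index_lookup(SEXP xp, std::string word) {
  XPtr<HashIndex> H(xp);
  if ((int)word.size() != H->h) stop("word length must equal hash length");
  uint64_t key = 0;
  for (size_t i = 0; i < word.size(); ++i) {
    uint8_t b = iupac_bits(word[i]);
    if (popcount4(b) != 1) stop("lookup word must be unambiguous ACGT");
    int c = b == 1 ? 0 : b == 2 ? 1 : b == 4 ? 2 : 3;
    key = (key << 2) | (uint64_t)c;
  }
  std::vector<int> genes;
  std::vector<double> offs;
  WordMap::const_iterator it = H->idx_h.find(key);
  if (it != H->idx_h.end()) {
    for (size_t t = 0; t < it->second.size(); ++t) {
      genes.push_back((int)(it->second[t] >> 32) + 1);
      offs.push_back((double)(uint32_t)(it->second[t] & 0xffffffffULL));
    }
  }
  return List::create(_["gene"] = wrap(genes), _["offset"] = wrap(offs));
}

static inline int verify(const std::vector<uint8_t> &ref, long pos,
                         const std::vector<uint8_t> &rb, int max_mm) {
  // returns mismatch count, or max_mm+1 as soon as it exceeds the cap
  int mm = 0;
  for (size_t i = 0; i < rb.size(); ++i) {
    if (!(rb[i] & ref[pos + i])) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

static void gather_word(const WordMap &idx, uint64_t key, long shift, long L,
                        const std::vector<std::vector<uint8_t> > &bits,
                        std::vector<uint64_t> &cands) {
  WordMap::const_iterator it = idx.find(key);
  if (it == idx.end()) return;
  for (size_t t = 0; t < it->second.size(); ++t) {
    long g = (long)(it->second[t] >> 32);
    long p = (long)(uint32_t)(it->second[t] & 0xffffffffULL);
    long pos0 = p - shift;
    if (pos0 >= 0 && pos0 + L <= (long)bits[g].size())
      cands.push_back(((uint64_t)g << 32) | (uint64_t)pos0);
  }
}

// Map reads; returns per-read status (0 unique, 1 multi, 2 mismatch-filtered,
// 3 unseeded/unmappable), unique gene (1-based) / offset (0-based) /
// mismatch count, per-gene unique counts, and optional per-gene unique depth.
// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, int max_mm, bool depth) {
  XPtr<HashIndex> H(xp);
  int nreads = reads.size();
  int ngenes = (int)H->names.size();
  IntegerVector status(nreads), ogene(nreads), opos(nreads), omm(nreads);
  std::vector<long> gcount(ngenes, 0);
  std::vector<std::vector<int> > dep;
  if (depth) {
    dep.resize(ngenes);
    for (int g = 0; g < ngenes; ++g) dep[g].assign(H->bits[g].size(), 0);
  }
  int h = H->h, rw = H->rescue_w;

  std::vector<uint8_t> rb;
  std::vector<uint64_t> cands, minset;
  for (int r = 0; r < nreads; ++r) {
    std::string R = as<std::string>(reads[r]);
    long L = (long)R.size();
    ogene[r] = NA_INTEGER;
    opos[r] = NA_INTEGER;
    omm[r] = NA_INTEGER;
    if (L < h) { status[r] = 3; continue; }
    rb.resize(L);
    for (long i = 0; i < L; ++i) rb[i] = iupac_bits(R[i]);
    // pre-pack 2-bit keys over valid stretches
    cands.clear();
    uint64_t maskbits = (1ULL << (2 * h)) - 1;
    uint64_t key = 0;
    int valid = 0;
    for (long i = 0; i < L; ++i) {
      uint8_t b = rb[i];
      int c = (b == 1) ? 0 : (b == 2) ? 1 : (b == 4) ? 2 : (b == 8) ? 3 : -1;
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & maskbits;
      if (++valid >= h) gather_word(H->idx_h, key, i - h + 1, L, H->bits, cands);
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    bool had_cand = !cands.empty();

    int minmm = max_mm + 1;
    minset.clear();
    for (size_t t = 0; t < cands.size(); ++t) {
      long g = (long)(cands[t] >> 32);
      long p = (long)(uint32_t)(cands[t] & 0xffffffffULL);
      int mm = verify(H->bits[g], p, rb, max_mm);
      if (mm < minmm) { minmm = mm; minset.clear(); }
      if (mm == minmm && mm <= max_mm) minset.push_back(cands[t]);
    }

    // exact h-mer seeding is provably complete at mismatch level 0, and at
    // level 1 only when L >= 2h (one mismatch cannot dirty every window);
    // anything else re-collects through pigeonhole rescue chunks
    bool complete = (minmm == 0) || (minmm == 1 && L >= 2L * h);
    if (!complete) {
      long chunk = L / (long)(max_mm + 1);
      if (rw > 0 && rw <= chunk) {
        cands.clear();
        for (int i = 0; i <= max_mm; ++i) {
          long off = (long)i * chunk;
          uint64_t k2 = 0;
          bool ok = true;
          for (int k = 0; k < rw; ++k) {
            uint8_t b = rb[off + k];
            int c = (b == 1) ? 0 : (b == 2) ? 1 : (b == 4) ? 2 : (b == 8) ? 3 : -1;
            if (c < 0) { ok = false; break; }
            k2 = (k2 << 2) | (uint64_t)c;
          }
          if (ok) gather_word((rw == h) ? H->idx_h : H->idx_r, k2, off, L,
                              H->bits, cands);
        }
      } else {
        // no usable rescue width: exhaustive candidate list
        cands.clear();
        for (long g = 0; g < ngenes; ++g)
          for (long p = 0; p + L <= (long)H->bits[g].size(); ++p)
            cands.push_back(((uint64_t)g << 32) | (uint64_t)p);
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      if (!cands.empty()) had_cand = true;
      minmm = max_mm + 1;
      minset.clear();
      for (size_t t = 0; t < cands.size(); ++t) {
        long g = (long)(cands[t] >> 32);
        long p = (long)(uint32_t)(cands[t] & 0xffffffffULL);
        int mm = verify(H->bits[g], p, rb, max_mm);
        if (mm < minmm) { minmm = mm; minset.clear(); }
        if (mm == minmm && mm <= max_mm) minset.push_back(cands[t]);
      }
    }

    if (minset.empty()) {
      status[r] = had_cand ? 2 : 3;
    } else if (minset.size() > 1) {
      status[r] = 1;
    } else {
      status[r] = 0;
      long g = (long)(minset[0] >> 32);
      long p = (long)(uint32_t)(minset[0] & 0xffffffffULL);
      ogene[r] = (int)g + 1;
      opos[r] = (int)p;
      omm[r] = minmm;
      gcount[g] += 1;
      if (depth)
        for (long i = 0; i < L; ++i) dep[g][p + i] += 1;
    }
  }

  NumericVector counts(ngenes);
  for (int g = 0; g < ngenes; ++g) counts[g] = (double)gcount[g];
  List dl = List(0);
  if (depth) {
    dl = List(ngenes);
    for (int g = 0; g < ngenes; ++g) dl[g] = wrap(dep[g]);
    dl.attr("names") = wrap(H->names);
  }
  counts.attr("names") = wrap(H->names);
  return List::create(_["status"] = status, _["gene"] = ogene,
                      _["offset"] = opos, _["mismatches"] = omm,
                      _["gene_counts"] = counts, _["depth"] = dl);
}
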