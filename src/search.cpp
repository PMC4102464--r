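// Seeded ungapped search used for contig-to-reference assignment.
// Word seeding over exact ACGT words; per shared diagonal the maximal-scoring
// ungapped segment is found by Kadane's algorithm. N (or any non-ACGT
// character) never matches and scores as a mismatch.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Seg {
  long score;
  long q_start, q_end, s_start, s_end;
  long matches, len;
};

static Seg best_on_diagonal(const std::string &q, const std::string &s,
                            long diag, int match, int mismatch) {
  long qi0 = diag < 0 ? -diag : 0;
  long si0 = qi0 + diag;
  long len = std::min((long)q.size() - qi0, (long)s.size() - si0);
  Seg best;
  best.score = LONG_MIN;
  best.q_start = best.q_end = best.s_start = best.s_end = 0;
  best.matches = best.len = 0;
  long cur = 0, curStart = 0, runMatch = 0;
  for (long i = 0; i < len; ++i) {
    int a = nt_code(q[qi0 + i]), b = nt_code(s[si0 + i]);
    bool m = (a >= 0 && a == b);
    if (cur < 0) { cur = 0; curStart = i; runMatch = 0; }
    cur += m ? match : mismatch;
    runMatch += m ? 1 : 0;
    if (cur > best.score) {
      best.score = cur;
      best.q_start = qi0 + curStart;
      best.q_end = qi0 + i + 1;
      best.s_start = si0 + curStart;
      best.s_end = si0 + i + 1;
      best.matches = runMatch;
      best.len = i + 1 - curStart;
    }
  }
  return best;
}

// Best ungapped hit per (query, subject) pair over all diagonals sharing at
// least one exact word of length word_size. Coordinates are 0-based
// half-open. Only pairs sharing a word are reported.
// [[Rcpp::export]]
DataFrame cpp_search_hits(CharacterVector queries, CharacterVector subjects,
                          int word_size, int match, int mismatch) {
  if (word_size < 1 || word_size > 15) stop("word_size must be in [1, 15]");
  int nq = queries.size(), ns = subjects.size();
  uint64_t maskbits = (1ULL << (2 * word_size)) - 1;

  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > widx;
  std::vector<std::string> subj(ns);
  for (int j = 0; j < ns; ++j) {
    subj[j] = as<std::string>(subjects[j]);
    const std::string &S = subj[j];
    uint64_t key = 0;
    int valid = 0;
    for (long i = 0; i < (long)S.size(); ++i) {
      int c = nt_code(S[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & maskbits;
      if (++valid >= word_size)
        widx[key].push_back(std::make_pair(j, (int)(i - word_size + 1)));
    }
  }

  std::vector<int> out_q, out_s;
  std::vector<long> out_score, out_matches, out_len;
  std::vector<long> out_qs, out_qe, out_ss, out_se;

  for (int qi = 0; qi < nq; ++qi) {
    std::string Q = as<std::string>(queries[qi]);
    // collect distinct (subject, diagonal) pairs
    std::vector<uint64_t> diags;
    uint64_t key = 0;
    int valid = 0;
    for (long i = 0; i < (long)Q.size(); ++i) {
      int c = nt_code(Q[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & maskbits;
      if (++valid >= word_size) {
        std::unordered_map<uint64_t,
          std::vector<std::pair<int, int> > >::const_iterator it = widx.find(key);
        if (it == widx.end()) continue;
        long qpos = i - word_size + 1;
        for (size_t t = 0; t < it->second.size(); ++t) {
          long diag = (long)it->second[t].second - qpos;
          // encode subject and shifted diagonal; diag in (-|Q|, |S|)
          uint64_t enc = ((uint64_t)it->second[t].first << 32) |
                         (uint64_t)(uint32_t)(diag + (long)Q.size());
          diags.push_back(enc);
        }
      }
    }
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

    int cur_subj = -1;
    Seg best;
    best.score = LONG_MIN;
    for (size_t t = 0; t <= diags.size(); ++t) {
      int j = (t < diags.size()) ? (int)(diags[t] >> 32) : -2;
      if (j != cur_subj) {
        if (cur_subj >= 0 && best.score > 0) {
          out_q.push_back(qi + 1);
          out_s.push_back(cur_subj + 1);
          out_score.push_back(best.score);
          out_matches.push_back(best.matches);
          out_len.push_back(best.len);
          out_qs.push_back(best.q_start);
          out_qe.push_back(best.q_end);
          out_ss.push_back(best.s_start);
          out_se.push_back(best.s_end);
        }
        cur_subj = j;
        best.score = LONG_MIN;
      }
      if (t == diags.size()) break;
      long diag = (long)(uint32_t)(diags[t] & 0xffffffffULL) - (long)Q.size();
      Seg seg = best_on_diagonal(Q, subj[j], diag, match, mismatch);
      if (seg.score > best.score) best = seg;
    }
  }

  return DataFrame::create(
    _["query"] = wrap(out_q), _["subject"] = wrap(out_s),
    _["score"] = wrap(out_score), _["matches"] = wrap(out_matches),
    _["length"] = wrap(out_len),
    _["q_start"] = wrap(out_qs), _["q_end"] = wrap(out_qe),
    _["s_start"] = wrap(out_ss), _["s_end"] = wrap(out_se));
}
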