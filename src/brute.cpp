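// Independent exhaustive-scan oracle for the seeded mapper: every reference
// position of every gene is tried for every read, with IUPAC-compatible
// mismatch counting. Deliberately simple and kept separate from the seeded
// implementation so the two can be compared as distinct routes.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static int compat_table_ready = 0;
static unsigned char tbl[256];

static void init_tbl() {
  if (compat_table_ready) return;
  for (int i = 0; i < 256; ++i) tbl[i] = 0;
  const char *codes = "ACGTRYSWKMBDHV";
  const unsigned char vals[] = {1, 2, 4, 8, 5, 10, 6, 9, 12, 3, 14, 13, 11, 7};
  for (int i = 0; i < 14; ++i) {
    tbl[(unsigned char)codes[i]] = vals[i];
    tbl[(unsigned char)tolower(codes[i])] = vals[i];
  }
  compat_table_ready = 1;
}

// [[Rcpp::export]]
List cpp_map_reads_bruteforce(CharacterVector names, CharacterVector seqs,
                              CharacterVector reads, int max_mm) {
  init_tbl();
  int ngenes = seqs.size(), nreads = reads.size();
  std::vector<std::string> ref(ngenes);
  for (int g = 0; g < ngenes; ++g) ref[g] = as<std::string>(seqs[g]);

  IntegerVector status(nreads), ogene(nreads), opos(nreads), omm(nreads);
  for (int r = 0; r < nreads; ++r) {
    std::string R = as<std::string>(reads[r]);
    long L = (long)R.size();
    int minmm = max_mm + 1;
    long nbest = 0, bg = -1, bp = -1;
    for (int g = 0; g < ngenes; ++g) {
      const std::string &S = ref[g];
      for (long p = 0; p + L <= (long)S.size(); ++p) {
        int mm = 0;
        for (long i = 0; i < L; ++i) {
          if (!(tbl[(unsigned char)R[i]] & tbl[(unsigned char)S[p + i]] &
                0x0f) ||
              tbl[(unsigned char)R[i]] == 0 || tbl[(unsigned char)S[p + i]] == 0) {
            if (++mm > minmm) break;
          }
        }
        if (mm < minmm && mm <= max_mm) {
          minmm = mm;
          nbest = 1;
          bg = g;
          bp = p;
        } else if (mm == minmm && mm <= max_mm) {
          ++nbest;
        }
      }
    }
    if (nbest == 0) {
      status[r] = 2;
      ogene[r] = NA_INTEGER;
      opos[r] = NA_INTEGER;
      omm[r] = NA_INTEGER;
    } else if (nbest > 1) {
      status[r] = 1;
      ogene[r] = NA_INTEGER;
      opos[r] = NA_INTEGER;
      omm[r] = NA_INTEGER;
    } else {
      status[r] = 0;
      ogene[r] = (int)bg + 1;
      opos[r] = (int)bp;
      omm[r] = minmm;
    }
  }
  return List::create(_["status"] = status, _["gene"] = ogene,
                      _["offset"] = opos, _["mismatches"] = omm);
}
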