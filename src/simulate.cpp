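#include <Rcpp.h>
using namespace Rcpp;

// Copy each template `reps[t]` times with independent per-base substitution
// errors at `error_rate` and (optionally) indels at `indel_rate` per base.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector tpl, IntegerVector reps,
                                 double error_rate, double indel_rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  long long total = 0;
  for (int t = 0; t < reps.size(); ++t) total += reps[t];
  CharacterVector out((R_xlen_t) total);
  R_xlen_t k = 0;
  for (int t = 0; t < tpl.size(); ++t) {
    const std::string base = as<std::string>(tpl[t]);
    const int L = (int) base.size();
    for (int r = 0; r < reps[t]; ++r) {
      std::string s = base;
      if (error_rate > 0) {
        int nerr = (int) R::rbinom(L, error_rate);
        for (int e = 0; e < nerr; ++e) {
          int pos = (int) std::floor(unif_rand() * L);
          if (pos >= L) pos = L - 1;
          char cur = s[pos];
          int ci = (cur == 'A') ? 0 : (cur == 'C') ? 1 : (cur == 'G') ? 2 : 3;
          int shift = 1 + (int) std::floor(unif_rand() * 3);
          if (shift > 3) shift = 3;
          s[pos] = BASES[(ci + shift) % 4];
        }
      }
      if (indel_rate > 0) {
        int nind = (int) R::rbinom(L, indel_rate);
        for (int e = 0; e < nind; ++e) {
          int pos = (int) std::floor(unif_rand() * (double) s.size());
          if (pos >= (int) s.size()) pos = (int) s.size() - 1;
          if (unif_rand() < 0.5 && s.size() > 1) {
            s.erase((size_t) pos, 1);
          } else {
            int bi = (int) std::floor(unif_rand() * 4);
            if (bi > 3) bi = 3;
            s.insert((size_t) pos, 1, BASES[bi]);
          }
        }
      }
      out[k++] = s;
    }
  }
  return out;
}
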