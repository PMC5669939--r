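#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Ungapped placement of small-RNA reads against mature miRNAs in hairpin
// context. For each read and each candidate (mature, 5' offset) the read is
// laid on the hairpin at mature_start + offset5; mismatches over the
// canonical body (including a templated 5' extension) are substitutions,
// while in the 3'-extension region beyond the mature end the minimal read
// suffix covering every mismatch (and any overhang past the hairpin) is the
// non-templated tail. Placements violating the parameter bounds are
// discarded; the surviving placement minimizing (n_subs, tail_len,
// |offset5| + |offset3|) lexicographically wins, ties resolved by ascending
// mature index (ids pre-sorted) then ascending offset5 -- implemented by
// strict-improvement iteration order.

struct Best {
  int mat = -1, o5 = 0, o3 = 0, nsub = 0, ntail = 0;
};

static bool evalPlacement(const std::string &r, const std::string &h,
                          int mstart, int mend, int o5, int maxSubs,
                          int maxTail, int &nsub, int &ntail) {
  const int L = (int)r.size();
  const int hl = (int)h.size();
  const int pstart = mstart + o5;
  if (pstart < 0) return false;  // 5' extension must be templated
  int bodyLen = mend - pstart;   // read positions covering [pstart, mend)
  if (bodyLen > L) bodyLen = L;
  if (bodyLen < 0) bodyLen = 0;
  nsub = 0;
  for (int i = 0; i < bodyLen; ++i) {
    const int q = pstart + i;
    if (q >= hl || h[q] != r[i]) {
      if (++nsub > maxSubs) return false;
    }
  }
  int firstMis = -1;
  for (int i = bodyLen; i < L; ++i) {
    const int q = pstart + i;
    const bool mis = (q >= hl) || (h[q] != r[i]);
    if (mis) { firstMis = i; break; }
  }
  ntail = (firstMis < 0) ? 0 : (L - firstMis);
  return ntail <= maxTail;
}

// [[Rcpp::export(name = ".assign_reads_cpp")]]
List assign_reads_cpp(CharacterVector reads, CharacterVector hairpins,
                      IntegerVector mstart, IntegerVector mend,
                      int max5, int max3, int maxTail, int maxSubs,
                      int minLen) {
  const int nr = reads.size();
  const int nm = hairpins.size();
  std::vector<std::string> hp(nm);
  for (int m = 0; m < nm; ++m) hp[m] = as<std::string>(hairpins[m]);

  IntegerVector outIdx(nr, NA_INTEGER), outO5(nr, NA_INTEGER),
      outO3(nr, NA_INTEGER);
  CharacterVector outSubs(nr, NA_STRING), outTail(nr, NA_STRING);

  for (int ri = 0; ri < nr; ++ri) {
    const std::string r = as<std::string>(reads[ri]);
    const int L = (int)r.size();
    if (L < minLen) continue;  // UNASSIGNED, not an error
    Best best;
    bool has = false;
    for (int m = 0; m < nm; ++m) {
      const int mlen = mend[m] - mstart[m];
      // offset3 = o5 + L - mlen must lie in [-max3, max3]
      int lo = mlen - L - max3; if (lo < -max5) lo = -max5;
      int hi = mlen - L + max3; if (hi > max5) hi = max5;
      for (int o5 = lo; o5 <= hi; ++o5) {
        int nsub, ntail;
        if (!evalPlacement(r, hp[m], mstart[m], mend[m], o5, maxSubs,
                           maxTail, nsub, ntail))
          continue;
        const int o3 = o5 + L - mlen;
        const int disp = std::abs(o5) + std::abs(o3);
        const int bdisp = std::abs(best.o5) + std::abs(best.o3);
        if (!has || nsub < best.nsub ||
            (nsub == best.nsub &&
             (ntail < best.ntail ||
              (ntail == best.ntail && disp < bdisp)))) {
          best.mat = m; best.o5 = o5; best.o3 = o3;
          best.nsub = nsub; best.ntail = ntail;
          has = true;
        }
      }
    }
    if (!has) continue;
    outIdx[ri] = best.mat + 1;
    outO5[ri] = best.o5;
    outO3[ri] = best.o3;
    // reconstruct substitution and tail detail for the winning placement
    const std::string &h = hp[best.mat];
    const int pstart = mstart[best.mat] + best.o5;
    int bodyLen = mend[best.mat] - pstart;
    if (bodyLen > L) bodyLen = L;
    if (bodyLen < 0) bodyLen = 0;
    std::string subs;
    for (int i = 0; i < bodyLen; ++i) {
      const int q = pstart + i;
      if (q >= (int)h.size() || h[q] != r[i]) {
        if (!subs.empty()) subs += ";";
        subs += std::to_string(q - mstart[best.mat]);
        subs += ":";
        subs += (q < (int)h.size() ? h[q] : 'N');
        subs += ">";
        subs += r[i];
      }
    }
    outSubs[ri] = subs;
    outTail[ri] = (best.ntail > 0) ? r.substr(L - best.ntail) : "";
  }
  return List::create(_["idx"] = outIdx, _["offset5"] = outO5,
                      _["offset3"] = outO3, _["subs"] = outSubs,
                      _["tail"] = outTail);
}
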