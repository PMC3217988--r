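#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Leftmost occurrence of the 3' adapter in each read, allowing up to
// max_mismatch mismatches over the overlapped region. Suffix overlaps at the
// read end count when at least min_overlap bases overlap. Returns the insert
// length for each read: position of the leftmost hit, or the full read
// length when the adapter is not found.
//' @noRd
// [[Rcpp::export(name = ".clip_adapter_cpp")]]
IntegerVector clip_adapter_cpp(CharacterVector reads, std::string adapter,
                               int max_mismatch, int min_overlap = 6) {
  int n = reads.size();
  int alen = adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    int rlen = read.size();
    int hit = rlen;
    for (int p = 0; p <= rlen - min_overlap; ++p) {
      int overlap = std::min(alen, rlen - p);
      int mm = 0;
      for (int q = 0; q < overlap && mm <= max_mismatch; ++q) {
        if (read[p + q] != adapter[q]) ++mm;
      }
      if (mm <= max_mismatch) { hit = p; break; }
    }
    out[r] = hit;
  }
  return out;
}
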