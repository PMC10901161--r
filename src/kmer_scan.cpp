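// k-mer scanning core: canonicalization and distinct-read hit counting.
// A read increments a key at most once (read-level presence), so the
// per-position counts are bounded by the library size and form valid
// margins for the downstream 2x2 G-test.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;   // non-ACGT
  }
}

// canonical form = lexicographic min of the k-mer and its reverse complement;
// returns false when the window contains a non-ACGT character
static bool canonical_window(const char* s, int k, std::string& out) {
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) {
    char cc = complement(s[k - 1 - i]);
    if (cc == 0) return false;
    rc[i] = cc;
  }
  if (std::char_traits<char>::compare(s, rc.data(), k) <= 0) {
    out.assign(s, k);
  } else {
    out = rc;
  }
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(kmers[i]);
    int k = LENGTH(kmers[i]);
    if (canonical_window(s, k, buf)) {
      out[i] = buf;
    } else {
      out[i] = NA_STRING;
    }
  }
  return out;
}

// For each key (already canonical, all of length k), count the number of
// distinct reads whose canonical k-mer multiset contains it.
// [[Rcpp::export]]
IntegerVector cpp_scan_reads(CharacterVector reads, CharacterVector keys, int k) {
  std::unordered_map<std::string, int> index;
  index.reserve(keys.size() * 2);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    index.emplace(std::string(CHAR(keys[i])), (int)i);
  }
  std::vector<int> counts(keys.size(), 0);
  std::vector<R_xlen_t> last_read(keys.size(), -1);
  std::string buf;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    const char* s = CHAR(reads[r]);
    int len = LENGTH(reads[r]);
    for (int p = 0; p + k <= len; ++p) {
      if (!canonical_window(s + p, k, buf)) continue;
      auto it = index.find(buf);
      if (it != index.end()) {
        int id = it->second;
        if (last_read[id] != r) {   // presence, not occurrence
          counts[id] += 1;
          last_read[id] = r;
        }
      }
    }
  }
  return IntegerVector(counts.begin(), counts.end());
}
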