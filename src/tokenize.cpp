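#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right longest-match tokenization of a repeat tract against
// a motif lexicon ordered longest-first (ties pre-broken by lexicon order).
// Positions matching no motif emit 1-nt NOISE tokens. Coordinates are
// 0-based half-open; tokens tile [0, nchar(seq)) exactly.
// [[Rcpp::export(name = ".tokenize_greedy")]]
DataFrame tokenize_greedy(std::string seq, std::vector<std::string> motifs) {
  const size_t n = seq.size();
  std::vector<int> tok_motif; // 1-based lexicon index, 0 = NOISE
  std::vector<int> tok_start, tok_end;
  tok_motif.reserve(n / 3 + 1);
  tok_start.reserve(n / 3 + 1);
  tok_end.reserve(n / 3 + 1);
  size_t pos = 0;
  while (pos < n) {
    int matched = 0;
    for (size_t m = 0; m < motifs.size(); ++m) {
      const std::string& mot = motifs[m];
      if (mot.size() <= n - pos && seq.compare(pos, mot.size(), mot) == 0) {
        tok_motif.push_back((int)m + 1);
        tok_start.push_back((int)pos);
        pos += mot.size();
        tok_end.push_back((int)pos);
        matched = 1;
        break;
      }
    }
    if (!matched) {
      tok_motif.push_back(0);
      tok_start.push_back((int)pos);
      ++pos;
      tok_end.push_back((int)pos);
    }
  }
  return DataFrame::create(
      _["motif_index"] = tok_motif, _["start"] = tok_start,
      _["end"] = tok_end);
}
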