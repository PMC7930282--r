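#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Exact substring search of each peptide in each subject sequence.
// Returns all occurrences as parallel vectors of 1-based peptide index,
// subject index, and 1-based match position. Case-sensitive; any
// sequence equivalence (e.g. I/L collapse) is applied by the caller
// before the call.

// [[Rcpp::export]]
List match_peptides_cpp(CharacterVector peptides, CharacterVector subjects) {
  std::vector<int> pep_i, sub_i, pos;
  const int np = peptides.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int j = 0; j < ns; ++j) subj[j] = as<std::string>(subjects[j]);
  for (int i = 0; i < np; ++i) {
    const std::string p = as<std::string>(peptides[i]);
    if (p.empty()) continue;
    for (int j = 0; j < ns; ++j) {
      size_t from = 0;
      while (true) {
        size_t at = subj[j].find(p, from);
        if (at == std::string::npos) break;
        pep_i.push_back(i + 1);
        sub_i.push_back(j + 1);
        pos.push_back((int)at + 1);
        from = at + 1;
      }
    }
  }
  return List::create(_["peptide"] = wrap(pep_i),
                      _["subject"] = wrap(sub_i),
                      _["pos"] = wrap(pos));
}
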