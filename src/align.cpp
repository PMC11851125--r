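#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global edit-distance alignment (match 0, mismatch/gap 1) with a full
// traceback. Operations are reported relative to the reference:
//   M match, X mismatch, I insertion (extra read base), D deletion
//   (reference base absent from the read).
// Tie-breaking during traceback is fixed: prefer match/mismatch, then
// deletion, then insertion, so reports are reproducible.
// [[Rcpp::export(name = ".align_cpp")]]
List align_cpp(std::string read, std::string ref) {
  const int n = read.size(), m = ref.size();
  std::vector<int> dp((size_t)(n + 1) * (m + 1));
  auto at = [m](int i, int j) -> size_t { return (size_t)i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) dp[at(0, j)] = j;  // all deletions
  for (int i = 0; i <= n; ++i) dp[at(i, 0)] = i;  // all insertions
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = dp[at(i - 1, j - 1)] + (read[i - 1] == ref[j - 1] ? 0 : 1);
      int del = dp[at(i, j - 1)] + 1;
      int ins = dp[at(i - 1, j)] + 1;
      dp[at(i, j)] = std::min(diag, std::min(del, ins));
    }
  }

  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cur = dp[at(i, j)];
    if (i > 0 && j > 0 &&
        cur == dp[at(i - 1, j - 1)] + (read[i - 1] == ref[j - 1] ? 0 : 1)) {
      ops.push_back(read[i - 1] == ref[j - 1] ? 'M' : 'X');
      --i; --j;
    } else if (j > 0 && cur == dp[at(i, j - 1)] + 1) {
      ops.push_back('D');
      --j;
    } else {
      ops.push_back('I');
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());

  int matches = 0, mismatches = 0, insertions = 0, deletions = 0;
  for (char c : ops) {
    if (c == 'M') ++matches;
    else if (c == 'X') ++mismatches;
    else if (c == 'I') ++insertions;
    else ++deletions;
  }
  return List::create(_["ops"] = ops, _["matches"] = matches,
                      _["mismatches"] = mismatches,
                      _["insertions"] = insertions,
                      _["deletions"] = deletions,
                      _["distance"] = dp[at(n, m)]);
}
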