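// Sequential parts of the digitizer chain: non-paralyzable dead time and
// open-by-first-single coincidence window processing.

#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Non-paralyzable dead time: a single arriving less than tau after the last
// ACCEPTED single in the same electronic unit is discarded.  Times must be
// sorted ascending.
// [[Rcpp::export]]
LogicalVector cpp_dead_time(NumericVector time, IntegerVector unit,
                            double tau_ns) {
  int n = time.size();
  LogicalVector keep(n);
  std::unordered_map<int, double> last;
  last.reserve(1024);
  for (int i = 0; i < n; ++i) {
    if (i > 0 && time[i] < time[i - 1])
      stop("singles must be sorted by time before dead-time filtering");
    auto it = last.find(unit[i]);
    if (it == last.end() || time[i] - it->second >= tau_ns) {
      keep[i] = true;
      last[unit[i]] = time[i];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}

// Coincidence windows: the first qualifying single opens a window of fixed
// width; all singles inside belong to that window; windows do not overlap.
// A window with exactly two singles in opposite panels forms a coincidence;
// windows with more than two singles are discarded entirely ("killAll").
// Returns 1-based indices with the -z panel member first.
// [[Rcpp::export]]
List cpp_coincidence_sort(NumericVector time, IntegerVector panel,
                          double window_ns) {
  int n = time.size();
  std::vector<int> ia, ib;
  int n_multiple = 0, n_same_panel = 0;
  int i = 0;
  while (i < n) {
    if (i > 0 && time[i] < time[i - 1])
      stop("singles must be sorted by time before coincidence sorting");
    int j = i + 1;
    while (j < n && time[j] - time[i] <= window_ns) ++j;
    int cnt = j - i;
    if (cnt == 2) {
      if (panel[i] != panel[i + 1]) {
        if (panel[i] < 0) { ia.push_back(i + 1); ib.push_back(i + 2); }
        else              { ia.push_back(i + 2); ib.push_back(i + 1); }
      } else {
        ++n_same_panel;
      }
    } else if (cnt > 2) {
      ++n_multiple;
    }
    i = j;
  }
  return List::create(_["a"] = wrap(ia), _["b"] = wrap(ib),
                      _["n_multiple"] = n_multiple,
                      _["n_same_panel"] = n_same_panel);
}
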