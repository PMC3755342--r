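#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Cell-type codes: 1 = ISC, 2 = EC, 3 = ee (shared with the R side).
//
// Division placement: the daughter is inserted at the neighbor of the ISC in
// the chosen direction; the ISC's contiguous run of own-lineage progeny along
// that direction shifts one site outward, and the first non-progeny cell at
// the end of the run dies. The walk fails (and a fallback direction is tried)
// when it meets another ISC, the end of the lattice, a blocked boundary, or
// wraps the full circumference. Fallback order after the drawn direction:
// circumferential +1, circumferential -1, away-from-boundary row, remaining
// row. Uses R's RNG so results are reproducible under set.seed().

enum Dir { CPLUS = 0, CMINUS = 1, RPLUS = 2, RMINUS = 3 };

struct Lattice {
  IntegerVector type, lineage, clone;
  NumericVector birth;
  const IntegerVector &region_of_row; // 1-based region index per row
  const LogicalVector &open_fwd, &open_bwd;
  int n_row, n_col;
};

// Walk from the ISC at (r, c) in direction dir collecting the push path.
// On success `path` holds sites p1..pk where pk is the victim (first cell
// not of lineage L); returns true. On failure returns false.
static bool walk(const Lattice &lat, int r, int c, int L, int dir,
                 std::vector<int> &path) {
  path.clear();
  if (dir == CPLUS || dir == CMINUS) {
    int dc = (dir == CPLUS) ? 1 : -1;
    for (int k = 1; k < lat.n_col; ++k) {
      int cc = ((c + dc * k) % lat.n_col + lat.n_col) % lat.n_col;
      int s = r * lat.n_col + cc;
      if (lat.type[s] == 1) return false; // never displace an ISC
      path.push_back(s);
      if (lat.lineage[s] != L) return true;
    }
    return false; // wrapped the whole ring through own progeny
  }
  int dr = (dir == RPLUS) ? 1 : -1;
  int cur = r;
  while (true) {
    int nr = cur + dr;
    if (nr < 0 || nr >= lat.n_row) return false; // tissue end
    int ra = lat.region_of_row[cur], rb = lat.region_of_row[nr];
    if (ra != rb) {
      int b = std::min(ra, rb) - 1; // boundary between region b+1 and b+2
      bool ok = (dr > 0) ? lat.open_fwd[b] : lat.open_bwd[b];
      if (!ok) return false; // blocked boundary
    }
    int s = nr * lat.n_col + c;
    if (lat.type[s] == 1) return false;
    path.push_back(s);
    if (lat.lineage[s] != L) return true;
    cur = nr;
  }
}

// [[Rcpp::export]]
List sim_core(IntegerVector type0, IntegerVector lineage0, IntegerVector clone0,
              NumericVector birth0, IntegerVector region_of_row,
              IntegerVector region_start, IntegerVector region_end,
              NumericVector rate_of_region, NumericVector pee_of_region,
              LogicalVector open_fwd, LogicalVector open_bwd,
              int n_row, int n_col, double t0, double t1, double anisotropy) {
  IntegerVector type = Rcpp::clone(type0);
  IntegerVector lineage = Rcpp::clone(lineage0);
  IntegerVector clone_id = Rcpp::clone(clone0);
  NumericVector birth = Rcpp::clone(birth0);
  Lattice lat{type, lineage, clone_id, birth, region_of_row,
              open_fwd, open_bwd, n_row, n_col};

  // ISC positions and rates are fixed for the whole run: ISCs are never
  // displaced and never change region, so the total event rate is constant.
  std::vector<int> isc;
  std::vector<double> cum;
  double total = 0.0;
  int n_sites = n_row * n_col;
  for (int s = 0; s < n_sites; ++s) {
    if (type[s] == 1) {
      double rate = rate_of_region[region_of_row[s / n_col] - 1];
      if (rate > 0) {
        total += rate;
        isc.push_back(s);
        cum.push_back(total);
      }
    }
  }

  long n_events = 0, n_skipped = 0;
  std::vector<int> path;
  if (total > 0) {
    double t = t0;
    while (true) {
      t += R::rexp(1.0) / total;
      if (t > t1) break;
      double u = R::runif(0.0, total);
      int i = int(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (i >= (int)isc.size()) i = (int)isc.size() - 1;
      int s = isc[i];
      int r = s / n_col, c = s % n_col;
      int L = lineage[s];
      int reg = region_of_row[r]; // 1-based

      // Primary direction: circumferential with probability `anisotropy`.
      int primary;
      if (R::runif(0.0, 1.0) < anisotropy) {
        primary = (R::runif(0.0, 1.0) < 0.5) ? CPLUS : CMINUS;
      } else {
        primary = (R::runif(0.0, 1.0) < 0.5) ? RPLUS : RMINUS;
      }
      // Away-from-boundary row direction: step toward the farther region edge.
      int dist_up = r - region_start[reg - 1];
      int dist_down = (region_end[reg - 1] - 1) - r;
      int away = (dist_up < dist_down) ? RPLUS : RMINUS;
      int order[5] = {primary, CPLUS, CMINUS, away,
                      (away == RPLUS) ? RMINUS : RPLUS};

      bool placed = false;
      for (int k = 0; k < 5 && !placed; ++k) {
        bool dup = false;
        for (int j = 0; j < k; ++j)
          if (order[j] == order[k]) { dup = true; break; }
        if (dup) continue;
        if (walk(lat, r, c, L, order[k], path)) {
          // Shift the own-lineage run outward by one site (victim dies).
          for (int j = (int)path.size() - 1; j >= 1; --j) {
            type[path[j]] = type[path[j - 1]];
            lineage[path[j]] = lineage[path[j - 1]];
            clone_id[path[j]] = clone_id[path[j - 1]];
            birth[path[j]] = birth[path[j - 1]];
          }
          int p1 = path[0];
          type[p1] = (R::runif(0.0, 1.0) < pee_of_region[reg - 1]) ? 3 : 2;
          lineage[p1] = L;
          clone_id[p1] = clone_id[s];
          birth[p1] = t;
          placed = true;
        }
      }
      if (placed) ++n_events; else ++n_skipped;
    }
  }

  return List::create(
    _["type"] = type, _["lineage"] = lineage, _["clone"] = clone_id,
    _["birth"] = birth, _["n_events"] = (double)n_events,
    _["n_skipped"] = (double)n_skipped);
}
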