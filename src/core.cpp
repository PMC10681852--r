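#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Direction order used throughout: 1=N, 2=NE, 3=E, 4=SE, 5=S, 6=SW, 7=W, 8=NW
// (row 1 of the matrix is the northernmost row).
static const int DR[8] = {-1, -1, 0, 1, 1,  1,  0, -1};
static const int DC[8] = { 0,  1, 1, 1, 0, -1, -1, -1};

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  // row-major scan so labels are assigned in first-encounter order
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != TRUE || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int cell = stack.back(); stack.pop_back();
        int cr = cell / nc, cc2 = cell % nc;
        for (int d = 0; d < 8; ++d) {
          int r2 = cr + DR[d], c2 = cc2 + DC[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) == TRUE && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}

static inline bool offmap(const NumericMatrix &cost, int r, int c) {
  return r < 0 || r >= cost.nrow() || c < 0 || c >= cost.ncol() ||
         NumericMatrix::is_na(cost(r, c));
}

// Inverse-distance-weighted mean cost along a directional ray of up to
// pr cells; truncated at the first off-map/nodata cell; +Inf if even the
// first cell is off-map (direction disallowed).
static double eff_cost(const NumericMatrix &cost, int r, int c, int dir, int pr) {
  double num = 0.0, den = 0.0;
  for (int d = 1; d <= pr; ++d) {
    int r2 = r + DR[dir] * d, c2 = c + DC[dir] * d;
    if (offmap(cost, r2, c2)) break;
    num += cost(r2, c2) / d;
    den += 1.0 / d;
  }
  if (den == 0.0) return R_PosInf;
  return num / den;
}

// [[Rcpp::export(name = ".eff_cost_cpp")]]
double eff_cost_export(NumericMatrix cost, int r, int c, int dir, int pr) {
  return eff_cost(cost, r - 1, c - 1, dir - 1, pr);
}

// Relative (unnormalised) step weights for the 8 directions.
// heading: 0 = none (first step), else 1..8. Persistence factor
// dp^((4-k)/4) where k is the number of 45-degree increments between the
// candidate direction and the current heading.
static void step_weights(const NumericMatrix &cost, int r, int c, int heading,
                         double dp, int pr, double *w) {
  for (int d = 0; d < 8; ++d) {
    double ec = eff_cost(cost, r, c, d, pr);
    if (!R_FINITE(ec)) { w[d] = 0.0; continue; }
    double persist = 1.0;
    if (heading >= 1) {
      int k = std::abs(d - (heading - 1));
      if (k > 4) k = 8 - k;
      persist = std::pow(dp, (4.0 - k) / 4.0);
    }
    w[d] = persist / ec;
  }
}

// [[Rcpp::export(name = ".step_weights_cpp")]]
NumericVector step_weights_export(NumericMatrix cost, int r, int c, int heading,
                                  double dp, int pr) {
  double w[8];
  step_weights(cost, r - 1, c - 1, heading, dp, pr, w);
  return NumericVector(w, w + 8);
}

static inline double settle_prob(double N, double K, double alpha, double beta) {
  double z = -alpha * (N / K - beta);
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(z));
}

// [[Rcpp::export(name = ".settle_prob_cpp")]]
double settle_prob_export(double N, double K, double alpha, double beta) {
  return settle_prob(N, K, alpha, beta);
}

// Transfer a batch of dispersers over the cost surface, sequentially (each
// settlement raises the destination's N before the next disperser moves).
// patch: integer patch-id matrix (0 = matrix habitat, NA = off-map).
// srow/scol: 1-based start cells. N, K: per-patch (index = patch id).
// max_path is the path-length budget in cardinal-step units; diagonal steps
// consume sqrt(2) units, so the maximum Euclidean displacement equals
// max_path * cell_size exactly (attained by a straight cardinal path).
// Returns outcome (settled patch id, 0 = died), steps taken, net
// displacement in cell units, and the updated N vector.
// [[Rcpp::export(name = ".transfer_batch_cpp")]]
List transfer_batch_cpp(IntegerMatrix patch, NumericMatrix cost,
                        IntegerVector natal, IntegerVector srow, IntegerVector scol,
                        NumericVector N0, NumericVector K,
                        double dp, int pr, double max_path,
                        double alpha, double beta) {
  int n = natal.size();
  NumericVector N = clone(N0);
  IntegerVector outcome(n);
  IntegerVector steps(n);
  NumericVector displacement(n);
  const double SQRT2 = std::sqrt(2.0);
  double w[8];
  for (int i = 0; i < n; ++i) {
    int r = srow[i] - 1, c = scol[i] - 1;
    int r0 = r, c0 = c;
    int heading = 0, nstep = 0;
    double dist = 0.0;
    int out = 0;
    while (true) {
      step_weights(cost, r, c, heading, dp, pr, w);
      double tot = 0.0;
      for (int d = 0; d < 8; ++d) tot += w[d];
      if (tot <= 0.0) break;               // fully enclosed: dies
      double u = unif_rand() * tot;
      int dir = 0;
      double acc = 0.0;
      for (int d = 0; d < 8; ++d) { acc += w[d]; if (u <= acc) { dir = d; break; } }
      double len = (DR[dir] != 0 && DC[dir] != 0) ? SQRT2 : 1.0;
      if (dist + len > max_path + 1e-9) break;   // budget exhausted: dies
      r += DR[dir]; c += DC[dir];
      dist += len; ++nstep;
      heading = dir + 1;
      int p = patch(r, c);
      if (p != NA_INTEGER && p > 0 && p != natal[i]) {
        double ps = settle_prob(N[p - 1], K[p - 1], alpha, beta);
        if (unif_rand() < ps) { out = p; N[p - 1] += 1.0; break; }
      }
    }
    outcome[i] = out;
    steps[i] = nstep;
    double dx = c - c0, dy = r - r0;
    displacement[i] = std::sqrt(dx * dx + dy * dy);
  }
  return List::create(_["outcome"] = outcome, _["steps"] = steps,
                      _["displacement"] = displacement, _["N"] = N);
}
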