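#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Half-away-from-zero rounding of a threshold before rule enforcement.
// std::round implements exactly this convention.
static inline int roundThreshold(double x) {
  return (int) std::round(x);
}

// Moore-neighbourhood offsets in fixed row-major order; parent choice
// indexes live neighbours in this order, so the order is part of the
// reproducibility contract.
static const int OFF_R[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int OFF_C[8] = {-1,  0,  1, -1, 1, -1, 0, 1};

// One synchronous generation of the mutable-rule Game of Life.
//
// Occupancy fates are always computed from the pre-step occupancy; the
// next occupancy buffer starts all-dead and only interior sites are
// written, so border sites are dead from generation 1 onward. Genome
// grids are updated either synchronously (inheritance reads the
// pre-step grids; order-independent) or in raster mode (in place, in
// row-major site order, emulating nested-loop implementations).
//
// Per birth the RNG draw sequence is fixed: parent index, uniform
// mutation gate, then (only if mutated) gene index and one standard
// normal deviate. Draws use unif_rand()/norm_rand(), i.e. the same
// stream as R's runif()/rnorm().
// [[Rcpp::export]]
List lifeStepCpp(IntegerMatrix occ,
                 NumericMatrix lonely,
                 NumericMatrix born,
                 NumericMatrix crowded,
                 double rate,
                 double magnitude,
                 bool parentalBirth,
                 bool rasterGenome,
                 bool collectEvents) {
  const int nr = occ.nrow(), nc = occ.ncol();
  IntegerMatrix newOcc(nr, nc);            // starts all dead
  NumericMatrix newLon = clone(lonely);
  NumericMatrix newBrn = clone(born);
  NumericMatrix newCrw = clone(crowded);

  // fate pass: pre-step occupancy and pre-step genomes only
  for (int i = 1; i < nr - 1; ++i) {
    for (int j = 1; j < nc - 1; ++j) {
      int m = 0;
      for (int k = 0; k < 8; ++k)
        m += occ(i + OFF_R[k], j + OFF_C[k]);
      if (occ(i, j) == 1) {
        int lo = roundThreshold(lonely(i, j));
        int hi = roundThreshold(crowded(i, j));
        if (m >= lo && m <= hi) newOcc(i, j) = 1;
      } else {
        if (parentalBirth) {
          // born if m matches the rounded born threshold of at least
          // one live neighbour
          for (int k = 0; k < 8; ++k) {
            int pi = i + OFF_R[k], pj = j + OFF_C[k];
            if (occ(pi, pj) == 1 && roundThreshold(born(pi, pj)) == m) {
              newOcc(i, j) = 1;
              break;
            }
          }
        } else {
          // site mode: the genome stored at the empty site decides
          if (m == roundThreshold(born(i, j))) newOcc(i, j) = 1;
        }
      }
    }
  }

  std::vector<int> bR, bC, pR, pC, gene, dR, dC;
  std::vector<int> mut;
  std::vector<double> delta;

  // genome pass in row-major site order over the full lattice
  // (deaths can occur on the border at generation 0)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool wasLive = occ(i, j) == 1;
      bool isLive = newOcc(i, j) == 1;
      if (wasLive && !isLive) {
        newLon(i, j) = 2.0; newBrn(i, j) = 3.0; newCrw(i, j) = 3.0;
        if (collectEvents) { dR.push_back(i + 1); dC.push_back(j + 1); }
      } else if (!wasLive && isLive) {
        // candidate parents among live neighbours (pre-step occupancy)
        int candR[8], candC[8], k = 0;
        int m = 0;
        for (int q = 0; q < 8; ++q) {
          int pi = i + OFF_R[q], pj = j + OFF_C[q];
          if (occ(pi, pj) == 1) ++m;
        }
        for (int q = 0; q < 8; ++q) {
          int pi = i + OFF_R[q], pj = j + OFF_C[q];
          if (occ(pi, pj) != 1) continue;
          if (parentalBirth) {
            double bsrc = rasterGenome ? newBrn(pi, pj) : born(pi, pj);
            if (roundThreshold(bsrc) != m) continue;
          }
          candR[k] = pi; candC[k] = pj; ++k;
        }
        if (k == 0) {
          // no eligible parent: wildtype child, no mutation, no draws
          newLon(i, j) = 2.0; newBrn(i, j) = 3.0; newCrw(i, j) = 3.0;
          if (collectEvents) {
            bR.push_back(i + 1); bC.push_back(j + 1);
            pR.push_back(NA_INTEGER); pC.push_back(NA_INTEGER);
            mut.push_back(0); gene.push_back(NA_INTEGER); delta.push_back(0.0);
          }
          continue;
        }
        int idx = (int)(k * unif_rand());
        if (idx >= k) idx = k - 1;
        int pi = candR[idx], pj = candC[idx];
        double cl, cb, cc;
        if (rasterGenome) {
          cl = newLon(pi, pj); cb = newBrn(pi, pj); cc = newCrw(pi, pj);
        } else {
          cl = lonely(pi, pj); cb = born(pi, pj); cc = crowded(pi, pj);
        }
        bool mutated = unif_rand() < rate;
        int g = NA_INTEGER;
        double d = 0.0;
        if (mutated) {
          g = (int)(3 * unif_rand());
          if (g >= 3) g = 2;
          d = magnitude * norm_rand();
          if (g == 0) cl += d; else if (g == 1) cb += d; else cc += d;
          g += 1;  // 1 = lonely, 2 = born, 3 = crowded
        }
        newLon(i, j) = cl; newBrn(i, j) = cb; newCrw(i, j) = cc;
        if (collectEvents) {
          bR.push_back(i + 1); bC.push_back(j + 1);
          pR.push_back(pi + 1); pC.push_back(pj + 1);
          mut.push_back(mutated ? 1 : 0); gene.push_back(g); delta.push_back(d);
        }
      }
      // survivors keep their genome
    }
  }

  List out = List::create(
    _["occupancy"] = newOcc,
    _["lonely"] = newLon,
    _["born"] = newBrn,
    _["crowded"] = newCrw);
  if (collectEvents) {
    out["births"] = DataFrame::create(
      _["row"] = bR, _["col"] = bC,
      _["parent_row"] = pR, _["parent_col"] = pC,
      _["mutated"] = mut, _["gene"] = gene, _["delta"] = delta);
    out["deaths"] = DataFrame::create(_["row"] = dR, _["col"] = dC);
  }
  return out;
}
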