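// Maximum common connected subgraph search (McGregor-style branch and
// bound) over two small molecular graphs. The hot loop of the crossover
// operator: called once per parent pair per run.
//
// Atoms are compared by a precomputed compatibility matrix, bonds by
// integer codes (0 = no bond). The search branches over mapping a
// frontier atom of A to each compatible neighbor image in B, or
// excluding it; it prunes when the incumbent cannot be beaten, and stops
// after a fixed node budget (deterministic anytime behaviour), returning
// the best mapping found.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Search {
  int nA, nB;
  const IntegerMatrix &codeA, &codeB;   // nA x nA / nB x nB bond codes
  const LogicalMatrix &compat;          // nA x nB atom compatibility
  std::vector<std::vector<int>> nbrA, nbrB;
  std::vector<int> degA;
  std::vector<int> mapAB;               // -2 unmapped, -1 excluded, >=0 image
  std::vector<char> usedB;
  std::vector<int> adjCnt;
  int nMapped = 0, nExcluded = 0;
  long nodesLeft;
  bool hitBudget = false;
  std::vector<int> bestA, bestB;

  Search(const IntegerMatrix &cA, const IntegerMatrix &cB,
         const LogicalMatrix &cm, long budget)
      : nA(cm.nrow()), nB(cm.ncol()), codeA(cA), codeB(cB), compat(cm),
        nodesLeft(budget) {
    nbrA.resize(nA);
    degA.resize(nA);
    for (int i = 0; i < nA; ++i) {
      for (int j = 0; j < nA; ++j)
        if (codeA(i, j) != 0) nbrA[i].push_back(j);
      degA[i] = (int)nbrA[i].size();
    }
    nbrB.resize(nB);
    for (int i = 0; i < nB; ++i)
      for (int j = 0; j < nB; ++j)
        if (codeB(i, j) != 0) nbrB[i].push_back(j);
    mapAB.assign(nA, -2);
    usedB.assign(nB, 0);
    adjCnt.assign(nA, 0);
  }

  void bump(int w, int d) {
    for (int u : nbrA[w]) adjCnt[u] += d;
  }

  void record() {
    if (nMapped > (int)bestA.size()) {
      bestA.clear();
      bestB.clear();
      for (int i = 0; i < nA; ++i)
        if (mapAB[i] >= 0) {
          bestA.push_back(i);
          bestB.push_back(mapAB[i]);
        }
    }
  }

  void grow() {
    if (hitBudget) return;
    if (--nodesLeft <= 0) {
      hitBudget = true;
      return;
    }
    record();
    int freeB = 0;
    for (int j = 0; j < nB; ++j)
      if (!usedB[j]) ++freeB;
    int potential = std::min(nA - nMapped - nExcluded, freeB);
    if (nMapped + potential <= (int)bestA.size()) return;
    // frontier atom with the highest degree
    int w = -1, wd = -1;
    for (int i = 0; i < nA; ++i)
      if (mapAB[i] == -2 && adjCnt[i] > 0 && degA[i] > wd) {
        w = i;
        wd = degA[i];
      }
    if (w < 0) return;
    // candidate images: unused compatible B atoms consistent on every
    // bond into the mapped part
    for (int jb = 0; jb < nB; ++jb) {
      if (usedB[jb] || !compat(w, jb)) continue;
      bool ok = true;
      for (int u : nbrA[w]) {
        if (mapAB[u] >= 0 && codeA(w, u) != codeB(jb, mapAB[u])) {
          ok = false;
          break;
        }
      }
      if (!ok) continue;
      mapAB[w] = jb;
      usedB[jb] = 1;
      ++nMapped;
      bump(w, 1);
      grow();
      bump(w, -1);
      mapAB[w] = -2;
      usedB[jb] = 0;
      --nMapped;
      if (hitBudget) return;
    }
    // branch: exclude w entirely
    mapAB[w] = -1;
    ++nExcluded;
    grow();
    mapAB[w] = -2;
    --nExcluded;
  }
};

}  // namespace

// [[Rcpp::export(name = ".mcsSearchCpp")]]
List mcsSearchCpp(IntegerMatrix codeA, IntegerMatrix codeB,
                  LogicalMatrix compat, double budget, int seedCap) {
  Search s(codeA, codeB, compat, (long)budget);
  // seed pairs in decreasing degree of the A atom (stable order)
  std::vector<std::pair<int, int>> seeds;
  for (int i = 0; i < s.nA; ++i)
    for (int j = 0; j < s.nB; ++j)
      if (compat(i, j)) seeds.push_back({i, j});
  std::stable_sort(seeds.begin(), seeds.end(),
                   [&](const std::pair<int, int> &x,
                       const std::pair<int, int> &y) {
                     return s.degA[x.first] > s.degA[y.first];
                   });
  if ((int)seeds.size() > seedCap) seeds.resize(seedCap);
  for (auto &sd : seeds) {
    if (s.hitBudget) break;
    if ((int)s.bestA.size() >= std::min(s.nA, s.nB)) break;
    int i = sd.first, j = sd.second;
    s.mapAB[i] = j;
    s.usedB[j] = 1;
    s.nMapped = 1;
    s.bump(i, 1);
    s.grow();
    s.bump(i, -1);
    s.mapAB[i] = -2;
    s.usedB[j] = 0;
    s.nMapped = 0;
  }
  IntegerVector a(s.bestA.begin(), s.bestA.end());
  IntegerVector b(s.bestB.begin(), s.bestB.end());
  return List::create(_["a"] = a + 1, _["b"] = b + 1,
                      _["budgetExhausted"] = s.hitBudget);
}
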