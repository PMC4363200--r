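// Explicit-duration (segment-level) Viterbi decoding for a generalised HMM.
//
// The R side precomputes, per state, everything needed to score a candidate
// segment in O(k):
//   type 0 (Markov chain): cum   -- (L+1) x 3 cumulative per-position
//                                   log-probabilities, one column per segment
//                                   start residue class (s-1) mod 3 (columns
//                                   identical for non-periodic chains);
//                          bc    -- L x k backoff corrections: bc(s-1, r) is
//                                   added when the segment starts at s and
//                                   covers offset r (segment-local context).
//   type 1 (window)      : wscore -- score of the fixed-length window
//                                    starting at each position.
// Durations arrive materialised on a grid (dmin, dstep, durlog); entries
// below -1e25 are inadmissible.  Constraint masks and composition penalties
// are folded into cum / wscore by the caller.
//
// Tie-break: among equal-scoring parses, the one whose boundary sequence
// (segment end positions, left to right) is lexicographically smallest wins;
// remaining ties are broken by state index, left to right.  Scores within a
// small relative tolerance are treated as tied so that the decoder agrees
// with the exhaustive-enumeration oracle on symmetric constructions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG_GUARD = -1e25;

struct StateSpec {
  int type;            // 0 Markov, 1 window
  int dmin, dstep;
  std::vector<double> durlog;
  NumericMatrix cum;   // type 0
  NumericMatrix bc;    // type 0 (L x k, k may be 0)
  IntegerMatrix fcum;  // type 0: (L+1) x 3 prefix counts of forbidden positions per start class
  std::vector<int> lastForb[3]; // per class: last forbidden position <= j
  int k;
  std::vector<double> wscore; // type 1
};

struct Decoder {
  int L, n;
  NumericMatrix ltrans;
  NumericVector lbegin, lend;
  std::vector<StateSpec> st;
  std::vector<double> V;      // (L+1) x n
  std::vector<int> btd, bts;  // chosen duration / predecessor state (-1 begin)
  std::vector<double> BPval;  // transposed: [q * (L+1) + pos]
  std::vector<int> BPstate;

  inline double &v(int pos, int q) { return V[(size_t)pos * n + q]; }
  inline int idx(int pos, int q) const { return pos * n + q; }
  inline int bidx(int pos, int q) const { return q * (L + 1) + pos; }

  // reconstruct (ends, states) of the stored best path at cell (pos, q)
  void reconstruct(int pos, int q, std::vector<int> &ends,
                   std::vector<int> &states) const {
    ends.clear(); states.clear();
    while (pos > 0) {
      ends.push_back(pos);
      states.push_back(q);
      int d = btd[idx(pos, q)];
      int pq = bts[idx(pos, q)];
      pos -= d;
      q = pq;
    }
    std::reverse(ends.begin(), ends.end());
    std::reverse(states.begin(), states.end());
  }

  // TRUE if path A (ends/states) is strictly preferred over path B
  static bool pathLess(const std::vector<int> &endsA, const std::vector<int> &statesA,
                       const std::vector<int> &endsB, const std::vector<int> &statesB) {
    size_t m = std::min(endsA.size(), endsB.size());
    for (size_t i = 0; i < m; ++i) {
      if (endsA[i] != endsB[i]) return endsA[i] < endsB[i];
    }
    if (endsA.size() != endsB.size()) return endsA.size() < endsB.size();
    for (size_t i = 0; i < m; ++i) {
      if (statesA[i] != statesB[i]) return statesA[i] < statesB[i];
    }
    return false;
  }

  // candidate path = best path at (prevend, pstate) + segment (q, end j)
  void candidatePath(int prevend, int pstate, int j, int q,
                     std::vector<int> &ends, std::vector<int> &states) const {
    if (prevend == 0) { ends.clear(); states.clear(); }
    else reconstruct(prevend, pstate, ends, states);
    ends.push_back(j);
    states.push_back(q);
  }
};

// exact emission score (the loop above had a placeholder; implement properly)
static double emission(const Decoder &D, int q, int s, int e) {
  const StateSpec &sp = D.st[q];
  if (sp.type == 1) return sp.wscore[s - 1];
  int c = (s - 1) % 3;
  if (sp.fcum(e, c) - sp.fcum(s - 1, c) > 0) return 2.0 * NEG_GUARD;
  double val = sp.cum(e, c) - sp.cum(s - 1, c);
  int len = e - s + 1;
  int kk = sp.k < len ? sp.k : len;
  for (int r = 0; r < kk; ++r) val += sp.bc(s - 1, r);
  return val;
}

// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(int L, NumericMatrix ltrans, NumericVector lbegin,
                 NumericVector lend, List stateSpecs) {
  Decoder D;
  D.L = L;
  D.n = stateSpecs.size();
  D.ltrans = ltrans;
  D.lbegin = lbegin;
  D.lend = lend;
  D.st.resize(D.n);
  for (int q = 0; q < D.n; ++q) {
    List s = stateSpecs[q];
    StateSpec sp;
    sp.type = as<int>(s["type"]);
    sp.dmin = as<int>(s["dmin"]);
    sp.dstep = as<int>(s["dstep"]);
    sp.durlog = as<std::vector<double> >(s["durlog"]);
    if (sp.type == 0) {
      sp.cum = as<NumericMatrix>(s["cum"]);
      sp.bc = as<NumericMatrix>(s["bc"]);
      sp.fcum = as<IntegerMatrix>(s["fcum"]);
      sp.k = sp.bc.ncol();
      for (int c = 0; c < 3; ++c) {
        sp.lastForb[c].assign(L + 1, 0);
        for (int j = 1; j <= L; ++j)
          sp.lastForb[c][j] = (sp.fcum(j, c) > sp.fcum(j - 1, c))
                              ? j : sp.lastForb[c][j - 1];
      }
    } else {
      sp.wscore = as<std::vector<double> >(s["wscore"]);
      sp.k = 0;
    }
    D.st[q] = sp;
  }

  int n = D.n;
  D.V.assign((size_t)(L + 1) * n, -std::numeric_limits<double>::infinity());
  D.btd.assign((size_t)(L + 1) * n, 0);
  D.bts.assign((size_t)(L + 1) * n, -1);
  D.BPval.assign((size_t)(L + 1) * n, -std::numeric_limits<double>::infinity());
  D.BPstate.assign((size_t)(L + 1) * n, -1);

  std::vector<int> eA, sA, eB, sB;

  for (int j = 1; j <= L; ++j) {
    for (int q = 0; q < n; ++q) {
      const StateSpec &sp = D.st[q];
      double best = -std::numeric_limits<double>::infinity();
      int bestd = 0, bestp = -1;
      int nd = (int)sp.durlog.size();
      int minlf = 0;
      if (sp.type == 0)
        minlf = std::min(sp.lastForb[0][j],
                         std::min(sp.lastForb[1][j], sp.lastForb[2][j]));
      for (int gi = 0; gi < nd; ++gi) {
        double dl = sp.durlog[gi];
        if (dl < NEG_GUARD) continue;
        int d = sp.dmin + gi * sp.dstep;
        if (d > j) break;
        int prevend = j - d;
        if (sp.type == 0) {
          // segment [prevend+1, j] must not cover a position forbidden for
          // its start residue class; prevend < lastForb means it does
          if (prevend < minlf) break;          // all classes forbidden onward
          if (prevend < sp.lastForb[prevend % 3][j]) continue;
        }
        double prior;
        int pstate;
        if (prevend == 0) {
          prior = D.lbegin[q];
          pstate = -1;
        } else {
          prior = D.BPval[D.bidx(prevend, q)];
          pstate = D.BPstate[D.bidx(prevend, q)];
        }
        if (prior < NEG_GUARD || !std::isfinite(prior)) continue;
        double em = emission(D, q, prevend + 1, j);
        if (em < NEG_GUARD) continue;
        double sc = prior + dl + em;
        if (sc < NEG_GUARD) continue;
        if (!std::isfinite(best)) { best = sc; bestd = d; bestp = pstate; continue; }
        double tol = 1e-10 * (1.0 + std::fabs(best));
        if (sc > best + tol) {
          best = sc; bestd = d; bestp = pstate;
        } else if (sc >= best - tol && bestd > 0) {
          // tie: compare full candidate paths
          D.candidatePath(prevend, pstate, j, q, eA, sA);
          D.candidatePath(j - bestd, bestp, j, q, eB, sB);
          if (Decoder::pathLess(eA, sA, eB, sB)) {
            best = sc; bestd = d; bestp = pstate;
          }
        }
      }
      if (std::isfinite(best) && best > NEG_GUARD) {
        D.v(j, q) = best;
        D.btd[D.idx(j, q)] = bestd;
        D.bts[D.idx(j, q)] = bestp;
      }
    }
    // incoming-best for the next rows: BP[j][q] = max_{q'} V[j][q'] + ltrans(q', q)
    for (int q = 0; q < n; ++q) {
      double best = -std::numeric_limits<double>::infinity();
      int bq = -1;
      for (int qp = 0; qp < n; ++qp) {
        double vq = D.v(j, qp);
        if (!std::isfinite(vq) || vq < NEG_GUARD) continue;
        double t = D.ltrans(qp, q);
        if (t < NEG_GUARD) continue;
        double sc = vq + t;
        if (!std::isfinite(best)) { best = sc; bq = qp; continue; }
        double tol = 1e-10 * (1.0 + std::fabs(best));
        if (sc > best + tol) { best = sc; bq = qp; }
        else if (sc >= best - tol && bq >= 0) {
          D.reconstruct(j, qp, eA, sA);
          D.reconstruct(j, bq, eB, sB);
          if (Decoder::pathLess(eA, sA, eB, sB)) { best = sc; bq = qp; }
        }
      }
      D.BPval[D.bidx(j, q)] = best;
      D.BPstate[D.bidx(j, q)] = bq;
    }
  }

  // termination
  double best = -std::numeric_limits<double>::infinity();
  int bq = -1;
  for (int q = 0; q < n; ++q) {
    double vq = D.v(L, q);
    if (!std::isfinite(vq) || vq < NEG_GUARD) continue;
    double e = D.lend[q];
    if (e < NEG_GUARD) continue;
    double sc = vq + e;
    if (!std::isfinite(best)) { best = sc; bq = q; continue; }
    double tol = 1e-10 * (1.0 + std::fabs(best));
    if (sc > best + tol) { best = sc; bq = q; }
    else if (sc >= best - tol && bq >= 0) {
      D.reconstruct(L, q, eA, sA);
      D.reconstruct(L, bq, eB, sB);
      if (Decoder::pathLess(eA, sA, eB, sB)) { best = sc; bq = q; }
    }
  }

  if (bq < 0 || !std::isfinite(best) || best < NEG_GUARD) {
    return List::create(Named("ok") = false);
  }

  std::vector<int> ends, states;
  D.reconstruct(L, bq, ends, states);
  int m = (int)ends.size();
  IntegerMatrix path(m, 3);
  int prev = 0;
  for (int i = 0; i < m; ++i) {
    path(i, 0) = states[i] + 1;
    path(i, 1) = prev + 1;
    path(i, 2) = ends[i];
    prev = ends[i];
  }
  return List::create(Named("ok") = true, Named("logprob") = best,
                      Named("path") = path);
}
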