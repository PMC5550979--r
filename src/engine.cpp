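// Core stochastic update engine for the off-lattice cell model.
//
// State layout (all 0-based inside C++):
//   nx, ny    : N x 8 node coordinates (um), ring order fixed
//   heading   : N   migration direction (radians)
//   leader    : N   index 0..7 of the leader node
//   pop       : N   population index 0/1
//   linkC     : N x 8 partner cell of the adhesion link on this node (-1 none)
//   linkN     : N x 8 partner node index
//   avoidC    : N x 8 partner cells this cell will not re-link to (-1 empty)
//   avoidS    : N x 8 remaining steps of each avoidance entry
//   commit    : N   remaining steps of the committed post-collapse escape
//                   phase (heading locked while positive)
//
// Adhesion links are compliant tethers: a linked node pair can separate up
// to linkStretch (membranes slide along each other while the cells stay in
// contact) before the constraint solver pulls it back.  Link breaking is
// stochastic at the per-minute pair-class hazard, evaluated once per
// decision tick.
//
// All randomness goes through R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <cmath>
#include <climits>
#include <vector>
using namespace Rcpp;

static const double RADIAL_STIFF = 0.2;  // per-sweep pull toward the ideal radius
static const double CONV_TOL = 1e-4;     // um; sweeps exit early below this

// ---------------------------------------------------------------------------
// uniform grid over node positions for neighbour queries
struct Grid {
  double minx, miny, bin;
  int nbx, nby;
  std::vector<int> head, nxt;

  void build(const NumericMatrix& X, const NumericMatrix& Y,
             double arenaR, double binsize) {
    bin = binsize;
    minx = -arenaR - bin;
    miny = -arenaR - bin;
    nbx = (int)std::ceil((2.0 * arenaR + 2.0 * bin) / bin) + 2;
    nby = nbx;
    head.assign((size_t)nbx * nby, -1);
    const int n = X.nrow() * 8;
    nxt.assign(n, -1);
    for (int c = 0; c < X.nrow(); ++c) {
      for (int i = 0; i < 8; ++i) {
        int id = c * 8 + i;
        int bx = (int)((X(c, i) - minx) / bin);
        int by = (int)((Y(c, i) - miny) / bin);
        if (bx < 0) bx = 0; if (bx >= nbx) bx = nbx - 1;
        if (by < 0) by = 0; if (by >= nby) by = nby - 1;
        int b = by * nbx + bx;
        nxt[id] = head[b];
        head[b] = id;
      }
    }
  }

  template <typename F>
  void forNeighbours(double x, double y, F f) const {
    int bx = (int)((x - minx) / bin);
    int by = (int)((y - miny) / bin);
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = by + dy;
      if (yy < 0 || yy >= nby) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = bx + dx;
        if (xx < 0 || xx >= nbx) continue;
        for (int id = head[(size_t)yy * nbx + xx]; id >= 0; id = nxt[id]) f(id);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// event log: 0 link_form, 1 link_break, 2 repulsion, 3 dir_change
struct EventLog {
  bool keep;
  std::vector<int> step, type, cellA, nodeA, cellB, nodeB;
  long counts[4];
  EventLog(bool keep_) : keep(keep_) { for (int k = 0; k < 4; ++k) counts[k] = 0; }
  void add(int s, int t, int ca, int na, int cb, int nb) {
    counts[t]++;
    if (keep) {
      step.push_back(s); type.push_back(t);
      cellA.push_back(ca); nodeA.push_back(na);
      cellB.push_back(cb); nodeB.push_back(nb);
    }
  }
  DataFrame frame() const {
    return DataFrame::create(_["step"] = step, _["type"] = type,
                             _["cell_a"] = cellA, _["node_a"] = nodeA,
                             _["cell_b"] = cellB, _["node_b"] = nodeB);
  }
};

static inline void centroidOf(const NumericMatrix& X, const NumericMatrix& Y,
                              int c, double& cx, double& cy) {
  cx = 0.0; cy = 0.0;
  for (int i = 0; i < 8; ++i) { cx += X(c, i); cy += Y(c, i); }
  cx /= 8.0; cy /= 8.0;
}

static inline void setHeadingToNode(NumericMatrix& X, NumericMatrix& Y,
                                    NumericVector& heading, IntegerVector& leader,
                                    int c, int k) {
  double cx, cy;
  centroidOf(X, Y, c, cx, cy);
  heading[c] = std::atan2(Y(c, k) - cy, X(c, k) - cx);
  leader[c] = k;
}

static inline int nearestNodeToHeading(const NumericMatrix& X, const NumericMatrix& Y,
                                       double h, int c) {
  double cx, cy, best = -2.0;
  int bi = 0;
  centroidOf(X, Y, c, cx, cy);
  for (int i = 0; i < 8; ++i) {
    double a = std::atan2(Y(c, i) - cy, X(c, i) - cx);
    double sc = std::cos(a - h);
    if (sc > best) { best = sc; bi = i; }
  }
  return bi;
}

// pairwise avoidance: after a break the two cells will not re-link to each
// other for a while; other partners are unaffected.  Entries live in both
// cells' tables, so checking one side suffices.
static inline bool avoids(const IntegerMatrix& avoidC, int c, int partner) {
  for (int k = 0; k < 8; ++k)
    if (avoidC(c, k) == partner) return true;
  return false;
}

static inline void addAvoid(IntegerMatrix& avoidC, IntegerMatrix& avoidS,
                            int c, int partner, int steps) {
  int slot = -1;
  for (int k = 0; k < 8; ++k) {
    if (avoidC(c, k) == partner) { slot = k; break; }
    if (slot < 0 && avoidC(c, k) < 0) slot = k;
  }
  if (slot < 0) {  // table full: evict the entry expiring soonest
    slot = 0;
    for (int k = 1; k < 8; ++k)
      if (avoidS(c, k) < avoidS(c, slot)) slot = k;
    avoidC(c, slot) = -1;
  }
  if (avoidC(c, slot) == partner) {
    if (avoidS(c, slot) < steps) avoidS(c, slot) = steps;
  } else {
    avoidC(c, slot) = partner;
    avoidS(c, slot) = steps;
  }
}

// ---------------------------------------------------------------------------
// phase 1: link formation. Greedy in node order; a node takes its nearest
// eligible partner within contactDist (ties: lower cell id, then node id).
static void phaseFormLinks(NumericMatrix& X, NumericMatrix& Y,
                           IntegerMatrix& linkC, IntegerMatrix& linkN,
                           const IntegerMatrix& avoidC,
                           double contactDist, double arenaR,
                           EventLog& log, int step) {
  Grid g;
  g.build(X, Y, arenaR, std::max(contactDist, 1.0));
  const double cd2 = contactDist * contactDist;
  const int N = X.nrow();
  for (int c = 0; c < N; ++c) {
    for (int i = 0; i < 8; ++i) {
      if (linkC(c, i) >= 0) continue;
      int bc = -1, bi = -1;
      double bd2 = R_PosInf;
      double x = X(c, i), y = Y(c, i);
      g.forNeighbours(x, y, [&](int id2) {
        int c2 = id2 / 8, i2 = id2 % 8;
        if (c2 == c) return;
        if (linkC(c2, i2) >= 0) return;
        double dx = X(c2, i2) - x, dy = Y(c2, i2) - y;
        double d2 = dx * dx + dy * dy;
        if (d2 > cd2) return;
        if (d2 < bd2 || (d2 == bd2 && (c2 < bc || (c2 == bc && i2 < bi)))) {
          if (avoids(avoidC, c, c2)) return;
          bd2 = d2; bc = c2; bi = i2;
        }
      });
      if (bc >= 0) {
        linkC(c, i) = bc; linkN(c, i) = bi;
        linkC(bc, bi) = c; linkN(bc, bi) = i;
        log.add(step, 0, c, i, bc, bi);
      }
    }
  }
}

// phases 2+3: stochastic link breaking and repulsion, evaluated once per
// decision tick at the per-minute pair-class hazard.  When a link breaks,
// each endpoint cell independently evaluates its response: under directed
// interaction a Bernoulli(pRep) success moves the leader to the node
// opposite the broken one (a collapse/repulsion) and commits the cell to
// that escape direction for the collapse refractory period; under
// undirected ("adhesion-only") interaction the leader is re-chosen
// uniformly at random.
static void phaseBreakLinks(NumericMatrix& X, NumericMatrix& Y,
                            NumericVector& heading, IntegerVector& leader,
                            const IntegerVector& pop,
                            IntegerMatrix& linkC, IntegerMatrix& linkN,
                            IntegerMatrix& avoidC, IntegerMatrix& avoidS,
                            int refractSteps, const IntegerMatrix& escapeSteps,
                            const NumericMatrix& pTick, const NumericMatrix& pRep,
                            const IntegerMatrix& directed,
                            std::vector<int>& repelled, IntegerVector& commit,
                            EventLog& log, int step) {
  const int N = X.nrow();
  for (int c = 0; c < N; ++c) {
    for (int i = 0; i < 8; ++i) {
      int c2 = linkC(c, i);
      if (c2 < 0 || c2 < c) continue;  // visit each link once
      if (unif_rand() >= pTick(pop[c], pop[c2])) continue;
      int i2 = linkN(c, i);
      linkC(c, i) = -1; linkN(c, i) = -1;
      linkC(c2, i2) = -1; linkN(c2, i2) = -1;
      log.add(step, 1, c, i, c2, i2);
      int avoidTime = refractSteps;
      const int cells[2] = { c, c2 };
      const int nodes[2] = { i, i2 };
      for (int s = 0; s < 2; ++s) {
        int cs = cells[s], ns = nodes[s], co = cells[1 - s];
        int ps = pop[cs], po = pop[co];
        if (directed(ps, po)) {
          if (unif_rand() < pRep(ps, po)) {
            const int esc = escapeSteps(ps, po);
            // repolarize away from the source of the activating signal:
            // the resultant of the broken contact and every remaining
            // contact with cells of the collapsing partner's population.
            // With a single contact this is exactly the membrane point
            // opposite the broken node.
            double cx, cy;
            centroidOf(X, Y, cs, cx, cy);
            double vx = X(cs, ns) - cx, vy = Y(cs, ns) - cy;
            double nrm = std::sqrt(vx * vx + vy * vy);
            if (nrm > 1e-12) { vx /= nrm; vy /= nrm; }
            for (int k = 0; k < 8; ++k) {
              int cp = linkC(cs, k);
              if (cp < 0 || pop[cp] != po) continue;
              double ux = X(cs, k) - cx, uy = Y(cs, k) - cy;
              double un = std::sqrt(ux * ux + uy * uy);
              if (un > 1e-12) { vx += ux / un; vy += uy / un; }
            }
            int L;
            if (vx * vx + vy * vy > 1e-12) {
              heading[cs] = std::atan2(-vy, -vx);
              L = nearestNodeToHeading(X, Y, heading[cs], cs);
              leader[cs] = L;
            } else {
              L = (ns + 4) % 8;
              setHeadingToNode(X, Y, heading, leader, cs, L);
            }
            repelled[cs] = 1;
            commit[cs] = esc;
            if (avoidTime < esc) avoidTime = esc;
            log.add(step, 2, cs, ns, co, L);
            // the collapse retracts the cell's processes: every remaining
            // link of the repelled cell is released and those partners are
            // avoided for the escape period, while the escaping cell stays
            // adhesive toward every other cell on its way
            for (int k = 0; k < 8; ++k) {
              int cp = linkC(cs, k);
              if (cp < 0) continue;
              int kp = linkN(cs, k);
              linkC(cp, kp) = -1; linkN(cp, kp) = -1;
              linkC(cs, k) = -1; linkN(cs, k) = -1;
              addAvoid(avoidC, avoidS, cs, cp, esc);
              addAvoid(avoidC, avoidS, cp, cs, esc);
            }
          }
        } else {
          int L = (int)(unif_rand() * 8.0);
          if (L > 7) L = 7;
          setHeadingToNode(X, Y, heading, leader, cs, L);
          log.add(step, 3, cs, L, co, -1);
        }
      }
      addAvoid(avoidC, avoidS, c, c2, avoidTime);
      addAvoid(avoidC, avoidS, c2, c, avoidTime);
    }
  }
}

// phase 4: spontaneous direction change, once per decision tick; cells in
// the committed post-collapse escape phase keep their heading
static void phaseDirChange(NumericMatrix& X, NumericMatrix& Y,
                           NumericVector& heading, IntegerVector& leader,
                           const IntegerVector& commit,
                           double pChange, EventLog& log, int step) {
  const int N = X.nrow();
  for (int c = 0; c < N; ++c) {
    if (commit[c] > 0) continue;
    if (unif_rand() < pChange) {
      int L = (int)(unif_rand() * 8.0);
      if (L > 7) L = 7;
      setHeadingToNode(X, Y, heading, leader, c, L);
      log.add(step, 3, c, L, -1, -1);
    }
  }
}

// phase 5: rigid translation of each cell along its heading
static void phaseMove(NumericMatrix& X, NumericMatrix& Y,
                      const NumericVector& heading, double dist) {
  const int N = X.nrow();
  for (int c = 0; c < N; ++c) {
    double dx = std::cos(heading[c]) * dist;
    double dy = std::sin(heading[c]) * dist;
    for (int i = 0; i < 8; ++i) { X(c, i) += dx; Y(c, i) += dy; }
  }
}

// phase 6: cohesive pull; linked neighbours of a repelled cell rotate their
// heading toward the repelled cell's new direction by fraction pullWeight
static void phaseCohesion(NumericMatrix& X, NumericMatrix& Y,
                          NumericVector& heading, IntegerVector& leader,
                          const IntegerMatrix& linkC,
                          const std::vector<int>& repelled,
                          const IntegerVector& commit, double w) {
  if (w <= 0.0) return;
  const int N = X.nrow();
  std::vector<int> seen(N, -1);
  for (int r = 0; r < N; ++r) {
    if (!repelled[r]) continue;
    double targ = heading[r];
    for (int i = 0; i < 8; ++i) {
      int c2 = linkC(r, i);
      if (c2 < 0 || repelled[c2] || commit[c2] > 0) continue;
      if (seen[c2] == r) continue;  // one pull per neighbour per repelled cell
      seen[c2] = r;
      double d = std::atan2(std::sin(targ - heading[c2]), std::cos(targ - heading[c2]));
      double h = heading[c2] + w * d;
      heading[c2] = std::atan2(std::sin(h), std::cos(h));
      leader[c2] = nearestNodeToHeading(X, Y, heading[c2], c2);
    }
  }
}

// phase 7: iterative position projection restoring the structural
// constraints: bond lengths near idealBond, nodes near the ideal radius and
// hard-capped at twice it, linked nodes within linkStretch (compliant
// tether), inter-cell node separation at least sep, all nodes inside the
// arena.
static int phaseConstraints(NumericMatrix& X, NumericMatrix& Y,
                            const IntegerMatrix& linkC, const IntegerMatrix& linkN,
                            double arenaR,
                            const NumericVector& radius, const NumericVector& ideal,
                            double sep, double linkStretch, int maxSweeps) {
  const int N = X.nrow();
  Grid g;
  // candidate separation pairs are collected with a margin and refreshed
  // every 10 sweeps; within-step displacements are far smaller than that
  const double margin = 1.0;
  const double reach = sep + margin;
  const double reach2 = reach * reach;
  std::vector<int> pa, pb;
  auto rebuildPairs = [&]() {
    pa.clear(); pb.clear();
    g.build(X, Y, arenaR, std::max(reach, 1.0));
    for (int c = 0; c < N; ++c) {
      for (int i = 0; i < 8; ++i) {
        int id = c * 8 + i;
        double x = X(c, i), y = Y(c, i);
        g.forNeighbours(x, y, [&](int id2) {
          if (id2 <= id) return;
          int c2 = id2 / 8;
          if (c2 == c) return;
          int i2 = id2 % 8;
          double dx = X(c2, i2) - x, dy = Y(c2, i2) - y;
          if (dx * dx + dy * dy <= reach2) { pa.push_back(id); pb.push_back(id2); }
        });
      }
    }
  };
  int sweep = 0;
  for (; sweep < maxSweeps; ++sweep) {
    if (sweep % 10 == 0) rebuildPairs();
    double maxCorr = 0.0;

    // radial: soft pull toward the ideal radius, hard cap at 2 * radius
    for (int c = 0; c < N; ++c) {
      double cx, cy;
      centroidOf(X, Y, c, cx, cy);
      for (int i = 0; i < 8; ++i) {
        double dx = X(c, i) - cx, dy = Y(c, i) - cy;
        double r = std::sqrt(dx * dx + dy * dy);
        if (r < 1e-12) continue;
        double corr;
        if (r > 2.0 * radius[c]) corr = 2.0 * radius[c] - r;  // hard projection
        else corr = RADIAL_STIFF * (radius[c] - r);
        X(c, i) += corr * dx / r;
        Y(c, i) += corr * dy / r;
        if (std::fabs(corr) > maxCorr) maxCorr = std::fabs(corr);
      }
    }

    // bonds: full pairwise projection to idealBond
    for (int c = 0; c < N; ++c) {
      for (int i = 0; i < 8; ++i) {
        int j = (i + 1) % 8;
        double dx = X(c, j) - X(c, i), dy = Y(c, j) - Y(c, i);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1e-12) { X(c, j) += 1e-6; continue; }
        double corr = 0.5 * (d - ideal[c]);
        double ux = dx / d, uy = dy / d;
        X(c, i) += corr * ux; Y(c, i) += corr * uy;
        X(c, j) -= corr * ux; Y(c, j) -= corr * uy;
        if (std::fabs(corr) > maxCorr) maxCorr = std::fabs(corr);
      }
    }

    // adhesion links: compliant tether, engages only beyond linkStretch
    for (int c = 0; c < N; ++c) {
      for (int i = 0; i < 8; ++i) {
        int c2 = linkC(c, i);
        if (c2 < 0 || c2 < c) continue;
        int i2 = linkN(c, i);
        double dx = X(c2, i2) - X(c, i), dy = Y(c2, i2) - Y(c, i);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= linkStretch || d < 1e-12) continue;
        double corr = 0.5 * (d - linkStretch);
        double ux = dx / d, uy = dy / d;
        X(c, i) += corr * ux; Y(c, i) += corr * uy;
        X(c2, i2) -= corr * ux; Y(c2, i2) -= corr * uy;
        if (corr > maxCorr) maxCorr = corr;
      }
    }

    // volume exclusion: nodes of distinct cells pushed apart to sep
    const double sep2 = sep * sep;
    for (size_t k = 0; k < pa.size(); ++k) {
      int c = pa[k] / 8, i = pa[k] % 8;
      int c2 = pb[k] / 8, i2 = pb[k] % 8;
      double dx = X(c2, i2) - X(c, i), dy = Y(c2, i2) - Y(c, i);
      double d2 = dx * dx + dy * dy;
      if (d2 >= sep2) continue;
      double d = std::sqrt(d2), ux, uy;
      if (d < 1e-12) { ux = 1.0; uy = 0.0; d = 0.0; }
      else { ux = dx / d; uy = dy / d; }
      double corr = 0.5 * (sep - d);
      X(c, i) -= corr * ux; Y(c, i) -= corr * uy;
      X(c2, i2) += corr * ux; Y(c2, i2) += corr * uy;
      if (corr > maxCorr) maxCorr = corr;
    }

    // arena wall: hard circular projection
    for (int c = 0; c < N; ++c) {
      for (int i = 0; i < 8; ++i) {
        double r = std::sqrt(X(c, i) * X(c, i) + Y(c, i) * Y(c, i));
        if (r > arenaR) {
          double s = arenaR / r;
          double corr = r - arenaR;
          X(c, i) *= s; Y(c, i) *= s;
          if (corr > maxCorr) maxCorr = corr;
        }
      }
    }

    if (maxCorr < CONV_TOL) { ++sweep; break; }
  }
  return sweep;
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
List cpp_enforce_constraints(NumericMatrix nx, NumericMatrix ny,
                             IntegerMatrix linkC, IntegerMatrix linkN,
                             double arenaR, NumericVector radius,
                             NumericVector idealBond, double sep,
                             double linkStretch, int maxSweeps) {
  NumericMatrix X = clone(nx), Y = clone(ny);
  int sweeps = phaseConstraints(X, Y, linkC, linkN, arenaR, radius, idealBond,
                                sep, linkStretch, maxSweeps);
  return List::create(_["nx"] = X, _["ny"] = Y, _["sweeps"] = sweeps);
}

// [[Rcpp::export]]
List cpp_form_links(NumericMatrix nx, NumericMatrix ny,
                    IntegerMatrix linkC, IntegerMatrix linkN,
                    IntegerMatrix avoidC, double contactDist, double arenaR,
                    int step) {
  NumericMatrix X = clone(nx), Y = clone(ny);
  IntegerMatrix LC = clone(linkC), LN = clone(linkN);
  EventLog log(true);
  phaseFormLinks(X, Y, LC, LN, avoidC, contactDist, arenaR, log, step);
  return List::create(_["linkC"] = LC, _["linkN"] = LN, _["events"] = log.frame());
}

// [[Rcpp::export]]
List cpp_break_links(NumericMatrix nx, NumericMatrix ny,
                     NumericVector heading, IntegerVector leader,
                     IntegerVector pop,
                     IntegerMatrix linkC, IntegerMatrix linkN,
                     IntegerMatrix avoidC, IntegerMatrix avoidS,
                     int refractSteps, IntegerMatrix escapeSteps,
                     NumericMatrix pTick, NumericMatrix pRep,
                     IntegerMatrix directed, int step) {
  NumericMatrix X = clone(nx), Y = clone(ny);
  NumericVector H = clone(heading);
  IntegerVector L = clone(leader);
  IntegerMatrix LC = clone(linkC), LN = clone(linkN);
  IntegerMatrix AC = clone(avoidC), AS = clone(avoidS);
  std::vector<int> repelled(X.nrow(), 0);
  IntegerVector commitV(X.nrow());
  EventLog log(true);
  phaseBreakLinks(X, Y, H, L, pop, LC, LN, AC, AS, refractSteps,
                  escapeSteps, pTick, pRep, directed, repelled,
                  commitV, log, step);
  return List::create(_["heading"] = H, _["leader"] = L,
                      _["linkC"] = LC, _["linkN"] = LN,
                      _["avoidC"] = AC, _["avoidS"] = AS,
                      _["repelled"] = IntegerVector(repelled.begin(), repelled.end()),
                      _["commit"] = commitV,
                      _["events"] = log.frame());
}

// [[Rcpp::export]]
List cpp_run_sim(List state, List par, int nSteps, int recordEvery,
                 bool recordEvents) {
  NumericMatrix X = clone(as<NumericMatrix>(state["nx"]));
  NumericMatrix Y = clone(as<NumericMatrix>(state["ny"]));
  NumericVector heading = clone(as<NumericVector>(state["heading"]));
  IntegerVector leader = clone(as<IntegerVector>(state["leader"]));
  IntegerVector pop = as<IntegerVector>(state["pop"]);
  IntegerMatrix linkC = clone(as<IntegerMatrix>(state["linkC"]));
  IntegerMatrix linkN = clone(as<IntegerMatrix>(state["linkN"]));
  IntegerMatrix avoidC = clone(as<IntegerMatrix>(state["avoidC"]));
  IntegerMatrix avoidS = clone(as<IntegerMatrix>(state["avoidS"]));
  IntegerVector commit = clone(as<IntegerVector>(state["commit"]));
  int step0 = as<int>(state["stepCount"]);

  const double arenaR = as<double>(par["arenaR"]);
  NumericVector radius = as<NumericVector>(par["radius"]);
  NumericVector ideal = as<NumericVector>(par["idealBond"]);
  const double contactDist = as<double>(par["contactDist"]);
  const double sep = as<double>(par["sep"]);
  const double linkStretch = as<double>(par["linkStretch"]);
  const double stepDist = as<double>(par["stepDist"]);  // um per step
  const double pChange = as<double>(par["pChangeDir"]);
  const int tickSteps = as<int>(par["tickSteps"]);
  const double pullWeight = as<double>(par["pullWeight"]);
  const int refractSteps = as<int>(par["refractSteps"]);
  IntegerMatrix escapeSteps = as<IntegerMatrix>(par["escapeSteps"]);
  const int maxSweeps = as<int>(par["maxSweeps"]);
  NumericMatrix pTick = as<NumericMatrix>(par["pTickBreak"]);
  NumericMatrix pRep = as<NumericMatrix>(par["pRepulsion"]);
  IntegerMatrix directed = as<IntegerMatrix>(par["directed"]);

  const int N = X.nrow();
  EventLog log(recordEvents);
  std::vector<int> repelled(N);
  std::vector<double> recStep, recCell, recX, recY;

  auto snapshot = [&](int atStep) {
    for (int c = 0; c < N; ++c) {
      double cx, cy;
      centroidOf(X, Y, c, cx, cy);
      recStep.push_back(atStep);
      recCell.push_back(c + 1);
      recX.push_back(cx);
      recY.push_back(cy);
    }
  };
  if (recordEvery > 0) snapshot(step0);

  for (int s = 0; s < nSteps; ++s) {
    const int step = step0 + s;
    std::fill(repelled.begin(), repelled.end(), 0);
    phaseFormLinks(X, Y, linkC, linkN, avoidC, contactDist, arenaR, log, step);
    // adhesion hazards are per-minute probabilities; links are evaluated
    // once per decision tick, not every 0.5-s step
    if (tickSteps > 0 && step % tickSteps == 0) {
      phaseBreakLinks(X, Y, heading, leader, pop, linkC, linkN, avoidC, avoidS,
                      refractSteps, escapeSteps, pTick, pRep, directed,
                      repelled, commit, log, step);
      phaseDirChange(X, Y, heading, leader, commit, pChange, log, step);
    }
    phaseMove(X, Y, heading, stepDist);
    phaseCohesion(X, Y, heading, leader, linkC, repelled, commit, pullWeight);
    phaseConstraints(X, Y, linkC, linkN, arenaR, radius, ideal, sep,
                     linkStretch, maxSweeps);
    for (int c = 0; c < N; ++c) {
      if (commit[c] > 0) commit[c]--;
      for (int k = 0; k < 8; ++k) {
        if (avoidC(c, k) >= 0 && --avoidS(c, k) <= 0) {
          avoidC(c, k) = -1;
          avoidS(c, k) = 0;
        }
      }
    }
    if (recordEvery > 0 && ((s + 1) % recordEvery == 0 || s + 1 == nSteps))
      snapshot(step0 + s + 1);
  }

  DataFrame snaps = DataFrame::create(
    _["step"] = NumericVector(recStep.begin(), recStep.end()),
    _["cell"] = NumericVector(recCell.begin(), recCell.end()),
    _["x"] = NumericVector(recX.begin(), recX.end()),
    _["y"] = NumericVector(recY.begin(), recY.end()));

  NumericVector counts = NumericVector::create(
    _["link_form"] = (double)log.counts[0], _["link_break"] = (double)log.counts[1],
    _["repulsion"] = (double)log.counts[2], _["dir_change"] = (double)log.counts[3]);

  return List::create(_["nx"] = X, _["ny"] = Y, _["heading"] = heading,
                      _["leader"] = leader, _["linkC"] = linkC,
                      _["linkN"] = linkN, _["avoidC"] = avoidC,
                      _["avoidS"] = avoidS, _["commit"] = commit,
                      _["stepCount"] = step0 + nSteps,
                      _["snapshots"] = snaps,
                      _["events"] = recordEvents ? (SEXP)log.frame() : R_NilValue,
                      _["counts"] = counts);
}

// ---------------------------------------------------------------------------
// 8-connectivity connected-component labelling of a binary mask
// (ImageJ-style particle analysis needs diagonal connectivity)

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qx, qy;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qx.clear(); qy.clear();
      qx.push_back(i); qy.push_back(j);
      while (!qx.empty()) {
        int ci = qx.back(), cj = qy.back();
        qx.pop_back(); qy.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              qx.push_back(ii); qy.push_back(jj);
            }
          }
        }
      }
    }
  }
  return lab;
}
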