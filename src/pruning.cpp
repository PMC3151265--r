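// Felsenstein pruning with per-node scaling and fast per-edge branch-length
// optimization (down/up partial caching, BFS Gauss-Seidel sweeps).
//
// The engine is "grouped": patterns are assigned to groups, each group
// carrying its own stationary frequencies, eigen-decomposed generator,
// discrete rate categories and a branch-length multiplier (used for
// codon-position proportional-rate models). All groups share the tree and
// the edge lengths.
//
// Partial arrays are laid out [category][state][pattern] with the pattern
// index fastest so the inner loops run over contiguous memory and
// vectorize.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Group {
  std::vector<int> pat;            // global pattern indices (0-based)
  std::vector<double> freq;        // 4
  std::vector<double> values;      // 4 eigenvalues
  std::vector<double> V;           // 4x4 row-major right eigenvectors
  std::vector<double> Vinv;        // 4x4 row-major inverse
  std::vector<double> rates;       // K category rates
  std::vector<double> probs;       // K category probs
  double scale;                    // branch-length multiplier
  int ncat = 0;
  int npat = 0;
};

// P(t) for one group and one category rate r: V diag(exp(values*t*r*scale)) Vinv
inline void pmat(const Group& g, double t, double r, double* P) {
  double ex[4];
  double tt = t * r * g.scale;
  for (int k = 0; k < 4; ++k) ex[k] = std::exp(g.values[k] * tt);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k)
        s += g.V[i * 4 + k] * ex[k] * g.Vinv[k * 4 + j];
      P[i * 4 + j] = s > 0.0 ? s : 0.0;
    }
  }
}

struct Engine {
  int nTip, nNode, nEdge, root;
  std::vector<int> eParent, eChild;         // per edge (0-based nodes)
  std::vector<std::vector<int> > children;  // node -> edge indices
  std::vector<int> parentEdge;              // node -> incoming edge (-1 root)
  std::vector<int> postorder;               // node order: children first
  std::vector<Group> groups;
  std::vector<double> wt;                   // pattern weights (global)
  std::vector<int> patmask;                 // nTip x nPat bitmasks, col-major
  int nPat;
  // partials per group, per node: ncat*4*npat, layout [cat][state][pat]
  std::vector<std::vector<std::vector<double> > > down;
  std::vector<std::vector<std::vector<double> > > dscal; // per group,node: npat
  std::vector<std::vector<std::vector<double> > > up;    // G/H partials
  std::vector<std::vector<std::vector<double> > > uscal;
  std::vector<double> tmp1;                 // scratch, npat-sized

  inline int pattern_at(int tip, int pat) const {
    return patmask[(size_t)pat * nTip + tip];
  }

  Engine(const IntegerMatrix& edge, int nTip_, const List& groupList,
         const IntegerVector& patGroup, const IntegerMatrix& patterns_,
         const NumericVector& weights)
      : nTip(nTip_) {
    nPat = patterns_.ncol();
    patmask.resize((size_t)nPat * nTip);
    for (int p = 0; p < nPat; ++p)
      for (int v = 0; v < nTip; ++v)
        patmask[(size_t)p * nTip + v] = patterns_(v, p);
    nEdge = edge.nrow();
    nNode = nEdge + 1;
    root = nTip;  // ape convention: root = nTip+1 (1-based)
    eParent.resize(nEdge);
    eChild.resize(nEdge);
    children.assign(nNode, std::vector<int>());
    parentEdge.assign(nNode, -1);
    for (int e = 0; e < nEdge; ++e) {
      eParent[e] = edge(e, 0) - 1;
      eChild[e] = edge(e, 1) - 1;
      children[eParent[e]].push_back(e);
      parentEdge[eChild[e]] = e;
    }
    postorder.reserve(nNode);
    std::vector<int> stack;
    std::vector<int> order;
    stack.push_back(root);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      order.push_back(u);
      for (size_t k = 0; k < children[u].size(); ++k)
        stack.push_back(eChild[children[u][k]]);
    }
    for (int i = (int)order.size() - 1; i >= 0; --i)
      postorder.push_back(order[i]);
    int nG = groupList.size();
    groups.resize(nG);
    wt.assign(weights.begin(), weights.end());
    for (int p = 0; p < nPat; ++p) {
      int g = patGroup[p] - 1;
      groups[g].pat.push_back(p);
    }
    for (int g = 0; g < nG; ++g) groups[g].npat = groups[g].pat.size();
    down.assign(nG, std::vector<std::vector<double> >(nNode));
    dscal.assign(nG, std::vector<std::vector<double> >(nNode));
    up.assign(nG, std::vector<std::vector<double> >(nNode));
    uscal.assign(nG, std::vector<std::vector<double> >(nNode));
    set_groups(groupList);
  }

  // update substitution parameters (eigen systems, rates, scales) in place;
  // pattern-to-group assignment stays fixed
  void set_groups(const List& groupList) {
    for (int g = 0; g < (int)groups.size(); ++g) {
      List gl = groupList[g];
      NumericVector f = gl["freq"], val = gl["values"], rr = gl["rates"],
                    pp = gl["probs"];
      NumericMatrix V = gl["V"], Vi = gl["Vinv"];
      Group& G = groups[g];
      if (G.ncat != 0 && G.ncat != (int)rr.size())
        for (int v = 0; v < nTip; ++v) down[g][v].clear();
      G.freq.assign(f.begin(), f.end());
      G.values.assign(val.begin(), val.end());
      G.rates.assign(rr.begin(), rr.end());
      G.probs.assign(pp.begin(), pp.end());
      G.scale = as<double>(gl["scale"]);
      G.ncat = rr.size();
      G.V.resize(16);
      G.Vinv.resize(16);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          G.V[i * 4 + j] = V(i, j);
          G.Vinv[i * 4 + j] = Vi(i, j);
        }
    }
  }

  inline double* slab(std::vector<double>& x, int npat, int c, int s) {
    return &x[((size_t)c * 4 + s) * npat];
  }

  // tip partials for group g, node v (a tip)
  void tip_partials(int g, int v) {
    Group& G = groups[g];
    std::vector<double>& D = down[g][v];
    D.assign((size_t)G.ncat * 4 * G.npat, 0.0);
    dscal[g][v].assign(G.npat, 0.0);
    for (int p = 0; p < G.npat; ++p) {
      int mask = pattern_at(v, G.pat[p]);
      for (int s = 0; s < 4; ++s)
        if (mask & (1 << s))
          for (int c = 0; c < G.ncat; ++c)
            D[((size_t)c * 4 + s) * G.npat + p] = 1.0;
    }
  }

  // child contribution: du[c][s][:] *= sum_j P_c[s][j] dv[c][j][:]
  void apply_child(Group& G, const double* P, const double* dv, double* du,
                   double* t) {
    int np = G.npat;
    for (int c = 0; c < G.ncat; ++c) {
      const double* Pc = P + (size_t)c * 16;
      const double* v0 = dv + ((size_t)c * 4 + 0) * np;
      const double* v1 = dv + ((size_t)c * 4 + 1) * np;
      const double* v2 = dv + ((size_t)c * 4 + 2) * np;
      const double* v3 = dv + ((size_t)c * 4 + 3) * np;
      for (int s = 0; s < 4; ++s) {
        double p0 = Pc[s * 4], p1 = Pc[s * 4 + 1], p2 = Pc[s * 4 + 2],
               p3 = Pc[s * 4 + 3];
        double* u = du + ((size_t)c * 4 + s) * np;
        for (int p = 0; p < np; ++p)
          u[p] *= p0 * v0[p] + p1 * v1[p] + p2 * v2[p] + p3 * v3[p];
      }
    }
  }

  // compute down partials for all nodes, given edge lengths; each internal
  // node is rescaled per pattern once fully assembled
  void compute_down(const std::vector<double>& blen) {
    int nG = groups.size();
    for (int g = 0; g < nG; ++g) {
      Group& G = groups[g];
      int np = G.npat;
      for (int v = 0; v < nTip; ++v)
        if (down[g][v].empty()) tip_partials(g, v);
      std::vector<double> P;
      for (size_t k = 0; k < postorder.size(); ++k) {
        int u = postorder[k];
        if (u < nTip) continue;
        down[g][u].assign((size_t)G.ncat * 4 * np, 1.0);
        dscal[g][u].assign(np, 0.0);
        std::vector<double>& Du = down[g][u];
        std::vector<double>& Su = dscal[g][u];
        for (size_t ci = 0; ci < children[u].size(); ++ci) {
          int e = children[u][ci];
          int v = eChild[e];
          P.resize((size_t)G.ncat * 16);
          for (int c = 0; c < G.ncat; ++c)
            pmat(G, blen[e], G.rates[c], &P[(size_t)c * 16]);
          apply_child(G, P.data(), down[g][v].data(), Du.data(), 0);
          std::vector<double>& Sv = dscal[g][v];
          for (int p = 0; p < np; ++p) Su[p] += Sv[p];
        }
        rescale(G, Du, Su);
      }
    }
  }

  void rescale(Group& G, std::vector<double>& D, std::vector<double>& S) {
    int np = G.npat;
    if (tmp1.size() < (size_t)np) tmp1.resize(np);
    double* m = tmp1.data();
    for (int p = 0; p < np; ++p) m[p] = 0.0;
    for (int i = 0; i < G.ncat * 4; ++i) {
      const double* d = &D[(size_t)i * np];
      for (int p = 0; p < np; ++p)
        if (d[p] > m[p]) m[p] = d[p];
    }
    bool any = false;
    for (int p = 0; p < np; ++p)
      if (m[p] < 1e-40) { any = true; break; }
    if (!any) return;
    for (int p = 0; p < np; ++p) {
      if (m[p] >= 1e-40) { m[p] = 1.0; continue; }
      if (m[p] == 0.0) {
        S[p] = -std::numeric_limits<double>::infinity();
        m[p] = 1.0;
      } else {
        S[p] += std::log(m[p]);
        m[p] = 1.0 / m[p];
      }
    }
    for (int i = 0; i < G.ncat * 4; ++i) {
      double* d = &D[(size_t)i * np];
      for (int p = 0; p < np; ++p) d[p] *= m[p];
    }
  }

  // total log-likelihood + per-pattern logliks from current down partials
  double loglik_from_down(std::vector<double>* patll) {
    int nG = groups.size();
    double total = 0.0;
    if (patll) patll->assign(nPat, 0.0);
    std::vector<double> site;
    for (int g = 0; g < nG; ++g) {
      Group& G = groups[g];
      int np = G.npat;
      std::vector<double>& D = down[g][root];
      std::vector<double>& S = dscal[g][root];
      site.assign(np, 0.0);
      for (int c = 0; c < G.ncat; ++c) {
        double pc = G.probs[c];
        for (int s = 0; s < 4; ++s) {
          double fs = pc * G.freq[s];
          const double* d = &D[((size_t)c * 4 + s) * np];
          for (int p = 0; p < np; ++p) site[p] += fs * d[p];
        }
      }
      for (int p = 0; p < np; ++p) {
        double ll = (site[p] > 0.0)
                        ? std::log(site[p]) + S[p]
                        : -std::numeric_limits<double>::infinity();
        if (patll) (*patll)[G.pat[p]] = ll;
        total += wt[G.pat[p]] * ll;
      }
    }
    return total;
  }

  double loglik(const std::vector<double>& blen, std::vector<double>* patll) {
    compute_down(blen);
    return loglik_from_down(patll);
  }

  // objective for one edge e = (u -> v) as a function of its length t,
  // using G-partials in up[g][v]/uscal[g][v] and down[v]
  double edge_loglik(int e, double t) {
    int v = eChild[e];
    int nG = groups.size();
    double total = 0.0;
    std::vector<double> P, site, y;
    for (int g = 0; g < nG; ++g) {
      Group& G = groups[g];
      int np = G.npat;
      std::vector<double>& Dv = down[g][v];
      std::vector<double>& Gv = up[g][v];
      std::vector<double>& Sv = dscal[g][v];
      std::vector<double>& Sg = uscal[g][v];
      P.resize((size_t)G.ncat * 16);
      for (int c = 0; c < G.ncat; ++c)
        pmat(G, t, G.rates[c], &P[(size_t)c * 16]);
      site.assign(np, 0.0);
      y.resize(np);
      for (int c = 0; c < G.ncat; ++c) {
        const double* Pc = &P[(size_t)c * 16];
        const double* v0 = &Dv[((size_t)c * 4 + 0) * np];
        const double* v1 = &Dv[((size_t)c * 4 + 1) * np];
        const double* v2 = &Dv[((size_t)c * 4 + 2) * np];
        const double* v3 = &Dv[((size_t)c * 4 + 3) * np];
        double pc = G.probs[c];
        for (int i = 0; i < 4; ++i) {
          double p0 = Pc[i * 4], p1 = Pc[i * 4 + 1], p2 = Pc[i * 4 + 2],
                 p3 = Pc[i * 4 + 3];
          const double* gv = &Gv[((size_t)c * 4 + i) * np];
          for (int p = 0; p < np; ++p)
            site[p] += pc * gv[p] *
                       (p0 * v0[p] + p1 * v1[p] + p2 * v2[p] + p3 * v3[p]);
        }
      }
      for (int p = 0; p < np; ++p) {
        double ll = (site[p] > 0.0) ? std::log(site[p]) + Sv[p] + Sg[p]
                                    : -1e300;
        total += wt[G.pat[p]] * ll;
      }
    }
    return total;
  }

  // golden-section + parabolic (Brent) maximization of edge_loglik over t,
  // seeded at the current length x0
  double brent_edge(int e, double a, double b, double x0, double tol,
                    double* fbest) {
    const double gr = 0.3819660112501051;
    double x, w, v, fx, fw, fv, d = 0.0, eold = 0.0;
    if (x0 <= a || x0 >= b) x0 = a + gr * (b - a);
    x = w = v = x0;
    fx = fw = fv = edge_loglik(e, x);
    for (int iter = 0; iter < 60; ++iter) {
      double m = 0.5 * (a + b);
      double tol1 = tol * std::fabs(x) + 1e-9;
      double tol2 = 2.0 * tol1;
      if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
      double dnew = 0.0;
      bool useGolden = true;
      if (std::fabs(eold) > tol1) {
        double r = (x - w) * (fx - fv);
        double q = (x - v) * (fx - fw);
        double p = (x - v) * q - (x - w) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) p = -p;
        q = std::fabs(q);
        if (std::fabs(p) < std::fabs(0.5 * q * eold) && p > q * (a - x) &&
            p < q * (b - x)) {
          dnew = p / q;
          useGolden = false;
          double u = x + dnew;
          if (u - a < tol2 || b - u < tol2)
            dnew = (x < m) ? tol1 : -tol1;
        }
      }
      if (useGolden) {
        eold = (x < m) ? (b - x) : (a - x);
        dnew = gr * eold;
      } else {
        eold = d;
      }
      d = dnew;
      double u = (std::fabs(d) >= tol1) ? x + d
                                        : x + ((d > 0) ? tol1 : -tol1);
      double fu = edge_loglik(e, u);
      if (fu >= fx) {
        if (u >= x) a = x; else b = x;
        v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu >= fw || w == x) {
          v = w; fv = fw; w = u; fw = fu;
        } else if (fu >= fv || v == x || v == w) {
          v = u; fv = fu;
        }
      }
    }
    *fbest = fx;
    return x;
  }

  // G-partial for edge (u -> v): H[u] times sibling subtree contributions
  void build_G(int u, int v, const std::vector<double>& blen) {
    int nG = groups.size();
    std::vector<double> P;
    for (int g = 0; g < nG; ++g) {
      Group& G = groups[g];
      int np = G.npat;
      std::vector<double>& Gv = up[g][v];
      Gv.assign(up[g][u].begin(), up[g][u].end());
      uscal[g][v] = uscal[g][u];
      for (size_t ci = 0; ci < children[u].size(); ++ci) {
        int e2 = children[u][ci];
        int w = eChild[e2];
        if (w == v) continue;
        P.resize((size_t)G.ncat * 16);
        for (int c = 0; c < G.ncat; ++c)
          pmat(G, blen[e2], G.rates[c], &P[(size_t)c * 16]);
        apply_child(G, P.data(), down[g][w].data(), Gv.data(), 0);
        std::vector<double>& Sw = dscal[g][w];
        for (int p = 0; p < np; ++p) uscal[g][v][p] += Sw[p];
      }
      rescale(G, Gv, uscal[g][v]);
    }
  }

  // H[v][j] = sum_i G[v][i] P(t_e)[i][j], overwriting up[g][v]
  void push_H(int e, const std::vector<double>& blen) {
    int v = eChild[e];
    int nG = groups.size();
    std::vector<double> P, h;
    for (int g = 0; g < nG; ++g) {
      Group& G = groups[g];
      int np = G.npat;
      std::vector<double>& Gv = up[g][v];
      P.resize((size_t)G.ncat * 16);
      for (int c = 0; c < G.ncat; ++c)
        pmat(G, blen[e], G.rates[c], &P[(size_t)c * 16]);
      h.resize((size_t)4 * np);
      for (int c = 0; c < G.ncat; ++c) {
        const double* Pc = &P[(size_t)c * 16];
        double* g0 = &Gv[((size_t)c * 4 + 0) * np];
        double* g1 = &Gv[((size_t)c * 4 + 1) * np];
        double* g2 = &Gv[((size_t)c * 4 + 2) * np];
        double* g3 = &Gv[((size_t)c * 4 + 3) * np];
        for (int j = 0; j < 4; ++j) {
          double p0 = Pc[j], p1 = Pc[4 + j], p2 = Pc[8 + j], p3 = Pc[12 + j];
          double* hj = &h[(size_t)j * np];
          for (int p = 0; p < np; ++p)
            hj[p] = g0[p] * p0 + g1[p] * p1 + g2[p] * p2 + g3[p] * p3;
        }
        for (int j = 0; j < 4; ++j)
          std::copy(&h[(size_t)j * np], &h[(size_t)(j + 1) * np],
                    &Gv[((size_t)c * 4 + j) * np]);
      }
    }
  }

  // one BFS sweep of per-edge optimization; returns loglik after sweep
  double sweep(std::vector<double>& blen, double lower, double upper,
               double tol) {
    compute_down(blen);
    int nG = groups.size();
    for (int g = 0; g < nG; ++g) {
      Group& G = groups[g];
      int np = G.npat;
      up[g][root].assign((size_t)G.ncat * 4 * np, 0.0);
      uscal[g][root].assign(np, 0.0);
      std::vector<double>& H = up[g][root];
      for (int c = 0; c < G.ncat; ++c)
        for (int s = 0; s < 4; ++s) {
          double fs = G.freq[s];
          double* h = &H[((size_t)c * 4 + s) * np];
          for (int p = 0; p < np; ++p) h[p] = fs;
        }
    }
    std::vector<std::vector<int> > byLevel;
    byLevel.push_back(std::vector<int>(1, root));
    for (size_t d = 0; d < byLevel.size(); ++d) {
      std::vector<int> next;
      for (size_t k = 0; k < byLevel[d].size(); ++k) {
        int u = byLevel[d][k];
        for (size_t c = 0; c < children[u].size(); ++c)
          next.push_back(eChild[children[u][c]]);
      }
      if (!next.empty()) byLevel.push_back(next);
    }
    double lastf = -std::numeric_limits<double>::infinity();
    for (size_t d = 0; d + 1 < byLevel.size(); ++d) {
      for (size_t k = 0; k < byLevel[d].size(); ++k) {
        int u = byLevel[d][k];
        for (size_t ci = 0; ci < children[u].size(); ++ci) {
          int e = children[u][ci];
          int v = eChild[e];
          build_G(u, v, blen);
          double f0 = edge_loglik(e, blen[e]);
          double fb;
          double t = brent_edge(e, lower, upper, blen[e], tol, &fb);
          if (fb > f0) blen[e] = t; else fb = f0;
          lastf = fb;
        }
      }
      // finalize H for the next level with final lengths
      for (size_t k = 0; k < byLevel[d].size(); ++k) {
        int u = byLevel[d][k];
        for (size_t ci = 0; ci < children[u].size(); ++ci) {
          int e = children[u][ci];
          int v = eChild[e];
          build_G(u, v, blen);
          push_H(e, blen);
        }
      }
    }
    return lastf;
  }
};

}  // namespace

static List optimize_blens_impl(Engine& eng, NumericVector blen, double lower,
                                double upper, double tol, int maxPass) {
  std::vector<double> bl(blen.begin(), blen.end());
  double cur = eng.loglik(bl, 0);
  int pass = 0;
  for (; pass < maxPass; ++pass) {
    std::vector<double> trial = bl;
    double f = eng.sweep(trial, lower, upper, 1e-6);
    if (f > cur) {
      bl = trial;
      double gain = f - cur;
      cur = f;
      if (gain < tol) { ++pass; break; }
    } else {
      break;
    }
  }
  cur = eng.loglik(bl, 0);
  return List::create(_["blen"] = NumericVector(bl.begin(), bl.end()),
                      _["loglik"] = cur, _["passes"] = pass);
}

// [[Rcpp::export(name = ".pp_siteloglik")]]
List pp_siteloglik(IntegerMatrix edge, int nTip, NumericVector blen,
                   List groups, IntegerVector patGroup,
                   IntegerMatrix patterns, NumericVector weights) {
  Engine eng(edge, nTip, groups, patGroup, patterns, weights);
  std::vector<double> bl(blen.begin(), blen.end());
  std::vector<double> patll;
  double ll = eng.loglik(bl, &patll);
  return List::create(_["loglik"] = ll,
                      _["pattern_loglik"] = NumericVector(patll.begin(),
                                                          patll.end()));
}

// [[Rcpp::export(name = ".pp_optimize_blens")]]
List pp_optimize_blens(IntegerMatrix edge, int nTip, NumericVector blen,
                       List groups, IntegerVector patGroup,
                       IntegerMatrix patterns, NumericVector weights,
                       double lower, double upper, double tol, int maxPass) {
  Engine eng(edge, nTip, groups, patGroup, patterns, weights);
  return optimize_blens_impl(eng, blen, lower, upper, tol, maxPass);
}

// ---- persistent engine (reused across evaluations within one fit) ----------

// [[Rcpp::export(name = ".pp_engine_new")]]
SEXP pp_engine_new(IntegerMatrix edge, int nTip, List groups,
                   IntegerVector patGroup, IntegerMatrix patterns,
                   NumericVector weights) {
  XPtr<Engine> ptr(new Engine(edge, nTip, groups, patGroup, patterns,
                              weights), true);
  return ptr;
}

// [[Rcpp::export(name = ".pp_engine_set")]]
void pp_engine_set(SEXP engine, List groups) {
  XPtr<Engine> eng(engine);
  eng->set_groups(groups);
}

// [[Rcpp::export(name = ".pp_engine_loglik")]]
List pp_engine_loglik(SEXP engine, NumericVector blen, bool per_pattern) {
  XPtr<Engine> eng(engine);
  std::vector<double> bl(blen.begin(), blen.end());
  if (per_pattern) {
    std::vector<double> patll;
    double ll = eng->loglik(bl, &patll);
    return List::create(_["loglik"] = ll,
                        _["pattern_loglik"] = NumericVector(patll.begin(),
                                                            patll.end()));
  }
  double ll = eng->loglik(bl, 0);
  return List::create(_["loglik"] = ll);
}

// [[Rcpp::export(name = ".pp_engine_optimize")]]
List pp_engine_optimize(SEXP engine, NumericVector blen, double lower,
                        double upper, double tol, int maxPass) {
  XPtr<Engine> eng(engine);
  return optimize_blens_impl(*eng, blen, lower, upper, tol, maxPass);
}
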