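#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// P(t) = U diag(exp(lambda * t)) V, with the sqrt(pi) similarity factors
// already folded into U and V on the R side. Small negative entries from
// round-off are clamped to zero.
static inline void pmat(const double* U, const double* V, const double* lam,
                        double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(lam[k] * t);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += U[i + 4 * k] * e[k] * V[k + 4 * j];
      P[i + 4 * j] = s > 0.0 ? s : 0.0;
    }
  }
}

// Felsenstein pruning for one partition: per-pattern log-likelihood under a
// GTR(+I)+Gamma mixture. edge must be in postorder (children before
// parents), 1-based node ids with tips 1..ntip and root ntip+1.
//
// part fields: tip (IntegerMatrix ntip x npat, codes 1..4 = A,C,G,T,
// 5 = fully ambiguous), U, V (4x4), lambda(4), pi(4), catrate, catw,
// pinv, invw (per-pattern stationary mass of compatible constant states).
// [[Rcpp::export]]
NumericVector peel_part_cpp(IntegerMatrix edge, int ntip, List part,
                            NumericVector blens) {
  IntegerMatrix tip = part["tip"];
  NumericMatrix Um = part["U"], Vm = part["V"];
  NumericVector lam = part["lambda"], pi = part["pi"];
  NumericVector catrate = part["catrate"], catw = part["catw"];
  double pinv = as<double>(part["pinv"]);
  NumericVector invw = part["invw"];

  const int nedge = edge.nrow();
  const int npat = tip.ncol();
  const int ncat = catrate.size();
  int nnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  const int root = ntip + 1;

  std::vector<double> partial((size_t)nnode * 4 * npat);
  std::vector<char> seen(nnode);
  std::vector<double> logscale(npat);
  std::vector<double> catll((size_t)ncat * npat);
  std::vector<double> P(16);

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    // tip partials are implicit: unit vector or all-ones
    for (int e = 0; e < nedge; ++e) {
      const int pa = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      pmat(&Um[0], &Vm[0], &lam[0], blens[e] * catrate[c], P.data());
      double* pp = &partial[(size_t)pa * 4 * npat];
      if (!seen[pa]) {
        std::fill(pp, pp + 4 * npat, 1.0);
        seen[pa] = 1;
      }
      if (ch < ntip) {
        for (int s = 0; s < npat; ++s) {
          const int code = tip(ch, s);
          if (code == 5) continue;  // ambiguous: sum_y P[x,y] = 1
          const int y = code - 1;
          for (int x = 0; x < 4; ++x) pp[x + 4 * s] *= P[x + 4 * y];
        }
      } else {
        const double* cp = &partial[(size_t)ch * 4 * npat];
        for (int s = 0; s < npat; ++s) {
          double m = 0.0;
          for (int x = 0; x < 4; ++x) {
            double v = 0.0;
            for (int y = 0; y < 4; ++y) v += P[x + 4 * y] * cp[y + 4 * s];
            pp[x + 4 * s] *= v;
            if (pp[x + 4 * s] > m) m = pp[x + 4 * s];
          }
          if (m < 1e-120 && m > 0.0) {
            const double inv = 1.0 / m;
            for (int x = 0; x < 4; ++x) pp[x + 4 * s] *= inv;
            logscale[s] += std::log(m);
          }
        }
      }
    }
    const double* rp = &partial[(size_t)(root - 1) * 4 * npat];
    for (int s = 0; s < npat; ++s) {
      double v = 0.0;
      for (int x = 0; x < 4; ++x) v += pi[x] * rp[x + 4 * s];
      catll[(size_t)c * npat + s] =
        (v > 0.0 ? std::log(v) : -1e308) + logscale[s];
    }
  }

  NumericVector out(npat);
  for (int s = 0; s < npat; ++s) {
    double M = -1e308;
    for (int c = 0; c < ncat; ++c) {
      const double v = catll[(size_t)c * npat + s];
      if (v > M) M = v;
    }
    double mix = 0.0;
    for (int c = 0; c < ncat; ++c)
      mix += catw[c] * std::exp(catll[(size_t)c * npat + s] - M);
    double var_part = (1.0 - pinv) * mix;   // still scaled by exp(M)
    if (pinv > 0.0) {
      const double inv_part = pinv * invw[s];
      if (inv_part > 0.0) {
        // log( inv_part + exp(M) * var_part )
        const double li = std::log(inv_part);
        const double lv = var_part > 0.0 ? M + std::log(var_part) : -1e308;
        const double mx = li > lv ? li : lv;
        out[s] = mx + std::log(std::exp(li - mx) + std::exp(lv - mx));
        continue;
      }
    }
    out[s] = var_part > 0.0 ? M + std::log(var_part) : R_NegInf;
  }
  return out;
}

// One partition's contribution to the total log-likelihood, with a
// linear-space fast path for patterns that needed no rescaling.
static double peel_part_total(IntegerMatrix& edge, int ntip, List& part,
                              NumericVector& blens) {
  IntegerMatrix tip = part["tip"];
  NumericMatrix Um = part["U"], Vm = part["V"];
  NumericVector lam = part["lambda"], pi = part["pi"];
  NumericVector catrate = part["catrate"], catw = part["catw"];
  double pinv = as<double>(part["pinv"]);
  NumericVector invw = part["invw"];
  NumericVector wts = part["wts"];

  const int nedge = edge.nrow();
  const int npat = tip.ncol();
  const int ncat = catrate.size();
  int nnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  const int root = ntip + 1;

  std::vector<double> partial((size_t)nnode * 4 * npat);
  std::vector<char> seen(nnode);
  std::vector<double> catv((size_t)ncat * npat);   // linear root sums
  std::vector<double> catls((size_t)ncat * npat);  // log scales
  bool any_scaled = false;
  std::vector<double> P(16);

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);
    double* ls = &catls[(size_t)c * npat];
    std::fill(ls, ls + npat, 0.0);
    for (int e = 0; e < nedge; ++e) {
      const int pa = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      pmat(&Um[0], &Vm[0], &lam[0], blens[e] * catrate[c], P.data());
      double* __restrict pp = &partial[(size_t)pa * 4 * npat];
      if (!seen[pa]) {
        std::fill(pp, pp + 4 * npat, 1.0);
        seen[pa] = 1;
      }
      if (ch < ntip) {
        const int* tr = &tip[0];
        const int nt = tip.nrow();
        for (int s = 0; s < npat; ++s) {
          const int code = tr[ch + nt * s];
          if (code == 5) continue;
          const double* Pc = &P[4 * (code - 1)];
          double* q = pp + 4 * s;
          q[0] *= Pc[0]; q[1] *= Pc[1]; q[2] *= Pc[2]; q[3] *= Pc[3];
        }
      } else {
        const double* __restrict cp = &partial[(size_t)ch * 4 * npat];
        for (int s = 0; s < npat; ++s) {
          const double* r = cp + 4 * s;
          double* q = pp + 4 * s;
          double m = 0.0;
          for (int x = 0; x < 4; ++x) {
            const double v = P[x] * r[0] + P[x + 4] * r[1] +
              P[x + 8] * r[2] + P[x + 12] * r[3];
            q[x] *= v;
            if (q[x] > m) m = q[x];
          }
          if (m < 1e-120 && m > 0.0) {
            const double inv = 1.0 / m;
            q[0] *= inv; q[1] *= inv; q[2] *= inv; q[3] *= inv;
            ls[s] += std::log(m);
            any_scaled = true;
          }
        }
      }
    }
    const double* rp = &partial[(size_t)(root - 1) * 4 * npat];
    double* cv = &catv[(size_t)c * npat];
    for (int s = 0; s < npat; ++s) {
      const double* r = rp + 4 * s;
      cv[s] = pi[0] * r[0] + pi[1] * r[1] + pi[2] * r[2] + pi[3] * r[3];
    }
  }

  double total = 0.0;
  if (!any_scaled) {
    for (int s = 0; s < npat; ++s) {
      double mix = 0.0;
      for (int c = 0; c < ncat; ++c) mix += catw[c] * catv[(size_t)c * npat + s];
      const double v = pinv * invw[s] + (1.0 - pinv) * mix;
      total += wts[s] * (v > 0.0 ? std::log(v) : -1e308);
    }
  } else {
    for (int s = 0; s < npat; ++s) {
      double M = -1e308;
      for (int c = 0; c < ncat; ++c) {
        const double v = catv[(size_t)c * npat + s];
        const double lv = (v > 0.0 ? std::log(v) : -1e308) +
          catls[(size_t)c * npat + s];
        catls[(size_t)c * npat + s] = lv;
        if (lv > M) M = lv;
      }
      double mix = 0.0;
      for (int c = 0; c < ncat; ++c)
        mix += catw[c] * std::exp(catls[(size_t)c * npat + s] - M);
      double out;
      const double inv_part = pinv * invw[s];
      const double var_part = (1.0 - pinv) * mix;
      if (inv_part > 0.0) {
        const double li = std::log(inv_part);
        const double lv = var_part > 0.0 ? M + std::log(var_part) : -1e308;
        const double mx = li > lv ? li : lv;
        out = mx + std::log(std::exp(li - mx) + std::exp(lv - mx));
      } else {
        out = var_part > 0.0 ? M + std::log(var_part) : -1e308;
      }
      total += wts[s] * out;
    }
  }
  return total;
}

// Total log-likelihood over all partitions in a single call.
// [[Rcpp::export]]
double peel_total_cpp(IntegerMatrix edge, int ntip, List parts,
                      NumericVector blens) {
  double total = 0.0;
  for (int p = 0; p < parts.size(); ++p) {
    List part = parts[p];
    total += peel_part_total(edge, ntip, part, blens);
  }
  return total;
}

static inline int seq_matches(const char* a, int la, const char* b, int lb) {
  const int l = la < lb ? la : lb;
  int m = 0;
  for (int i = 0; i < l; ++i)
    if (a[i] == b[i] && a[i] != 'N') ++m;
  return m;
}

// Greedy centroid clustering over reads given in processing order
// (abundance desc, length desc, id). Identity = matching columns of the
// left-aligned ungapped comparison / length of the longer sequence; N never
// matches. Each read joins the FIRST (oldest) centroid reaching the
// threshold on either strand (when rc is supplied), else founds a cluster.
// [[Rcpp::export]]
List greedy_cluster_cpp(CharacterVector seqs, CharacterVector rcs,
                        double threshold) {
  const int n = seqs.size();
  const bool both = rcs.size() == n;
  IntegerVector assign(n);
  CharacterVector strand(n);
  std::vector<int> centroids;
  centroids.reserve(256);
  std::vector<const char*> cs;
  std::vector<int> cl;

  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const int ls = LENGTH(STRING_ELT(seqs, i));
    const char* r = both ? CHAR(STRING_ELT(rcs, i)) : nullptr;
    int hit = -1;
    char hs = '+';
    for (size_t c = 0; c < centroids.size(); ++c) {
      const int lc = cl[c];
      const int lmax = ls > lc ? ls : lc;
      const int lmin = ls < lc ? ls : lc;
      if ((double)lmin / (double)lmax < threshold) continue;
      if ((double)seq_matches(s, ls, cs[c], lc) / lmax >= threshold) {
        hit = (int)c; hs = '+'; break;
      }
      if (both &&
          (double)seq_matches(r, ls, cs[c], lc) / lmax >= threshold) {
        hit = (int)c; hs = '-'; break;
      }
    }
    if (hit < 0) {
      centroids.push_back(i);
      cs.push_back(s);
      cl.push_back(ls);
      assign[i] = i + 1;
      strand[i] = "+";
    } else {
      assign[i] = centroids[hit] + 1;
      strand[i] = hs == '+' ? "+" : "-";
    }
  }
  return List::create(_["centroid"] = assign, _["strand"] = strand);
}
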