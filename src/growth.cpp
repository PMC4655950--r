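#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Wiring-rule codes; kept in sync with wiring_rule_names() on the R side.
enum Rule {
  GEOMETRIC = 0,
  CLU_AVG, CLU_DIFF, CLU_MAX, CLU_MIN, CLU_PROD,
  DEG_AVG, DEG_DIFF, DEG_MAX, DEG_MIN, DEG_PROD,
  NEIGHBORS, MATCHING
};

static int rule_code(const std::string &name) {
  if (name == "geometric") return GEOMETRIC;
  if (name == "clu-avg")   return CLU_AVG;
  if (name == "clu-diff")  return CLU_DIFF;
  if (name == "clu-max")   return CLU_MAX;
  if (name == "clu-min")   return CLU_MIN;
  if (name == "clu-prod")  return CLU_PROD;
  if (name == "deg-avg")   return DEG_AVG;
  if (name == "deg-diff")  return DEG_DIFF;
  if (name == "deg-max")   return DEG_MAX;
  if (name == "deg-min")   return DEG_MIN;
  if (name == "deg-prod")  return DEG_PROD;
  if (name == "neighbors") return NEIGHBORS;
  if (name == "matching")  return MATCHING;
  stop("unknown wiring rule '" + name + "'");
  return -1; // not reached
}

static inline double local_clu(int deg, double tri) {
  return deg < 2 ? 0.0 : 2.0 * tri / (static_cast<double>(deg) * (deg - 1));
}

// packed index of pair {i, j}, i < j, in the fixed column-major
// upper-triangle ordering (j = 1..n-1, i = 0..j-1): contiguous scans keep
// the per-step cumulative-sum walk cache-friendly
static inline int pidx(int i, int j) { return j * (j - 1) / 2 + i; }

// Edge-by-edge growth under P(u,v) = dterm(u,v) * (K(u,v) + eps)^gamma.
// dterm is precomputed on the R side (E^eta or exp(eta*E)); K is maintained
// incrementally from degree, triangle and common-neighbour counts, so each
// step only recomputes the probability entries touched by the new edge.
// Randomness comes from R's RNG stream (unif_rand), so set.seed() governs it.
// [[Rcpp::export(name = ".grow_cpp")]]
List grow_cpp(IntegerMatrix seed_adj, NumericMatrix dterm, double gamma,
              double epsilon, int m_target, std::string rule_name) {
  const int n = seed_adj.nrow();
  if (seed_adj.ncol() != n) stop("adjacency matrix must be square");
  if (dterm.nrow() != n || dterm.ncol() != n)
    stop("distance-term matrix dimensions must match the adjacency");
  const int rule = rule_code(rule_name);
  const int npair = n * (n - 1) / 2;

  std::vector<int> A(n * n, 0), deg(n, 0), cn(n * n, 0);
  std::vector<double> tri(n, 0.0);
  int m0 = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (seed_adj(i, j)) A[i * n + j] = 1;
  for (int i = 0; i < n; ++i) {
    if (A[i * n + i]) stop("adjacency has a nonzero diagonal entry");
    for (int j = 0; j < n; ++j) {
      if (A[i * n + j] != A[j * n + i]) stop("adjacency must be symmetric");
      deg[i] += A[i * n + j];
      if (j > i) m0 += A[i * n + j];
    }
  }
  // common-neighbour counts cn = A^2 and per-node triangle counts
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int s = 0;
      for (int w = 0; w < n; ++w) s += A[i * n + w] * A[w * n + j];
      cn[i * n + j] = s;
    }
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    for (int j = 0; j < n; ++j) t += A[i * n + j] * cn[i * n + j];
    tri[i] = t / 2.0;
  }

  const int steps = m_target - m0;
  if (steps < 0) stop("target edge count is below the seed edge count");
  if (m_target > npair) stop("target edge count exceeds n(n-1)/2");

  // K(u,v) from the maintained counts
  auto kval = [&](int i, int j) -> double {
    switch (rule) {
    case GEOMETRIC: return 1.0;
    case DEG_AVG:   return 0.5 * (deg[i] + deg[j]);
    case DEG_DIFF:  return std::abs(deg[i] - deg[j]);
    case DEG_MAX:   return std::max(deg[i], deg[j]);
    case DEG_MIN:   return std::min(deg[i], deg[j]);
    case DEG_PROD:  return static_cast<double>(deg[i]) * deg[j];
    case CLU_AVG:   return 0.5 * (local_clu(deg[i], tri[i]) + local_clu(deg[j], tri[j]));
    case CLU_DIFF:  return std::abs(local_clu(deg[i], tri[i]) - local_clu(deg[j], tri[j]));
    case CLU_MAX:   return std::max(local_clu(deg[i], tri[i]), local_clu(deg[j], tri[j]));
    case CLU_MIN:   return std::min(local_clu(deg[i], tri[i]), local_clu(deg[j], tri[j]));
    case CLU_PROD:  return local_clu(deg[i], tri[i]) * local_clu(deg[j], tri[j]);
    case NEIGHBORS: return cn[i * n + j];
    case MATCHING: {
      const int a = A[i * n + j];
      const int inter = cn[i * n + j];
      const int uni = (deg[i] - a) + (deg[j] - a) - inter;
      return uni <= 0 ? 0.0 : static_cast<double>(inter) / uni;
    }
    }
    return 0.0; // not reached
  };

  // packed distance term and weights over the upper triangle
  std::vector<double> dpk(npair), W(npair);
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i) dpk[pidx(i, j)] = dterm(i, j);
  auto wval = [&](int i, int j) -> double { // requires i < j
    if (A[i * n + j]) return 0.0;
    return dpk[pidx(i, j)] * std::pow(kval(i, j) + epsilon, gamma);
  };
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i) {
      const double w = wval(i, j);
      if (!R_finite(w))
        stop("non-finite connection weight for pair (%d, %d)", i + 1, j + 1);
      W[pidx(i, j)] = w;
    }

  IntegerMatrix edges(steps, 2);
  std::vector<int> touched;
  touched.reserve(n);

  for (int s = 0; s < steps; ++s) {
    double total = 0.0;
    for (int p = 0; p < npair; ++p) total += W[p];
    if (!(total > 0.0))
      stop("all relative connection probabilities are zero with %d edges still to place",
           steps - s);
    const double r = unif_rand() * total;
    int su = -1, sv = -1;
    double acc = 0.0;
    {
      int p = 0;
      for (int j = 1; j < n && su < 0; ++j)
        for (int i = 0; i < j; ++i, ++p) {
          const double w = W[p];
          acc += w;
          if (w > 0.0 && acc >= r) { su = i; sv = j; break; }
        }
    }
    if (su < 0) { // numerical guard: fall back to the last positive pair
      for (int j = n - 1; j >= 1 && su < 0; --j)
        for (int i = j - 1; i >= 0; --i)
          if (W[pidx(i, j)] > 0.0) { su = i; sv = j; break; }
    }
    const int u = su, v = sv;

    // structural updates: triangles, common neighbours, adjacency, degree
    const int c_uv = cn[u * n + v];
    touched.clear();
    for (int w = 0; w < n; ++w)
      if (A[u * n + w] && A[v * n + w]) { tri[w] += 1.0; touched.push_back(w); }
    tri[u] += c_uv;
    tri[v] += c_uv;
    for (int w = 0; w < n; ++w) {
      if (w != u && A[v * n + w]) { ++cn[u * n + w]; ++cn[w * n + u]; }
      if (w != v && A[u * n + w]) { ++cn[v * n + w]; ++cn[w * n + v]; }
    }
    A[u * n + v] = A[v * n + u] = 1;
    ++deg[u];
    ++deg[v];
    edges(s, 0) = u + 1;
    edges(s, 1) = v + 1;

    // weight entries affected by the insertion
    std::vector<int> S;
    if (rule >= CLU_AVG && rule <= CLU_PROD) {
      S = touched;          // common neighbours: their clustering changed
      S.push_back(u);
      S.push_back(v);
    } else if (rule != GEOMETRIC) {
      S.push_back(u);       // degree / neighbours / matching: endpoint rows only
      S.push_back(v);
    }
    for (size_t a = 0; a < S.size(); ++a) {
      const int i = S[a];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const int lo = std::min(i, j), hi = std::max(i, j);
        const double w = wval(lo, hi);
        if (!R_finite(w))
          stop("non-finite connection weight for pair (%d, %d)", lo + 1, hi + 1);
        W[pidx(lo, hi)] = w;
      }
    }
    W[pidx(u, v)] = 0.0;
  }

  IntegerMatrix adj(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) adj(i, j) = A[i * n + j];
  return List::create(_["adjacency"] = adj, _["edges"] = edges);
}

// Unweighted node betweenness (Brandes), undirected convention: endpoints
// excluded, every unordered pair counted once, unnormalized.
// [[Rcpp::export(name = ".betweenness_cpp")]]
NumericVector betweenness_cpp(IntegerMatrix adj) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency matrix must be square");
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) nbr[i].push_back(j);

  NumericVector bc(n);
  std::vector<int> dist(n), queue(n), order(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    int qh = 0, qt = 0, no = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    queue[qt++] = s;
    while (qh < qt) {
      const int v = queue[qh++];
      order[no++] = v;
      for (size_t a = 0; a < nbr[v].size(); ++a) {
        const int w = nbr[v][a];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue[qt++] = w;
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int a = no - 1; a >= 0; --a) {
      const int w = order[a];
      for (size_t b = 0; b < pred[w].size(); ++b) {
        const int v = pred[w][b];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0; // undirected: each pair once
  return bc;
}
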