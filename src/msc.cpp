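// Multispecies-coalescent simulation core.
//
// The species tree arrives as parallel arrays over nodes (1-based parents,
// node times tau in expected substitutions/site, per-branch theta = 4*Ne*mu)
// plus a child-before-parent processing order. Within each species branch,
// k lineages coalesce at total rate k*(k-1)/theta per unit tau (pairwise
// rate 2/theta); survivors enter the parent branch; above the root
// coalescence continues until one lineage remains. Mutations are dropped on
// the gene tree as a Poisson process with rate 1 per unit branch length and
// resolved under Jukes-Cantor (a mutation moves to one of the three other
// bases, so back-mutation can restore a state).
//
// All randomness comes from R's RNG, so set.seed() in R governs everything.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct SpeciesTree {
  std::vector<int> parent;     // 0-based, -1 for root
  std::vector<double> tau;
  std::vector<double> theta;
  std::vector<int> order;      // children before parents
  std::vector<int> n_hap;      // haplotypes sampled per node (0 internal)
  int n_nodes;
  int total_haps;
};

SpeciesTree build(IntegerVector parent, NumericVector tau, NumericVector theta,
                  IntegerVector order, IntegerVector n_hap) {
  SpeciesTree st;
  st.n_nodes = parent.size();
  st.parent.resize(st.n_nodes);
  st.tau.assign(tau.begin(), tau.end());
  st.theta.assign(theta.begin(), theta.end());
  st.n_hap.assign(n_hap.begin(), n_hap.end());
  st.total_haps = 0;
  for (int i = 0; i < st.n_nodes; ++i) {
    st.parent[i] = parent[i] - 1;  // -1 becomes root marker via 0 - 1
    st.total_haps += st.n_hap[i];
  }
  st.order.resize(order.size());
  for (int i = 0; i < (int)order.size(); ++i) st.order[i] = order[i] - 1;
  return st;
}

// One gene tree: fills gparent / gtime (2H-1 nodes, tips 0..H-1 in species
// processing order grouped per tip node) and returns the root index.
struct GeneTree {
  std::vector<int> gparent;
  std::vector<double> gtime;
};

void sim_gene_tree(const SpeciesTree& st, GeneTree& gt,
                   const std::vector<int>& hap_offset) {
  const int H = st.total_haps;
  const int G = 2 * H - 1;
  gt.gparent.assign(G, -1);
  gt.gtime.assign(G, 0.0);
  int next_node = H;
  std::vector<std::vector<int>> active(st.n_nodes);
  for (int oi = 0; oi < (int)st.order.size(); ++oi) {
    int v = st.order[oi];
    std::vector<int>& act = active[v];
    if (st.n_hap[v] > 0)
      for (int h = 0; h < st.n_hap[v]; ++h)
        act.push_back(hap_offset[v] + h);
    double t = st.tau[v];
    bool is_root = st.parent[v] < 0;
    double end = is_root ? std::numeric_limits<double>::infinity()
                         : st.tau[st.parent[v]];
    double th = st.theta[v];
    int k = (int)act.size();
    while (k > 1) {
      double rate = (double)k * (k - 1) / th;
      double w = R::rexp(1.0 / rate);
      if (t + w > end) break;
      t += w;
      int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int g = next_node++;
      gt.gtime[g] = t;
      gt.gparent[act[i]] = g;
      gt.gparent[act[j]] = g;
      act[i] = g;
      act.erase(act.begin() + j);
      --k;
    }
    if (!is_root) {
      std::vector<int>& up = active[st.parent[v]];
      up.insert(up.end(), act.begin(), act.end());
    }
  }
}

// branch lengths (to parent); root excluded
double total_length(const GeneTree& gt, std::vector<double>& len) {
  int G = gt.gparent.size();
  len.assign(G, 0.0);
  double tot = 0.0;
  for (int v = 0; v < G; ++v)
    if (gt.gparent[v] >= 0) {
      len[v] = gt.gtime[gt.gparent[v]] - gt.gtime[v];
      tot += len[v];
    }
  return tot;
}

// Evolve one site: given per-branch mutation counts, produce tip states.
// Gene nodes were created in an order where every parent has a higher index
// than its children, so a single descending sweep suffices.
void evolve_site(const GeneTree& gt, const std::vector<int>& nmut,
                 std::vector<int>& state) {
  int G = gt.gparent.size();
  state.assign(G, 0);
  int root = G - 1;
  state[root] = (int)(R::unif_rand() * 4); if (state[root] > 3) state[root] = 3;
  for (int v = G - 2; v >= 0; --v) {
    int s = state[gt.gparent[v]];
    for (int m = 0; m < nmut[v]; ++m) {
      int step = 1 + (int)(R::unif_rand() * 3); if (step > 3) step = 3;
      s = (s + step) % 4;
    }
    state[v] = s;
  }
}

// distribute n mutations over branches proportionally to length
void scatter_mutations(const std::vector<double>& len, double tot, int n,
                       std::vector<int>& nmut) {
  nmut.assign(len.size(), 0);
  for (int m = 0; m < n; ++m) {
    double u = R::unif_rand() * tot;
    double acc = 0.0;
    for (size_t v = 0; v < len.size(); ++v) {
      acc += len[v];
      if (u <= acc || v + 1 == len.size()) { nmut[v]++; break; }
    }
  }
}

std::vector<int> offsets(const SpeciesTree& st) {
  std::vector<int> off(st.n_nodes, 0);
  int acc = 0;
  for (int oi = 0; oi < (int)st.order.size(); ++oi) {
    int v = st.order[oi];
    if (st.n_hap[v] > 0) { off[v] = acc; acc += st.n_hap[v]; }
  }
  return off;
}

} // namespace

// [[Rcpp::export]]
List msc_gene_trees(IntegerVector parent, NumericVector tau, NumericVector theta,
                    IntegerVector order, IntegerVector n_hap, int n_loci) {
  SpeciesTree st = build(parent, tau, theta, order, n_hap);
  std::vector<int> off = offsets(st);
  int G = 2 * st.total_haps - 1;
  IntegerMatrix gparent(G, n_loci);
  NumericMatrix gtime(G, n_loci);
  GeneTree gt;
  for (int l = 0; l < n_loci; ++l) {
    sim_gene_tree(st, gt, off);
    for (int v = 0; v < G; ++v) {
      gparent(v, l) = gt.gparent[v] + 1;  // 1-based, 0 = root
      gtime(v, l) = gt.gtime[v];
    }
  }
  IntegerVector hap_node(st.total_haps);
  for (int v = 0; v < st.n_nodes; ++v)
    for (int h = 0; h < st.n_hap[v]; ++h)
      hap_node[off[v] + h] = v + 1;
  return List::create(_["gparent"] = gparent, _["gtime"] = gtime,
                      _["hap_node"] = hap_node);
}

// [[Rcpp::export]]
List msc_snp(IntegerVector parent, NumericVector tau, NumericVector theta,
             IntegerVector order, IntegerVector n_hap,
             int target_poly, int max_raw) {
  SpeciesTree st = build(parent, tau, theta, order, n_hap);
  std::vector<int> off = offsets(st);
  const int H = st.total_haps;
  IntegerMatrix alleles(H, target_poly);
  GeneTree gt;
  std::vector<double> len;
  std::vector<int> nmut, state;
  int got = 0, raw = 0;
  while (got < target_poly && raw < max_raw) {
    ++raw;
    sim_gene_tree(st, gt, off);
    double tot = total_length(gt, len);
    int n = (int)R::rpois(tot);
    if (n == 0) continue;  // monomorphic
    scatter_mutations(len, tot, n, nmut);
    evolve_site(gt, nmut, state);
    bool poly = false;
    for (int h = 1; h < H; ++h) if (state[h] != state[0]) { poly = true; break; }
    if (!poly) continue;   // back-mutation restored monomorphy
    for (int h = 0; h < H; ++h) alleles(h, got) = state[h];
    ++got;
  }
  IntegerVector hap_node(H);
  for (int v = 0; v < st.n_nodes; ++v)
    for (int h = 0; h < st.n_hap[v]; ++h)
      hap_node[off[v] + h] = v + 1;
  return List::create(_["alleles"] = alleles, _["n_poly"] = got,
                      _["raw_used"] = raw, _["hap_node"] = hap_node);
}

// [[Rcpp::export]]
List msc_aflp(IntegerVector parent, NumericVector tau, NumericVector theta,
              IntegerVector order, IntegerVector n_hap,
              int target_poly, int max_raw, int n_sites) {
  SpeciesTree st = build(parent, tau, theta, order, n_hap);
  std::vector<int> off = offsets(st);
  const int H = st.total_haps;
  if (H % 2 != 0) stop("AFLP simulation needs an even number of haplotypes");
  const int N = H / 2;  // diploid individuals, consecutive haplotype pairs
  IntegerMatrix bands(N, target_poly);
  GeneTree gt;
  std::vector<double> len;
  std::vector<int> state;
  std::vector<std::vector<int>> site_mut(n_sites);
  std::vector<int> hap_band(H);
  int got = 0, raw = 0;
  while (got < target_poly && raw < max_raw) {
    ++raw;
    sim_gene_tree(st, gt, off);
    double tot = total_length(gt, len);
    int n = (int)R::rpois(n_sites * tot);
    if (n == 0) continue;  // all recognition sites intact -> monomorphic
    for (int s = 0; s < n_sites; ++s) site_mut[s].assign(len.size(), 0);
    for (int m = 0; m < n; ++m) {
      int s = (int)(R::unif_rand() * n_sites); if (s >= n_sites) s = n_sites - 1;
      double u = R::unif_rand() * tot;
      double acc = 0.0;
      for (size_t v = 0; v < len.size(); ++v) {
        acc += len[v];
        if (u <= acc || v + 1 == len.size()) { site_mut[s][v]++; break; }
      }
    }
    std::fill(hap_band.begin(), hap_band.end(), 1);
    int root = 2 * H - 2;
    for (int s = 0; s < n_sites; ++s) {
      bool any = false;
      for (size_t v = 0; v < site_mut[s].size(); ++v)
        if (site_mut[s][v] > 0) { any = true; break; }
      if (!any) continue;  // site identical to ancestral state everywhere
      evolve_site(gt, site_mut[s], state);
      for (int h = 0; h < H; ++h)
        if (state[h] != state[root]) hap_band[h] = 0;
    }
    // dominance: an individual shows the band if either haplotype is intact
    bool all0 = true, all1 = true;
    for (int i = 0; i < N; ++i) {
      int b = hap_band[2 * i] | hap_band[2 * i + 1];
      if (b) all0 = false; else all1 = false;
      bands(i, got) = b;
    }
    if (all0 || all1) continue;  // monomorphic across individuals
    ++got;
  }
  return List::create(_["bands"] = bands, _["n_poly"] = got,
                      _["raw_used"] = raw);
}
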