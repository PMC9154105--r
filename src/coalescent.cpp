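// Neutral backward-in-time simulator for a single panmictic population with
// piecewise-constant diploid size and uniform per-bp mutation/recombination
// rates.  The genealogy at the left end of the segment is drawn from the
// exact coalescent; along the sequence the ancestral recombination graph is
// approximated by the sequentially Markov coalescent (a floating lineage
// created at each recombination point re-coalesces into the pruned tree).
// With r = 0 the single-tree path is the exact coalescent.
//
// Time is measured in generations before sampling; the pairwise coalescence
// rate in an epoch of diploid size N is 1/(2N) per generation.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

namespace {

struct Demog {
    std::vector<double> size;  // diploid sizes
    std::vector<double> time;  // backward start times, ascending, time[0] == 0

    double n_at(double t) const {
        int i = static_cast<int>(time.size()) - 1;
        while (i > 0 && t < time[i]) --i;
        return size[i];
    }
    // waiting time from t0 until one event at hazard k2 / (2N(t))
    double wait(double t0, double k2, Xoshiro& rng) const {
        double target = -std::log(rng.unif_pos());
        double t = t0;
        int i = static_cast<int>(time.size()) - 1;
        while (i > 0 && t0 < time[i]) --i;
        for (;;) {
            double rate = k2 / (2.0 * size[i]);
            double tend = (i + 1 < static_cast<int>(time.size())) ? time[i + 1] : R_PosInf;
            if (!R_FINITE(tend)) return t + target / rate;
            double span = tend - t;
            if (rate * span >= target) return t + target / rate;
            target -= rate * span;
            t = tend;
            ++i;
        }
    }
};

struct Tree {
    int n;                        // leaves
    std::vector<double> time;     // node times
    std::vector<int> parent, ch1, ch2;
    int root;

    int n_nodes() const { return 2 * n - 1; }

    double total_length() const {
        double B = 0.0;
        for (int v = 0; v < n_nodes(); ++v)
            if (parent[v] >= 0) B += time[parent[v]] - time[v];
        return B;
    }
};

void first_tree(Tree& tr, const Demog& dem, Xoshiro& rng) {
    int n = tr.n;
    tr.time.assign(tr.n_nodes(), 0.0);
    tr.parent.assign(tr.n_nodes(), -1);
    tr.ch1.assign(tr.n_nodes(), -1);
    tr.ch2.assign(tr.n_nodes(), -1);
    std::vector<int> active(n);
    for (int i = 0; i < n; ++i) active[i] = i;
    double t = 0.0;
    int next_id = n;
    for (int k = n; k >= 2; --k) {
        t = dem.wait(t, k * (k - 1) / 2.0, rng);
        int i = rng.rint(k);
        int j = rng.rint(k - 1);
        if (j >= i) ++j;
        int a = active[i], b = active[j];
        tr.time[next_id] = t;
        tr.ch1[next_id] = a; tr.ch2[next_id] = b;
        tr.parent[a] = next_id; tr.parent[b] = next_id;
        if (i > j) std::swap(i, j);
        active[i] = next_id;
        active[j] = active[k - 1];
        ++next_id;
    }
    tr.root = next_id - 1;
}

// pick a point uniformly on the tree; returns (node, height)
std::pair<int, double> pick_point(const Tree& tr, double B, Xoshiro& rng) {
    double u = rng.unif() * B;
    for (int v = 0; v < tr.n_nodes(); ++v) {
        if (tr.parent[v] < 0) continue;
        double len = tr.time[tr.parent[v]] - tr.time[v];
        if (u < len) return std::make_pair(v, tr.time[v] + u);
        u -= len;
    }
    // numerical edge: fall back to the last real edge
    for (int v = tr.n_nodes() - 1; v >= 0; --v)
        if (tr.parent[v] >= 0)
            return std::make_pair(v, tr.time[v]);
    return std::make_pair(0, 0.0);
}

void mark_subtree(const Tree& tr, int v, std::vector<char>& flag) {
    std::vector<int> stack(1, v);
    while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        flag[u] = 1;
        if (tr.ch1[u] >= 0) { stack.push_back(tr.ch1[u]); stack.push_back(tr.ch2[u]); }
    }
}

// SMC transition at one recombination point
void smc_update(Tree& tr, double B, const Demog& dem, Xoshiro& rng) {
    std::pair<int, double> pt = pick_point(tr, B, rng);
    int v = pt.first;
    double h = pt.second;

    // detach edge above the point; P becomes a free node
    int P = tr.parent[v];
    int sib = (tr.ch1[P] == v) ? tr.ch2[P] : tr.ch1[P];
    int G = tr.parent[P];
    if (G >= 0) {
        if (tr.ch1[G] == P) tr.ch1[G] = sib; else tr.ch2[G] = sib;
        tr.parent[sib] = G;
    } else {
        tr.parent[sib] = -1;
        tr.root = sib;
    }
    tr.parent[v] = -1;
    tr.ch1[P] = tr.ch2[P] = -1;

    // nodes of the floating subtree are not re-coalescence partners
    std::vector<char> in_float(tr.n_nodes(), 0);
    mark_subtree(tr, v, in_float);
    in_float[P] = 1; // free node

    // lineage count of the pruned tree as a function of time:
    // k(t) = leaves - #internal nodes with time <= t (and 1 above the root)
    std::vector<double> itimes;
    int leaves_rem = 0;
    for (int u = 0; u < tr.n_nodes(); ++u) {
        if (in_float[u]) continue;
        if (tr.ch1[u] >= 0) itimes.push_back(tr.time[u]);
        else ++leaves_rem;
    }
    std::sort(itimes.begin(), itimes.end());

    // piecewise-constant hazard k(t)/(2N(t)) starting at h
    double target = -std::log(rng.unif_pos());
    double t = h;
    double tstar = -1.0;
    for (;;) {
        // current k
        int below = static_cast<int>(std::upper_bound(itimes.begin(), itimes.end(), t) - itimes.begin());
        int k = leaves_rem - below;
        if (k < 1) k = 1; // above the pruned root a single ancestral lineage remains
        // next breakpoint: next internal-node time or demography change
        double tnext = R_PosInf;
        if (below < static_cast<int>(itimes.size())) tnext = itimes[below];
        for (size_t e = 0; e < dem.time.size(); ++e)
            if (dem.time[e] > t && dem.time[e] < tnext) tnext = dem.time[e];
        double rate = k / (2.0 * dem.n_at(t));
        if (!R_FINITE(tnext)) { tstar = t + target / rate; break; }
        double span = tnext - t;
        if (rate * span >= target) { tstar = t + target / rate; break; }
        target -= rate * span;
        t = tnext;
    }

    // partners: pruned-tree edges spanning tstar, or the root lineage
    std::vector<int> cand;
    for (int u = 0; u < tr.n_nodes(); ++u) {
        if (in_float[u] || u == tr.root) continue;
        if (tr.time[u] <= tstar && tstar < tr.time[tr.parent[u]]) cand.push_back(u);
    }
    int partner;
    if (cand.empty() || tstar >= tr.time[tr.root]) {
        partner = tr.root;
    } else {
        partner = cand[rng.rint(static_cast<int>(cand.size()))];
    }

    // splice the recycled node P in at tstar
    tr.time[P] = tstar;
    tr.ch1[P] = partner; tr.ch2[P] = v;
    if (partner == tr.root) {
        tr.parent[partner] = P; tr.parent[v] = P;
        tr.parent[P] = -1;
        tr.root = P;
    } else {
        int G2 = tr.parent[partner];
        if (tr.ch1[G2] == partner) tr.ch1[G2] = P; else tr.ch2[G2] = P;
        tr.parent[partner] = P; tr.parent[v] = P;
        tr.parent[P] = G2;
    }
}

void collect_leaves(const Tree& tr, int v, std::vector<int>& out) {
    out.clear();
    std::vector<int> stack(1, v);
    while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        if (tr.ch1[u] < 0) out.push_back(u);
        else { stack.push_back(tr.ch1[u]); stack.push_back(tr.ch2[u]); }
    }
}

} // namespace

// [[Rcpp::export]]
List coalescent_sim_cpp(int n, int L, double mu, double rec,
                        NumericVector dem_sizes, NumericVector dem_times,
                        int replicates, double seed) {
    if (n < 2) stop("need at least two haplotypes");
    if (mu < 0 || rec < 0) stop("rates must be non-negative");
    Demog dem;
    dem.size.assign(dem_sizes.begin(), dem_sizes.end());
    dem.time.assign(dem_times.begin(), dem_times.end());

    Xoshiro rng(static_cast<uint64_t>(seed));
    List out(replicates);

    std::vector<char> used(L, 0);
    std::vector<int> touched;
    std::vector<int> leaves;

    for (int rep = 0; rep < replicates; ++rep) {
        Rcpp::checkUserInterrupt();
        Tree tr;
        tr.n = n;
        first_tree(tr, dem, rng);

        std::vector<int> site_pos;
        std::vector<std::vector<int> > site_carriers;
        touched.clear();

        double x = 0.0;
        for (;;) {
            double B = tr.total_length();
            double xend;
            if (rec > 0.0) {
                double d = rng.rexp(rec * B);
                xend = std::min(x + d, static_cast<double>(L));
            } else {
                xend = static_cast<double>(L);
            }
            // mutations on the marginal tree of [x, xend)
            if (mu > 0.0 && xend > x) {
                int m = rng.rpois(mu * (xend - x) * B);
                for (int k = 0; k < m; ++k) {
                    int pos = -1;
                    for (int tries = 0; tries < 200; ++tries) {
                        int p = static_cast<int>(x + rng.unif() * (xend - x));
                        if (p >= L) p = L - 1;
                        if (!used[p]) { pos = p; break; }
                    }
                    if (pos < 0) continue; // segment saturated; drop
                    used[pos] = 1;
                    touched.push_back(pos);
                    std::pair<int, double> pt = pick_point(tr, B, rng);
                    collect_leaves(tr, pt.first, leaves);
                    site_pos.push_back(pos);
                    site_carriers.push_back(leaves);
                }
            }
            if (xend >= static_cast<double>(L)) break;
            smc_update(tr, B, dem, rng);
            x = xend;
        }

        // order sites by position and emit the 0/1 matrix
        std::vector<int> ord(site_pos.size());
        for (size_t i = 0; i < ord.size(); ++i) ord[i] = static_cast<int>(i);
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return site_pos[a] < site_pos[b]; });
        int S = static_cast<int>(ord.size());
        IntegerMatrix G(n, S);
        IntegerVector positions(S);
        for (int c = 0; c < S; ++c) {
            positions[c] = site_pos[ord[c]];
            for (int leaf : site_carriers[ord[c]]) G(leaf, c) = 1;
        }
        out[rep] = List::create(_["positions"] = positions, _["genotypes"] = G);
        for (int p : touched) used[p] = 0;
    }
    return out;
}
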