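// Discrete-generation Wright-Fisher forward simulator with multiplicative
// selection across sites, block-wise mutation/recombination rate maps,
// piecewise-constant demography and optional progeny skew (a fixed fraction
// of each generation descends from a single focal parent).
//
// Mutations live in a registry (position, homozygous effect, class, origin
// generation); haplotypes are sorted vectors of registry ids.  Fixed and lost
// mutations are harvested every `purge_interval` generations and their ids
// recycled, so memory stays proportional to the number of segregating sites.
// An occupancy bitmap enforces the infinite-sites convention within the run:
// a proposed mutation at a currently segregating position is re-drawn.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

namespace {

// mutation classes
enum MutClass { NEUTRAL = 0, DEL1 = 1, DEL2 = 2, DEL3 = 3, DEL4 = 4, BENEFICIAL = 5 };

struct Registry {
    std::vector<int> pos;
    std::vector<double> s;      // homozygous selection coefficient
    std::vector<int> cls;
    std::vector<int> origin;
    std::vector<char> live;
    std::vector<int> free_ids;

    int alloc(int p, double sh, int c, int gen) {
        int id;
        if (!free_ids.empty()) {
            id = free_ids.back();
            free_ids.pop_back();
            pos[id] = p; s[id] = sh; cls[id] = c; origin[id] = gen; live[id] = 1;
        } else {
            id = static_cast<int>(pos.size());
            pos.push_back(p); s.push_back(sh); cls.push_back(c);
            origin.push_back(gen); live.push_back(1);
        }
        return id;
    }
    void release(int id) { live[id] = 0; free_ids.push_back(id); }
    size_t size() const { return pos.size(); }
};

struct Hap {
    std::vector<int> neu;  // neutral ids, sorted by position
    std::vector<int> sel;  // selected ids, sorted by position
    void clear() { neu.clear(); sel.clear(); }
};

// cumulative per-block weights for sampling a genomic position
struct BlockSampler {
    std::vector<double> cum;     // cumulative weight per block
    std::vector<int> start, len; // block spans
    double total = 0.0;

    void build(const NumericVector& rates, int block_len, int L) {
        int nb = rates.size();
        cum.resize(nb); start.resize(nb); len.resize(nb);
        double acc = 0.0;
        for (int b = 0; b < nb; ++b) {
            start[b] = b * block_len;
            len[b] = std::min(block_len, L - start[b]);
            acc += rates[b] * len[b];
            cum[b] = acc;
        }
        total = acc;
    }
    // integer bp position, weighted by block rate, uniform within block
    int draw_pos(Xoshiro& rng) const {
        double u = rng.unif() * total;
        int b = static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (b >= static_cast<int>(cum.size())) b = static_cast<int>(cum.size()) - 1;
        return start[b] + rng.rint(len[b]);
    }
    // continuous breakpoint position
    double draw_break(Xoshiro& rng) const {
        double u = rng.unif() * total;
        int b = static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (b >= static_cast<int>(cum.size())) b = static_cast<int>(cum.size()) - 1;
        return start[b] + rng.unif() * len[b];
    }
};

inline void copy_pos_range(const std::vector<int>& src, const Registry& reg,
                           double a, double b, std::vector<int>& out) {
    // append ids with position in [a, b)
    auto lo = std::lower_bound(src.begin(), src.end(), a,
        [&](int id, double val) { return reg.pos[id] < val; });
    auto hi = std::lower_bound(lo, src.end(), b,
        [&](int id, double val) { return reg.pos[id] < val; });
    out.insert(out.end(), lo, hi);
}

// copy one recombinant gamete of parent (hapA, hapB) into out
void make_gamete(const Hap& hapA, const Hap& hapB, const Registry& reg,
                 const std::vector<double>& breaks, int start_hap,
                 Hap& out, int L) {
    out.clear();
    const Hap* cur = (start_hap == 0) ? &hapA : &hapB;
    const Hap* oth = (start_hap == 0) ? &hapB : &hapA;
    double a = 0.0;
    for (size_t k = 0; k <= breaks.size(); ++k) {
        double b = (k < breaks.size()) ? breaks[k] : static_cast<double>(L);
        if (b > a) {
            copy_pos_range(cur->neu, reg, a, b, out.neu);
            copy_pos_range(cur->sel, reg, a, b, out.sel);
        }
        std::swap(cur, oth);
        a = b;
    }
}

inline double diploid_fitness(const Hap& h1, const Hap& h2, const Registry& reg,
                              double hdom) {
    double w = 1.0;
    size_t i = 0, j = 0;
    const std::vector<int>& a = h1.sel;
    const std::vector<int>& b = h2.sel;
    while (i < a.size() && j < b.size()) {
        int pa = reg.pos[a[i]], pb = reg.pos[b[j]];
        if (pa < pb) { w *= 1.0 + hdom * reg.s[a[i]]; ++i; }
        else if (pb < pa) { w *= 1.0 + hdom * reg.s[b[j]]; ++j; }
        else { // same position implies same id (infinite sites): homozygote
            w *= 1.0 + reg.s[a[i]]; ++i; ++j;
        }
    }
    for (; i < a.size(); ++i) w *= 1.0 + hdom * reg.s[a[i]];
    for (; j < b.size(); ++j) w *= 1.0 + hdom * reg.s[b[j]];
    if (w > 1e300) w = 1e300; // keep cumulative sums finite at extreme gamma
    return (w > 0.0) ? w : 0.0;
}

inline int weighted_pick(const std::vector<double>& cumw, Xoshiro& rng) {
    double u = rng.unif() * cumw.back();
    int k = static_cast<int>(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
    if (k >= static_cast<int>(cumw.size())) k = static_cast<int>(cumw.size()) - 1;
    return k;
}

} // namespace

// [[Rcpp::export]]
List forward_sim_cpp(int L,
                     LogicalVector exonic,
                     NumericVector mu_block,
                     NumericVector rec_block,
                     int block_len,
                     bool del_enabled,
                     NumericVector del_weights,
                     NumericVector del_lower,  // scaled 2N*s_het lower bounds (negative), length 4
                     NumericVector del_upper,  // scaled upper bounds, length 4
                     double gamma,
                     double fpos,
                     double hdom,
                     double dfe_two_n,         // 2*N_anc used to de-scale the DFE
                     IntegerVector epoch_sizes,
                     IntegerVector epoch_starts,
                     int total_gens,
                     double psi,
                     bool psi_fitness_weighted,
                     int n_sample,
                     bool track_neutral,
                     int purge_interval,
                     int init_poly_count,
                     double init_poly_freq,
                     double seed) {
    if (total_gens < 1) stop("total_gens must be >= 1");
    if (epoch_sizes.size() < 1) stop("empty demography");
    Xoshiro rng(static_cast<uint64_t>(seed));

    BlockSampler mu_map, rec_map;
    mu_map.build(mu_block, block_len, L);
    rec_map.build(rec_block, block_len, L);

    Registry reg;
    std::vector<uint8_t> occupied(L, 0);

    const bool sweeps = (fpos > 0.0 && gamma > 0.0);
    const bool selection_input = del_enabled || sweeps;
    const double sbar_hom = sweeps ? 2.0 * gamma / dfe_two_n : 0.0;

    // cumulative deleterious class weights
    double del_cum[4] = {0, 0, 0, 0};
    if (del_enabled) {
        double acc = 0.0;
        for (int c = 0; c < 4; ++c) { acc += del_weights[c]; del_cum[c] = acc; }
    }

    int N = epoch_sizes[0];
    std::vector<Hap> pop(2 * N), nxt;
    long long total_introduced = 0, total_fixed = 0, total_lost = 0;
    long long introduced_by_class[6] = {0, 0, 0, 0, 0, 0};

    // fixation log
    std::vector<int> fix_cls, fix_origin, fix_gen;
    std::vector<double> fix_s;

    // optional standing variation at generation 0
    for (int k = 0; k < init_poly_count; ++k) {
        int p;
        do { p = rng.rint(L); } while (occupied[p]);
        occupied[p] = 1;
        int id = reg.alloc(p, 0.0, NEUTRAL, 0);
        ++total_introduced;
        int carriers = static_cast<int>(std::lround(init_poly_freq * 2 * N));
        carriers = std::max(1, std::min(2 * N - 1, carriers));
        // partial Fisher-Yates over haplotype indices
        std::vector<int> idx(2 * N);
        for (int i = 0; i < 2 * N; ++i) idx[i] = i;
        for (int i = 0; i < carriers; ++i) {
            int j = i + rng.rint(2 * N - i);
            std::swap(idx[i], idx[j]);
            std::vector<int>& v = pop[idx[i]].neu;
            v.insert(std::lower_bound(v.begin(), v.end(), p,
                [&](int id2, int val) { return reg.pos[id2] < val; }), id);
        }
    }

    std::vector<double> cumw;
    std::vector<int> cnt;
    std::vector<char> remove_flag;
    std::vector<double> breaks;
    std::vector<int> new_neu, new_sel;
    int epoch_ptr = 0;

    auto draw_mutation = [&](int gen) -> std::pair<int, int> {
        // returns (id, is_selected); id = -1 for a dropped (untracked) neutral
        int p;
        int tries = 0;
        do {
            p = mu_map.draw_pos(rng);
            if (++tries > 10000) stop("mutation position sampling failed (segment saturated)");
        } while (occupied[p]);
        int c = NEUTRAL;
        double sh = 0.0;
        if (exonic[p]) {
            double u = rng.unif();
            if (sweeps && u < fpos) {
                c = BENEFICIAL;
                // exponential heterozygous effect, homozygote twice that
                sh = 2.0 * (gamma / dfe_two_n) * (-std::log(rng.unif_pos()));
            } else if (del_enabled) {
                double v = rng.unif();
                int cc = 0;
                while (cc < 3 && v > del_cum[cc]) ++cc;
                double lo = del_lower[cc], hi = del_upper[cc];
                double scaled = lo + rng.unif() * (hi - lo); // 2N*s_het, negative
                sh = 2.0 * scaled / dfe_two_n;
                if (sh < -1.0) sh = -1.0; // lethal bound for the homozygote
                c = DEL1 + cc;
            }
        }
        ++total_introduced;
        ++introduced_by_class[c];
        if (c == NEUTRAL && !track_neutral) {
            ++total_lost; // untracked neutrals are accounted as lost immediately
            return std::make_pair(-1, 0);
        }
        occupied[p] = 1;
        int id = reg.alloc(p, sh, c, gen);
        return std::make_pair(id, c != NEUTRAL ? 1 : 0);
    };

    auto purge = [&](int gen, int two_n) {
        cnt.assign(reg.size(), 0);
        for (const Hap& h : pop) {
            for (int id : h.neu) ++cnt[id];
            for (int id : h.sel) ++cnt[id];
        }
        bool any_fixed = false;
        remove_flag.assign(reg.size(), 0);
        for (size_t id = 0; id < reg.size(); ++id) {
            if (!reg.live[id]) continue;
            if (cnt[id] == 0) {
                ++total_lost;
                occupied[reg.pos[id]] = 0;
                reg.release(static_cast<int>(id));
            } else if (cnt[id] == two_n) {
                ++total_fixed;
                fix_cls.push_back(reg.cls[id]);
                fix_s.push_back(reg.s[id]);
                fix_origin.push_back(reg.origin[id]);
                fix_gen.push_back(gen);
                occupied[reg.pos[id]] = 0;
                remove_flag[id] = 1;
                any_fixed = true;
                reg.release(static_cast<int>(id));
            }
        }
        if (any_fixed) {
            for (Hap& h : pop) {
                h.neu.erase(std::remove_if(h.neu.begin(), h.neu.end(),
                    [&](int id) { return remove_flag[id]; }), h.neu.end());
                h.sel.erase(std::remove_if(h.sel.begin(), h.sel.end(),
                    [&](int id) { return remove_flag[id]; }), h.sel.end());
            }
        }
    };

    for (int g = 1; g <= total_gens; ++g) {
        if (g % 256 == 0) Rcpp::checkUserInterrupt();
        // population size for the generation being created
        while (epoch_ptr + 1 < epoch_sizes.size() && g >= epoch_starts[epoch_ptr + 1])
            ++epoch_ptr;
        int N_next = epoch_sizes[epoch_ptr];

        // parental fitnesses (uniform when nothing is selected)
        bool weighted = false;
        if (selection_input) {
            cumw.resize(N);
            double acc = 0.0;
            bool any_sel = false;
            for (int i = 0; i < N; ++i) {
                double w = diploid_fitness(pop[2 * i], pop[2 * i + 1], reg, hdom);
                if (!pop[2 * i].sel.empty() || !pop[2 * i + 1].sel.empty()) any_sel = true;
                acc += w;
                cumw[i] = acc;
            }
            if (any_sel) {
                if (acc <= 0.0) stop("entire population inviable (all fitness zero)");
                weighted = true;
            }
        }

        int n_skew = (psi > 0.0) ? static_cast<int>(std::floor(psi * N_next)) : 0;
        int focal = -1;
        if (n_skew > 0) {
            focal = (psi_fitness_weighted && weighted) ? weighted_pick(cumw, rng)
                                                       : rng.rint(N);
        }

        nxt.resize(2 * N_next);
        for (int j = 0; j < N_next; ++j) {
            int p1, p2;
            if (j < n_skew) {
                p1 = focal;
                p2 = weighted ? weighted_pick(cumw, rng) : rng.rint(N);
            } else {
                p1 = weighted ? weighted_pick(cumw, rng) : rng.rint(N);
                p2 = weighted ? weighted_pick(cumw, rng) : rng.rint(N);
            }
            for (int side = 0; side < 2; ++side) {
                int par = (side == 0) ? p1 : p2;
                int nx = rng.rpois(rec_map.total);
                breaks.clear();
                for (int k = 0; k < nx; ++k) breaks.push_back(rec_map.draw_break(rng));
                std::sort(breaks.begin(), breaks.end());
                Hap& out = nxt[2 * j + side];
                make_gamete(pop[2 * par], pop[2 * par + 1], reg, breaks,
                            rng.rint(2), out, L);
                // new mutations
                int m = rng.rpois(mu_map.total);
                if (m > 0) {
                    new_neu.clear(); new_sel.clear();
                    for (int k = 0; k < m; ++k) {
                        std::pair<int, int> mu = draw_mutation(g);
                        if (mu.first < 0) continue;
                        if (mu.second) new_sel.push_back(mu.first);
                        else new_neu.push_back(mu.first);
                    }
                    for (int id : new_neu)
                        out.neu.insert(std::lower_bound(out.neu.begin(), out.neu.end(),
                            reg.pos[id], [&](int id2, int val) { return reg.pos[id2] < val; }), id);
                    for (int id : new_sel)
                        out.sel.insert(std::lower_bound(out.sel.begin(), out.sel.end(),
                            reg.pos[id], [&](int id2, int val) { return reg.pos[id2] < val; }), id);
                }
            }
        }
        std::swap(pop, nxt);
        N = N_next;
        if (g % purge_interval == 0 || g == total_gens) purge(g, 2 * N);
    }

    // final segregating count in the population
    long long segregating = 0;
    for (size_t id = 0; id < reg.size(); ++id)
        if (reg.live[id]) ++segregating;

    // sample n haplotypes without replacement
    int two_n = 2 * N;
    if (n_sample > two_n) stop("sample size exceeds 2N at sampling time");
    std::vector<int> idx(two_n);
    for (int i = 0; i < two_n; ++i) idx[i] = i;
    for (int i = 0; i < n_sample; ++i) {
        int j = i + rng.rint(two_n - i);
        std::swap(idx[i], idx[j]);
    }

    cnt.assign(reg.size(), 0);
    for (int i = 0; i < n_sample; ++i) {
        const Hap& h = pop[idx[i]];
        for (int id : h.neu) ++cnt[id];
        for (int id : h.sel) ++cnt[id];
    }
    std::vector<int> site_ids;
    for (size_t id = 0; id < reg.size(); ++id)
        if (reg.live[id] && cnt[id] >= 1 && cnt[id] <= n_sample - 1)
            site_ids.push_back(static_cast<int>(id));
    std::sort(site_ids.begin(), site_ids.end(),
              [&](int a, int b) { return reg.pos[a] < reg.pos[b]; });

    int S = static_cast<int>(site_ids.size());
    std::vector<int> col_of(reg.size(), -1);
    for (int c = 0; c < S; ++c) col_of[site_ids[c]] = c;

    IntegerMatrix G(n_sample, S);
    for (int i = 0; i < n_sample; ++i) {
        const Hap& h = pop[idx[i]];
        for (int id : h.neu) if (col_of[id] >= 0) G(i, col_of[id]) = 1;
        for (int id : h.sel) if (col_of[id] >= 0) G(i, col_of[id]) = 1;
    }
    IntegerVector positions(S), site_class(S);
    for (int c = 0; c < S; ++c) {
        positions[c] = reg.pos[site_ids[c]];
        site_class[c] = reg.cls[site_ids[c]];
    }

    return List::create(
        _["positions"] = positions,
        _["genotypes"] = G,
        _["site_class"] = site_class,
        _["fix_class"] = IntegerVector(fix_cls.begin(), fix_cls.end()),
        _["fix_s"] = NumericVector(fix_s.begin(), fix_s.end()),
        _["fix_origin"] = IntegerVector(fix_origin.begin(), fix_origin.end()),
        _["fix_gen"] = IntegerVector(fix_gen.begin(), fix_gen.end()),
        _["total_introduced"] = static_cast<double>(total_introduced),
        _["introduced_by_class"] = NumericVector(introduced_by_class,
                                                 introduced_by_class + 6),
        _["total_fixed"] = static_cast<double>(total_fixed),
        _["total_lost"] = static_cast<double>(total_lost),
        _["segregating"] = static_cast<double>(segregating),
        _["final_N"] = N);
}

// One round of offspring-parent assignment under progeny skew: the first
// floor(psi*N) offspring share a single focal parent.  Exposed for direct
// testing of the skew contract.
// [[Rcpp::export]]
List offspring_parents_cpp(int n_offspring, double psi, NumericVector fitness,
                           bool psi_fitness_weighted, double seed) {
    Xoshiro rng(static_cast<uint64_t>(seed));
    int N = fitness.size();
    bool weighted = false;
    std::vector<double> cumw(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) { acc += fitness[i]; cumw[i] = acc; }
    for (int i = 0; i < N; ++i)
        if (fitness[i] != fitness[0]) { weighted = true; break; }

    int n_skew = (psi > 0.0) ? static_cast<int>(std::floor(psi * n_offspring)) : 0;
    int focal = -1;
    if (n_skew > 0)
        focal = (psi_fitness_weighted && weighted) ? weighted_pick(cumw, rng)
                                                   : rng.rint(N);
    IntegerVector p1(n_offspring), p2(n_offspring);
    for (int j = 0; j < n_offspring; ++j) {
        if (j < n_skew) {
            p1[j] = focal;
            p2[j] = weighted ? weighted_pick(cumw, rng) : rng.rint(N);
        } else {
            p1[j] = weighted ? weighted_pick(cumw, rng) : rng.rint(N);
            p2[j] = weighted ? weighted_pick(cumw, rng) : rng.rint(N);
        }
    }
    return List::create(_["parent1"] = p1 + 1, _["parent2"] = p2 + 1,
                        _["focal"] = focal + 1, _["n_skew"] = n_skew);
}
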