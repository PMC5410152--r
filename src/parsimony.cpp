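#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shared tree bookkeeping for the parsimony kernels.  Trees arrive as an
// ape-style edge matrix (parent, child), tips numbered 1..ntip, internal
// nodes above that, in any row order; the root is the node that never
// appears as a child.  Polytomies (including a basal trifurcation from an
// unrooted tree) are handled.
struct TreeIndex {
    int root;
    int nmax;                              // largest node id
    std::vector<std::vector<int> > kids;   // children per node
    std::vector<int> post;                 // internal nodes, postorder
};

static TreeIndex index_tree(const IntegerMatrix& edge, int ntip) {
    TreeIndex ti;
    int ne = edge.nrow();
    ti.nmax = 0;
    for (int i = 0; i < ne; i++)
        ti.nmax = std::max(ti.nmax, std::max(edge(i, 0), edge(i, 1)));
    ti.nmax = std::max(ti.nmax, ntip);
    ti.kids.assign(ti.nmax + 1, std::vector<int>());
    std::vector<char> ischild(ti.nmax + 1, 0);
    for (int i = 0; i < ne; i++) {
        ti.kids[edge(i, 0)].push_back(edge(i, 1));
        ischild[edge(i, 1)] = 1;
    }
    ti.root = -1;
    for (int v = ntip + 1; v <= ti.nmax; v++)
        if (!ischild[v] && !ti.kids[v].empty()) { ti.root = v; break; }
    if (ti.root < 0) stop("edge matrix has no root");
    // iterative preorder, reversed -> postorder over internal nodes
    std::vector<int> stack, order;
    stack.push_back(ti.root);
    while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        order.push_back(v);
        const std::vector<int>& k = ti.kids[v];
        for (size_t j = 0; j < k.size(); j++)
            if (k[j] > ntip) stack.push_back(k[j]);
    }
    ti.post.assign(order.rbegin(), order.rend());
    return ti;
}

static void char_lengths_one(const TreeIndex& ti, int ntip,
                             const IntegerMatrix& tipmask, int nstates,
                             bool ordered, double* out) {
    int nchar = tipmask.ncol();
    if (!ordered) {
        // Fitch over state bitmasks, generalised to polytomies by
        // sequential pairwise combination of child sets.
        std::vector<int> mask(ti.nmax + 1, 0);
        for (int ch = 0; ch < nchar; ch++) {
            int len = 0;
            for (int t = 1; t <= ntip; t++) mask[t] = tipmask(t - 1, ch);
            for (size_t p = 0; p < ti.post.size(); p++) {
                int v = ti.post[p];
                const std::vector<int>& k = ti.kids[v];
                int m = mask[k[0]];
                for (size_t j = 1; j < k.size(); j++) {
                    int inter = m & mask[k[j]];
                    if (inter) m = inter;
                    else { m |= mask[k[j]]; len++; }
                }
                mask[v] = m;
            }
            out[ch] = len;
        }
    } else {
        // Sankoff with linear-scale cost |a-b|; the child min-plus step is
        // a two-sweep distance transform, so each node costs O(k).
        const double BIG = 1e9;
        std::vector<std::vector<double> > dp(
            ti.nmax + 1, std::vector<double>(nstates, 0.0));
        std::vector<double> tmp(nstates);
        for (int ch = 0; ch < nchar; ch++) {
            for (int t = 1; t <= ntip; t++) {
                int m = tipmask(t - 1, ch);
                for (int s = 0; s < nstates; s++)
                    dp[t][s] = ((m >> s) & 1) ? 0.0 : BIG;
            }
            for (size_t p = 0; p < ti.post.size(); p++) {
                int v = ti.post[p];
                std::vector<double>& d = dp[v];
                std::fill(d.begin(), d.end(), 0.0);
                const std::vector<int>& k = ti.kids[v];
                for (size_t j = 0; j < k.size(); j++) {
                    std::vector<double>& dc = dp[k[j]];
                    tmp[0] = dc[0];
                    for (int s = 1; s < nstates; s++)
                        tmp[s] = std::min(dc[s], tmp[s - 1] + 1.0);
                    for (int s = nstates - 2; s >= 0; s--)
                        tmp[s] = std::min(tmp[s], tmp[s + 1] + 1.0);
                    for (int s = 0; s < nstates; s++) d[s] += tmp[s];
                }
            }
            double best = BIG;
            for (int s = 0; s < nstates; s++)
                best = std::min(best, dp[ti.root][s]);
            out[ch] = best;
        }
    }
}

//' @noRd
// [[Rcpp::export(name = ".pars_char_lengths_cpp")]]
NumericVector pars_char_lengths_cpp(IntegerMatrix edge, int ntip,
                                    IntegerMatrix tipmask, int nstates,
                                    bool ordered) {
    TreeIndex ti = index_tree(edge, ntip);
    NumericVector out(tipmask.ncol());
    char_lengths_one(ti, ntip, tipmask, nstates, ordered, REAL(out));
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".pars_total_multi_cpp")]]
NumericVector pars_total_multi_cpp(List edges, int ntip,
                                   IntegerMatrix tipmask, int nstates,
                                   bool ordered) {
    int nt = edges.size(), nchar = tipmask.ncol();
    NumericVector out(nt);
    std::vector<double> buf(nchar);
    for (int i = 0; i < nt; i++) {
        IntegerMatrix e = edges[i];
        TreeIndex ti = index_tree(e, ntip);
        char_lengths_one(ti, ntip, tipmask, nstates, ordered, &buf[0]);
        double s = 0.0;
        for (int ch = 0; ch < nchar; ch++) s += buf[ch];
        out[i] = s;
    }
    return out;
}
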