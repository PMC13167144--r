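#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Linear sum assignment (Hungarian / Jonker-Volgenant shortest augmenting
// path, O(n^3)) on a dense square cost matrix stored row-major.
// Returns for every row the assigned column (0-based); total cost in *costOut.
static std::vector<int> lsap_core(const std::vector<double>& a, int n,
                                  double* costOut) {
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
    std::vector<int> p(n + 1, 0), way(n + 1, 0);
    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::vector<double> minv(n + 1, INF);
        std::vector<char> used(n + 1, 0);
        do {
            used[j0] = 1;
            int i0 = p[j0], j1 = -1;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                double cur = a[(size_t)(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
    }
    std::vector<int> rowToCol(n, -1);
    double c = 0.0;
    for (int j = 1; j <= n; ++j) {
        if (p[j] > 0) {
            rowToCol[p[j] - 1] = j - 1;
            c += a[(size_t)(p[j] - 1) * n + (j - 1)];
        }
    }
    if (costOut) *costOut = c;
    return rowToCol;
}

static double lsap_submatrix(const NumericMatrix& C,
                             const std::vector<int>& rows,
                             const std::vector<int>& cols) {
    int m = (int)rows.size();
    if (m == 0) return 0.0;
    std::vector<double> a((size_t)m * m);
    for (int i = 0; i < m; ++i)
        for (int j = 0; j < m; ++j)
            a[(size_t)i * m + j] = C(rows[i], cols[j]);
    double c = 0.0;
    lsap_core(a, m, &c);
    return c;
}

// [[Rcpp::export]]
List cpp_lsap(NumericMatrix C) {
    int n = C.nrow();
    if (C.ncol() != n) stop("cost matrix must be square");
    std::vector<double> a((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            a[(size_t)i * n + j] = C(i, j);
    double cost = 0.0;
    std::vector<int> as = lsap_core(a, n, &cost);
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = as[i];
    return List::create(_["assignment"] = out, _["cost"] = cost);
}

// Lexicographically smallest cost-optimal assignment: fix rows in order,
// choosing the smallest column that still admits an optimal completion
// (checked by re-solving the reduced problem).
// [[Rcpp::export]]
List cpp_lsap_lex(NumericMatrix C, double tol) {
    int n = C.nrow();
    if (C.ncol() != n) stop("cost matrix must be square");
    std::vector<double> a((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            a[(size_t)i * n + j] = C(i, j);
    double opt = 0.0;
    lsap_core(a, n, &opt);

    std::vector<char> colUsed(n, 0);
    IntegerVector assign(n, -1);
    double fixedCost = 0.0;
    for (int r = 0; r < n; ++r) {
        std::vector<int> freeRows;
        for (int i = r + 1; i < n; ++i) freeRows.push_back(i);
        bool placed = false;
        for (int d = 0; d < n && !placed; ++d) {
            if (colUsed[d]) continue;
            std::vector<int> freeCols;
            for (int j = 0; j < n; ++j)
                if (!colUsed[j] && j != d) freeCols.push_back(j);
            double sub = lsap_submatrix(C, freeRows, freeCols);
            if (fixedCost + C(r, d) + sub <= opt + tol) {
                assign[r] = d;
                colUsed[d] = 1;
                fixedCost += C(r, d);
                placed = true;
            }
        }
        if (!placed) stop("internal error: no feasible column in lex refinement");
    }
    return List::create(_["assignment"] = assign, _["cost"] = opt);
}

// ---- exact surjective cross-K alignment ------------------------------------
//
// Cost of assigning source clusters (k2 of them) onto target clusters (k1)
// decomposes over targets d:
//   f_d(S) = qaa[d] - 2 * sum_{c in S} B(c,d) + sum_{c,c' in S} G(c,c')
// with qaa[d] = ||Qa[,d]||^2, B(c,d) = <Qb[,c], Qa[,d]>, G the Gram matrix of
// source columns.  Every surjection is a set partition of the k2 source
// clusters into k1 non-empty blocks plus a bijection blocks -> targets, so we
// enumerate restricted-growth strings with exactly k1 blocks and solve an LSAP
// per partition.

struct SurjSearch {
    int k1, k2;
    const NumericVector& qaa;
    const NumericMatrix& B;
    const NumericMatrix& G;
    double tol;
    std::vector<int> block;     // block id per source cluster
    double bestCost;
    std::vector<int> bestAssign;  // target per source cluster
    bool haveBest;

    SurjSearch(int k1_, int k2_, const NumericVector& qaa_,
               const NumericMatrix& B_, const NumericMatrix& G_, double tol_)
        : k1(k1_), k2(k2_), qaa(qaa_), B(B_), G(G_), tol(tol_),
          block(k2_, -1),
          bestCost(std::numeric_limits<double>::infinity()),
          bestAssign(k2_, -1), haveBest(false) {}

    // assignment of blocks to targets for the current partition (lex-optimal)
    void evalPartition() {
        // block cost matrix M[b][d]
        std::vector<std::vector<int>> members(k1);
        for (int c = 0; c < k2; ++c) members[block[c]].push_back(c);
        NumericMatrix M(k1, k1);
        for (int b = 0; b < k1; ++b) {
            double g = 0.0;
            const std::vector<int>& mb = members[b];
            for (size_t x = 0; x < mb.size(); ++x)
                for (size_t y = 0; y < mb.size(); ++y)
                    g += G(mb[x], mb[y]);
            for (int d = 0; d < k1; ++d) {
                double s = 0.0;
                for (size_t x = 0; x < mb.size(); ++x) s += B(mb[x], d);
                M(b, d) = qaa[d] - 2.0 * s + g;
            }
        }
        List plain = cpp_lsap(M);
        double cost = as<double>(plain["cost"]);
        if (haveBest && cost > bestCost + tol) return;

        // candidate assignment vector (lex-optimal within this partition)
        List lex = cpp_lsap_lex(M, tol);
        IntegerVector bt = lex["assignment"];
        std::vector<int> cand(k2);
        for (int c = 0; c < k2; ++c) cand[c] = bt[block[c]];

        if (!haveBest || cost < bestCost - tol) {
            bestCost = cost;
            bestAssign = cand;
            haveBest = true;
        } else {
            // cost tie: keep lexicographically smaller assignment vector
            for (int c = 0; c < k2; ++c) {
                if (cand[c] < bestAssign[c]) { bestAssign = cand; break; }
                if (cand[c] > bestAssign[c]) break;
            }
            if (cost < bestCost) bestCost = cost;
        }
    }

    void recurse(int c, int used) {
        if (c == k2) {
            if (used == k1) evalPartition();
            return;
        }
        // prune: remaining items must be able to open the missing blocks
        if (used + (k2 - c) < k1) return;
        int maxNew = (used < k1) ? used + 1 : used;
        for (int b = 0; b < maxNew; ++b) {
            block[c] = b;
            recurse(c + 1, b == used ? used + 1 : used);
        }
        block[c] = -1;
    }
};

// [[Rcpp::export]]
List cpp_surjection_align(NumericVector qaa, NumericMatrix B, NumericMatrix G,
                          double tol) {
    int k1 = qaa.size();
    int k2 = B.nrow();
    if (B.ncol() != k1) stop("B must be k2 x k1");
    if (G.nrow() != k2 || G.ncol() != k2) stop("G must be k2 x k2");
    if (k1 >= k2) stop("surjective alignment requires k1 < k2");
    SurjSearch s(k1, k2, qaa, B, G, tol);
    s.recurse(0, 0);
    if (!s.haveBest) stop("no surjection found (internal error)");
    IntegerVector out(k2);
    for (int c = 0; c < k2; ++c) out[c] = s.bestAssign[c];
    double cost = s.bestCost;
    if (cost < 0 && cost > -1e-9) cost = 0.0;  // Gram round-off
    return List::create(_["assignment"] = out, _["cost"] = cost);
}
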