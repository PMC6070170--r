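#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted Nussinov-style minimum-energy folding.
//
// codes:  sequence encoded 0=A, 1=C, 2=G, 3=U, 4=N (1-based R vector)
// W:      5x5 pairing-energy matrix, kcal/mol; +Inf marks an illegal pair
// min_loop: minimum number of unpaired bases in a hairpin loop
//
// Recursion over intervals [i,j]:
//   E[i][j] = min( pairable(i,j) ? W(i,j) + E[i+1][j-1] : +Inf,
//                  min_k E[i][k] + E[k+1][j] )
// with E = 0 for intervals too short to hold a pair.  The split case
// covers unpaired terminal bases because E of a single base is 0.
//
// Traceback is fully deterministic: pairing (i,j) is preferred whenever
// it attains the optimum; otherwise the leftmost optimal split is taken.
// This makes the dot-bracket string bit-stable across runs.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nussinov_fold(IntegerVector codes, NumericMatrix W, int min_loop) {
    const int n = codes.size();
    std::string db(n, '.');
    if (n == 0)
        return List::create(_["dotbracket"] = db, _["energy"] = 0.0);

    std::vector<double> E((size_t)n * n, 0.0);
    auto at = [&](int i, int j) -> double& { return E[(size_t)i * n + j]; };
    auto w = [&](int i, int j) -> double {
        return W(codes[i], codes[j]);
    };

    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            double best = INF;
            if (j - i - 1 >= min_loop && w(i, j) < INF)
                best = w(i, j) + at(i + 1, j - 1);
            for (int k = i; k < j; ++k) {
                double v = at(i, k) + at(k + 1, j);
                if (v < best) best = v;
            }
            if (best > 0.0) best = 0.0;  // never worse than all-unpaired
            at(i, j) = best;
        }
    }

    // iterative traceback with an explicit stack of intervals
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i + 1 < min_loop + 2) continue;
        double e = at(i, j);
        if (e == 0.0) continue;  // all unpaired on this interval
        if (j - i - 1 >= min_loop && w(i, j) < INF &&
            e == w(i, j) + at(i + 1, j - 1)) {
            db[i] = '(';
            db[j] = ')';
            stack.push_back(std::make_pair(i + 1, j - 1));
            continue;
        }
        for (int k = i; k < j; ++k) {
            if (e == at(i, k) + at(k + 1, j)) {
                stack.push_back(std::make_pair(k + 1, j));
                stack.push_back(std::make_pair(i, k));
                break;
            }
        }
    }

    return List::create(_["dotbracket"] = db, _["energy"] = at(0, n - 1));
}
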