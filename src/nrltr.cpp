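#include <Rcpp.h>
using namespace Rcpp;

// Best gapless suffix(a)-prefix(b) overlap: the longest overlap whose
// mismatch count stays within (1 - min_identity) * length. Returns
// {length, mismatches} or {0, 0} when none reaches min_ov.
static inline void best_overlap(const std::string& a, const std::string& b,
                                int min_ov, double min_identity,
                                int& best_len, int& best_mm) {
    best_len = 0; best_mm = 0;
    const int la = a.size(), lb = b.size();
    const int max_ov = std::min(la, lb);
    for (int ov = max_ov; ov >= min_ov; --ov) {
        const int budget = (int)std::floor((1.0 - min_identity) * ov);
        int mm = 0;
        const char* pa = a.data() + (la - ov);
        const char* pb = b.data();
        bool ok = true;
        for (int k = 0; k < ov; ++k) {
            if (pa[k] != pb[k]) {
                if (++mm > budget) { ok = false; break; }
            }
        }
        if (ok) { best_len = ov; best_mm = mm; return; }
    }
}

// All candidate overlaps among a set of sequences (forward) with their
// reverse complements, for greedy overlap-layout-consensus. For each
// unordered pair i<j and orientation o (0: j forward, 1: j reverse
// complement) both merge directions are scanned. Rows of the returned
// matrix: i, j, orient, dir (0: i then j, 1: j then i), len, mismatches
// (i, j are 1-based).
// [[Rcpp::export]]
IntegerMatrix C_overlap_pairs(CharacterVector seqs, CharacterVector rcs,
                              int min_ov, double min_identity) {
    const int n = seqs.size();
    std::vector<int> rows;
    for (int i = 0; i < n; ++i) {
        const std::string si = as<std::string>(seqs[i]);
        for (int j = i + 1; j < n; ++j) {
            for (int o = 0; o < 2; ++o) {
                const std::string sj =
                    as<std::string>(o == 0 ? seqs[j] : rcs[j]);
                int len, mm;
                best_overlap(si, sj, min_ov, min_identity, len, mm);
                if (len > 0) {
                    int r[6] = {i + 1, j + 1, o, 0, len, mm};
                    rows.insert(rows.end(), r, r + 6);
                }
                best_overlap(sj, si, min_ov, min_identity, len, mm);
                if (len > 0) {
                    int r[6] = {i + 1, j + 1, o, 1, len, mm};
                    rows.insert(rows.end(), r, r + 6);
                }
            }
        }
    }
    const int k = rows.size() / 6;
    IntegerMatrix out(k, 6);
    for (int r = 0; r < k; ++r)
        for (int c = 0; c < 6; ++c) out(r, c) = rows[6 * r + c];
    colnames(out) = CharacterVector::create("i", "j", "orient", "dir",
                                            "len", "mism");
    return out;
}

// Candidate overlaps of one new sequence against each member of a set.
// Rows: j, orient, dir (0: new then j, 1: j then new), len, mismatches.
// [[Rcpp::export]]
IntegerMatrix C_overlap_one(std::string a, std::string arc,
                            CharacterVector seqs, CharacterVector rcs,
                            int min_ov, double min_identity) {
    const int n = seqs.size();
    std::vector<int> rows;
    for (int j = 0; j < n; ++j) {
        for (int o = 0; o < 2; ++o) {
            const std::string sj = as<std::string>(o == 0 ? seqs[j] : rcs[j]);
            int len, mm;
            best_overlap(a, sj, min_ov, min_identity, len, mm);
            if (len > 0) {
                int r[5] = {j + 1, o, 0, len, mm};
                rows.insert(rows.end(), r, r + 5);
            }
            best_overlap(sj, a, min_ov, min_identity, len, mm);
            if (len > 0) {
                int r[5] = {j + 1, o, 1, len, mm};
                rows.insert(rows.end(), r, r + 5);
            }
        }
    }
    const int k = rows.size() / 5;
    IntegerMatrix out(k, 5);
    for (int r = 0; r < k; ++r)
        for (int c = 0; c < 5; ++c) out(r, c) = rows[5 * r + c];
    colnames(out) = CharacterVector::create("j", "orient", "dir", "len",
                                            "mism");
    return out;
}

// Global profile-profile alignment with affine gaps for progressive MSA.
// A and B are 5 x m / 5 x n frequency matrices (rows A, C, G, T, gap).
// Column score: sum_{x,y in ACGT} fA(x) fB(y) * (x==y ? match : mismatch);
// profile gap frequencies contribute zero. A gap of length k costs
// gap_open + k * gap_ext. Returns the op sequence of the optimal path
// (0 = align columns, 1 = column from A vs gap, 2 = column from B vs gap),
// with deterministic tie-breaking (align > A-gap > B-gap).
// [[Rcpp::export]]
IntegerVector C_profile_align(NumericMatrix A, NumericMatrix B,
                              double match, double mismatch,
                              double gap_open, double gap_ext) {
    const int m = A.ncol(), n = B.ncol();
    const double NEG = -1e30;
    // substitution score between column i of A and column j of B
    std::vector<double> sub((size_t)m * n);
    for (int i = 0; i < m; ++i) {
        double fa[4] = {A(0, i), A(1, i), A(2, i), A(3, i)};
        for (int j = 0; j < n; ++j) {
            double s = 0.0;
            for (int x = 0; x < 4; ++x) {
                if (fa[x] == 0.0) continue;
                for (int y = 0; y < 4; ++y) {
                    double fb = B(y, j);
                    if (fb == 0.0) continue;
                    s += fa[x] * fb * (x == y ? match : mismatch);
                }
            }
            sub[(size_t)i * n + j] = s;
        }
    }
    const size_t sz = (size_t)(m + 1) * (n + 1);
    std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
    // X: last op consumes a column of A (gap in B); Y: consumes B column.
    auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= m; ++i)
        X[at(i, 0)] = -(gap_open + gap_ext * i);
    for (int j = 1; j <= n; ++j)
        Y[at(0, j)] = -(gap_open + gap_ext * j);
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            const double s = sub[(size_t)(i - 1) * n + (j - 1)];
            double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)],
                   dy = Y[at(i - 1, j - 1)];
            M[at(i, j)] = std::max(dm, std::max(dx, dy)) + s;
            double xo = M[at(i - 1, j)] - gap_open - gap_ext;
            double xe = X[at(i - 1, j)] - gap_ext;
            double xy = Y[at(i - 1, j)] - gap_open - gap_ext;
            X[at(i, j)] = std::max(xo, std::max(xe, xy));
            double yo = M[at(i, j - 1)] - gap_open - gap_ext;
            double ye = Y[at(i, j - 1)] - gap_ext;
            double yx = X[at(i, j - 1)] - gap_open - gap_ext;
            Y[at(i, j)] = std::max(yo, std::max(ye, yx));
        }
    }
    // traceback
    std::vector<int> ops;
    int i = m, j = n;
    double vm = M[at(i, j)], vx = X[at(i, j)], vy = Y[at(i, j)];
    int state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
    while (i > 0 || j > 0) {
        if (state == 0) {
            // arrived by aligning columns i-1, j-1
            if (i == 0 || j == 0) { state = (i > 0) ? 1 : 2; continue; }
            ops.push_back(0);
            const double tgt = M[at(i, j)] -
                sub[(size_t)(i - 1) * n + (j - 1)];
            --i; --j;
            double pm = M[at(i, j)], px = X[at(i, j)], py = Y[at(i, j)];
            state = (pm >= tgt - 1e-9) ? 0 : ((px >= tgt - 1e-9) ? 1 : 2);
        } else if (state == 1) {
            if (i == 0) { state = 2; continue; }
            ops.push_back(1);
            const double v = X[at(i, j)];
            --i;
            if (M[at(i, j)] - gap_open - gap_ext >= v - 1e-9) state = 0;
            else if (X[at(i, j)] - gap_ext >= v - 1e-9) state = 1;
            else state = 2;
        } else {
            if (j == 0) { state = 1; continue; }
            ops.push_back(2);
            const double v = Y[at(i, j)];
            --j;
            if (M[at(i, j)] - gap_open - gap_ext >= v - 1e-9) state = 0;
            else if (Y[at(i, j)] - gap_ext >= v - 1e-9) state = 2;
            else state = 1;
        }
    }
    std::reverse(ops.begin(), ops.end());
    return wrap(ops);
}

// Tandem-array scan at a fixed period. For every phase s (0-based), a seed
// block extends while the next u-mer matches the running per-column
// majority consensus with at most max_mism mismatches. Returns rows
// (start_1based, copies, total_mismatches) for arrays with >= min_copies.
// [[Rcpp::export]]
IntegerMatrix C_tandem_scan(IntegerVector b, int u, int min_copies,
                            int max_mism) {
    const int L = b.size();
    std::vector<int> rows;
    std::vector<int> counts(4 * u);
    for (int s = 0; s + 2 * u <= L; ++s) {
        std::fill(counts.begin(), counts.end(), 0);
        for (int k = 0; k < u; ++k) {
            int base = b[s + k];
            if (base > 0) counts[4 * k + (base - 1)]++;
        }
        int copies = 1, mism_total = 0;
        for (;;) {
            int ns = s + copies * u;
            if (ns + u > L) break;
            int mism = 0;
            for (int k = 0; k < u; ++k) {
                int base = b[ns + k];
                // consensus: max count, ties to the lowest base index
                int ci = 0, cv = counts[4 * k];
                for (int x = 1; x < 4; ++x)
                    if (counts[4 * k + x] > cv) { cv = counts[4 * k + x]; ci = x; }
                if (base <= 0 || (base - 1) != ci) ++mism;
            }
            if (mism > max_mism) break;
            for (int k = 0; k < u; ++k) {
                int base = b[ns + k];
                if (base > 0) counts[4 * k + (base - 1)]++;
            }
            ++copies;
            mism_total += mism;
        }
        if (copies >= min_copies) {
            int r[3] = {s + 1, copies, mism_total};
            rows.insert(rows.end(), r, r + 3);
        }
    }
    const int n = rows.size() / 3;
    IntegerMatrix out(n, 3);
    for (int r = 0; r < n; ++r)
        for (int c = 0; c < 3; ++c) out(r, c) = rows[3 * r + c];
    colnames(out) = CharacterVector::create("start", "copies", "mism");
    return out;
}
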