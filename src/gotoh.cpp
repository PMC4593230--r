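#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP) with an optional band
// around the main diagonal.
//
// Gap cost convention: a gap run of length L costs gap_open + L * gap_extend.
// Terminal gaps are penalized (true global alignment).
//
// States: M = a[i] aligned to b[j]; X = gap in b (a consumed); Y = gap in a
// (b consumed). Co-optimal choices resolve with fixed priority M > X > Y
// (diagonal > up > left) at every cell, so the traceback is reproducible
// across platforms and input orders.
//
// 'N' scores 0 against anything: neither rewarded nor penalized, matching its
// exclusion from the distance numerator and denominator downstream.

static const double NEG_INF = -1e30;

static inline double subscore(char x, char y, double match, double mismatch) {
    if (x == 'N' || y == 'N') return 0.0;
    return (x == y) ? match : mismatch;
}

// pick predecessor among (m, x, y) with priority M > X > Y; returns state code
static inline int argbest3(double m, double x, double y, double *best) {
    if (m >= x && m >= y) { *best = m; return 0; }
    if (x >= y)           { *best = x; return 1; }
    *best = y; return 2;
}

// reusable DP workspace so the all-versus-all loop does not reallocate
struct GotohWork {
    std::vector<double> Mp, Xp, Yp, Mc, Xc, Yc;
    std::vector<unsigned char> ptr; // 2 bits per state per cell
};

// Fill the DP and return the final score; leaves the traceback pointer
// matrix in w.ptr (band geometry in *klo_out / *W_out) and the final state
// in *state_out.
static double gotoh_core(const std::string &a, const std::string &b,
                         double match, double mismatch,
                         double gap_open, double gap_extend, int band,
                         GotohWork &w, int *klo_out, int *W_out,
                         int *state_out) {
    const int la = (int) a.size();
    const int lb = (int) b.size();

    int klo, khi; // allowed diagonal offsets k = j - i
    if (band < 0) {
        klo = -la;
        khi = lb;
    } else {
        klo = std::min(0, lb - la) - band;
        khi = std::max(0, lb - la) + band;
        if (klo < -la) klo = -la;
        if (khi > lb)  khi = lb;
    }
    const int W = khi - klo + 1;

    w.Mp.assign(W, NEG_INF); w.Xp.assign(W, NEG_INF); w.Yp.assign(W, NEG_INF);
    w.Mc.assign(W, NEG_INF); w.Xc.assign(W, NEG_INF); w.Yc.assign(W, NEG_INF);
    w.ptr.assign((size_t)(la + 1) * W, 0xFF);

    double *Mp = w.Mp.data(), *Xp = w.Xp.data(), *Yp = w.Yp.data();
    double *Mc = w.Mc.data(), *Xc = w.Xc.data(), *Yc = w.Yc.data();

    // row 0: only Y moves (gaps in a) along j
    {
        int c0 = 0 - klo; // j = 0
        if (c0 >= 0 && c0 < W) Mp[c0] = 0.0;
        for (int j = std::max(1, klo); j <= std::min(lb, khi); ++j) {
            int c = j - klo;
            Yp[c] = -(gap_open + j * gap_extend);
            unsigned char pred = (j == 1) ? 0 : 2; // from M at origin else Y
            w.ptr[(size_t)0 * W + c] =
                (unsigned char)(0xC0 | (pred << 4) | 0x0F);
        }
    }

    for (int i = 1; i <= la; ++i) {
        std::fill(w.Mc.begin(), w.Mc.end(), NEG_INF);
        std::fill(w.Xc.begin(), w.Xc.end(), NEG_INF);
        std::fill(w.Yc.begin(), w.Yc.end(), NEG_INF);
        unsigned char *prow = &w.ptr[(size_t)i * W];

        const int jlo = std::max(0, i + klo);
        const int jhi = std::min(lb, i + khi);
        const char ai = a[i - 1];

        for (int j = jlo; j <= jhi; ++j) {
            const int c = j - i - klo;
            unsigned char cell = 0xFF;

            if (j == 0) {
                // leading gap in b
                Xc[c] = -(gap_open + i * gap_extend);
                unsigned char pred = (i == 1) ? 0 : 1;
                cell = (unsigned char)(0xC0 | 0x30 | (pred << 2) | 0x03);
                prow[c] = cell;
                continue;
            }

            // M: from (i-1, j-1), same column c in previous row
            {
                double best;
                int p = argbest3(Mp[c], Xp[c], Yp[c], &best);
                if (best > NEG_INF / 2) {
                    Mc[c] = best + subscore(ai, b[j - 1], match, mismatch);
                    cell = (unsigned char)((cell & ~0x03) | p);
                }
            }
            // X: from (i-1, j), column c+1 in previous row
            if (c + 1 < W) {
                double best;
                int p = argbest3(Mp[c + 1] - gap_open - gap_extend,
                                 Xp[c + 1] - gap_extend,
                                 Yp[c + 1] - gap_open - gap_extend, &best);
                if (best > NEG_INF / 2) {
                    Xc[c] = best;
                    cell = (unsigned char)((cell & ~0x0C) | (p << 2));
                }
            }
            // Y: from (i, j-1), column c-1 in current row
            if (c - 1 >= 0) {
                double best;
                int p = argbest3(Mc[c - 1] - gap_open - gap_extend,
                                 Xc[c - 1] - gap_open - gap_extend,
                                 Yc[c - 1] - gap_extend, &best);
                if (best > NEG_INF / 2) {
                    Yc[c] = best;
                    cell = (unsigned char)((cell & ~0x30) | (p << 4));
                }
            }
            prow[c] = cell;
        }
        std::swap(w.Mp, w.Mc); std::swap(w.Xp, w.Xc); std::swap(w.Yp, w.Yc);
        Mp = w.Mp.data(); Xp = w.Xp.data(); Yp = w.Yp.data();
        Mc = w.Mc.data(); Xc = w.Xc.data(); Yc = w.Yc.data();
    }

    const int cfin = lb - la - klo;
    double score;
    int state = argbest3(w.Mp[cfin], w.Xp[cfin], w.Yp[cfin], &score);
    if (score <= NEG_INF / 2)
        stop("band too narrow: no valid global alignment path");
    *klo_out = klo; *W_out = W; *state_out = state;
    return score;
}

// column classes produced by the traceback
enum ColOp { OP_MATCH = 0, OP_MISMATCH = 1, OP_NCOL = 2,
             OP_GAP_A = 3, OP_GAP_B = 4 };

// Traceback into a per-column op vector, ordered 5' -> 3'.
static void gotoh_traceback(const std::string &a, const std::string &b,
                            const GotohWork &w, int klo, int W, int state,
                            std::vector<unsigned char> &ops) {
    ops.clear();
    int i = (int) a.size(), j = (int) b.size();
    while (i > 0 || j > 0) {
        const int c = j - i - klo;
        unsigned char cell = w.ptr[(size_t)i * W + c];
        int pred;
        if (state == 0) {
            pred = cell & 0x03;
            char x = a[i - 1], y = b[j - 1];
            ops.push_back(x == 'N' || y == 'N' ? OP_NCOL :
                          (x == y ? OP_MATCH : OP_MISMATCH));
            --i; --j;
        } else if (state == 1) {
            pred = (cell >> 2) & 0x03;
            ops.push_back(OP_GAP_B); // gap in b, base from a
            --i;
        } else {
            pred = (cell >> 4) & 0x03;
            ops.push_back(OP_GAP_A); // gap in a, base from b
            --j;
        }
        if (i == 0 && j == 0) break;
        state = pred;
    }
    std::reverse(ops.begin(), ops.end());
}

// Distance from an op vector: strip terminal gap runs (either row), drop
// internal single-base gap runs when remove_single_indels, count each
// surviving run once in the numerator and (collapsed or full-length) in the
// denominator; N columns excluded. Returns NaN when nothing remains.
static void ops_distance(const std::vector<unsigned char> &ops,
                         bool remove_single_indels, bool collapse_runs,
                         double out[4]) {
    int n = (int) ops.size();
    int start = 0, end = n;
    while (start < n && (ops[start] == OP_GAP_A || ops[start] == OP_GAP_B))
        ++start;
    while (end > start && (ops[end - 1] == OP_GAP_A ||
                           ops[end - 1] == OP_GAP_B))
        --end;
    long mism = 0, matched = 0, runs = 0, run_cols = 0;
    int i = start;
    while (i < end) {
        unsigned char op = ops[i];
        if (op == OP_GAP_A || op == OP_GAP_B) {
            int k = i;
            while (k < end && ops[k] == op) ++k;
            int rl = k - i;
            if (!(rl == 1 && remove_single_indels)) {
                runs += 1;
                run_cols += rl;
            }
            i = k;
        } else {
            if (op == OP_MATCH) ++matched;
            else if (op == OP_MISMATCH) ++mism;
            ++i;
        }
    }
    double denom = (double) matched + mism +
                   (collapse_runs ? (double) runs : (double) run_cols);
    out[0] = (double) mism;
    out[1] = (double) runs;
    out[2] = denom;
    out[3] = (denom > 0) ? (mism + runs) / denom : NA_REAL;
}

// [[Rcpp::export(name = ".gotoh_align_c")]]
List gotoh_align_c(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_extend,
                   int band) {
    if (a.empty() || b.empty())
        stop("sequences must be non-empty");
    GotohWork w;
    int klo, W, state;
    double score = gotoh_core(a, b, match, mismatch, gap_open, gap_extend,
                              band, w, &klo, &W, &state);
    // rebuild the two gapped rows from the traceback
    std::string ra, rb;
    ra.reserve(a.size() + b.size());
    rb.reserve(a.size() + b.size());
    int i = (int) a.size(), j = (int) b.size();
    int st = state;
    while (i > 0 || j > 0) {
        const int c = j - i - klo;
        unsigned char cell = w.ptr[(size_t)i * W + c];
        int pred;
        if (st == 0) {
            pred = cell & 0x03;
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j;
        } else if (st == 1) {
            pred = (cell >> 2) & 0x03;
            ra.push_back(a[i - 1]); rb.push_back('-');
            --i;
        } else {
            pred = (cell >> 4) & 0x03;
            ra.push_back('-'); rb.push_back(b[j - 1]);
            --j;
        }
        if (i == 0 && j == 0) break;
        st = pred;
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["row_a"] = ra, _["row_b"] = rb, _["score"] = score);
}

// Post-processing + genetic distance on one already-aligned pair of rows.
// Mirrors the R-level strip_terminal_gaps / remove_single_base_indels /
// genetic_distance exactly (self-consistency is asserted in the tests).
// Returns c(mismatches, indel_events, examined, distance).
// [[Rcpp::export(name = ".pair_distance_c")]]
NumericVector pair_distance_c(std::string ra, std::string rb,
                              bool remove_single_indels,
                              bool collapse_runs) {
    const int n = (int) ra.size();
    if ((int) rb.size() != n) stop("alignment rows differ in length");
    std::vector<unsigned char> ops(n);
    for (int i = 0; i < n; ++i) {
        char x = ra[i], y = rb[i];
        if (x == '-' && y == '-') stop("column gapped in both rows");
        if (y == '-') ops[i] = OP_GAP_B;
        else if (x == '-') ops[i] = OP_GAP_A;
        else ops[i] = (x == 'N' || y == 'N') ? OP_NCOL :
                      (x == y ? OP_MATCH : OP_MISMATCH);
    }
    double out[4];
    ops_distance(ops, remove_single_indels, collapse_runs, out);
    return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// Batch driver for the all-versus-all loop: aligns seqs[ii[k]] versus
// seqs[jj[k]] (1-based indices) and returns the post-processed genetic
// distance per pair. Same algorithm as the single-pair path, with reused
// buffers and no intermediate row strings.
// [[Rcpp::export(name = ".dist_pairs_c")]]
NumericVector dist_pairs_c(CharacterVector seqs,
                           IntegerVector ii, IntegerVector jj,
                           double match, double mismatch,
                           double gap_open, double gap_extend,
                           int band, bool remove_single_indels,
                           bool collapse_runs) {
    const int np = ii.size();
    if (jj.size() != np) stop("ii and jj differ in length");
    std::vector<std::string> ss(seqs.size());
    for (int k = 0; k < seqs.size(); ++k) ss[k] = as<std::string>(seqs[k]);
    NumericVector out(np);
    GotohWork w;
    std::vector<unsigned char> ops;
    double st[4];
    for (int k = 0; k < np; ++k) {
        if (k % 256 == 0) checkUserInterrupt();
        const std::string &a = ss[ii[k] - 1];
        const std::string &b = ss[jj[k] - 1];
        if (a.empty() || b.empty()) stop("sequences must be non-empty");
        int klo, W, state;
        gotoh_core(a, b, match, mismatch, gap_open, gap_extend, band,
                   w, &klo, &W, &state);
        gotoh_traceback(a, b, w, klo, W, state, ops);
        ops_distance(ops, remove_single_indels, collapse_runs, st);
        out[k] = st[3];
    }
    return out;
}
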