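#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (incl. N) is invalid in a word.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline bool base_match(char x, char y) {
    // N never counts as a match, on either side
    if (x == 'N' || x == 'n' || y == 'N' || y == 'n') return false;
    return x == y;
}

// Roll over a sequence emitting (position, key) for every word of width w
// made only of ACGT.  Callback-style via template would be cleaner but Rcpp
// exports plain functions; we duplicate the small rolling loop instead.

// [[Rcpp::export]]
List cpp_build_postings(CharacterVector reads_fwd, CharacterVector reads_rev,
                        int word_size, int polyA_threshold) {
    const int w = word_size;
    const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
    std::vector<double> keys;
    std::vector<int> readv, offv, strandv;
    std::unordered_set<uint64_t> masked_polyA;
    int n_short = 0;

    for (int r = 0; r < reads_fwd.size(); ++r) {
        for (int s = 0; s < 2; ++s) {
            const char *seq = (s == 0) ? CHAR(STRING_ELT(reads_fwd, r))
                                       : CHAR(STRING_ELT(reads_rev, r));
            const int n = (int) LENGTH((s == 0) ? STRING_ELT(reads_fwd, r)
                                                : STRING_ELT(reads_rev, r));
            if (n < w) { if (s == 0) ++n_short; continue; }
            uint64_t key = 0;
            int run = 0;   // length of current valid-base run
            int nA = 0, nT = 0;   // A/T counts in the current window
            for (int p = 0; p < n; ++p) {
                int c = base_code(seq[p]);
                if (c < 0) { run = 0; nA = 0; nT = 0; key = 0; continue; }
                key = ((key << 2) | (uint64_t) c) & mask;
                if (run < w) ++run;
                nA += (c == 0); nT += (c == 3);
                if (run >= w) {
                    int start = p - w + 1;
                    if (start > 0) {   // drop base leaving the window
                        int out = base_code(seq[start - 1]);
                        nA -= (out == 0); nT -= (out == 3);
                    }
                    if (nA >= polyA_threshold || nT >= polyA_threshold) {
                        masked_polyA.insert(key);
                    } else {
                        keys.push_back((double) key);
                        readv.push_back(r + 1);
                        offv.push_back(start);
                        strandv.push_back(s);
                    }
                }
            }
        }
    }
    NumericVector mk(masked_polyA.begin(), masked_polyA.end());
    return List::create(_["key"] = NumericVector(keys.begin(), keys.end()),
                        _["read"] = IntegerVector(readv.begin(), readv.end()),
                        _["offset"] = IntegerVector(offv.begin(), offv.end()),
                        _["strand"] = IntegerVector(strandv.begin(), strandv.end()),
                        _["masked_polyA"] = mk,
                        _["n_short_reads"] = n_short);
}

// Count occurrences in the reference of exactly those words present in the
// read lookup (plus-strand reference words only; both read orientations are
// indexed so reverse-complement repeats are caught through the read side).
// [[Rcpp::export]]
List cpp_count_ref_words(CharacterVector ref_seqs, int word_size,
                         NumericVector candidate_keys) {
    const int w = word_size;
    const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
    std::unordered_set<uint64_t> cand;
    cand.reserve(candidate_keys.size() * 2 + 1);
    for (double k : candidate_keys) cand.insert((uint64_t) k);
    std::unordered_map<uint64_t, int> counts;

    for (int r = 0; r < ref_seqs.size(); ++r) {
        const char *seq = CHAR(STRING_ELT(ref_seqs, r));
        const int n = (int) LENGTH(STRING_ELT(ref_seqs, r));
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < n; ++p) {
            int c = base_code(seq[p]);
            if (c < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t) c) & mask;
            if (run < w) ++run;
            if (run >= w && cand.count(key)) ++counts[key];
        }
    }
    NumericVector ck(counts.size());
    IntegerVector cn(counts.size());
    int i = 0;
    for (auto &kv : counts) { ck[i] = (double) kv.first; cn[i] = kv.second; ++i; }
    return List::create(_["key"] = ck, _["count"] = cn);
}

// Scan one reference sequence against the posting table.  Postings arrive
// sorted by key: ukey[u] owns postings pstart[u] .. pstart[u+1]-1 (0-based).
// Word hits are extended to the maximal exact run on their diagonal and
// deduplicated, then filtered at seed_len.
// [[Rcpp::export]]
List cpp_scan_reference(std::string ref, int word_size, int seed_len,
                        NumericVector ukey, IntegerVector pstart,
                        IntegerVector pread, IntegerVector poffset,
                        IntegerVector pstrand,
                        CharacterVector reads_fwd, CharacterVector reads_rev) {
    const int w = word_size;
    const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
    const int nref = (int) ref.size();
    const char *rf = ref.c_str();
    std::vector<int> out_read, out_strand, out_rs, out_re, out_ps, out_pe;
    // per (read,strand,diagonal): exclusive ref end of the last extended run
    std::unordered_map<uint64_t, int> covered;

    uint64_t key = 0; int run = 0;
    const double *uk = REAL(ukey);
    const int nu = ukey.size();
    for (int p = 0; p < nref; ++p) {
        int c = base_code(rf[p]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) c) & mask;
        if (run < w) ++run;
        if (run < w) continue;
        const int wstart = p - w + 1;
        // binary search the sorted unique keys
        double dk = (double) key;
        int lo = 0, hi = nu;
        while (lo < hi) { int mid = (lo + hi) / 2; if (uk[mid] < dk) lo = mid + 1; else hi = mid; }
        if (lo >= nu || uk[lo] != dk) continue;
        for (int q = pstart[lo]; q < pstart[lo + 1]; ++q) {
            const int rd = pread[q];          // 1-based read index
            const int s = pstrand[q];
            const int off = poffset[q];
            const char *rs = (s == 0) ? CHAR(STRING_ELT(reads_fwd, rd - 1))
                                      : CHAR(STRING_ELT(reads_rev, rd - 1));
            const int rlen = (int) LENGTH((s == 0) ? STRING_ELT(reads_fwd, rd - 1)
                                                   : STRING_ELT(reads_rev, rd - 1));
            const int diag = wstart - off;
            uint64_t dkey = ((uint64_t)(unsigned)((rd << 1) | s) << 32)
                          | (uint32_t)(diag + nref);
            auto it = covered.find(dkey);
            if (it != covered.end() && wstart < it->second) continue;
            // maximal exact run around the word hit
            int a0 = off, b0 = wstart;
            while (a0 > 0 && b0 > 0 && base_match(rs[a0 - 1], rf[b0 - 1])) { --a0; --b0; }
            int a1 = off + w, b1 = wstart + w;
            while (a1 < rlen && b1 < nref && base_match(rs[a1], rf[b1])) { ++a1; ++b1; }
            covered[dkey] = b1;
            if (a1 - a0 >= seed_len) {
                out_read.push_back(rd); out_strand.push_back(s);
                out_rs.push_back(a0); out_re.push_back(a1);
                out_ps.push_back(b0); out_pe.push_back(b1);
            }
        }
    }
    return List::create(_["read"] = IntegerVector(out_read.begin(), out_read.end()),
                        _["strand"] = IntegerVector(out_strand.begin(), out_strand.end()),
                        _["read_start"] = IntegerVector(out_rs.begin(), out_rs.end()),
                        _["read_end"] = IntegerVector(out_re.begin(), out_re.end()),
                        _["ref_start"] = IntegerVector(out_ps.begin(), out_ps.end()),
                        _["ref_end"] = IntegerVector(out_pe.begin(), out_pe.end()));
}

// --- greedy extension state machine -------------------------------------

// Does rule (kind,k,req,allowed) hold with tails a (read) and b (reference)?
// kind: 0 substitution, 1 insertion (extra read bases), 2 deletion.
// Requirement window: of the (req + allowed) bases following the applied
// operation, at least req must match; a window truncated by a sequence end
// requires all remaining bases to match up to the allowed mismatches.
static bool rule_ok(const char *a, int la, const char *b, int lb,
                    int kind, int k, int req, int allowed) {
    const int ai = (kind == 2) ? 0 : k;   // read bases consumed by the op
    const int bi = (kind == 1) ? 0 : k;   // reference bases consumed
    if (ai > la || bi > lb) return false;
    const int t = std::min(req + allowed, std::min(la - ai, lb - bi));
    const int need = std::max(0, std::min(req, t - allowed));
    int m = 0;
    for (int u = 0; u < t; ++u) m += base_match(a[ai + u], b[bi + u]);
    return m >= need;
}

// First rule in table order whose requirement is met; -1 = fallback (single
// substitution).  table columns: kind, length, required, allowed.
static int choose_rule(const char *a, int la, const char *b, int lb,
                       const IntegerMatrix &table) {
    for (int r = 0; r < table.nrow(); ++r) {
        if (rule_ok(a, la, b, lb, table(r, 0), table(r, 1),
                    table(r, 2), table(r, 3))) return r;
    }
    return -1;
}

// [[Rcpp::export]]
List cpp_step_state_machine(std::string read_tail, std::string ref_tail,
                            IntegerMatrix table) {
    int r = choose_rule(read_tail.c_str(), (int) read_tail.size(),
                        ref_tail.c_str(), (int) ref_tail.size(), table);
    int kind = 0, len = 1;
    if (r >= 0) { kind = table(r, 0); len = table(r, 1); }
    return List::create(_["kind"] = kind, _["length"] = len,
                        _["rule"] = (r >= 0) ? (r + 1) : NA_INTEGER);
}

struct ExtResult { std::vector<char> ops; int score; };

// Extend rightward from the start of tails a (read) and b (reference),
// stopping by X-drop and backtracking to the running-score maximum.
static ExtResult extend_dir(const char *a, int la, const char *b, int lb,
                            const IntegerMatrix &table,
                            int match, int mismatch, int gap_open,
                            int gap_extend, int xdrop) {
    ExtResult res; res.score = 0;
    std::vector<char> ops;
    int i = 0, j = 0, score = 0, best = 0;
    size_t best_len = 0;
    bool stop = false;
    while (!stop && i < la && j < lb) {
        if (base_match(a[i], b[j])) {
            score += match; ops.push_back('M'); ++i; ++j;
            if (score > best) { best = score; best_len = ops.size(); }
            continue;
        }
        int r = choose_rule(a + i, la - i, b + j, lb - j, table);
        int kind = 0, k = 1;
        if (r >= 0) { kind = table(r, 0); k = table(r, 1); }
        if (kind == 0) {
            for (int t = 0; t < k && i < la && j < lb; ++t) {
                score += mismatch; ops.push_back('X'); ++i; ++j;
                if (score > best) { best = score; best_len = ops.size(); }
                if (score < best - xdrop) { stop = true; break; }
            }
        } else {
            score += gap_open;
            for (int t = 0; t < k; ++t) {
                if (kind == 1) { if (i >= la) break; ops.push_back('I'); ++i; }
                else           { if (j >= lb) break; ops.push_back('D'); ++j; }
                score += gap_extend;
                if (score > best) { best = score; best_len = ops.size(); }
                if (score < best - xdrop) { stop = true; break; }
            }
        }
    }
    ops.resize(best_len);
    res.ops = ops; res.score = best;
    return res;
}

// Extend a seed (exact match read[seed_rs,seed_re) == ref[seed_ps,...)) in
// both directions.  Leftward extension mirrors the operation table on the
// reversed sequences.  Returns run-length op/len vectors (M,X,I,D), the
// 0-based half-open intervals, and the total score.
// [[Rcpp::export]]
List cpp_greedy_extend(std::string read, std::string ref,
                       int seed_read_start, int seed_read_end,
                       int seed_ref_start,
                       IntegerMatrix table,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int xdrop) {
    const int seed_len = seed_read_end - seed_read_start;
    const int seed_ref_end = seed_ref_start + seed_len;
    // right tails
    ExtResult right = extend_dir(read.c_str() + seed_read_end,
                                 (int) read.size() - seed_read_end,
                                 ref.c_str() + seed_ref_end,
                                 (int) ref.size() - seed_ref_end,
                                 table, match, mismatch, gap_open, gap_extend,
                                 xdrop);
    // left tails: reversed prefixes
    std::string ra(read.rend() - seed_read_start, read.rend());
    std::string rb(ref.rend() - seed_ref_start, ref.rend());
    ExtResult left = extend_dir(ra.c_str(), (int) ra.size(),
                                rb.c_str(), (int) rb.size(),
                                table, match, mismatch, gap_open, gap_extend,
                                xdrop);
    // assemble per-base ops: reversed left + seed matches + right
    std::vector<char> all;
    all.reserve(left.ops.size() + seed_len + right.ops.size());
    for (auto it = left.ops.rbegin(); it != left.ops.rend(); ++it) all.push_back(*it);
    for (int t = 0; t < seed_len; ++t) all.push_back('M');
    for (char c : right.ops) all.push_back(c);
    // run-length encode
    std::vector<char> opv; std::vector<int> lenv;
    for (char c : all) {
        if (!opv.empty() && opv.back() == c) ++lenv.back();
        else { opv.push_back(c); lenv.push_back(1); }
    }
    int lread = 0, lref = 0;
    for (char c : left.ops) { if (c != 'D') ++lread; if (c != 'I') ++lref; }
    int rread = 0, rref = 0;
    for (char c : right.ops) { if (c != 'D') ++rread; if (c != 'I') ++rref; }
    CharacterVector opc(opv.size());
    for (size_t t = 0; t < opv.size(); ++t) opc[t] = std::string(1, opv[t]);
    return List::create(_["op"] = opc,
                        _["len"] = IntegerVector(lenv.begin(), lenv.end()),
                        _["read_start"] = seed_read_start - lread,
                        _["read_end"] = seed_read_end + rread,
                        _["ref_start"] = seed_ref_start - lref,
                        _["ref_end"] = seed_ref_end + rref,
                        _["score"] = left.score + seed_len * match + right.score);
}
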