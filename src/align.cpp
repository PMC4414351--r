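#include <Rcpp.h>
#include <string>
#include <cmath>

using namespace Rcpp;

static inline char complement_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string reverse_complement(const std::string &s) {
    std::string out(s.size(), 'N');
    for (std::size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = complement_base(s[i]);
    return out;
}

// Exhaustive end-to-end alignment of fixed-length reads against the
// telomeric index.  The index sequence is the telomeric tiling (tel_len =
// rl + pl - 1 bases) followed by an N-tail; positions >= tel_len match any
// base at zero penalty, so mismatches are only ever counted over the first
// min(rl, tel_len - offset) bases of a placement (the telomeric overlap).
// A placement is feasible when mismatches <= floor(max_mismatch_rate *
// overlap).  The best feasible placement maximises telomeric overlap, then
// minimises mismatches; remaining ties go to the smallest offset on the
// forward strand (guaranteed by scan order + strict improvement).
// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector reads, std::string index_seq,
                          int tel_len, int rl, double max_mismatch_rate,
                          bool both_strands) {
    const int n = reads.size();
    const int full_len = (int) index_seq.size();
    const int max_off = full_len - rl;

    LogicalVector mapped(n);
    IntegerVector offset(n, NA_INTEGER);
    IntegerVector mismatches(n, NA_INTEGER);
    IntegerVector overlap(n, NA_INTEGER);
    CharacterVector strand(n, NA_STRING);

    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(reads[i]);
        if ((int) s.size() != rl) {  // guarded upstream; defensive only
            mapped[i] = false;
            continue;
        }
        int best_ov = -1, best_mm = 0, best_off = -1, best_strand = -1;
        const int n_strands = both_strands ? 2 : 1;
        for (int st = 0; st < n_strands; ++st) {
            const std::string q = (st == 0) ? s : reverse_complement(s);
            for (int o = 0; o <= max_off; ++o) {
                const int ov = std::min(rl, tel_len - o);
                if (ov <= 0) continue;
                const int budget =
                    (int) std::floor(max_mismatch_rate * ov + 1e-9);
                int mm = 0;
                bool ok = true;
                for (int j = 0; j < ov; ++j) {
                    if (q[j] != index_seq[o + j]) {
                        if (++mm > budget) { ok = false; break; }
                    }
                }
                // strict improvement keeps the earliest (smallest offset,
                // forward strand) candidate on ties
                if (ok && (ov > best_ov || (ov == best_ov && mm < best_mm))) {
                    best_ov = ov; best_mm = mm;
                    best_off = o; best_strand = st;
                }
            }
        }
        if (best_ov >= 0) {
            mapped[i] = true;
            offset[i] = best_off;
            mismatches[i] = best_mm;
            overlap[i] = best_ov;
            strand[i] = (best_strand == 0) ? "+" : "-";
        } else {
            mapped[i] = false;
        }
    }

    return DataFrame::create(_["mapped"] = mapped,
                             _["offset"] = offset,
                             _["strand"] = strand,
                             _["mismatches"] = mismatches,
                             _["telomeric_overlap"] = overlap,
                             _["stringsAsFactors"] = false);
}
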