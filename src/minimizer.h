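#ifndef LPMPHF_MINIMIZER_H
#define LPMPHF_MINIMIZER_H

#include <cstdint>
#include <deque>
#include <string>
#include <vector>
#include <stdexcept>

#include "hash.h"

namespace lpmphf {

struct Scheme {
    int k;
    int m;
    uint64_t seed;
    int w() const { return k - m + 1; }
};

inline void check_acgt(const std::string& s, const char* what) {
    for (size_t i = 0; i < s.size(); ++i) {
        char c = s[i];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
            throw std::runtime_error(std::string(what) + " contains a non-ACGT symbol '" +
                                     std::string(1, c) + "' at position " + std::to_string(i + 1));
    }
}

// Per-k-mer minimizer: the absolute (0-based) start position in the parent
// sequence of the chosen minimal m-mer, plus its hash.  Ties by hash are
// broken towards the leftmost m-mer.
struct MinHit {
    uint64_t abs_pos; // 0-based start of the m-mer in the sequence
    uint64_t hash;
};

// Sliding-window minimum over m-mer hashes (monotone deque), amortized O(1)
// per position.  Produces one MinHit per k-mer of the sequence.  Keeping
// strictly-greater elements only (popping on >) leaves the leftmost of any
// equal-hash run at the front, which realizes the leftmost tie rule.
inline std::vector<MinHit> streaming_minimizers(const std::string& seq, const Scheme& sc) {
    const int k = sc.k, m = sc.m, w = sc.w();
    if ((int)seq.size() < k)
        throw std::runtime_error("sequence shorter than k (" + std::to_string(seq.size()) +
                                 " < " + std::to_string(k) + ")");
    const uint64_t n_mmers = seq.size() - m + 1;
    const uint64_t n_kmers = seq.size() - k + 1;
    std::vector<MinHit> out;
    out.reserve(n_kmers);
    std::deque<MinHit> dq;
    for (uint64_t j = 0; j < n_mmers; ++j) {
        uint64_t h = murmur64(seq.data() + j, m, sc.seed);
        while (!dq.empty() && dq.back().hash > h) dq.pop_back();
        dq.push_back({j, h});
        // k-mer i spans m-mers [i, i + w); complete once j = i + w - 1
        if (j + 1 >= (uint64_t)w) {
            uint64_t i = j + 1 - w;
            while (dq.front().abs_pos < i) dq.pop_front();
            out.push_back(dq.front());
        }
    }
    return out;
}

enum FlType { FL_LEFT_RIGHT_MAX = 0, FL_LEFT_MAX = 1, FL_RIGHT_MAX = 2, FL_NON_MAX = 3 };

inline int classify_fl(int p_first, int p_last, int w) {
    if (p_last < 1 || p_first > w || p_last > p_first)
        throw std::runtime_error("invalid (p_first, p_last, w) for FL classification");
    bool left = (p_first == w);   // minimizer position maximal in first k-mer
    bool right = (p_last == 1);   // minimizer position minimal in last k-mer
    if (left && right) return FL_LEFT_RIGHT_MAX;
    if (right) return FL_LEFT_MAX;
    if (left) return FL_RIGHT_MAX;
    return FL_NON_MAX;
}

// One super-k-mer: a maximal run of consecutive k-mers selecting the same
// minimizer occurrence (same m-mer at the same absolute position).
struct SuperKmer {
    uint64_t string_id;   // 0-based index of the source string
    uint64_t start;       // 0-based offset of the first symbol in the string
    uint64_t kmer_start;  // 0-based index of the first k-mer in the string
    int size;             // number of k-mers
    int p_first;          // 1-based minimizer start in the first k-mer
    int p_last;           // 1-based minimizer start in the last k-mer
    uint64_t min_pos;     // absolute 0-based start of the minimizer occurrence
    int fl_type;
};

inline std::vector<SuperKmer> decompose(const std::string& seq, uint64_t string_id,
                                        const Scheme& sc) {
    std::vector<MinHit> hits = streaming_minimizers(seq, sc);
    const int w = sc.w();
    std::vector<SuperKmer> out;
    uint64_t run_start = 0;
    for (uint64_t i = 1; i <= hits.size(); ++i) {
        if (i == hits.size() || hits[i].abs_pos != hits[run_start].abs_pos) {
            SuperKmer g;
            g.string_id = string_id;
            g.kmer_start = run_start;
            g.start = run_start;
            g.size = (int)(i - run_start);
            g.min_pos = hits[run_start].abs_pos;
            g.p_first = (int)(g.min_pos - run_start + 1);
            g.p_last = g.p_first - g.size + 1;
            g.fl_type = classify_fl(g.p_first, g.p_last, w);
            out.push_back(g);
            run_start = i;
        }
    }
    return out;
}

} // namespace lpmphf

#endif
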