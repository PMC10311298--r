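#ifndef LPMPHF_WAVELET_H
#define LPMPHF_WAVELET_H

#include <cstdint>
#include <vector>
#include <stdexcept>

#include "bitvec.h"
#include "bytestream.h"

namespace lpmphf {

// Two-level wavelet tree over the 4-symbol alphabet {0,1,2,3}.
// Level 1 stores the high bit of each symbol; level 2 stores the low bits,
// first for the symbols with high bit 0 (in order), then for those with
// high bit 1.  Payload is exactly 2 bits per symbol; the rank samples of
// the two bitvectors add ~12.5% each, within the 2.5 bits/symbol budget.
class Wavelet4 {
public:
    uint64_t n = 0;
    uint64_t n0 = 0;   // symbols with high bit 0
    BitVec level1, level2;

    static Wavelet4 build(const std::vector<uint8_t>& syms) {
        Wavelet4 wt;
        wt.n = syms.size();
        for (size_t i = 0; i < syms.size(); ++i)
            if (syms[i] > 3)
                throw std::runtime_error("wavelet tree symbol out of {0,1,2,3} at element " +
                                         std::to_string(i + 1));
        wt.level1.resize(wt.n);
        for (uint64_t i = 0; i < wt.n; ++i)
            if (syms[i] >> 1) wt.level1.set(i);
        wt.level1.finish();
        wt.n0 = wt.n - wt.level1.ones();
        wt.level2.resize(wt.n);
        uint64_t i0 = 0, i1 = wt.n0;
        for (uint64_t i = 0; i < wt.n; ++i) {
            if (syms[i] >> 1) {
                if (syms[i] & 1) wt.level2.set(i1);
                ++i1;
            } else {
                if (syms[i] & 1) wt.level2.set(i0);
                ++i0;
            }
        }
        wt.level2.finish();
        return wt;
    }

    uint8_t access(uint64_t i) const { // 0-based
        if (i >= n) throw std::runtime_error("wavelet tree access out of range");
        if (!level1.get(i)) {
            uint64_t idx = i - level1.rank1(i);      // rank0(i)
            return level2.get(idx) ? 1 : 0;
        }
        uint64_t idx = n0 + level1.rank1(i);
        return level2.get(idx) ? 3 : 2;
    }

    // number of occurrences of symbol t in the prefix of length i (positions [0, i))
    uint64_t rank(uint8_t t, uint64_t i) const {
        if (t > 3) throw std::runtime_error("wavelet tree rank symbol out of {0,1,2,3}");
        if (i > n) throw std::runtime_error("wavelet tree rank position out of range");
        if ((t >> 1) == 0) {
            uint64_t m = i - level1.rank1(i);        // symbols with high bit 0 in prefix
            uint64_t ones = level2.rank1(m);
            return (t & 1) ? ones : m - ones;
        }
        uint64_t m = level1.rank1(i);                // symbols with high bit 1 in prefix
        uint64_t ones = level2.rank1(n0 + m) - level2.rank1(n0);
        return (t & 1) ? ones : m - ones;
    }

    uint64_t bits_payload() const { return 2 * n; }
    uint64_t bits_total() const { return 128 + level1.bits_total() + level2.bits_total(); }

    void encode_stream(ByteWriter& w) const {
        w.u64(n);
        w.u64(n0);
        level1.encode(w);
        level2.encode(w);
    }
    static Wavelet4 decode(ByteReader& r) {
        Wavelet4 wt;
        wt.n = r.u64();
        wt.n0 = r.u64();
        wt.level1 = BitVec::decode(r);
        wt.level2 = BitVec::decode(r);
        return wt;
    }
};

} // namespace lpmphf

#endif
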