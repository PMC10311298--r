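#ifndef LPMPHF_ELIASFANO_H
#define LPMPHF_ELIASFANO_H

#include <cstdint>
#include <vector>
#include <stdexcept>

#include "bitvec.h"
#include "bytestream.h"

namespace lpmphf {

// Elias-Fano encoding of a non-decreasing sequence of n values over
// universe [0, u].  Each value is split into l = max(0, floor(log2(u/n)))
// low bits, stored verbatim, and a high part stored in unary in a bitvector
// of n + (u >> l) + 1 bits.  access(i) is exact and O(1) thanks to select
// samples on the high bits (one sampled position every 256 ones).
class EliasFano {
public:
    uint64_t n = 0;
    uint64_t universe = 0;
    uint8_t l = 0;
    std::vector<uint64_t> low;             // packed l-bit integers
    BitVec high;
    std::vector<uint64_t> select_samples;  // bit position of every 256th one

    static const uint64_t SELECT_EVERY = 256;

    static EliasFano encode(const std::vector<uint64_t>& v) {
        EliasFano ef;
        ef.n = v.size();
        if (ef.n == 0) return ef;
        ef.universe = v.back();
        for (size_t i = 1; i < v.size(); ++i)
            if (v[i] < v[i - 1])
                throw std::runtime_error("Elias-Fano input must be non-decreasing (violated at element " +
                                         std::to_string(i + 1) + ")");
        // l = floor(log2(u/n)) when u > n, else 0
        uint8_t l = 0;
        if (ef.universe > ef.n) {
            uint64_t ratio = ef.universe / ef.n;
            while (ratio > 1) { ratio >>= 1; ++l; }
        }
        ef.l = l;
        ef.low.assign((ef.n * l + 63) / 64, 0ULL);
        ef.high.resize(ef.n + (ef.universe >> l) + 1);
        for (uint64_t i = 0; i < ef.n; ++i) {
            uint64_t x = v[i];
            if (l) ef.set_low(i, x & ((1ULL << l) - 1));
            ef.high.set((x >> l) + i);
        }
        ef.high.finish();
        ef.build_select();
        return ef;
    }

    uint64_t access(uint64_t i) const { // 0-based
        if (i >= n) throw std::runtime_error("Elias-Fano access out of range");
        uint64_t hi = select1(i) - i;
        uint64_t lo = l ? get_low(i) : 0;
        return (hi << l) | lo;
    }

    uint64_t bits_total() const {
        return 192 + low.size() * 64 + high.bits_total() + select_samples.size() * 64;
    }

    void encode_stream(ByteWriter& w) const {
        w.u64(n);
        w.u64(universe);
        w.u8(l);
        w.u64vec(low);
        high.encode(w);
        // select samples rebuilt on decode
    }
    static EliasFano decode(ByteReader& r) {
        EliasFano ef;
        ef.n = r.u64();
        ef.universe = r.u64();
        ef.l = r.u8();
        ef.low = r.u64vec();
        ef.high = BitVec::decode(r);
        if (ef.n > 0) ef.build_select();
        return ef;
    }

private:
    void set_low(uint64_t i, uint64_t val) {
        uint64_t bitpos = i * l;
        uint64_t w = bitpos >> 6, o = bitpos & 63;
        low[w] |= val << o;
        if (o + l > 64) low[w + 1] |= val >> (64 - o);
    }
    uint64_t get_low(uint64_t i) const {
        uint64_t bitpos = i * l;
        uint64_t w = bitpos >> 6, o = bitpos & 63;
        uint64_t val = low[w] >> o;
        if (o + l > 64) val |= low[w + 1] << (64 - o);
        return val & ((1ULL << l) - 1);
    }
    void build_select() {
        select_samples.clear();
        uint64_t seen = 0;
        for (uint64_t w = 0; w < high.words.size(); ++w) {
            uint64_t word = high.words[w];
            while (word) {
                uint64_t b = word & (~word + 1);
                if (seen % SELECT_EVERY == 0) {
                    uint64_t pos = w * 64 + (uint64_t)popcount64(b - 1);
                    select_samples.push_back(pos);
                }
                ++seen;
                word ^= b;
            }
        }
    }
    // position of the i-th (0-based) set bit of the high bitvector
    uint64_t select1(uint64_t i) const {
        uint64_t pos = select_samples[i / SELECT_EVERY];
        uint64_t seen = (i / SELECT_EVERY) * SELECT_EVERY;
        uint64_t w = pos >> 6;
        uint64_t word = high.words[w] & ~((pos & 63) ? ((1ULL << (pos & 63)) - 1) : 0ULL);
        while (true) {
            int c = popcount64(word);
            if (seen + c > i) {
                // the target bit is inside this word
                while (true) {
                    uint64_t b = word & (~word + 1);
                    if (seen == i) return w * 64 + (uint64_t)popcount64(b - 1);
                    ++seen;
                    word ^= b;
                }
            }
            seen += c;
            ++w;
            word = high.words[w];
        }
    }
};

} // namespace lpmphf

#endif
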