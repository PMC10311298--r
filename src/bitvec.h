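#ifndef LPMPHF_BITVEC_H
#define LPMPHF_BITVEC_H

#include <cstdint>
#include <vector>
#include <stdexcept>

#include "bytestream.h"

namespace lpmphf {

#if defined(__GNUC__) || defined(__clang__)
inline int popcount64(uint64_t x) { return __builtin_popcountll(x); }
#else
inline int popcount64(uint64_t x) {
    int c = 0;
    while (x) { x &= x - 1; ++c; }
    return c;
}
#endif

// Plain bitvector with absolute rank counters sampled every 512 bits
// (8 words), in the spirit of Rank9.  rank1(i) counts set bits in the
// prefix [0, i) and is exact for every i in [0, n].
class BitVec {
public:
    uint64_t n = 0;                  // number of bits
    std::vector<uint64_t> words;     // ceil(n/64) words, little-endian bit order
    std::vector<uint64_t> samples;   // absolute rank at the start of each 512-bit block

    static const uint64_t BLOCK_BITS = 512;
    static const uint64_t BLOCK_WORDS = 8;

    BitVec() {}
    explicit BitVec(uint64_t nbits) { resize(nbits); }

    void resize(uint64_t nbits) {
        n = nbits;
        words.assign((n + 63) / 64, 0ULL);
    }

    void set(uint64_t i) { words[i >> 6] |= 1ULL << (i & 63); }
    bool get(uint64_t i) const { return (words[i >> 6] >> (i & 63)) & 1ULL; }

    // Build the rank samples; must be called after the last set().
    void finish() {
        uint64_t nblocks = (n + BLOCK_BITS - 1) / BLOCK_BITS;
        samples.assign(nblocks, 0ULL);
        uint64_t acc = 0;
        for (uint64_t b = 0; b < nblocks; ++b) {
            samples[b] = acc;
            uint64_t w0 = b * BLOCK_WORDS;
            uint64_t w1 = w0 + BLOCK_WORDS;
            if (w1 > words.size()) w1 = words.size();
            for (uint64_t w = w0; w < w1; ++w) acc += popcount64(words[w]);
        }
        total_ones_ = acc;
    }

    // Number of set bits in the prefix of length i (i.e. positions [0, i)).
    uint64_t rank1(uint64_t i) const {
        if (i > n) throw std::runtime_error("rank1: position out of range");
        if (i == 0) return 0;
        uint64_t block = i / BLOCK_BITS;
        uint64_t r = samples[block];
        uint64_t w = block * BLOCK_WORDS;
        uint64_t last_word = i / 64;
        for (; w < last_word; ++w) r += popcount64(words[w]);
        uint64_t rem = i & 63;
        if (rem) r += popcount64(words[last_word] & ((1ULL << rem) - 1));
        return r;
    }

    uint64_t ones() const { return total_ones_; }

    uint64_t bits_payload() const { return words.size() * 64; }
    uint64_t bits_overhead() const { return samples.size() * 64; }
    uint64_t bits_total() const { return bits_payload() + bits_overhead() + 64; }

    void encode(ByteWriter& w) const {
        w.u64(n);
        w.u64vec(words);
        // samples are rebuilt on decode; only payload is serialized
    }
    static BitVec decode(ByteReader& r) {
        BitVec bv;
        bv.n = r.u64();
        bv.words = r.u64vec();
        if (bv.words.size() != (bv.n + 63) / 64)
            throw std::runtime_error("bitvector payload length mismatch at offset " +
                                     std::to_string(r.off));
        bv.finish();
        return bv;
    }

private:
    uint64_t total_ones_ = 0;
};

} // namespace lpmphf

#endif
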