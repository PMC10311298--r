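#ifndef LPMPHF_HASH_H
#define LPMPHF_HASH_H

#include <cstdint>
#include <cstring>
#include <string>

namespace lpmphf {

// splitmix64: used to derive per-level / per-component seeds from a master seed.
inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// Seeded 64-bit MurmurHash2 (64A variant) over a byte string.  This is the
// random hash h of the minimizer scheme and the key hash of the MPHF levels.
// Strings are hashed as their ASCII bytes (uppercase A,C,G,T for DNA),
// independent of host byte order.
inline uint64_t murmur64(const void* key, size_t len, uint64_t seed) {
    const uint64_t mul = 0xC6A4A7935BD1E995ULL;
    const int r = 47;
    uint64_t h = seed ^ (len * mul);
    const uint8_t* data = (const uint8_t*)key;
    const size_t nblocks = len / 8;
    for (size_t i = 0; i < nblocks; ++i) {
        uint64_t k;
        std::memcpy(&k, data + i * 8, 8); // little-endian hosts only (x86/arm64)
        k *= mul; k ^= k >> r; k *= mul;
        h ^= k; h *= mul;
    }
    const uint8_t* tail = data + nblocks * 8;
    uint64_t k = 0;
    switch (len & 7) {
        case 7: k ^= (uint64_t)tail[6] << 48; /* fall through */
        case 6: k ^= (uint64_t)tail[5] << 40; /* fall through */
        case 5: k ^= (uint64_t)tail[4] << 32; /* fall through */
        case 4: k ^= (uint64_t)tail[3] << 24; /* fall through */
        case 3: k ^= (uint64_t)tail[2] << 16; /* fall through */
        case 2: k ^= (uint64_t)tail[1] << 8;  /* fall through */
        case 1: k ^= (uint64_t)tail[0];
                h ^= k * mul;
    }
    h *= mul;
    h ^= h >> r; h *= mul; h ^= h >> r;
    return h;
}

inline uint64_t hash_str(const std::string& s, uint64_t seed) {
    return murmur64(s.data(), s.size(), seed);
}

inline std::string hash_hex(uint64_t h) {
    static const char* digits = "0123456789abcdef";
    std::string s(16, '0');
    for (int i = 15; i >= 0; --i) { s[i] = digits[h & 0xF]; h >>= 4; }
    return s;
}

} // namespace lpmphf

#endif
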