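#ifndef LPMPHF_MPHF_H
#define LPMPHF_MPHF_H

#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
#include <stdexcept>

#include "bitvec.h"
#include "bytestream.h"
#include "hash.h"

namespace lpmphf {

// Generic minimal perfect hash function over distinct byte strings, built
// with multi-level collision-cascading bitmaps (gamma = expansion factor
// per level).  Keys that collide at one level cascade to the next; a small
// remainder after the last level is stored in an explicit sorted table so
// construction always terminates.  Evaluation is a bijection onto
// [0, n) over the construction keys; alien keys return an arbitrary
// in-range value.
class Mphf {
public:
    uint64_t n = 0;
    uint64_t seed = 0;
    double gamma = 2.0;
    std::vector<BitVec> levels;
    std::vector<uint64_t> level_offset;      // ones in all previous levels
    std::vector<std::string> rem_keys;       // sorted
    uint64_t rem_base = 0;

    static const int MAX_LEVELS = 48;

    static Mphf build(const std::vector<std::string>& keys, uint64_t seed, double gamma = 2.0) {
        if (keys.empty()) throw std::runtime_error("MPHF build requires a nonempty key set");
        Mphf f;
        f.n = keys.size();
        f.seed = seed;
        f.gamma = gamma;
        std::vector<const std::string*> cur;
        cur.reserve(keys.size());
        for (const auto& k : keys) cur.push_back(&k);
        uint64_t acc = 0;
        for (int lev = 0; lev < MAX_LEVELS && !cur.empty(); ++lev) {
            uint64_t size = (uint64_t)(gamma * (double)cur.size()) + 1;
            size = ((size + 63) / 64) * 64;
            uint64_t lseed = level_seed(seed, lev);
            BitVec once(size), coll(size);
            for (const std::string* k : cur) {
                uint64_t pos = hash_str(*k, lseed) % size;
                if (once.get(pos)) coll.set(pos); else once.set(pos);
            }
            std::vector<const std::string*> next;
            for (const std::string* k : cur) {
                uint64_t pos = hash_str(*k, lseed) % size;
                if (coll.get(pos)) next.push_back(k);
            }
            for (uint64_t w = 0; w < once.words.size(); ++w)
                once.words[w] &= ~coll.words[w];
            once.finish();
            f.level_offset.push_back(acc);
            acc += once.ones();
            f.levels.push_back(std::move(once));
            cur.swap(next);
        }
        f.rem_base = acc;
        for (const std::string* k : cur) f.rem_keys.push_back(*k);
        std::sort(f.rem_keys.begin(), f.rem_keys.end());
        for (size_t i = 1; i < f.rem_keys.size(); ++i)
            if (f.rem_keys[i] == f.rem_keys[i - 1])
                throw std::runtime_error("duplicate key in MPHF input: \"" + f.rem_keys[i] + "\"");
        return f;
    }

    uint64_t eval(const std::string& key) const {
        for (size_t lev = 0; lev < levels.size(); ++lev) {
            const BitVec& bv = levels[lev];
            uint64_t pos = hash_str(key, level_seed(seed, (int)lev)) % bv.n;
            if (bv.get(pos)) return level_offset[lev] + bv.rank1(pos);
        }
        auto it = std::lower_bound(rem_keys.begin(), rem_keys.end(), key);
        if (it != rem_keys.end() && *it == key)
            return rem_base + (uint64_t)(it - rem_keys.begin());
        return 0; // alien key: arbitrary in-range value
    }

    uint64_t bits_total() const {
        uint64_t bits = 256; // header fields
        for (const BitVec& bv : levels) bits += bv.bits_total();
        for (const std::string& k : rem_keys) bits += 64 + 8 * k.size();
        return bits;
    }
    double bits_per_key() const { return (double)bits_total() / (double)n; }

    void encode_stream(ByteWriter& w) const {
        w.u64(n);
        w.u64(seed);
        w.f64(gamma);
        w.u64(levels.size());
        for (const BitVec& bv : levels) bv.encode(w);
        w.u64(rem_base);
        w.u64(rem_keys.size());
        for (const std::string& k : rem_keys) w.str(k);
    }
    static Mphf decode(ByteReader& r) {
        Mphf f;
        f.n = r.u64();
        f.seed = r.u64();
        f.gamma = r.f64();
        uint64_t nl = r.u64();
        uint64_t acc = 0;
        for (uint64_t i = 0; i < nl; ++i) {
            f.levels.push_back(BitVec::decode(r));
            f.level_offset.push_back(acc);
            acc += f.levels.back().ones();
        }
        f.rem_base = r.u64();
        uint64_t nr = r.u64();
        for (uint64_t i = 0; i < nr; ++i) f.rem_keys.push_back(r.str());
        return f;
    }

private:
    static uint64_t level_seed(uint64_t master, int level) {
        return splitmix64(master + 0x9E3779B97F4A7C15ULL * (uint64_t)(level + 1));
    }
};

} // namespace lpmphf

#endif
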