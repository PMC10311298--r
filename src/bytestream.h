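#ifndef LPMPHF_BYTESTREAM_H
#define LPMPHF_BYTESTREAM_H

#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <stdexcept>

namespace lpmphf {

// Little-endian byte stream helpers used by every serialized structure.
// All multi-byte integers are written least-significant byte first,
// independently of the host byte order.

class ByteWriter {
public:
    std::vector<uint8_t> buf;

    void u8(uint8_t v) { buf.push_back(v); }
    void u16(uint16_t v) { for (int i = 0; i < 2; ++i) buf.push_back((uint8_t)(v >> (8 * i))); }
    void u32(uint32_t v) { for (int i = 0; i < 4; ++i) buf.push_back((uint8_t)(v >> (8 * i))); }
    void u64(uint64_t v) { for (int i = 0; i < 8; ++i) buf.push_back((uint8_t)(v >> (8 * i))); }
    void f64(double v) { uint64_t x; std::memcpy(&x, &v, 8); u64(x); }
    void bytes(const void* p, size_t n) {
        const uint8_t* q = (const uint8_t*)p;
        buf.insert(buf.end(), q, q + n);
    }
    void str(const std::string& s) { u64(s.size()); bytes(s.data(), s.size()); }
    void u64vec(const std::vector<uint64_t>& v) {
        u64(v.size());
        for (uint64_t x : v) u64(x);
    }
};

class ByteReader {
public:
    const uint8_t* p;
    size_t len;
    size_t off = 0;

    ByteReader(const uint8_t* p_, size_t len_) : p(p_), len(len_) {}

    void need(size_t n) const {
        if (off + n > len)
            throw std::runtime_error("truncated stream: need " + std::to_string(n) +
                                     " byte(s) at offset " + std::to_string(off) +
                                     " but only " + std::to_string(len - off) + " remain");
    }
    uint8_t u8() { need(1); return p[off++]; }
    uint16_t u16() { need(2); uint16_t v = 0; for (int i = 0; i < 2; ++i) v |= (uint16_t)p[off + i] << (8 * i); off += 2; return v; }
    uint32_t u32() { need(4); uint32_t v = 0; for (int i = 0; i < 4; ++i) v |= (uint32_t)p[off + i] << (8 * i); off += 4; return v; }
    uint64_t u64() { need(8); uint64_t v = 0; for (int i = 0; i < 8; ++i) v |= (uint64_t)p[off + i] << (8 * i); off += 8; return v; }
    double f64() { uint64_t x = u64(); double v; std::memcpy(&v, &x, 8); return v; }
    std::string str() {
        uint64_t n = u64();
        need(n);
        std::string s((const char*)p + off, (size_t)n);
        off += n;
        return s;
    }
    std::vector<uint64_t> u64vec() {
        uint64_t n = u64();
        need(n * 8);
        std::vector<uint64_t> v;
        v.reserve(n);
        for (uint64_t i = 0; i < n; ++i) v.push_back(u64());
        return v;
    }
};

} // namespace lpmphf

#endif
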