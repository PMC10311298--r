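#ifndef LPMPHF_INDEX_H
#define LPMPHF_INDEX_H

#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
#include <stdexcept>

#include "bytestream.h"
#include "eliasfano.h"
#include "hash.h"
#include "minimizer.h"
#include "mphf.h"
#include "wavelet.h"

namespace lpmphf {

// Fixed-width bit-packed vector for minimizer positions (values in [1..w],
// stored as value-1 in ceil(log2(w)) bits).
class PackedVec {
public:
    uint64_t n = 0;
    uint8_t width = 1;
    std::vector<uint64_t> words;

    static PackedVec pack(const std::vector<uint32_t>& v, uint32_t maxval) {
        PackedVec pv;
        pv.n = v.size();
        uint8_t wbits = 1;
        while ((1ULL << wbits) < (uint64_t)maxval) ++wbits;
        pv.width = wbits;
        pv.words.assign((pv.n * wbits + 63) / 64, 0ULL);
        for (uint64_t i = 0; i < pv.n; ++i) pv.set(i, v[i] - 1);
        return pv;
    }
    void set(uint64_t i, uint64_t val) {
        uint64_t bitpos = i * width, w = bitpos >> 6, o = bitpos & 63;
        words[w] |= val << o;
        if (o + width > 64) words[w + 1] |= val >> (64 - o);
    }
    uint32_t get(uint64_t i) const { // returns the original value in [1..maxval]
        uint64_t bitpos = i * width, w = bitpos >> 6, o = bitpos & 63;
        uint64_t val = words[w] >> o;
        if (o + width > 64) val |= words[w + 1] << (64 - o);
        return (uint32_t)((val & ((1ULL << width) - 1)) + 1);
    }
    uint64_t bits_total() const { return 128 + words.size() * 64; }

    void encode_stream(ByteWriter& w) const {
        w.u64(n);
        w.u8(width);
        w.u64vec(words);
    }
    static PackedVec decode(ByteReader& r) {
        PackedVec pv;
        pv.n = r.u64();
        pv.width = r.u8();
        pv.words = r.u64vec();
        return pv;
    }
};

// The LP-MPHF over an SPSS, in either the unpartitioned layout
// (fm + prefix sums L + positions P) or the partitioned layout
// (fm + type sequence R + per-type prefix sums + non-max positions).
// Codes are 0-based: the unambiguous k-mers occupy [0, n_unamb) and the
// k-mers of ambiguous minimizers occupy the tail [n_unamb, n) through the
// fallback MPHF.
struct Index {
    bool partitioned = false;
    Scheme sc{31, 21, 0};
    uint64_t n = 0;        // distinct k-mers
    uint64_t n_unamb = 0;  // k-mers covered by unambiguous minimizers
    uint64_t nM = 0;       // distinct minimizers
    Mphf fm;
    bool has_fallback = false;
    Mphf fallback;

    // unpartitioned layout
    EliasFano L;    // nM + 1 prefix sums of slot sizes in fm order
    PackedVec P;    // nM first-k-mer minimizer positions (filler w for ambiguous)

    // partitioned layout
    Wavelet4 R;             // slot types in fm order (ambiguous slots typed right-max)
    EliasFano Ll, Lr, Ln;   // per-type prefix sums (leading 0 entry each)
    PackedVec Pn;           // first-k-mer positions of non-max slots
    uint64_t Nlr = 0, Nl = 0, Nr = 0, Nn = 0;           // k-mer totals per partition
    uint64_t c_lr = 0, c_l = 0, c_r = 0, c_n = 0;       // slot counts per type

    static const int64_t NOT_FOUND = -1;

    static Index build(const std::vector<std::string>& strings, const Scheme& sc,
                       bool partitioned);

    // Lookup of a single k-mer whose minimizer is already resolved:
    // mu = minimizer m-mer, p = its 1-based position in the k-mer.
    // The k-mer string itself is needed only for the fallback path.
    int64_t lookup_resolved(const char* kmer, const std::string& mu, int p,
                            bool strict) const {
        uint64_t i = fm.eval(mu);
        if (i >= nM) return wrap(NOT_FOUND, strict); // alien minimizer beyond slots
        if (!partitioned) {
            uint64_t lo = L.access(i), hi = L.access(i + 1);
            uint64_t size = hi - lo;
            if (size == 0) return fallback_code(kmer);
            int p1 = (int)P.get(i);
            if (strict) {
                int r = p1 - p + 1;
                if (r < 1 || r > (int)size) return NOT_FOUND;
            }
            return wrap((int64_t)lo + p1 - p, strict);
        }
        uint8_t t = R.access(i);
        uint64_t j = R.rank(t, i + 1); // 1-based rank of slot i among type t
        int64_t prefix, offset;
        int p1;
        int w = sc.w();
        uint64_t size;
        switch (t) {
        case FL_LEFT_RIGHT_MAX:
            prefix = 0; offset = (int64_t)(j - 1) * w; p1 = w; size = w;
            break;
        case FL_LEFT_MAX: {
            uint64_t lo = Ll.access(j - 1), hi = Ll.access(j);
            prefix = (int64_t)Nlr; offset = (int64_t)lo; size = hi - lo; p1 = (int)size;
            break;
        }
        case FL_RIGHT_MAX: {
            uint64_t lo = Lr.access(j - 1), hi = Lr.access(j);
            size = hi - lo;
            if (size == 0) return fallback_code(kmer); // ambiguous minimizer sentinel
            prefix = (int64_t)(Nlr + Nl); offset = (int64_t)lo; p1 = w;
            break;
        }
        default: { // FL_NON_MAX
            uint64_t lo = Ln.access(j - 1), hi = Ln.access(j);
            prefix = (int64_t)(Nlr + Nl + Nr); offset = (int64_t)lo; size = hi - lo;
            p1 = (int)Pn.get(j - 1);
            break;
        }
        }
        if (strict) {
            int r = p1 - p + 1;
            if (r < 1 || r > (int)size) return NOT_FOUND;
        }
        return wrap(prefix + offset + p1 - p, strict);
    }

    int64_t lookup(const std::string& kmer, bool strict) const {
        if ((int)kmer.size() != sc.k)
            throw std::runtime_error("query k-mer has length " + std::to_string(kmer.size()) +
                                     " but the index was built with k = " + std::to_string(sc.k));
        check_acgt(kmer, "query k-mer");
        // leftmost minimal m-mer of the k-mer
        uint64_t best = 0;
        int bpos = 0;
        for (int j = 0; j < sc.w(); ++j) {
            uint64_t h = murmur64(kmer.data() + j, sc.m, sc.seed);
            if (j == 0 || h < best) { best = h; bpos = j; }
        }
        return lookup_resolved(kmer.data(), kmer.substr(bpos, sc.m), bpos + 1, strict);
    }

    // Streaming lookup: one code per k-mer of the sequence.  The minimizer
    // occurrence is tracked with a sliding window; while it is unchanged the
    // slot is not re-resolved and consecutive codes are produced directly
    // (identical arithmetic to per-k-mer lookup, hence elementwise equal).
    std::vector<int64_t> stream(const std::string& seq, bool strict) const {
        check_acgt(seq, "query sequence");
        std::vector<MinHit> hits = streaming_minimizers(seq, sc);
        std::vector<int64_t> out;
        out.reserve(hits.size());
        uint64_t run_start = 0;
        for (uint64_t i = 1; i <= hits.size(); ++i) {
            if (i == hits.size() || hits[i].abs_pos != hits[run_start].abs_pos) {
                uint64_t q = hits[run_start].abs_pos;
                std::string mu = seq.substr(q, sc.m);
                for (uint64_t t = run_start; t < i; ++t) {
                    int p = (int)(q - t + 1); // 1-based minimizer position in k-mer t
                    out.push_back(lookup_resolved(seq.data() + t, mu, p, strict));
                }
                run_start = i;
            }
        }
        return out;
    }

    uint64_t bits_fm() const { return fm.bits_total(); }
    uint64_t bits_fallback() const { return has_fallback ? fallback.bits_total() : 0; }
    uint64_t bits_main() const {
        if (!partitioned) return L.bits_total() + P.bits_total();
        return R.bits_total() + Ll.bits_total() + Lr.bits_total() + Ln.bits_total() +
               Pn.bits_total() + 4 * 64;
    }
    uint64_t bits_total() const { return 512 + bits_fm() + bits_fallback() + bits_main(); }

    void encode_stream(ByteWriter& w) const {
        w.bytes("LPMH", 4);
        w.u16(1); // format version
        w.u8(partitioned ? 1 : 0);
        w.u32((uint32_t)sc.k);
        w.u32((uint32_t)sc.m);
        w.u64(sc.seed);
        w.u64(n);
        w.u64(n_unamb);
        w.u64(nM);
        fm.encode_stream(w);
        w.u8(has_fallback ? 1 : 0);
        if (has_fallback) fallback.encode_stream(w);
        if (!partitioned) {
            L.encode_stream(w);
            P.encode_stream(w);
        } else {
            R.encode_stream(w);
            Ll.encode_stream(w);
            Lr.encode_stream(w);
            Ln.encode_stream(w);
            Pn.encode_stream(w);
            w.u64(Nlr); w.u64(Nl); w.u64(Nr); w.u64(Nn);
            w.u64(c_lr); w.u64(c_l); w.u64(c_r); w.u64(c_n);
        }
    }

    static Index decode(ByteReader& r) {
        Index ix;
        char magic[4];
        r.need(4);
        for (int i = 0; i < 4; ++i) magic[i] = (char)r.u8();
        if (magic[0] != 'L' || magic[1] != 'P' || magic[2] != 'M' || magic[3] != 'H')
            throw std::runtime_error("bad magic bytes at offset 0: not an LP-MPHF index");
        uint16_t version = r.u16();
        if (version != 1)
            throw std::runtime_error("unsupported index format version " +
                                     std::to_string(version) + " at offset 4");
        ix.partitioned = r.u8() != 0;
        ix.sc.k = (int)r.u32();
        ix.sc.m = (int)r.u32();
        ix.sc.seed = r.u64();
        ix.n = r.u64();
        ix.n_unamb = r.u64();
        ix.nM = r.u64();
        ix.fm = Mphf::decode(r);
        ix.has_fallback = r.u8() != 0;
        if (ix.has_fallback) ix.fallback = Mphf::decode(r);
        if (!ix.partitioned) {
            ix.L = EliasFano::decode(r);
            ix.P = PackedVec::decode(r);
        } else {
            ix.R = Wavelet4::decode(r);
            ix.Ll = EliasFano::decode(r);
            ix.Lr = EliasFano::decode(r);
            ix.Ln = EliasFano::decode(r);
            ix.Pn = PackedVec::decode(r);
            ix.Nlr = r.u64(); ix.Nl = r.u64(); ix.Nr = r.u64(); ix.Nn = r.u64();
            ix.c_lr = r.u64(); ix.c_l = r.u64(); ix.c_r = r.u64(); ix.c_n = r.u64();
        }
        return ix;
    }

private:
    int64_t fallback_code(const char* kmer) const {
        if (!has_fallback) return 0; // cannot happen for indexed k-mers
        return (int64_t)(n_unamb + fallback.eval(std::string(kmer, (size_t)sc.k)));
    }
    // Alien k-mers may produce codes outside [0, n); fold them back so the
    // non-strict contract (arbitrary but deterministic in-range value) holds.
    int64_t wrap(int64_t code, bool strict) const {
        if (code >= 0 && (uint64_t)code < n) return code;
        if (strict) return NOT_FOUND;
        int64_t nn = (int64_t)n;
        return ((code % nn) + nn) % nn;
    }
};

} // namespace lpmphf

#endif
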