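#include "index.h"

namespace lpmphf {

// Seed diversifiers so that fm, the fallback MPHF and the minimizer hash h
// are pairwise-independent functions of the one user-supplied seed.
static const uint64_t FM_SEED_TAG = 0x66D1A5E0C0FFEE01ULL;
static const uint64_t FB_SEED_TAG = 0xFA11BACC0FFEE002ULL;

Index Index::build(const std::vector<std::string>& strings, const Scheme& sc,
                   bool partitioned) {
    if (strings.empty()) throw std::runtime_error("SPSS is empty");
    const int k = sc.k, m = sc.m, w = sc.w();
    if (m < 1 || m > k) throw std::runtime_error("scheme requires 1 <= m <= k");

    Index ix;
    ix.partitioned = partitioned;
    ix.sc = sc;

    // Pass 1: decompose every string into super-k-mers.
    struct Rec {
        uint32_t sid;
        uint64_t kmer_start;
        uint32_t size;
        uint32_t p_first;
    };
    std::vector<Rec> recs;
    std::vector<std::string> rec_min; // minimizer m-mer per super-k-mer
    uint64_t n = 0;
    for (size_t s = 0; s < strings.size(); ++s) {
        const std::string& S = strings[s];
        if ((int)S.size() < k)
            throw std::runtime_error("SPSS string " + std::to_string(s + 1) +
                                     " is shorter than k");
        n += S.size() - k + 1;
        std::vector<SuperKmer> sks = decompose(S, s, sc);
        for (const SuperKmer& g : sks) {
            recs.push_back({(uint32_t)s, g.kmer_start, (uint32_t)g.size, (uint32_t)g.p_first});
            rec_min.push_back(S.substr(g.min_pos, m));
        }
    }
    ix.n = n;

    // Group super-k-mers by minimizer value; |G_mu| > 1 means mu is ambiguous.
    struct Grp { uint32_t count; uint64_t rec; };
    std::unordered_map<std::string, Grp> grp;
    grp.reserve(recs.size() * 2);
    std::vector<std::string> distinct;
    distinct.reserve(recs.size());
    for (uint64_t i = 0; i < recs.size(); ++i) {
        auto it = grp.find(rec_min[i]);
        if (it == grp.end()) {
            grp.emplace(rec_min[i], Grp{1, i});
            distinct.push_back(rec_min[i]);
        } else {
            ++it->second.count;
        }
    }
    ix.nM = distinct.size();
    ix.fm = Mphf::build(distinct, splitmix64(sc.seed ^ FM_SEED_TAG));

    // Slot arrays in fm order.
    std::vector<uint32_t> slot_size(ix.nM), slot_p(ix.nM);
    std::vector<uint8_t> slot_type(ix.nM);
    for (const std::string& mu : distinct) {
        uint64_t i = ix.fm.eval(mu);
        const Grp& g = grp[mu];
        if (g.count == 1) {
            const Rec& r = recs[g.rec];
            slot_size[i] = r.size;
            slot_p[i] = r.p_first;
            slot_type[i] = (uint8_t)classify_fl((int)r.p_first,
                                                (int)r.p_first - (int)r.size + 1, w);
        } else {
            // ambiguous: size-0 sentinel, typed right-max, filler position w
            slot_size[i] = 0;
            slot_p[i] = (uint32_t)w;
            slot_type[i] = FL_RIGHT_MAX;
        }
    }

    // Fallback keys: every k-mer of every super-k-mer of an ambiguous minimizer.
    std::vector<std::string> fb;
    for (uint64_t i = 0; i < recs.size(); ++i) {
        if (grp[rec_min[i]].count > 1) {
            const Rec& r = recs[i];
            for (uint32_t t = 0; t < r.size; ++t)
                fb.push_back(strings[r.sid].substr(r.kmer_start + t, k));
        }
    }
    ix.n_unamb = n - fb.size();
    ix.has_fallback = !fb.empty();
    if (ix.has_fallback)
        ix.fallback = Mphf::build(fb, splitmix64(sc.seed ^ FB_SEED_TAG));

    if (!partitioned) {
        std::vector<uint64_t> L(ix.nM + 1, 0);
        for (uint64_t i = 0; i < ix.nM; ++i) L[i + 1] = L[i] + slot_size[i];
        ix.L = EliasFano::encode(L);
        ix.P = PackedVec::pack(slot_p, (uint32_t)w);
        return ix;
    }

    // Partitioned layout: per-type prefix sums in fm order.
    std::vector<uint8_t> types(slot_type.begin(), slot_type.end());
    ix.R = Wavelet4::build(types);
    std::vector<uint64_t> ll{0}, lr{0}, ln{0};
    std::vector<uint32_t> pn;
    for (uint64_t i = 0; i < ix.nM; ++i) {
        switch (slot_type[i]) {
        case FL_LEFT_RIGHT_MAX: ++ix.c_lr; break;
        case FL_LEFT_MAX:
            ++ix.c_l;
            ll.push_back(ll.back() + slot_size[i]);
            break;
        case FL_RIGHT_MAX:
            ++ix.c_r;
            lr.push_back(lr.back() + slot_size[i]); // ambiguous slots add 0
            break;
        default:
            ++ix.c_n;
            ln.push_back(ln.back() + slot_size[i]);
            pn.push_back(slot_p[i]);
            break;
        }
    }
    ix.Nlr = (uint64_t)w * ix.c_lr;
    ix.Nl = ll.back();
    ix.Nr = lr.back();
    ix.Nn = ln.back();
    if (ix.Nlr + ix.Nl + ix.Nr + ix.Nn != ix.n_unamb)
        throw std::runtime_error("internal error: partition k-mer totals do not sum to n_unamb");
    ix.Ll = EliasFano::encode(ll);
    ix.Lr = EliasFano::encode(lr);
    ix.Ln = EliasFano::encode(ln);
    ix.Pn = PackedVec::pack(pn, (uint32_t)w);
    return ix;
}

} // namespace lpmphf
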