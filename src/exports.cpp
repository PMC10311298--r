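#include <Rcpp.h>

#include <random>
#include <unordered_map>

#include "index.h"

using namespace Rcpp;
using namespace lpmphf;

static uint64_t as_seed(double s) {
    if (s < 0) throw std::runtime_error("seed must be non-negative");
    return (uint64_t)s;
}

static RawVector to_raw(const ByteWriter& w) {
    RawVector out(w.buf.size());
    std::copy(w.buf.begin(), w.buf.end(), out.begin());
    return out;
}

static ByteReader reader(const RawVector& r) {
    return ByteReader((const uint8_t*)RAW(r), (size_t)r.size());
}

static std::vector<std::string> to_strings(const CharacterVector& x) {
    std::vector<std::string> v;
    v.reserve(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) v.push_back(as<std::string>(x[i]));
    return v;
}

// ---------------------------------------------------------------- hashing

// [[Rcpp::export]]
CharacterVector cpp_mmer_hash(CharacterVector mmers, double seed) {
    uint64_t s = as_seed(seed);
    CharacterVector out(mmers.size());
    for (R_xlen_t i = 0; i < mmers.size(); ++i) {
        std::string mm = as<std::string>(mmers[i]);
        out[i] = hash_hex(hash_str(mm, s));
    }
    return out;
}

// ------------------------------------------------------------- minimizers

static void check_kmer(const std::string& x, int k) {
    if ((int)x.size() != k)
        throw std::runtime_error("k-mer has length " + std::to_string(x.size()) +
                                 ", expected k = " + std::to_string(k));
    check_acgt(x, "k-mer");
}

// [[Rcpp::export]]
List cpp_minimizer_of_kmer(CharacterVector kmers, int k, int m, double seed) {
    Scheme sc{k, m, as_seed(seed)};
    R_xlen_t nk = kmers.size();
    CharacterVector mmer(nk), hash(nk);
    IntegerVector pos(nk);
    for (R_xlen_t i = 0; i < nk; ++i) {
        std::string x = as<std::string>(kmers[i]);
        check_kmer(x, k);
        uint64_t best = 0;
        int bpos = 0;
        for (int j = 0; j < sc.w(); ++j) {
            uint64_t h = murmur64(x.data() + j, m, sc.seed);
            if (j == 0 || h < best) { best = h; bpos = j; }
        }
        mmer[i] = x.substr(bpos, m);
        pos[i] = bpos + 1;
        hash[i] = hash_hex(best);
    }
    return List::create(_["mmer"] = mmer, _["pos"] = pos, _["hash"] = hash);
}

// [[Rcpp::export]]
List cpp_streaming_minimizers(std::string seq, int k, int m, double seed) {
    Scheme sc{k, m, as_seed(seed)};
    check_acgt(seq, "sequence");
    std::vector<MinHit> hits = streaming_minimizers(seq, sc);
    R_xlen_t nk = hits.size();
    CharacterVector mmer(nk), hash(nk);
    IntegerVector pos(nk), abs_pos(nk);
    for (R_xlen_t i = 0; i < nk; ++i) {
        mmer[i] = seq.substr(hits[i].abs_pos, m);
        pos[i] = (int)(hits[i].abs_pos - i + 1);
        abs_pos[i] = (int)hits[i].abs_pos;
        hash[i] = hash_hex(hits[i].hash);
    }
    return List::create(_["mmer"] = mmer, _["pos"] = pos, _["absPos"] = abs_pos,
                        _["hash"] = hash);
}

// [[Rcpp::export]]
List cpp_superkmers(std::string seq, double string_id, int k, int m, double seed) {
    Scheme sc{k, m, as_seed(seed)};
    check_acgt(seq, "sequence");
    std::vector<SuperKmer> sks = decompose(seq, (uint64_t)string_id, sc);
    R_xlen_t ng = sks.size();
    NumericVector start(ng);
    IntegerVector length(ng), size(ng), p_first(ng), p_last(ng), fl(ng);
    CharacterVector minimizer(ng);
    for (R_xlen_t i = 0; i < ng; ++i) {
        const SuperKmer& g = sks[i];
        start[i] = (double)g.start;
        length[i] = g.size + k - 1;
        size[i] = g.size;
        p_first[i] = g.p_first;
        p_last[i] = g.p_last;
        fl[i] = g.fl_type;
        minimizer[i] = seq.substr(g.min_pos, m);
    }
    return List::create(_["start"] = start, _["length"] = length, _["size"] = size,
                        _["minimizer"] = minimizer, _["pFirst"] = p_first,
                        _["pLast"] = p_last, _["flType"] = fl);
}

// ---------------------------------------------------------------- succinct

// [[Rcpp::export]]
RawVector cpp_bv_build(IntegerVector bits) {
    BitVec bv((uint64_t)bits.size());
    for (R_xlen_t i = 0; i < bits.size(); ++i) {
        int b = bits[i];
        if (b != 0 && b != 1) throw std::runtime_error("bitvector input must be 0/1");
        if (b) bv.set((uint64_t)i);
    }
    bv.finish();
    ByteWriter w;
    bv.encode(w);
    return to_raw(w);
}

// [[Rcpp::export]]
NumericVector cpp_bv_rank1(RawVector bytes, NumericVector i) {
    ByteReader r = reader(bytes);
    BitVec bv = BitVec::decode(r);
    NumericVector out(i.size());
    for (R_xlen_t j = 0; j < i.size(); ++j) {
        double ii = i[j];
        if (ii < 0 || ii > (double)bv.n)
            throw std::runtime_error("rank position out of range [0, " +
                                     std::to_string(bv.n) + "]");
        out[j] = (double)bv.rank1((uint64_t)ii);
    }
    return out;
}

// [[Rcpp::export]]
List cpp_bv_info(RawVector bytes) {
    ByteReader r = reader(bytes);
    BitVec bv = BitVec::decode(r);
    return List::create(_["n"] = (double)bv.n, _["ones"] = (double)bv.ones(),
                        _["bitsPayload"] = (double)bv.bits_payload(),
                        _["bitsOverhead"] = (double)bv.bits_overhead(),
                        _["bitsTotal"] = (double)bv.bits_total());
}

// [[Rcpp::export]]
RawVector cpp_ef_encode(NumericVector values) {
    std::vector<uint64_t> v;
    v.reserve(values.size());
    for (R_xlen_t i = 0; i < values.size(); ++i) {
        if (values[i] < 0) throw std::runtime_error("Elias-Fano values must be non-negative");
        v.push_back((uint64_t)values[i]);
    }
    EliasFano ef = EliasFano::encode(v);
    ByteWriter w;
    ef.encode_stream(w);
    return to_raw(w);
}

// [[Rcpp::export]]
NumericVector cpp_ef_access(RawVector bytes, NumericVector i0) {
    ByteReader r = reader(bytes);
    EliasFano ef = EliasFano::decode(r);
    NumericVector out(i0.size());
    for (R_xlen_t j = 0; j < i0.size(); ++j)
        out[j] = (double)ef.access((uint64_t)i0[j]);
    return out;
}

// [[Rcpp::export]]
List cpp_ef_info(RawVector bytes) {
    ByteReader r = reader(bytes);
    EliasFano ef = EliasFano::decode(r);
    return List::create(_["n"] = (double)ef.n, _["universe"] = (double)ef.universe,
                        _["lowWidth"] = (int)ef.l, _["bitsTotal"] = (double)ef.bits_total());
}

// [[Rcpp::export]]
RawVector cpp_wt_build(IntegerVector syms) {
    std::vector<uint8_t> v;
    v.reserve(syms.size());
    for (R_xlen_t i = 0; i < syms.size(); ++i) {
        if (syms[i] < 0 || syms[i] > 3)
            throw std::runtime_error("wavelet tree symbol out of {0,1,2,3} at element " +
                                     std::to_string(i + 1));
        v.push_back((uint8_t)syms[i]);
    }
    Wavelet4 wt = Wavelet4::build(v);
    ByteWriter w;
    wt.encode_stream(w);
    return to_raw(w);
}

// [[Rcpp::export]]
IntegerVector cpp_wt_access(RawVector bytes, NumericVector i0) {
    ByteReader r = reader(bytes);
    Wavelet4 wt = Wavelet4::decode(r);
    IntegerVector out(i0.size());
    for (R_xlen_t j = 0; j < i0.size(); ++j)
        out[j] = (int)wt.access((uint64_t)i0[j]);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_wt_rank(RawVector bytes, IntegerVector t, NumericVector i) {
    ByteReader r = reader(bytes);
    Wavelet4 wt = Wavelet4::decode(r);
    if (t.size() != i.size()) throw std::runtime_error("t and i must have equal length");
    NumericVector out(i.size());
    for (R_xlen_t j = 0; j < i.size(); ++j)
        out[j] = (double)wt.rank((uint8_t)t[j], (uint64_t)i[j]);
    return out;
}

// [[Rcpp::export]]
List cpp_wt_info(RawVector bytes) {
    ByteReader r = reader(bytes);
    Wavelet4 wt = Wavelet4::decode(r);
    return List::create(_["n"] = (double)wt.n, _["bitsPayload"] = (double)wt.bits_payload(),
                        _["bitsTotal"] = (double)wt.bits_total());
}

// -------------------------------------------------------------------- MPHF

// [[Rcpp::export]]
RawVector cpp_mphf_build(CharacterVector keys, double seed, double gamma) {
    Mphf f = Mphf::build(to_strings(keys), as_seed(seed), gamma);
    ByteWriter w;
    f.encode_stream(w);
    return to_raw(w);
}

// [[Rcpp::export]]
NumericVector cpp_mphf_eval(RawVector bytes, CharacterVector keys) {
    ByteReader r = reader(bytes);
    Mphf f = Mphf::decode(r);
    NumericVector out(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i)
        out[i] = (double)f.eval(as<std::string>(keys[i]));
    return out;
}

// [[Rcpp::export]]
List cpp_mphf_info(RawVector bytes) {
    ByteReader r = reader(bytes);
    Mphf f = Mphf::decode(r);
    return List::create(_["n"] = (double)f.n, _["nLevels"] = (double)f.levels.size(),
                        _["nRemainder"] = (double)f.rem_keys.size(),
                        _["gamma"] = f.gamma, _["bitsTotal"] = (double)f.bits_total(),
                        _["bitsPerKey"] = f.bits_per_key());
}

// ------------------------------------------------------------------- index

// [[Rcpp::export]]
RawVector cpp_index_build(CharacterVector strings, int k, int m, double seed,
                          bool partitioned) {
    Scheme sc{k, m, as_seed(seed)};
    Index ix = Index::build(to_strings(strings), sc, partitioned);
    ByteWriter w;
    ix.encode_stream(w);
    return to_raw(w);
}

// [[Rcpp::export]]
List cpp_index_info(RawVector bytes) {
    ByteReader r = reader(bytes);
    Index ix = Index::decode(r);
    List space = List::create(
        _["fm"] = (double)ix.bits_fm(), _["fallback"] = (double)ix.bits_fallback(),
        _["main"] = (double)ix.bits_main(), _["total"] = (double)ix.bits_total());
    return List::create(
        _["layout"] = ix.partitioned ? "partitioned" : "unpartitioned",
        _["k"] = ix.sc.k, _["m"] = ix.sc.m, _["w"] = ix.sc.w(),
        _["seed"] = (double)ix.sc.seed, _["n"] = (double)ix.n,
        _["nUnambiguous"] = (double)ix.n_unamb,
        _["nFallback"] = (double)(ix.n - ix.n_unamb),
        _["nMinimizers"] = (double)ix.nM,
        _["kmerTotals"] = NumericVector::create(
            _["lr"] = (double)ix.Nlr, _["l"] = (double)ix.Nl,
            _["r"] = (double)ix.Nr, _["n"] = (double)ix.Nn),
        _["slotCounts"] = NumericVector::create(
            _["lr"] = (double)ix.c_lr, _["l"] = (double)ix.c_l,
            _["r"] = (double)ix.c_r, _["n"] = (double)ix.c_n),
        _["bits"] = space,
        _["bitsPerKmer"] = (double)ix.bits_total() / (double)ix.n);
}

// Decoded slot arrays, for white-box checks of the layout invariants.
// [[Rcpp::export]]
List cpp_index_components(RawVector bytes) {
    ByteReader r = reader(bytes);
    Index ix = Index::decode(r);
    if (!ix.partitioned) {
        NumericVector L(ix.nM + 1);
        IntegerVector P(ix.nM);
        for (uint64_t i = 0; i <= ix.nM; ++i) L[i] = (double)ix.L.access(i);
        for (uint64_t i = 0; i < ix.nM; ++i) P[i] = (int)ix.P.get(i);
        return List::create(_["L"] = L, _["P"] = P);
    }
    IntegerVector types(ix.nM);
    for (uint64_t i = 0; i < ix.nM; ++i) types[i] = (int)ix.R.access(i);
    NumericVector ll(ix.c_l + 1), lr(ix.c_r + 1), ln(ix.c_n + 1);
    IntegerVector pn(ix.c_n);
    for (uint64_t i = 0; i <= ix.c_l; ++i) ll[i] = (double)ix.Ll.access(i);
    for (uint64_t i = 0; i <= ix.c_r; ++i) lr[i] = (double)ix.Lr.access(i);
    for (uint64_t i = 0; i <= ix.c_n; ++i) ln[i] = (double)ix.Ln.access(i);
    for (uint64_t i = 0; i < ix.c_n; ++i) pn[i] = (int)ix.Pn.get(i);
    return List::create(_["types"] = types, _["Ll"] = ll, _["Lr"] = lr, _["Ln"] = ln,
                        _["Pn"] = pn);
}

// [[Rcpp::export]]
NumericVector cpp_index_lookup(RawVector bytes, CharacterVector kmers, bool strict) {
    ByteReader r = reader(bytes);
    Index ix = Index::decode(r);
    NumericVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        int64_t c = ix.lookup(as<std::string>(kmers[i]), strict);
        out[i] = (c == Index::NOT_FOUND) ? NA_REAL : (double)c;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_index_stream(RawVector bytes, CharacterVector seqs, bool strict) {
    ByteReader r = reader(bytes);
    Index ix = Index::decode(r);
    List out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::vector<int64_t> codes = ix.stream(as<std::string>(seqs[i]), strict);
        NumericVector v(codes.size());
        for (size_t j = 0; j < codes.size(); ++j)
            v[j] = (codes[j] == Index::NOT_FOUND) ? NA_REAL : (double)codes[j];
        out[i] = v;
    }
    return out;
}

// Locality defect: fraction of consecutive in-string k-mer pairs that do NOT
// receive consecutive codes.
// [[Rcpp::export]]
List cpp_measure_epsilon(RawVector bytes, CharacterVector seqs) {
    ByteReader r = reader(bytes);
    Index ix = Index::decode(r);
    uint64_t n = 0, a = 0;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::vector<int64_t> codes = ix.stream(as<std::string>(seqs[i]), false);
        n += codes.size();
        for (size_t j = 1; j < codes.size(); ++j)
            if (codes[j] == codes[j - 1] + 1) ++a;
    }
    if (n != ix.n)
        throw std::runtime_error("SPSS has " + std::to_string(n) +
                                 " k-mers but the index was built over " +
                                 std::to_string(ix.n));
    return List::create(_["n"] = (double)n, _["nConsecutive"] = (double)a,
                        _["epsilon"] = 1.0 - (double)a / (double)n);
}

// ------------------------------------------------------------- measurement

// [[Rcpp::export]]
List cpp_measure_scheme(CharacterVector strings, int k, int m, double seed) {
    Scheme sc{k, m, as_seed(seed)};
    std::vector<std::string> S = to_strings(strings);
    if (S.empty()) throw std::runtime_error("SPSS is empty");
    struct Grp { uint32_t count; };
    std::unordered_map<std::string, uint32_t> grp;
    std::vector<std::string> rec_min;
    std::vector<uint32_t> rec_size;
    std::vector<uint8_t> rec_type;
    uint64_t n = 0;
    for (size_t s = 0; s < S.size(); ++s) {
        if ((int)S[s].size() < k)
            throw std::runtime_error("SPSS string " + std::to_string(s + 1) +
                                     " is shorter than k");
        n += S[s].size() - k + 1;
        std::vector<SuperKmer> sks = decompose(S[s], s, sc);
        for (const SuperKmer& g : sks) {
            rec_min.push_back(S[s].substr(g.min_pos, m));
            rec_size.push_back((uint32_t)g.size);
            rec_type.push_back((uint8_t)g.fl_type);
            ++grp[rec_min.back()];
        }
    }
    uint64_t n_sk = rec_min.size();
    uint64_t amb_min = 0;
    for (const auto& kv : grp) if (kv.second > 1) ++amb_min;
    uint64_t amb_sk = 0, amb_kmers = 0;
    NumericVector type_counts(4);
    for (uint64_t i = 0; i < n_sk; ++i) {
        if (grp[rec_min[i]] > 1) {
            ++amb_sk;
            amb_kmers += rec_size[i];
        } else {
            type_counts[rec_type[i]] += 1;
        }
    }
    type_counts.attr("names") = CharacterVector::create("lr", "l", "r", "n");
    return List::create(
        _["n"] = (double)n, _["nStrings"] = (double)S.size(),
        _["nSuperKmers"] = (double)n_sk,
        _["nMinimizers"] = (double)grp.size(),
        _["nAmbiguousMinimizers"] = (double)amb_min,
        _["nAmbiguousSuperKmers"] = (double)amb_sk,
        _["nAmbiguousKmers"] = (double)amb_kmers,
        _["xi"] = (double)amb_kmers / (double)n,
        _["alpha"] = (double)(S.size() - 1) / (double)n,
        _["density"] = (double)n_sk / (double)n,
        _["typeCounts"] = type_counts);
}

// -------------------------------------------------------------------- SPSS

// [[Rcpp::export]]
List cpp_spss_validate(CharacterVector strings, int k) {
    std::vector<std::string> S = to_strings(strings);
    if (S.empty()) throw std::runtime_error("SPSS is empty");
    std::unordered_multimap<uint64_t, std::pair<uint32_t, uint64_t>> seen;
    uint64_t n = 0;
    for (size_t s = 0; s < S.size(); ++s) {
        const std::string& str = S[s];
        if ((int)str.size() < k)
            return List::create(_["ok"] = false,
                                _["message"] = "string " + std::to_string(s + 1) +
                                               " is shorter than k = " + std::to_string(k));
        try {
            check_acgt(str, ("string " + std::to_string(s + 1)).c_str());
        } catch (const std::exception& e) {
            return List::create(_["ok"] = false, _["message"] = std::string(e.what()));
        }
        uint64_t nk = str.size() - k + 1;
        n += nk;
        for (uint64_t p = 0; p < nk; ++p) {
            uint64_t h = murmur64(str.data() + p, k, 0x5B55U);
            auto range = seen.equal_range(h);
            for (auto it = range.first; it != range.second; ++it) {
                uint32_t s2 = it->second.first;
                uint64_t p2 = it->second.second;
                if (std::memcmp(S[s2].data() + p2, str.data() + p, k) == 0) {
                    return List::create(
                        _["ok"] = false,
                        _["message"] = "duplicate k-mer '" + str.substr(p, k) +
                                       "' at string " + std::to_string(s2 + 1) + " position " +
                                       std::to_string(p2 + 1) + " and string " +
                                       std::to_string(s + 1) + " position " +
                                       std::to_string(p + 1),
                        _["kmer"] = str.substr(p, k));
                }
            }
            seen.emplace(h, std::make_pair((uint32_t)s, p));
        }
    }
    return List::create(_["ok"] = true, _["n"] = (double)n);
}

// Random SPSS generator: strings of i.i.d. uniform bases, grown base by base
// under a global distinct-k-mer constraint (candidate bases are tried in
// random order; the string is re-drawn on a dead end, which for 4^k >> n
// essentially never happens).
// [[Rcpp::export]]
CharacterVector cpp_spss_synthetic(double n_target_d, int k, double n_strings_d,
                                   double seed) {
    uint64_t n_target = (uint64_t)n_target_d;
    uint64_t n_strings = (uint64_t)n_strings_d;
    if (n_strings < 1 || n_target < n_strings)
        throw std::runtime_error("need nKmers >= nStrings >= 1");
    if (2 * k < 62 && (double)n_target > std::pow(4.0, k))
        throw std::runtime_error("infeasible: more k-mers requested than 4^k distinct ones exist");
    std::mt19937_64 rng(splitmix64(as_seed(seed) ^ 0x5EED5EED5EED5EEDULL));
    static const char BASES[4] = {'A', 'C', 'G', 'T'};
    std::vector<std::string> out;
    out.reserve(n_strings);
    std::unordered_multimap<uint64_t, std::pair<uint32_t, uint64_t>> seen;
    seen.reserve(n_target * 2);
    const uint64_t KSEED = 0x5B55U;

    auto is_seen = [&](const char* kmer, const std::string& cur, uint32_t cur_sid) {
        uint64_t h = murmur64(kmer, k, KSEED);
        auto range = seen.equal_range(h);
        for (auto it = range.first; it != range.second; ++it) {
            const std::string& src = (it->second.first == cur_sid) ? cur
                                   : out[it->second.first];
            if (std::memcmp(src.data() + it->second.second, kmer, k) == 0) return true;
        }
        return false;
    };

    for (uint64_t s = 0; s < n_strings; ++s) {
        uint64_t nk = n_target / n_strings + (s < n_target % n_strings ? 1 : 0);
        uint64_t len = nk + k - 1;
        bool done = false;
        for (int attempt = 0; attempt < 1000 && !done; ++attempt) {
            std::string cur;
            cur.reserve(len);
            std::vector<uint64_t> placed; // hashes recorded for this attempt
            bool dead = false;
            while (cur.size() < len && !dead) {
                int order[4] = {0, 1, 2, 3};
                for (int i = 3; i > 0; --i) std::swap(order[i], order[(int)(rng() % (i + 1))]);
                bool ok = false;
                for (int c = 0; c < 4 && !ok; ++c) {
                    cur.push_back(BASES[order[c]]);
                    if ((int)cur.size() < k) { ok = true; break; }
                    const char* kmer = cur.data() + cur.size() - k;
                    if (!is_seen(kmer, cur, (uint32_t)s)) {
                        uint64_t h = murmur64(kmer, k, KSEED);
                        seen.emplace(h, std::make_pair((uint32_t)s, cur.size() - k));
                        placed.push_back(h);
                        ok = true;
                    } else {
                        cur.pop_back();
                    }
                }
                if (!ok) dead = true;
            }
            if (!dead) {
                out.push_back(cur);
                done = true;
            } else {
                // roll back the k-mers recorded during this failed attempt
                for (uint64_t h : placed) {
                    auto range = seen.equal_range(h);
                    for (auto it = range.first; it != range.second; ++it)
                        if (it->second.first == (uint32_t)s) { seen.erase(it); break; }
                }
            }
        }
        if (!done)
            throw std::runtime_error("could not place distinct k-mers for string " +
                                     std::to_string(s + 1) +
                                     "; the k-mer space is too saturated");
    }
    CharacterVector res(out.size());
    for (size_t i = 0; i < out.size(); ++i) res[i] = out[i];
    return res;
}

// All k-mers of the given sequences, concatenated in order.
// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(CharacterVector seqs, int k) {
    std::vector<std::string> S = to_strings(seqs);
    uint64_t total = 0;
    for (const auto& s : S) {
        if ((int)s.size() < k) throw std::runtime_error("sequence shorter than k");
        total += s.size() - k + 1;
    }
    CharacterVector out(total);
    uint64_t at = 0;
    for (const auto& s : S)
        for (uint64_t p = 0; p + k <= s.size(); ++p)
            out[at++] = s.substr(p, k);
    return out;
}
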