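#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// splitmix64 finalizer: well-mixed 64-bit hash of a 64-bit word.
static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

// Doubles represent integers exactly only up to 2^53, so hashes handed back
// to R are truncated to the low 53 bits.
static const uint64_t MASK53 = (1ULL << 53) - 1;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// [[Rcpp::export(name = ".canonical_kmer_hashes")]]
NumericVector canonical_kmer_hashes(std::string seq, int k, double seed) {
    if (k < 2 || k > 31)
        stop("k must be in [2, 31]");
    const uint64_t s = (uint64_t) seed;
    const int L = (int) seq.size();
    std::vector<uint64_t> out;
    if (L < k) return NumericVector(0);
    out.reserve(L - k + 1);

    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // run length of consecutive ACGT bases ending here
    for (int i = 0; i < L; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t) c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
        if (++valid >= k) {
            // 2-bit codes preserve lexicographic order (A<C<G<T), so the
            // smaller packed word is the lexicographically smaller strand.
            uint64_t canon = fwd < rev ? fwd : rev;
            out.push_back(splitmix64(canon ^ s) & MASK53);
        }
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
    NumericVector res(out.size());
    for (size_t i = 0; i < out.size(); ++i) res[i] = (double) out[i];
    return res;
}

// Hash explicit k-mer strings (no canonicalization): the oracle path used in
// tests to cross-check the rolling implementation above.
// [[Rcpp::export(name = ".hash_kmers")]]
NumericVector hash_kmers(CharacterVector kmers, double seed) {
    const uint64_t s = (uint64_t) seed;
    NumericVector res(kmers.size());
    for (int i = 0; i < kmers.size(); ++i) {
        std::string km = as<std::string>(kmers[i]);
        uint64_t packed = 0;
        for (size_t j = 0; j < km.size(); ++j) {
            int c = base_code(km[j]);
            if (c < 0) stop("k-mer contains a non-ACGT base");
            packed = (packed << 2) | (uint64_t) c;
        }
        res[i] = (double) (splitmix64(packed ^ s) & MASK53);
    }
    return res;
}
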