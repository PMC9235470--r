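#ifndef KTSKETCH_CORE_H
#define KTSKETCH_CORE_H

#include <cstdint>
#include <string>
#include <vector>
#include <stdexcept>

// 2-bit packed k-mers: A=0, C=1, G=2, T=3, first base in the most
// significant position so that unsigned comparison == lexicographic order.
// 128-bit words bound k at 64.
typedef unsigned __int128 u128;

static const int KTS_MAX_K = 64;

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char code_base(int c) { return "ACGT"[c & 3]; }

static inline u128 kmer_mask(int k) {
    return (k >= 64) ? ~(u128)0 : (((u128)1 << (2 * k)) - 1);
}

// returns false if any non-ACGT character
static inline bool pack_kmer(const char* s, int k, u128& out) {
    u128 x = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[i]);
        if (c < 0) return false;
        x = (x << 2) | (u128)c;
    }
    out = x;
    return true;
}

static inline std::string unpack_kmer(u128 x, int k) {
    std::string s((size_t)k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[(size_t)i] = code_base((int)(x & 3));
        x >>= 2;
    }
    return s;
}

static inline u128 revcomp_packed(u128 x, int k) {
    u128 r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (u128)(3 - (int)(x & 3));
        x >>= 2;
    }
    return r;
}

// MurmurHash3 64-bit finalizer
static inline uint64_t fmix64(uint64_t h) {
    h ^= h >> 33;
    h *= 0xff51afd7ed558ccdULL;
    h ^= h >> 33;
    h *= 0xc4ceb9fe1a85ec53ULL;
    h ^= h >> 33;
    return h;
}

// The single hash order shared by sketch construction, the classic MinHash
// baselines and the bloom prefilter (with salted seeds). Salting with k makes
// a k-mer and its own prefixes independent.
static inline uint64_t hash_packed(u128 x, int k, uint64_t seed) {
    uint64_t lo = (uint64_t)x;
    uint64_t hi = (uint64_t)(x >> 64);
    uint64_t h = seed ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(unsigned)k);
    h = fmix64(h ^ fmix64(lo + 0x8B72E1FDD8CFAE33ULL));
    h = fmix64(h ^ fmix64(hi + 0x2545F4914F6CDD1DULL));
    return h;
}

// (hash, element) total order with lexicographic tie-break
static inline bool hash_less(uint64_t ha, u128 xa, uint64_t hb, u128 xb) {
    if (ha != hb) return ha < hb;
    return xa < xb;
}

// splitmix64 / xoshiro256** for the seeded simulators (independent of R's RNG)
struct SplitMix64 {
    uint64_t s;
    explicit SplitMix64(uint64_t seed) : s(seed) {}
    uint64_t next() {
        uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
};

struct Xoshiro256 {
    uint64_t s[4];
    explicit Xoshiro256(uint64_t seed) {
        SplitMix64 sm(seed);
        for (int i = 0; i < 4; ++i) s[i] = sm.next();
    }
    static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
    uint64_t next() {
        uint64_t result = rotl(s[1] * 5, 7) * 9;
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    // uniform in [0,1)
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    // uniform integer in [0, n)
    uint64_t below(uint64_t n) {
        // unbiased rejection sampling
        uint64_t lim = UINT64_MAX - UINT64_MAX % n;
        uint64_t v;
        do { v = next(); } while (v >= lim);
        return v % n;
    }
};

// Iterate all valid k-mer windows of a sequence, maintaining packed forward
// and reverse-complement words; windows containing non-ACGT bases are
// skipped. f(fwd, rc) is called once per valid window. Returns the number of
// valid windows (callers derive the skipped count from length - k + 1).
template <typename F>
static inline long long for_each_window(const char* s, size_t n, int k, F f) {
    if ((long long)n < (long long)k) return 0;
    u128 mask = kmer_mask(k);
    u128 fwd = 0, rc = 0;
    int run = 0;
    long long valid = 0;
    int shift_rc = 2 * (k - 1);
    for (size_t i = 0; i < n; ++i) {
        int c = base_code(s[i]);
        if (c < 0) {
            run = 0; fwd = 0; rc = 0;
            continue;
        }
        fwd = ((fwd << 2) | (u128)c) & mask;
        rc = (rc >> 2) | ((u128)(3 - c) << shift_rc);
        if (++run >= k) { f(fwd, rc); ++valid; }
    }
    return valid;
}

struct U128Hash {
    size_t operator()(const u128& x) const {
        return (size_t)fmix64((uint64_t)x ^ fmix64((uint64_t)(x >> 64)));
    }
};

#endif
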