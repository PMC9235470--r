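#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include "core.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector kmers) {
    R_xlen_t n = kmers.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        std::string s = as<std::string>(kmers[i]);
        std::string r(s.size(), 'N');
        bool ok = true;
        for (size_t j = 0; j < s.size(); ++j) {
            int c = base_code(s[s.size() - 1 - j]);
            if (c < 0) { ok = false; break; }
            r[j] = code_base(3 - c);
        }
        out[i] = ok ? String(r) : NA_STRING;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_canonical")]]
CharacterVector cpp_canonical(CharacterVector kmers) {
    R_xlen_t n = kmers.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        std::string s = as<std::string>(kmers[i]);
        std::string r(s.size(), 'N');
        bool ok = true;
        for (size_t j = 0; j < s.size(); ++j) {
            int c = base_code(s[s.size() - 1 - j]);
            if (c < 0) { ok = false; break; }
            r[j] = code_base(3 - c);
        }
        if (!ok) { out[i] = NA_STRING; continue; }
        out[i] = (r < s) ? String(r) : String(s);
    }
    return out;
}

// Distinct k-mers of a sequence collection, lexicographically sorted.
// [[Rcpp::export(name = ".cpp_enumerate_kmers")]]
List cpp_enumerate_kmers(CharacterVector seqs, int k, bool canonical) {
    if (k < 1) stop("k must be >= 1");
    if (k > KTS_MAX_K) stop("k must be <= %d", KTS_MAX_K);
    std::unordered_set<u128, U128Hash> seen;
    long long total_windows = 0, valid = 0;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        size_t n = (size_t)LENGTH(STRING_ELT(seqs, i));
        if ((long long)n >= k) total_windows += (long long)n - k + 1;
        valid += for_each_window(s, n, k, [&](u128 fwd, u128 rc) {
            seen.insert(canonical ? (fwd < rc ? fwd : rc) : fwd);
        });
    }
    std::vector<u128> v(seen.begin(), seen.end());
    std::sort(v.begin(), v.end());
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = unpack_kmer(v[i], k);
    return List::create(_["kmers"] = out,
                        _["n_windows"] = (double)total_windows,
                        _["n_skipped"] = (double)(total_windows - valid));
}

// Exact |A^k| for several k in one call over the in-memory records.
// [[Rcpp::export(name = ".cpp_exact_cardinalities")]]
NumericVector cpp_exact_cardinalities(CharacterVector seqs, IntegerVector ks,
                                      bool canonical) {
    NumericVector out(ks.size());
    for (R_xlen_t j = 0; j < ks.size(); ++j) {
        int k = ks[j];
        if (k < 1) stop("k must be >= 1");
        if (k > KTS_MAX_K) stop("k must be <= %d", KTS_MAX_K);
        std::unordered_set<u128, U128Hash> seen;
        for (R_xlen_t i = 0; i < seqs.size(); ++i) {
            const char* s = CHAR(STRING_ELT(seqs, i));
            size_t n = (size_t)LENGTH(STRING_ELT(seqs, i));
            for_each_window(s, n, k, [&](u128 fwd, u128 rc) {
                seen.insert(canonical ? (fwd < rc ? fwd : rc) : fwd);
            });
        }
        out[j] = (double)seen.size();
    }
    return out;
}

// 64-bit hash of each k-mer under the given seed, as fixed-width hex strings
// (lexicographic order of the hex equals numeric order of the hash).
// [[Rcpp::export(name = ".cpp_hash_kmers")]]
CharacterVector cpp_hash_kmers(CharacterVector kmers, double seed) {
    uint64_t sd = (uint64_t)(int64_t)seed;
    R_xlen_t n = kmers.size();
    CharacterVector out(n);
    char buf[17];
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        if (s.empty()) stop("k-mer %d is empty", (int)(i + 1));
        if ((int)s.size() > KTS_MAX_K)
            stop("k-mer length must be <= %d", KTS_MAX_K);
        u128 x;
        if (!pack_kmer(s.c_str(), (int)s.size(), x))
            stop("k-mer %d contains a non-ACGT character", (int)(i + 1));
        snprintf(buf, sizeof(buf), "%016llx",
                 (unsigned long long)hash_packed(x, (int)s.size(), sd));
        out[i] = buf;
    }
    return out;
}

// Index (1-based) of the hash-argmin of a fixed k-mer set for each of
// n_seeds consecutive seeds starting at seed0. Ties broken lexicographically.
// [[Rcpp::export(name = ".cpp_argmin_per_seed")]]
IntegerVector cpp_argmin_per_seed(CharacterVector kmers, int n_seeds,
                                  double seed0) {
    R_xlen_t n = kmers.size();
    if (n == 0) stop("empty k-mer set");
    int k = (int)LENGTH(STRING_ELT(kmers, 0));
    std::vector<u128> packed((size_t)n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        if ((int)s.size() != k) stop("k-mers must share one length");
        if (!pack_kmer(s.c_str(), k, packed[(size_t)i]))
            stop("k-mer %d contains a non-ACGT character", (int)(i + 1));
    }
    IntegerVector out(n_seeds);
    for (int t = 0; t < n_seeds; ++t) {
        uint64_t sd = (uint64_t)(int64_t)seed0 + (uint64_t)t;
        uint64_t best_h = 0; u128 best_x = 0; int best_i = -1;
        for (R_xlen_t i = 0; i < n; ++i) {
            uint64_t h = hash_packed(packed[(size_t)i], k, sd);
            if (best_i < 0 || hash_less(h, packed[(size_t)i], best_h, best_x)) {
                best_h = h; best_x = packed[(size_t)i]; best_i = (int)i;
            }
        }
        out[t] = best_i + 1;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_xptr_dead")]]
bool cpp_xptr_dead(SEXP p) {
    return TYPEOF(p) != EXTPTRSXP || R_ExternalPtrAddr(p) == NULL;
}
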