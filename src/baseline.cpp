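#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "core.h"

using namespace Rcpp;

static std::vector<u128> pack_all(CharacterVector kmers, int k,
                                  const char* what) {
    std::vector<u128> v((size_t)kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        if (LENGTH(STRING_ELT(kmers, i)) != k)
            stop("%s: element %d does not have length %d", what,
                 (int)(i + 1), k);
        if (!pack_kmer(CHAR(STRING_ELT(kmers, i)), k, v[(size_t)i]))
            stop("%s: element %d contains a non-ACGT character", what,
                 (int)(i + 1));
    }
    return v;
}

// Classic streaming containment at a single fixed k: for each dataset's
// fresh bottom-m sketch (elements given), count how many distinct sketch
// elements occur among the query k-mers (canonicalized when canonical=TRUE).
// [[Rcpp::export(name = ".cpp_containment_baseline_multi")]]
IntegerVector cpp_containment_baseline_multi(List sketch_elements,
                                             CharacterVector query_seqs,
                                             int k, bool canonical) {
    int nd = sketch_elements.size();
    std::unordered_map<u128, int32_t, U128Hash> elem_id; // distinct element -> slot
    std::vector<std::vector<int32_t> > owners;           // slot -> datasets
    std::vector<std::vector<int32_t> > per_dataset_slots((size_t)nd);
    for (int d = 0; d < nd; ++d) {
        CharacterVector el = sketch_elements[d];
        std::vector<u128> v = pack_all(el, k, "sketch element");
        for (size_t i = 0; i < v.size(); ++i) {
            std::unordered_map<u128, int32_t, U128Hash>::iterator it =
                elem_id.find(v[i]);
            int32_t slot;
            if (it == elem_id.end()) {
                slot = (int32_t)owners.size();
                elem_id.insert({v[i], slot});
                owners.push_back(std::vector<int32_t>());
            } else slot = it->second;
            owners[(size_t)slot].push_back(d);
            per_dataset_slots[(size_t)d].push_back(slot);
        }
    }
    std::vector<uint8_t> found(owners.size(), 0);
    for (R_xlen_t i = 0; i < query_seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(query_seqs, i));
        size_t n = (size_t)LENGTH(STRING_ELT(query_seqs, i));
        for_each_window(s, n, k, [&](u128 fwd, u128 rc) {
            u128 key = canonical ? (fwd < rc ? fwd : rc) : fwd;
            std::unordered_map<u128, int32_t, U128Hash>::iterator it =
                elem_id.find(key);
            if (it != elem_id.end()) found[(size_t)it->second] = 1;
        });
    }
    IntegerVector out(nd);
    for (int d = 0; d < nd; ++d) {
        int c = 0;
        const std::vector<int32_t>& slots = per_dataset_slots[(size_t)d];
        for (size_t i = 0; i < slots.size(); ++i)
            if (found[(size_t)slots[i]]) ++c;
        out[d] = c;
    }
    return out;
}

// Bottom-m hash-value MinHash Jaccard estimator |S(AuB) n S(A) n S(B)| / m
// evaluated for each seed. kmersA/kmersB are the distinct k-mer sets.
// [[Rcpp::export(name = ".cpp_jaccard_baseline_seeds")]]
NumericVector cpp_jaccard_baseline_seeds(CharacterVector kmersA,
                                         CharacterVector kmersB,
                                         int k, int m,
                                         NumericVector seeds) {
    std::vector<u128> a = pack_all(kmersA, k, "A");
    std::vector<u128> b = pack_all(kmersB, k, "B");
    // union with membership flags
    std::unordered_map<u128, int, U128Hash> idx;
    std::vector<u128> u;
    std::vector<uint8_t> inA, inB;
    for (size_t i = 0; i < a.size(); ++i) {
        if (idx.insert({a[i], (int)u.size()}).second) {
            u.push_back(a[i]); inA.push_back(1); inB.push_back(0);
        }
    }
    for (size_t i = 0; i < b.size(); ++i) {
        std::unordered_map<u128, int, U128Hash>::iterator it = idx.find(b[i]);
        if (it == idx.end()) {
            idx.insert({b[i], (int)u.size()});
            u.push_back(b[i]); inA.push_back(0); inB.push_back(1);
        } else inB[(size_t)it->second] = 1;
    }
    size_t nu = u.size(), na = a.size(), nb = b.size();
    NumericVector out(seeds.size());
    std::vector<uint64_t> hu(nu), tmp;
    for (R_xlen_t t = 0; t < seeds.size(); ++t) {
        uint64_t sd = (uint64_t)(int64_t)seeds[t];
        for (size_t i = 0; i < nu; ++i) hu[i] = hash_packed(u[i], k, sd);
        // thresholds: m-th smallest hash of U, of A, of B (max if fewer)
        uint64_t tU, tA, tB;
        tmp.assign(hu.begin(), hu.end());
        if ((size_t)m < nu) {
            std::nth_element(tmp.begin(), tmp.begin() + (m - 1), tmp.end());
            tU = tmp[(size_t)(m - 1)];
        } else tU = UINT64_MAX;
        tmp.clear();
        for (size_t i = 0; i < nu; ++i) if (inA[i]) tmp.push_back(hu[i]);
        if ((size_t)m < na) {
            std::nth_element(tmp.begin(), tmp.begin() + (m - 1), tmp.end());
            tA = tmp[(size_t)(m - 1)];
        } else tA = UINT64_MAX;
        tmp.clear();
        for (size_t i = 0; i < nu; ++i) if (inB[i]) tmp.push_back(hu[i]);
        if ((size_t)m < nb) {
            std::nth_element(tmp.begin(), tmp.begin() + (m - 1), tmp.end());
            tB = tmp[(size_t)(m - 1)];
        } else tB = UINT64_MAX;
        uint64_t thr = std::min(tU, std::min(tA, tB));
        long long shared = 0;
        for (size_t i = 0; i < nu; ++i)
            if (inA[i] && inB[i] && hu[i] <= thr) ++shared;
        long long denom = std::min((long long)m, (long long)nu);
        out[t] = (double)shared / (double)denom;
    }
    return out;
}

// Monte-Carlo sampler for the truncation experiment, one trial per seed.
// method 1 ("union_minimizer"): does the k-prefix of the hash-minimizer of
//   A^{k+L} u B^{k+L} lie in A^k n B^k? (the event whose expectation the
//   closed-form truncated Jaccard index equals)
// method 2 ("two_sketch"): do the hash-minimizers of A^{k+L} and of B^{k+L}
//   share their k-prefix? (the literal m=1 truncated-sketch collision)
// [[Rcpp::export(name = ".cpp_mc_truncation")]]
NumericVector cpp_mc_truncation(CharacterVector kmersA_KL,
                                CharacterVector kmersB_KL,
                                CharacterVector shared_k,
                                int k, int kl, int n_seeds, double seed0,
                                int method) {
    std::vector<u128> a = pack_all(kmersA_KL, kl, "A^{k+L}");
    std::vector<u128> b = pack_all(kmersB_KL, kl, "B^{k+L}");
    int shift = 2 * (kl - k);
    std::unordered_set<u128, U128Hash> shared;
    for (R_xlen_t i = 0; i < shared_k.size(); ++i) {
        u128 x;
        if (!pack_kmer(CHAR(STRING_ELT(shared_k, i)), k, x))
            stop("shared k-mer contains a non-ACGT character");
        shared.insert(x);
    }
    // distinct union for the union-minimizer method
    std::vector<u128> u;
    {
        std::unordered_set<u128, U128Hash> us(a.begin(), a.end());
        us.insert(b.begin(), b.end());
        u.assign(us.begin(), us.end());
        std::sort(u.begin(), u.end());
    }
    long long hits = 0;
    for (int t = 0; t < n_seeds; ++t) {
        uint64_t sd = (uint64_t)(int64_t)seed0 + (uint64_t)t;
        if (method == 1) {
            uint64_t bh = 0; u128 bx = 0; bool first = true;
            for (size_t i = 0; i < u.size(); ++i) {
                uint64_t h = hash_packed(u[i], kl, sd);
                if (first || hash_less(h, u[i], bh, bx)) {
                    bh = h; bx = u[i]; first = false;
                }
            }
            if (shared.count(bx >> shift)) ++hits;
        } else {
            uint64_t bh = 0; u128 bx = 0; bool first = true;
            for (size_t i = 0; i < a.size(); ++i) {
                uint64_t h = hash_packed(a[i], kl, sd);
                if (first || hash_less(h, a[i], bh, bx)) {
                    bh = h; bx = a[i]; first = false;
                }
            }
            uint64_t ch_ = 0; u128 cx = 0; first = true;
            for (size_t i = 0; i < b.size(); ++i) {
                uint64_t h = hash_packed(b[i], kl, sd);
                if (first || hash_less(h, b[i], ch_, cx)) {
                    ch_ = h; cx = b[i]; first = false;
                }
            }
            if ((bx >> shift) == (cx >> shift)) ++hits;
        }
    }
    return NumericVector::create((double)hits / (double)n_seeds);
}
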