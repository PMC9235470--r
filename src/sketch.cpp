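#include <Rcpp.h>
#include <queue>
#include <unordered_set>
#include <algorithm>
#include "core.h"

using namespace Rcpp;

namespace {
struct HeapLess {
    // max-heap on (hash, element): top is the largest kept entry
    bool operator()(const std::pair<uint64_t, u128>& a,
                    const std::pair<uint64_t, u128>& b) const {
        return hash_less(a.first, a.second, b.first, b.second);
    }
};
}

// Bottom-m argmin sketch: the m distinct kmax-mers with the smallest hash
// values, built streaming with a bounded max-heap (memory ~ m, not |A^kmax|).
// [[Rcpp::export(name = ".cpp_build_sketch")]]
List cpp_build_sketch(CharacterVector seqs, int kmax, int m, double seed,
                      bool canonical) {
    if (kmax < 1 || kmax > KTS_MAX_K)
        stop("kmax must be in 1..%d", KTS_MAX_K);
    if (m < 1) stop("m must be >= 1");
    uint64_t sd = (uint64_t)(int64_t)seed;

    std::priority_queue<std::pair<uint64_t, u128>,
                        std::vector<std::pair<uint64_t, u128> >,
                        HeapLess> heap;
    std::unordered_set<u128, U128Hash> in_heap;
    long long total_windows = 0, valid = 0;

    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        size_t n = (size_t)LENGTH(STRING_ELT(seqs, i));
        if ((long long)n >= kmax) total_windows += (long long)n - kmax + 1;
        valid += for_each_window(s, n, kmax, [&](u128 fwd, u128 rc) {
            u128 key = canonical ? (fwd < rc ? fwd : rc) : fwd;
            uint64_t h = hash_packed(key, kmax, sd);
            if ((int)heap.size() < m) {
                if (in_heap.insert(key).second) heap.push({h, key});
            } else {
                const std::pair<uint64_t, u128>& top = heap.top();
                if (hash_less(h, key, top.first, top.second) &&
                    !in_heap.count(key)) {
                    in_heap.erase(top.second);
                    heap.pop();
                    in_heap.insert(key);
                    heap.push({h, key});
                }
            }
        });
    }

    size_t ne = heap.size();
    std::vector<std::pair<uint64_t, u128> > kept;
    kept.reserve(ne);
    while (!heap.empty()) { kept.push_back(heap.top()); heap.pop(); }
    std::reverse(kept.begin(), kept.end()); // ascending (hash, element)

    CharacterVector elements(ne), hashes(ne);
    char buf[17];
    for (size_t i = 0; i < ne; ++i) {
        elements[i] = unpack_kmer(kept[i].second, kmax);
        snprintf(buf, sizeof(buf), "%016llx",
                 (unsigned long long)kept[i].first);
        hashes[i] = buf;
    }
    return List::create(_["elements"] = elements,
                        _["hashes"] = hashes,
                        _["n_windows"] = (double)total_windows,
                        _["n_skipped"] = (double)(total_windows - valid));
}
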