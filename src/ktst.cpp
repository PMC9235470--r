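#include <Rcpp.h>
#include <unordered_set>
#include <set>
#include <algorithm>
#include <cmath>
#include "core.h"

using namespace Rcpp;

// K-mer ternary search tree over the sketch kmax-mers of N datasets.
// Every root-to-depth-kmax path spells a sketch element of at least one
// dataset; a depth-k node reachable by consuming a full k-character prefix
// carries the ids of the datasets owning an element with that prefix
// (labels are materialized at the depths in k_range, the only queryable
// depths). A bloom filter over every k_range-prefix of every element
// prefilters lookups.
struct KTST {
    int kmax;
    std::vector<int> k_range;            // sorted ascending
    int n_datasets;
    bool canonical;
    uint64_t order_seed;                 // insertion-shuffle seed

    // node arrays
    std::vector<char> ch;
    std::vector<int32_t> lo, eq, hi;
    std::vector<int32_t> depth;          // prefix length this node completes
    std::vector<uint8_t> is_word;        // depth-kmax terminal
    int32_t root;

    // per-node label lists as a linked pool
    std::vector<int32_t> label_head;     // node -> first entry or -1
    std::vector<int32_t> lab_dataset;
    std::vector<int32_t> lab_next;

    // bloom prefilter
    std::vector<uint64_t> bloom;
    uint64_t n_bits;
    int n_hashes;
    uint64_t bloom_seed1, bloom_seed2;
    double bloom_fp;

    KTST() : kmax(0), n_datasets(0), canonical(true), order_seed(0),
             root(-1), n_bits(0), n_hashes(0),
             bloom_seed1(0), bloom_seed2(0), bloom_fp(0.01) {}

    bool in_k_range(int k) const {
        return std::binary_search(k_range.begin(), k_range.end(), k);
    }

    int32_t new_node(char c, int32_t d) {
        ch.push_back(c);
        lo.push_back(-1); eq.push_back(-1); hi.push_back(-1);
        depth.push_back(d);
        is_word.push_back(0);
        label_head.push_back(-1);
        return (int32_t)ch.size() - 1;
    }

    void add_label(int32_t node, int32_t ds) {
        for (int32_t e = label_head[node]; e >= 0; e = lab_next[e])
            if (lab_dataset[e] == ds) return;
        lab_dataset.push_back(ds);
        lab_next.push_back(label_head[node]);
        label_head[node] = (int32_t)lab_dataset.size() - 1;
    }

    void insert(const char* s, int len, int32_t ds) {
        if (root < 0) root = new_node(s[0], 1);
        int32_t n = root;
        int i = 0;
        while (true) {
            char c = s[i];
            if (c < ch[n]) {
                if (lo[n] < 0) lo[n] = new_node(c, i + 1);
                n = lo[n];
            } else if (c > ch[n]) {
                if (hi[n] < 0) hi[n] = new_node(c, i + 1);
                n = hi[n];
            } else {
                if (in_k_range(i + 1)) add_label(n, ds);
                if (i + 1 == len) { is_word[n] = 1; return; }
                ++i;
                if (eq[n] < 0) eq[n] = new_node(s[i], i + 1);
                n = eq[n];
            }
        }
    }

    // node completing the prefix s[0..len-1], or -1
    int32_t lookup(const char* s, int len) const {
        int32_t n = root;
        int i = 0;
        while (n >= 0) {
            char c = s[i];
            if (c < ch[n]) n = lo[n];
            else if (c > ch[n]) n = hi[n];
            else {
                if (i + 1 == len) return n;
                ++i;
                n = eq[n];
            }
        }
        return -1;
    }

    int32_t lookup_packed(u128 x, int k) const {
        int32_t n = root;
        int i = 0;
        int c = (int)((x >> (2 * (k - 1))) & 3);
        char cc = code_base(c);
        while (n >= 0) {
            if (cc < ch[n]) n = lo[n];
            else if (cc > ch[n]) n = hi[n];
            else {
                if (i + 1 == k) return n;
                ++i;
                cc = code_base((int)((x >> (2 * (k - 1 - i))) & 3));
                n = eq[n];
            }
        }
        return -1;
    }

    // bloom over (prefix, length) pairs
    void bloom_sizing(uint64_t n_items, double fp) {
        bloom_fp = fp;
        if (n_items < 1) n_items = 1;
        double bits = -(double)n_items * std::log(fp) /
                      (std::log(2.0) * std::log(2.0));
        n_bits = (uint64_t)std::ceil(bits);
        if (n_bits < 64) n_bits = 64;
        n_hashes = (int)std::round((double)n_bits / (double)n_items *
                                   std::log(2.0));
        if (n_hashes < 1) n_hashes = 1;
        if (n_hashes > 16) n_hashes = 16;
        bloom.assign((size_t)((n_bits + 63) / 64), 0);
    }

    void bloom_add(u128 x, int k) {
        uint64_t h1 = hash_packed(x, k, bloom_seed1);
        uint64_t h2 = hash_packed(x, k, bloom_seed2) | 1ULL;
        for (int j = 0; j < n_hashes; ++j) {
            uint64_t b = (h1 + (uint64_t)j * h2) % n_bits;
            bloom[b >> 6] |= (1ULL << (b & 63));
        }
    }

    bool bloom_has(u128 x, int k) const {
        uint64_t h1 = hash_packed(x, k, bloom_seed1);
        uint64_t h2 = hash_packed(x, k, bloom_seed2) | 1ULL;
        for (int j = 0; j < n_hashes; ++j) {
            uint64_t b = (h1 + (uint64_t)j * h2) % n_bits;
            if (!(bloom[b >> 6] & (1ULL << (b & 63)))) return false;
        }
        return true;
    }
};

// [[Rcpp::export(name = ".cpp_build_ktst")]]
SEXP cpp_build_ktst(List elements_by_dataset, int kmax, IntegerVector k_range,
                    double bloom_fp, double order_seed, bool canonical) {
    int nd = elements_by_dataset.size();
    if (nd < 1) stop("at least one sketch is required");
    KTST* t = new KTST();
    t->kmax = kmax;
    t->n_datasets = nd;
    t->canonical = canonical;
    t->order_seed = (uint64_t)(int64_t)order_seed;
    t->k_range.assign(k_range.begin(), k_range.end());
    std::sort(t->k_range.begin(), t->k_range.end());

    // collect (element, dataset) pairs and the distinct element set
    std::vector<std::pair<u128, int32_t> > pairs;
    std::unordered_set<u128, U128Hash> distinct;
    for (int d = 0; d < nd; ++d) {
        CharacterVector el = elements_by_dataset[d];
        for (R_xlen_t i = 0; i < el.size(); ++i) {
            std::string s = as<std::string>(el[i]);
            if ((int)s.size() != kmax) {
                delete t;
                stop("sketch element of dataset %d has length %d, expected kmax=%d",
                     d + 1, (int)s.size(), kmax);
            }
            u128 x;
            if (!pack_kmer(s.c_str(), kmax, x)) {
                delete t;
                stop("sketch element contains a non-ACGT character");
            }
            pairs.push_back({x, (int32_t)d});
            distinct.insert(x);
        }
    }
    if (pairs.empty()) { delete t; stop("no sketch elements to index"); }

    // seeded shuffle of the insertion order avoids degenerate tree depth
    Xoshiro256 rng(t->order_seed ^ 0x7A5C3B1D2E4F6987ULL);
    for (size_t i = pairs.size() - 1; i > 0; --i) {
        size_t j = (size_t)rng.below(i + 1);
        std::swap(pairs[i], pairs[j]);
    }

    size_t approx_nodes = distinct.size() * (size_t)kmax / 2 + 64;
    t->ch.reserve(approx_nodes);
    std::string buf;
    for (size_t i = 0; i < pairs.size(); ++i) {
        buf = unpack_kmer(pairs[i].first, kmax);
        t->insert(buf.c_str(), kmax, pairs[i].second);
    }

    // bloom filter over every k_range-prefix of every distinct element
    t->bloom_seed1 = fmix64(t->order_seed ^ 0xB100F11ABCDE0101ULL);
    t->bloom_seed2 = fmix64(t->order_seed ^ 0x5EED5EED5EED5EEDULL);
    t->bloom_sizing((uint64_t)distinct.size() * t->k_range.size(), bloom_fp);
    for (std::unordered_set<u128, U128Hash>::iterator it = distinct.begin();
         it != distinct.end(); ++it) {
        for (size_t j = 0; j < t->k_range.size(); ++j) {
            int k = t->k_range[j];
            u128 pref = *it >> (2 * (kmax - k));
            t->bloom_add(pref, k);
        }
    }

    XPtr<KTST> p(t, true);
    return p;
}

// [[Rcpp::export(name = ".cpp_ktst_info")]]
List cpp_ktst_info(SEXP ptr) {
    XPtr<KTST> t(ptr);
    long long words = 0;
    for (size_t i = 0; i < t->is_word.size(); ++i) words += t->is_word[i];
    return List::create(_["n_nodes"] = (double)t->ch.size(),
                        _["n_words"] = (double)words,
                        _["kmax"] = t->kmax,
                        _["k_range"] = IntegerVector(t->k_range.begin(),
                                                     t->k_range.end()),
                        _["n_datasets"] = t->n_datasets,
                        _["bloom_bits"] = (double)t->n_bits,
                        _["bloom_hashes"] = t->n_hashes);
}

// [[Rcpp::export(name = ".cpp_ktst_prefix_query")]]
List cpp_ktst_prefix_query(SEXP ptr, std::string kmer) {
    XPtr<KTST> t(ptr);
    int len = (int)kmer.size();
    int32_t n = t->lookup(kmer.c_str(), len);
    std::vector<int> ds;
    if (n >= 0) {
        for (int32_t e = t->label_head[n]; e >= 0; e = t->lab_next[e])
            ds.push_back(t->lab_dataset[e] + 1);
        std::sort(ds.begin(), ds.end());
    }
    return List::create(_["node"] = (n >= 0 && !ds.empty()) ? n : NA_INTEGER,
                        _["datasets"] = IntegerVector(ds.begin(), ds.end()));
}

// [[Rcpp::export(name = ".cpp_ktst_bloom_check")]]
bool cpp_ktst_bloom_check(SEXP ptr, std::string kmer) {
    XPtr<KTST> t(ptr);
    u128 x;
    if (!pack_kmer(kmer.c_str(), (int)kmer.size(), x))
        stop("k-mer contains a non-ACGT character");
    return t->bloom_has(x, (int)kmer.size());
}

// Subtree label set of an arbitrary prefix-completing node, computed by
// walking its word-descendants (used by tests of label conservation).
// [[Rcpp::export(name = ".cpp_ktst_subtree_labels")]]
IntegerVector cpp_ktst_subtree_labels(SEXP ptr, std::string prefix) {
    XPtr<KTST> t(ptr);
    int32_t n = t->lookup(prefix.c_str(), (int)prefix.size());
    std::set<int> ds;
    if (n >= 0) {
        // descend: the subtree below via eq, plus lo/hi of descendants
        std::vector<int32_t> stack;
        if (t->is_word[n]) {
            for (int32_t e = t->label_head[n]; e >= 0; e = t->lab_next[e])
                ds.insert(t->lab_dataset[e] + 1);
        }
        if (t->eq[n] >= 0) stack.push_back(t->eq[n]);
        while (!stack.empty()) {
            int32_t v = stack.back(); stack.pop_back();
            if (t->is_word[v]) {
                for (int32_t e = t->label_head[v]; e >= 0; e = t->lab_next[e])
                    ds.insert(t->lab_dataset[e] + 1);
            }
            if (t->lo[v] >= 0) stack.push_back(t->lo[v]);
            if (t->hi[v] >= 0) stack.push_back(t->hi[v]);
            if (t->eq[v] >= 0) stack.push_back(t->eq[v]);
        }
    }
    return IntegerVector(ds.begin(), ds.end());
}

// Stream all query k-mers (for each k in k_range) through the tree.
// Counters have set semantics: each (dataset, node) pair counts once over
// the whole stream. In canonical mode each window is looked up in both
// orientations (a prefix of a canonical kmax-mer need not be canonical).
// [[Rcpp::export(name = ".cpp_ktst_stream")]]
List cpp_ktst_stream(SEXP ptr, CharacterVector seqs, IntegerVector k_range,
                     bool use_prefilter, bool compute_cardinality) {
    XPtr<KTST> t(ptr);
    int nk = k_range.size();
    int nd = t->n_datasets;
    IntegerMatrix counts(nd, nk);
    NumericVector cards(nk, NA_REAL);
    std::vector<uint8_t> visited(t->ch.size(), 0);
    double n_windows = 0, n_skipped = 0, n_bloom_pass = 0, n_tree_hits = 0;

    for (int kk = 0; kk < nk; ++kk) {
        int k = k_range[kk];
        if (!t->in_k_range(k))
            stop("k=%d is not in the index k_range", k);
        std::unordered_set<u128, U128Hash> card_set;
        long long total = 0, valid = 0;
        for (R_xlen_t i = 0; i < seqs.size(); ++i) {
            const char* s = CHAR(STRING_ELT(seqs, i));
            size_t n = (size_t)LENGTH(STRING_ELT(seqs, i));
            if ((long long)n >= k) total += (long long)n - k + 1;
            valid += for_each_window(s, n, k, [&](u128 fwd, u128 rc) {
                if (compute_cardinality)
                    card_set.insert(t->canonical ? (fwd < rc ? fwd : rc)
                                                 : fwd);
                u128 keys[2];
                int nkeys = 1;
                keys[0] = fwd;
                if (t->canonical && rc != fwd) { keys[1] = rc; nkeys = 2; }
                for (int q = 0; q < nkeys; ++q) {
                    if (use_prefilter && !t->bloom_has(keys[q], k)) continue;
                    if (use_prefilter) n_bloom_pass += 1;
                    int32_t node = t->lookup_packed(keys[q], k);
                    if (node >= 0 && t->label_head[node] >= 0 &&
                        !visited[node]) {
                        visited[node] = 1;
                        n_tree_hits += 1;
                        for (int32_t e = t->label_head[node]; e >= 0;
                             e = t->lab_next[e])
                            counts(t->lab_dataset[e], kk) += 1;
                    }
                }
            });
        }
        n_windows += (double)total;
        n_skipped += (double)(total - valid);
        if (compute_cardinality) cards[kk] = (double)card_set.size();
    }
    return List::create(_["counts"] = counts,
                        _["query_cardinalities"] = cards,
                        _["n_windows"] = n_windows,
                        _["n_skipped"] = n_skipped,
                        _["n_bloom_pass"] = n_bloom_pass,
                        _["n_tree_hits"] = n_tree_hits);
}
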