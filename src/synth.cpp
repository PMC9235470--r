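#include <Rcpp.h>
#include <string>
#include <vector>
#include "core.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_random_genome")]]
std::string cpp_random_genome(double length, double seed) {
    long long n = (long long)length;
    if (n < 1) stop("length must be >= 1");
    Xoshiro256 rng((uint64_t)(int64_t)seed);
    std::string s((size_t)n, 'A');
    for (long long i = 0; i < n; ++i)
        s[(size_t)i] = code_base((int)(rng.next() & 3));
    return s;
}

// Point mutations: each site substituted to a uniformly chosen different
// base with probability `divergence`; with probability `indel_rate` a small
// indel (1-3 bp, insertion or deletion equally likely) is introduced at the
// site instead.
// [[Rcpp::export(name = ".cpp_mutate_genome")]]
std::string cpp_mutate_genome(std::string parent, double divergence,
                              double indel_rate, double seed) {
    Xoshiro256 rng((uint64_t)(int64_t)seed ^ 0x6D75746174655F67ULL);
    std::string out;
    out.reserve(parent.size() + 16);
    for (size_t i = 0; i < parent.size(); ++i) {
        char c = parent[i];
        if (indel_rate > 0 && rng.unif() < indel_rate) {
            int len = 1 + (int)rng.below(3);
            if (rng.next() & 1) {
                // insertion before this site
                for (int j = 0; j < len; ++j)
                    out.push_back(code_base((int)(rng.next() & 3)));
                out.push_back(c);
            } else {
                // deletion of up to len sites starting here
                i += (size_t)(len - 1);
            }
            continue;
        }
        if (divergence > 0 && rng.unif() < divergence) {
            int cc = base_code(c);
            int nc = cc < 0 ? (int)(rng.next() & 3)
                            : (cc + 1 + (int)rng.below(3)) & 3;
            out.push_back(code_base(nc));
        } else {
            out.push_back(c);
        }
    }
    return out;
}

// Shotgun reads: genome chosen by weight, uniform start, either strand with
// probability 1/2, per-base substitution errors. Genomes shorter than the
// read length are given weight zero.
// [[Rcpp::export(name = ".cpp_simulate_reads")]]
List cpp_simulate_reads(CharacterVector genomes, int n_reads, int read_length,
                        double error_rate, NumericVector weights,
                        double seed, bool both_strands) {
    int ng = genomes.size();
    if (ng < 1) stop("at least one genome is required");
    if (weights.size() != ng) stop("one weight per genome is required");
    std::vector<std::string> gs((size_t)ng);
    std::vector<double> w((size_t)ng);
    double tot = 0;
    bool any_skipped = false;
    for (int g = 0; g < ng; ++g) {
        gs[(size_t)g] = as<std::string>(genomes[g]);
        double wg = weights[g];
        if (wg < 0) stop("weights must be non-negative");
        if ((int)gs[(size_t)g].size() < read_length && wg > 0) {
            any_skipped = true;
            wg = 0;
        }
        w[(size_t)g] = wg;
        tot += wg;
    }
    if (tot <= 0) stop("no genome is long enough (or positively weighted)");
    std::vector<double> cum((size_t)ng);
    double acc = 0;
    for (int g = 0; g < ng; ++g) { acc += w[(size_t)g] / tot; cum[(size_t)g] = acc; }
    cum[(size_t)ng - 1] = 1.0;

    Xoshiro256 rng((uint64_t)(int64_t)seed ^ 0x7265616473696D31ULL);
    CharacterVector reads(n_reads);
    IntegerVector origin(n_reads);
    std::string buf((size_t)read_length, 'A');
    for (int r = 0; r < n_reads; ++r) {
        double uu = rng.unif();
        int g = 0;
        while (g < ng - 1 && uu > cum[(size_t)g]) ++g;
        const std::string& gseq = gs[(size_t)g];
        size_t start = (size_t)rng.below((uint64_t)(gseq.size() - read_length + 1));
        bool rev = both_strands && (rng.next() & 1);
        for (int j = 0; j < read_length; ++j) {
            char c = rev ? gseq[start + (size_t)(read_length - 1 - j)]
                         : gseq[start + (size_t)j];
            int cc = base_code(c);
            if (rev && cc >= 0) cc = 3 - cc;
            if (cc >= 0 && error_rate > 0 && rng.unif() < error_rate)
                cc = (cc + 1 + (int)rng.below(3)) & 3;
            buf[(size_t)j] = cc < 0 ? 'N' : code_base(cc);
        }
        reads[r] = buf;
        origin[r] = g + 1;
    }
    return List::create(_["reads"] = reads, _["origin"] = origin,
                        _["skipped_genomes"] = any_skipped);
}

// Deterministic uniform draw in [0,1) from a seed (used to place each
// community member's divergence within the requested range).
// [[Rcpp::export(name = ".cpp_unit_interval")]]
double cpp_unit_interval(double seed) {
    Xoshiro256 rng((uint64_t)(int64_t)seed ^ 0x756E69666F726D31ULL);
    return rng.unif();
}
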