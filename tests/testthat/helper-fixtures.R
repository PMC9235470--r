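# Shared fixtures, all generated in code.

# the single-sequence worked-example dataset: A = {AATAAG}
worked_example <- function() seq_records("AATAAG", "g1")

# a related pair: ancestor + point-mutated descendant
sibling_pair <- function(length = 20000, divergence = 0.05, seed = 1) {
  a <- generate_genome(length, seed = seed, id = "anc")
  b <- mutate_genome(a, divergence = divergence, seed = seed + 1000,
                     id = "child")
  list(a = a, b = b)
}

# brute-force k-mer enumeration in plain R (the oracle the C++ scan is
# checked against)
r_enumerate <- function(seqs, k, canonical = FALSE) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, 1:(n - k + 1), k:n)
    w <- w[!grepl("[^ACGT]", w)]
    out <- c(out, w)
  }
  if (canonical) out <- canonical_form(out)
  sort(unique(out))
}

# linear-scan prefix ownership oracle over sketches
r_prefix_owners <- function(sketches, kmer) {
  ids <- vapply(sketches, `[[`, "", "dataset_id")
  own <- vapply(sketches, function(s)
    any(startsWith(s$elements, kmer)), TRUE)
  ids[own]
}

expect_same_set <- function(x, y) expect_setequal(as.character(x),
                                                  as.character(y))
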