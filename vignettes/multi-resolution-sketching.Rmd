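---
title: "Multi-resolution k-mer similarity with truncatable sketches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution k-mer similarity with truncatable sketches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, which knobs
matter, what the synthetic data does and does not emulate, and where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Estimands and estimators

For sequence collections $A$ and $B$, write $A^k$ for the set of distinct
k-mers of $A$ (canonical by default: each k-mer folded with its reverse
complement). The package estimates, for every $k$ in a user-chosen range up
to $k_{\max}$,

* the containment index $C_k(A,B) = |A^k \cap B^k| / |A^k|$, and
* the Jaccard index $J_k(A,B) = |A^k \cap B^k| / |A^k \cup B^k|$,

the latter always derived from the former through the cardinality identity
$J = |A|C / (|A| + |B| - |A|C)$, because containment is the quantity that
streams well when $|A^k| \ll |B^k|$ (a genome against a metagenome).

The sketch of a reference is an *argmin* bottom-$m$ sketch: the $m$ distinct
$k_{\max}$-mers with the smallest values under one shared 64-bit hash, ties
broken lexicographically so the order is total. Storing elements rather than
hash values is the load-bearing choice: the length-$k$ prefix of a stored
element is a valid k-mer of the data, so one sketch built at $k_{\max}$
serves every $k \le k_{\max}$, whereas truncating a hash value means
nothing.

All reference sketches are inserted into one k-mer ternary search tree. A
depth-$k$ node reachable by consuming $k$ characters represents a truncated
sketch element and carries the owning dataset ids; a bloom filter over every
query-length prefix rejects absent k-mers cheaply (it is an optimization
only — a test asserts that disabling it changes no counter). Streaming a
query increments a per-dataset, per-$k$ counter at most once per (dataset,
node) pair, giving set semantics to the match counts; the containment
estimate is $c_{i,k}/m$.

Assumptions worth stating: the hash behaves as a uniform random order on
k-mers (min-wise independence in spirit); queries are bags of k-mers, so
coverage, order and quality of reads are irrelevant beyond which k-mers
exist; and sketches are only comparable when built under the same seed,
$k_{\max}$ and canonical flag (the index constructor and the database header
enforce this).

## 2. Truncation bias, exactly

Truncating sketch elements collapses duplicate prefixes, so the truncated
sketch is not a uniform $m$-sample of $A^k$. The package quantifies this
instead of correcting it:

* `truncated_jaccard_closed_form()` evaluates the exact expected value of
  the truncated Jaccard estimator by full enumeration: the probability that
  the minimizer of $A^{k+L} \cup B^{k+L}$ truncates into
  $A^k \cap B^k$, computable as
  $\sum_{x \in A^k \cap B^k} RE(x) / |A^{k+L} \cup B^{k+L}|$, where the
  right-extension count $RE(x)$ is the number of pooled $(k+L)$-mers with
  prefix $x$.
* `jaccard_bias_factor()` rewrites that as the exact Jaccard at $k$ times a
  multiplicative factor — the mean right-extension count over the
  intersection divided by the mean over the union — and verifies the
  identity internally at $10^{-9}$ relative tolerance. The factor is 1 when
  $L = 0$, when $A = B$, and tends to 1 whenever prefixes are nearly unique
  ($4^k$ far above the pooled set size), which is why large $k$ is the safe
  regime.
* On the containment side, `ci_bias_terms()` reports the two counting terms
  of the decomposition: $a$, the duplicate prefixes collapsed by truncating
  the sketch, and $b$, the deficit in overlap-with-$B$ relative to a fresh
  bottom-$m$ sketch built directly at $k$.

**A derivation subtlety the package makes explicit.** The literal
single-element truncated-sketch collision — "do the minimizers of
$A^{k+L}$ and of $B^{k+L}$ share their $k$-prefix?" — is *implied by* but
does not imply the union-minimizer event above, and the two probabilities
genuinely differ outside the near-unique-prefix regime. The extreme case is
saturated small $k$: two unrelated genomes of a few kb share *all* 4-mers,
so the closed form is 1 while two independent minimizers rarely agree on a
4-prefix. `truncated_jaccard_mc()` therefore samples both events
(`method = "union_minimizer"`, whose expectation the closed form *is*, and
`method = "two_sketch"`, the literal collision). The test suite validates
each against its own exact expectation — for the two-sketch event we derive
it by conditioning on the union minimizer:
$P = \big[|A \cap B| + \sum_{w \in A \setminus B} RE_B(w_{1..k})/|B| +
\sum_{w \in B \setminus A} RE_A(w_{1..k})/|A|\big] / |A \cup B|$
over the $(k+L)$-mer sets — and a dedicated test pins the saturated-$k$
counterexample. Practical consequence: trust the truncated estimates at
$k$ large enough that $4^k$ dwarfs the k-mer counts involved; below that,
compute the bias factor rather than assuming it is 1.

## 3. Parameters

* `m` (sketch size, default 2000): the estimator's standard error is
  binomial, about $\sqrt{C(1-C)/m}$ per cell ($\le 0.011$ at $m = 2000$),
  verified within a factor of 1.5 by a repeated-seeds test. Memory and query
  time grow linearly in $m$.
* `kmax` (default 60 in the CLI): upper bound 64, because k-mers are 2-bit
  packed into 128-bit words end to end. Choose the largest $k$ of interest;
  there is no cost to a generous $k_{\max}$ beyond sketch-element length.
* `k_range`: the queryable depths. Tree labels and the prefilter are
  materialized only at these depths; the stored payload is independent of
  how many there are (a test asserts the database payload is identical for
  one k versus five).
* `bloom_fp` (default 0.01): target false-positive rate, sized by the
  standard $-n\ln p/(\ln 2)^2$ bits rule with the hash count capped at 16.
  A Monte-Carlo test bounds the realized rate at twice the target.
* `hash_order(seed = 7919)`: the shared order. The hash is a murmur-style
  finalizer over the packed k-mer salted with its length and the seed; any
  uniform 64-bit hash would do, and the seed is recorded in the database
  header so independent builds interoperate or refuse loudly.
* Canonicalization is on by default. Stored elements are canonical
  $k_{\max}$-mers, but a prefix of a canonical k-mer need not itself be
  canonical, so the streaming estimator looks each query window up in
  *both* orientations and counts a node once. This preserves
  strand-insensitivity under truncation; the full-sketch oracle
  (`exact_truncated_containment()`) mirrors the same convention so the
  equivalence test is exact. Non-canonical mode exists for the
  orientation-free bias math, which is the oracle default.

## 4. Numerical and degenerate-input choices

Denominator of the containment estimate: $m$ (the paper-faithful estimator),
not the number of distinct truncated prefixes $m - a$; the bias report
exposes both counts. When a sketch saturates ($|A^{k_{\max}}| < m$), the
actual element count replaces $m$, which makes the saturated estimator
coincide exactly with the brute-force truncated index — the dual-route test
the whole stack hangs on. The bias-factor identity is checked at $10^{-9}$
relative tolerance; all counting is integer so the only rounding is the
final divisions. Ties in the hash order are broken lexicographically, making
every argmin unique and every build byte-reproducible. Windows containing an
ambiguous base are skipped and counted in the scan statistics; empty inputs
(no valid $k_{\max}$-mer, empty query, empty sketch list) raise explicit
errors naming the dataset. Tree insertion order is shuffled with a seeded
generator so sorted input cannot degrade the ternary tree; tree shape never
affects results, only balance, and the external pointer is rebuilt
deterministically after deserialization. The CSV writers round to 6 decimals
at write time only.

## 5. What the synthetic data emulates

`generate_community()` produces clades of point-mutated descendants of
random i.i.d. ancestors (divergence drawn per genome from 1–10% by default),
and `simulate_reads()` draws fixed-length reads with uniform starts, random
strand and i.i.d. substitution errors. This captures what the estimators
consume — k-mer overlap structure that decays with divergence and with $k$,
plus error k-mers that dilute containment — and it is the regime the
screening experiment needs (within-"genus" relatives at realistic read error
of 0.5%).

It does not emulate: real genome composition (repeats, skew, low-complexity
tracts), structural variation, indel-dominated divergence (indels exist in
`mutate_genome()` but default off, and are kept off wherever the bias
oracles are involved, whose bookkeeping assumes substitution-only edits),
quality-dependent error profiles, chimeras, or abundance distributions
beyond user weights. Passing tests therefore demonstrate correctness of the
estimators and data structures under the stated model, and agreement bounds
(for example the median absolute difference between truncated and fixed-k
containment) transfer to real data only to the extent that prefix-collision
statistics of real genomes resemble those of near-random sequence at the
same k — at $k \ge 20$ that resemblance is good, which is exactly why the
screening comparison uses $k \ge 20$.

Scale choices: the screening experiment runs at 100 references × 500 kb with
one million reads — one-tenth the reference count of the original screening
design, with genome lengths at bacterial-plasmid rather than chromosome
scale — chosen so the full comparison (both estimators, nine k values)
completes in a few minutes on one CPU while keeping every per-cell standard
error at the $m = 2000$ level. The bias-identity property runs on 100
sibling pairs of 1–50 kb with $k \in 4..12$, $L \in 0..6$, where full
enumeration is exact and fast.

## 6. Statistical test calibration

Monte-Carlo checks compare an empirical frequency over $n$ seeds to its
exact expectation with standard error $\sqrt{p(1-p)/n}$. A single
comparison uses a 3–4 SE band. The bias-identity acceptance check makes 100
simultaneous 3SE comparisons; requiring all to pass would fail about a
quarter of the time under the null, so the test allows the binomial 99.9%
quantile of exceedances (3 of 100) and caps every deviation at 5 SE. Where
the expectation is exactly 0 or 1 the sampled frequency must match exactly
(the event is deterministic).

## 7. Known limitations

* $k_{\max} \le 64$ (2-bit packing); no spaced seeds, minimizer schemes or
  indel-tolerant sketches — truncation only preserves uniformity for
  contiguous prefixes.
* Presence/absence only: no abundance-weighted Jaccard, no taxonomic
  profiling; the similarity table is the product.
* The truncated estimator is biased below $k_{\max}$ by construction; the
  package reports the bias terms but deliberately does not correct the
  estimate, so the default output matches the plain $c_{i,k}/m$ estimator.
* The whole tree lives in memory (roughly 13 bytes per node plus labels;
  about 10M nodes for 200k sketch elements at $k_{\max} = 60$); there is no
  on-disk paging.
* Exact distinct counting is used for all cardinalities; for very large
  query sets the per-k distinct count is the memory high-water mark, and
  can be skipped (`compute_ji = FALSE`) when only containment is needed.
* The oracles enumerate every k-mer and warn above a few Mb of input; they
  are validation tools, not production paths.
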