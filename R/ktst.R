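# The k-mer ternary search tree index: prefix (truncation) lookups,
# per-dataset per-k counters and the bloom prefilter.

#' Build a ternary-search-tree index over argmin sketches
#'
#' Inserts the sketch kmax-mers of all datasets into a single ternary
#' search tree. A depth-k node reachable by consuming a full k-character
#' prefix represents the truncation of sketch elements to length k and is
#' labeled with the datasets owning at least one element with that prefix.
#' A bloom filter over every prefix of every element at every `k` in
#' `k_range` prefilters lookups (no false negatives; it is an optimization
#' only and never changes results).
#'
#' Insertion order is shuffled deterministically (seeded) to avoid the
#' degenerate tree depth a sorted insertion would cause.
#'
#' @param sketches a single [build_sketch()] result or a list of them; all
#'   must share `kmax`, hash seed and the canonical flag, and have distinct
#'   dataset ids.
#' @param k_range sorted vector of query k sizes, each in `[1, kmax]`.
#' @param bloom_fp target false-positive rate of the prefilter.
#' @param tree_seed seed for the insertion shuffle; defaults to the hash
#'   seed (tree shape never affects results, only balance).
#' @return an object of class `ktst_index`.
#' @export
build_index <- function(sketches, k_range, bloom_fp = 0.01,
                        tree_seed = NULL) {
  if (inherits(sketches, "argmin_sketch")) sketches <- list(sketches)
  if (!length(sketches)) stop("at least one sketch is required")
  if (!all(vapply(sketches, inherits, TRUE, "argmin_sketch")))
    stop("`sketches` must be argmin_sketch objects")
  kmax <- unique(vapply(sketches, `[[`, 1L, "kmax"))
  seed <- unique(vapply(sketches, `[[`, 1L, "seed"))
  canonical <- unique(vapply(sketches, `[[`, TRUE, "canonical"))
  if (length(kmax) != 1L || length(seed) != 1L || length(canonical) != 1L)
    stop("all sketches must share kmax, hash seed and canonical flag")
  ids <- vapply(sketches, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > kmax))
    stop("k_range must lie within [1, kmax]")
  if (is.null(tree_seed)) tree_seed <- seed
  idx <- structure(list(kmax = kmax, k_range = k_range,
                        dataset_ids = ids, sketches = sketches,
                        canonical = canonical, seed = seed,
                        bloom_fp = bloom_fp,
                        tree_seed = as.integer(tree_seed),
                        .cache = new.env(parent = emptyenv())),
                   class = "ktst_index")
  idx$.cache$ptr <- .build_ptr(idx)
  idx
}

.build_ptr <- function(idx) {
  .cpp_build_ktst(lapply(idx$sketches, `[[`, "elements"),
                  idx$kmax, idx$k_range, idx$bloom_fp,
                  as.double(idx$tree_seed), idx$canonical)
}

# The external pointer does not survive serialization; rebuild on demand
# (deterministic: same elements, same seeds, same tree).
.index_ptr <- function(idx) {
  p <- idx$.cache$ptr
  if (is.null(p) || isTRUE(.cpp_xptr_dead(p))) {
    p <- .build_ptr(idx)
    idx$.cache$ptr <- p
  }
  p
}

#' @export
print.ktst_index <- function(x, ...) {
  info <- .cpp_ktst_info(.index_ptr(x))
  cat(sprintf("<ktst_index> %d dataset(s), kmax=%d, k_range={%s}%s\n",
              length(x$dataset_ids), x$kmax,
              paste(x$k_range, collapse = ","),
              if (x$canonical) ", canonical" else ""))
  cat(sprintf("  %s nodes, %s distinct elements, bloom: %s bits / %d hashes (target fp %.3g)\n",
              format(info$n_nodes, big.mark = ","),
              format(info$n_words, big.mark = ","),
              format(info$bloom_bits, big.mark = ","),
              info$bloom_hashes, x$bloom_fp))
  invisible(x)
}

#' Prefix (truncation) lookup
#'
#' Finds the datasets owning at least one sketch element whose length-k
#' prefix equals `kmer` exactly (no orientation folding; callers wanting
#' strand-insensitive matching query both orientations, as the streaming
#' estimator does).
#'
#' @param index a [build_index()] result.
#' @param kmer a single k-mer whose length is in `index$k_range`.
#' @return list with `node` (an opaque node identity for deduplication, or
#'   `NA` if absent) and `datasets` (character vector of owning ids).
#' @export
prefix_query <- function(index, kmer) {
  stopifnot(inherits(index, "ktst_index"), length(kmer) == 1L)
  kmer <- toupper(kmer)
  if (!(nchar(kmer) %in% index$k_range))
    stop("query length ", nchar(kmer), " is not in the index k_range")
  res <- .cpp_ktst_prefix_query(.index_ptr(index), kmer)
  list(node = res$node, datasets = index$dataset_ids[res$datasets])
}

#' Bloom prefilter membership
#'
#' `FALSE` guarantees the k-mer is not a prefix in the tree; `TRUE` must
#' still be confirmed with [prefix_query()] (target false-positive rate is
#' the index's `bloom_fp`).
#'
#' @inheritParams prefix_query
#' @return logical.
#' @export
passes_prefilter <- function(index, kmer) {
  stopifnot(inherits(index, "ktst_index"), length(kmer) == 1L)
  kmer <- toupper(kmer)
  if (!(nchar(kmer) %in% index$k_range))
    stop("query length ", nchar(kmer), " is not in the index k_range")
  .cpp_ktst_bloom_check(.index_ptr(index), kmer)
}

#' Multiset of truncated sketch prefixes
#'
#' Truncates the elements of a sketch to length-k prefixes and tabulates
#' multiplicities. The number of duplicates collapsed
#' (`sum(multiplicity) - length(multiplicity)`) is the `a` term of the
#' containment truncation-bias decomposition.
#'
#' @param x an `argmin_sketch` or a `ktst_index` (elements pooled per
#'   dataset are not distinguished for an index; pass a sketch for
#'   per-dataset terms).
#' @param k truncation length, `k <= kmax`.
#' @return named integer vector: prefix -> multiplicity, sorted by prefix.
#' @export
truncated_prefix_multiset <- function(x, k) {
  elements <-
    if (inherits(x, "argmin_sketch")) x$elements
    else if (inherits(x, "ktst_index"))
      unique(unlist(lapply(x$sketches, `[[`, "elements"), use.names = FALSE))
    else stop("`x` must be an argmin_sketch or a ktst_index")
  kmax <- nchar(elements[1])
  stopifnot(k >= 1, k <= kmax)
  tab <- table(substr(elements, 1L, k))
  setNames(as.integer(tab), names(tab))
}

# Internal: subtree label set computed from word-descendants (test oracle
# for label conservation).
.subtree_labels <- function(index, prefix) {
  index$dataset_ids[.cpp_ktst_subtree_labels(.index_ptr(index),
                                             toupper(prefix))]
}
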