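# Streaming multi-k containment estimation, Jaccard conversion, and the
# classic fixed-k MinHash baselines.

#' Stream a query through the index: containment for all k in one pass
#'
#' Every k-mer window of the query (for each `k` in `k_range`) is checked
#' against the bloom prefilter and, on a pass, looked up in the ternary
#' search tree; in canonical mode both orientations of the window are
#' looked up and a hit in either counts once. Matched (dataset, node)
#' pairs are deduplicated over the whole stream, so the counter `c[i,k]`
#' is the number of *distinct* truncated sketch prefixes of dataset i seen
#' in the query. The containment estimate is `c[i,k] / m` (with the actual
#' element count replacing `m` for saturated sketches); no truncation-bias
#' correction is applied — the bias terms are available from
#' [ci_bias_terms()] as diagnostics.
#'
#' @param index a [build_index()] result.
#' @param query query sequences (anything [as_seq_records()] accepts).
#' @param k_range k sizes to estimate at; defaults to the index's full
#'   `k_range`, and must be a subset of it.
#' @param prefilter use the bloom prefilter? Disabling it changes no
#'   result, only speed.
#' @param compute_ji also record exact query cardinalities `|B^k|` and
#'   derive Jaccard estimates via [ji_from_ci()]? Skipping this (e.g. for
#'   containment-only screens of large read sets) avoids the distinct
#'   k-mer count of the query.
#' @param query_id label stored in the result metadata.
#' @param verbose log scan statistics?
#' @return a `similarity_table`: data.frame with columns `dataset_id`,
#'   `k`, `ci`, `ji`, `matches`, `sketch_size`, plus metadata attributes
#'   (`m`, `kmax`, `seed`, `query_id`, `query_cardinalities`).
#' @export
stream_containment <- function(index, query, k_range = index$k_range,
                               prefilter = TRUE, compute_ji = TRUE,
                               query_id = "query", verbose = FALSE) {
  stopifnot(inherits(index, "ktst_index"))
  query <- as_seq_records(query)
  if (nrow(query) == 0L) stop("empty query")
  k_range <- sort(unique(as.integer(k_range)))
  if (!all(k_range %in% index$k_range))
    stop("k_range must be a subset of the index k_range")
  res <- .cpp_ktst_stream(.index_ptr(index), query$seq, k_range,
                          isTRUE(prefilter), isTRUE(compute_ji))
  if (res$n_windows - res$n_skipped <= 0)
    stop("query contains no valid k-mer window")
  if (verbose)
    message(sprintf(
      "[stream %s] %s windows, %s skipped (ambiguous), %s prefilter passes, %s node hits",
      query_id, format(res$n_windows, big.mark = ","),
      format(res$n_skipped, big.mark = ","),
      format(res$n_bloom_pass, big.mark = ","),
      format(res$n_tree_hits, big.mark = ",")))
  sizes <- vapply(index$sketches, function(s) length(s$elements), 1L)
  nd <- length(index$dataset_ids)
  nk <- length(k_range)
  counts <- res$counts
  ci <- sweep(counts, 1L, sizes, "/")
  qcards <- setNames(res$query_cardinalities, as.character(k_range))
  ji <- matrix(NA_real_, nd, nk)
  if (isTRUE(compute_ji)) {
    for (j in seq_len(nk)) {
      kk <- as.character(k_range[j])
      for (i in seq_len(nd)) {
        ca <- index$sketches[[i]]$cardinalities[kk]
        if (!is.na(ca) && !is.na(qcards[kk]) && qcards[kk] >= 1)
          ji[i, j] <- ji_from_ci(ci[i, j], ca, qcards[kk])
      }
    }
  }
  out <- data.frame(
    dataset_id = rep(index$dataset_ids, times = nk),
    k = rep(k_range, each = nd),
    ci = as.vector(ci),
    ji = as.vector(ji),
    matches = as.vector(counts),
    sketch_size = rep(sizes, times = nk),
    stringsAsFactors = FALSE)
  structure(out, class = c("similarity_table", "data.frame"),
            m = index$sketches[[1]]$m, kmax = index$kmax,
            seed = index$seed, query_id = query_id,
            query_cardinalities = qcards)
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> query '%s' vs %d dataset(s), k in {%s} (kmax=%d, m=%d, seed=%d)\n",
              attr(x, "query_id"), length(unique(x$dataset_id)),
              paste(sort(unique(x$k)), collapse = ","),
              attr(x, "kmax"), attr(x, "m"), attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 12) cat(sprintf("  ... %d rows total\n", nrow(x)))
  invisible(x)
}

#' Jaccard index from containment index and cardinalities
#'
#' Exact algebraic conversion
#' `J = |A| C / (|A| + |B| - |A| C)`; the result is clipped to `[0, 1]`
#' to absorb estimator noise in `C`.
#'
#' @param ci containment of A in B, in `[0, 1]`.
#' @param card_a,card_b cardinalities `|A|`, `|B|` (positive).
#' @return Jaccard value(s) in `[0, 1]`.
#' @export
ji_from_ci <- function(ci, card_a, card_b) {
  if (any(card_a < 1) || any(card_b < 1))
    stop("cardinalities must be >= 1")
  if (any(ci < 0 | ci > 1)) stop("ci must lie in [0, 1]")
  pmin(1, pmax(0, card_a * ci / (card_a + card_b - card_a * ci)))
}

#' Classic fixed-k MinHash containment baseline
#'
#' Builds a fresh bottom-m sketch of `records_a` at exactly this `k` (no
#' truncation) and streams the query over it: the fraction of sketch
#' elements found among the query k-mers. At `k = kmax` and with the same
#' seed and `m`, this agrees bit-for-bit with [stream_containment()].
#'
#' @param records_a reference sequences.
#' @param query_b query sequences.
#' @param k k-mer size.
#' @param m sketch size.
#' @param order the [hash_order()].
#' @param canonical strand-insensitive k-mers?
#' @return containment estimate in `[0, 1]`.
#' @export
minhash_containment_baseline <- function(records_a, query_b, k, m = 2000L,
                                         order = hash_order(),
                                         canonical = TRUE) {
  sk <- build_sketch(records_a, kmax = k, m = m, order = order,
                     canonical = canonical, cardinality_ks = integer(0))
  query_b <- as_seq_records(query_b)
  if (nrow(query_b) == 0L) stop("empty query")
  hits <- .cpp_containment_baseline_multi(list(sk$elements), query_b$seq,
                                          as.integer(k), canonical)
  hits[1] / length(sk$elements)
}

#' Classic fixed-k MinHash containment screen over many references
#'
#' The batched form of [minhash_containment_baseline()]: builds a fresh
#' bottom-m sketch per reference at each requested `k` and streams the
#' query once per `k` against all sketches together. This is the
#' "rebuild-per-k" comparator the truncation approach is measured
#' against: its cost (and storage) grows linearly with the number of k
#' values, while a single truncatable index serves them all.
#'
#' @param references named list of sequence collections (anything
#'   [as_seq_records()] accepts), one per reference dataset.
#' @param query query sequences.
#' @param ks integer vector of k sizes.
#' @param m sketch size.
#' @param order the [hash_order()].
#' @param canonical strand-insensitive k-mers?
#' @return data.frame with columns `dataset_id`, `k`, `ci`, `matches`,
#'   `sketch_size`.
#' @export
minhash_containment_screen <- function(references, query, ks, m = 2000L,
                                       order = hash_order(),
                                       canonical = TRUE) {
  order <- as_hash_order(order)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("`references` must be a named list")
  query <- as_seq_records(query)
  refs <- lapply(references, as_seq_records)
  ks <- sort(unique(as.integer(ks)))
  out <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    sketches <- lapply(names(refs), function(id)
      build_sketch(refs[[id]], kmax = k, m = m, order = order,
                   canonical = canonical, dataset_id = id,
                   cardinality_ks = integer(0)))
    sizes <- vapply(sketches, function(s) length(s$elements), 1L)
    hits <- .cpp_containment_baseline_multi(
      lapply(sketches, `[[`, "elements"), query$seq, k, canonical)
    out[[j]] <- data.frame(dataset_id = names(refs), k = k,
                           ci = hits / sizes, matches = hits,
                           sketch_size = sizes,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classic bottom-m MinHash Jaccard baseline
#'
#' The hash-value bottom sketch estimator
#' `|S_m(A u B) n S_m(A) n S_m(B)| / m` with one shared hash; an unbiased
#' estimate of the Jaccard index.
#'
#' @inheritParams minhash_containment_baseline
#' @param records_b second sequence collection.
#' @return Jaccard estimate in `[0, 1]`.
#' @export
minhash_jaccard_baseline <- function(records_a, records_b, k, m = 2000L,
                                     order = hash_order(),
                                     canonical = TRUE) {
  order <- as_hash_order(order)
  ka <- enumerate_kmers(records_a, k, canonical)
  kb <- enumerate_kmers(records_b, k, canonical)
  if (!length(ka) || !length(kb)) stop("both collections need >= 1 k-mer")
  .cpp_jaccard_baseline_seeds(ka, kb, as.integer(k), as.integer(m),
                              as.double(order$seed))[1]
}

#' Write a similarity table as CSV
#'
#' Columns `dataset_id,k,ci_estimate,ji_estimate,matches,sketch_size`, one
#' row per (dataset, k); estimates rounded to 6 decimals at write time
#' only.
#'
#' @param x a `similarity_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(x, path) {
  stopifnot(inherits(x, "similarity_table"))
  out <- data.frame(dataset_id = x$dataset_id, k = x$k,
                    ci_estimate = round(x$ci, 6),
                    ji_estimate = round(x$ji, 6),
                    matches = x$matches, sketch_size = x$sketch_size,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
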