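# Argmin bottom-m sketches and exact per-k cardinalities.

#' Build an argmin bottom-m sketch
#'
#' The sketch of a dataset is the set of `m` distinct kmax-mers with the
#' smallest hash values under the shared [hash_order()] — the k-mers
#' themselves are stored, not their hash values, which is what makes the
#' sketch truncatable to smaller k by prefix lookup. Construction streams
#' the input through a bounded max-heap, so memory is proportional to `m`,
#' not to the number of distinct kmax-mers.
#'
#' Exact distinct k-mer counts (needed to convert containment to Jaccard
#' values) are computed for `cardinality_ks` from the same in-memory copy
#' of the records.
#'
#' @param records sequences (anything [as_seq_records()] accepts).
#' @param kmax sketch k-mer size, between 1 and 64; sketches can later be
#'   queried at any `k <= kmax`.
#' @param m sketch size; the default 2000 trades estimator standard error
#'   (about `sqrt(C(1-C)/m)`) against space.
#' @param order the [hash_order()]; must match between all sketches that
#'   will share an index and any baseline they are compared to.
#' @param canonical use [canonical_form()] k-mers (strand-insensitive)?
#' @param dataset_id label for the dataset; defaults to `"dataset"`.
#' @param cardinality_ks integer vector of k values at which to record
#'   exact distinct-k-mer counts; `NULL` records `kmax` only, and
#'   `integer(0)` skips counting (containment-only workflows).
#' @param verbose log window/skip counts?
#' @return an object of class `argmin_sketch`: list with `dataset_id`,
#'   `kmax`, `m` (requested size), `elements` (kmax-mers sorted ascending
#'   by (hash, lexicographic)), `hashes` (hex), `cardinalities` (named
#'   numeric), `seed`, `canonical`, and scan statistics.
#' @export
build_sketch <- function(records, kmax, m = 2000L, order = hash_order(),
                         canonical = TRUE, dataset_id = "dataset",
                         cardinality_ks = NULL, verbose = FALSE) {
  records <- as_seq_records(records)
  order <- as_hash_order(order)
  stopifnot(kmax >= 1, kmax <= 64, m >= 1)
  res <- .cpp_build_sketch(records$seq, as.integer(kmax), as.integer(m),
                           as.double(order$seed), isTRUE(canonical))
  if (length(res$elements) == 0L)
    stop("empty sketch for dataset '", dataset_id,
         "': no valid ", kmax, "-mer in the input")
  if (is.null(cardinality_ks)) cardinality_ks <- as.integer(kmax)
  cardinality_ks <- sort(unique(as.integer(cardinality_ks)))
  cards <- if (length(cardinality_ks))
    setNames(.cpp_exact_cardinalities(records$seq, cardinality_ks,
                                      isTRUE(canonical)),
             as.character(cardinality_ks))
  else setNames(numeric(0), character(0))
  if (verbose)
    message(sprintf(
      "[sketch %s] kmax=%d m=%d: %d elements kept; %s windows scanned, %s skipped (ambiguous)",
      dataset_id, kmax, m, length(res$elements),
      format(res$n_windows, big.mark = ","),
      format(res$n_skipped, big.mark = ",")))
  structure(list(dataset_id = as.character(dataset_id),
                 kmax = as.integer(kmax), m = as.integer(m),
                 elements = res$elements, hashes = res$hashes,
                 cardinalities = cards,
                 seed = order$seed, canonical = isTRUE(canonical),
                 n_windows = res$n_windows, n_skipped = res$n_skipped),
            class = "argmin_sketch")
}

#' @export
print.argmin_sketch <- function(x, ...) {
  cat(sprintf("<argmin_sketch> '%s': kmax=%d, %d/%d elements, seed=%d%s\n",
              x$dataset_id, x$kmax, length(x$elements), x$m, x$seed,
              if (x$canonical) ", canonical" else ""))
  if (length(x$cardinalities))
    cat("  cardinalities:",
        paste(sprintf("|A^%s|=%g", names(x$cardinalities), x$cardinalities),
              collapse = ", "), "\n")
  invisible(x)
}

#' Exact number of distinct k-mers
#'
#' @inheritParams build_sketch
#' @param k k-mer size(s); a value is returned per k.
#' @return numeric vector of exact distinct counts, named by k.
#' @export
exact_cardinality <- function(records, k, canonical = TRUE) {
  records <- as_seq_records(records)
  k <- as.integer(k)
  setNames(.cpp_exact_cardinalities(records$seq, k, isTRUE(canonical)),
           as.character(k))
}
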