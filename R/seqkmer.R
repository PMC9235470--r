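# Sequence I/O, canonicalization, k-mer enumeration and the hash order.

#' Sequence records
#'
#' A plain container for named DNA sequences: a data.frame with columns
#' `id` and `seq`. Sequences are upper-cased on construction; ids must be
#' non-empty and unique within a collection read from one file.
#'
#' @param seq character vector of DNA sequences (A/C/G/T/N; lower case
#'   accepted and folded).
#' @param id character vector of labels, one per sequence.
#' @return an object of class `seq_records` (a data.frame).
#' @export
seq_records <- function(seq, id = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(id)) {
    id <- names(seq)
    if (is.null(id)) id <- paste0("seq", seq_along(seq))
  }
  id <- as.character(id)
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length")
  if (any(is.na(id) | !nzchar(id)))
    stop("every record needs a non-empty id")
  structure(data.frame(id = id, seq = seq, stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d record(s), %s bp total\n",
              nrow(x), format(sum(nchar(x$seq)), big.mark = ",")))
  n <- min(nrow(x), 5L)
  for (i in seq_len(n)) {
    s <- x$seq[i]
    cat(sprintf("  %s: %s%s (%d bp)\n", x$id[i],
                substr(s, 1, 40), if (nchar(s) > 40) "..." else "",
                nchar(s)))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Coerce to sequence records
#'
#' @param x a `seq_records` object, a (possibly named) character vector,
#'   or a data.frame with `id` and `seq` columns.
#' @return a `seq_records` object.
#' @export
as_seq_records <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.character(x)) return(seq_records(x))
  if (is.data.frame(x) && all(c("id", "seq") %in% names(x)))
    return(seq_records(x$seq, x$id))
  stop("cannot interpret `x` as sequence records")
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads all records of a FASTA or FASTQ file (plain or gzip-compressed,
#' auto-detected) in file order. Qualities are discarded; bases are folded
#' to upper case; no length filtering is applied.
#'
#' @param path path to the sequence file.
#' @param format `"auto"` (default, sniffed from the first record marker),
#'   `"fasta"` or `"fastq"`.
#' @return a [seq_records] object.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    con <- gzfile(path, "rt")  # reads plain files transparently too
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    if (length(first) == 0L || !nzchar(trimws(first[1])))
      return(seq_records(character(0), character(0)))
    ch <- substr(trimws(first[1]), 1, 1)
    format <- if (ch == ">") "fasta" else if (ch == "@") "fastq" else
      stop("'", path, "': first record marker is neither '>' nor '@'")
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e)
      stop("parse error in '", path, "' (", format, "): ",
           conditionMessage(e), call. = FALSE))
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  # FASTA headers: id is the first whitespace-delimited token
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1L)
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad))
    stop("parse error in '", path, "': record ", bad[1], " has no id")
  seq_records(as.character(x), ids)
}

#' Reverse complement
#'
#' @param kmer character vector of DNA strings over A/C/G/T.
#' @return the reverse complements; `NA` for strings containing any other
#'   character.
#' @export
reverse_complement <- function(kmer) .cpp_revcomp(toupper(kmer))

#' Canonical form of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement, which
#' makes downstream comparisons strand-insensitive. Idempotent.
#'
#' @param kmer character vector of k-mers over A/C/G/T.
#' @return canonical k-mers; `NA` (the rejection signal callers use to skip
#'   a window) for k-mers containing an ambiguous base.
#' @export
canonical_form <- function(kmer) .cpp_canonical(toupper(kmer))

#' Enumerate the distinct k-mers of a sequence collection
#'
#' Every length-k window that contains no ambiguous base contributes one
#' element; multiplicities are dropped. With `canonical = TRUE` each window
#' is replaced by its [canonical_form()].
#'
#' @param records sequences (anything [as_seq_records()] accepts).
#' @param k k-mer size, between 1 and 64.
#' @param canonical fold each k-mer with its reverse complement?
#' @return a character vector of class `kmer_set`, sorted lexicographically,
#'   with attributes `k`, `canonical`, `n_windows` and `n_skipped` (windows
#'   dropped for ambiguous bases).
#' @export
enumerate_kmers <- function(records, k, canonical = TRUE) {
  records <- as_seq_records(records)
  stopifnot(length(k) == 1L, k >= 1)
  res <- .cpp_enumerate_kmers(records$seq, as.integer(k), isTRUE(canonical))
  structure(res$kmers, k = as.integer(k), canonical = isTRUE(canonical),
            n_windows = res$n_windows, n_skipped = res$n_skipped,
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k=%d, %d distinct k-mer(s)%s\n",
              attr(x, "k"), length(x),
              if (isTRUE(attr(x, "canonical"))) ", canonical" else ""))
  if (length(x)) print(utils::head(unclass(x), 10))
  invisible(x)
}

#' The shared hash order
#'
#' All sketches, baselines and the bloom prefilter rank k-mers by a single
#' deterministic 64-bit hash of the 2-bit-packed k-mer, salted with the
#' k-mer length and this seed; ties (which essentially never occur) are
#' broken by lexicographic order, making the order total.
#'
#' @param seed integer seed. The default is the package-wide documented
#'   default; databases record the seed in their header, and sketches are
#'   only comparable when built under the same seed.
#' @return an object of class `hash_order`.
#' @export
hash_order <- function(seed = 7919L) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(list(seed = seed), class = "hash_order")
}

#' @export
print.hash_order <- function(x, ...) {
  cat(sprintf("<hash_order> 64-bit, seed=%d, lexicographic tie-break\n",
              x$seed))
  invisible(x)
}

as_hash_order <- function(order) {
  if (inherits(order, "hash_order")) return(order)
  if (is.numeric(order) && length(order) == 1L) return(hash_order(order))
  stop("`order` must be a hash_order or a single seed")
}

#' Hash k-mers under a hash order
#'
#' @param kmer character vector of k-mers (lengths may differ; the length
#'   salts the hash).
#' @param order a [hash_order()] (or a bare seed).
#' @return 64-bit hash values as fixed-width lower-case hex strings, whose
#'   lexicographic order equals the numeric order of the underlying values.
#' @export
hash_kmer <- function(kmer, order = hash_order()) {
  order <- as_hash_order(order)
  .cpp_hash_kmers(toupper(kmer), as.double(order$seed))
}
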