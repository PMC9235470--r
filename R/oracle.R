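# Brute-force ground truth and the closed-form truncation-bias math.
# Everything here works on full k-mer enumerations and is meant for
# desk-scale inputs (up to a few Mb); the estimators are validated against
# these functions, never the other way around.

.oracle_guard <- function(...) {
  total <- sum(vapply(list(...), function(r) sum(nchar(r$seq)), 0))
  if (total > 5e6)
    warning("oracle computations enumerate all k-mers; input is ",
            format(total, big.mark = ","), " bp", call. = FALSE)
}

#' Exact Jaccard and containment indices
#'
#' Set arithmetic on full k-mer enumerations: `J = |A n B| / |A u B|` and
#' `C(A,B) = |A n B| / |A|` (the fraction of A's k-mers found in B).
#'
#' @param records_a,records_b sequence collections (anything
#'   [as_seq_records()] accepts).
#' @param k k-mer size.
#' @param canonical fold k-mers with their reverse complements? The oracle
#'   default is `FALSE`, matching the orientation-free bias derivation; use
#'   `TRUE` to mirror the estimators end-to-end.
#' @return a fraction in `[0, 1]`.
#' @export
exact_jaccard <- function(records_a, records_b, k, canonical = FALSE) {
  .oracle_guard(as_seq_records(records_a), as_seq_records(records_b))
  a <- enumerate_kmers(records_a, k, canonical)
  b <- enumerate_kmers(records_b, k, canonical)
  if (!length(a) || !length(b)) stop("both k-mer sets must be non-empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' @rdname exact_jaccard
#' @export
exact_containment <- function(records_a, records_b, k, canonical = FALSE) {
  .oracle_guard(as_seq_records(records_a), as_seq_records(records_b))
  a <- enumerate_kmers(records_a, k, canonical)
  b <- enumerate_kmers(records_b, k, canonical)
  if (!length(a)) stop("A^k is empty: containment undefined")
  length(intersect(a, b)) / length(a)
}

#' Exact truncated containment (the quantity the streaming estimator
#' samples)
#'
#' With the full kmax-mer set of A playing the role of a saturated sketch,
#' the truncated containment at `k` is the fraction of elements whose
#' length-k prefix occurs among the query k-mers. In canonical mode the
#' elements are canonical kmax-mers and a prefix matches if either its
#' forward or reverse-complement form occurs in the query, mirroring the
#' two-orientation lookup of [stream_containment()]; the denominator is
#' the element count, and the numerator counts *distinct* prefixes, as the
#' tree counters do.
#'
#' @inheritParams exact_jaccard
#' @param kmax sketch k-mer size the truncation starts from.
#' @return a fraction in `[0, 1]`.
#' @export
exact_truncated_containment <- function(records_a, records_b, k, kmax,
                                        canonical = FALSE) {
  stopifnot(k >= 1, k <= kmax)
  s <- enumerate_kmers(records_a, kmax, canonical)
  if (!length(s)) stop("A^kmax is empty")
  prefixes <- unique(substr(s, 1L, k))
  bk <- enumerate_kmers(records_b, k, canonical = FALSE)
  keys <- if (canonical) union(bk, reverse_complement(bk)) else bk
  sum(prefixes %in% keys) / length(s)
}

#' Right extensions of a k-mer prefix
#'
#' The number of (k+L)-mers in `pool` having `x` as prefix; the building
#' block of the truncation-bias factor.
#'
#' @param x character vector of k-mers.
#' @param L extension length (non-negative).
#' @param pool a `kmer_set` (or character vector) of (k+L)-mers.
#' @return integer vector of counts, one per element of `x`.
#' @export
right_extensions <- function(x, L, pool) {
  k <- unique(nchar(x))
  if (length(k) != 1L) stop("all elements of `x` must share one length")
  kl <- unique(nchar(pool))
  if (length(kl) != 1L || kl != k + L)
    stop("`pool` must consist of (k+L)-mers; expected length ", k + L)
  tab <- table(substr(pool, 1L, k))
  out <- as.integer(tab[x])
  out[is.na(out)] <- 0L
  out
}

#' Closed-form truncated Jaccard index
#'
#' The exact expected value of the truncation-based Jaccard estimator,
#' evaluated analytically (no hashing, no sampling): the probability that
#' the minimizer of `A^{k+L} u B^{k+L}` under a uniform random order
#' truncates to a k-mer present in both `A^k` and `B^k`, i.e.
#' `sum_{x in A^k n B^k} RE(x) / |A^{k+L} u B^{k+L}|` with right
#' extensions taken over the union pool. At `L = 0` this reduces to the
#' exact Jaccard index at `k`.
#'
#' @inheritParams exact_jaccard
#' @param L truncation length; the sketch is built at `k + L` and read at
#'   `k`.
#' @return a fraction in `[0, 1]`.
#' @export
truncated_jaccard_closed_form <- function(records_a, records_b, k, L,
                                          canonical = FALSE) {
  stopifnot(L >= 0)
  .oracle_guard(as_seq_records(records_a), as_seq_records(records_b))
  shared <- intersect(enumerate_kmers(records_a, k, canonical),
                      enumerate_kmers(records_b, k, canonical))
  u_kl <- union(enumerate_kmers(records_a, k + L, canonical),
                enumerate_kmers(records_b, k + L, canonical))
  if (!length(u_kl)) stop("both (k+L)-mer sets are empty")
  sum(substr(u_kl, 1L, k) %in% shared) / length(u_kl)
}

#' Multiplicative truncation-bias factor of the Jaccard index
#'
#' Decomposes the closed-form truncated Jaccard index as the exact Jaccard
#' index at `k` times the ratio of mean right-extension counts over the
#' intersection versus the union of the k-mer sets (right extensions taken
#' over the pooled (k+L)-mers). The identity
#' `ji_truncated = ji_exact * bias_factor` is verified internally to
#' floating tolerance.
#'
#' @inheritParams truncated_jaccard_closed_form
#' @return a `bias_report` with fields `k`, `L`, `ji_exact_at_k`,
#'   `ji_truncated_closed_form`, `bias_factor_ji`,
#'   `mean_re_intersection`, `mean_re_union` (and `a`, `b` set to `NA`;
#'   see [ci_bias_terms()] for the containment-side terms). With an empty
#'   intersection the factor is undefined and reported as `NA`.
#' @export
jaccard_bias_factor <- function(records_a, records_b, k, L,
                                canonical = FALSE) {
  stopifnot(L >= 0)
  .oracle_guard(as_seq_records(records_a), as_seq_records(records_b))
  ak <- enumerate_kmers(records_a, k, canonical)
  bk <- enumerate_kmers(records_b, k, canonical)
  if (!length(ak) || !length(bk)) stop("both k-mer sets must be non-empty")
  shared <- intersect(ak, bk)
  pooled <- union(ak, bk)
  u_kl <- union(enumerate_kmers(records_a, k + L, canonical),
                enumerate_kmers(records_b, k + L, canonical))
  ji_exact <- length(shared) / length(pooled)
  pref <- substr(u_kl, 1L, k)
  # sums accumulated over integer tables: exact
  sum_int <- sum(pref %in% shared)
  sum_uni <- length(u_kl)  # every (k+L)-mer's prefix lies in A^k u B^k
  ji_trunc <- sum_int / sum_uni
  if (!length(shared)) {
    return(bias_report(k = k, L = L, ji_exact_at_k = ji_exact,
                       ji_truncated_closed_form = ji_trunc,
                       bias_factor_ji = NA_real_,
                       mean_re_intersection = NA_real_,
                       mean_re_union = sum_uni / length(pooled)))
  }
  mean_int <- sum_int / length(shared)
  mean_uni <- sum_uni / length(pooled)
  factor <- mean_int / mean_uni
  stopifnot(abs(ji_trunc - ji_exact * factor) <=
              1e-9 * max(ji_trunc, .Machine$double.eps))
  bias_report(k = k, L = L, ji_exact_at_k = ji_exact,
              ji_truncated_closed_form = ji_trunc,
              bias_factor_ji = factor,
              mean_re_intersection = mean_int,
              mean_re_union = mean_uni)
}

bias_report <- function(k, L, ji_exact_at_k = NA_real_,
                        ji_truncated_closed_form = NA_real_,
                        bias_factor_ji = NA_real_,
                        mean_re_intersection = NA_real_,
                        mean_re_union = NA_real_,
                        a = NA_integer_, b = NA_integer_,
                        ci_at_k = NA_real_, ci_truncated = NA_real_) {
  structure(list(k = as.integer(k), L = as.integer(L),
                 ji_exact_at_k = ji_exact_at_k,
                 ji_truncated_closed_form = ji_truncated_closed_form,
                 bias_factor_ji = bias_factor_ji,
                 mean_re_intersection = mean_re_intersection,
                 mean_re_union = mean_re_union,
                 a = a, b = b, ci_at_k = ci_at_k,
                 ci_truncated = ci_truncated),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> k=%d, L=%d\n", x$k, x$L))
  if (!is.na(x$ji_exact_at_k))
    cat(sprintf("  JI exact at k: %.6g | truncated closed form: %.6g | bias factor: %.6g\n",
                x$ji_exact_at_k, x$ji_truncated_closed_form,
                x$bias_factor_ji))
  if (!is.na(x$mean_re_intersection))
    cat(sprintf("  mean right extensions: intersection %.6g, union %.6g\n",
                x$mean_re_intersection, x$mean_re_union))
  if (!is.na(x$a))
    cat(sprintf("  containment terms: a=%d duplicate prefixes, b=%d overlap difference\n",
                x$a, x$b))
  invisible(x)
}

#' Monte-Carlo sampler of the truncation experiment
#'
#' One trial per hash seed, on full enumerations. Two events can be
#' sampled:
#' \describe{
#'   \item{`"union_minimizer"`}{does the length-k prefix of the hash
#'     minimizer of `A^{k+L} u B^{k+L}` lie in `A^k n B^k`? The closed
#'     form of [truncated_jaccard_closed_form()] is exactly the
#'     expectation of this event, for every k and L.}
#'   \item{`"two_sketch"`}{do the minimizers of `A^{k+L}` and of
#'     `B^{k+L}`, truncated to k, coincide? This is the literal
#'     single-element truncated-sketch collision. Its expectation matches
#'     the closed form only when length-k prefixes are nearly unique
#'     (`4^k` much larger than the pooled (k+L)-mer count); at small k the
#'     two quantities genuinely differ — see the methods vignette.}
#' }
#'
#' @inheritParams truncated_jaccard_closed_form
#' @param n_seeds number of independent hash seeds (trials).
#' @param seed first seed; trials use consecutive seeds.
#' @param method which event to sample.
#' @return the empirical frequency, a fraction in `[0, 1]`.
#' @export
truncated_jaccard_mc <- function(records_a, records_b, k, L,
                                 n_seeds = 5000L, seed = 1L,
                                 method = c("union_minimizer",
                                            "two_sketch"),
                                 canonical = FALSE) {
  method <- match.arg(method)
  stopifnot(L >= 0, n_seeds >= 1)
  a_kl <- enumerate_kmers(records_a, k + L, canonical)
  b_kl <- enumerate_kmers(records_b, k + L, canonical)
  if (!length(a_kl) || !length(b_kl))
    stop("both (k+L)-mer sets must be non-empty")
  shared <- intersect(enumerate_kmers(records_a, k, canonical),
                      enumerate_kmers(records_b, k, canonical))
  .cpp_mc_truncation(a_kl, b_kl, shared, as.integer(k), as.integer(k + L),
                     as.integer(n_seeds), as.double(seed),
                     if (method == "union_minimizer") 1L else 2L)
}

#' Containment truncation-bias terms
#'
#' The two counting terms of the containment-side bias decomposition,
#' reported as diagnostics (the streaming estimator applies no
#' correction): `a` is the number of duplicate prefixes collapsed when the
#' kmax sketch is truncated to k, and `b` is how many fewer of the
#' overlap-with-B elements the truncated sketch retains compared with a
#' fresh bottom-m sketch built directly at k (same seed, same m).
#'
#' `a` is computed two ways (multiset-minus-set size of the truncated
#' prefixes, and the sketch-size difference definition) and both must
#' agree.
#'
#' @param sketch an [build_sketch()] result at `kmax`.
#' @param records_a the sequences the sketch was built from (needed for
#'   the fresh bottom sketch at `k`).
#' @param records_b the query collection.
#' @param k truncation target, `k <= sketch$kmax`.
#' @return a `bias_report` with `a`, `b`, `ci_at_k` (fresh-sketch
#'   containment) and `ci_truncated` (truncated-sketch containment, both
#'   with denominator m).
#' @export
ci_bias_terms <- function(sketch, records_a, records_b, k) {
  stopifnot(inherits(sketch, "argmin_sketch"), k >= 1, k <= sketch$kmax)
  m_eff <- length(sketch$elements)
  pref_multi <- truncated_prefix_multiset(sketch, k)
  a1 <- m_eff - length(pref_multi)
  a2 <- as.integer(sum(pref_multi) - length(pref_multi))
  stopifnot(a1 == a2)
  fresh <- build_sketch(records_a, kmax = k, m = sketch$m,
                        order = hash_order(sketch$seed),
                        canonical = sketch$canonical,
                        cardinality_ks = integer(0))
  bk <- enumerate_kmers(records_b, k, sketch$canonical)
  n_fresh_in_b <- sum(fresh$elements %in% bk)
  n_trunc_in_b <- sum(names(pref_multi) %in% bk)
  bias_report(k = k, L = sketch$kmax - k,
              a = a1, b = as.integer(n_fresh_in_b - n_trunc_in_b),
              ci_at_k = n_fresh_in_b / length(fresh$elements),
              ci_truncated = n_trunc_in_b / m_eff)
}

#' Write bias reports as CSV
#'
#' @param reports a `bias_report` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bias_csv <- function(reports, path) {
  if (inherits(reports, "bias_report")) reports <- list(reports)
  rows <- lapply(reports, function(r)
    data.frame(k = r$k, L = r$L, ji_exact = r$ji_exact_at_k,
               ji_truncated = r$ji_truncated_closed_form,
               bias_factor = r$bias_factor_ji,
               a = r$a, b = r$b, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
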