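# A reproducible, fully synthetic version of the simulated-metagenome
# screening experiment: does the single truncatable index agree with the
# rebuild-per-k classic MinHash screen?

#' Truncation-vs-fixed-k agreement experiment
#'
#' Generates a community of related reference genomes, simulates shotgun
#' reads from a subset of them (the community members), then estimates
#' the containment of every reference in the read set at each `k` twice:
#' once by streaming through the single truncatable index built at
#' `kmax`, and once with a fresh classic bottom-m MinHash sketch built at
#' each `k` (same hash seed and sketch size). Returns the cell-wise
#' comparison; the headline summary is the median absolute CI difference
#' over all (reference, k) cells.
#'
#' All randomness (community, member choice, reads) derives from `seed`.
#'
#' @param n_genomes number of reference genomes.
#' @param genome_length reference genome length in bp.
#' @param n_members how many references emit reads.
#' @param n_reads number of simulated reads.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate of the reads.
#' @param divergence_range within-clade divergence range of the
#'   community.
#' @param kmax sketch k-mer size of the truncatable index.
#' @param ks k values to compare at (all `<= kmax`).
#' @param m sketch size for both methods.
#' @param seed master seed.
#' @param verbose log progress?
#' @return list with `cells` (data.frame: `dataset_id`, `k`, `ci_trunc`,
#'   `ci_fixed`, `abs_diff`, `member`), `median_abs_diff`, `members`
#'   (ids), and the generation parameters.
#' @export
truncation_agreement_experiment <- function(n_genomes = 100L,
                                            genome_length = 500000L,
                                            n_members = 20L,
                                            n_reads = 1000000L,
                                            read_length = 150L,
                                            error_rate = 0.005,
                                            divergence_range = c(0.01, 0.10),
                                            kmax = 60L,
                                            ks = seq(20L, 60L, by = 5L),
                                            m = 2000L,
                                            seed = 1L,
                                            verbose = FALSE) {
  stopifnot(n_members <= n_genomes, all(ks <= kmax))
  ord <- hash_order(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating %d genomes of %d bp", n_genomes, genome_length)
  com <- generate_community(n_genomes, genome_length,
                            divergence_range = divergence_range,
                            seed = seed)
  members <- sort(.deterministic_sample(n_genomes, n_members,
                                        seed = seed * 13 + 7))
  w <- numeric(n_genomes)
  w[members] <- 1
  say("simulating %d reads of %d bp from %d members (error %.3g)",
      n_reads, read_length, n_members, error_rate)
  reads <- simulate_reads(com, n_reads, read_length,
                          error_rate = error_rate, weights = w,
                          seed = seed + 1L)
  say("building %d sketches at kmax=%d, m=%d", n_genomes, kmax, m)
  sketches <- lapply(seq_len(n_genomes), function(i)
    build_sketch(com[i, ], kmax = kmax, m = m, order = ord,
                 dataset_id = com$id[i], cardinality_ks = integer(0)))
  idx <- build_index(sketches, k_range = ks)
  say("streaming reads through the index (%d k values)", length(ks))
  trunc <- stream_containment(idx, reads, compute_ji = FALSE,
                              verbose = verbose)
  say("classic fixed-k screen (rebuilds sketches per k)")
  refs <- setNames(lapply(seq_len(n_genomes), function(i) com[i, ]),
                   com$id)
  fixed <- minhash_containment_screen(refs, reads, ks, m = m, order = ord)
  cells <- merge(
    data.frame(dataset_id = trunc$dataset_id, k = trunc$k,
               ci_trunc = trunc$ci, stringsAsFactors = FALSE),
    data.frame(dataset_id = fixed$dataset_id, k = fixed$k,
               ci_fixed = fixed$ci, stringsAsFactors = FALSE),
    by = c("dataset_id", "k"))
  cells$abs_diff <- abs(cells$ci_trunc - cells$ci_fixed)
  cells$member <- cells$dataset_id %in% com$id[members]
  list(cells = cells,
       median_abs_diff = stats::median(cells$abs_diff),
       members = com$id[members],
       params = list(n_genomes = n_genomes,
                     genome_length = genome_length,
                     n_members = n_members, n_reads = n_reads,
                     read_length = read_length, error_rate = error_rate,
                     kmax = kmax, ks = ks, m = m, seed = seed))
}

# Seeded sample of n_pick from 1..n without replacement, independent of
# R's global RNG state (selection sort over deterministic draws).
.deterministic_sample <- function(n, n_pick, seed) {
  u <- vapply(seq_len(n), function(i)
    .cpp_unit_interval(as.double(seed) * 65537 + i), 0)
  order(u)[seq_len(n_pick)]
}
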