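# Seeded generators for synthetic communities of related genomes and
# shotgun reads with substitution errors. Everything is deterministic per
# seed and independent of R's global RNG state.

#' Generate a random genome
#'
#' I.i.d. uniform bases, deterministic per seed.
#'
#' @param length genome length in bp.
#' @param seed integer seed.
#' @param id record id.
#' @return a [seq_records] object with one record.
#' @export
generate_genome <- function(length, seed = 1L, id = "genome") {
  seq_records(.cpp_random_genome(as.double(length), as.double(seed)),
              id = id)
}

#' Mutate a genome
#'
#' Each site is substituted to a uniformly chosen *different* base with
#' probability `divergence`; with probability `indel_rate` a small indel
#' (1-3 bp, insertion or deletion equally likely) is introduced instead.
#' Emulates within-genus relatedness when descendants of one ancestor are
#' generated at divergences of a few percent.
#'
#' @param parent a [seq_records] object with one record (or a single
#'   string).
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param indel_rate per-site indel probability in `[0, 1]`; keep 0 when
#'   feeding the truncation-bias oracles, whose math is cleanest under
#'   substitution-only evolution.
#' @param seed integer seed.
#' @param id id of the mutated record.
#' @return a [seq_records] object with one record.
#' @export
mutate_genome <- function(parent, divergence, indel_rate = 0, seed = 1L,
                          id = NULL) {
  parent <- as_seq_records(parent)
  stopifnot(nrow(parent) == 1L,
            divergence >= 0, divergence <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (is.null(id)) id <- paste0(parent$id[1], "_mut")
  seq_records(.cpp_mutate_genome(parent$seq[1], divergence, indel_rate,
                                 as.double(seed)), id = id)
}

#' Generate a community of related genomes
#'
#' `n_genomes` genomes are generated as point-mutated descendants of
#' random ancestors: genomes are grouped into clades of size
#' `clade_size`; each clade gets an independent random ancestor and each
#' member diverges from it by a per-site substitution probability drawn
#' uniformly from `divergence_range`.
#'
#' @param n_genomes number of genomes.
#' @param genome_length length of each ancestor in bp.
#' @param divergence_range range of per-site substitution probabilities.
#' @param clade_size genomes per shared ancestor.
#' @param indel_rate per-site indel probability (default off).
#' @param seed integer seed.
#' @return a [seq_records] object with ids `g001`, `g002`, ...
#' @export
generate_community <- function(n_genomes, genome_length,
                               divergence_range = c(0.01, 0.10),
                               clade_size = 5L, indel_rate = 0,
                               seed = 1L) {
  stopifnot(n_genomes >= 1, genome_length >= 1, clade_size >= 1)
  ids <- sprintf("g%03d", seq_len(n_genomes))
  seqs <- character(n_genomes)
  n_clades <- ceiling(n_genomes / clade_size)
  for (cl in seq_len(n_clades)) {
    anc <- .cpp_random_genome(as.double(genome_length),
                              as.double(seed) * 1009 + cl)
    members <- seq.int((cl - 1L) * clade_size + 1L,
                       min(cl * clade_size, n_genomes))
    for (g in members) {
      # deterministic per-genome divergence in the requested range
      u <- .cpp_unit_interval(as.double(seed) * 2003 + g)
      d <- divergence_range[1] + u * diff(divergence_range)
      seqs[g] <- .cpp_mutate_genome(anc, d, indel_rate,
                                    as.double(seed) * 4001 + g)
    }
  }
  seq_records(seqs, ids)
}

#' Simulate shotgun reads
#'
#' Reads are drawn from the genomes proportionally to `weights`, with
#' uniform start positions, either strand with probability 1/2 (when
#' `both_strands`), and i.i.d. per-base substitution errors. No quality
#' model: presence/absence of k-mers is all the estimators consume.
#'
#' @param genomes a [seq_records] collection.
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param weights per-genome abundance weights (default uniform); genomes
#'   shorter than `read_length` are skipped with a warning.
#' @param both_strands sample reads from either strand?
#' @param seed integer seed.
#' @return a [seq_records] object of reads with ids `read0000001`, ...;
#'   the 1-based index of the source genome is in attribute `origin`.
#' @export
simulate_reads <- function(genomes, n_reads, read_length,
                           error_rate = 0.005, weights = NULL,
                           both_strands = TRUE, seed = 1L) {
  genomes <- as_seq_records(genomes)
  stopifnot(n_reads >= 1, read_length >= 1)
  if (is.null(weights)) weights <- rep(1, nrow(genomes))
  res <- .cpp_simulate_reads(genomes$seq, as.integer(n_reads),
                             as.integer(read_length), error_rate,
                             as.double(weights), as.double(seed),
                             isTRUE(both_strands))
  if (isTRUE(res$skipped_genomes))
    warning("genomes shorter than the read length were skipped",
            call. = FALSE)
  out <- seq_records(res$reads,
                     sprintf("read%07d", seq_len(n_reads)))
  attr(out, "origin") <- res$origin
  out
}

#' Write sequences as FASTA / reads as FASTQ
#'
#' FASTQ records carry a constant dummy quality (the simulators have no
#' quality model).
#'
#' @param records a [seq_records] object.
#' @param path output file; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_seq_records(records)
  x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  records <- as_seq_records(records)
  x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  qual <- Biostrings::BStringSet(vapply(nchar(records$seq), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path),
                              format = "fastq", qualities = qual)
  invisible(path)
}
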