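# The ternary search tree: prefix lookups, labels, counters, prefilter.

# a saturated two-element sketch holding exactly the given kmax-mers
manual_sketch <- function(elements, id, order = hash_order(1)) {
  build_sketch(seq_records(elements, paste0(id, seq_along(elements))),
               kmax = nchar(elements[1]), m = length(elements) * 4L,
               order = order, canonical = FALSE, dataset_id = id)
}

test_that("hand-built index answers prefix and leaf lookups", {
  sk <- manual_sketch(c("AAT", "AAG"), "d1")
  idx <- build_index(sk, k_range = c(2, 3))
  q <- prefix_query(idx, "AA")
  expect_equal(q$datasets, "d1")
  expect_false(is.na(q$node))
  expect_true(passes_prefilter(idx, "AA"))
  expect_true(passes_prefilter(idx, "AAT"))
  expect_true(passes_prefilter(idx, "AAG"))
  expect_equal(prefix_query(idx, "CC")$datasets, character(0))
  # leaf lookup returns exactly the owners of that element
  expect_equal(prefix_query(idx, "AAT")$datasets, "d1")
  expect_error(prefix_query(idx, "A"), "k_range")
})

test_that("label sets are unions over owning datasets", {
  s1 <- manual_sketch(c("AAT", "AAG"), "d1")
  s2 <- manual_sketch(c("AAT", "CGT"), "d2")
  idx <- build_index(list(s1, s2), k_range = c(2, 3))
  expect_same_set(prefix_query(idx, "AAT")$datasets, c("d1", "d2"))
  expect_same_set(prefix_query(idx, "AA")$datasets, c("d1", "d2"))
  expect_equal(prefix_query(idx, "CG")$datasets, "d2")
})

test_that("degenerate and inconsistent configurations are refused", {
  expect_error(build_index(list(), k_range = 3), "at least one sketch")
  s1 <- manual_sketch(c("AAT"), "d1")
  s2 <- build_sketch(seq_records("ACGTACGTAC"), kmax = 4, m = 2,
                     canonical = FALSE, dataset_id = "d2")
  expect_error(build_index(list(s1, s2), k_range = 2), "share kmax")
  s3 <- manual_sketch(c("AAG"), "d1")
  expect_error(build_index(list(s1, s3), k_range = 2), "duplicate")
  expect_error(build_index(s1, k_range = 5), "within")
})

test_that("prefix_query agrees with a linear scan over sketch elements", {
  com <- generate_community(4, 1500, divergence_range = c(0.02, 0.08),
                            clade_size = 2, seed = 21)
  ord <- hash_order(3)
  sketches <- lapply(seq_len(4), function(i)
    build_sketch(com[i, ], kmax = 8, m = 30, order = ord,
                 dataset_id = com$id[i]))
  idx <- build_index(sketches, k_range = c(3, 5, 8))
  set.seed(99)
  for (k in c(3, 5, 8)) {
    present <- unique(substr(unlist(lapply(sketches, `[[`, "elements")),
                             1, k))
    random <- vapply(1:30, function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
            collapse = ""), "")
    for (q in c(sample(present, min(20, length(present))), random)) {
      expect_same_set(prefix_query(idx, q)$datasets,
                      r_prefix_owners(sketches, q))
    }
  }
})

test_that("the prefilter has no false negatives and a bounded fp rate", {
  com <- generate_community(3, 4000, seed = 31)
  sketches <- lapply(seq_len(3), function(i)
    build_sketch(com[i, ], kmax = 20, m = 200, dataset_id = com$id[i]))
  idx <- build_index(sketches, k_range = c(10, 20), bloom_fp = 0.01)
  prefixes <- unique(substr(unlist(lapply(sketches, `[[`, "elements")),
                            1, 10))
  expect_true(all(vapply(prefixes, function(p)
    passes_prefilter(idx, p), TRUE)))
  # absent 20-mers: essentially all random ones are absent
  set.seed(5)
  absent <- vapply(1:10000, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
          collapse = ""), "")
  absent <- setdiff(absent, unlist(lapply(sketches, `[[`, "elements")))
  fp <- mean(vapply(absent, function(p) passes_prefilter(idx, p), TRUE))
  expect_lte(fp, 2 * 0.01)
})

test_that("disabling the prefilter changes no counter", {
  pair <- sibling_pair(6000, 0.04, seed = 41)
  sk <- build_sketch(pair$a, kmax = 16, m = 150, dataset_id = "ref",
                     cardinality_ks = c(8, 12, 16))
  idx <- build_index(sk, k_range = c(8, 12, 16))
  with_f <- stream_containment(idx, pair$b, prefilter = TRUE)
  without <- stream_containment(idx, pair$b, prefilter = FALSE)
  expect_identical(with_f$matches, without$matches)
  expect_identical(with_f$ci, without$ci)
})

test_that("truncated prefix multisets collapse duplicates as expected", {
  expect_equal(truncated_prefix_multiset(manual_sketch(c("AAT", "AAG"),
                                                       "d"), 2),
               c(AA = 2L))
  expect_equal(truncated_prefix_multiset(manual_sketch(c("AAT", "ATA"),
                                                       "d"), 2),
               c(AA = 1L, AT = 1L))
  # full-set sketch of the worked example truncated to 2: the four
  # 3-mers AAT, ATA, TAA, AAG truncate to AA (twice), AT and TA -- note
  # AG is a 2-mer of the data but not a prefix of any 3-mer
  full <- build_sketch(worked_example(), kmax = 3, m = 10,
                       canonical = FALSE)
  ms <- truncated_prefix_multiset(full, 2)
  expect_same_set(names(ms), c("AA", "AT", "TA"))
  expect_equal(unname(ms["AA"]), 2L)
  expect_equal(sum(ms), length(full$elements))
})

test_that("labels and words are conserved across the tree", {
  com <- generate_community(5, 2000, seed = 51)
  sketches <- lapply(seq_len(5), function(i)
    build_sketch(com[i, ], kmax = 10, m = 60, dataset_id = com$id[i]))
  idx <- build_index(sketches, k_range = c(4, 7, 10))
  info <- ktsketch:::.cpp_ktst_info(idx$.cache$ptr)
  all_elements <- unique(unlist(lapply(sketches, `[[`, "elements")))
  expect_equal(info$n_words, length(all_elements))
  # node label set equals the union over its word-descendants
  some <- unique(substr(all_elements, 1, 4))[1:15]
  for (p in some) {
    expect_same_set(prefix_query(idx, p)$datasets,
                    ktsketch:::.subtree_labels(idx, p))
  }
})

test_that("the index external pointer is rebuilt after serialization", {
  sk <- manual_sketch(c("AAT", "AAG", "CGT"), "d1")
  idx <- build_index(sk, k_range = c(2, 3))
  f <- tempfile(fileext = ".rds")
  saveRDS(idx, f)
  idx2 <- readRDS(f)
  expect_same_set(prefix_query(idx2, "AA")$datasets, "d1")
  expect_identical(stream_containment(idx2, seq_records("AATAAG"))$ci,
                   stream_containment(idx, seq_records("AATAAG"))$ci)
})
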