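# Brute-force indices, right extensions, closed-form truncation bias and
# its Monte-Carlo validation.

test_that("exact Jaccard and containment match direct set arithmetic", {
  a <- worked_example()          # A^2 = {AA, AT, TA, AG}
  b <- seq_records("AAT", "b")   # B^2 = {AA, AT}
  expect_equal(exact_jaccard(a, b, 2), 0.5)
  expect_equal(exact_containment(b, a, 2), 1.0)   # B fully contained
  expect_equal(exact_containment(a, b, 2), 0.5)
  expect_equal(exact_jaccard(a, a, 3), 1)
  polyA <- seq_records(strrep("A", 20))
  polyC <- seq_records(strrep("C", 20))
  expect_equal(exact_jaccard(polyA, polyC, 3), 0)
  expect_error(exact_containment(seq_records("AC"), a, 5), "empty")
})

test_that("right extensions count prefix continuations in the pool", {
  pool <- enumerate_kmers(worked_example(), 3, canonical = FALSE)
  expect_equal(right_extensions("AA", 1, pool), 2L)
  expect_equal(right_extensions("TA", 1, pool), 1L)
  expect_equal(right_extensions("CC", 1, pool), 0L)
  expect_equal(right_extensions(c("AA", "TA", "CC"), 1, pool),
               c(2L, 1L, 0L))
  expect_error(right_extensions("AA", 2, pool), "k\\+L")
})

test_that("the closed form reduces to the exact index at L=0 and 1 for A=B", {
  pair <- sibling_pair(3000, 0.06, seed = 121)
  for (k in c(5, 9)) {
    expect_equal(truncated_jaccard_closed_form(pair$a, pair$b, k, 0),
                 exact_jaccard(pair$a, pair$b, k), tolerance = 1e-12)
  }
  for (L in c(0, 3, 6)) {
    expect_equal(truncated_jaccard_closed_form(pair$a, pair$a, 8, L), 1.0)
  }
})

test_that("closed form, sum-ratio form and bias-factor form agree", {
  set.seed(131)
  for (i in 1:12) {
    len <- sample(1000:8000, 1)
    pair <- sibling_pair(len, runif(1, 0.01, 0.1), seed = 131 + i)
    k <- sample(4:12, 1); L <- sample(0:6, 1)
    rep <- jaccard_bias_factor(pair$a, pair$b, k, L)
    cf <- truncated_jaccard_closed_form(pair$a, pair$b, k, L)
    # Eq-by-hand: sum of right extensions over intersection / over union
    ak <- enumerate_kmers(pair$a, k, FALSE)
    bk <- enumerate_kmers(pair$b, k, FALSE)
    pool <- union(enumerate_kmers(pair$a, k + L, FALSE),
                  enumerate_kmers(pair$b, k + L, FALSE))
    num <- sum(right_extensions(intersect(ak, bk), L, pool))
    den <- sum(right_extensions(union(ak, bk), L, pool))
    expect_equal(cf, num / den, tolerance = 1e-12)
    expect_equal(den, length(pool))
    expect_equal(cf, rep$ji_exact_at_k * rep$bias_factor_ji,
                 tolerance = 1e-9)
    expect_equal(rep$ji_truncated_closed_form, cf, tolerance = 1e-12)
    if (L == 0) expect_equal(rep$bias_factor_ji, 1, tolerance = 1e-12)
  }
  # A = B: factor exactly 1 (intersection = union)
  g <- generate_genome(2000, seed = 141)
  rep <- jaccard_bias_factor(g, g, 6, 4)
  expect_equal(rep$bias_factor_ji, 1, tolerance = 1e-12)
})

test_that("the union-minimizer Monte-Carlo converges to the closed form", {
  pair <- sibling_pair(4000, 0.05, seed = 151)
  for (cfg in list(c(6, 3), c(10, 4))) {
    k <- cfg[1]; L <- cfg[2]
    cf <- truncated_jaccard_closed_form(pair$a, pair$b, k, L)
    mc <- truncated_jaccard_mc(pair$a, pair$b, k, L, n_seeds = 4000,
                               seed = 7, method = "union_minimizer")
    se <- sqrt(cf * (1 - cf) / 4000)
    expect_lt(abs(mc - cf), max(4 * se, 1e-12))
  }
})

test_that("the literal two-sketch collision departs from the closed form at small k", {
  # saturated-alphabet regime: two unrelated genomes share all 4-mers, so
  # the closed form is ~1 while two independent minimizers rarely share a
  # 4-prefix -- the first step of the bias derivation is an approximation,
  # not an identity (see the methods vignette)
  a <- generate_genome(5000, seed = 161, id = "a")
  b <- generate_genome(5000, seed = 162, id = "b")
  k <- 4; L <- 6
  cf <- truncated_jaccard_closed_form(a, b, k, L)
  expect_gt(cf, 0.99)
  two <- truncated_jaccard_mc(a, b, k, L, n_seeds = 3000, seed = 11,
                              method = "two_sketch")
  uni <- truncated_jaccard_mc(a, b, k, L, n_seeds = 3000, seed = 11,
                              method = "union_minimizer")
  expect_lt(two, 0.5)
  expect_lt(abs(uni - cf), 0.02)
})

# Exact expectation of the two-sketch collision, by conditioning on the
# union minimizer: if it lies in both (k+L)-mer sets the prefixes agree
# trivially; if it lies in one set only, the other set's minimizer is
# uniform over that set, so the collision chance is a right-extension
# fraction.
r_two_sketch_expectation <- function(a, b, k, L) {
  akl <- enumerate_kmers(a, k + L, canonical = FALSE)
  bkl <- enumerate_kmers(b, k + L, canonical = FALSE)
  u <- union(akl, bkl)
  both <- intersect(akl, bkl)
  only_a <- setdiff(akl, bkl)
  only_b <- setdiff(bkl, akl)
  re_b <- right_extensions(unique(substr(only_a, 1, k)), L, bkl)
  names(re_b) <- unique(substr(only_a, 1, k))
  re_a <- right_extensions(unique(substr(only_b, 1, k)), L, akl)
  names(re_a) <- unique(substr(only_b, 1, k))
  (length(both) +
     sum(re_b[substr(only_a, 1, k)]) / length(bkl) +
     sum(re_a[substr(only_b, 1, k)]) / length(akl)) / length(u)
}

test_that("the two-sketch Monte-Carlo matches its own exact expectation", {
  cases <- list(list(sibling_pair(1500, 0.04, seed = 163), 12, 2),
                list(sibling_pair(2500, 0.08, seed = 164), 6, 4),
                list(list(a = generate_genome(2000, seed = 165),
                          b = generate_genome(2000, seed = 166)), 4, 5))
  for (cs in cases) {
    pair <- cs[[1]]; k <- cs[[2]]; L <- cs[[3]]
    p_exact <- r_two_sketch_expectation(pair$a, pair$b, k, L)
    mc <- truncated_jaccard_mc(pair$a, pair$b, k, L, n_seeds = 4000,
                               seed = 12, method = "two_sketch")
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(mc - p_exact), max(4 * se, 1e-12))
  }
})

test_that("containment bias terms a and b behave as defined", {
  pair <- sibling_pair(3000, 0.05, seed = 171)
  sk <- build_sketch(pair$a, kmax = 14, m = 80, canonical = FALSE,
                     dataset_id = "ref")
  # no truncation: a = b = 0
  rep0 <- ci_bias_terms(sk, pair$a, pair$b, k = 14)
  expect_equal(rep0$a, 0L)
  expect_equal(rep0$b, 0L)
  expect_equal(rep0$ci_at_k, rep0$ci_truncated, tolerance = 1e-12)
  # the {AAT, AAG} example: one collapsed duplicate at k=2
  recs <- seq_records(c("AAT", "AAG"), c("x1", "x2"))
  sk2 <- build_sketch(recs, kmax = 3, m = 10, canonical = FALSE,
                      dataset_id = "two")
  rep2 <- ci_bias_terms(sk2, recs, pair$b, k = 2)
  expect_equal(rep2$a, 1L)
  # saturated sketch: a computed from the multiset equals the definition
  rep1 <- ci_bias_terms(sk, pair$a, pair$b, k = 7)
  ms <- truncated_prefix_multiset(sk, 7)
  expect_equal(rep1$a, as.integer(length(sk$elements) - length(ms)))
  expect_gte(rep1$a, 0L)
})

test_that("bias reports export to the documented CSV layout", {
  pair <- sibling_pair(2000, 0.05, seed = 181)
  reports <- list(jaccard_bias_factor(pair$a, pair$b, 6, 2),
                  jaccard_bias_factor(pair$a, pair$b, 8, 0))
  f <- tempfile(fileext = ".csv")
  write_bias_csv(reports, f)
  got <- read.csv(f)
  expect_equal(names(got), c("k", "L", "ji_exact", "ji_truncated",
                             "bias_factor", "a", "b"))
  expect_equal(got$k, c(6L, 8L))
  expect_equal(got$ji_truncated[2], got$ji_exact[2])
})
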