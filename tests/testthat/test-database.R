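# Database serialization and the command-line surface.

make_test_index <- function(seed = 201, k_range = c(4, 8, 12)) {
  com <- generate_community(3, 2000, seed = seed)
  sketches <- lapply(seq_len(3), function(i)
    build_sketch(com[i, ], kmax = 12, m = 50, dataset_id = com$id[i],
                 cardinality_ks = k_range))
  list(index = build_index(sketches, k_range = k_range), com = com)
}

test_that("save -> load reproduces sketches and query results exactly", {
  x <- make_test_index()
  db <- tempfile(fileext = ".json")
  save_database(x$index, db)
  idx2 <- load_database(db)
  for (i in 1:3) {
    expect_identical(idx2$sketches[[i]]$elements,
                     x$index$sketches[[i]]$elements)
    expect_identical(idx2$sketches[[i]]$hashes,
                     x$index$sketches[[i]]$hashes)
    expect_equal(idx2$sketches[[i]]$cardinalities,
                 x$index$sketches[[i]]$cardinalities)
  }
  q <- simulate_reads(x$com, 300, 60, seed = 202)
  t1 <- stream_containment(x$index, q)
  t2 <- stream_containment(idx2, q)
  expect_identical(t1$ci, t2$ci)
  expect_identical(t1$ji, t2$ji)
  expect_identical(t1$matches, t2$matches)
  # saving twice gives byte-identical files
  db2 <- tempfile(fileext = ".json")
  save_database(x$index, db2)
  expect_identical(readLines(db), readLines(db2))
  # gzip round-trip
  dbz <- tempfile(fileext = ".json.gz")
  save_database(x$index, dbz)
  expect_identical(load_database(dbz)$sketches[[1]]$elements,
                   x$index$sketches[[1]]$elements)
})

test_that("foreign or future-versioned files are refused explicitly", {
  x <- make_test_index()
  db <- tempfile(fileext = ".json")
  save_database(x$index, db)
  doc <- jsonlite::fromJSON(db, simplifyDataFrame = FALSE)
  doc$version <- 99L
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), db)
  expect_error(load_database(db), "version 99")
  writeLines('{"format": "something-else"}', db)
  expect_error(load_database(db), "not a ktsketch-db")
  expect_error(load_database(tempfile()), "no such file")
})

test_that("the element payload does not grow with the number of k values", {
  com <- generate_community(3, 2000, seed = 211)
  build_db <- function(k_range) {
    sketches <- lapply(seq_len(3), function(i)
      build_sketch(com[i, ], kmax = 12, m = 50, dataset_id = com$id[i],
                   cardinality_ks = integer(0)))
    idx <- build_index(sketches, k_range = k_range)
    db <- tempfile(fileext = ".json")
    save_database(idx, db)
    jsonlite::fromJSON(db, simplifyDataFrame = FALSE)
  }
  one <- build_db(6L)
  five <- build_db(c(4L, 6L, 8L, 10L, 12L))
  expect_identical(one$elements, five$elements)  # same payload
  expect_identical(vapply(one$datasets, `[[`, 1L, "n_elements"),
                   vapply(five$datasets, `[[`, 1L, "n_elements"))
})

test_that("the cli builds, queries and reproduces byte-identical CSVs", {
  wd <- tempfile(); dir.create(wd)
  old <- setwd(wd); on.exit(setwd(old))
  com <- generate_community(3, 1500, seed = 221)
  paths <- vapply(1:3, function(i) {
    p <- file.path(wd, paste0(com$id[i], ".fasta"))
    write_fasta(com[i, ], p)
    p
  }, "")
  suppressMessages({
    s <- cli_main(c("build", paths, "--kmax", "12",
                    "--k-range", "6,12", "--m", "40",
                    "--out", "db.json"))
    expect_equal(s, 0L)
    expect_true(file.exists("db.json"))
    # query one of the references against the database
    s <- cli_main(c("query", paths[2], "--db", "db.json",
                    "--out", "out.csv"))
    expect_equal(s, 0L)
  })
  got <- read.csv("out.csv")
  self <- got[got$dataset_id == com$id[2] & got$k == 12, ]
  expect_equal(self$ci_estimate, 1.0)
  suppressMessages(cli_main(c("query", paths[2], "--db", "db.json",
                              "--out", "out2.csv")))
  expect_identical(readLines("out.csv"), readLines("out2.csv"))
  # prefilter off: same values
  suppressMessages(cli_main(c("query", paths[2], "--db", "db.json",
                              "--out", "out3.csv", "--no-prefilter")))
  expect_identical(readLines("out.csv"), readLines("out3.csv"))
  # a query sharing nothing with the references
  write_fasta(seq_records(strrep("AC", 400), "probe"), "probe.fasta")
  suppressMessages(cli_main(c("query", "probe.fasta", "--db", "db.json",
                              "--out", "zero.csv")))
  z <- read.csv("zero.csv")
  expect_true(all(z$ci_estimate == 0))
})

test_that("the remaining cli subcommands run end to end", {
  wd <- tempfile(); dir.create(wd)
  old <- setwd(wd); on.exit(setwd(old))
  suppressMessages({
    expect_equal(cli_main(c("simulate", "--genomes", "2", "--length",
                            "800", "--reads", "50", "--read-length",
                            "60", "--out-prefix", "toy")), 0L)
    expect_true(file.exists("toy_genomes.fasta"))
    expect_true(file.exists("toy_reads.fastq"))
    com <- read_sequences("toy_genomes.fasta")
    write_fasta(com[1, ], "a.fasta")
    write_fasta(com[2, ], "b.fasta")
    out <- capture.output(
      expect_equal(cli_main(c("exact", "a.fasta", "b.fasta",
                              "--k", "6,12")), 0L))
    expect_length(out, 2)
    expect_match(out[1], "^k=6\tJI=")
    expect_equal(cli_main(c("bias", "a.fasta", "b.fasta", "--k", "6",
                            "--L", "0,2", "--out", "bias.csv")), 0L)
    bias <- read.csv("bias.csv")
    expect_equal(bias$ji_exact[1], bias$ji_truncated[1])  # L = 0 row
  })
  capture.output({
    expect_equal(cli_main("frobnicate"), 1L)
    expect_equal(cli_main(character(0)), 1L)
  })
})
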