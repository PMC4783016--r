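test_that("read_fasta parses records in file order and normalizes sequences", {
  fa <- write_tmp_fasta(c("r1", "r2"), c("ACGT", "TTAA"))
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("r1", "r2"))
  expect_equal(recs$seq, c("ACGT", "TTAA"))
  expect_equal(recs$length, c(4L, 4L))

  # lowercase and RNA letters are normalized
  fa2 <- write_tmp_fasta("r1", "acguACGU")
  expect_equal(read_fasta(fa2)$seq, "ACGTACGT")

  # wrapped and gzip inputs parse identically
  s <- replicate(3, random_dna(137))
  plain <- read_fasta(write_tmp_fasta(paste0("w", 1:3), s, width = 60))
  gz <- read_fasta(write_tmp_fasta(paste0("w", 1:3), s, gz = TRUE))
  expect_equal(plain$seq, s)
  expect_equal(gz$seq, s)

  # header descriptions after whitespace are dropped from the id
  fa3 <- tempfile(fileext = ".fasta")
  writeLines(c(">readA some description", "ACGT"), fa3)
  expect_equal(read_fasta(fa3)$id, "readA")
})

test_that("read_fasta rejects malformed inputs with informative errors", {
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no sequences")

  dup <- write_tmp_fasta(c("same_id", "same_id"), c("ACGT", "TTTT"))
  expect_error(read_fasta(dup), "same_id")

  noseq <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", ">c", "GGGG"), noseq)
  expect_error(read_fasta(noseq), "empty sequence")

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("dereplicate collapses exact duplicates and keeps input order", {
  recs <- seq_records(paste0("r", 1:5),
                      c("ACGT", "ACGT", "GGGG", "TTTT", "ACGT"))
  d <- dereplicate(recs)
  expect_equal(nrow(d$uniques), 3L)
  expect_equal(d$uniques$seq, c("ACGT", "GGGG", "TTTT"))
  expect_equal(d$abundance, c(3L, 1L, 1L))
  expect_equal(d$members[[1]], c("r1", "r2", "r5"))
  # representative's own id comes first in each member list
  expect_equal(vapply(d$members, `[[`, character(1), 1L), d$uniques$id)

  all_distinct <- seq_records(paste0("u", 1:4),
                              vapply(1:4, function(i) random_dna(30),
                                     character(1)))
  d2 <- dereplicate(all_distinct)
  expect_equal(d2$uniques$seq, all_distinct$seq)
  expect_equal(d2$abundance, rep(1L, 4))

  one_string <- seq_records(paste0("x", 1:10), rep("ACACAC", 10))
  d3 <- dereplicate(one_string)
  expect_equal(nrow(d3$uniques), 1L)
  expect_equal(d3$abundance, 10L)
})

test_that("rehydrate restores every original read exactly once", {
  recs <- seq_records(paste0("r", 1:3), c("AAAA", "AAAA", "CCCC"))
  d <- dereplicate(recs)
  out <- rehydrate(list(c(1L, 2L)), d)
  expect_equal(sort(out[[1]]), c("r1", "r2", "r3"))

  # all abundances 1: identity up to index -> id substitution
  recs2 <- seq_records(c("a", "b"), c("AAAA", "CCCC"))
  d2 <- dereplicate(recs2)
  expect_equal(rehydrate(list(1L, 2L), d2), list("a", "b"))

  # conservation with abundances [3, 1, 2, 1] over 2 clusters
  seqs <- c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG", "GGGG", "TTTT")
  d3 <- dereplicate(seq_records(paste0("q", 1:7), seqs))
  out3 <- rehydrate(list(c(1L, 2L), c(3L, 4L)), d3)
  expect_equal(sum(lengths(out3)), 7L)

  expect_error(rehydrate(list(1L), d3), "exactly once")
  expect_error(rehydrate(list(c(1L, 2L), c(2L, 3L, 4L)), d3), "exactly once")
})

test_that("dereplicate -> rehydrate round trip conserves the read-id multiset", {
  set.seed(4021)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    pool <- replicate(sample(2:6, 1), random_dna(25))
    recs <- seq_records(sprintf("rt%d_%d", rep, seq_len(n)),
                        sample(pool, n, replace = TRUE))
    d <- dereplicate(recs)
    expect_equal(sum(d$abundance), n)
    # arbitrary random partition of the uniques into clusters
    nu <- nrow(d$uniques)
    grp <- sample(seq_len(sample(nu, 1)), nu, replace = TRUE)
    clusters <- unname(split(seq_len(nu), grp))
    out <- rehydrate(clusters, d)
    expect_equal(sort(unlist(out)), sort(recs$id))
  }
})

test_that("write_outputs produces re-parseable, consistently sorted files", {
  mc <- mock_community(n_strains = 2, reads_per_strain = 6,
                       center_length = 120, seed = 3)
  fit <- otu_cluster(mc$records, kmer_threshold = 0.3)
  outdir <- tempfile("out")
  paths <- write_outputs(fit, outdir)
  expect_true(all(file.exists(paths)))

  counts <- read.table(paths[["counts"]], sep = "\t",
                       col.names = c("otu", "size"))
  expect_equal(nrow(counts), length(fit$otus))
  expect_true(all(diff(counts$size) <= 0))
  expect_equal(sum(counts$size), nrow(mc$records))

  reps <- Biostrings::readBStringSet(paths[["representatives"]])
  expect_equal(length(reps), length(fit$otus))

  assignments <- read_members_fasta(paths[["members"]])
  expect_setequal(names(assignments), mc$records$id)
  expect_equal(assignments[names(otu_assignments(fit))],
               otu_assignments(fit))
})
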