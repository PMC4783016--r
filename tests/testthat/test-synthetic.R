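test_that("generation is fully reproducible for a fixed seed", {
  a <- mock_community(n_strains = 3, reads_per_strain = 8,
                      center_length = 150, seed = 42)
  b <- mock_community(n_strains = 3, reads_per_strain = 8,
                      center_length = 150, seed = 42)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$centers, b$centers)

  c_ <- mock_community(n_strains = 3, reads_per_strain = 8,
                       center_length = 150, seed = 43)
  expect_false(identical(a$records$seq, c_$records$seq))

  # generation must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(mock_community(n_strains = 2, reads_per_strain = 2,
                                        center_length = 100, seed = 5))
  expect_identical(runif(1), before)
})

test_that("strain centers respect the divergence floor and labels are even", {
  mc <- mock_community(n_strains = 3, reads_per_strain = 10,
                       center_length = 150, seed = 7)
  expect_equal(nrow(mc$records), 30L)
  for (a in 1:2) {
    for (b in seq(a + 1, 3)) {
      expect_gte(nw_distance(mc$centers[[a]], mc$centers[[b]]), 0.10)
    }
  }
  expect_true(all(table(mc$truth) == 10))
  expect_equal(length(mc$truth), nrow(mc$records))
})

test_that("zero-noise reads equal their centers exactly", {
  mc <- mock_community(n_strains = 2, reads_per_strain = 5,
                       center_length = 100, read_mutation_rate = 0,
                       indel_rate = 0, duplicate_fraction = 0, seed = 11)
  expect_true(all(mc$records$seq == mc$centers[mc$truth]))
})

test_that("the duplicate fraction produces an exact count of copied reads", {
  # mutation rate high enough that unmutated reads (natural byte collisions)
  # are vanishingly unlikely, so duplicated() counts exactly the copies
  mc <- mock_community(n_strains = 5, reads_per_strain = 20,
                       duplicate_fraction = 0.5, read_mutation_rate = 0.02,
                       seed = 19)
  expect_equal(sum(duplicated(mc$records$seq)), 50L)
  # copies stay within their strain: dereplication classes are label-pure
  d <- dereplicate(mc$records)
  for (mem in d$members) {
    expect_equal(length(unique(mc$truth[mem])), 1L)
  }

  none <- mock_community(n_strains = 2, reads_per_strain = 10,
                         read_mutation_rate = 0.03,
                         duplicate_fraction = 0, seed = 20)
  expect_equal(sum(duplicated(none$records$seq)), 0L)

  expect_error(mock_community(n_strains = 2, reads_per_strain = 2,
                              duplicate_fraction = 0.9, seed = 1),
               "duplicate_fraction")
})

test_that("expected within-strain divergence is analytic and linear in the rates", {
  mc <- mock_community(n_strains = 2, reads_per_strain = 3,
                       center_length = 100, seed = 1)
  expect_equal(expected_within_divergence(mc), 0.0055)
  expect_equal(expected_within_divergence(0.004, 0.001), 0.005)
  expect_equal(expected_within_divergence(0.008, 0.002),
               2 * expected_within_divergence(0.004, 0.001))
  zero <- mock_community(n_strains = 2, reads_per_strain = 3,
                         center_length = 100, read_mutation_rate = 0,
                         indel_rate = 0, seed = 2)
  expect_equal(expected_within_divergence(zero), 0)
})

test_that("observed read-to-center divergence matches the expectation", {
  mc <- mock_community(n_strains = 5, reads_per_strain = 30,
                       duplicate_fraction = 0, seed = 33)
  d <- vapply(seq_len(nrow(mc$records)), function(r) {
    nw_distance(mc$records$seq[r], mc$centers[[mc$truth[r]]])
  }, numeric(1))
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected_within_divergence(mc)), 3 * se)

  zero <- mock_community(n_strains = 2, reads_per_strain = 5,
                         center_length = 120, read_mutation_rate = 0,
                         indel_rate = 0, duplicate_fraction = 0, seed = 3)
  dz <- vapply(seq_len(10), function(r) {
    nw_distance(zero$records$seq[r], zero$centers[[zero$truth[r]]])
  }, numeric(1))
  expect_true(all(dz == 0))
})

test_that("invalid rates and unreachable divergence floors are rejected", {
  expect_error(mock_community(read_mutation_rate = 1.2, seed = 1), "rates")
  # under classical global scoring random centers sit near ~0.6 dissimilarity,
  # so a 0.95 floor exhausts the repair budget
  expect_error(
    mock_community(n_strains = 4, reads_per_strain = 2, center_length = 100,
                   min_center_divergence = 0.95, seed = 1, max_retries = 3,
                   params = nw_params(terminal_gaps_free = FALSE,
                                      count_terminal_gaps_in_distance = TRUE)),
    "divergence"
  )
})

test_that("mock communities round-trip through FASTA and truth files", {
  mc <- mock_community(n_strains = 2, reads_per_strain = 4,
                       center_length = 100, seed = 8)
  fa <- tempfile(fileext = ".fasta")
  tr <- tempfile(fileext = ".tsv")
  write_mock_community(mc, fa, tr)
  expect_identical(read_fasta(fa)$seq, mc$records$seq)
  expect_identical(read_truth_tsv(tr), mc$truth)
})
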