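edge_df <- function(...) {
  m <- do.call(rbind, list(...))
  data.frame(i = m[, 1], j = m[, 2], d = 0)
}

test_that("network construction collapses duplicates and rejects self-loops", {
  net <- build_network(edge_df(c(1, 2), c(2, 3)), n = 4)
  expect_equal(lengths(net$adj), c(1L, 2L, 1L, 0L))

  empty <- build_network(data.frame(i = integer(0), j = integer(0)), n = 3)
  expect_equal(lengths(empty$adj), c(0L, 0L, 0L))

  dup <- build_network(edge_df(c(1, 2), c(2, 1), c(1, 2)), n = 2)
  expect_equal(lengths(dup$adj), c(1L, 1L))

  expect_error(build_network(edge_df(c(2, 2)), n = 3), "self-loop")
})

test_that("weighted degree counts neighbor abundance plus own duplicates", {
  star <- build_network(edge_df(c(1, 2), c(1, 3), c(1, 4)), n = 4)
  expect_equal(weighted_degree(star, 1, rep(1L, 4)), 3)

  iso <- build_network(data.frame(i = integer(0), j = integer(0)), n = 1)
  expect_equal(weighted_degree(iso, 1, 5L), 4)

  pair <- build_network(edge_df(c(1, 2), c(1, 3)), n = 3)
  expect_equal(weighted_degree(pair, 1, c(2L, 2L, 3L)), 2 + 3 + 1)

  active <- c(TRUE, FALSE, TRUE)
  expect_equal(weighted_degree(pair, 1, c(2L, 2L, 3L), active), 3 + 1)
  expect_error(weighted_degree(pair, 2, c(2L, 2L, 3L), active), "not active")
})

test_that("seed selection prefers maximal weighted degree with index tie-break", {
  star <- build_network(edge_df(c(3, 1), c(3, 2), c(3, 4), c(3, 5)), n = 5)
  expect_equal(select_seed(star, rep(1L, 5)), 3L)

  two_edges <- build_network(edge_df(c(1, 2), c(3, 4)), n = 4)
  expect_equal(select_seed(two_edges, rep(1L, 4)), 1L)

  # a heavily duplicated near-leaf outweighs a 3-neighbor hub; its own
  # unit-abundance partner ties at 10 and loses the index tie-break
  g <- build_network(edge_df(c(1, 2), c(1, 3), c(1, 4), c(5, 6)), n = 6)
  ab <- c(1L, 1L, 1L, 1L, 10L, 1L)
  expect_equal(weighted_degree(g, 5, ab), 10)
  expect_equal(weighted_degree(g, 6, ab), 10)
  expect_equal(weighted_degree(g, 1, ab), 3)
  expect_equal(select_seed(g, ab), 5L)

  expect_error(select_seed(star, rep(1L, 5), active = rep(FALSE, 5)),
               "no active")
})

test_that("peeling forms star clusters and leaves isolated nodes as singletons", {
  two_stars <- build_network(
    edge_df(c(1, 2), c(1, 3), c(1, 4), c(5, 6), c(5, 7), c(5, 8)), n = 8)
  res <- peel_clusters(two_stars, rep(1L, 8))
  expect_equal(length(res$clusters), 2L)
  expect_setequal(res$clusters[[1]], 1:4)
  expect_setequal(res$clusters[[2]], 5:8)
  expect_equal(res$seeds, c(1L, 5L))
  expect_equal(length(res$singletons), 0L)

  path <- build_network(edge_df(c(1, 2), c(2, 3)), n = 3)
  res2 <- peel_clusters(path, rep(1L, 3))
  expect_equal(res2$clusters, list(c(2L, 1L, 3L)))

  edgeless <- build_network(data.frame(i = integer(0), j = integer(0)), n = 4)
  res3 <- peel_clusters(edgeless, rep(1L, 4))
  expect_equal(res3$singletons, 1:4)
  expect_equal(lengths(res3$clusters), rep(1L, 4))
})

# Two star clusters whose seed sequences differ by ~1%, with leaves within
# 1% of their seed; leaves are attached to seeds only via initial edges.
two_star_toy <- function() {
  set.seed(77)
  s1 <- random_dna(200)
  s2 <- s1
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(s1, 50, 50))[1]
  mut1 <- function(s, p) {
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    s
  }
  seqs <- c(s1, mut1(s1, 10), mut1(s1, 20), s2, mut1(s2, 110), mut1(s2, 120))
  seq_records(paste0("t", 1:6), seqs)
}

test_that("refinement merges clusters whose seeds are within the NW threshold", {
  uniq <- two_star_toy()
  net <- build_network(edge_df(c(1, 2), c(1, 3), c(4, 5), c(4, 6)), n = 6)
  initial <- peel_clusters(net, rep(1L, 6))
  expect_equal(length(initial$clusters), 2L)
  fin <- refine(initial, net, uniq, rep(1L, 6), nw_threshold = 0.03)
  expect_equal(length(fin$clusters), 1L)
  expect_setequal(fin$clusters[[1]], 1:6)
})

test_that("refinement is a no-op when all seeds are mutually beyond the threshold", {
  set.seed(31)
  seqs <- c(replicate(3, random_dna(150)))
  uniq <- seq_records(paste0("far", 1:3), seqs)
  # pretend the prefilter connected nothing
  net <- build_network(data.frame(i = integer(0), j = integer(0)), n = 3)
  initial <- peel_clusters(net, rep(1L, 3))
  fin <- refine(initial, net, uniq, rep(1L, 3), nw_threshold = 0.03)
  expect_equal(length(fin$clusters), 3L)
  expect_equal(sort(unlist(fin$clusters)), 1:3)
})

test_that("a singleton within the threshold of a seed is absorbed", {
  uniq <- two_star_toy()  # node 4 is within 1% of node 1
  net <- build_network(edge_df(c(1, 2), c(1, 3)), n = 4)
  uniq <- uniq[1:4, ]
  initial <- peel_clusters(net, rep(1L, 4))
  expect_equal(initial$singletons, 4L)
  fin <- refine(initial, net, uniq, rep(1L, 4), nw_threshold = 0.03)
  expect_equal(length(fin$clusters), 1L)
  expect_setequal(fin$clusters[[1]], 1:4)
})

test_that("end-to-end clustering recovers a well-separated synthetic community", {
  mc <- mock_community(n_strains = 3, reads_per_strain = 20,
                       center_length = 250, seed = 5)
  fit <- otu_cluster(mc$records, sample_size = nrow(mc$records),
                     min_qualifying = 20)
  expect_equal(length(fit$otus), 3L)
  r <- evaluate_clustering(fit, mc$truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)

  # OTU names are assigned by decreasing size
  expect_true(all(diff(fit$sizes) <= 0))
  expect_equal(names(fit$otus), sprintf("OTU_%04d", seq_along(fit$otus)))
})

test_that("degenerate inputs cluster sensibly", {
  ident <- seq_records(paste0("i", 1:8), rep(strrep("ACGT", 20), 8))
  fit <- otu_cluster(ident, kmer_threshold = 0.2)
  expect_equal(length(fit$otus), 1L)
  expect_equal(unname(fit$sizes), 8L)

  set.seed(64)
  two <- seq_records(c("a", "b"), c(random_dna(100), random_dna(100)))
  fit2 <- otu_cluster(two, kmer_threshold = 0.2)
  expect_equal(length(fit2$otus), 2L)
  expect_equal(unname(fit2$sizes), c(1L, 1L))

  expect_error(otu_cluster(two, nw_threshold = 1.5), "nw_threshold")
  expect_error(otu_cluster(two, k = 200), "k must be")
})

test_that("every read lands in exactly one OTU and structure invariants hold", {
  mc <- mock_community(n_strains = 4, reads_per_strain = 12,
                       center_length = 200, read_mutation_rate = 0.01,
                       seed = 9)
  fit <- otu_cluster(mc$records, sample_size = 60, min_qualifying = 20)
  ids <- unlist(fit$otus, use.names = FALSE)
  expect_equal(sort(ids), sort(mc$records$id))
  expect_equal(sum(fit$sizes), nrow(mc$records))
  expect_true(check_membership_structure(fit))
  # seeds belong to their own OTUs
  expect_true(all(mapply(function(o, s) s %in% o, fit$otus, fit$seeds)))
})

test_that("S3 methods render and convert", {
  mc <- mock_community(n_strains = 2, reads_per_strain = 5,
                       center_length = 120, seed = 2)
  fit <- otu_cluster(mc$records, kmer_threshold = 0.3)
  expect_output(print(fit), "OTU clustering")
  expect_output(print(summary(fit)), "size distribution")
  df <- as.data.frame(fit)
  expect_setequal(df$read_id, mc$records$id)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
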