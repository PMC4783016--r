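#' All-pairs k-mer and alignment distances for a sequence sample
#'
#' Computes both the k-mer distance and the Needleman-Wunsch dissimilarity
#' for every unordered pair of the given sequences; the table drives the
#' threshold calibration.
#'
#' @param sample Record data frame (at least 2 rows) or character vector of
#'   sequences.
#' @param params [nw_params()] scoring.
#' @param k k-mer word length.
#' @return Data frame with `n(n-1)/2` rows and columns `i`, `j` (1-based,
#'   `i < j`), `kmer_d` and `nw_d`.
#' @export
pairwise_distance_table <- function(sample, params = nw_params(), k = 6L) {
  seqs <- if (is.data.frame(sample)) sample$seq else as.character(sample)
  m <- length(seqs)
  stopifnot(m >= 2L)
  codebook <- build_codebook(seqs, k)
  profiles <- lapply(seqs, encode_kmer_profile, codebook = codebook)
  ij <- pair_index_to_ij(seq(0, pair_count(m) - 1), m)
  i <- ij[, 1L] + 1L
  j <- ij[, 2L] + 1L
  kmer_d <- vapply(seq_along(i), function(r) {
    kmer_distance(profiles[[i[r]]], profiles[[j[r]]])
  }, numeric(1))
  nw_d <- vapply(seq_along(i), function(r) {
    nw_distance(seqs[i[r]], seqs[j[r]], params)
  }, numeric(1))
  data.frame(i = i, j = j, kmer_d = kmer_d, nw_d = nw_d)
}

#' Calibrate the k-mer prefilter threshold against the alignment threshold
#'
#' Maps the user's Needleman-Wunsch dissimilarity threshold (e.g. 0.03) to a
#' k-mer distance threshold by sampling: a random subset of the unique
#' sequences is drawn, both distances are computed for all sampled pairs,
#' and the threshold is set to the `quantile` level of the k-mer distances
#' among pairs whose NW distance is within `nw_threshold`. A high quantile
#' (default 0.99) trades a few extra candidate pairs for near-zero prefilter
#' false negatives.
#'
#' If fewer than `min_qualifying` pairs qualify, a least-squares line of
#' k-mer distance on NW distance over all sampled pairs is evaluated at
#' `nw_threshold` instead; if even that fit is degenerate (all NW distances
#' equal) the function stops and asks for an explicit threshold.
#'
#' @param uniques Record data frame of dereplicated sequences (duplicate
#'   pairs carry no calibration information).
#' @param nw_threshold Target alignment dissimilarity in (0, 1).
#' @param sample_size Maximum sequences to sample (default 1000).
#' @param quantile Quantile level of qualifying k-mer distances (default
#'   0.99).
#' @param params [nw_params()] scoring.
#' @param k k-mer word length.
#' @param rng_seed Integer seed making the draw reproducible.
#' @param min_qualifying Minimum qualifying pairs before the regression
#'   fallback engages (default 50).
#' @return An object of class `kmer_calibration`: list with `nw_threshold`,
#'   `kmer_threshold`, `n_sampled_seqs`, `n_pairs`, `n_qualifying_pairs`,
#'   `quantile_used`, `rng_seed` and `method` (`"quantile"` or
#'   `"regression"`).
#' @export
determine_kmer_threshold <- function(uniques, nw_threshold = 0.03,
                                     sample_size = 1000L, quantile = 0.99,
                                     params = nw_params(), k = 6L,
                                     rng_seed = 42L, min_qualifying = 50L) {
  stopifnot(is.data.frame(uniques), nrow(uniques) >= 2L)
  if (!(nw_threshold > 0 && nw_threshold < 1)) {
    stop("nw_threshold must be in (0, 1)")
  }
  if (!(quantile > 0 && quantile <= 1)) stop("quantile must be in (0, 1]")
  sample_size <- max(2L, as.integer(sample_size))
  n_take <- min(sample_size, nrow(uniques))
  idx <- with_seed(rng_seed, sample.int(nrow(uniques), n_take))
  tab <- pairwise_distance_table(uniques[idx, , drop = FALSE], params, k)
  qualifying <- tab$kmer_d[tab$nw_d <= nw_threshold]

  if (length(qualifying) >= min_qualifying) {
    kt <- unname(stats::quantile(qualifying, probs = quantile, type = 7))
    method <- "quantile"
  } else {
    if (length(unique(tab$nw_d)) < 2L) {
      stop("calibration failed: all sampled NW distances are equal and only ",
           length(qualifying), " pair(s) qualify; set kmer_threshold manually")
    }
    fit <- stats::lm(kmer_d ~ nw_d, data = tab)
    kt <- unname(predict(fit, data.frame(nw_d = nw_threshold)))
    method <- "regression"
  }
  kt <- min(max(kt, 1e-6), 1)
  structure(
    list(nw_threshold = nw_threshold, kmer_threshold = kt,
         n_sampled_seqs = n_take, n_pairs = nrow(tab),
         n_qualifying_pairs = length(qualifying),
         quantile_used = quantile, rng_seed = as.integer(rng_seed),
         method = method),
    class = "kmer_calibration"
  )
}

#' @export
print.kmer_calibration <- function(x, ...) {
  cat(sprintf(
    "k-mer threshold calibration (%s): NW %.4g -> k-mer %.4g\n  %d sequences sampled, %d pairs, %d qualifying (quantile %.2f, seed %d)\n",
    x$method, x$nw_threshold, x$kmer_threshold, x$n_sampled_seqs,
    x$n_pairs, x$n_qualifying_pairs, x$quantile_used, x$rng_seed))
  invisible(x)
}

#' Write a calibration record as TSV
#'
#' One-row provenance table stored alongside the clustering outputs.
#'
#' @param calibration A `kmer_calibration` object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "kmer_calibration"))
  df <- as.data.frame(unclass(calibration), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
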