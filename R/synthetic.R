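#' Simulate a mock community of 16S-like amplicon reads
#'
#' Generates a labeled read set emulating a mock community of known strain
#' composition: a small number of mutually divergent "strain" center
#' sequences, even per-strain read counts derived from the centers by
#' i.i.d. point substitutions and single-base indels, and a configurable
#' fraction of exact duplicate reads (real pyrosequencing runs carry
#' roughly 20-37% duplicates). Fully reproducible for a fixed seed.
#'
#' Centers are drawn uniformly over A/C/G/T and repaired by re-randomizing
#' one member of the closest pair until all pairwise Needleman-Wunsch
#' dissimilarities reach `min_center_divergence` (bounded retries).
#' Substitutions pick uniformly among the three alternative bases; indels
#' are single-base insertions or deletions with equal probability.
#'
#' @param n_strains Number of strains (default 5).
#' @param reads_per_strain Reads simulated per strain (default 20; even
#'   abundances, matching an even-concentration mock community).
#' @param center_length Center sequence length in bp (default 450, typical
#'   of 454 16S amplicons).
#' @param min_center_divergence Minimum pairwise NW dissimilarity between
#'   centers (default 0.10).
#' @param read_mutation_rate Per-base substitution probability per read
#'   (default 0.005).
#' @param indel_rate Per-base single-base indel probability (default
#'   0.0005).
#' @param duplicate_fraction Fraction of reads replaced by exact copies of
#'   earlier reads of the same strain (default 0.25).
#' @param seed Integer RNG seed (default 1).
#' @param params [nw_params()] used for the center-divergence check.
#' @param max_retries Center repair budget (default 100).
#' @return An object of class `mock_community`: list with `records` (record
#'   data frame), `truth` (named character vector read id -> strain label),
#'   `centers` (named character vector of center sequences) and `spec` (the
#'   generating parameters).
#' @examples
#' mc <- mock_community(n_strains = 3, reads_per_strain = 5,
#'                      center_length = 120, seed = 7)
#' mc
#' @export
mock_community <- function(n_strains = 5L, reads_per_strain = 20L,
                           center_length = 450L,
                           min_center_divergence = 0.10,
                           read_mutation_rate = 0.005,
                           indel_rate = 0.0005,
                           duplicate_fraction = 0.25,
                           seed = 1L, params = nw_params(),
                           max_retries = 100L) {
  n_strains <- as.integer(n_strains)
  reads_per_strain <- as.integer(reads_per_strain)
  stopifnot(n_strains >= 1L, reads_per_strain >= 1L, center_length >= 10L)
  for (r in c(min_center_divergence, read_mutation_rate, indel_rate,
              duplicate_fraction)) {
    if (!(r >= 0 && r <= 1)) stop("rates must be in [0, 1]")
  }
  spec <- list(n_strains = n_strains, reads_per_strain = reads_per_strain,
               center_length = as.integer(center_length),
               min_center_divergence = min_center_divergence,
               read_mutation_rate = read_mutation_rate,
               indel_rate = indel_rate,
               duplicate_fraction = duplicate_fraction,
               seed = as.integer(seed))
  with_seed(seed, {
    centers <- generate_centers(n_strains, center_length,
                                min_center_divergence, params, max_retries)
    strain_labels <- sprintf("strain_%02d", seq_len(n_strains))
    names(centers) <- strain_labels

    total <- n_strains * reads_per_strain
    ids <- character(total)
    seqs <- character(total)
    strains <- character(total)
    r <- 0L
    for (s in seq_len(n_strains)) {
      for (w in seq_len(reads_per_strain)) {
        r <- r + 1L
        ids[r] <- sprintf("S%02d_read%04d", s, w)
        seqs[r] <- mutate_read(centers[[s]], read_mutation_rate, indel_rate)
        strains[r] <- strain_labels[s]
      }
    }

    # Replace a fixed count of reads by exact copies of an earlier read of
    # the same strain; only reads with a within-strain predecessor qualify.
    n_dup <- round(duplicate_fraction * total)
    within_idx <- rep(seq_len(reads_per_strain), times = n_strains)
    eligible <- which(within_idx >= 2L)
    if (n_dup > length(eligible)) {
      stop("duplicate_fraction too high for reads_per_strain")
    }
    if (n_dup > 0L) {
      dup_at <- sort(sample(eligible, n_dup))
      for (d in dup_at) {
        strain_start <- d - within_idx[d] + 1L
        earlier <- seq(strain_start, d - 1L)
        src <- earlier[sample.int(length(earlier), 1L)]
        seqs[d] <- seqs[src]
      }
    }

    structure(
      list(records = seq_records(ids, seqs),
           truth = stats::setNames(strains, ids),
           centers = centers, spec = spec),
      class = "mock_community"
    )
  })
}

#' @export
print.mock_community <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Mock community: %d strains x %d reads (%d bp centers, seed %d)\n",
              s$n_strains, s$reads_per_strain, s$center_length, s$seed))
  cat(sprintf("  substitution rate %.4g, indel rate %.4g, duplicate fraction %.2f\n",
              s$read_mutation_rate, s$indel_rate, s$duplicate_fraction))
  invisible(x)
}

generate_centers <- function(n_strains, center_length, min_div, params,
                             max_retries) {
  bases <- c("A", "C", "G", "T")
  rand_center <- function() {
    paste(sample(bases, center_length, replace = TRUE), collapse = "")
  }
  centers <- vapply(seq_len(n_strains), function(i) rand_center(),
                    character(1))
  if (n_strains == 1L || min_div == 0) return(centers)
  tries <- 0L
  repeat {
    dmin <- 1
    worst <- NULL
    for (a in seq_len(n_strains - 1L)) {
      for (b in seq(a + 1L, n_strains)) {
        d <- nw_distance(centers[a], centers[b], params)
        if (d < dmin) {
          dmin <- d
          worst <- c(a, b)
        }
      }
    }
    if (dmin >= min_div) return(centers)
    if (tries >= max_retries) {
      stop("could not reach the requested center divergence within ",
           max_retries, " retries; use longer centers or fewer strains")
    }
    tries <- tries + 1L
    centers[worst[2L]] <- rand_center()
  }
}

# Apply i.i.d. substitutions then single-base indels to one center string.
mutate_read <- function(center, sub_rate, indel_rate) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(center, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (sub_rate > 0) {
    hit <- which(runif(L) < sub_rate)
    for (p in hit) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
  }
  if (indel_rate > 0) {
    hit <- which(runif(length(chars)) < indel_rate)
    # process right to left so earlier positions stay valid
    for (p in rev(hit)) {
      if (runif(1) < 0.5) {
        chars <- append(chars, sample(bases, 1L), after = p)
      } else {
        chars <- chars[-p]
      }
    }
  }
  if (length(chars) == 0L) chars <- sample(bases, 1L)
  paste(chars, collapse = "")
}

#' Expected read-to-center dissimilarity of a mock community
#'
#' First-order analytic expectation of the Needleman-Wunsch dissimilarity
#' between a simulated read and its strain center: each substitution and
#' each single-base indel contributes one non-identical column per
#' affected base, so the expectation is approximately
#' `read_mutation_rate + indel_rate`. Used to sanity-check generated sets.
#'
#' @param x A `mock_community` object, or a numeric substitution rate.
#' @param indel_rate Indel rate (only when `x` is numeric).
#' @return Expected dissimilarity.
#' @export
expected_within_divergence <- function(x, indel_rate = NULL) {
  if (inherits(x, "mock_community")) {
    return(x$spec$read_mutation_rate + x$spec$indel_rate)
  }
  stopifnot(is.numeric(x), is.numeric(indel_rate))
  x + indel_rate
}

#' Write a mock community to FASTA and truth TSV
#'
#' @param mc A `mock_community` object.
#' @param fasta_path Output FASTA path.
#' @param truth_path Output truth TSV path (read id, strain label).
#' @return Invisibly, the two paths.
#' @export
write_mock_community <- function(mc, fasta_path, truth_path) {
  stopifnot(inherits(mc, "mock_community"))
  set <- Biostrings::BStringSet(stats::setNames(mc$records$seq,
                                                mc$records$id))
  Biostrings::writeXStringSet(set, fasta_path, width = 20000L)
  write_truth_tsv(mc$truth, truth_path)
  invisible(c(fasta = fasta_path, truth = truth_path))
}
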