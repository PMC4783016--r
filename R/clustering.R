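#' Build a sequence network from thresholded distance edges
#'
#' Undirected graph over unique sequences whose edges are the pairs that
#' passed a distance threshold. Duplicate edges collapse; self loops are
#' rejected.
#'
#' @param edges Data frame with integer columns `i` and `j` (1-based node
#'   indices) as returned by [run_pair_tasks()].
#' @param n Node count.
#' @return An object of class `seq_network`: list with `n` and `adj`, a
#'   length-`n` list of sorted neighbor index vectors.
#' @export
build_network <- function(edges, n) {
  n <- as.integer(n)
  i <- as.integer(edges$i)
  j <- as.integer(edges$j)
  stopifnot(all(i >= 1L), all(j >= 1L), all(i <= n), all(j <= n))
  if (any(i == j)) stop("self-loop edge(s) at node(s): ",
                        paste(unique(i[i == j]), collapse = ", "))
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  nb <- split(c(hi, lo), factor(c(lo, hi), levels = seq_len(n)))
  adj <- lapply(nb, function(v) sort(unique(as.integer(v))))
  names(adj) <- NULL
  structure(list(n = n, adj = adj), class = "seq_network")
}

#' @export
print.seq_network <- function(x, ...) {
  cat(sprintf("Sequence network: %d nodes, %d edges\n",
              x$n, sum(lengths(x$adj)) / 2))
  invisible(x)
}

#' Abundance-weighted degree of a network node
#'
#' The connectivity score used for seed selection: the summed abundance of
#' the node's active neighbors plus `abundance[node] - 1` for the node's own
#' exact duplicates, which sit at distance 0 and act as implicit neighbors.
#' This makes a 10-fold-duplicated read as attractive a seed as a hub with
#' ten unit-abundance neighbors.
#'
#' @param network A `seq_network`.
#' @param node Node index (1-based); must be active.
#' @param abundance Integer abundance per node (from [dereplicate()]).
#' @param active Logical vector of not-yet-clustered nodes (default all).
#' @return Integer weighted degree.
#' @export
weighted_degree <- function(network, node, abundance,
                            active = rep(TRUE, network$n)) {
  stopifnot(inherits(network, "seq_network"))
  if (!active[node]) stop("node ", node, " is not active")
  nb <- network$adj[[node]]
  nb <- nb[active[nb]]
  sum(abundance[nb]) + abundance[node] - 1L
}

#' Select the next cluster seed
#'
#' The active node with maximal [weighted_degree()]; ties break to the
#' smallest node index for determinism.
#'
#' @inheritParams weighted_degree
#' @return Seed node index.
#' @export
select_seed <- function(network, abundance, active = rep(TRUE, network$n)) {
  idx <- which(active)
  if (length(idx) == 0L) stop("no active nodes")
  wd <- vapply(idx, function(v) weighted_degree(network, v, abundance, active),
               numeric(1))
  idx[which.max(wd)]   # which.max takes the first maximum: smallest index
}

#' Greedy peeling of a sequence network into initial clusters
#'
#' Repeatedly selects the most-connected active node as seed, forms a
#' cluster from the seed and its active direct neighbors, and deactivates
#' them, until every remaining active node has no active neighbor. Those
#' remaining nodes are singletons; each is also recorded as a size-1
#' cluster so that every node belongs to exactly one initial cluster.
#'
#' @inheritParams weighted_degree
#' @return List with `clusters` (list of integer member vectors, seed
#'   first), `seeds` (integer vector, one per cluster) and `singletons`
#'   (integer vector of the leftover zero-degree nodes).
#' @export
peel_clusters <- function(network, abundance) {
  stopifnot(inherits(network, "seq_network"))
  n <- network$n
  active <- rep(TRUE, n)
  clusters <- list()
  seeds <- integer(0)
  repeat {
    idx <- which(active)
    if (length(idx) == 0L) break
    has_nb <- vapply(idx, function(v) any(active[network$adj[[v]]]),
                     logical(1))
    if (!any(has_nb)) break
    s <- select_seed(network, abundance, active)
    nb <- network$adj[[s]]
    members <- c(s, nb[active[nb]])
    clusters[[length(clusters) + 1L]] <- members
    seeds <- c(seeds, s)
    active[members] <- FALSE
  }
  singletons <- which(active)
  for (s in singletons) {
    clusters[[length(clusters) + 1L]] <- s
    seeds <- c(seeds, s)
  }
  list(clusters = clusters, seeds = seeds, singletons = singletons)
}

#' Refine initial clusters at the exact alignment threshold
#'
#' Second clustering pass: the initial seeds and singletons become the
#' candidate set, Needleman-Wunsch distances are computed for all candidate
#' pairs through the chunked scheduler, and a refined network keeps pairs
#' within `nw_threshold`. Peeling the refined network yields the final
#' clusters: each refined seed claims its active refined-network neighbors
#' plus every not-yet-assigned leaf of the initial network directly
#' connected to the seed or to one of those neighbors. Assignment is
#' greedy: once claimed, a node is removed from both networks, so
#' earlier-formed clusters win contested leaves. Only non-candidate nodes
#' can be absorbed through initial-network edges, which guarantees that
#' every unique sequence ends in exactly one final cluster.
#'
#' @param initial Result of [peel_clusters()].
#' @param network The initial `seq_network` (k-mer edges).
#' @param uniques Record data frame of unique sequences.
#' @param abundance Integer abundance per unique sequence.
#' @param nw_threshold Alignment dissimilarity threshold.
#' @param params [nw_params()] scoring.
#' @param granularity,workers Scheduler configuration, see
#'   [run_pair_tasks()].
#' @param verbose Log progress.
#' @return List with `clusters` (list of integer member vectors over unique
#'   indices, refined seed first) and `seeds` (integer vector).
#' @export
refine <- function(initial, network, uniques, abundance, nw_threshold = 0.03,
                   params = nw_params(), granularity = 2000, workers = 1L,
                   verbose = FALSE) {
  stopifnot(inherits(network, "seq_network"))
  n <- network$n
  cand <- sort(unique(c(initial$seeds, initial$singletons)))
  m <- length(cand)
  is_cand <- rep(FALSE, n)
  is_cand[cand] <- TRUE

  seqs <- uniques$seq
  nw_fn <- function(a, b) nw_distance(seqs[cand[a]], seqs[cand[b]], params)
  nw_edges <- if (m >= 2L) {
    run_pair_tasks(m, nw_fn, nw_threshold, granularity, workers,
                   verbose = verbose)
  } else {
    data.frame(i = integer(0), j = integer(0), d = numeric(0))
  }
  refined <- build_network(nw_edges, m)

  assigned <- rep(FALSE, n)
  cand_active <- rep(TRUE, m)
  clusters <- list()
  seeds <- integer(0)
  while (any(cand_active)) {
    s_loc <- select_seed(refined, abundance[cand], cand_active)
    nb_loc <- refined$adj[[s_loc]]
    nb_loc <- nb_loc[cand_active[nb_loc]]
    core <- cand[c(s_loc, nb_loc)]
    pulled <- unique(unlist(network$adj[core], use.names = FALSE))
    pulled <- pulled[!assigned[pulled] & !is_cand[pulled]]
    members <- c(core, pulled)
    clusters[[length(clusters) + 1L]] <- members
    seeds <- c(seeds, cand[s_loc])
    assigned[members] <- TRUE
    cand_active[c(s_loc, nb_loc)] <- FALSE
  }
  if (any(!assigned)) {
    stop("internal error: ", sum(!assigned),
         " unique sequence(s) left unassigned after refinement")
  }
  list(clusters = clusters, seeds = seeds)
}

#' Cluster 16S rRNA reads into OTUs
#'
#' End-to-end two-pass network clustering: dereplicate, build the k-mer
#' codebook and profiles, calibrate the k-mer prefilter threshold against
#' the alignment threshold (unless `kmer_threshold` is given), evaluate all
#' unique-sequence pairs through the chunked scheduler, peel the initial
#' k-mer network, refine seeds and singletons at the exact
#' Needleman-Wunsch threshold, recover duplicates, and name OTUs
#' `OTU_0001, ...` by decreasing size (ties by seed read id). Deterministic
#' for a fixed seed and configuration, independent of `workers` and
#' `granularity`.
#'
#' @param records Record data frame from [read_fasta()] or [seq_records()],
#'   or a path to a FASTA file.
#' @param nw_threshold Alignment dissimilarity defining OTUs (default 0.03,
#'   the conventional species-level cutoff; 0.05 approximates genus level).
#' @param k k-mer word length for the prefilter (default 6).
#' @param kmer_threshold Optional explicit prefilter threshold; bypasses
#'   calibration entirely.
#' @param granularity Pairs per scheduler task (default 2000).
#' @param workers Worker processes for pair tasks (default 1).
#' @param sample_size,quantile,min_qualifying Calibration controls, see
#'   [determine_kmer_threshold()].
#' @param params [nw_params()] alignment scoring.
#' @param rng_seed Seed for the calibration sample (default 42).
#' @param verbose Log per-stage progress.
#' @return An object of class `otu_clustering` with components `otus`
#'   (named list of read-id vectors), `seeds` (named vector of seed read
#'   ids), `sizes` (named integer vector), `n_reads`, `n_uniques`,
#'   `calibration` (or `NULL` when bypassed), `derep`, `unique_clusters`
#'   and `unique_seeds` (clustering over unique indices), `network` (the
#'   initial k-mer network) and `config`.
#' @examples
#' recs <- seq_records(
#'   paste0("r", 1:6),
#'   c("ACGTACGTACGTACGT", "ACGTACGTACGTACGT", "ACGTACGAACGTACGT",
#'     "TTGCAATTGGCCAATT", "TTGCAATTGGCCAATC", "TTGCAATTGGCCAATT")
#' )
#' fit <- otu_cluster(recs, k = 4, kmer_threshold = 0.5)
#' fit
#' @export
otu_cluster <- function(records, nw_threshold = 0.03, k = 6L,
                        kmer_threshold = NULL, granularity = 2000,
                        workers = 1L, sample_size = 1000L, quantile = 0.99,
                        min_qualifying = 50L, params = nw_params(),
                        rng_seed = 42L, verbose = FALSE) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_fasta(records)
  }
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!(nw_threshold > 0 && nw_threshold < 1)) {
    stop("nw_threshold must be in (0, 1)")
  }
  k <- as.integer(k)
  if (k < 1L || k > min(records$length)) {
    stop("k must be in [1, shortest read length]")
  }
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(...) if (verbose) message(sprintf(...))

  derep <- dereplicate(records)
  n <- nrow(derep$uniques)
  log_stage("dereplication: %d reads -> %d uniques", nrow(records), n)

  codebook <- build_codebook(derep$uniques$seq, k)
  profiles <- lapply(derep$uniques$seq, encode_kmer_profile,
                     codebook = codebook)
  log_stage("k-mer transformation: %d codes (k = %d)", codebook$next_code, k)

  calibration <- NULL
  if (is.null(kmer_threshold)) {
    if (n < 2L) {
      kmer_threshold <- 1
    } else {
      calibration <- determine_kmer_threshold(
        derep$uniques, nw_threshold = nw_threshold,
        sample_size = sample_size, quantile = quantile, params = params,
        k = k, rng_seed = rng_seed, min_qualifying = min_qualifying
      )
      kmer_threshold <- calibration$kmer_threshold
      log_stage("calibration (%s): k-mer threshold %.4f",
                calibration$method, kmer_threshold)
    }
  }

  kmer_fn <- function(a, b) kmer_distance(profiles[[a]], profiles[[b]])
  edges <- run_pair_tasks(n, kmer_fn, kmer_threshold, granularity, workers,
                          verbose = verbose)
  network <- build_network(edges, n)
  log_stage("initial network: %d edges within k-mer threshold", nrow(edges))

  initial <- peel_clusters(network, derep$abundance)
  log_stage("initial clustering: %d clusters (%d singletons)",
            length(initial$clusters), length(initial$singletons))

  final <- refine(initial, network, derep$uniques, derep$abundance,
                  nw_threshold = nw_threshold, params = params,
                  granularity = granularity, workers = workers,
                  verbose = verbose)
  log_stage("refinement: %d final clusters", length(final$clusters))

  read_clusters <- rehydrate(final$clusters, derep)
  sizes <- lengths(read_clusters)
  seed_ids <- derep$uniques$id[final$seeds]
  ord <- order(-sizes, seed_ids)
  otu_names <- sprintf("OTU_%04d", seq_along(ord))
  otus <- stats::setNames(read_clusters[ord], otu_names)
  structure(
    list(
      otus = otus,
      seeds = stats::setNames(seed_ids[ord], otu_names),
      sizes = stats::setNames(as.integer(sizes[ord]), otu_names),
      n_reads = nrow(records),
      n_uniques = n,
      nw_threshold = nw_threshold,
      kmer_threshold = kmer_threshold,
      calibration = calibration,
      derep = derep,
      unique_clusters = final$clusters[ord],
      unique_seeds = final$seeds[ord],
      initial_seeds = initial$seeds,
      initial_singletons = initial$singletons,
      network = network,
      config = list(
        nw_threshold = nw_threshold, k = k, kmer_threshold = kmer_threshold,
        granularity = granularity, workers = workers,
        sample_size = sample_size, quantile = quantile,
        min_qualifying = min_qualifying, params = unclass(params),
        rng_seed = rng_seed
      ),
      elapsed = proc.time()[["elapsed"]] - t_start
    ),
    class = "otu_clustering"
  )
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("OTU clustering: %d reads (%d unique) -> %d OTUs at %.3g NW dissimilarity\n",
              x$n_reads, x$n_uniques, length(x$otus), x$nw_threshold))
  cat(sprintf("k-mer prefilter threshold: %.4f%s\n", x$kmer_threshold,
              if (is.null(x$calibration)) " (user-supplied)"
              else sprintf(" (calibrated, %s)", x$calibration$method)))
  sz <- x$sizes
  show <- utils::head(sz, 5L)
  cat("largest OTUs: ",
      paste(sprintf("%s (%d)", names(show), show), collapse = ", "),
      if (length(sz) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.otu_clustering <- function(object, ...) {
  sz <- object$sizes
  structure(
    list(n_reads = object$n_reads, n_uniques = object$n_uniques,
         n_otus = length(sz), nw_threshold = object$nw_threshold,
         kmer_threshold = object$kmer_threshold,
         n_singleton_otus = sum(sz == 1L),
         size_summary = summary(as.integer(sz))),
    class = "summary.otu_clustering"
  )
}

#' @export
print.summary.otu_clustering <- function(x, ...) {
  cat(sprintf("%d reads (%d unique) clustered into %d OTUs at %.3g NW dissimilarity\n",
              x$n_reads, x$n_uniques, x$n_otus, x$nw_threshold))
  cat(sprintf("k-mer prefilter threshold %.4f; %d singleton OTUs\n",
              x$kmer_threshold, x$n_singleton_otus))
  cat("OTU size distribution:\n")
  print(x$size_summary)
  invisible(x)
}

#' @describeIn otu_cluster Rank-size barplot of OTU sizes.
#' @param x,y,... Standard plot-method arguments.
#' @export
plot.otu_clustering <- function(x, y, ...) {
  graphics::barplot(x$sizes, names.arg = NA,
                    xlab = "OTU (decreasing size)", ylab = "reads",
                    main = sprintf("%d OTUs at %.3g dissimilarity",
                                   length(x$sizes), x$nw_threshold), ...)
  invisible(x)
}

#' @export
as.data.frame.otu_clustering <- function(x, ...) {
  data.frame(
    read_id = unlist(x$otus, use.names = FALSE),
    otu = rep(names(x$otus), lengths(x$otus)),
    stringsAsFactors = FALSE
  )
}

#' Read-to-OTU assignment vector of a clustering
#'
#' @param fit An `otu_clustering` object.
#' @return Named character vector mapping every read id to its OTU name.
#' @export
otu_assignments <- function(fit) {
  stopifnot(inherits(fit, "otu_clustering"))
  df <- as.data.frame(fit)
  stats::setNames(df$otu, df$read_id)
}
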