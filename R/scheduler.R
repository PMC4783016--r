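#' Number of unordered sequence pairs
#'
#' For `n` sequences, all-pairs distance computation spans `n(n-1)/2` pairs
#' (the triangular pair space that chunked tasks partition).
#'
#' @param n Non-negative integer.
#' @return `n * (n - 1) / 2` as a double (exact for the sizes in scope).
#' @export
pair_count <- function(n) {
  n <- as.numeric(n)
  stopifnot(length(n) == 1L, !is.na(n))
  if (n < 0) stop("n must be non-negative")
  n * (n - 1) / 2
}

#' Map linear pair indices to sequence index pairs
#'
#' Canonical linearization of the triangular pair space:
#' `index(i, j) = j * (j - 1) / 2 + i` for `0 <= i < j <= n - 1`, filling the
#' triangle column by column (top to bottom, left to right). Indices are
#' 0-based at this level; the scheduler converts to 1-based sequence indices
#' when invoking a distance function.
#'
#' @param t Vector of 0-based linear pair indices, each in
#'   `[0, pair_count(n))`.
#' @param n Number of sequences.
#' @return Integer matrix with columns `i` and `j` (0-based, `i < j`).
#' @export
pair_index_to_ij <- function(t, n) {
  t <- as.numeric(t)
  total <- pair_count(n)
  if (any(t < 0 | t >= total)) {
    stop("pair index out of range [0, ", total, ")")
  }
  # j is the largest integer with j(j-1)/2 <= t; solve and fix up any
  # floating-point slip at the boundary.
  j <- floor((1 + sqrt(1 + 8 * t)) / 2)
  j <- j - (j * (j - 1) / 2 > t)
  j <- j + ((j + 1) * j / 2 <= t)
  i <- t - j * (j - 1) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

# Inverse of pair_index_to_ij (0-based).
ij_to_pair_index <- function(i, j) {
  stopifnot(all(i < j))
  unname(as.numeric(j) * (j - 1) / 2 + i)
}

#' Cut the pair space into fixed-size chunks
#'
#' Splits the `pair_count(n)` linear pair indices into consecutive chunks of
#' `granularity` pairs (the last chunk may be smaller). Granularity is the
#' per-task workload knob; 2000 pairs is the measured optimum used as the
#' default throughout the package.
#'
#' @param n Number of sequences.
#' @param granularity Pairs per chunk, at least 1.
#' @return Data frame with columns `chunk_id` (1-based ordinal), `start`
#'   (inclusive, 0-based) and `stop` (exclusive).
#' @export
chunk_pairs <- function(n, granularity = 2000) {
  granularity <- as.numeric(granularity)
  if (length(granularity) != 1L || is.na(granularity) || granularity < 1) {
    stop("granularity must be at least 1")
  }
  total <- pair_count(n)
  if (total == 0) {
    return(data.frame(chunk_id = integer(0), start = numeric(0),
                      stop = numeric(0)))
  }
  starts <- seq(0, total - 1, by = granularity)
  data.frame(chunk_id = seq_along(starts), start = starts,
             stop = pmin(starts + granularity, total))
}

#' Evaluate all sequence pairs in chunked, optionally parallel tasks
#'
#' Runs `distance_fn` on every one of the `pair_count(n)` pairs exactly
#' once, in fixed-size chunks executed on a local worker pool, and retains
#' only edges with distance at or below `threshold` (the sparse network
#' representation; the dense matrix is never materialized). Chunk results
#' are merged into the edge store as each task completes, in chunk order,
#' so the returned edge set is identical for every worker count and every
#' granularity.
#'
#' @param n Number of sequences.
#' @param distance_fn Function of two 1-based sequence indices `(i, j)`
#'   returning a numeric distance. An error raised here aborts the run with
#'   the originating pair reported.
#' @param threshold Retain pairs with `d <= threshold`.
#' @param granularity Pairs per task (default 2000).
#' @param workers Local worker processes (default 1; forked via the
#'   parallel package when greater).
#' @param verbose Log per-chunk progress.
#' @return Data frame of edges with columns `i`, `j` (1-based, `i < j`) and
#'   `d`, ordered by linear pair index.
#' @export
run_pair_tasks <- function(n, distance_fn, threshold, granularity = 2000,
                           workers = 1L, verbose = FALSE) {
  stopifnot(is.function(distance_fn), is.numeric(threshold))
  workers <- max(1L, as.integer(workers))
  chunks <- chunk_pairs(n, granularity)
  eval_chunk <- function(ci) {
    ts <- seq(chunks$start[ci], chunks$stop[ci] - 1)
    ij <- pair_index_to_ij(ts, n)
    i <- ij[, 1L] + 1L
    j <- ij[, 2L] + 1L
    d <- vapply(seq_along(i), function(r) {
      tryCatch(as.numeric(distance_fn(i[r], j[r])),
               error = function(e) {
                 stop("distance evaluation failed for pair (", i[r], ", ",
                      j[r], "): ", conditionMessage(e), call. = FALSE)
               })
    }, numeric(1))
    keep <- !is.na(d) & d <= threshold
    list(i = i[keep], j = j[keep], d = d[keep])
  }

  acc <- vector("list", nrow(chunks))
  ids <- chunks$chunk_id
  # Waves of `workers` tasks; each completed task is merged before the next
  # wave starts, bounding the intermediate state held at any time.
  waves <- split(ids, ceiling(seq_along(ids) / workers))
  for (wave in waves) {
    res <- if (workers > 1L) {
      parallel::mclapply(wave, eval_chunk, mc.cores = workers)
    } else {
      lapply(wave, eval_chunk)
    }
    for (w in seq_along(res)) {
      r <- res[[w]]
      if (inherits(r, "try-error")) {
        cond <- attr(r, "condition")
        stop(if (is.null(cond)) as.character(r) else conditionMessage(cond),
             call. = FALSE)
      }
      if (!is.list(r)) stop("pair task ", wave[w], " failed")
      acc[[wave[w]]] <- r
    }
    if (verbose) {
      message(sprintf("  pair tasks: %d/%d chunks merged",
                      max(wave), nrow(chunks)))
    }
  }
  data.frame(
    i = as.integer(unlist(lapply(acc, `[[`, "i"), use.names = FALSE)),
    j = as.integer(unlist(lapply(acc, `[[`, "j"), use.names = FALSE)),
    d = as.numeric(unlist(lapply(acc, `[[`, "d"), use.names = FALSE))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
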