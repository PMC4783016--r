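# Shared fixtures and independent oracles used across the suite.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(ids, seqs, gz = FALSE, width = NULL) {
  path <- tempfile(fileext = if (gz) ".fasta.gz" else ".fasta")
  lines <- unlist(lapply(seq_along(ids), function(i) {
    s <- seqs[i]
    body <- if (is.null(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    c(paste0(">", ids[i]), body)
  }))
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

# O(m^2) pair-enumeration confusion counts -- the definitional oracle for the
# contingency-table implementation.
brute_confusion <- function(clusters, truth) {
  ids <- intersect(names(clusters), names(truth))
  TP <- FP <- TN <- FN <- 0
  m <- length(ids)
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      same_otu <- clusters[ids[a]] == clusters[ids[b]]
      same_strain <- truth[ids[a]] == truth[ids[b]]
      if (same_otu && same_strain) TP <- TP + 1
      else if (same_otu && !same_strain) FP <- FP + 1
      else if (!same_otu && same_strain) FN <- FN + 1
      else TN <- TN + 1
    }
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN, m = m)
}

# Pure-R recount of an alignment's distance from its gapped strings, written
# against the documented column policy (not the C++ code path).
recount_distance <- function(ax, ay, params, min_len) {
  cx <- strsplit(ax, "", fixed = TRUE)[[1]]
  cy <- strsplit(ay, "", fixed = TRUE)[[1]]
  L <- length(cx)
  gap_col <- cx == "-" | cy == "-"
  lead <- 0
  while (lead < L && gap_col[lead + 1]) lead <- lead + 1
  trail <- 0
  while (trail < L && gap_col[L - trail]) trail <- trail + 1
  counted_idx <- if (params$count_terminal_gaps_in_distance) {
    seq_len(L)
  } else {
    seq_len(L)[seq_len(L) > lead & seq_len(L) <= L - trail]
  }
  identical <- sum(!gap_col[counted_idx] &
                     cx[counted_idx] == cy[counted_idx] &
                     cx[counted_idx] %in% c("A", "C", "G", "T"))
  counted <- length(counted_idx)
  d <- if (counted > 0) 1 - identical / counted else 1
  if (counted < ceiling(params$min_overlap_frac * min_len)) d <- 1
  min(max(d, 0), 1)
}

# Structural membership check: every member of a final OTU must be the
# refined seed, within the NW threshold of it, or connected in the initial
# k-mer network to a node of the first two kinds.
check_membership_structure <- function(fit) {
  params <- do.call(nw_params, fit$config$params)
  t <- fit$nw_threshold
  seqs <- fit$derep$uniques$seq
  adj <- fit$network$adj
  for (o in seq_along(fit$unique_clusters)) {
    members <- fit$unique_clusters[[o]]
    seed <- fit$unique_seeds[o]
    near <- vapply(members, function(u) {
      u == seed || nw_distance(seqs[u], seqs[seed], params) <= t
    }, logical(1))
    anchor <- members[near]
    for (u in members[!near]) {
      if (!any(adj[[u]] %in% anchor)) return(FALSE)
    }
  }
  TRUE
}

fixture_fasta <- function() {
  system.file("extdata", "synthetic_mock_reads.fasta", package = "otunet")
}

fixture_truth <- function() {
  system.file("extdata", "synthetic_mock_truth.tsv", package = "otunet")
}
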