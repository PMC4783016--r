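#' Read amplicon reads from a FASTA file
#'
#' Reads a plain or gzip-compressed FASTA file of quality-controlled 16S rRNA
#' reads. Sequences are uppercased and RNA `U` is mapped to `T`; both wrapped
#' and single-line FASTA are accepted. Record identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' No quality control is performed: inputs are expected to be already
#' trimmed, error-corrected and chimera-checked.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A data frame of sequence records with columns `id` (character),
#'   `seq` (uppercase nucleotide string) and `length` (bp).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgtACGT", ">r2", "TTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no sequences in ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA records with empty identifiers in ", path)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("record(s) with empty sequence: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  seq_records(ids, seqs)
}

#' Construct a set of sequence records
#'
#' Lightweight constructor for the record table used throughout the package.
#' Sequences are uppercased and `U` mapped to `T`.
#'
#' @param id Character vector of unique, non-empty read identifiers.
#' @param seq Character vector of nucleotide strings, same length as `id`.
#' @return A data frame with columns `id`, `seq` and `length`.
#' @export
seq_records <- function(id, seq) {
  id <- as.character(id)
  seq <- chartr("U", "T", toupper(as.character(seq)))
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id)) || anyDuplicated(id)) {
    stop("read identifiers must be unique and non-empty")
  }
  if (any(!nzchar(seq))) {
    stop("sequences must be non-empty")
  }
  data.frame(id = id, seq = seq, length = nchar(seq),
             stringsAsFactors = FALSE)
}

#' Collapse exact-duplicate reads
#'
#' Dereplicates a read set by exact full-length string identity. The
#' representative of each duplicate class is its first occurrence, and
#' representatives keep their input order. Abundances feed the
#' abundance-weighted seed selection during clustering; the member map allows
#' duplicates to be recovered into the final OTUs.
#'
#' @param records A record data frame from [read_fasta()] or [seq_records()].
#' @return An object of class `derep_set`: a list with `uniques` (record data
#'   frame of representatives), `abundance` (integer vector, one count per
#'   representative) and `members` (list of original read-id vectors; the
#'   first element of each is the representative's own id).
#' @examples
#' recs <- seq_records(paste0("r", 1:5),
#'                     c("ACGT", "ACGT", "GGGG", "ACGT", "TTTT"))
#' dereplicate(recs)
#' @export
dereplicate <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  first <- !duplicated(records$seq)
  uniques <- records[first, , drop = FALSE]
  rownames(uniques) <- NULL
  rep_idx <- match(records$seq, uniques$seq)
  members <- split(records$id, factor(rep_idx, levels = seq_len(nrow(uniques))))
  names(members) <- NULL
  abundance <- lengths(members)
  structure(
    list(uniques = uniques, abundance = as.integer(abundance),
         members = members),
    class = "derep_set"
  )
}

#' @export
print.derep_set <- function(x, ...) {
  cat(sprintf("Dereplicated set: %d unique sequences from %d reads (%.1f%% duplicates)\n",
              nrow(x$uniques), sum(x$abundance),
              100 * (1 - nrow(x$uniques) / sum(x$abundance))))
  invisible(x)
}

#' Expand clusters of unique sequences back to original reads
#'
#' Replaces each unique-sequence index in a clustering with the full list of
#' original read ids it represents, recovering the duplicates removed by
#' [dereplicate()].
#'
#' @param clusters List of integer vectors of unique-sequence indices; the
#'   vectors must jointly partition `1:length(derep$members)`.
#' @param derep A `derep_set` from [dereplicate()].
#' @return List of character vectors of original read ids, one per cluster.
#' @export
rehydrate <- function(clusters, derep) {
  stopifnot(inherits(derep, "derep_set"), is.list(clusters))
  n <- length(derep$members)
  got <- sort(unlist(clusters, use.names = FALSE))
  if (!identical(as.integer(got), seq_len(n))) {
    stop("clusters must assign every unique sequence index exactly once")
  }
  lapply(clusters, function(ix) {
    unlist(derep$members[ix], use.names = FALSE)
  })
}

#' Write the three standard clustering output files
#'
#' Writes (1) a members FASTA with every original read under a
#' `"<OTU>|<read_id>"` header, (2) a representatives FASTA with one seed
#' record per OTU under `"<OTU>|<seed_read_id>"`, and (3) a tab-separated
#' counts file `"<OTU>\t<size>"` sorted by decreasing size then OTU name.
#' All files are UTF-8 with LF line endings.
#'
#' @param fit An [otu_cluster()] result.
#' @param outdir Output directory (created if missing).
#' @param prefix File name prefix, default `"otunet"`.
#' @return Invisibly, a named character vector of the three paths
#'   (`members`, `representatives`, `counts`).
#' @export
write_outputs <- function(fit, outdir, prefix = "otunet") {
  stopifnot(inherits(fit, "otu_clustering"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  if (file.access(outdir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", outdir)
  }
  paths <- c(
    members = file.path(outdir, paste0(prefix, "_otu_members.fasta")),
    representatives = file.path(outdir, paste0(prefix, "_otu_representatives.fasta")),
    counts = file.path(outdir, paste0(prefix, "_otu_counts.tsv"))
  )

  read_seq <- read_sequence_map(fit)
  otu_names <- names(fit$otus)

  members <- Biostrings::BStringSet(unlist(lapply(otu_names, function(o) {
    ids <- fit$otus[[o]]
    stats::setNames(read_seq[ids], paste0(o, "|", ids))
  })))
  Biostrings::writeXStringSet(members, paths[["members"]], width = 20000L)

  reps <- Biostrings::BStringSet(stats::setNames(
    read_seq[fit$seeds[otu_names]],
    paste0(otu_names, "|", fit$seeds[otu_names])
  ))
  Biostrings::writeXStringSet(reps, paths[["representatives"]], width = 20000L)

  counts <- data.frame(otu = otu_names, size = fit$sizes[otu_names])
  counts <- counts[order(-counts$size, counts$otu), , drop = FALSE]
  writeLines(paste(counts$otu, counts$size, sep = "\t"), paths[["counts"]])

  invisible(paths)
}

# Named character vector read_id -> sequence for every original read (a
# duplicate inherits its representative's string).
read_sequence_map <- function(fit) {
  derep <- fit$derep
  ids <- unlist(derep$members, use.names = FALSE)
  seqs <- rep(derep$uniques$seq, lengths(derep$members))
  stats::setNames(seqs, ids)
}

#' Read a members FASTA back into a read-to-OTU assignment
#'
#' Parses the `"<OTU>|<read_id>"` headers of a members FASTA written by
#' [write_outputs()].
#'
#' @param path Path to a members FASTA file.
#' @return Named character vector mapping read id to OTU name.
#' @export
read_members_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  parts <- strsplit(sub("\\s.*$", "", names(set)), "|", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed members FASTA header(s) in ", path)
  otu <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(parts, function(p) paste(p[-1L], collapse = "|"), character(1))
  stats::setNames(otu, id)
}
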