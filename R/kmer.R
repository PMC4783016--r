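#' Build a k-mer codebook over a set of sequences
#'
#' Assigns a small integer code to every distinct A/C/G/T-only word of length
#' `k` occurring in the input, in first-encounter order (sequences scanned in
#' order, positions left to right). Replacing k-mer strings by integer codes
#' is a pure representation change that lets the distance kernel compare
#' integers instead of strings; it must not (and does not) alter any
#' distance.
#'
#' Words containing characters outside `A`, `C`, `G`, `T` (ambiguity codes,
#' `N`) are skipped: they receive no code and are never counted.
#'
#' @param seqs Character vector of uppercase sequences (or a record data
#'   frame from [read_fasta()]).
#' @param k Word length, default 6.
#' @return An object of class `kmer_codebook`: a list with `mapping` (named
#'   integer vector, k-mer string to code starting at 0), `k`, and
#'   `next_code` (number of codes assigned).
#' @examples
#' build_codebook("ACGT", k = 2)
#' @export
build_codebook <- function(seqs, k = 6L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  k <- as.integer(k)
  stopifnot(length(seqs) >= 1L, k >= 1L)
  if (k > max(nchar(seqs))) {
    stop("k = ", k, " exceeds every sequence length")
  }
  words <- unlist(lapply(seqs, kmer_words, k = k), use.names = FALSE)
  words <- words[!is.na(words)]
  keys <- unique(words)   # first-encounter order
  mapping <- stats::setNames(seq_along(keys) - 1L, keys)
  structure(list(mapping = mapping, k = k, next_code = length(keys)),
            class = "kmer_codebook")
}

#' @export
print.kmer_codebook <- function(x, ...) {
  cat(sprintf("k-mer codebook: %d codes over words of length %d\n",
              x$next_code, x$k))
  invisible(x)
}

# All words of length k of one sequence, in position order; words containing
# non-ACGT characters are returned as NA.
kmer_words <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  w <- substring(seq, starts, starts + k - 1L)
  w[grepl("[^ACGT]", w)] <- NA_character_
  w
}

#' Encode a sequence as a coded k-mer profile
#'
#' Replaces every valid k-mer of the sequence by its codebook integer and
#' tallies occurrences. The codebook must cover every A/C/G/T word of the
#' sequence (build it over a superset of the inputs).
#'
#' @param seq A single sequence string (or one-row record data frame).
#' @param codebook A `kmer_codebook` from [build_codebook()].
#' @return An object of class `kmer_profile`: a list with `codes` (strictly
#'   increasing integer vector), `counts` (occurrences per code),
#'   `n_kmers` (total counted words) and `seq_length` (bp).
#' @export
encode_kmer_profile <- function(seq, codebook) {
  stopifnot(inherits(codebook, "kmer_codebook"))
  if (is.data.frame(seq)) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L)
  w <- kmer_words(seq, codebook$k)
  w <- w[!is.na(w)]
  codes <- unname(codebook$mapping[w])
  if (anyNA(codes)) {
    stop("k-mer(s) absent from the codebook: ",
         paste(unique(w[is.na(codes)]), collapse = ", "))
  }
  if (length(codes) > 0L) {
    tab <- sort(unique(codes))
    counts <- tabulate(match(codes, tab), nbins = length(tab))
  } else {
    tab <- integer(0)
    counts <- integer(0)
  }
  structure(list(codes = as.integer(tab), counts = as.integer(counts),
                 n_kmers = length(codes), seq_length = nchar(seq),
                 k = codebook$k),
            class = "kmer_profile")
}

#' k-mer distance between two coded profiles
#'
#' The common-word dissimilarity used to build the initial sequence network:
#' \deqn{d = 1 - \frac{\sum_w \min(c_x(w), c_y(w))}{\min(L_x, L_y) - k + 1}}
#' clamped to \[0, 1\]. Shared counts are summed over coded words only;
#' the denominator is the word capacity of the shorter sequence regardless
#' of skipped ambiguous words. The formula is isolated here (and in the
#' C++ kernel it calls) so an alternative normalization can be swapped in.
#'
#' @param px,py `kmer_profile` objects built with the same codebook.
#' @return Numeric distance in \[0, 1\]; symmetric; 0 for identical
#'   sequences.
#' @examples
#' cb <- build_codebook(c("ACGTACGT", "ACGTTCGT"), k = 4)
#' kmer_distance(encode_kmer_profile("ACGTACGT", cb),
#'               encode_kmer_profile("ACGTTCGT", cb))
#' @export
kmer_distance <- function(px, py) {
  stopifnot(inherits(px, "kmer_profile"), inherits(py, "kmer_profile"))
  if (px$k != py$k) {
    stop("profiles were built with different k (", px$k, " vs ", py$k, ")")
  }
  .kmer_profile_distance_cpp(px$codes, px$counts, py$codes, py$counts,
                             px$seq_length, py$seq_length, px$k)
}

#' k-mer distance computed directly on word strings
#'
#' Reference path that bypasses the codebook entirely: words are counted as
#' strings and the same formula as [kmer_distance()] is applied. Because the
#' codebook transformation is a pure re-labelling, the two paths agree
#' exactly for all inputs; this function serves as the in-package oracle for
#' that contract.
#'
#' @param x,y Sequence strings of length at least `k`.
#' @param k Word length.
#' @return Numeric distance in \[0, 1\].
#' @export
kmer_distance_strings <- function(x, y, k = 6L) {
  k <- as.integer(k)
  stopifnot(nchar(x) >= k, nchar(y) >= k, k >= 1L)
  wx <- kmer_words(toupper(x), k)
  wy <- kmer_words(toupper(y), k)
  cx <- table(wx[!is.na(wx)])
  cy <- table(wy[!is.na(wy)])
  common <- intersect(names(cx), names(cy))
  shared <- sum(pmin(as.integer(cx[common]), as.integer(cy[common])))
  denom <- min(nchar(x), nchar(y)) - k + 1L
  min(max(1 - shared / denom, 0), 1)
}
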