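#' Pair-counting confusion counts against strain labels
#'
#' Classifies every unordered pair of labeled reads into one of four
#' categories: same strain and same OTU (TP), different strain but same OTU
#' (FP), same strain but different OTUs (FN), different strain and
#' different OTUs (TN). Computed from the per-(OTU, strain) contingency
#' table with pair-count binomials, which is exactly equivalent to
#' enumerating all `m(m-1)/2` pairs.
#'
#' Reads present in `clusters` but missing from `truth` are excluded with a
#' warning; reads present only in `truth` are ignored.
#'
#' @param clusters Named character vector mapping read id to OTU (see
#'   [otu_assignments()]), or an `otu_clustering` object.
#' @param truth Named character vector mapping read id to strain label.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`, `m` (labeled reads used) and `n_unlabeled` (excluded).
#' @examples
#' cl <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "B")
#' tr <- c(r1 = "s1", r2 = "s1", r3 = "s2", r4 = "s2")
#' confusion_counts(cl, tr)
#' @export
confusion_counts <- function(clusters, truth) {
  if (inherits(clusters, "otu_clustering")) {
    clusters <- otu_assignments(clusters)
  }
  stopifnot(!is.null(names(clusters)), !is.null(names(truth)))
  ids <- intersect(names(clusters), names(truth))
  if (length(ids) == 0L) {
    stop("no reads shared between clustering and truth labels")
  }
  n_unlabeled <- sum(!(names(clusters) %in% names(truth)))
  if (n_unlabeled > 0L) {
    warning(n_unlabeled, " clustered read(s) without a truth label excluded")
  }
  otu <- clusters[ids]
  strain <- truth[ids]
  m <- length(ids)
  tab <- table(otu, strain)
  pairs2 <- function(v) sum(v * (v - 1) / 2)
  TP <- pairs2(as.numeric(tab))
  same_otu <- pairs2(as.numeric(rowSums(tab)))
  same_strain <- pairs2(as.numeric(colSums(tab)))
  FP <- same_otu - TP
  FN <- same_strain - TP
  TN <- m * (m - 1) / 2 - TP - FP - FN
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, m = m,
                 n_unlabeled = n_unlabeled),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("pair confusion over %d labeled reads (%g pairs):\n",
              x$m, x$m * (x$m - 1) / 2))
  cat(sprintf("  TP %g  FP %g  FN %g  TN %g\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Precision, recall and F-measure from pair confusion counts
#'
#' Precision `TP / (TP + FP)`, recall `TP / (TP + FN)` (each defined as 1
#' when its denominator is 0) and the recall-weighted F-measure
#' \deqn{F_\beta = \frac{(1 + \beta^2) P R}{\beta^2 P + R}}
#' with `beta = 2` by default (F-measure II; `beta = 1` gives the plain
#' harmonic mean). `f_beta` is 0 when precision and recall are both 0.
#'
#' @param counts A `confusion_counts` object.
#' @param beta Recall weight, default 2.
#' @return An object of class `accuracy_report`: list with `precision`,
#'   `recall`, `f_beta`, `beta` and the counts.
#' @export
accuracy_report <- function(counts, beta = 2) {
  stopifnot(inherits(counts, "confusion_counts"), beta > 0)
  precision <- if (counts$TP + counts$FP == 0) 1 else {
    counts$TP / (counts$TP + counts$FP)
  }
  recall <- if (counts$TP + counts$FN == 0) 1 else {
    counts$TP / (counts$TP + counts$FN)
  }
  f_beta <- if (precision == 0 && recall == 0) 0 else {
    (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
  }
  structure(list(precision = precision, recall = recall, f_beta = f_beta,
                 beta = beta, counts = counts),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F%g %.4f\n",
              x$precision, x$recall, x$beta, x$f_beta))
  invisible(x)
}

#' Number of non-empty OTUs in a clustering
#'
#' @param clusters An `otu_clustering` object, a named read-to-OTU vector,
#'   or a list of member vectors.
#' @return Integer OTU count.
#' @export
count_otus <- function(clusters) {
  if (inherits(clusters, "otu_clustering")) {
    return(sum(lengths(clusters$otus) > 0L))
  }
  if (is.list(clusters)) {
    if (length(clusters) == 0L) stop("empty clustering")
    return(sum(lengths(clusters) > 0L))
  }
  if (length(clusters) == 0L) stop("empty clustering")
  length(unique(clusters))
}

#' Read a two-column truth table
#'
#' Tab-separated `read_id<TAB>strain_label`, no header.
#'
#' @param path TSV path.
#' @return Named character vector read id -> strain label.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("truth table must have two tab-separated columns")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a truth table as TSV
#'
#' @param truth Named character vector read id -> strain label.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  writeLines(paste(names(truth), truth, sep = "\t"), path)
  invisible(path)
}

#' Evaluate a clustering against strain labels
#'
#' Convenience wrapper combining [confusion_counts()] and
#' [accuracy_report()], with the OTU count attached.
#'
#' @inheritParams confusion_counts
#' @inheritParams accuracy_report
#' @return An `accuracy_report` with an added `n_otus` component.
#' @export
evaluate_clustering <- function(clusters, truth, beta = 2) {
  counts <- confusion_counts(clusters, truth)
  rep <- accuracy_report(counts, beta)
  rep$n_otus <- count_otus(clusters)
  rep
}
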