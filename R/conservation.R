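#' Protein alignments
#'
#' A thin container for an aligned set of amino-acid sequences (gap `-`),
#' as used for the PsaL residue-conservation survey. All sequences must
#' have equal aligned length and unique ids.
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of aligned sequences (upper-cased).
#' @return Object of class `alignment`.
#' @export
alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("aligned sequences have unequal lengths")
  structure(list(ids = as.character(ids), seqs = seqs, length = L),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment>", length(x$ids), "sequences x", x$length, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Aligned-FASTA path.
#' @return An [alignment()].
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  alignment(names(aa), unname(as.character(aa)))
}

#' Write an alignment to FASTA
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(aln$seqs, aln$ids)), path)
  invisible(path)
}

#' Map an ungapped reference position to an alignment column
#'
#' Returns the alignment column (1-based) containing the `ref_position`-th
#' non-gap character of the reference sequence; this anchors a structural
#' position (e.g. the PsaL calcium-coordinating residue) in the alignment.
#'
#' @param aln An `alignment`.
#' @param ref_id Id of the reference sequence.
#' @param ref_position 1-based ungapped residue index in the reference.
#' @return Integer column index.
#' @export
anchor_column <- function(aln, ref_id, ref_position) {
  i <- match(ref_id, aln$ids)
  if (is.na(i)) stop("reference id '", ref_id, "' not in alignment")
  chars <- strsplit(aln$seqs[i], "")[[1]]
  nongap <- cumsum(chars != "-")
  if (ref_position < 1 || ref_position > nongap[length(nongap)]) {
    stop("ref_position ", ref_position, " beyond ungapped reference length ",
         nongap[length(nongap)])
  }
  match(ref_position, nongap)
}

.residue_classes <- list(
  `negatively charged` = c("D", "E"),
  `positively charged` = c("K", "R", "H"),
  asparagine = "N"
)

#' Residue composition of one alignment column
#'
#' Counts residues at a column and reports per-residue fractions over the
#' non-gap entries together with charge-class fractions (negatively charged
#' D/E; positively charged K/R/H; asparagine; other). Percentages use the
#' non-gap count as denominator; the gap fraction is reported separately
#' so columns with many gaps are conspicuous.
#'
#' @param aln An `alignment`.
#' @param column 1-based column index.
#' @return Object of class `column_profile`: list with `column`, `counts`
#'   (named integer incl. `-` for gaps), `n_sequences`, `non_gap`,
#'   `fractions` (over non-gap), `class_fractions`, `gap_fraction`.
#' @export
column_profile <- function(aln, column) {
  if (column < 1 || column > aln$length) stop("column outside alignment")
  ch <- toupper(substr(aln$seqs, column, column))
  ok <- ch %in% c(LETTERS, "-")
  if (!all(ok)) {
    stop("non-amino characters at column ", column, " in sequence(s): ",
         paste(aln$ids[!ok], collapse = ", "))
  }
  counts <- table(factor(ch, levels = sort(unique(ch))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  gaps <- if ("-" %in% names(counts)) counts[["-"]] else 0L
  non_gap <- length(ch) - gaps
  res_counts <- counts[names(counts) != "-"]
  fractions <- if (non_gap > 0) res_counts / non_gap else
    stats::setNames(numeric(0), character(0))
  cls <- vapply(.residue_classes, function(rr)
    sum(fractions[names(fractions) %in% rr]), numeric(1))
  cls <- c(cls, other = if (non_gap > 0) 1 - sum(cls) else 0)
  if (non_gap == 0) cls[] <- NA_real_
  structure(list(column = as.integer(column), counts = counts,
                 n_sequences = length(ch), non_gap = non_gap,
                 fractions = fractions, class_fractions = cls,
                 gap_fraction = gaps / length(ch)),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> column %d: %d sequences, %d non-gap (gap fraction %.3f)\n",
              x$column, x$n_sequences, x$non_gap, x$gap_fraction))
  if (x$non_gap > 0) {
    print(round(sort(x$fractions, decreasing = TRUE), 3))
    print(round(x$class_fractions, 3))
  }
  invisible(x)
}

#' Write a column profile as CSV
#'
#' @param profile A `column_profile`.
#' @param path Output path; columns `residue,count,fraction` (gap row has an
#'   empty fraction denominator contribution and reports the gap fraction).
#' @export
write_profile_csv <- function(profile, path) {
  res <- names(profile$counts)
  frac <- ifelse(res == "-", profile$gap_fraction,
                 as.numeric(profile$fractions[res]))
  utils::write.csv(data.frame(residue = res,
                              count = as.integer(profile$counts),
                              fraction = frac),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
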