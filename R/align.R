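#' Scoring scheme for global alignment
#'
#' Affine gap scoring: a gap run of length k costs
#' \code{gap_open + k * gap_extend} (both are penalties, i.e. non-positive).
#' The default (+1 match, -1 mismatch, -2 open, -0.5 extend) keeps a single
#' substitution cheaper than an insertion/deletion pair, so point mutations
#' align as mismatch columns rather than as paired gaps.
#'
#' @param match Score for an identical column; must exceed \code{mismatch}.
#' @param mismatch Score for a substitution column.
#' @param gap_open Penalty charged once per gap run, \code{<= gap_extend}.
#' @param gap_extend Penalty charged per gapped column, \code{<= 0}.
#' @return An object of class \code{"scoring_scheme"}.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -0.5) {
  vals <- c(match = match, mismatch = mismatch,
            gap_open = gap_open, gap_extend = gap_extend)
  if (!all(is.finite(vals))) stop("scoring scheme values must be finite")
  if (match <= mismatch) stop("match score must exceed mismatch score")
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("gap penalties must satisfy gap_open <= gap_extend <= 0")
  structure(as.list(vals), class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "Alignment scoring: match %+g, mismatch %+g, gap open %+g, gap extend %+g\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

# substitution matrix over A,C,G,T,N; N always scores as a mismatch
scheme_matrix <- function(scheme) {
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(scheme$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(mat)[1:4] <- scheme$match
  mat
}

check_sequence <- function(seq, what, allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (nchar(seq) == 0L) stop(what, " is empty")
  seq <- toupper(seq)
  ok <- c("A", "C", "G", "T", if (allow_n) "N")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad))
    stop(what, " contains illegal character '", chars[bad[1]],
         "' at position ", bad[1])
  seq
}

#' Global pairwise alignment of a sample exon against its reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, end gaps
#' included. The reference must be plain ACGT; the sample may additionally
#' contain N (an ambiguous base call), which scores as a mismatch and is
#' skipped by the variant caller.
#'
#' @param ref Reference exon sequence (character scalar, ACGT).
#' @param sample Sample exon sequence (character scalar, ACGT plus N).
#' @param scheme A [scoring_scheme()].
#' @return An object of class \code{"pairwise_alignment"}: list with
#'   \code{ref_row} and \code{sample_row} (equal-length gapped strings over
#'   ACGTN-), \code{score} (optimal global score) and \code{scheme}.
#' @examples
#' aln <- global_align("ACGTACGTAC", "ACGTACGTAC")
#' identity_score(aln)  # 1
#' @export
global_align <- function(ref, sample, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  ref <- check_sequence(ref, "reference sequence")
  sample <- check_sequence(sample, "sample sequence", allow_n = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = sample, subject = ref, type = "global",
    substitutionMatrix = scheme_matrix(scheme),
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  # pattern()/subject() are far cheaper to extract than alignedPattern()/
  # alignedSubject() but silently drop gaps at the alignment edges; fall back
  # to the slow accessors whenever degapping does not recover the inputs
  ref_row <- as.character(Biostrings::subject(pa))
  sample_row <- as.character(Biostrings::pattern(pa))
  if (gsub("-", "", ref_row, fixed = TRUE) != ref ||
      gsub("-", "", sample_row, fixed = TRUE) != sample) {
    ref_row <- as.character(Biostrings::alignedSubject(pa))
    sample_row <- as.character(Biostrings::alignedPattern(pa))
  }
  structure(list(ref_row = ref_row,
                 sample_row = sample_row,
                 scheme = scheme,
                 score = Biostrings::score(pa)),
            class = "pairwise_alignment")
}

# columns of an alignment as two character vectors
alignment_columns <- function(aln) {
  list(ref = strsplit(aln$ref_row, "", fixed = TRUE)[[1]],
       sample = strsplit(aln$sample_row, "", fixed = TRUE)[[1]])
}

#' Identity score of an alignment
#'
#' Fraction of alignment columns in which both rows carry the same non-gap
#' residue, over all columns. Gapped columns count in the denominator but can
#' never count as identical, so gaps depress the score; the value is 1 exactly
#' when the two rows are identical and gap-free.
#'
#' @param aln A [global_align()] result.
#' @return A number in [0, 1].
#' @export
identity_score <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  cols <- alignment_columns(aln)
  n <- length(cols$ref)
  if (n == 0L) stop("alignment has zero columns")
  sum(cols$ref == cols$sample & cols$ref != "-") / n
}

# per-column classification, used for the machine-readable TSV output
alignment_table <- function(aln) {
  cols <- alignment_columns(aln)
  cls <- ifelse(cols$sample == "-", "deletion",
         ifelse(cols$ref == "-", "insertion",
         ifelse(cols$ref == cols$sample, "match", "mismatch")))
  data.frame(column = seq_along(cols$ref), ref = cols$ref,
             sample = cols$sample, class = cls)
}

#' Render an alignment as wrapped text
#'
#' Two sequence rows with a marker line ('|' on identical columns) between
#' them, wrapped at \code{width} columns — the "juxtaposition" view printed by
#' the command-line \code{compare} command.
#'
#' @param aln A [global_align()] result.
#' @param width Columns per block.
#' @return Character vector of text lines.
#' @export
format_alignment <- function(aln, width = 60L) {
  stopifnot(inherits(aln, "pairwise_alignment"), width >= 1L)
  cols <- alignment_columns(aln)
  n <- length(cols$ref)
  marks <- ifelse(cols$ref == cols$sample & cols$ref != "-", "|", " ")
  out <- character(0)
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    out <- c(out,
             sprintf("ref     %s %d", paste(cols$ref[s:e], collapse = ""), e),
             sprintf("        %s", paste(marks[s:e], collapse = "")),
             sprintf("sample  %s %d", paste(cols$sample[s:e], collapse = ""), e),
             "")
  }
  out[-length(out)]
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("Global alignment (%d columns, score %g, identity %.4f)\n",
              nchar(x$ref_row), x$score, identity_score(x)))
  cat(format_alignment(x, width), sep = "\n")
  invisible(x)
}
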