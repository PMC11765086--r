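# Global pairwise protein alignment and transfer of the phosphosite
# through alignment columns.
#
# Alignment is Needleman-Wunsch with affine gaps via
# Biostrings::pairwiseAlignment (type = "global", end gaps penalised).
# Defaults are the field-standard BLOSUM62 with gap open 11 / extend 1; a
# gap of length g costs open + g * extend.  Rare letters outside the
# substitution matrix alphabet (U, O) are scored as X but the returned
# gapped strings carry the original letters, so stripping gaps always
# recovers the inputs exactly.

#' Global pairwise protein alignment
#'
#' @param query_sequence,subject_sequence nonempty amino-acid strings.
#' @param matrix substitution matrix or name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class `protein_alignment`: list with `aligned_query`,
#'   `aligned_subject` (equal-length gapped strings, gap = `"-"`) and
#'   `score`.
#' @export
#' @examples
#' aln <- global_align("ACDEF", "ACEF")
#' aln$aligned_subject  # "AC-EF"
global_align <- function(query_sequence, subject_sequence,
                         matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (!nzchar(query_sequence) || !nzchar(subject_sequence))
    stop("cannot align an empty sequence")
  m <- similarity_matrix(matrix)
  sanitize <- function(s) {
    s <- toupper(s)
    chartr("UO", "XX", s)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = sanitize(query_sequence), subject = sanitize(subject_sequence),
    type = "global", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  # restore original letters at non-gap positions
  restore <- function(gapped, original) {
    g <- strsplit(gapped, "", fixed = TRUE)[[1]]
    o <- strsplit(toupper(original), "", fixed = TRUE)[[1]]
    g[g != "-"] <- o
    paste(g, collapse = "")
  }
  structure(list(
    aligned_query = restore(as.character(Biostrings::alignedPattern(pa)),
                            query_sequence),
    aligned_subject = restore(as.character(Biostrings::alignedSubject(pa)),
                              subject_sequence),
    score = Biostrings::score(pa)
  ), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment (score ", x$score, ", ",
      nchar(x$aligned_query), " columns)\n", sep = "")
  invisible(x)
}

#' Transfer a phosphosite through an alignment
#'
#' Locates the alignment column holding the 1-based query site position and
#' reports the subject character there: either an amino acid with its
#' ungapped subject coordinate, or the gap sentinel `"-"` (the site has no
#' counterpart and cannot be conserved).
#'
#' @param alignment a [protein_alignment][global_align()].
#' @param query_site_position 1-based position on the ungapped query.
#' @return object of class `site_alignment_context`: list with
#'   `aligned_query`, `aligned_subject`, `site_column` (1-based alignment
#'   column), `subject_site_position` (NA if gapped),
#'   `subject_site_residue` (`"-"` if gapped), `alignment_score`.
#' @export
transfer_site <- function(alignment, query_site_position) {
  aq <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  as_ <- strsplit(alignment$aligned_subject, "", fixed = TRUE)[[1]]
  qpos <- cumsum(aq != "-")
  if (query_site_position < 1L || query_site_position > max(qpos))
    stop("query site position out of range: ", query_site_position)
  col <- which(aq != "-" & qpos == query_site_position)[1]
  sres <- as_[col]
  spos <- if (sres == "-") NA_integer_ else sum(as_[1:col] != "-")
  structure(list(
    aligned_query = alignment$aligned_query,
    aligned_subject = alignment$aligned_subject,
    site_column = col,
    subject_site_position = spos,
    subject_site_residue = sres,
    alignment_score = alignment$score
  ), class = "site_alignment_context")
}
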