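# Conservation scoring of the phosphosite neighbourhood.
#
# All scoring operates on 15-character windows centred on the phosphosite
# (site at 1-based index 8), the same +/-7 flank convention used by the
# catalog.  Underscores (terminus padding), gaps ("-") and ambiguity codes
# are never identical to anything and never conservative.

.chars <- function(x) {
  if (length(x) == 1L && is.character(x)) strsplit(x, "", fixed = TRUE)[[1]] else x
}

.check_window <- function(x, what) {
  cx <- toupper(.chars(x))
  if (length(cx) != 15L)
    stop(what, " must have length 15, got ", length(cx))
  cx
}

# Per-position identity: both carry the same standard amino acid.
.identical_positions <- function(q, s) {
  q == s & q %in% AA20
}

#' Longest identical run through the phosphosite
#'
#' Length of the maximal contiguous block of positions, containing the site,
#' at which two 15-mer windows carry identical standard amino acids.  This is
#' the "conserved region (continuous AA)" statistic used to summarise
#' validated cross-reactive antibodies.  If the two windows differ at the
#' site itself (or either carries a gap/padding character there) the run is 0.
#'
#' @param query_window,subject_window 15-character windows (strings or
#'   character vectors); case-insensitive.
#' @param site_index 1-based index of the phosphosite within the window
#'   (default 8, the centre of a +/-7 flank).
#' @return integer run length in amino acids (0..15).
#' @export
#' @examples
#' longest_identical_run("RPHFPQFSYSASGTA", "EPLFPQFSYQGDMAS")  # 6
#' longest_identical_run("MILLSELSRRRIRSI", "MILLSELSRRRIRSI")  # 15
longest_identical_run <- function(query_window, subject_window, site_index = 8L) {
  q <- .check_window(query_window, "query_window")
  s <- .check_window(subject_window, "subject_window")
  stopifnot(site_index >= 1L, site_index <= 15L)
  ident <- .identical_positions(q, s)
  if (!ident[site_index]) return(0L)
  lo <- site_index
  while (lo > 1L && ident[lo - 1L]) lo <- lo - 1L
  hi <- site_index
  while (hi < 15L && ident[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

#' Is a replacement conservative?
#'
#' TRUE iff the two residues differ and their similarity-matrix entry is
#' strictly positive (default BLOSUM62).  Identity is not a replacement;
#' non-standard letters, gaps and padding are never conservative.
#'
#' @param a,b single amino-acid characters.
#' @param matrix similarity matrix or its name (see [similarity_matrix()]).
#' @return logical.
#' @export
#' @examples
#' is_conservative_substitution("K", "R")  # TRUE  (BLOSUM62 +2)
#' is_conservative_substitution("H", "L")  # FALSE (negative score)
#' is_conservative_substitution("A", "A")  # FALSE (not a replacement)
is_conservative_substitution <- function(a, b, matrix = similarity_matrix()) {
  a <- toupper(a); b <- toupper(b)
  if (!(a %in% AA20) || !(b %in% AA20)) return(FALSE)
  a != b && matrix[a, b] > 0
}

#' Does a window of length L spanning the site qualify as conserved?
#'
#' A window qualifies when there exists a contiguous sub-window of length
#' `L` containing the site such that every position is identical, except at
#' most one position which (i) is a conservative replacement, (ii) is not
#' the site itself and (iii) is not immediately adjacent to the site
#' (site +/- 1).  Windows containing padding, gap or ambiguity characters
#' never qualify.  This is the per-cutoff rule behind the cross-reactivity
#' call: only one conserved amino-acid replacement is tolerated, and not
#' right next to the target S/T/Y.
#'
#' @inheritParams longest_identical_run
#' @param L window length, 6..11.
#' @param matrix similarity matrix defining "conservative".
#' @param allow_substitution set FALSE to demand full identity (no
#'   replacement allowance).
#' @return logical; when TRUE and a replacement was used, carries an
#'   attribute `substitution_note`, a list with `position` (1-based index in
#'   the 15-mer), `query` and `subject` residues.
#' @export
#' @examples
#' window_qualifies("RPHFPQFSYSASGTA", "EPLFPQFSYQGDMAS", L = 6)  # TRUE
#' window_qualifies("RPHFPQFSYSASGTA", "EPLFPQFSYQGDMAS", L = 7)  # FALSE
window_qualifies <- function(query_window, subject_window, site_index = 8L,
                             L, matrix = similarity_matrix(),
                             allow_substitution = TRUE) {
  if (L < 6L || L > 11L) stop("window length L must be in 6..11, got ", L)
  q <- .check_window(query_window, "query_window")
  s <- .check_window(subject_window, "subject_window")
  ident <- .identical_positions(q, s)
  scoreable <- q %in% AA20 & s %in% AA20
  cons <- logical(15L)
  for (p in which(!ident & scoreable))
    cons[p] <- matrix[q[p], s[p]] > 0
  # positions where the one allowed replacement may sit
  allowed <- cons & !(seq_len(15L) %in% (site_index + c(-1L, 0L, 1L)))

  starts <- seq.int(max(1L, site_index - L + 1L), min(site_index, 15L - L + 1L))
  for (st in starts) {
    idx <- st:(st + L - 1L)
    if (!all(scoreable[idx])) next
    bad <- idx[!ident[idx]]
    if (length(bad) == 0L) return(TRUE)
    if (allow_substitution && length(bad) == 1L && allowed[bad]) {
      out <- TRUE
      attr(out, "substitution_note") <-
        list(position = bad, query = q[bad], subject = s[bad])
      return(out)
    }
  }
  FALSE
}

#' Conservation result for an aligned phosphosite
#'
#' Extracts the 15-column slice of a pairwise alignment centred on the
#' phosphosite column (padding with the gap sentinel at alignment ends) and
#' evaluates both conservation statistics: the longest identical run through
#' the site and window qualification at each length in `lengths`.  A subject
#' gap or non-identical residue at the site column yields an all-negative
#' result.  Gap columns inside a candidate window disqualify that window: an
#' indel within an epitope breaks the binding surface.
#'
#' @param context a `site_alignment_context` from [transfer_site()], or any
#'   list with elements `aligned_query`, `aligned_subject`, `site_column`
#'   (1-based alignment column of the phosphosite).
#' @param lengths window lengths to evaluate (subset of 6..11).
#' @param matrix similarity matrix defining "conservative".
#' @param allow_substitution passed to [window_qualifies()].
#' @return an object of class `conservation_result`: list with
#'   `longest_identical_run`, `qualified_lengths` (named logical),
#'   `max_qualified_length`, `site_identical`, `substitution_note`.
#' @export
score_site <- function(context, lengths = 6:11, matrix = similarity_matrix(),
                       allow_substitution = TRUE) {
  stopifnot(all(lengths >= 6L), all(lengths <= 11L))
  aq <- .chars(context$aligned_query)
  as_ <- .chars(context$aligned_subject)
  col <- context$site_column
  stopifnot(length(aq) == length(as_), col >= 1L, col <= length(aq))
  idx <- (col - 7L):(col + 7L)
  pad <- function(v) ifelse(idx >= 1L & idx <= length(v), v[pmax(idx, 1L)], "-")
  score_window_pair(pad(aq), pad(as_), lengths = lengths, matrix = matrix,
                    allow_substitution = allow_substitution)
}

#' Conservation result for a raw pair of 15-mer flank windows
#'
#' The alignment-free code path: scores two 15-mer windows directly, site at
#' index 8.  For gap-free alignments this coincides with [score_site()] on
#' the alignment slice.
#'
#' @inheritParams longest_identical_run
#' @inheritParams score_site
#' @return a `conservation_result` (see [score_site()]).
#' @export
#' @examples
#' r <- score_window_pair("RPHFPQFSYSASGTA", "EPLFPQFSYQGDMAS")
#' r$longest_identical_run   # 6
#' r$max_qualified_length    # 6
score_window_pair <- function(query_window, subject_window, site_index = 8L,
                              lengths = 6:11, matrix = similarity_matrix(),
                              allow_substitution = TRUE) {
  q <- .check_window(query_window, "query_window")
  s <- .check_window(subject_window, "subject_window")
  run <- longest_identical_run(q, s, site_index)
  quals <- setNames(logical(length(lengths)), as.character(lengths))
  note <- NULL
  for (i in seq_along(lengths)) {
    w <- window_qualifies(q, s, site_index, lengths[i], matrix,
                          allow_substitution)
    quals[i] <- isTRUE(as.logical(w))
    if (quals[i] && is.null(note))
      note <- attr(w, "substitution_note")
  }
  structure(list(
    longest_identical_run = run,
    qualified_lengths = quals,
    max_qualified_length =
      if (any(quals)) max(lengths[quals]) else 0L,
    site_identical = run > 0L,
    substitution_note = note
  ), class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat("Phosphosite conservation\n")
  cat("  longest identical run:", x$longest_identical_run, "aa\n")
  cat("  qualified window lengths:",
      if (any(x$qualified_lengths))
        paste(names(x$qualified_lengths)[x$qualified_lengths], collapse = " ")
      else "none", "\n")
  if (!is.null(x$substitution_note))
    cat("  allowed replacement: ", x$substitution_note$query, "->",
        x$substitution_note$subject, " at window position ",
        x$substitution_note$position, "\n", sep = "")
  invisible(x)
}
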