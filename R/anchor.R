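# Anchoring catalog phosphosites onto current full-length protein sequences.
#
# Catalog accessions drift relative to current proteome releases, so a site
# is validated in three stages: (1) accession lookup + positional check of
# the stated coordinate; (2) same protein, exact scan for the flank peptide
# elsewhere (isoform/version coordinate drift); (3) gene-symbol rescue —
# map the catalog symbol to gene id(s), scan every protein of those genes.
# Matching here is exact; mismatch tolerance belongs to the conservation
# stage, not to anchoring, because a false anchor poisons every downstream
# alignment.

#' Locate a flank peptide on a protein sequence
#'
#' Returns every 1-based site position at which the non-underscore core of a
#' normalised 15-mer flank matches the sequence exactly, with underscore
#' padding matching only the sequence termini (padding means the catalog
#' asserts the site lies within 7 residues of an end).
#'
#' @param flank_peptide normalised 15-mer (site at index 8, underscores only
#'   terminal; see [normalize_flank()]).
#' @param sequence protein sequence string.
#' @return integer vector of site positions (possibly empty; overlapping
#'   occurrences are all reported).
#' @export
#' @examples
#' locate_peptide("______MSGRGKGGK", "MSGRGKGGKGLGKGGAKRHRKV")  # 2
locate_peptide <- function(flank_peptide, sequence) {
  ch <- strsplit(toupper(flank_peptide), "", fixed = TRUE)[[1]]
  if (length(ch) != 15L) stop("flank must be 15 characters")
  core_idx <- which(ch != "_")
  npre <- core_idx[1] - 1L
  nsuf <- 15L - core_idx[length(core_idx)]
  core <- paste(ch[core_idx], collapse = "")
  n <- nchar(sequence); k <- nchar(core)
  if (k > n) return(integer(0))
  seq_up <- toupper(sequence)

  starts <- if (npre > 0L && nsuf > 0L) {
    if (n == k && seq_up == core) 1L else integer(0)
  } else if (npre > 0L) {
    if (substr(seq_up, 1L, k) == core) 1L else integer(0)
  } else if (nsuf > 0L) {
    if (substr(seq_up, n - k + 1L, n) == core) n - k + 1L else integer(0)
  } else {
    m <- gregexpr(paste0("(?=", core, ")"), seq_up, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  starts + (8L - npre) - 1L
}

# Does the flank match the sequence exactly with the site at `pos`?
# Underscore positions must fall outside the sequence (terminus assertion).
.flank_matches_at <- function(flank_chars, sequence, pos) {
  n <- nchar(sequence)
  for (i in 1:15) {
    sp <- pos + (i - 8L)
    if (flank_chars[i] == "_") {
      if (sp >= 1L && sp <= n) return(FALSE)
    } else {
      if (sp < 1L || sp > n) return(FALSE)
      if (substr(sequence, sp, sp) != flank_chars[i]) return(FALSE)
    }
  }
  TRUE
}

#' Anchor a catalog phosphosite onto a current protein sequence
#'
#' Tries, in order: direct positional validation on the catalogued
#' accession; an exact flank-peptide scan on that protein (corrects
#' coordinate drift, status `anchored_shifted`); and gene-symbol rescue over
#' all proteins of the symbol's gene(s).  Any ambiguity — the flank found at
#' more than one position, or rescue hitting more than one gene or protein —
#' fails the site rather than guessing.  Failures are data, reported
#' downstream, never errors.
#'
#' @param record one phosphosite record (a one-row data.frame or list with
#'   fields `protein_accession`, `gene_symbol`, `residue`, `position`,
#'   `flank_peptide`).
#' @param store the source-species [protein_store][load_proteome()].
#' @param id_map a [gene_id_map][load_id_map()] used for the symbol rescue.
#' @return an object of class `anchored_site`: list with `record`,
#'   `protein` (NULL on failure), `site_position`, `status` (one of
#'   `anchored_direct`, `anchored_shifted`, `rescued_by_symbol`, `failed`)
#'   and `failure_reason` (one of `no_protein`, `peptide_not_found`,
#'   `ambiguous_peptide`, `ambiguous_gene`, or NA).
#' @export
anchor_site <- function(record, store, id_map) {
  record <- as.list(record)
  flank <- toupper(record$flank_peptide)
  fch <- strsplit(flank, "", fixed = TRUE)[[1]]

  result <- function(protein, pos, status, reason = NA_character_) {
    structure(list(record = record, protein = protein,
                   site_position = pos, status = status,
                   failure_reason = reason),
              class = "anchored_site")
  }
  fail <- function(reason) result(NULL, NA_integer_, "failed", reason)

  prot <- store_get(store, record$protein_accession)
  if (!is.null(prot)) {
    pos <- record$position
    if (pos >= 1L && pos <= nchar(prot$sequence) &&
        substr(prot$sequence, pos, pos) == record$residue &&
        .flank_matches_at(fch, prot$sequence, pos))
      return(result(prot, pos, "anchored_direct"))
    hits <- locate_peptide(flank, prot$sequence)
    if (length(hits) == 1L)
      return(result(prot, hits, "anchored_shifted"))
    if (length(hits) > 1L)
      return(fail("ambiguous_peptide"))
    # peptide absent from the catalogued protein: fall through to rescue
  }

  gids <- map_to_gene_id(id_map, record$gene_symbol, "symbol")
  if (length(gids) == 0L)
    return(fail("no_protein"))
  candidates <- do.call(rbind, lapply(gids, function(g) isoforms(store, g)))
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(fail("no_protein"))

  hit_rows <- list()
  for (j in seq_len(nrow(candidates))) {
    hp <- locate_peptide(flank, candidates$sequence[j])
    for (p in hp)
      hit_rows[[length(hit_rows) + 1L]] <-
        list(protein = as.list(candidates[j, , drop = FALSE]), pos = p)
  }
  if (length(hit_rows) == 0L)
    return(fail("peptide_not_found"))
  hit_genes <- unique(vapply(hit_rows, function(h) h$protein$gene_id,
                             character(1)))
  if (length(hit_genes) > 1L)
    return(fail("ambiguous_gene"))
  if (length(hit_rows) > 1L)
    return(fail("ambiguous_peptide"))
  result(hit_rows[[1]]$protein, hit_rows[[1]]$pos, "rescued_by_symbol")
}

#' @export
print.anchored_site <- function(x, ...) {
  cat("anchored_site:", x$record$gene_symbol,
      paste0(x$record$residue, x$record$position), "->", x$status)
  if (x$status == "failed") cat(" (", x$failure_reason, ")", sep = "")
  else cat(" at", x$site_position, "on", x$protein$accession_full)
  cat("\n")
  invisible(x)
}
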