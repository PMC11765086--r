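# Reference proteomes and identifier / ortholog mapping tables.
#
# A protein store holds one species' proteome keyed by accession (both the
# full versioned form and the version-stripped form; version drift between
# catalog and current RefSeq releases is the commonest cause of stale
# accessions, so the stripped form is the join key everywhere).

.strip_version <- function(acc) sub("\\.[0-9]+$", "", acc)

#' Load a reference proteome with its gene mapping
#'
#' Reads a protein FASTA (accession = first whitespace-delimited header
#' token) and a two-column tab-separated gene map (`gene_id`, `accession`).
#' Proteins whose accession has no gene mapping are retained but flagged
#' unmapped (`gene_id` NA): they can still anchor an epitope by accession.
#'
#' @param fasta_path protein FASTA, optionally gzipped.
#' @param mapping_path TSV with header columns `gene_id` and `accession`.
#' @param species species token stored on every record.
#' @return an object of class `protein_store`.
#' @export
load_proteome <- function(fasta_path, mapping_path, species = "unknown") {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  acc_full <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  sequence <- toupper(as.character(seqs))
  acc <- .strip_version(acc_full)

  dup <- duplicated(acc)
  if (any(dup)) {
    for (a in unique(acc[dup])) {
      if (length(unique(sequence[acc == a])) > 1L)
        stop("duplicate accession with differing sequence: ", a)
    }
    keep <- !dup
    acc_full <- acc_full[keep]; sequence <- sequence[keep]; acc <- acc[keep]
  }

  map <- read.delim(mapping_path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character")
  if (!all(c("gene_id", "accession") %in% names(map)))
    stop("gene map must have columns gene_id, accession: ", mapping_path)
  gene_of <- setNames(map$gene_id, .strip_version(map$accession))
  gene_id <- unname(gene_of[acc])

  proteins <- data.frame(accession = acc, accession_full = acc_full,
                         species = species, gene_id = gene_id,
                         sequence = sequence, stringsAsFactors = FALSE)
  structure(list(proteins = proteins,
                 by_acc = setNames(seq_len(nrow(proteins)), acc),
                 species = species),
            class = "protein_store")
}

#' @export
print.protein_store <- function(x, ...) {
  cat("protein_store:", nrow(x$proteins), "proteins (", x$species, "),",
      sum(!is.na(x$proteins$gene_id)), "gene-mapped\n")
  invisible(x)
}

#' Look up a protein by accession
#'
#' Versioned and version-stripped accessions both resolve.
#'
#' @param store a `protein_store`.
#' @param accession accession text.
#' @return a one-row list (accession, accession_full, species, gene_id,
#'   sequence) or NULL if absent.
#' @export
store_get <- function(store, accession) {
  i <- store$by_acc[.strip_version(accession)]
  if (is.na(i)) return(NULL)
  as.list(store$proteins[i, , drop = FALSE])
}

#' All isoforms mapped to a gene
#'
#' @param store a `protein_store`.
#' @param gene_id gene identifier (character or numeric).
#' @return data.frame of protein records (possibly 0 rows).
#' @export
isoforms <- function(store, gene_id) {
  p <- store$proteins
  p[!is.na(p$gene_id) & p$gene_id == as.character(gene_id), , drop = FALSE]
}

# Ortholog table -------------------------------------------------------------

.RANK_LEVELS <- c("low", "moderate", "high")

#' Load a flat ortholog table
#'
#' TSV with columns `source_gene_id`, `target_gene_id`, `rank` (one of
#' high/moderate/low) and optionally `score` plus taxon columns.  Rank is an
#' opaque ordered confidence label, high > moderate > low.
#'
#' @param path ortholog TSV.
#' @return data.frame of class `ortholog_table`.
#' @export
load_ortholog_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character")
  need <- c("source_gene_id", "target_gene_id", "rank")
  if (!all(need %in% names(df)))
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  bad <- !df$rank %in% .RANK_LEVELS
  if (any(bad)) stop("unknown ortholog rank value(s): ",
                     paste(unique(df$rank[bad]), collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_character_
  class(df) <- c("ortholog_table", class(df))
  df
}

#' Orthologs of a gene at or above a confidence rank
#'
#' Only high- and moderate-confidence ortholog calls are trusted by default;
#' `min_rank = "low"` disables the filter.  Unknown genes return an empty
#' set, not an error.
#'
#' @param table an `ortholog_table`.
#' @param source_gene_id gene identifier.
#' @param min_rank minimum confidence, one of `"high"`, `"moderate"`,
#'   `"low"`.
#' @return data.frame of qualifying pairs (possibly 0 rows).
#' @export
get_orthologs <- function(table, source_gene_id, min_rank = "moderate") {
  min_rank <- match.arg(min_rank, .RANK_LEVELS)
  keep <- table$source_gene_id == as.character(source_gene_id) &
    match(table$rank, .RANK_LEVELS) >= match(min_rank, .RANK_LEVELS)
  out <- table[keep, , drop = FALSE]
  out[order(out$target_gene_id), , drop = FALSE]
}

# Identifier map --------------------------------------------------------------

#' Load an identifier-to-gene map
#'
#' TSV with columns `namespace` (symbol / refseq / uniprot), `token`,
#' `gene_id`.  One token may map to several gene ids; lookups return the
#' whole set and the caller resolves ambiguity.
#'
#' @param path id map TSV.
#' @return data.frame of class `gene_id_map`.
#' @export
load_id_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character")
  need <- c("namespace", "token", "gene_id")
  if (!all(need %in% names(df)))
    stop("id map must have columns ", paste(need, collapse = ", "))
  class(df) <- c("gene_id_map", class(df))
  df
}

#' Map a symbol or accession to gene id(s)
#'
#' @param map a `gene_id_map`.
#' @param token symbol or accession text (accessions are matched
#'   version-stripped).
#' @param namespace one of `"symbol"`, `"refseq"`, `"uniprot"`.
#' @return character vector of gene ids (possibly empty), sorted,
#'   deduplicated.
#' @export
map_to_gene_id <- function(map, token, namespace = "symbol") {
  namespace <- match.arg(namespace, c("symbol", "refseq", "uniprot"))
  tok <- if (namespace == "symbol") token else .strip_version(token)
  hits <- map$gene_id[map$namespace == namespace & map$token == tok]
  sort(unique(hits))
}
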