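# Antibody/phosphosite catalog IO.
#
# The catalog dialect is the tab-separated "phosphorylation site dataset"
# layout used by the large commercial phosphosite resources: one row per
# modified site, with a MOD_RSD token like "Y1150-p", a 15-mer flank peptide
# with the phospho-residue in lowercase at the centre and underscore padding
# where the site is within 7 residues of a terminus, and catalog numbers of
# antibodies recognising the site.

#' Default column-name map for the catalog dialect
#'
#' Maps the logical fields (gene, accession, species, mod_rsd, flank,
#' antibody) to the column names found in the file.  Override entries to
#' read a customised catalog.
#' @export
default_column_map <- function() {
  c(gene = "GENE", accession = "ACC_ID", species = "ORGANISM",
    mod_rsd = "MOD_RSD", flank = "SITE_+/-7_AA", antibody = "CST_CAT#")
}

#' Parse a MOD_RSD token
#'
#' `"Y1150-p"` encodes phospho-tyrosine at 1-based position 1150.  Only
#' phosphorylatable residues (S/T/Y) are in scope; other modifications are
#' row-level rejects.
#'
#' @param token character scalar.
#' @return list with `residue`, `position` and `error` (NULL on success,
#'   otherwise a reason code: `"bad_mod_rsd"` or `"non_STY_residue"`).
#' @export
#' @examples
#' parse_mod_rsd("Y1150-p")
#' parse_mod_rsd("S473-p")
parse_mod_rsd <- function(token) {
  m <- regmatches(token,
                  regexec("^([A-Za-z])([0-9]+)(-[a-z0-9]+)?$", token))[[1]]
  if (length(m) == 0L)
    return(list(residue = NA_character_, position = NA_integer_,
                error = "bad_mod_rsd"))
  res <- toupper(m[2])
  pos <- suppressWarnings(as.integer(m[3]))
  if (is.na(pos) || pos < 1L)
    return(list(residue = NA_character_, position = NA_integer_,
                error = "bad_mod_rsd"))
  if (!res %in% c("S", "T", "Y"))
    return(list(residue = res, position = pos, error = "non_STY_residue"))
  if (nzchar(m[4]) && m[4] != "-p")
    return(list(residue = res, position = pos, error = "bad_mod_rsd"))
  list(residue = res, position = pos, error = NULL)
}

#' Normalise a 15-mer flank peptide
#'
#' Uppercases the peptide, verifies it is 15 characters of letters and
#' underscores with the lowercase phospho-residue at index 8 and underscores
#' (terminus padding) only as a contiguous prefix and/or suffix, and rejects
#' ambiguity codes (X): an ambiguous epitope cannot be matched exactly.
#'
#' @param peptide raw flank peptide string.
#' @return list with `flank` (normalised, uppercase), `site_index` and
#'   `error` (NULL, or one of `"bad_flank_length"`, `"bad_flank_chars"`,
#'   `"bad_padding"`, `"site_not_centered"`, `"ambiguity_code"`).
#' @export
#' @examples
#' normalize_flank("RPHFPQFsYSASGTA")$flank   # "RPHFPQFSYSASGTA"
#' normalize_flank("______MsGRGKGGK")$flank   # N-terminal padding kept
normalize_flank <- function(peptide) {
  fail <- function(code) list(flank = NA_character_, site_index = NA_integer_,
                              error = code)
  if (is.na(peptide) || nchar(peptide) != 15L) return(fail("bad_flank_length"))
  ch <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!all(grepl("^[A-Za-z_]$", ch))) return(fail("bad_flank_chars"))
  us <- ch == "_"
  if (any(us)) {
    # underscores must form a contiguous prefix and/or suffix
    core <- range(which(!us))
    if (length(which(!us)) == 0L || any(us[core[1]:core[2]]))
      return(fail("bad_padding"))
  }
  lower <- which(ch %in% letters)
  if (length(lower) != 1L || lower != 8L) return(fail("site_not_centered"))
  up <- toupper(ch)
  if (any(up == "X")) return(fail("ambiguity_code"))
  list(flank = paste(up, collapse = ""), site_index = 8L, error = NULL)
}

#' Parse an antibody/phosphosite catalog
#'
#' Reads a tab-separated catalog (optionally gzip-compressed), validates and
#' normalises each row into a phosphosite record, and accounts for every
#' input row: `nrow(records) + nrow(rejects)` equals the number of data rows.
#' Multi-site antibody products are expected as one row per site sharing an
#' antibody id; scoring downstream is per site.
#'
#' @param path catalog file.
#' @param species_filter optional character vector of species tokens to
#'   retain (case-insensitive); rows for other species are rejected with
#'   reason `"species_excluded"`.
#' @param require_antibody if TRUE (default), rows with no antibody id are
#'   rejected with reason `"no_antibody"` — the screen targets sites an
#'   existing antibody can detect.
#' @param column_map named character vector, see [default_column_map()].
#' @return list with `records` (data.frame: row_number, source_species,
#'   gene_symbol, protein_accession, residue, position, flank_peptide,
#'   antibody_ids) and `rejects` (data.frame: row_number, reason_code,
#'   raw_line).
#' @export
parse_catalog <- function(path, species_filter = NULL, require_antibody = TRUE,
                          column_map = default_column_map()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, colClasses = "character",
                   na.strings = character())
  needed <- c("gene", "accession", "species", "mod_rsd", "flank")
  missing <- needed[!column_map[needed] %in% names(df)]
  if (length(missing))
    stop("catalog is missing mandatory column(s): ",
         paste(column_map[missing], collapse = ", "))
  has_ab <- column_map[["antibody"]] %in% names(df)

  recs <- vector("list", nrow(df))
  rej <- vector("list", nrow(df))
  raw_line <- function(i) paste(unlist(df[i, ]), collapse = "\t")
  for (i in seq_len(nrow(df))) {
    reject <- function(code) {
      rej[[i]] <<- data.frame(row_number = i, reason_code = code,
                              raw_line = raw_line(i),
                              stringsAsFactors = FALSE)
    }
    species <- tolower(trimws(df[i, column_map[["species"]]]))
    if (!is.null(species_filter) &&
        !species %in% tolower(species_filter)) {
      reject("species_excluded"); next
    }
    ab <- if (has_ab) trimws(df[i, column_map[["antibody"]]]) else ""
    if (require_antibody && (is.na(ab) || ab == "")) {
      reject("no_antibody"); next
    }
    mr <- parse_mod_rsd(trimws(df[i, column_map[["mod_rsd"]]]))
    if (!is.null(mr$error)) { reject(mr$error); next }
    fl <- normalize_flank(trimws(df[i, column_map[["flank"]]]))
    if (!is.null(fl$error)) { reject(fl$error); next }
    if (substr(fl$flank, 8L, 8L) != mr$residue) {
      reject("flank_site_mismatch"); next
    }
    recs[[i]] <- data.frame(
      row_number = i,
      source_species = species,
      gene_symbol = trimws(df[i, column_map[["gene"]]]),
      protein_accession = trimws(df[i, column_map[["accession"]]]),
      residue = mr$residue,
      position = mr$position,
      flank_peptide = fl$flank,
      antibody_ids = ab,
      stringsAsFactors = FALSE)
  }
  list(records = rbind_or(recs, empty_records()),
       rejects = rbind_or(rej, empty_rejects()))
}

rbind_or <- function(pieces, empty) {
  keep <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(keep) == 0L) return(empty)
  do.call(rbind, c(keep, list(make.row.names = FALSE)))
}

empty_records <- function() {
  data.frame(row_number = integer(), source_species = character(),
             gene_symbol = character(), protein_accession = character(),
             residue = character(), position = integer(),
             flank_peptide = character(), antibody_ids = character(),
             stringsAsFactors = FALSE)
}

empty_rejects <- function() {
  data.frame(row_number = integer(), reason_code = character(),
             raw_line = character(), stringsAsFactors = FALSE)
}

#' Write phosphosite records back to the catalog dialect
#'
#' Inverse of [parse_catalog()] for retained records: the site residue is
#' written in lowercase at flank index 8 and the MOD_RSD token carries the
#' "-p" suffix.  Round-tripping retained records reproduces them exactly.
#'
#' @param records data.frame as returned in `parse_catalog()$records`.
#' @param path output file.
#' @param column_map see [default_column_map()].
#' @export
write_catalog <- function(records, path, column_map = default_column_map()) {
  flank <- vapply(records$flank_peptide, function(f) {
    substr(f, 8L, 8L) <- tolower(substr(f, 8L, 8L)); f
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(records$gene_symbol, records$protein_accession,
                    records$source_species,
                    paste0(records$residue, records$position, "-p"),
                    flank, records$antibody_ids,
                    stringsAsFactors = FALSE)
  names(out) <- column_map[c("gene", "accession", "species", "mod_rsd",
                             "flank", "antibody")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the rejects report
#' @param rejects data.frame from [parse_catalog()].
#' @param path output TSV.
#' @export
write_rejects <- function(rejects, path) {
  write.table(rejects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
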