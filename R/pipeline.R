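# End-to-end screen: parse -> anchor -> id-map -> ortholog -> align ->
# score -> report.  Fully deterministic: fixed processing order (catalog
# row), fixed report ordering (source gene, target gene, isoform accession),
# no randomness anywhere.

#' Configuration for [run_pipeline()]
#'
#' @param catalog antibody/phosphosite catalog TSV.
#' @param source_proteome,source_gene_map source-species FASTA and
#'   gene_id/accession TSV.
#' @param target_proteome,target_gene_map target-species FASTA and map.
#' @param id_map identifier map TSV (namespace, token, gene_id).
#' @param ortholog_table ortholog TSV (source_gene_id, target_gene_id, rank).
#' @param species_filter optional species tokens to retain from the catalog.
#' @param require_antibody drop catalog rows without an antibody id.
#' @param min_rank minimum ortholog confidence (`"high"`, `"moderate"`,
#'   `"low"`).
#' @param lengths window lengths scored, subset of 6..11.
#' @param matrix similarity matrix name.
#' @param gap_open,gap_extend affine gap penalties for the alignment stage.
#' @param allow_substitution allow the single conservative replacement.
#' @param source_species,target_species species tokens for the stores.
#' @param out_dir if non-NULL, report/summary/anchoring/rejects TSVs are
#'   written there.
#' @return a named list, suitable for [run_pipeline()].
#' @export
pipeline_config <- function(catalog, source_proteome, source_gene_map,
                            target_proteome, target_gene_map,
                            id_map, ortholog_table,
                            species_filter = NULL, require_antibody = TRUE,
                            min_rank = "moderate", lengths = 6:11,
                            matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1, allow_substitution = TRUE,
                            source_species = "source",
                            target_species = "target", out_dir = NULL) {
  as.list(environment())
}

#' Run the full cross-reactivity screen
#'
#' Executes the five stages end to end: (1) anchor every catalog epitope on
#' the source proteome (with gene-symbol rescue for stale accessions);
#' (2) map the source protein/symbol to a gene id; (3) map the gene to
#' orthologs at or above `min_rank`; (4) globally align the source protein
#' against every isoform of each ortholog; (5) transfer the site through the
#' alignment and score conservation of its 15-column neighbourhood.  Every
#' catalog row is traceable to either report rows, a parse reject, an
#' anchoring failure, or a mapping failure.
#'
#' @param config list from [pipeline_config()] (missing input files are a
#'   fatal error naming the path).
#' @return object of class `crossphos_result`: list with `report`
#'   (one row per anchored site x ortholog gene x isoform), `summary`
#'   (per-cutoff aggregate, see [aggregate_counts()]), `anchoring`
#'   (per-record anchoring report), `rejects` (catalog rejects), and
#'   `failures` (post-anchoring mapping failures).
#' @export
run_pipeline <- function(config) {
  for (f in c("catalog", "source_proteome", "source_gene_map",
              "target_proteome", "target_gene_map", "id_map",
              "ortholog_table"))
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])

  cat_parsed <- parse_catalog(config$catalog,
                              species_filter = config$species_filter,
                              require_antibody = config$require_antibody)
  src <- load_proteome(config$source_proteome, config$source_gene_map,
                       species = config$source_species %||% "source")
  tgt <- load_proteome(config$target_proteome, config$target_gene_map,
                       species = config$target_species %||% "target")
  idm <- load_id_map(config$id_map)
  ort <- load_ortholog_table(config$ortholog_table)
  m <- similarity_matrix(config$matrix %||% "BLOSUM62")
  lengths <- config$lengths %||% 6:11
  min_rank <- config$min_rank %||% "moderate"
  allow_sub <- config$allow_substitution %||% TRUE

  records <- cat_parsed$records
  anchoring <- vector("list", nrow(records))
  failures <- list()
  report <- list()
  # memoised alignments: one per (source protein, target isoform)
  aln_cache <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    anc <- anchor_site(rec, src, idm)
    anchoring[[i]] <- data.frame(
      catalog_row = rec$row_number,
      accession_used = if (is.null(anc$protein)) NA_character_
                       else anc$protein$accession_full,
      status = anc$status, site_position = anc$site_position,
      failure_reason = anc$failure_reason, stringsAsFactors = FALSE)
    if (anc$status == "failed") next

    gids <- if (!is.na(anc$protein$gene_id)) anc$protein$gene_id
            else map_to_gene_id(idm, rec$gene_symbol, "symbol")
    if (length(gids) == 0L) {
      failures[[length(failures) + 1L]] <- data.frame(
        catalog_row = rec$row_number, stage = "id_mapping",
        reason = "unmapped_gene", stringsAsFactors = FALSE)
      next
    }
    ambiguous_source <- length(gids) > 1L

    any_orth <- FALSE
    for (g in gids) {
      pairs <- get_orthologs(ort, g, min_rank = min_rank)
      for (j in seq_len(nrow(pairs))) {
        tg <- pairs$target_gene_id[j]
        iso <- isoforms(tgt, tg)
        if (nrow(iso) == 0L) next
        any_orth <- TRUE
        iso <- iso[order(iso$accession), , drop = FALSE]
        for (k in seq_len(nrow(iso))) {
          key <- paste0(anc$protein$accession, "|", iso$accession[k])
          aln <- if (!is.null(aln_cache[[key]])) aln_cache[[key]] else {
            a <- global_align(anc$protein$sequence, iso$sequence[k],
                              matrix = m,
                              gap_open = config$gap_open %||% 11,
                              gap_extend = config$gap_extend %||% 1)
            aln_cache[[key]] <- a
            a
          }
          ctx <- transfer_site(aln, anc$site_position)
          cons <- score_site(ctx, lengths = lengths, matrix = m,
                             allow_substitution = allow_sub)
          qual <- as.list(cons$qualified_lengths)
          names(qual) <- paste0("qualified_", names(cons$qualified_lengths))
          note <- cons$substitution_note
          report[[length(report) + 1L]] <- data.frame(
            catalog_row = rec$row_number,
            source_species = rec$source_species,
            source_gene_symbol = rec$gene_symbol,
            source_gene_id = g,
            source_accession = anc$protein$accession_full,
            residue = rec$residue,
            source_position = anc$site_position,
            antibody_ids = rec$antibody_ids,
            anchor_status = anc$status,
            ambiguous_source_gene = ambiguous_source,
            ortholog_rank = pairs$rank[j],
            target_gene_id = tg,
            target_accession = iso$accession_full[k],
            target_isoform_length = nchar(iso$sequence[k]),
            target_site_position = ctx$subject_site_position,
            target_site_residue = ctx$subject_site_residue,
            alignment_score = ctx$alignment_score,
            longest_identical_run = cons$longest_identical_run,
            as.data.frame(qual),
            max_qualified_length = cons$max_qualified_length,
            substitution_note = if (is.null(note)) NA_character_ else
              paste0(note$query, note$position, note$subject),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!any_orth) {
      failures[[length(failures) + 1L]] <- data.frame(
        catalog_row = rec$row_number, stage = "ortholog_mapping",
        reason = "unmapped_ortholog", stringsAsFactors = FALSE)
    }
  }

  anchoring <- rbind_or(anchoring, data.frame(
    catalog_row = integer(), accession_used = character(),
    status = character(), site_position = integer(),
    failure_reason = character(), stringsAsFactors = FALSE))
  failures <- rbind_or(failures, data.frame(
    catalog_row = integer(), stage = character(), reason = character(),
    stringsAsFactors = FALSE))
  report <- rbind_or(report, NULL)
  if (!is.null(report)) {
    o <- order(report$source_gene_id, report$target_gene_id,
               report$target_accession, report$catalog_row)
    report <- report[o, , drop = FALSE]
    rownames(report) <- NULL
  } else {
    report <- data.frame()
  }

  summary <- aggregate_counts(report, lengths = lengths)
  out <- structure(list(report = report, summary = summary,
                        anchoring = anchoring, rejects = cat_parsed$rejects,
                        failures = failures, config = config),
                   class = "crossphos_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' @export
print.crossphos_result <- function(x, ...) {
  cat("crossphos screen\n")
  cat("  catalog rows retained:", nrow(x$anchoring) , "| rejected:",
      nrow(x$rejects), "\n")
  if (nrow(x$anchoring))
    cat("  anchoring:", paste(names(table(x$anchoring$status)),
                              table(x$anchoring$status),
                              collapse = ", ", sep = "="), "\n")
  cat("  report rows:", nrow(x$report), "| mapping failures:",
      nrow(x$failures), "\n")
  if (nrow(x$summary)) {
    all6 <- x$summary[x$summary$source_species == "all", , drop = FALSE]
    cat("  target genes by cutoff:",
        paste(all6$cutoff, all6$n_target_genes, sep = ":", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Aggregate per-cutoff conservation counts
#'
#' For each window-length cutoff, counts distinct target genes with at least
#' one qualifying site and qualifying (site, target gene) pairs, judging
#' each gene by its longest isoform (ties broken by lexicographically
#' smallest accession).  Counts are reported per source species and overall
#' (`source_species == "all"`), and are non-increasing in the cutoff.
#'
#' @param report report data.frame from [run_pipeline()].
#' @param lengths cutoffs, default 6..11.
#' @return data.frame with columns `cutoff`, `source_species`,
#'   `n_target_genes`, `n_site_gene_pairs`.
#' @export
aggregate_counts <- function(report, lengths = 6:11) {
  empty <- do.call(rbind, lapply(lengths, function(L) data.frame(
    cutoff = L, source_species = "all", n_target_genes = 0L,
    n_site_gene_pairs = 0L, stringsAsFactors = FALSE)))
  if (is.null(report) || nrow(report) == 0L) return(empty)

  # longest-isoform filter, per target gene
  keep <- unlist(lapply(split(seq_len(nrow(report)), report$target_gene_id),
    function(ix) {
      r <- report[ix, , drop = FALSE]
      best_len <- max(r$target_isoform_length)
      cand <- r$target_accession[r$target_isoform_length == best_len]
      ix[r$target_accession == min(cand)]
    }))
  r <- report[sort(keep), , drop = FALSE]
  r$.site_key <- paste(r$source_species, r$source_accession, r$residue,
                       r$source_position)

  one <- function(L, rows, species) {
    q <- rows[[paste0("qualified_", L)]]
    data.frame(cutoff = L, source_species = species,
               n_target_genes = length(unique(rows$target_gene_id[q])),
               n_site_gene_pairs = length(unique(
                 paste(rows$.site_key, rows$target_gene_id)[q])),
               stringsAsFactors = FALSE)
  }
  species_levels <- c("all", sort(unique(r$source_species)))
  out <- list()
  for (L in lengths) {
    for (sp in species_levels) {
      rows <- if (sp == "all") r else r[r$source_species == sp, , drop = FALSE]
      out[[length(out) + 1L]] <- one(L, rows, sp)
    }
  }
  do.call(rbind, out)
}

#' Write pipeline outputs as TSVs
#'
#' Writes `report.tsv`, `summary.tsv`, `anchoring.tsv` and `rejects.tsv`.
#'
#' @param result a `crossphos_result`.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  w(result$report, "report.tsv")
  w(result$summary, "summary.tsv")
  w(result$anchoring, "anchoring.tsv")
  w(result$rejects, "rejects.tsv")
  invisible(out_dir)
}
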