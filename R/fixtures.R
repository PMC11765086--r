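# Deterministic synthetic fixture bundles with planted conservation
# structure.  One gene pair per planted site; the truth table states, per
# site, the expected anchoring status, longest identical run and qualified
# window lengths, derived from the construction itself (edits are
# rule-targeted, not an evolutionary model).

#' Conservation classes available to the fixture generator
#'
#' * `identical_15` — target window identical: run 15, all cutoffs qualify.
#' * `run_6` .. `run_14` — non-conservative substitutions planted at the run
#'   boundaries so the identical run through the site is exactly k; cutoffs
#'   qualify up to min(k, 11).
#' * `conservative_sub_pass` — single K->R replacement at site-3: run 10,
#'   every cutoff qualifies via the one-replacement allowance.
#' * `adjacent_sub_fail` — conservative replacement at site+1 plus a
#'   non-conservative one at site-4: no window survives the adjacency rule.
#' * `site_mismatch_fail` — target site residue differs: run 0, nothing
#'   qualifies.
#' * `gap_fail` — two-residue deletion next to the site and the site letter
#'   scrubbed from the target neighbourhood: the site cannot be identical
#'   under any alignment.
#' * `low_rank_fail` — conserved window but the ortholog call is rank
#'   "low": filtered before alignment.
#' * `bad_accession_rescue` — stale catalog accession; anchored through the
#'   gene-symbol rescue path.
#' * `shifted_anchor_pass` — stated position off by 12; recovered by the
#'   exact flank scan (`anchored_shifted`).
#' * `ambiguous_peptide_fail` — flank planted twice on the source protein
#'   with a wrong stated position: anchoring must refuse to guess.
#' * `multi_isoform_pass` — target gene carries a second, shorter isoform
#'   lacking the site; the gene is judged by its longest isoform.
#' * `n_term_pad_pass` — site at protein position 2 with underscore padding
#'   in the flank; alignment-edge padding caps the run at 9 and the
#'   qualifying cutoffs at 9.
#' @export
fixture_classes <- function() {
  c("identical_15", paste0("run_", 6:14), "conservative_sub_pass",
    "adjacent_sub_fail", "site_mismatch_fail", "gap_fail", "low_rank_fail",
    "bad_accession_rescue", "shifted_anchor_pass", "ambiguous_peptide_fail",
    "multi_isoform_pass", "n_term_pad_pass")
}

#' Fixture specification
#'
#' @param seed integer RNG seed; the same seed yields byte-identical files.
#' @param classes character vector of planted-site classes, one gene pair
#'   per entry (see [fixture_classes()]); the default plants every class
#'   three times (60 gene pairs).
#' @param protein_length integer range for background protein lengths.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         classes = rep(fixture_classes(), 3L),
                         protein_length = c(160L, 240L)) {
  bad <- setdiff(classes, fixture_classes())
  if (length(bad)) stop("unknown fixture class(es): ",
                        paste(unique(bad), collapse = ", "))
  structure(list(seed = as.integer(seed), classes = classes,
                 protein_length = as.integer(protein_length)),
            class = "fixture_spec")
}

# first non-conservative partner (matrix entry <= -1) in fixed AA order
.nonconservative_partner <- function(x, matrix = similarity_matrix()) {
  for (y in AA20) if (y != x && matrix[x, y] <= -1) return(y)
  stop("no non-conservative partner for ", x)  # unreachable for AA20
}

#' Apply an edit plan to a 15-mer window
#'
#' Edits are `list(pos =, type =)` with type one of `"conservative"`,
#' `"nonconservative"` or `"set"` (with a `to` letter).  For classes meant
#' to pass the window rule, edits at the site or site +/- 1 are refused:
#' such an edit would contradict the planted truth.
#'
#' @param base_window source 15-mer (site at index 8).
#' @param plan list of edits.
#' @param allow_site_region permit edits at site +/- 1 and the site
#'   (fail-class plans only).
#' @param matrix similarity matrix used to pick replacement letters.
#' @return mutated 15-mer string (the target-species window).
#' @export
plant_window <- function(base_window, plan, allow_site_region = FALSE,
                         matrix = similarity_matrix()) {
  ch <- strsplit(toupper(base_window), "", fixed = TRUE)[[1]]
  stopifnot(length(ch) == 15L)
  for (ed in plan) {
    p <- ed$pos
    if (!allow_site_region && p %in% 7:9)
      stop("edit at window position ", p,
           " touches the site region of a pass-class plan")
    ch[p] <- switch(ed$type,
      conservative = {
        cand <- AA20[vapply(AA20, function(y)
          y != ch[p] && matrix[ch[p], y] > 0, logical(1))]
        if (length(cand) == 0L)
          stop("no conservative partner for ", ch[p])
        cand[1]
      },
      nonconservative = .nonconservative_partner(ch[p], matrix),
      set = ed$to,
      stop("unknown edit type: ", ed$type))
  }
  paste(ch, collapse = "")
}

# truth bookkeeping: expected qualified lengths as a named logical row
.qrow <- function(upto) {
  setNames(as.list(6:11 <= upto), paste0("expect_q", 6:11))
}

#' Generate a synthetic fixture bundle
#'
#' Writes `catalog.tsv`, `source.fasta`, `target.fasta`,
#' `source_gene_map.tsv`, `target_gene_map.tsv`, `id_map.tsv`,
#' `orthologs.tsv` and `truth.tsv` into `out_dir`.  Background sequence is
#' drawn uniformly from the 20 amino acids under the spec seed; each
#' planted flank is kept locally unique within its protein (checked, and
#' redrawn on the rare collision) so anchoring ambiguity only occurs where
#' it is planted.  `truth.tsv` states the expected anchoring status, report
#' membership, longest identical run and qualified cutoffs for every site.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of the file paths plus the truth
#'   data.frame.
#' @export
make_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  m <- similarity_matrix()
  species_cycle <- c("human", "mouse", "rat")
  residue_cycle <- c("S", "T", "Y")

  catalog <- list(); truth <- list()
  src_fa <- character(); tgt_fa <- character()
  src_map <- list(); tgt_map <- list(); idm <- list(); ort <- list()

  rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
  count_hits <- function(core, seqs) {
    sum(vapply(seqs, function(s)
      length(gregexpr(paste0("(?=", core, ")"), s, perl = TRUE)[[1]]) *
        (regexpr(core, s, fixed = TRUE) > 0), integer(1)))
  }

  for (i in seq_along(spec$classes)) {
    cls <- spec$classes[i]
    sp <- species_cycle[(i - 1L) %% 3L + 1L]
    res <- residue_cycle[(i - 1L) %% 3L + 1L]
    sgid <- as.character(1000L + i); tgid <- as.character(2000L + i)
    sym <- sprintf("SRCG%03d", i)
    sacc <- sprintf("NP_%04d.1", i); tacc <- sprintf("XP_%04d.1", i)

    n_term <- cls == "n_term_pad_pass"
    plen <- if (cls == "ambiguous_peptide_fail") 220L else
      sample(spec$protein_length[1]:spec$protein_length[2], 1L)
    pos <- if (n_term) 2L else
      if (cls == "ambiguous_peptide_fail") 50L else
      sample(40L:(plen - 40L), 1L)

    # source window with the phospho-residue at index 8; for classes that
    # plant a specific replacement, force the donor residue first
    repeat {
      w <- sample(AA20, 15L, replace = TRUE)
      w[8] <- res
      if (cls == "conservative_sub_pass") w[5] <- "K"
      if (cls == "adjacent_sub_fail") w[9] <- "K"
      window <- paste(w, collapse = "")
      core <- if (n_term) substr(window, 7L, 15L) else window

      base <- rand_seq(plen)
      if (n_term) {
        seq_src <- paste0(core, substr(base, 10L, plen))
      } else {
        seq_src <- paste0(substr(base, 1L, pos - 8L), window,
                          substr(base, pos + 8L, plen))
      }
      if (cls == "ambiguous_peptide_fail")
        seq_src <- paste0(substr(seq_src, 1L, 129L), window,
                          substr(seq_src, 145L, nchar(seq_src)))
      n_expected <- if (cls == "ambiguous_peptide_fail") 2L else 1L
      if (count_hits(core, seq_src) == n_expected) break
    }

    # target window and protein -------------------------------------------
    run_k <- if (grepl("^run_", cls)) as.integer(sub("run_", "", cls)) else NA
    twindow <- switch(cls,
      conservative_sub_pass = plant_window(window,
        list(list(pos = 5L, type = "set", to = "R")), matrix = m),
      adjacent_sub_fail = plant_window(window,
        list(list(pos = 9L, type = "set", to = "R"),
             list(pos = 4L, type = "nonconservative")),
        allow_site_region = TRUE, matrix = m),
      site_mismatch_fail = plant_window(window,
        list(list(pos = 8L, type = "nonconservative")),
        allow_site_region = TRUE, matrix = m),
      {
        if (!is.na(run_k)) {
          a <- max(1L, 10L - run_k)
          edits <- list()
          if (a - 1L >= 1L)
            edits <- c(edits, list(list(pos = a - 1L,
                                        type = "nonconservative")))
          if (a + run_k <= 15L)
            edits <- c(edits, list(list(pos = a + run_k,
                                        type = "nonconservative")))
          plant_window(window, edits, matrix = m)
        } else window
      })

    seq_tgt <- seq_src
    if (!n_term)
      seq_tgt <- paste0(substr(seq_tgt, 1L, pos - 8L), twindow,
                        substr(seq_tgt, pos + 8L, nchar(seq_tgt)))
    else
      seq_tgt <- paste0(substr(twindow, 7L, 15L),
                        substr(seq_tgt, 10L, nchar(seq_tgt)))
    if (cls == "gap_fail") {
      # scrub the site letter from the target neighbourhood so the site
      # cannot be identical under any alignment, then delete 2 residues
      lo <- max(1L, pos - 12L); hi <- min(nchar(seq_tgt), pos + 12L)
      ch <- strsplit(seq_tgt, "", fixed = TRUE)[[1]]
      ch[lo:hi][ch[lo:hi] == res] <- .nonconservative_partner(res, m)
      ch <- ch[-c(pos + 3L, pos + 4L)]
      seq_tgt <- paste(ch, collapse = "")
    }

    # catalog row -----------------------------------------------------------
    stated_pos <- pos +
      if (cls %in% c("shifted_anchor_pass", "ambiguous_peptide_fail")) 12L
      else 0L
    cat_acc <- if (cls == "bad_accession_rescue")
      sprintf("NP_%04d9.9", i) else sacc
    flank <- window
    substr(flank, 8L, 8L) <- tolower(res)
    if (n_term) flank <- paste0("______", substr(flank, 7L, 15L))
    catalog[[i]] <- data.frame(
      GENE = sym, ACC_ID = cat_acc, ORGANISM = sp,
      MOD_RSD = paste0(res, stated_pos, "-p"),
      `SITE_+/-7_AA` = flank, `CST_CAT#` = sprintf("AB%04d", 1000L + i),
      check.names = FALSE, stringsAsFactors = FALSE)

    # stores / maps ----------------------------------------------------------
    src_fa <- c(src_fa, paste0(">", sacc, " ", sym), seq_src)
    tgt_fa <- c(tgt_fa, paste0(">", tacc, " t", sym), seq_tgt)
    src_map[[length(src_map) + 1L]] <-
      data.frame(gene_id = sgid, accession = sacc, stringsAsFactors = FALSE)
    tgt_map[[length(tgt_map) + 1L]] <-
      data.frame(gene_id = tgid, accession = tacc, stringsAsFactors = FALSE)
    if (cls == "multi_isoform_pass") {
      short_acc <- sprintf("XP_%04dS.1", i)
      short_seq <- substr(seq_tgt, 1L, pos - 10L)
      tgt_fa <- c(tgt_fa, paste0(">", short_acc, " t", sym, " short"),
                  short_seq)
      tgt_map[[length(tgt_map) + 1L]] <-
        data.frame(gene_id = tgid, accession = short_acc,
                   stringsAsFactors = FALSE)
    }
    idm[[length(idm) + 1L]] <-
      data.frame(namespace = "symbol", token = sym, gene_id = sgid,
                 stringsAsFactors = FALSE)
    ort[[length(ort) + 1L]] <- data.frame(
      source_taxon = c(human = "9606", mouse = "10090", rat = "10116")[[sp]],
      source_gene_id = sgid, target_taxon = "7227", target_gene_id = tgid,
      rank = if (cls == "low_rank_fail") "low"
             else c("high", "moderate")[(i %% 2L) + 1L],
      score = sprintf("%.1f", 5 + (i %% 10L)), stringsAsFactors = FALSE)

    # truth -----------------------------------------------------------------
    expect <- switch(cls,
      identical_15 = , low_rank_fail = , multi_isoform_pass =
        list(status = "anchored_direct", reason = NA, run = 15L, upto = 11L),
      bad_accession_rescue =
        list(status = "rescued_by_symbol", reason = NA, run = 15L,
             upto = 11L),
      shifted_anchor_pass =
        list(status = "anchored_shifted", reason = NA, run = 15L,
             upto = 11L),
      ambiguous_peptide_fail =
        list(status = "failed", reason = "ambiguous_peptide", run = NA,
             upto = NA),
      conservative_sub_pass =
        list(status = "anchored_direct", reason = NA, run = 10L, upto = 11L),
      adjacent_sub_fail =
        list(status = "anchored_direct", reason = NA, run = 4L, upto = 0L),
      site_mismatch_fail = , gap_fail =
        list(status = "anchored_direct", reason = NA, run = 0L, upto = 0L),
      n_term_pad_pass =
        list(status = "anchored_direct", reason = NA, run = 9L, upto = 9L),
      list(status = "anchored_direct", reason = NA, run = run_k,
           upto = min(run_k, 11L)))
    in_report <- !(cls %in% c("low_rank_fail", "ambiguous_peptide_fail"))
    truth[[i]] <- data.frame(
      site_id = i, catalog_row = i, class = cls, gene_symbol = sym,
      target_gene_id = tgid,
      expect_status = expect$status,
      expect_failure_reason = if (is.na(expect$reason[1])) NA_character_
                              else expect$reason,
      expect_in_report = in_report,
      expect_run = if (in_report) expect$run else NA_integer_,
      as.data.frame(if (in_report) .qrow(expect$upto) else .qrow(-1L)),
      stringsAsFactors = FALSE)
    if (!in_report) truth[[i]][paste0("expect_q", 6:11)] <- NA
  }

  paths <- list(
    catalog = file.path(out_dir, "catalog.tsv"),
    source_proteome = file.path(out_dir, "source.fasta"),
    target_proteome = file.path(out_dir, "target.fasta"),
    source_gene_map = file.path(out_dir, "source_gene_map.tsv"),
    target_gene_map = file.path(out_dir, "target_gene_map.tsv"),
    id_map = file.path(out_dir, "id_map.tsv"),
    ortholog_table = file.path(out_dir, "orthologs.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  wt <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(do.call(rbind, catalog), paths$catalog)
  writeLines(src_fa, paths$source_proteome)
  writeLines(tgt_fa, paths$target_proteome)
  wt(do.call(rbind, src_map), paths$source_gene_map)
  wt(do.call(rbind, tgt_map), paths$target_gene_map)
  wt(do.call(rbind, idm), paths$id_map)
  wt(do.call(rbind, ort), paths$ortholog_table)
  truth_df <- do.call(rbind, truth)
  wt(truth_df, paths$truth)
  invisible(c(paths, list(truth_df = truth_df)))
}
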