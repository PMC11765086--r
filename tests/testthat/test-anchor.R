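# Epitope anchoring: exact peptide location and the three-stage anchor.

test_that("locate_peptide finds interior, terminal and repeated matches", {
  flank <- "MILLSELSRRRIRSI"
  seqc <- paste0(paste(rep("G", 9), collapse = ""), flank, "GGGG")
  expect_equal(locate_peptide(flank, seqc), 17L)  # match starts at 10, site +7

  # N-terminal padding anchors the match to the sequence start
  expect_equal(locate_peptide("______MSGRGKGGK", "MSGRGKGGKGLGKGGAK"), 2L)
  expect_length(locate_peptide("______MSGRGKGGK", "AMSGRGKGGKGLGKGGAK"), 0L)

  # C-terminal padding anchors to the end
  expect_equal(locate_peptide("QFSYSASGTA_____", "KKKQFSYSASGTA"), 11L)

  # duplicated peptide: both site positions reported
  twice <- paste0("AAA", flank, "CCCCC", flank, "AAA")
  expect_equal(locate_peptide(flank, twice), c(11L, 31L))
})

test_that("locate_peptide finds every true window and agrees with the naive scan", {
  set.seed(41)
  for (rep in 1:25) {
    seqc <- paste(sample(ORACLE_AA, sample(40:120, 1), replace = TRUE),
                  collapse = "")
    n <- nchar(seqc)
    # completeness: every interior 15-mer window is recovered at its site
    for (p in sample(8:(n - 7), 5)) {
      w <- substr(seqc, p - 7, p + 7)
      expect_true(p %in% locate_peptide(w, seqc))
    }
    # oracle equivalence, including padded flanks at the termini
    nterm <- paste0("______", substr(seqc, 1, 9))
    cterm <- paste0(substr(seqc, n - 9, n), "_____")
    random15 <- paste(sample(ORACLE_AA, 15, replace = TRUE), collapse = "")
    for (fl in list(substr(seqc, 3, 17), nterm, cterm, random15)) {
      expect_equal(locate_peptide(fl, seqc), oracle_locate(fl, seqc))
    }
  }
})

make_anchor_world <- function(env = parent.frame()) {
  fa <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  map <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  im <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  set.seed(9)
  core <- paste(sample(ORACLE_AA, 60, replace = TRUE), collapse = "")
  flank <- substr(core, 18, 32)  # site at core position 25
  writeLines(c(">NP_100.1 current", core,
               ">NP_200.1 shifted isoform",
               paste0("MGSTAGSPA", core)), fa)  # +9 offset
  writeLines(c("gene_id\taccession", "55\tNP_100", "55\tNP_200"), map)
  writeLines(c("namespace\ttoken\tgene_id", "symbol\tGENEA\t55"), im)
  list(store = load_proteome(fa, map, "human"), id_map = load_id_map(im),
       flank = flank, residue = substr(core, 25, 25))
}

test_that("anchoring tries direct position, peptide scan, then symbol rescue", {
  w <- make_anchor_world()
  rec <- list(gene_symbol = "GENEA", protein_accession = "NP_100.1",
              residue = w$residue, position = 25L, flank_peptide = w$flank)

  direct <- anchor_site(rec, w$store, w$id_map)
  expect_equal(direct$status, "anchored_direct")
  expect_equal(direct$site_position, 25L)

  # stated coordinate drifted by an isoform offset: exact scan recovers it
  shifted <- rec
  shifted$protein_accession <- "NP_200.1"
  res <- anchor_site(shifted, w$store, w$id_map)
  expect_equal(res$status, "anchored_shifted")
  expect_equal(res$site_position, 34L)
  expect_equal(substr(res$protein$sequence, res$site_position,
                      res$site_position), rec$residue)

  # stale accession: symbol rescue, but two isoforms match -> ambiguous
  stale <- rec
  stale$protein_accession <- "NP_404.9"
  res <- anchor_site(stale, w$store, w$id_map)
  expect_equal(res$status, "failed")
  expect_equal(res$failure_reason, "ambiguous_peptide")

  # unknown accession and symbol: nothing to anchor to
  lost <- stale
  lost$gene_symbol <- "NOSUCH"
  expect_equal(anchor_site(lost, w$store, w$id_map)$failure_reason,
               "no_protein")

  # peptide absent everywhere
  gone <- rec
  gone$protein_accession <- "NP_404.9"
  gone$flank_peptide <- strrep("W", 15)
  expect_equal(anchor_site(gone, w$store, w$id_map)$failure_reason,
               "peptide_not_found")
})

test_that("anchoring is deterministic and idempotent", {
  w <- make_anchor_world()
  rec <- list(gene_symbol = "GENEA", protein_accession = "NP_200.1",
              residue = w$residue, position = 25L, flank_peptide = w$flank)
  a <- anchor_site(rec, w$store, w$id_map)
  b <- anchor_site(rec, w$store, w$id_map)
  expect_identical(a, b)
})
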