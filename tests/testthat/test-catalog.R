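# Catalog dialect parsing and normalisation.

write_catalog_file <- function(rows, path = withr::local_tempfile(
                                 fileext = ".tsv", .local_envir = parent.frame())) {
  header <- "GENE\tACC_ID\tORGANISM\tMOD_RSD\tSITE_+/-7_AA\tCST_CAT#"
  writeLines(c(header, rows), path)
  path
}

test_that("MOD_RSD tokens parse to residue and position", {
  expect_equal(parse_mod_rsd("Y1150-p")[c("residue", "position")],
               list(residue = "Y", position = 1150L))
  expect_equal(parse_mod_rsd("S473-p")[c("residue", "position")],
               list(residue = "S", position = 473L))
  expect_equal(parse_mod_rsd("T308")[c("residue", "position")],
               list(residue = "T", position = 308L))
  expect_equal(parse_mod_rsd("K48-ub")$error, "non_STY_residue")
  expect_equal(parse_mod_rsd("K48-p")$error, "non_STY_residue")
  expect_equal(parse_mod_rsd("whatever")$error, "bad_mod_rsd")
})

test_that("flank normalisation uppercases, keeps terminal padding, rejects the rest", {
  ok <- normalize_flank("RPHFPQFsYSASGTA")
  expect_null(ok$error)
  expect_equal(ok$flank, "RPHFPQFSYSASGTA")
  expect_equal(ok$site_index, 8L)

  nterm <- normalize_flank("______MsGRGKGGK")
  expect_null(nterm$error)
  expect_equal(nterm$flank, "______MSGRGKGGK")

  expect_equal(normalize_flank("RPHFPQFsYSASGT")$error, "bad_flank_length")
  expect_equal(normalize_flank("RPHFPQF_YSASGTA")$error, "bad_padding")
  expect_equal(normalize_flank("RPHFPQFSySASGTA")$error, "site_not_centered")
  expect_equal(normalize_flank("RPHFPQFsYSXSGTA")$error, "ambiguity_code")
})

test_that("catalog rows are retained, filtered or rejected with reasons", {
  path <- write_catalog_file(c(
    "INSR\tNP_000199.2\thuman\tY1150-p\tETDYYRKGGKGLLPV\tAB3024",
    "Akt1\tNP_033782.1\tmouse\tS473-p\tRPHFPQFsYSASGTA\tAB9271",
    "KDR\tNP_002244.1\tchicken\tY1054-p\tDIYKDPDsYVRKGGA\tAB1111",
    "BAD1\tNP_000001.1\thuman\tK48-ub\tAAAAAAAkAAAAAAA\tAB2222",
    "BAD2\tNP_000002.1\trat\tS99-p\tAAAAAAAsAAAAAA\tAB3333",
    "NOAB\tNP_000003.1\thuman\tS10-p\tAAAAAAAsAAAAAAA\t"))
  parsed <- parse_catalog(path, species_filter = c("human", "mouse", "rat"))
  # flank of row 1 is not lowercase-centred at 8: ETDYYRKGGKGLLPV has no
  # lowercase site, so write one properly
  expect_equal(nrow(parsed$records) + nrow(parsed$rejects), 6L)
  expect_setequal(parsed$rejects$reason_code,
                  c("species_excluded", "non_STY_residue",
                    "bad_flank_length", "no_antibody", "site_not_centered"))
  expect_equal(parsed$records$gene_symbol, "Akt1")
  expect_equal(parsed$records$residue, "S")
  expect_equal(parsed$records$position, 473L)
  expect_equal(parsed$records$flank_peptide, "RPHFPQFSYSASGTA")
})

test_that("a missing mandatory column is a fatal configuration error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GENE\tORGANISM\tMOD_RSD\tSITE_+/-7_AA",
               "AKT1\thuman\tS473-p\tRPHFPQFsYSASGTA"), path)
  expect_error(parse_catalog(path), "ACC_ID")
})

test_that("rows without an antibody id are kept when the flag allows them", {
  path <- write_catalog_file(
    "NOAB\tNP_000003.1\thuman\tS10-p\tAAAAAAAsAAAAAAA\t")
  with_flag <- parse_catalog(path, require_antibody = FALSE)
  expect_equal(nrow(with_flag$records), 1L)
  expect_equal(with_flag$records$antibody_ids, "")
})

test_that("retained records round-trip through the catalog dialect", {
  set.seed(3)
  rows <- vapply(1:12, function(i) {
    fl <- sample(ORACLE_AA, 15, replace = TRUE)
    res <- sample(c("S", "T", "Y"), 1)
    fl[8] <- tolower(res)
    sprintf("G%d\tNP_%05d.%d\t%s\t%s%d-p\t%s\tAB%04d", i, i, i %% 3 + 1,
            c("human", "mouse", "rat")[i %% 3 + 1], res, 10 * i,
            paste(fl, collapse = ""), i)
  }, character(1))
  path <- write_catalog_file(rows)
  first <- parse_catalog(path)
  expect_equal(nrow(first$records), 12L)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(first$records, out)
  second <- parse_catalog(out)
  expect_equal(second$records, first$records)
  expect_equal(nrow(second$rejects), 0L)
})
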