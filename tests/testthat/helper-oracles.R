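# Independent oracles used to cross-check the implementation.  These are
# written from the rules themselves, not from the package internals.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# The twelve published human/fly flank-peptide pairs with validated
# cross-reactive antibodies, and their conserved-region lengths.
validated_pairs <- list(
  list(q = "RPHFPQFSYSASGTA", s = "EPLFPQFSYQGDMAS", run = 6L),
  list(q = "SDGEFLRTSCGSPNY", s = "LDGEFLRTSCGSPNY", run = 14L),
  list(q = "AGTSFMMTPYVVTRY", s = "AGTTFMMTPYVVTRY", run = 11L),
  list(q = "TSFMMTPYVVTRYYR", s = "TTFMMTPYVVTRYYR", run = 13L),
  list(q = "MILLSELSRRRIRSI", s = "MILLSELSRRRIRSI", run = 15L),
  list(q = "RQADSEMTGYVVTRW", s = "RPTENEMTGYVATRW", run = 6L),
  list(q = "ADSEMTGYVVTRWYR", s = "TENEMTGYVATRWYR", run = 6L),
  list(q = "HDHTGFLTEYVATRW", s = "HDHTGFLTEYVATRW", run = 15L),
  list(q = "HTGFLTEYVATRWYR", s = "HTGFLTEYVATRWYR", run = 15L),
  list(q = "NQVFLGFTYVAPSVL", s = "NLIFQGFTYVAPSIL", run = 8L),
  list(q = "PPGDYSTTPGGTLFS", s = "MPEVYSSTPGGTLYS", run = 6L),
  list(q = "GGTLFSTTPGGTRII", s = "GGTLYSTTPGGTKLI", run = 7L))

# Literal enumerator for the window rule: try every sub-window of length L
# containing the site; it qualifies if all positions are identical, or all
# but one are identical and that one is a strictly-positive-scoring
# replacement neither at nor adjacent to the site.
oracle_window_qualifies <- function(qw, sw, site = 8L, L, mat = blosum62) {
  q <- strsplit(toupper(qw), "")[[1]]
  s <- strsplit(toupper(sw), "")[[1]]
  for (st in 1:(16L - L)) {
    idx <- st:(st + L - 1L)
    if (!(site %in% idx)) next
    if (!all(q[idx] %in% ORACLE_AA) || !all(s[idx] %in% ORACLE_AA)) next
    diff <- idx[q[idx] != s[idx]]
    if (length(diff) == 0L) return(TRUE)
    if (length(diff) == 1L) {
      p <- diff
      if (p != site && abs(p - site) != 1L && mat[q[p], s[p]] > 0)
        return(TRUE)
    }
  }
  FALSE
}

# Brute-force longest identical run through the site: enumerate every
# contiguous interval containing the site and keep the longest fully
# identical one.
oracle_longest_run <- function(qw, sw, site = 8L) {
  q <- strsplit(toupper(qw), "")[[1]]
  s <- strsplit(toupper(sw), "")[[1]]
  best <- 0L
  for (lo in 1:site) for (hi in site:15) {
    idx <- lo:hi
    if (all(q[idx] == s[idx] & q[idx] %in% ORACLE_AA))
      best <- max(best, hi - lo + 1L)
  }
  best
}

# Independent affine-gap global DP (Gotoh); gap of length g costs
# open + g * ext, end gaps penalised.
oracle_global_score <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in subject
  Y <- matrix(NEG, n + 1, m + 1)  # gap in query
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- mat[A[i], B[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# All-positions substring comparison for peptide location, independent of
# locate_peptide(): slide the flank across every site position and compare
# character by character, underscores demanding out-of-range (terminus).
oracle_locate <- function(flank, sequence) {
  fch <- strsplit(toupper(flank), "")[[1]]
  sch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(sch)
  hits <- integer(0)
  for (p in seq_len(n)) {
    ok <- TRUE
    for (i in 1:15) {
      sp <- p + i - 8L
      if (fch[i] == "_") {
        if (sp >= 1L && sp <= n) { ok <- FALSE; break }
      } else if (sp < 1L || sp > n || sch[sp] != fch[i]) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# Random 15-mer pair with a phosphosite at index 8 and 0..max_edits random
# substitutions (so qualifying and non-qualifying windows both occur).
random_window_pair <- function(max_edits = 6L) {
  q <- sample(ORACLE_AA, 15L, replace = TRUE)
  q[8] <- sample(c("S", "T", "Y"), 1L)
  s <- q
  k <- sample(0:max_edits, 1L)
  if (k > 0L) {
    pos <- sample.int(15L, k)
    s[pos] <- sample(ORACLE_AA, k, replace = TRUE)
  }
  list(q = paste(q, collapse = ""), s = paste(s, collapse = ""))
}

# A small self-consistent fixture for quick pipeline tests.
quick_fixture <- function(seed = 11L,
                          classes = c("identical_15", "run_7",
                                      "conservative_sub_pass",
                                      "site_mismatch_fail",
                                      "low_rank_fail",
                                      "bad_accession_rescue")) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  make_fixture(fixture_spec(seed = seed, classes = classes), dir)
}

fixture_config <- function(fx, ...) {
  pipeline_config(catalog = fx$catalog,
                  source_proteome = fx$source_proteome,
                  source_gene_map = fx$source_gene_map,
                  target_proteome = fx$target_proteome,
                  target_gene_map = fx$target_gene_map,
                  id_map = fx$id_map,
                  ortholog_table = fx$ortholog_table, ...)
}

# Compare a pipeline result against a fixture truth table; returns a
# character vector of discrepancies (empty when everything agrees).
truth_discrepancies <- function(res, truth) {
  bad <- character(0)
  note <- function(...) bad <<- c(bad, paste(...))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    anc <- res$anchoring[res$anchoring$catalog_row == tr$catalog_row, ]
    if (nrow(anc) != 1L || anc$status != tr$expect_status) {
      note(tr$class, "status", anc$status, "!=", tr$expect_status); next
    }
    if (tr$expect_status == "failed" &&
        !identical(anc$failure_reason, tr$expect_failure_reason))
      note(tr$class, "failure reason", anc$failure_reason)
    rows <- res$report[res$report$catalog_row == tr$catalog_row, ]
    if (!tr$expect_in_report) {
      if (nrow(rows) > 0L) note(tr$class, "unexpected report rows")
      next
    }
    if (nrow(rows) == 0L) { note(tr$class, "missing report rows"); next }
    best <- rows[which.max(rows$target_isoform_length), ]
    if (best$longest_identical_run != tr$expect_run)
      note(tr$class, "run", best$longest_identical_run, "!=", tr$expect_run)
    for (L in 6:11)
      if (best[[paste0("qualified_", L)]] != tr[[paste0("expect_q", L)]])
        note(tr$class, "qualified at", L)
  }
  bad
}
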