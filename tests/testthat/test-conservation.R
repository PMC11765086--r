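# The conservation scoring core: identical runs through the phosphosite and
# window qualification with the single non-adjacent conservative
# replacement.

test_that("validated cross-reactive pairs reproduce their conserved-region lengths", {
  for (p in validated_pairs) {
    expect_equal(longest_identical_run(p$q, p$s), p$run,
                 info = paste(p$q, p$s))
    expect_equal(oracle_longest_run(p$q, p$s), p$run)
  }
})

test_that("the run is zero when the site differs and bounded by mismatches", {
  expect_equal(longest_identical_run("AAAAAAASAAAAAAA", "AAAAAAATAAAAAAA"), 0L)
  # underscore padding is never identical
  expect_equal(longest_identical_run("______MSGRGKGGK", "______MSGRGKGGK"), 9L)
  # case-insensitive
  expect_equal(longest_identical_run("aaaaaaasaaaaaaa", "AAAAAAASAAAAAAA"), 15L)
  expect_error(longest_identical_run("SHORT", "SHORT"), "length 15")
})

test_that("conservative replacement means a strictly positive matrix score", {
  expect_true(is_conservative_substitution("K", "R"))
  expect_true(is_conservative_substitution("R", "K"))   # symmetric
  expect_false(is_conservative_substitution("H", "L"))
  expect_false(is_conservative_substitution("S", "Q"))  # zero is not positive
  expect_false(is_conservative_substitution("A", "A"))  # identity
  expect_false(is_conservative_substitution("K", "X"))  # ambiguity code
  expect_false(is_conservative_substitution("K", "_"))
})

test_that("window qualification follows the one-replacement, non-adjacent rule", {
  akt <- validated_pairs[[1]]
  expect_true(window_qualifies(akt$q, akt$s, L = 6))
  expect_false(window_qualifies(akt$q, akt$s, L = 7))
  prk <- validated_pairs[[2]]
  expect_true(window_qualifies(prk$q, prk$s, L = 11))

  base <- "VDEKQLSSYMNWAFR"
  sub3 <- base; substr(sub3, 5, 5) <- "R"  # Q->R at site-3: allowed
  expect_true(is_conservative_substitution("Q", "R"))
  w <- window_qualifies(base, sub3, L = 8)
  expect_true(as.logical(w))
  note <- attr(w, "substitution_note")
  expect_equal(note$position, 5L)
  expect_equal(c(note$query, note$subject), c("Q", "R"))

  # Y->F at site+1: conservative but adjacent, so it can never be the one
  # allowed replacement; only windows that end at the site (L <= 8) dodge it
  adj <- base; substr(adj, 9, 9) <- "F"
  expect_true(is_conservative_substitution("Y", "F"))
  for (L in 6:8) expect_true(as.logical(window_qualifies(base, adj, L = L)))
  for (L in 9:11) expect_false(window_qualifies(base, adj, L = L))

  at_site <- base; substr(at_site, 8, 8) <- "T"  # S->T at the site itself
  expect_true(is_conservative_substitution("S", "T"))
  for (L in 6:11) expect_false(window_qualifies(base, at_site, L = L))

  expect_error(window_qualifies(base, base, L = 5), "6..11")
  expect_error(window_qualifies(base, base, L = 12), "6..11")
})

test_that("qualification is monotone decreasing in window length", {
  set.seed(99)
  for (i in 1:400) {
    p <- random_window_pair()
    q <- vapply(6:11, function(L)
      isTRUE(as.logical(window_qualifies(p$q, p$s, L = L))), logical(1))
    expect_true(all(diff(q) <= 0),
                info = paste(p$q, p$s, paste(q, collapse = "")))
    r <- score_window_pair(p$q, p$s)
    expect_equal(unname(r$qualified_lengths), q)
    if (r$longest_identical_run >= 6) expect_true(q[1])
    if (r$longest_identical_run == 0) expect_false(any(q))
  }
})

test_that("with the replacement allowance disabled, qualification equals the run", {
  set.seed(17)
  for (i in 1:300) {
    p <- random_window_pair()
    r <- score_window_pair(p$q, p$s, allow_substitution = FALSE)
    expected <- if (r$longest_identical_run >= 6)
      min(11L, r$longest_identical_run) else 0L
    expect_equal(r$max_qualified_length, expected,
                 info = paste(p$q, p$s))
  }
})

test_that("scoring an alignment slice handles gaps and alignment edges", {
  aln <- global_align("MKTAYIAKQRQISFVKSHFSRQ", "MKTAYIAKQRQISFVKSHFSRQ")
  ctx <- transfer_site(aln, 11L)
  r <- score_site(ctx)
  expect_equal(r$longest_identical_run, 15L)
  expect_equal(r$max_qualified_length, 11L)

  # site near the start: columns beyond the alignment edge cap the window
  ctx2 <- transfer_site(aln, 2L)
  r2 <- score_site(ctx2)
  expect_equal(r2$longest_identical_run, 9L)
  expect_equal(r2$max_qualified_length, 9L)

  # subject gap at the site column: nothing can qualify
  gapped <- list(aligned_query = "MKTAYIAKQRQISFVKS",
                 aligned_subject = "MKTAYIAK-RQISFVKS",
                 site_column = 9L, alignment_score = 0)
  r3 <- score_site(gapped)
  expect_false(r3$site_identical)
  expect_equal(r3$longest_identical_run, 0L)
  expect_false(any(r3$qualified_lengths))

  # gap inside a candidate window disqualifies windows spanning it
  near_gap <- list(aligned_query = "MKTAYIAKQRQISFVKS",
                   aligned_subject = "MKTA-IAKQRQISFVKS",
                   site_column = 9L, alignment_score = 0)
  r4 <- score_site(near_gap)
  expect_equal(r4$longest_identical_run, 11L)  # slice runs from past the gap
  expect_true(r4$qualified_lengths[["6"]])
})
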