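---
title: "Epitope conservation screening across species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope conservation screening across species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossphos)
```

## The prediction problem

A phospho-specific antibody binds a peptide surface of roughly 6–15
residues centred on the phosphorylated S/T/Y. Whether an antibody raised
against a mammalian protein detects the orthologous protein in another
species is therefore, to first order, a question of local sequence
identity around the phosphosite. Antibodies with validated cross-species
reactivity show identical stretches through the site as short as six
residues, which motivates the screen implemented here: enumerate
candidate ortholog sites and grade the conservation of their immediate
neighbourhood, rather than attempt a structural or energetic model of
binding.

The unit of analysis is the *site*, not the antibody: products raised
against multi-site peptides appear as one catalog row per site sharing an
antibody identifier, and every row is scored independently.

## Scoring model

Both statistics operate on a 15-residue window with the phosphosite at
position 8 (the `±7` flank convention of the major phosphosite
databases).

**Longest identical run.** The length of the maximal contiguous block of
positions, containing the site, at which query and subject carry
identical standard amino acids. If the site itself is not identical the
run is 0 — a phospho-epitope cannot survive substitution of the
phospho-acceptor. Underscore padding, alignment gaps and ambiguity codes
(X/B/Z/U) never count as identical.

**Window qualification.** For each cutoff $L \in \{6,\dots,11\}$, the
site qualifies if some contiguous $L$-mer containing the site is fully
identical except at most one position that is

1. a *conservative replacement* — operationalised as a strictly positive
   entry of the similarity matrix (default BLOSUM62; zero scores such as
   S/Q do **not** qualify),
2. not the site itself, and
3. not adjacent to the site (site ± 1) — the positions in closest contact
   with the phospho-residue are where antibody recognition is least
   tolerant.

Qualification is monotone by construction: a window of length $L$
containing the site contains a window of length $L-1$ containing it, so
`qualified(L)` implies `qualified(L-1)` down to 6. An identical run of
$k \ge 6$ guarantees qualification at all cutoffs up to $\min(k, 11)$;
the replacement allowance can qualify cutoffs *beyond* the identical run.

Three readings of the rule were genuinely open and are resolved as
follows. *Adjacency* is sequence adjacency within the peptide (site ± 1),
a literal reading — the epitope an antibody sees is the linear peptide.
*The replacement may sit at a window edge*: only site-adjacency is
excluded, so an edge replacement is allowed. *The site residue must be
identical*, not merely any phospho-acceptor: every validated
cross-reactive pair has an identical site residue, and S→T exchange at
the acceptor would change the phospho-epitope itself.

Two code paths expose the statistic: `score_window_pair()` on raw 15-mer
pairs and `score_site()` on a 15-column alignment slice. They coincide
whenever the alignment is gap-free across the window, which is the case
for all validated pairs used as references; the alignment path
additionally rules that any gap column inside a candidate window
disqualifies it (an indel inside an epitope breaks the binding surface,
and it keeps window length well defined), and pads with the gap sentinel
when the site lies within 7 columns of an alignment end.

## Pipeline stages and their assumptions

**Anchoring** validates each catalog row against the current proteome
before anything else, because catalog accessions and coordinates drift
across releases. The stages are strictly exact-match: direct positional
check, then a full-protein scan for the flank (all overlapping
occurrences; underscore padding must coincide with the protein terminus),
then gene-symbol rescue across all proteins of the mapped gene(s). Any
ambiguity — two match positions, two matching proteins, two candidate
genes — is a failure with a reason code, never a guess: one wrong anchor
would contaminate every downstream alignment for that site. Sites
recovered at a different coordinate are flagged `anchored_shifted` so the
report exposes catalog drift, but proceed to scoring normally.

**Ortholog mapping** consumes a flat table with opaque ordered confidence
ranks (high > moderate > low). The default threshold keeps high and
moderate calls; the filter is monotone in the threshold. Orthology is
deliberately file-based — the screen runs fully offline and any ortholog
resource that can be exported to TSV can drive it.

**Alignment** is global (Needleman–Wunsch) with affine gaps, BLOSUM62,
gap open 11, gap extend 1 — the field-standard protein defaults, exposed
as configuration (`matrix`, `gap_open`, `gap_extend`) since nothing in
the method depends on these particular values; a gap of length $g$ costs
$11 + g$. Global rather than local alignment is essential: the site must
be placed in its genuine positional context, and end gaps are penalised
so isoform length differences surface as gap columns rather than silent
truncation. Alignment is performed against **every isoform** of each
ortholog gene — a conserved site present in several isoforms of
different lengths predicts multiple western-blot bands — while
gene-level summaries judge each gene by its **longest** isoform (ties
broken by lexicographically smallest accession, for determinism).

The implementation delegates the dynamic programming to
`Biostrings::pairwiseAlignment`; the test suite cross-checks its scores
against an independently written affine-gap (Gotoh) dynamic program on
exhaustively small sequences, and checks the gap-strip round trip on all
alignments produced.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `lengths` | 6–11 | residues | window cutoffs scored; 6 is the shortest validated cross-reactive epitope core, 11 a strict screen |
| `min_rank` | `"moderate"` | rank | minimum ortholog confidence retained |
| `matrix` | BLOSUM62 | — | defines both alignment scores and "conservative" (entry > 0) |
| `gap_open`, `gap_extend` | 11, 1 | score | affine gap costs of the global alignment |
| `allow_substitution` | `TRUE` | — | disable to demand full identity within a window |
| `require_antibody` | `TRUE` | — | restrict the screen to sites an existing antibody detects |
| `species_filter` | none | — | retain only catalog rows from the listed source species |

## The synthetic fixture generator

`make_fixture()` emits a complete, self-consistent input bundle —
catalog, two proteomes, gene maps, identifier map, ortholog table — plus
a truth table stating the expected anchoring status, run length and
qualifying cutoffs of every planted site. Background sequence is drawn
uniformly from the 20 amino acids under a fixed seed, planted flanks are
kept locally unique (collisions are redrawn), and edits are
*rule-targeted*: non-conservative substitutions pin the identical run to
an exact length, a K→R substitution exercises the replacement allowance,
deliberate duplications and stale accessions exercise the anchoring
failure modes, and rank-low ortholog rows exercise the confidence
filter. The truth values follow analytically from the construction, so
the end-to-end comparison is against expectations derived independently
of the scoring code.

For the `gap_fail` class the construction is made alignment-path
independent: the site's residue letter is scrubbed from the whole target
neighbourhood before a two-residue deletion is planted, so the site
column cannot be identical under *any* optimal alignment and the truth
(run 0, nothing qualifies) does not depend on where the aligner places
the gap. Similarly, a conservative substitution adjacent to the site is
paired with a non-conservative one on the other flank, because an
adjacent substitution alone still leaves fully identical windows ending
at the site.

What the generator does **not** emulate: realistic phylogenetic
divergence (edits are targeted, not drawn from an evolutionary model),
paralogy, alternative splicing beyond simple truncation, and the
scale and redundancy of real catalogs and proteomes. Passing the
planted-truth suite therefore demonstrates that the machinery implements
its rules exactly — not that the rules themselves capture antibody
biology; that evidence comes from the validated cross-reactive pairs,
whose published conserved-region lengths the scoring reproduces
row for row.

## Numerical and degenerate-input choices

* All comparison is case-insensitive after normalisation; flank peptides
  are uppercased on parse with the lowercase phospho-residue required at
  index 8.
* Accession version suffixes are stripped for every join; the versioned
  form is preserved for reporting.
* Ambiguity codes: an X in a catalog flank rejects the row (an ambiguous
  epitope cannot be matched exactly); X/B/Z/U in proteome sequences are
  tolerated but never identical and never conservative. U/O are scored
  as X during alignment without altering the reported sequences.
* Co-optimal alignments are resolved by the aligner's fixed traceback,
  making site transfer reproducible; the pipeline orders its report by
  (source gene, target gene, isoform accession, catalog row) so repeated
  runs are byte-identical.
* Empty sequences refuse to align; unknown genes yield empty ortholog
  sets rather than errors; every catalog row ends up in exactly one of
  report / reject / anchoring-failure / mapping-failure.

## Problem sizes used in validation

The shipped validation uses 60-gene synthetic screens (20 conservation
classes × 3, proteins of 160–240 residues), 10,000 random window pairs
against a literal brute-force enumerator of the window rule, 200 short
random sequence pairs against the independent alignment oracle, and the
twelve validated human→fly epitope pairs as exact references. These
sizes give exhaustive class coverage while a full run of the test suite
stays comfortably interactive.

## Known limitations

* Conservation of the linear peptide is a proxy; the screen knows
  nothing about phosphorylation state in vivo, epitope accessibility, or
  antibody affinity. Predictions rank candidates for bench validation.
* The conservative-replacement definition (positive BLOSUM62 entry) is a
  standard but crude surrogate for immunochemical equivalence.
* Sites within 7 residues of a terminus are scored on a truncated
  neighbourhood; cutoffs longer than the available context cannot
  qualify, which is conservative by design.
* The original alignment parameters behind the published screen are not
  documented; the defaults here are explicit configuration, so exact
  parameter-level emulation is possible if they become known.
* Paralog-mode screening (cross-gene reactivity) is out of scope.
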