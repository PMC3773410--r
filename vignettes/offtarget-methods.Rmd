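---
title: "Predicting siRNA off-target transcripts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting siRNA off-target transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedseq)
```

## The problem

An siRNA loaded into RISC silences its intended transcript through
near-perfect base pairing, but the same machinery tolerates mismatches,
gaps and G:U wobble pairs, so a typical 21-nt duplex can measurably
down-regulate many unintended transcripts. Three bodies of evidence shape
how such off-targets are predicted:

* transcripts with roughly 90% complementarity to the guide strand
  (17 of the 19 duplex-core nucleotides) are silenced much like on-targets;
* as few as 11 contiguous complementary nucleotides, or 15 in total, can
  reduce transcript levels;
* most off-targeting is *miRNA-like*: it is driven by the guide-strand
  seed (antisense positions 2–8) pairing sites in the 3'UTR, with a single
  seed mismatch rescuable by perfect pairing of the guide's 3' region
  (the 3'-compensatory configuration), and abolished by mismatches
  opposite the mRNA cleavage site (antisense positions 8–10).

`seedseq` implements this rule set behind three complementarity-search
variants — whole-transcript local alignment, seed-anchored windowed
alignment, and the positional miRNA-like rules — plus conservation
filtering of seed sites, a validation layer that scores predictions
against expression-change tables, and a GenBank-dialect writer that
attaches `target_siRNAs` features to transcript records.

## Sequence model and coordinate conventions

All sequences are normalized to an uppercase RNA alphabet (`T` → `U`);
writers restore the source alphabet. Transcript intervals are 0-based
half-open throughout the API; flat-file feature locations are 1-based
inclusive, following GenBank convention. All duplex numbering is fixed on
the **antisense strand, 5'→3'**. Published descriptions sometimes number
the same region from the 3' end of the sense strand; the two coincide on a
19-nt duplex core, and pinning everything to the antisense strand keeps
the numbering well defined for 21-nt strands with 2-nt overhangs (which
never participate in scoring). When the sense strand is not supplied it is
derived as the reverse complement of antisense positions 1–19.

The seed defaults to antisense positions 2–8 (the 7mer-m8 register). Some
published siRNA/miRNA seed pairings are only consistent with a 1–7
register; since the sources conflict, the register is an explicit
`seed_def` argument rather than something the package switches silently.
The 6-mer seed option trims to positions 2–7, i.e. the 3'-most six
residues of the mRNA-side motif.

## Seed scanning and windows

`find_seed_sites()` reports **every** occurrence of the mRNA-side motif
(the reverse complement of the seed), including overlapping ones, because
seed-match frequency per transcript is itself an off-target correlate and
must not be undercounted. Matching is exact string equality by default;
G:U wobble inside the seed is opt-in (`allow_wobble_in_seed`), since
wobble tolerance is best characterized at the alignment stage.

Around each site a window of ~50 nt is cut for alignment. "~50" is fixed
at exactly `window_width = 50` with a deterministic asymmetry rule — left
flank `floor((width − seed_len)/2)`, remainder right, clipped at
transcript ends — chosen purely so that outputs are reproducible and
testable. Clipping can only remove flank, never seed residues.

## Alignment engine

`smith_waterman()` is a textbook local aligner with linear gap costs.
The published method names the algorithm but not its parameters; the
defaults (+2 match, −1 mismatch, −2 per gapped position) were chosen so
that a 7-nt exact seed outscores scattered isolated matches, and all three
values are configuration. The linear gap model (no separate open/extend)
keeps the engine equivalent to a small enumeration oracle, which the test
suite exploits: scores are checked against a plain recursive enumeration
of all local alignments (exhaustively for all pairs up to length 2, and on
seeded random pairs up to length 6), and against an independently
implemented aligner (`Biostrings::pairwiseAlignment`, local mode, zero gap
opening) on 500 seeded random pairs up to length 10. Literally exhausting
all sequence pairs up to length 6 (~30 M pairs) buys no additional
coverage and is far outside a sensible test budget; the instance sizes
above are the package's own choice.

Determinism is pinned down explicitly: the best cell is the first maximum
in column-major order, and the traceback prefers diagonal over
consume-query over consume-target moves. Ties therefore never introduce
run-to-run variation.

`align_duplex()` aligns the siRNA's *expected target site* (the reverse
complement of the duplex core) against an mRNA window, with the two
wobble-equivalent substitutions honored (site `C` ~ mRNA `U`, site `A` ~
mRNA `G`, i.e. antisense G:U and U:G). Whether a wobble *counts* as paired
is the `wobble_as_match` switch (default `TRUE`, reflecting the finding
that RISC treats G:U like a Watson-Crick pair). Pairing statistics —
`paired_positions` and `longest_contiguous_run` — are reported over the
19-nt duplex core so the "17 of 19" denominator is well defined for any
strand length.

## The classifier

`classify_alignment()` applies two threshold rules, which may co-occur:

* **near_exact** — `paired_positions ≥ 17` (of the 19-nt core);
* **partial** — `longest_contiguous_run ≥ 11` or `paired_positions ≥ 15`.

Under the defaults near-exact implies partial (17 ≥ 15); the test suite
asserts this as a consequence rather than hard-coding it.

`classify_mirna_like()` is positional, not alignment-based: a seed site
qualifies if the seed is perfectly paired, or if it carries **exactly
one** seed mismatch while antisense positions 13–19 (the 3'-compensatory
region) are perfectly paired. "Exactly one" is deliberate — zero
mismatches is already covered by the first clause, so the two clauses
partition cleanly. The compensatory region is described in the sources in
sense-strand numbering; it is mapped to antisense 13–19 of the core under
the fixed numbering above and remains configurable. miRNA-like sites are
restricted to the 3'UTR by default (`require_utr3_for_mirna_like`),
matching canonical miRNA biology; whole-transcript mode is available
because seed complementarity anywhere in a transcript has also been
associated with off-targeting.

`cleavage_competent()` demands pairing (wobble included, scheme
permitting) across antisense positions 8–10, opposite the mRNA cleavage
site.

Seed G/C content is reported with every record but never used as a
filter: high seed G/C is a documented off-target correlate with no
accepted threshold.

### Search variants

`call_offtargets()` and the pipeline expose the three search variants as
an explicit user choice (never auto-selected): `full_sw` aligns the
duplex against whole transcripts (guarded by `max_full_sw_targets`,
default 200 — a runtime guardrail, not semantics), `seed_window_sw`
aligns only the ~50-nt windows, and `mirna_like` applies the positional
rules to exact and single-mismatch seed sites. The default `all` combines
the windowed alignment with the miRNA-like rules. Windowed calls are
provably a subset of full-alignment calls (a window restriction can only
remove evidence), which the suite checks on fixtures.

One behaviour worth knowing: with wobble counted as match, a random
background window around a genuine seed site reaches the 15-paired
partial threshold reasonably often — gapped local alignment accumulates
scattered pairs cheaply. That is a property of the published thresholds
under a permissive scheme, not an implementation artifact; the fixture
generator (below) controls for it exactly.

## Conservation filtering

Conserved intervals are consumed pre-computed, in transcript coordinates,
as a BED-like 3-column table (0-based half-open — stated explicitly since
BED dialects vary); deriving them from a 46-way genomic alignment is out
of scope and happens upstream under the caller's species definition (the
default label records the human/chimp/mouse/rat/dog set). Intervals merge
when overlapping or adjacent, and only merged intervals of length ≥ 8 are
retained. A seed site counts as conserved only when **fully contained**
in a retained interval — containment is the strictest deterministic
reading of "conserved at the orthologous location", whereas any
overlap-based rule would make a site's status depend on how much flank an
upstream pipeline happened to keep. `filter_conserved()` restricts
miRNA-like support to conserved sites and drops records left with no
category; near-exact/partial evidence is untouched, since conservation is
a seed-site notion.

## Validation

An expression-change table (accession, log-ratio, p-value; one row per
transcript) defines the truth set: transcripts with a *negative* change
at `p < alpha` (default 0.01, an upper bound — one source caption prints
the inequality the other way; the body text wins) count as true
off-targets. No multiple-testing correction is applied, matching the raw
threshold used in the transfection studies this emulates.
`validation_report()` reports, per siRNA and pooled: the pooled rate over
(siRNA, transcript) prediction pairs is primary; the mean of per-siRNA
rates and a unique-transcript pooled view are emitted alongside because
either denominator convention is defensible and the sources do not say
which they used. siRNAs with predictions but no table are reported as
missing rather than silently dropped.

## The fixture generator

Everything above is testable offline because `generate_transcriptome()`
plants sites of known classes into random backgrounds and returns an
exhaustive manifest:

| class | construction | detected by |
|---|---|---|
| `near_exact` | exact 19-nt core partner | windowed/full alignment (19/19) |
| `partial_contiguous11` | partners of antisense 9–19 only | full alignment (run 11, no seed) |
| `partial_total15` | partners of 1–7 and 9–16; 8, 17–19 non-pairing | full alignment (15 paired, run 8) |
| `m8_seed` | exact 7-mer motif in the 3'UTR | seed scan + miRNA-like rule 1 |
| `compensatory` | one seed mismatch (position 5), 9–12 non-pairing, 13–19 perfect | near-miss scan + rule 2 |
| `decoy_nonconserved` | as `m8_seed`, never covered by the conservation track | miRNA-like; removed by the filter |

Backgrounds are rejection-sampled: a candidate transcript is accepted
only when, for every library siRNA, the exact-motif occurrences and the
default classifier's calls match the manifest exactly. Rejection (rather
than post-hoc masking) makes false-positive counts in tests zero *by
construction* — including the chance background `partial` calls noted
above. Mutated positions use bases that neither Watson-Crick- nor
wobble-pair the guide, so planted pairing statistics are exact under
either wobble setting. The generated library is itself rejection-sampled
so no two siRNAs share a seed motif and no motif occurs inside another
siRNA's expected site, keeping every planted site attributable to exactly
one siRNA.

Each generator reseeds its own RNG stream (`rng_seed` plus a fixed
documented offset), so outputs are byte-identical across runs and adding
one generator never shifts another's draws. Defaults — 14 transcripts of
400–600 nt, 40% 3'UTR, one planted site per transcript across the six
classes, a 3-siRNA library, 65% planted true-positive rate, ~30%
background conservation coverage — are fixed study conditions, not tuning
knobs: transcript lengths and library sizes are desk-scale stand-ins for
a transcriptome, and 65% is the true-positive rate the validation layer
is expected to recover. In the generated expression tables, predictions
that lose the truth coin are rejection-sampled off the truth criterion,
so the planted rate is exact ground truth; only non-predicted universe
rows follow an unconditioned null.

What the generator does **not** emulate: realistic base composition,
codon structure, repeats, UTR length distributions, expression
measurement error correlated with sequence, or pooled-siRNA effects.
Passing on fixtures therefore demonstrates algorithmic correctness —
recovery of exactly the planted signal — not predictive accuracy on real
transcriptomes.

## The SeedSeq dialect

Records are GenBank-like: LOCUS, DEFINITION (pipe-joined `key=value`
metadata preserved verbatim, with a parsed view), ACCESSION, FEATURES
with `target_siRNAs` entries, a BASE COUNT line always recomputed from
the sequence, and an ORIGIN block (60 residues/line in 10-residue groups,
1-based position labels). The reader is tolerant — missing FEATURES,
missing terminal `//`, ORIGIN case and spacing variations, `#` comment
lines — because the reference record this dialect derives from lacks both
FEATURES and the terminator; the writer always emits the full layout,
lowercase ORIGIN by default (the GenBank convention; comparisons are
case-insensitive). The qualifier vocabulary (`sirna_id`, `supplier`,
`categories`, `seed_occurrences`) is fixed by this package and versioned
in the file header comment. A BASE COUNT line that disagrees with the
sequence is a warning, or an error in strict mode. Full GenBank feature
grammar (joins, remote accessions) and the EMBL/DDBJ dialects are out of
scope.

## Worked example

```{r example}
lib <- mirna_matched_sirnas()
s <- lib[[1]]
extract_seed(s)
seed_site_motif(s)

t <- transcript("NM_DEMO",
                paste0(strrep("GA", 20), seed_site_motif(s),
                       strrep("CU", 20)),
                gene_symbol = "DEMO", utr3_start = 30L)
recs <- call_offtargets(s, list(t))
offtarget_table(recs)

cat(substr(write_seedseq(annotate_transcript(t, recs)), 1, 400))
```

## Known limitations

* Pure-R dynamic programming: fine for windows and desk-scale
  transcriptomes, not for genome-scale full alignment (hence the
  `full_sw` guardrail).
* No thermodynamics: duplex stability, target-site accessibility and
  chemical modifications are not modeled.
* No quantitative knock-down prediction; categories are rule-based calls.
* Conservation input is taken at face value; the package does not verify
  the species set or alignment quality behind it.
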