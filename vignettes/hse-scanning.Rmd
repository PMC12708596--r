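---
title: "Scanning promoters for heat shock elements: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoters for heat shock elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsescan)
```

## The element model

Heat shock factors (HSFs) activate heat-responsive transcription by
binding heat shock elements (HSEs) in promoter DNA. An HSE is an array
of tandemly alternating 5-bp units of the form nGAAn, where the two
flanking `n` positions are unconstrained and the 3-bp core reads GAA on
one strand or, for the head-to-head unit, its reverse complement TTC.
`hsescan` models an element as a tiling of 2 or 3 such units with
strictly alternating core orientation:

* **canonical** — three perfect units (`nGAAnnTTCnnGAAn` or
  `nTTCnnGAAnnTTCn`), 15 bp;
* **minimal_perfect** — two perfect units (`nGAAnnTTCn` or
  `nTTCnnGAAn`), 10 bp, generally regarded as partially functional;
* **imperfect_triple** / **imperfect_minimal** — 3- or 2-unit arrays
  carrying bounded degeneracy: core substitutions and/or extra bases
  inserted between adjacent units.

Functional HSEs tolerate considerable sequence degeneracy, which is why
a bounded-mismatch, bounded-insertion search is used rather than exact
pattern matching. A match records its 0-based half-open span, the
orientation of each unit, which core positions are substituted, how many
bases sit in each inter-unit gap, its class, its distance to the
transcription start site (TSS), and its rank.

## Scan parameters

A search is defined by an `scan_params()` envelope:

| parameter           | meaning                                   | preset defaults |
|---------------------|-------------------------------------------|-----------------|
| `n_units`           | pentamer units required (2 or 3)          | 3 or 2          |
| `max_subs_total`    | summed core substitutions over all units  | 2 (triple), 1 (minimal), 0 (perfect) |
| `max_ins_per_gap`   | extra bases allowed in one gap            | 2 (imperfect), 0 (perfect) |
| `max_ins_total`     | summed extra bases over all gaps          | 2 (imperfect), 0 (perfect) |
| `max_subs_per_unit` | optional per-unit substitution cap        | 3 (unconstrained) |

The substitution budget is interpreted as a **total across all unit
cores** of one match; this reading reproduces the four class presets
most parsimoniously, and a per-unit cap is exposed separately for users
who prefer the stricter reading. The insertion budget is capped both
per gap and in total (both default to 2), which keeps default match
lengths within `5 * n_units + 2`. The imperfect presets allow up to two
substitutions for triple repeats but only one for minimal repeats —
two substitutions in a 6-bp core territory would leave little of the
minimal element's information content — and both budgets remain
configurable.

Two further modelling decisions matter in practice:

* **N handling.** `N` never satisfies a core position (it counts as a
  substitution there) but is freely accepted at wildcard and gap
  positions. This is deliberately conservative: an uncalled base is
  never evidence for a core.
* **Sense-strand-only scanning.** The motif family is closed under
  reverse complement (the reverse complement of `nGAAnnTTCnnGAAn` is
  `nTTCnnGAAnnTTCn`), so scanning one strand already finds every
  element; scanning both would double-count. A property test checks the
  mirror symmetry explicitly.

## Duplicate alignments and canonicalization

With insertions allowed, one genomic span can often be explained by
several gap placements (and occasionally by different substitution
sets). All distinct spans are reported — including overlapping ones,
since dense promoters genuinely contain overlapping degenerate elements
— but alignments identical in (start, end, orientation sequence) are
collapsed to a single canonical alignment: minimal total substitutions,
then the lexicographically smallest gap-insertion vector. The
tie-break is arbitrary but fixed, which is what matters for
reproducibility and for the oracle-equivalence testing described below.
An optional left-to-right maximal non-overlapping post-filter
(`filter_nonoverlapping()`) is available for users who want one call
per locus.

## TSS distance and the proximal window

Each match is annotated with `tss - end`: the number of bases between
its last base and the first transcribed base (0 when the element abuts
the TSS, negative when it extends past it — records may contain
transcribed sequence). A match counts as "within 100 bp of the TSS"
only when it is **entirely contained** in the 100-bp window upstream of
the TSS; partial overlap does not count. The TSS itself is
caller-supplied through a sidecar table because promoter fragments are
annotated upstream of this package; when no annotation is given the TSS
defaults to the sequence end, the correct choice for pure upstream
fragments.

## Ranking

Detected elements are ranked by predicted functionality, best first:

1. fewer total core substitutions;
2. fewer substitutions at core position 1 (the G of GAA / first T of
   TTC);
3. fewer inter-unit insertions;
4. smaller absolute TSS distance;
5. start position (then end, then orientation) as a deterministic
   tie-break, so ranks are always the permutation `1..n`.

Component 2 operationalizes the "type" of a substitution: position-1
substitutions disrupt the most conserved contact of the HSF binding
site, so they are taken as more damaging than positions 2–3. No
experimentally calibrated hierarchy exists for this choice, so the key
composition is a documented knob (`key` argument of `rank_matches()`,
`rank_key` in the CLI config) rather than hard-coded ground truth.
Ranking is ordinal only; the package deliberately does not invent a
combined numeric functionality score.

## Class summaries

`summarize_hse()` pools per-preset match sets for one promoter,
collapses alignments found under more than one envelope (a perfect
element found again under a wider imperfect envelope is counted once,
as perfect), and tallies matches by class. The reported `union_total`
is the **plain sum of the four class counts**, with no cross-class
span deduplication — overlapping elements of different classes are
genuine distinct binding configurations — and a separate
`dedup_span_total` (distinct spans) is reported alongside for users who
want the collapsed view.

## The synthetic benchmark

`generate_benchmark()` produces seeded, fully reproducible test data:
i.i.d. random backgrounds with controlled GC content (defaults: 300-bp
records, GC 0.5, typical of the AT-rich upstream regions the scanner
targets) into which concrete HSE instances of a requested class mix are
planted at known positions. Planting overwrites the 5-per-unit
footprint bases (wildcards keep the background base) and inserts the
planned gap bases, so record length grows only by the internal
insertions and planted coordinates remain exact. Placements are
non-overlapping with a small margin, and every record is audited with
the brute-force oracle before acceptance: the canonical alignment at
each planted span must reproduce the planted substitution and insertion
accounting exactly, and records where random context would alias a plan
to a cheaper alignment are redrawn. `sample_background()` can also
rejection-sample backgrounds that are provably free of matches under a
given envelope, with an attempt cap.

What the simulation does **not** emulate: real promoter base
composition beyond mononucleotide GC content (no dinucleotide
structure, no CpG/TATA context), chromatin or nucleosome context,
cooperative HSF binding, and the clustering of elements near the TSS.
Passing the recall and false-positive tests therefore demonstrates
algorithmic correctness of the search — not that detected elements are
functional in vivo, a gap that in-planta reporter assays repeatedly
confirm.

## The brute-force oracle

`oracle_scan()` is an independent reference implementation used in
testing: it expands the whole envelope into explicit degenerate
templates — every combination of first-unit orientation, substitution
placement within budget, and gap-insertion vector — and slides each
template over the sequence with the regex engine (overlapping hits via
a zero-width lookahead). A substituted core position becomes a negated
character class (any base but the consensus, `N` included), which keeps
the template count at the closed form `2 x placements x insertion
vectors` (2 templates for the canonical preset, 2 for the perfect
minimal) and makes the oracle's N semantics agree with the scanner's.
The two paths share no matching code: the scanner counts mismatches
arithmetically over precomputed per-position flags, the oracle delegates
to the regex engine. A template-count cap (default 1e6) guards against
combinatorial blow-up for widened envelopes.

## Validation suite and problem sizes

The package's own account of correctness rests on computed properties,
each fixed-seed and re-run by the test suite:

* **oracle equivalence** — 100 random 300-bp promoters x the full
  envelope sweep (2–3 units, 0–2 substitutions, insertion caps 0–2):
  scanner and oracle return identical match sets;
* **planted recall** — 50 records x 4 planted truths covering all four
  classes: 100% recovered with exact span and accounting;
* **structural identities** — `end - start = 5 * n_units +
  insertions_total` on every match; canonical matches are 15 bp,
  perfect minimal 10 bp; `union_total` equals the sum of the class
  counts;
* **reverse-complement symmetry** — 50 sequences, mirrored spans and
  equal counts;
* **monotonicity** — widening any budget never loses a matched span;
* **determinism** — simulate → scan → summarize is byte-identical
  across reruns with the same seed.

These sizes were chosen to exercise every envelope combination and both
orientation phases at realistic promoter lengths while keeping the
whole suite fast enough to run routinely. `scripts/acceptance.R`
recomputes the same quantities from scratch against the installed
package.

## A worked example

```{r example}
fa <- tempfile(fileext = ".fasta")
writeLines(c(">prom1", paste0(strrep("C", 30), "AGAACATTCGAGAAT",
                              strrep("T", 25), "AGAACGTTCG")), fa)
promoters <- read_promoters(fa)
matches <- scan_promoters(promoters)
matches <- rank_matches(matches)
matches[, c("start", "end", "class", "substitutions_total",
            "insertions_total", "distance_to_tss", "rank")]
summarize_promoters(promoters)
```

## Known limitations

* No position-weight-matrix or HSF-affinity scoring; classification and
  ranking are combinatorial.
* Only head-to-head alternating arrays are modelled (the canonical
  configuration); same-orientation repeat variants are out of scope.
* IUPAC ambiguity codes other than `N` are rejected at input.
* The oracle is intentionally slow and is not meant for genome-scale
  scanning; the scanner itself is comfortable at promoter scale
  (kilobases), not chromosome scale.
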