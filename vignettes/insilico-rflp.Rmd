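---
title: "In silico PCR-RFLP: models, parameters and design choices"
author: "rflpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR-RFLP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpkit)
```

## The problem

PCR-RFLP assays identify species from the band pattern a restriction
digest of a marker amplicon leaves on an agarose gel. The motivating
application is tick surveillance: the invasive Asian longhorned tick
*Haemaphysalis longicornis* must be told apart from the native North
American *H. leporispalustris*, *H. juxtakochi* and *H. chordeilis*, whose
morphological identification fails when mouthparts are damaged. A 438 bp
16S rRNA amplicon digested with DraI (TTT^AAA), and a ~690 bp COI amplicon
digested with AluI (AG^CT), give species-diagnostic fragment patterns that
can be read from a 4% agarose gel in an afternoon, far cheaper than
sequencing.

rflpkit models every dry-lab step of designing and applying such an assay:
locating degenerate primer binding sites, extracting amplicons, simulating
digestion, converting fragments to gel-visible bands, grouping patterns
per species, screening candidate enzymes, and building and applying
dichotomous fragment-size keys.

## Degenerate matching semantics

All matching reduces to IUPAC base-set comparisons, in two modes:

* **strict** — a template symbol matches a pattern symbol only if the
  template's base set is a *subset* of the pattern's. A hit is then
  guaranteed whatever the true base under the ambiguity code.
* **permissive** — the two sets merely intersect; a hit is possible but
  not guaranteed.

Strict matching is the default for both primer binding and restriction
sites. The rationale is reproducibility: an in-silico digest should only
report cuts that every molecule consistent with the recorded sequence
would actually receive. Permissive mode is exposed for exploratory
screening, and its cut set is always a superset of the strict one.

## In silico PCR

`findPrimerMatches()` scans every offset of the template and counts
strict mismatches. `amplify()` pairs plus-strand forward-primer hits with
minus-strand reverse-primer hits; both template orientations are
considered, so a template and its reverse complement give identical
product lengths. Defaults:

* `maxMismatch = 2` whole-primer mismatches. Published tick surveys
  amplify across genera with these primers, so some tolerance is needed;
  two mismatches in an 18--26 nt primer is a conventional in-silico PCR
  stringency.
* `anchor3 = 3`: the three 3'-terminal primer positions must match
  exactly. Polymerase extension is far more sensitive to 3' mispairing
  than to internal mismatches, and the anchor suppresses most spurious
  hits that the mismatch budget would otherwise admit.
* `maxProduct = 2000` bp suppresses pairings between distant chance hits;
  all real products here are under 900 bp.
* Products retain both primer-binding regions, because the wet protocol
  digests PCR products untrimmed. `trimPrimers = TRUE` removes them for
  comparison against deposited sequences that lack primer regions.

Coordinates are 0-based half-open on the plus strand. On circular
templates (whole mitochondrial genomes) origin-spanning products report
`end` past the template length, interpreted modulo length. A primer pair
that finds no valid pairing returns an empty list rather than an error:
failed amplification is an observed outcome of the assay, not a bug --
several *Haemaphysalis* species fail to amplify with any of the three COI
primer sets.

## Digestion and the gel model

`digestLinear()` uses a blunt, single-coordinate cut model: a top-strand
site occurrence at position *i* cuts at *i* + offset; occurrences of the
reverse-complement site (relevant for non-palindromic enzymes) cut at
*i* + |site| − offset. Overhang geometry is deliberately ignored because
only fragment *lengths* are observable on an agarose gel. Fragment lengths
always sum to the molecule length; cuts falling exactly on a molecule end
are dropped as they produce no new boundary.

`toVisibleBands()` applies the gel resolution model
(`gelModel()`):

* `minVisible = 40` bp -- shorter fragments diffuse or run off a 4% gel
  and are not scored.
* `coMigrationTol = 5` bp -- fragments within 5 bp co-migrate. Merging is
  single-linkage (chains merge transitively, as they do visually on a
  gel), and a merged band is reported at the rounded mean of its members,
  since the gel shows one indistinguishable band.

The source assay read patterns visually from 4% agarose and published no
numeric tolerances, so both knobs are package choices emulating that gel
percentage; both are recorded in every catalog and key and can be
overridden everywhere they matter.

Because tolerance-based equality of band patterns is *not transitive*,
`groupPatterns()` uses leader clustering in input order: a digest joins
the first cataloged pattern it equals under `patternsEqual()`, else founds
a new pattern. File order therefore defines the catalog deterministically;
the representative of each pattern is its first member. At tolerance 0 and
`minVisible = 1` this reduces to exact partitioning by fragment multiset.

## Enzyme screening

`screenEnzymes()` formalizes "screen commercial enzymes for candidates":
a species pair is *separated* by an enzyme when no cataloged pattern of
one species equals any pattern of the other, and the score is the fraction
of pairs separated. Intra-species pattern multiplicity is a secondary
penalty rather than a disqualifier -- assays tolerate several patterns per
species so long as none collides with another species. Remaining ties
break toward fewer total cuts (simpler gels) and then name, making the
ranking deterministic.

## Key construction

`buildKey()` grows a binary decision tree by greedy splitting and prints
it as numbered couplets (breadth-first, with back-references, the layout
of printed taxonomic keys). Candidate features at each node:

1. band-count thresholds at each observed count;
2. *n*-th largest band size thresholds at midpoints of adjacent observed
   values whose gap exceeds twice the co-migration tolerance -- the
   midpoint then keeps at least a full tolerance of safety margin on both
   sides;
3. presence of a band near each observed size (tolerance = gel tolerance).

The feature maximizing the minimum branch size wins; ties prefer
band-count features (cheapest to read on a gel), then smaller rank, then
larger margin. Construction fails loudly with `IndistinguishableSpecies`
when two species share a pattern, as no fragment-size key can separate
them -- exactly the situation of *H. longicornis* and *H. asiatica* under
the 16S/DraI assay, where a second marker is required.

Feature semantics worth stating explicitly:

* "approximately X bp" means |band − X| ≤ co-migration tolerance;
* "top band" / "middle band" are ranks 1 and 2 of the visible bands
  sorted descending -- consistent with three-band patterns; for larger
  patterns "middle" always means rank 2 here, which is stated rather than
  assumed;
* a pattern lacking the band at a feature's rank fails `>`/`<`/`≈`
  statements, while the complementary "at most" lead of a generated
  couplet holds vacuously, keeping generated couplets exhaustive;
* in applied keys, a band within tolerance of a strict size threshold
  adds an ambiguity warning to the trace, since that comparison is within
  gel reading error.

The bundled `naKey16S()` is the printed five-couplet key to North American
*Haemaphysalis* under DraI digestion of the 16S amplicon, shipped as a
plain-text file in the canonical machine format (`parseKey()`/
`formatKey()` round-trip it byte-stably). Its couplet 3 covers two-band
patterns with largest band > 400 bp or < 300 bp only; a largest band
between 300 and 400 bp is returned as `undetermined` rather than forcing a
species, preserving the printed key's behaviour. Likewise couplet 1
covers "more than two" and "exactly two" bands, so single-band patterns
stop there as `undetermined`.

## The synthetic-data generator

`simulateAmplicons()` is the package's ground-truth instrument, standing
in for curated GenBank sequence sets. For each species and planted
fragment pattern it builds a master amplicon: the forward primer's
concrete sequence at the 5' end, the reverse complement of the reverse
primer at the 3' end, a concrete recognition-site instance at every
planted cut, and random background elsewhere, with rejection sampling
purging chance recognition sites so the planted fragments are exact
truth. Defaults mirror the 16S assay geometry: 438 bp amplicons, the 16S
primer pair, DraI. Per-sequence variation is then injected outside the
protected windows (primers and planted sites), either as a per-site
substitution rate, as a bounded per-sequence mutation count
(`maxMutations`), or as indels. With `sharedBackground = TRUE` all
species share one background and differ *only* at planted sites -- the
right fixture for enzyme screening, since otherwise unrelated random
backgrounds let every enzyme separate the species trivially.

What the simulator does *not* emulate: phylogenetic covariance between
sequences, compositional bias of mitochondrial DNA, length variation of
real 16S amplicons, and sequencing error. Passing tests on simulated data
therefore demonstrate the correctness of the machinery (site finding,
digestion arithmetic, grouping, key logic), not the field performance of
any particular assay on real populations.

## Numerical and degenerate-input choices

* Merged band size = `round()` of the member mean (R's banker's rounding;
  deterministic).
* A digest in which no fragment reaches `minVisible` raises
  `EmptyPattern` rather than returning an empty pattern.
* Duplicate FASTA ids, non-IUPAC characters (with record and position),
  empty inputs, enzyme/region mismatches in pattern comparisons, cyclic
  or dangling key files, and infeasible simulator geometries all raise
  classed errors (`AlphabetError`, `IncomparablePatterns`,
  `KeyParseError`, `InfeasibleConfig`, ...), so callers can react
  specifically.
* All simulator randomness flows from a single integer seed; the same
  seed reproduces a dataset byte for byte.

## Validation scale

The test suite and `scripts/acceptance.R` exercise the package at desk
scale, chosen to finish in minutes on one CPU while still being
statistically meaningful: digestion is checked against an independent
regex re-scan oracle on 1000 random 500 nt molecules across seven
enzymes; noise-free pattern recovery on 50 random planted configurations;
enzyme screening on 100 seeded two-species datasets of 20 sequences per
species with up to two mutations each (the planted enzyme must rank first
in at least 95); and key self-consistency on 200 random catalogs.
Published full-catalog figures (for example, 41 distinct 16S patterns
across 309 sequences) depend on GenBank sequence sets that are not
enumerated anywhere and so cannot be recomputed offline; they are out of
scope here.

## Limitations

* Methylation sensitivity, star activity and partial digestion are not
  modeled; digests are complete and exact.
* Band intensity (fragment stoichiometry) is not rendered; two co-migrating
  fragments look like one band of ordinary intensity.
* Keys are strict decision trees over band features; there is no
  probabilistic or partial-match classification.
* Double digests (enzyme combinations) are not searched by
  `screenEnzymes()`.
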