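---
title: "Typing tephritid fruit flies by mitochondrial intergenic spacer length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing tephritid fruit flies by mitochondrial intergenic spacer length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igstyper)
```

## The marker and the model

Five tephritid fruit flies drive phytosanitary decisions for South African
fruit exports: *Ceratitis capitata*, *C. cosyra*, *C. rosa*, *C. quilicii*
and *Bactrocera dorsalis*. Adults key out morphologically; larvae and
damaged specimens often do not, and COI barcoding cannot separate the
cryptic FARQ complex (*C. fasciventris*, *C. anonae*, *C. rosa*,
*C. quilicii*). Mitochondrial intergenic spacers evolve faster than the
coding genes around them, and in these flies the spacer between tRNA-Ile
and tRNA-Gln ("intergenic region I", IGS-I) turns out to carry a clean
species-diagnostic *length* signal.

A single primer pair, Mito_F/R, anchored inside the conserved tRNAs,
amplifies across the tRNA-Ile — tRNA-Met block. The amplicon decomposes
as

```
  [ partial tRNA-Ile, 56 bp | IGS-I | tRNA-Gln, 69 bp | IGS-II | partial tRNA-Met, 29 bp ]
```

so its total length is `154 + |IGS-I| + |IGS-II|`. The IGS-I length
signature is:

| species | IGS-I (bp) | IGS-II (bp) |
|---|---|---|
| *C. capitata* | 40 | not windowed |
| *C. cosyra* | 2 | not windowed |
| *C. quilicii* | 62–64 | 16–18 |
| *C. rosa* | 34 | 18–22 |
| *B. dorsalis* | 0 (absent) | not windowed |

IGS-II is recorded only for the rosa/quilicii pair, and its two windows
overlap at 18 bp — which is precisely why IGS-II cannot separate those two
species and why the classifier treats it as corroborating evidence only.

The pipeline is: **in-silico PCR** (locate primer sites, extract the
product) → **dissection** (semi-global anchor alignment of the three tRNA
segments, exact spacer extraction) → **length call** against the signature
table, with an identity fallback and confounder caveats.

## Parameters that matter

* **Matching tolerance, 1 bp** (`default_signature_table()`). The raw
  IGS-I windows are pairwise disjoint. A 1 bp symmetric tolerance absorbs
  the single-indel sequencing errors that dominate Sanger-style noise, at
  one arithmetic cost: the expanded *B. dorsalis* window [0, 1] and
  *C. cosyra* window [1, 3] share the length 1. An observed IGS-I of
  exactly 1 bp is therefore reported `ambiguous` with both candidates —
  the honest reading of the arithmetic, since no species exhibits that
  length and it can only arise from an error. At tolerance 0 all windows
  are disjoint; at tolerance ≥ 3 the capitata/rosa windows begin to close
  in on each other (they merge at 15). `validate_signature_table()`
  reports these overlaps as data.
* **Primer-site search: max 3 mismatches, clean 3' end** (last 5 primer
  bases must match exactly). Polymerase extension is launched from the 3'
  end, so 3' mismatches are what actually kill a PCR; no published
  mismatch tolerance exists for this assay, and 3/25 with a clean 3' end
  is the conventional conservative choice. Matching is IUPAC
  set-intersection on both strands; circular templates are scanned across
  the origin via the doubled sequence.
* **Anchor alignment: match +1, mismatch −1, gap open −2, gap extend −1;
  per-anchor identity floor 0.80.** tRNAs are conserved; random AT-rich
  sequence aligned semi-globally against a 56–69 bp anchor rarely exceeds
  ~0.6 identity, while a 1 % error rate costs ~0.01–0.02, so 0.80 cleanly
  separates anchor from background.
* **Identity fallback: floor 90 %, margin 2.0 points.** Used only when
  the length pipeline fails and a reference panel is present. The
  interspecific amplicon identities in this group sit around 84 % for the
  closest cryptic pair, against ~100 % within species, so a 90 % floor
  plus a 2-point nearest-neighbour margin can rescue a genuine amplicon
  with a corrupted anchor but can never promote a random or
  foreign sequence: the floor is what guarantees "never unambiguous on
  junk", which a margin alone cannot between highly correlated
  references.

## What the simulator emulates — and what it does not

`make_amplicon()` reproduces the amplicon architecture exactly: fixed
per-genus tRNA stand-in segments (56/69/29 bp; one Ceratitis set, one
Bactrocera set, ≥ 85 % mutually identical, both carrying the real primer
footprints at the termini), spacer lengths drawn uniformly from the
species' windows, spacer content drawn i.i.d. AT-rich (default AT
fraction 0.77, the tephritid mitogenome composition; the real genomes
span ~73.6–77.4 %). `make_genome()` embeds one amplicon in a circular
AT-rich filler guaranteed free of secondary primer sites, at a seeded
rotation. `apply_noise()` adds per-base substitutions and indels with a
full edit log. IGS-II lengths for the three species without a recorded
window are simulator constants (capitata 19, cosyra 19, dorsalis 62 — the
last forced by the 216 bp product arithmetic), not biological claims.

Deliberately **not** emulated: real tRNA sequences (real-mode dissection
takes its references from the input annotation instead), intraspecific
spacer *sequence* variants, chromatogram artefacts, quality scores, PCR
chimeras. Two consequences matter for interpreting green tests. First,
synthetic amplicons of the same species share anchors but not spacer
content, so same-species whole-amplicon identities are ~85–90 % in
synthetic mode where real resequenced specimens would sit near 100 %;
the identity fallback is therefore *more* conservative on simulator
output than on real data. Second, passing round-trip tests demonstrate
the machinery (site finding, anchoring, extraction, calling), not the
biological claim that field specimens always match the printed windows —
that claim rests on the original survey, and the real-data check
(annotated mitogenome in, printed IGS-I length out) requires the
deposited accessions, which must be supplied by the user as downloaded
flat files.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GenBank/IRanges
  convention), including anchor intervals and primer-site reports.
* Anchoring order: Ile is aligned first and pinned to position 1; Met is
  aligned and pinned to the amplicon end; Gln is aligned only within the
  remaining interior. This removes placement ambiguity when a spacer is
  short or absent (B. dorsalis has no IGS-I at all: the Gln anchor abuts
  the Ile segment directly).
* Equal-score Gln placements resolve to the alignment engine's single
  deterministic optimum (leftmost in the constructible degenerate cases).
* Zero-length spacers are empty strings with length 0, not missing
  values; length conservation `L = 154 + |IGS-I| + |IGS-II|` holds
  exactly for every dissected zero-noise amplicon.
* Orientation is auto-detected by dissecting both strands and keeping the
  higher total anchor score, so reverse-complemented input classifies
  identically.
* Multiple PCR products are returned flagged with a warning, not raised
  as an error: a multi-band result is evidence about the template.
  A missing pairing raises a typed `no_product_error`.
* All randomness flows from explicit integer seeds; one user seed fans
  out to per-operation seeds through a fixed integer map, so any run is
  reproduced byte-for-byte by (config, seed).

## Problem sizes

The bundled analyses and tests run on deliberately small instances chosen
to exercise every code path: 50-amplicon zero-noise panels, 200-amplicon
noise experiments (1 % substitutions, 0.2 % insertions, 0.2 % deletions),
50 random templates up to 5 kb for the brute-force site-search
cross-check, and 1.6–16 kb toy genomes. These sizes are orders of
magnitude above the decision boundaries involved (windows 0–64 bp) while
keeping the full suite under a minute.

## Known limitations

* Spacer-length windows are taken from the published survey; taxa outside
  the five study species are represented only as confounder caveats. The
  JSON signature schema is the extension point.
* tRNA boundary conventions differ between annotation pipelines by
  ±1–2 bp; real-data spacer lengths inherit whatever convention the input
  annotation used. The 1 bp tolerance absorbs part of this, not all.
* The confounder identities stored in the table are the published
  BLASTn values and are metadata only; this package's
  `percent_identity()` (global alignment, gaps in the denominator) will
  not reproduce them bit-exactly and is never asked to.
* HRM melt-curve analysis and COI barcoding are out of scope; the former
  was reported unsuccessful for this amplicon, the latter is the baseline
  this marker improves upon.

## A worked example

```{r example}
a <- make_amplicon("Ceratitis quilicii", rng_seed = 9)
nchar(a$sequence)
cl <- classify(a)
cl
```

The call is unambiguous on the IGS-I length alone; the attached caveats
record that public-database searches of this amplicon also hit
*C. fasciventris* (100 %) and *C. anonae* (97.78 %) — taxa absent from
South Africa, reported but never used to reject a call.
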