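---
title: "Designing premature-stop sgRNAs for cytosine base editors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing premature-stop sgRNAs for cytosine base editors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbei)
```

## The editing model

A cytosine base editor (CBE) is a catalytically impaired Cas protein fused
to a cytidine deaminase. Guided by an sgRNA to a protospacer with a valid
protospacer-adjacent motif (PAM), it deaminates cytosines within a
positional *editing window* of the protospacer; replication then fixes the
lesion as a C-to-T transition on the edited strand. On a coding sequence
this chemistry can create a premature stop codon in two ways:

* a **sense-strand** spacer exposes CDS cytosines: `CAA -> TAA`,
  `CAG -> TAG`, `CGA -> TGA`;
* an **antisense-strand** spacer exposes the cytosines pairing sense-strand
  guanines, so the sense codon experiences G-to-A: `TGG -> TAG / TGA / TAA`.

`cbei` does not hard-code these four codons. `find_cbei_sites()` simulates
every nonempty subset of in-window, strand-consistent edits inside each
codon and asks the active genetic code whether a stop appears. Under the
standard code the qualifying set comes out as exactly
`{CAA, CAG, CGA, TGG}` — the test suite asserts this as an emergent
property — and under non-standard codes (25 NCBI tables are shipped) the
set is whatever the simulation yields. Edits on the two strands are never
mixed within one site, because one spacer exposes one strand.

A site is reported once per *(placement, edited codon)* pair: a single
spacer that can disrupt two codons yields two rows, since downstream
filtering is per codon and context. `edit_positions` records the *minimal*
qualifying edit subset — fewest edited bases, ties broken by the 5'-most
window position on the spacer strand. Bystander in-window cytosines may of
course also be edited by a real CBE; minimality is a reporting convention,
not an efficiency claim.

## Coordinates, windows, and the search region

Internally all coordinates are 0-based half-open; every user-facing table
is 1-based inclusive, matching the convention biologists use. Editing
window positions are counted from the 5' end of the protospacer as written
5'→3': position 1 is PAM-distal for Cas9-family (3'-PAM) editors and
PAM-proximal for Cas12a (5'-PAM). This is the numbering in which "only
position 6 is editable" describes YEE-BE3, and it applies uniformly to
both PAM sides.

The *search region* ("top N% of the CDS body", default 50%) restricts how
deep into the CDS the premature stop may fall: a truncation near the C
terminus often fails to inactivate. Nothing in the window or PAM anchors
this filter; we anchor it at the **first base of the edited codon**,
because the stop position — not the spacer position — determines the
truncation point. A codon starting at base 31 of a 60-nt CDS (fraction
0.517) is therefore outside the 50% region even though its spacer begins
earlier.

Other conventions, chosen once and kept:

* A codon qualifies only if the stop-creating C itself is inside the
  window; codons straddling the window edge do not qualify through
  out-of-window edits.
* An edit that recreates a stop at the final codon index is not premature
  and is not reported.
* Candidate placements containing `N` anywhere in protospacer or PAM are
  skipped silently — design needs unambiguous codons; `N` is expected only
  in genome-scale inputs.
* `proto_start` is always the leftmost (plus-strand) CDS coordinate of the
  protospacer span, for both strands.
* Sequence-context preference is annotated as the 5' dinucleotide of the
  stop-creating C on the edited strand, ranked `TC > CC > AC > GC` by
  default (a per-model field, so future editors can override it). A
  stop-creating C at the CDS terminus has no 5' base and is reported with
  an `NA` context rather than a guessed rank.

## Editor presets and genetic codes

Thirteen editor presets ship in `inst/extdata/cbe_presets.json`. The
distinguishing parameters that are well established — YEE-BE3's
single-position window, the NG PAMs of Target-AID-NG and xBE3, Cas12a-BE's
5' TTTV PAM, VRER-BE3's NGCG — are fixed; the remaining windows and spacer
lengths are taken from the primary literature cited per editor in the data
file. Users can override any preset or add editors via YAML/JSON configs
(`read_cbe_config()`); degenerate IUPAC letters are supported everywhere,
and a genomic `N` never satisfies any PAM letter, including pattern `N`.

The 25 genetic-code tables follow NCBI translation-table numbering (the
set used by ORFfinder) and are shipped as a JSON data file. Three NCBI
tables (27, 28, 31) list certain codons as both stop and sense
("dual-coding"); we record those codons as stops, because inactivation
design needs an unambiguous stop set. Table 1 is cross-checked against
`Biostrings::GENETIC_CODE` in the tests.

## ORF detection

`detect_orfs()` scans all six frames and reports maximal start→stop ORFs
(stop codon included in the length; 5'-most qualifying start per in-frame
stop; alternative internal starts are not enumerated). ORFs lacking a
terminating stop before the sequence end are *not* reported: the
downstream design consumes complete, bounded CDSs. Codons containing `N`
never match a start or stop. The default minimum length is 75 nt with a
supported configuration range of 24–150 nt; outside that range the
function warns, or errors in strict mode. In unattended batch runs each
input record is assumed to *be* a CDS; `validate_cds()` checks frame +1
only and warns rather than fails, so one malformed record cannot abort a
batch, and the ability denominator is never silently reduced.

## Off-target search

The off-target module implements an anchor (pigeonhole) search: a spacer
is split into `m + 1` contiguous fragments of near-equal length. If a
genomic window lies within Hamming distance `m` of the spacer, the `m`
mismatches can damage at most `m` fragments, so at least one fragment
occurs exactly — exact fragment matching is therefore a complete candidate
generator. Each candidate window is then confirmed by an exact IUPAC PAM
check on the editor's side and a full-spacer Hamming count; `mismatches
<= m` is inclusive, so exact matches are found at `m = 0`. Mismatch
counting is substitution-only (no indels), PAM mismatches are not
licensed, and genomic `N` counts as a mismatch. Seed-region weighting is
deliberately *not* applied as a filter; the mismatch count is reported so
users can impose their own seed rules.

Large genomes are processed in segments (default 50 Mb). Windows running
off a segment edge are skipped, and recovered by junction segments of
2×100 nt spanning every internal boundary; hits discovered by several
anchors, or by both a tile and a junction segment, are deduplicated by
`(spacer, contig, start, strand)`. Both parameters are configurable, and
the tests force 1-kb segments to exercise the boundary logic at desk
scale. The tests also show the pigeonhole bound is tight: for each anchor
there exists a planted site that only that anchor discovers.

## CBEI ability

For a CDS set and an editor, the *CBEI ability* at region fraction `f` is
the fraction of CDSs with at least one qualifying site whose premature
stop falls within the top `f`% of the CDS body. `run_batch()` computes
sites once per (CDS, editor) on the whole CDS; the per-region tables
(default 25/50/75%) and `ability_curve()` are filtered views of that one
computation, so region results cannot drift from the design step. The
curve is a non-decreasing step function, and an editor whose window is a
superset of another's (same PAM) dominates it pointwise — both are
asserted in the tests. Invalid CDSs are logged and *kept* in the
denominator.

## The synthetic-data generator

`make_cds()` and `make_genome()` produce the study material for the test
suite, with ground truth fixed by construction:

* CDS backgrounds are i.i.d. codons at a target GC (default 0.5, the
  neutral midpoint), stop codons rejected, `ATG` start and a terminal
  stop enforced. Plants overwrite codon-aligned cassettes so a chosen
  codon's C lands on a chosen window position next to a concrete valid
  PAM.
* For exact ability counts, an `at_head_fraction` builds CDSs whose 5'
  region contains only A/T codons: with no C or G there, no premature stop
  can be created in that region, so "exactly 3 of 10 CDSs are available in
  the top half" holds constructively, without consulting the search code.
* Genome backgrounds are scrubbed before planting: any accidental window
  within the search distance of a planted spacer next to a valid PAM is
  mutated away, so planted loci are the *only* expected hits and test
  counts are exact rather than probabilistic.
* Every generator takes a mandatory seed; identical specs give identical
  output.

What the generator does not emulate: repeats and low-complexity regions,
isochore/GC gradients along a genome, codon-usage bias, introns, and real
CDS length distributions. Passing tests therefore demonstrate algorithmic
correctness (oracle equivalence, completeness, invariants) on controlled
material — not species-level conclusions, which require the user's own CDS
FASTA (any Ensembl-style CDS file can be fed to `run_batch()` unchanged).

## Verification strategy and problem sizes

Every search algorithm is checked against an independent brute-force
oracle kept in the test helpers: a six-frame enumerate-and-walk ORF scan;
a design enumerator that tries every placement, strand and edit subset and
re-translates the edited CDS; and a naive sliding-window Hamming scan with
PAM checks. The design oracle enumerates edit subsets per codon rather
than across the whole window; edits in one codon cannot affect whether
another codon becomes a stop, so this restriction is exact while keeping
enumeration bounded for wide-window editors. Suite sizes are chosen to
finish in minutes on one CPU while covering the interesting regimes: 50
random CDSs up to 3 kb across four presets for the design oracle, 20
synthetic genomes of 10–60 kb (four mismatch budgets, both strands,
boundary-straddling plants at 1-kb segmentation) for the off-target
oracle, and 20 random 10–50 kb sequences for the ORF oracle.

## Known limitations

* No editing-efficiency prediction: context rank is an annotation, not a
  score; outcomes such as partial bystander editing are out of scope.
* The off-target search is the anchor scan itself — no FM-index or suffix
  array — so very large genomes trade time for the algorithm's simplicity
  and zero index-build cost.
* Dual-coding codons in NCBI tables 27/28/31 are treated as stops (see
  above); contexts where readthrough dominates would need a custom code.
* Exon splicing trusts the user-supplied spans; no intron prediction is
  attempted.
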