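# cbei

sgRNA design for **cytosine base editor-mediated gene inactivation**
(CBEI): finding the spacers whose C→T edits write a premature stop codon
into a gene of interest.

Cytosine base editors (CBEs) — a nickase or dead Cas protein fused to a
cytidine deaminase — convert C•G pairs to T•A within a positional editing
window of the protospacer, with no double-strand break. On a coding
sequence this chemistry can truncate the protein: a sense-strand spacer
converts `CAA→TAA`, `CAG→TAG` or `CGA→TGA`, and an antisense-strand
spacer edits the cytosines pairing sense guanines, so `TGG→TAG/TGA/TAA`.
That makes CBEs a practical route to loss-of-function mutants and
gene-inactivation libraries in recombination- or NHEJ-deficient species —
provided you can find, among all PAM-compatible spacers, the ones whose
*in-window* edits actually create an early stop.

`cbei` is for researchers building such guides or such libraries. It
provides:

* **Design** — `find_cbei_sites()` enumerates every protospacer placement
  on both strands of a CDS and reports each placement/codon pair where
  some subset of in-window, strand-consistent C→T (or sense G→A) edits
  yields a premature stop under any of 25 NCBI genetic codes, with
  sequence-context annotation (`TC ≥ CC ≥ AC > GC`) and a search-region
  filter (default: the stop must fall in the top 50% of the CDS body).
* **ORF detection** — `detect_orfs()`, all six frames, to locate the CDS
  inside an arbitrary input (exon spans supported via `splice_exons()`).
* **Editors** — 13 built-in CBE presets (`list_presets()`), from BE3 to
  Target-AID-NG and Cas12a-BE, plus fully custom editors (PAM pattern and
  side, spacer length, editing window) from YAML/JSON configs.
* **Off-target verification** — `offtarget_search()` scans arbitrary
  genome FASTA with an anchor (pigeonhole) algorithm: the spacer is split
  into *m*+1 fragments so any site within *m* mismatches contains one
  fragment exactly; candidates are confirmed by PAM match and full-spacer
  Hamming distance. Genomes of any size are processed in 50-Mb segments
  with junction flanks so boundary-straddling sites are kept.
* **Evaluation** — `run_batch()` and `cbei_ability()` score a whole CDS
  set against many editors: the *CBEI ability* of an editor is the
  fraction of CDSs with at least one qualifying site within a given
  search region, reported per region (25/50/75%) and as ability curves.
* **Synthetic data** — `make_cds()` / `make_genome()` generate CDSs and
  genomes with planted, exactly-known sites for testing and benchmarking.

## Worked example

Design BE3 guides on a synthetic 300-nt CDS with one planted editable
codon, then verify the top guide against its own source:

```r
library(cbei)

fx  <- make_cds(cds_fixture_spec(seed = 42, n_cds = 1, length_range = c(300, 300),
                                 plants = list(plant_cbei_site(cds = 1, window_pos = 5))))
rep <- find_cbei_sites(fx$records[[1]], load_preset("BE3"), load_genetic_code(1))
rep
#> <design_report> syncds_001 x BE3: 2 site(s) in whole CDS, 1 in top 50%

rep$sites[, c("strand", "proto_start", "spacer", "pam", "codon_index",
              "codon_before", "codon_after", "edit_positions", "context")]
#>   strand proto_start               spacer pam codon_index codon_before codon_after edit_positions context
#> 1      +           6 GGGACAACGTTACGATCCCC AGG           4          CAA         TAA              5      AC
#> 2      +          19 GATCCCCAGGCGAGTCACCA TGG           9          CAG         TAG              7      CC

rep$sites$annotation[1]
#> {GGG[A(C>T)AAC]GTTACGATCCCC}|AGG CAA>TAA@4
```

Row 1 is the planted site: a 20-nt spacer starting at CDS base 6 with an
`AGG` PAM; editing the C at window position 5 turns codon 4 (`CAA`) into
the stop `TAA`, 21% into the CDS — well inside the default 50% search
region. The annotation string shows the spacer in braces, the editing
window in brackets, the stop-creating edit in parentheses and the PAM
after the pipe. Row 2 would stop codon 9 (`CAG→TAG`) but begins at 52% of
the CDS, so the default region filter drops it (`1 in top 50%`).

Off-target check of the first guide (here against its own source, so the
only hit is the on-target site):

```r
offtarget_search(rep$sites$spacer[1], fx$records, load_preset("BE3"), m = 3)
#>                 spacer     contig start strand mismatches             site_seq pam_seq is_on_target
#> 1 GGGACAACGTTACGATCCCC syncds_001     6      +          0 GGGACAACGTTACGATCCCC     AGG         TRUE
```

The same operations are available from the shell via the installed
`cbei` script:

```sh
cbei presets
cbei orf       --in input.fasta --table 11 --min-len 75 --select 1 --out cds.fasta
cbei design    --in cds.fasta --cbe Target-AID-NG --region 50 --out sites.tsv
cbei offtarget --spacers sites.tsv --genome genome.fa --cbe Target-AID-NG --mismatch 3 --out hits.tsv
cbei evaluate  --in all_cds.fasta --cbe all --regions 25,50,75 --out-dir results/
```

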