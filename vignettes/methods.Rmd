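---
title: "Detecting conserved gene arrays: model, rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved gene arrays: model, rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening model

Many clinically interesting bacterial modules pair one conserved,
HMM-detectable gene with partners too variable for direct homology
search: a type II toxin–antitoxin (TA) system couples a conserved toxin
with any of several unrelated antitoxins; an RND efflux pump is
transcriptionally coupled to a membrane fusion protein encoded
immediately upstream. `operondetect` exploits the conserved component as
an anchor and recovers the module from *structure*: a qualifying partner
gene must sit on the same strand, on the required side of the anchor's
direction of transcription, within bounded distance/overlap, and within
protein-length bounds. This turns an impossible homology problem
("find all antitoxins") into a tractable one ("find all toxins, then
read their neighbourhood under the rules").

The pipeline is: six-frame ORF extraction (optionally merged with GFF3
annotation) → profile-HMM search → bit-score and expected-length filters
→ per-locus dedup → structural partner filter → similarity-network
clustering → copy-number matrices and iTOL export. Discarded hits are
first-class output: a conserved toxin without a qualifying antitoxin is
biologically informative (degraded module, mis-assembly, atypical
architecture), so it is clustered separately and mapped back to its
nearest accepted cluster as `<cluster>_discarded`.

## Parameters that matter

* **Bit-score gate, 20 bits** (full-sequence score). The gate is applied
  to the *overall* sequence/profile comparison, not the best domain, and
  is deliberately permissive: structure, not score, is the main filter.
* **TA preset**: partner on either side; toxin 30–200 aa; antitoxin
  50–150 aa; gap ≤ 50 bp; overlap ≤ 20 bp; expected-length deviation
  100 aa when a per-profile length table is supplied.
* **RND preset**: partner upstream (the MFP position); pump 700–1500 aa;
  partner 100–1000 aa; gap ≤ 500 bp; overlap ≤ 20 bp. The source
  material calls its RND settings "flexible" without printing the
  orientation flag; upstream follows its statement that the MFP is
  encoded upstream of and co-transcribed with the pump, and is exposed
  for override.
* **flex preset**: effectively unbounded lengths with distance/overlap
  capped at 300 bp. Taking "no limitations" literally would pair every
  hit with its nearest neighbour at any distance, which stops being an
  operon hypothesis; the 300 bp cap keeps "nearest" biologically
  meaningful and is this package's choice.
* **SSN thresholds**: edge iff E ≤ 0.01 and identity ≥ 30%, clusters =
  connected components (single-linkage transitivity is the intended
  semantics). Identity is the aligner-reported value over the best local
  alignment with no coverage requirement, because the method defines
  none; the BLAST database is always exactly the sequence set being
  clustered so E-values are reproducible for a given set.
* **Ambiguity filter**: partners with ≥ 8 consecutive N/X are removed —
  they are assembly artefacts more often than genes.
* **min_len_aa = 10** for six-frame output. No floor is inherent to the
  method; downstream length bounds dominate, and 10 aa merely bounds the
  ORF-set size. Exposed as an argument.

## Gap arithmetic and coordinate conventions

Coordinates are 1-based inclusive on the forward strand (GFF
convention). The stop codon belongs to the gene's nucleotide extent and
not to its protein, which makes the intergenic gap unambiguous:
`gap = start(B) − end(A) − 1`, so 0 means abutting and −k means k shared
nucleotides. "Upstream"/"downstream" follow the hit's transcription: on
the minus strand, upstream means larger forward coordinates. When
several candidates qualify on one side the nearest (smallest |gap|)
wins — transcriptional coupling decays with distance — with ties broken
by smaller start coordinate.

## Decisions where the method description was open

* **Same-strand requirement.** Operonic co-transcription, the premise of
  the screen, requires it; `allow_antisense = TRUE` relaxes it.
* **Six-frame/annotation merge.** Two ORFs are the same gene iff they
  share contig, strand and 3′ end (the stop-delimited CDS); the
  annotated version wins, so curated non-canonical starts override the
  six-frame call and alternative starts never double-count.
* **Per-locus dedup.** One hit per ORF (best score, ties to the
  lexicographically smaller profile name) and, across ORFs, overlaps
  > 50% of the shorter ORF collapse to the best hit, so one locus
  matched by two related profiles or in two frames is counted once.
  Disable with `collapse_overlaps = FALSE`.
* **Discard reasons.** When no candidate fully qualifies the most
  informative near-miss within 100 bp beyond the limits is reported,
  with precedence ambiguous > overlap > distance > partner_length;
  otherwise `no_partner`. The margin bounds "near": a gene 5 kb away is
  absence, not a distance violation.
* **Hit-length bounds are applied in the structural filter**, not the
  HMM stage, so one hit list can be re-filtered under different presets
  without re-searching.
* **Cluster labels** are assigned in decreasing component size, ties by
  lexicographically smallest member id — deterministic under any input
  permutation. The alphabetic scheme (hits `a, b, …`; partners
  `A, B, …`; `A1…` past 26) mirrors the field's labelling habit but the
  ordering convention is this package's own.
* **Operon-type labels** concatenate partner cluster(s) (upstream first)
  and hit cluster (`A-a`); under orientation `both` the two partner
  networks are clustered independently and the count-matrix columns are
  suffixed `_up`/`_down` to keep the label spaces apart.
* **Discarded→accepted mapping.** The method states the mapping exists
  but not its computation. Here every discarded component is compared
  against accepted hit sequences under the same SSN thresholds; the best
  E-value picks the accepted cluster, components with no qualifying
  pairing get fresh `X<i>_discarded` labels.
* **iTOL flavour**: heatmap of counts (copy number is analytically
  meaningful — multi-copy arrays exist); `binary = TRUE` gives
  presence/absence. Separator comma with a tab fallback.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds genomes of inert spacer DNA with planted
two-gene cassettes at exact geometry: every violation class (distance,
overlap, partner/hit length, orphan, ambiguous run, antisense), both
strands, both sides, and boundary values at each limit. Three sequence
design rules make the planted truth table *exact* rather than
probabilistic:

1. spacers, guards and gap filler use only A/T — every permitted start
   codon contains G, so inter-gene DNA contains no ORF at all;
2. gene codons never end in T and generated proteins avoid W and C. A
   start codon spanning a codon junction needs either a codon ending in
   T followed by G, or a codon starting "TG"; both are excluded, so
   genes contribute no ORFs in alternative same-strand frames;
3. antisense partners use C-free codons, so their reverse complement is
   G-free and start-free on the hit's strand.

A per-cassette check verifies that exactly the intended ORFs are
recovered and no stray same-strand ORF enters the hit's partner-search
window, regenerating deterministically on failure. Families are 20
variants of a 100-aa gene at 5% conservative substitution — divergent
enough for non-trivial clustering, conserved enough that even a
truncated 29-aa hit clears the 20-bit gate.

Two overlap constructions deserve a note. A same-strand overlap of k
nucleotides forces both genes to be codon-aligned to the two ends of the
shared region, so they share a frame iff k ≡ 0 (mod 3) — in which case
the upstream gene's stop would sit in-frame inside the downstream gene.
k = 21 (and 2 and 5, where the forced stop would have to start with the
G of the partner's ATG) therefore cannot exist on one strand; the
overlap-violation fixture uses k = 22, and the rule-level boundary at 21
is tested with fabricated coordinates instead. Second, realising an
overlap constrains codons of the hit itself (its tail for downstream
partners, its head for upstream ones), so those few residues are
re-coded — conservatively at the protein level where synonymous codons
cannot satisfy the constraint. The hit remains a full-length,
high-scoring family member.

What the generator does **not** emulate: realistic GC content and codon
usage (spacers are A/T-only by design), mobile elements, phylogenetic
structure among genomes, assembly gaps other than literal N runs, and
genuinely homologous partner families. A green end-to-end test therefore
establishes that the *rules* are implemented exactly and deterministically
— not that the thresholds are well-chosen for any particular organism,
nor how the screen behaves on diverged real toxin families; those
properties come from the published parameterisations it mirrors.

## Numerical and degenerate-input behaviour

All thresholds are closed bounds (`>= 20` bits, `<= 50` bp, `>= 30`%
identity, `<= 0.01` E-value) and tests pin each boundary and one unit
past it. Ties are broken lexicographically everywhere (profiles,
cluster members), never by input order. Empty inputs flow through: a
genome with no hits appears as an all-zero matrix row; zero accepted
operons yield matrices with zero columns; an empty expected-length
table makes that filter the identity. ORFs running off a contig end
without a stop are kept at their longest codon-multiple extent, since
draft assemblies routinely split operons across contigs; CDS features
that fail codon-multiple or internal-stop checks are skipped with
warnings rather than aborting a 1000-genome run.

## Known limitations

Arrays of more than three genes are out of scope (orientation `both` is
the maximum); partner search never crosses contig boundaries; no
promoter or terminator evidence is used; profile-HMM scoring and local
alignment are delegated to HMMER3 and BLAST+ rather than reimplemented,
so results inherit those tools' exact scoring behaviour (versions are
recorded in the run log).
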