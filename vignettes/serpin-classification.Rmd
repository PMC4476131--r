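---
title: "Classifying vertebrate serpin genes by intron codes"
author: "serpintron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying vertebrate serpin genes by intron codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpintron)
```

## The classification problem

Serpins (serine proteinase inhibitors) form a large superfamily with a
conserved ~350–400 residue core but highly divergent sequences, which makes
sequence-only phylogeny of the whole family fragile. Vertebrate serpin genes,
however, carry a remarkably stable signal in their *gene structure*: the
number, position and phase of the introns interrupting the coding sequence.
On that basis vertebrate serpins fall into six groups, V1–V6, each with a
characteristic set of intron positions, supplemented by rare diagnostic
indels. The groups are stable from lampreys to mammals, i.e. over roughly
500 million years, which is what makes them useful as a classification
frame.

`serpintron` implements this system as a reproducible computation: given a
gene model (GFF3 + genome FASTA, or a protein plus a table of intron
offsets), it expresses each coding intron as a **code** in a common
coordinate system, matches the code set against the group signatures, and
reports the protein-level diagnostics that accompany the system.

## The intron-code coordinate system

All positions are expressed on the **mature human α1-antitrypsin protein**
(394 residues, 1-based numbering), bundled in the package as
`reference_frame()`. An intron that falls after `cds_offset` coding
nucleotides of some serpin gene is first given a *local* code:

* codon `N = ceiling(cds_offset / 3)`,
* phase letter `a`, `b` or `c` for an intron after the 1st, 2nd or 3rd
  base of codon `N`.

The letter convention is fixed once and used everywhere; it reproduces the
standard published code spellings (e.g. an intron after coding nucleotide
499 is `167a`) and maps onto GFF3 phases as `a↔2`, `b↔1`, `c↔0` — the phase
of the CDS segment *after* the intron is `(3 - cds_offset mod 3) mod 3`,
which the package asserts on every synthetic gene it writes.

The local codon is then *projected* onto the reference frame through a
global protein alignment (`global_align()` + `project_residue()`): a query
residue paired with a reference residue projects exactly; a residue inside
an insertion (reference gap) projects to the nearest preceding reference
residue and the code is marked **approximate**, rendered with a tilde
(`174a~`). Approximate codes participate in classification with a widened
codon tolerance rather than being discarded.

Alignment defaults are conventional for within-family protein comparison:
BLOSUM62, affine gap cost `open + L·extend` with open 10 and extend 1, `X`
scored 0 against everything. All are configurable through
`align_scoring()` and are recorded in every alignment object. The aligner
(Needleman–Wunsch via Biostrings) resolves equal-scoring paths with its own
fixed deterministic tie-break; we rely on score optimality (checked in the
test suite against an independent brute-force recursion) and on
determinism, not on a particular optimal path.

## Group signatures and the matching rule

The registry (`load_registry()`) stores the six signatures:

| group | required intron codes | notes |
|---|---|---|
| V1 | 78c, 128c, 167a, 212c, 262c | optional 85c defines sub-groups V1a (present) / V1b (absent) |
| V2 | 192a, 282b, 331c | most members also carry a UTR intron (counted, never coded) |
| V3 | 86a/88a/90a, 167a, 230a, 290b, 323a, 352a, 380a | first position is an alternative-set |
| V4 | 67a, 123a, 192a, 238c, 307a | |
| V5 | *(count 6, positions unspecified)* | antithrombin III only |
| V6 | 192a, 225a, 300c | HSP47 |

plus six fish-specific intron gains (94a, 215c, 241c, 77c, 233c, 262c) with
their host genes, human locus notes, and the packaged lamprey serpin table.

A single observed code matches a target when the phase letters agree
exactly and the codon numbers differ by at most `tolerance` (default 2,
widened by 2 for approximate codes). The phase letter is never allowed to
differ: a phase change is a different intron, not a shifted one. The V3
first intron is an alternative-set — any of 86a/88a/90a counts, reflecting
genuine alignment ambiguity at that site; we treat it as one intron with
uncertain placement, not as three ancestral sites.

`classify()` scores each group as

```
score = matched − 0.5 · missing − 0.25 · extra
```

where `matched`/`missing` count required positions (an alternative-set
counts once) and codes explained by optional positions or by the registered
fish-specific gains are neither matched nor extra. The published system
classifies by exact signature identity; the graded score is this package's
extension so that real annotations with a lost or gained intron — both are
documented events in this family — degrade gracefully instead of falling
off a cliff. The weights err on the side of the positional evidence:
a missing intron costs more than an unexplained extra one, because intron
loss within a group is the commoner artifact of incomplete gene models.
All weights are arguments.

**Decision rule.** The winner is the top-scoring group with at least two
required positions matched. Ties at the top yield `"ambiguous"` with the
ranked candidate list. When *no* group reaches the two-match floor, a set
of exactly six codes falls through to the count-only V5 signature (see
below); otherwise the call is `"ambiguous"` when two or more groups with at
least one match tie at the top (a single shared position like 192a, which
occurs in V2, V4 and V6, is real but insufficient evidence), and
`"unclassified"` when there is no such tie.

**V5.** The antithrombin III group is described in the literature by an
exon/intron *count* (seven exons, six introns); its positions have been
published only graphically, never as printed coordinates.
Rather than invent coordinates, the registry stores V5 as count-only and
`classify()` assigns V5 only as a fall-through (exactly six codes, no
positional support for any other group), flagged `v5_by_count` and noted
loudly in printed output. Users with trusted V5 positions can supply them
(`load_registry(v5_positions = ...)`), which turns V5 into an ordinary
positional signature.

**Sub-groups.** A V1 winner is V1a when 85c is present, V1b otherwise.

## Protein diagnostics

Three protein-level features accompany the intron system:

* **The 173–174 indel** (`detect_indel_173_174()`): the number of query
  residues inserted strictly between reference residues 173 and 174; a
  length of exactly 2 (configurable) is the diagnostic state. The
  measurement is projection-based, so N-terminal extensions do not shift
  it. Which groups are "+" for this indel is published only as figure
  colouring, so the registry stores per-group status as a configurable
  field defaulting to unknown, and the detector always reports the
  observed state.
* **RCL / P1–P1′** (`annotate_rcl()`, `parse_rcl_string()`): the reactive
  center loop is extracted from the reference window 342–361 (20 residues,
  within the 17–20 typical of serpin RCLs) with P1/P1′ read at reference
  358/359 — the canonical α1-antitrypsin coordinates, configurable because
  the RCL is defined only qualitatively. Printed RCL strings with a dash at
  the scissile bond parse with either en-dash or hyphen-minus.
* **ER retention** (`scan_er_retention()`): canonical if the C-terminal
  tetrapeptide matches the PROSITE class `[KRHQSA]-[DENQ]-E-L` (KDEL, HEEL,
  SDEL, ...), `eel_variant` for tails ending in `EEL` outside the class
  (e.g. the HDFEEL end of tetrapod neuroserpin), else `none`.

## The synthetic-gene generator

`generate_gene()` inverts the coding scheme: it back-translates a scaffold
protein with seeded synonymous codons and inserts `GT...AG` introns at the
exact coding offsets implied by the requested codes. Two properties make it
a useful validation instrument:

* With the default scaffold — the reference protein itself — the
  query-to-reference alignment is the identity, so the expected codes are
  *provable*, not merely probable: the round-trip
  generate → GFF3/FASTA → gene model → alignment → codes must reproduce
  the request exactly, with no approximate flags.
* With `mutation_rate > 0` (seeded point substitutions, up to 0.3) the
  scaffold diverges from the reference and the round-trip exercises the
  aligner and the projection tolerance instead.

Intron lengths are uniform in 120–300 nt with fixed `GT`/`AG` termini and
random interior — enough structure for coordinate arithmetic, with no claim
of splice-site realism. What the generator does **not** emulate: base
composition of real introns, UTRs and alternative transcripts, sequencing
or annotation errors in exon boundaries, and genuine intron gain/loss
processes. Passing the round-trip suites therefore demonstrates that the
coordinate machinery and classifier are correct, not that real genome
annotations are clean; on real data the approximate-code mechanism and the
graded score are expected to carry more of the load.

`generate_panel()` builds one gene per signature variant (V1a, V1b, V2,
each V3 first-intron alternative, V4, V6) plus V2 carrying each registered
fish-specific gain, alternating strands so both orientations are exercised.

## Tree concordance

`tree_concordance()` checks the classification against an externally
inferred phylogeny: after rooting at a designated outgroup tip, a group is
concordant when the smallest clade containing all its tips holds no tips of
any other group (monophyly). Groups with fewer than two tips are vacuously
monophyletic and flagged. This is deliberately a topology-only criterion —
posterior supports or bootstrap values belong to the external tree
software, are tolerated in the newick input, and are ignored.

## Validation scale and numerical choices

The test suite validates, among other things:

* aligner optimality against an independent brute-force affine-gap
  recursion on 100 random pairs of length ≤ 12;
* exact round-trip recovery for every positional signature plus 50 random
  code sets (and correct classification of each);
* classification robustness at 10% scaffold mutation over 50 seeds,
  rotating through all 12 panel variants;
* concordance against an all-clades enumeration oracle on 200 random
  10-tip, 3-group trees.

These sizes give each property many independent chances to fail while
keeping the default run fast; all stochastic cases run under fixed seeds.
Degenerate inputs are handled explicitly rather than by accident: empty
code sets are `unclassified`, single-exon genes code to an empty set,
zero-length sequences are alignment errors, a query truncated before the
RCL raises "RCL absent", and deletion of a 173/174 flank makes the indel
length undefined rather than zero.

## Known limitations

* The package classifies *gene structure*; it does not assign clades A–I
  (a sequence-similarity concept) and does not attempt orthology calls
  within the α1-antitrypsin-like cluster, where one-to-one orthology is
  known to be unreliable.
* V5 classification is count-based unless positions are supplied, and a
  six-code set that matches nothing else will be called V5 — a documented,
  deliberately loud behaviour.
* Introns in non-serpin accessory domains (e.g. the Ig domains of fish C1
  inhibitor) are outside the reference frame and are never projected onto
  it; exon/intron structure outside the CDS is recorded only as a UTR
  intron count.
* The composition of the 24 conserved intron positions across all six
  groups cannot be reconstructed from printed text alone (the V5 positions
  are graphical only), so the registry records the per-group signatures and
  makes no claim about the total.
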