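---
title: "snoscout: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snoscout: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoscout)
```

This vignette is the package's own account of its methods: what each
stage assumes, which parameters matter and why their defaults are what
they are, what the synthetic data emulates, and where the genuinely open
design choices were made.

## The data model

Everything is tabular. Sequences travel as tibbles (`id`, `seq`,
`alphabet`); coordinates are 0-based half-open everywhere inside the
package and convert to 1-based inclusive only at the format boundaries
(GFF3, 12-column hit tables). RNA input is normalised to the DNA alphabet
(`U → T`) on ingest so that one comparison alphabet serves alignment,
motif scanning and folding; the source alphabet is recorded and restored
on output, making a FASTA read/write round trip byte-identical.

The packaged catalog fixture transcribes the published table of 117
intermediate-size rhesus monkey ncRNAs exactly as printed, including its
anomalies: two U2 paralogs sit in expression group 1 despite a `no`
chicken call, one SNORD116 entry sits in group 2 despite a `no` mouse
call, and one row prints all conservation scores as unavailable (`**`,
loaded as `NA` and excluded from every score filter). The printed group
label — not the recomputed call pattern — defines block membership, and
the package performs no silent correction. Likewise the printed
consistency column does not equal what any mechanical rule reproduces
(97 `Y` entries where the text reports 96 supported patterns), so the
package computes its own flag (below) and does not attempt to reproduce
the hand-curated column.

## Library annotation

Hits are ingested from the standard 12-column tab-separated format.
Percent identity becomes a fraction; strand is derived from subject
coordinate order. Annotation discards minus-strand hits and hits weaker
than the e-value stringency floor, then assigns each query from the first
database in the priority order (Rfam, NCBI nt, ENSEMBL ncRNA, RefSeq
mRNA, ENSEMBL cDNA) holding a surviving hit. The floor is `1e-20`,
read as "at least this significant" (`evalue <= 1e-20`): a filter that
*retained* only weak hits would discard every good alignment, so the
stringency reading is the only sensible one.

Redundancy collapsing is greedy by decreasing length: a sequence joins a
longer representative when it aligns at ≥ 99 % identity over ≥ 95 % of
its own length. The two thresholds are package choices — the upstream
protocol says only that redundant sequences were removed — and both are
arguments of `cluster_redundant()`.

## Alignment and conservation

`local_align()` is an explicit affine-gap Smith–Waterman (Gotoh)
implementation; a gap of length $k$ costs $\mathrm{open} + k \cdot
\mathrm{ext}$. The default scoring (match $+1$, mismatch $-3$, gap open
$-5$, gap extend $-2$) mirrors common nucleotide-search defaults; the
original analysis used a BLAST-family tool without stating parameters, so
the scheme is configurable. Ties are resolved deterministically: the best
cell with the smallest query coordinate wins and the traceback prefers
diagonal moves. The test suite checks equivalence against an independent
plain-R reference DP on hundreds of random pairs, under two scoring
schemes.

The conservation score of sequence $q$ in a genome is

$$\mathrm{cons}(q) = \max_{\text{hits}} \; \min\!\left(1,\;
  \frac{\text{alignment length}}{|q|} \times \text{identity}\right),$$

zero without a qualifying hit. The exact functional form of
"maximal alignment length and identity" was never published; the product
form is this package's declared convention. It has the two properties any
candidate must have: a full-length perfect hit scores exactly 1, and no
hit scores 0. Gapped hits whose alignment length exceeds the query length
clip to 1 rather than erroring. No e-value model is computed in-process;
statistical significance belongs to the external search engine that
produced an imported hit table.

## Box detection and classification

Box consensus strings are not stated in the source analysis; the package
adopts the standard snoRNA literature conventions: C/C′ `RTGATGA`
(mismatch ceilings 2/3), D/D′ `CTGA` (1/1), H `ANANNA` (1), `ACA` exact.
`N` positions are unconstrained and never count as mismatches — which
means an A-rich string can legitimately match the H consensus; the H box
is therefore only meaningful inside the positional and structural
requirements of the H/ACA architecture, never alone.

`pair_cd_boxes()` requires a terminal pair: the best C box starting in
the first 25 nt plus the best D box inside the last 25 nt. The 25-nt
windows follow canonical C/D snoRNA architecture (the boxes abut the
termini, typically within a kink-turn's reach). On top of the per-box
ceilings the *combined* terminal mismatch count must not exceed 1. This
stricter joint ceiling is a deliberate design decision: with the per-box
ceilings alone, roughly one random 120-nt sequence in four contains a
passable C and D box by chance, which would make the classifier useless
as a screen; the joint ceiling drives the false positive rate below a few
percent (measured by a fixed-seed Monte-Carlo test over 100 random
sequences) while planted, unmutated elements always carry exact boxes.
An internal C′/D′ pair is annotated when both boxes occur in order
between the terminal boxes; each pair's guide is the interval between its
C-type box 3′ end and its D-type box 5′ start.

## Folding and pseudouridylation pockets

`fold_max_pairing()` maximises the number of allowed pairs (`AT`, `GC`,
`GT`) with a minimum hairpin loop of 3 nt — a Nussinov-style dynamic
program, chosen over free-energy minimisation because it is deterministic
and exactly checkable against brute-force structure enumeration at test
scale (the suite verifies equality for all test strings up to 20 nt).
A `min_helix` argument (default 1 = classic maximum pairing) optionally
forbids helices shorter than a given stack length, and a dot-bracket
string may be supplied to bypass folding entirely. The traceback closes
the current helix before opening a new one, so reported structures are
reproducible. The error threshold for a fold region is the structural
minimum (6 nt, one pair around a 3-nt loop).

Pockets — the internal loops that hold H/ACA guide sequences — are read
*between successive nested major helices* (≥ 4 stacked pairs, the
`min_stem` argument): the two arms are everything between the outer
helix's innermost pair and the nested helix's outermost pair. Short
chance stacks inside a loop are treated as part of the single-stranded
pocket. This is the central robustness decision of the structure module:
under maximum pairing, a loop of realistic size almost always admits one
or two spurious short stacks, and a literal reading of "internal loop =
maximal unpaired stretch" would fragment nearly every pocket. Anchoring
pockets to stable stems keeps the loop junctions — which is where target
pairing physically initiates — exact, at the cost of occasionally
including a transiently paired base inside an arm.

`detect_haca_architecture()` then demands the full architecture: `ACA`
starting exactly 6 nt before the 3′ end (followed by exactly 3 nt), an H
box in the middle third, both halves folding with ≥ 4 pairs, and at
least one pocket with arms ≥ 3 nt. A dinucleotide-shuffle Monte-Carlo
(fixed seeds) bounds the false positive rate. `classify_sequence()`
prefers C/D over H/ACA and warns when a sequence satisfies both.

## Target prediction

C/D guides are antisense-aligned to each target without gaps:
Watson–Crick pairs score 1.0, G·U wobble 0.5 (weight configurable — the
upstream method is silent on wobble), and any non-pairing position
terminates the duplex, so a reported duplex is a contiguous block of
complementarity. Duplexes shorter than 7 nt are discarded; the best score
wins, with ties broken by target class priority (rRNA > snRNA > tRNA >
other) and then the lowest target coordinate. The 2′-O-methylated residue
is annotated by the D+5 convention (the target base paired to the guide
base five positions upstream of the D/D′ box); it is an annotation only
and never affects target selection.

H/ACA prediction slides over every uridine of every target: the target
segment 3′ of the site must pair the pocket's left arm and the segment 5′
of the site the right arm, extending outward from the stem junctions,
with an unpaired dinucleotide between the halves. "At least seven
complementary nucleotides" is read as the *total* over both halves with a
minimum of 3 nt per half; the per-half minimum is a package decision
(one-sided seven-base duplexes describe a different geometry). The ψ is
the first unpaired target base of that dinucleotide; the wording of the
source criteria leaves first-versus-second ambiguous, and the first-base
reading is exposed as the fixed convention here. Predictions re-validate
base by base in the test suite, and a planted-pocket test demands 100 %
ψ recovery with every reported ψ a uridine.

## Expression groups, consistency, families

The six expression groups are a fixed mapping of the
(chicken, mouse, human) call triple; the two patterns unobserved in the
catalog map to 0 with a warning rather than an error, keeping the
function total. The consistency rule is one-sided — a row is inconsistent
only when some species is conserved (score ≥ `tau`, default 0.6) yet
silent. A two-sided rule would contradict the catalog itself (the vault
RNA is detected in human at conservation 0.53 and still marked
consistent), and 0.6 is the same threshold the catalog's own
low-conservation tally uses.

Family collapsing strips exactly one trailing lowercase letter when the
remainder contains a digit (`SNORA36a → SNORA36`, `U3k → U3`), leaving
hyphen-number suffixes alone (`snoU6-53`). scaRNAs count as snoRNAs and
as H/ACA for the class split — the convention that reproduces the
published 32 + 48 = 80 partition.

## Retrogene features

Poly(A) runs must start and end on `A`, reach 8 nt, stay ≥ 90 % A, and
lie within 100 nt of the element's 3′ end; runs grow greedily and never
overlap. TSD search takes the longest duplicated substring (8–50 nt,
≤ 10 % mismatches) between the last 50 nt of the 5′ flank and the first
50 nt of the 3′ flank after the last poly(A) run; ties prefer fewer
mismatches, then the copy nearest the insertion boundary. The 8-nt
minimum deliberately exceeds the 5-bp lower bound of integration biology:
in 50-nt windows a 5–7-mer repeat is overwhelmingly a chance match, and
the full 5–50 range stays available through `tsd_min_len`. The L1
endonuclease site is the best `TTAAAA` match (≤ 1 mismatch) whose 6-mer
overlaps a 10-nt region centred on the 5′ TSD start. The verdict ladder
is: poly(A) only → `candidate`; + TSD → `retrogene`; + L1 site →
`L1_retrogene`.

Flank consensus discovery uses star alignment against the longest flank
(pairwise local alignments projected onto its coordinates) rather than
progressive multiple alignment: deterministic, linear in the number of
flanks, and sufficient for block detection. A block is a maximal run of
≥ 100 columns in which ≥ 70 % of members carry the majority base. The
number of members required before a consensus call is meaningful is left
to the caller (the packaged tests use five).

## The synthetic data generator

`synth_study()` is the statistical stand-in for the survey's raw data:
i.i.d. genomes at a requested GC content with non-overlapping 2–5-exon
genes; C/D elements (70–120 nt) whose guides are reverse complements of
real windows of the generated target database; H/ACA elements
(~120–140 nt) whose 5′ hairpin pocket is complementary to a
uridine-centred target site with the ψ dinucleotide left unpaired;
retrocopies with poly(A) tail, duplicated insertion site, optional
`TTAAAA` junction motif, and i.i.d. substitution noise. Every planted
feature is written to a truth ledger (a tibble, exported as TSV) that
shares no code with the detectors.

Two generator behaviours deserve emphasis. First, constructions are
*validated at build time*: random spacers are resampled until the planted
element is unambiguous — e.g. a C/D spacer must not contain a chance
C′/D′ pair (with a ≤ 3-mismatch C′ ceiling, unconstrained random spacers
almost always would), and an H/ACA element must re-fold with its pocket
junctions at the planted stems. Pseudouridine sites whose flanking
complementarity folds back on itself (so that no unambiguous pocket can
exist) are skipped for the next candidate site. This is a property of the
generator's study conditions — planted elements are canonical by design —
not of the detectors, which never see the truth ledger. Second, the TSD
site sampler avoids sites beginning with adenosines, because a
duplication that starts with `A`s is biologically indistinguishable from
the end of the poly(A) tail.

Consequently, passing recovery tests demonstrate correctness of the
detectors on canonical, unambiguously planted architectures — boxes at
exact consensus, clean stems, substitution-only noise. They do not
demonstrate sensitivity on real genomic snoRNAs, which carry degenerate
boxes, indels, and non-canonical folds; nor do i.i.d. genomes model
repeat families, GC isochores or phylogenetic divergence.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`withr::with_seed`,
so the global RNG state is untouched). The test suite works at desk
scale, as a deliberate design of the package's verification strategy:
aligner equivalence on 200 random pairs (length ≤ 12), folding
enumeration up to 20 nt, 50 planted C/D + 50 planted H/ACA elements in a
700-kb genome for recovery, 50 retrocopies at mutation 0 and 3 × 50 at
2 % substitution in 300-kb genomes, and 100-trial Monte-Carlo false
positive bounds. Genome-scale searches against real assemblies are
supported only through imported hit tables.

## Known limitations

* Maximum base pairing is not free-energy minimisation; pseudoknots,
  non-canonical pairs and thermodynamic stability are out of scope, and a
  dot-bracket structure from an external folder can be supplied instead.
* Target prediction reports complementarity, not binding energy, and
  scans supplied target databases only — no genome-wide target search.
* The catalog's conservation scores are reproduced from the printed
  table, not re-derived from vertebrate genomes; the published per-genome
  values depend on assembly versions and a search engine configuration
  that is not fully specified.
* The published C/D box-pair total over the deposited cDNA set (GenBank
  FJ915946–FJ916062) can only be checked when those sequences are
  supplied as FASTA; they are not redistributable with the package.
* scaRNA recognition is by name in the catalog module; composite scaRNA
  architectures are not detected structurally.
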