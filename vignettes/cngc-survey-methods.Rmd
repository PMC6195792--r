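---
title: "Methods: motif-based CNGC family surveys with famscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based CNGC family surveys with famscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

## The problem

Plant cyclic nucleotide-gated channels (CNGCs) are Ca²⁺-permeable cation
channels built from six transmembrane segments, a pore, and a C-terminal
cyclic nucleotide-binding domain (CNBD). The CNBD alone cannot identify a
CNGC: potassium AKT/KAT (Shaker-type) channels carry one too. What is
diagnostic is a short motif spanning the phosphate-binding cassette (PBC)
and the adjacent hinge inside the CNBD, conventionally written in the
PROSITE dialect as

```
L-X(2)-G-[ED]-ELL-[TSG]-W-[ACY]-L-X(10,20)-[SA]-X-T-X(7)-[EQ]-[AG]-F-X-L
```

famscan implements a family survey built around that motif: identification
of candidates from a proteome, physicochemical characterization,
duplication dating from synonymous substitutions, exon–intron structure,
promoter cis-element content, a neighbor-joining phylogeny with group
assignment, and tissue-specificity summaries. Every stage has a seeded
synthetic generator that emulates its input, so the whole pipeline is
testable end to end without genome downloads.

## Motif dialect and scanning semantics

`compile_pattern()` reads hyphen-separated tokens: literal residues
(multi-letter literals such as `ELL` are runs of single positions),
bracketed sets, the `X` wildcard, and `(n)`/`(n,m)` repeats. Two readings
had to be fixed by design because the published motif strings leave them
undefined:

* **The `0` token.** Consensus strings contain sets like `[LIMV0]` and
  repeats `X(0,1)`. We read a `0` inside a bracket, and a zero minimum
  repeat, as "this position is optional" (matched 0 or 1 times). This is
  the only reading under which the published consensus is a well-formed
  pattern.
* **Variable repeats.** For spans such as `X(10,20)` a start position may
  admit several match lengths. `scan_motif()` reports, for every matching
  start, the *shortest* match anchored there. This makes scanning
  deterministic and exactly checkable against a brute-force backtracking
  matcher, which the test suite does on random patterns × random
  sequences.

`identify_cngc()` accepts a protein when it has at least one motif hit, is
at least 200 aa long (fragments below that are conventionally discarded in
family surveys), and is not redundant. Redundancy is operationalized
explicitly — exact duplicates, plus near-duplicates at ≥ 99% identity over
a global alignment of the shorter sequence, keeping the longer — because
the "manual correction" such surveys describe is otherwise untestable. The
homology pre-search (HMM/BLAST against a real proteome) is replaced by
whole-proteome motif scanning; `candidates=` accepts an externally
produced id list when such a search is available.

## Physicochemical properties

`molecular_weight()` sums average (not monoisotopic) residue masses plus
one water; `gravy()` is the mean Kyte–Doolittle hydropathy; both follow the
ExPASy conventions, and ambiguity letters are rejected loudly rather than
averaged. `isoelectric_point()` finds the pH of zero net charge with the
Bjellqvist pKa set (side chains D/E/C/Y/H/K/R, C-terminus 3.55,
residue-dependent N-terminus) by bisection on [0, 14] to |charge| < 1e-4;
the charge is strictly decreasing in pH so the root is unique. The tests
check the machinery against a dense pH-grid search and against the
independent seqinr implementations of both MW and pI.

## Ka/Ks and duplication dating

`kaks_pair()` is the Nei–Gojobori (1986) counting method: per-codon
synonymous site fractions (changes to stop codons count as nonsynonymous),
observed differences averaged over all minimal substitution paths with
stop-crossing paths excluded and the average renormalized, and Jukes–Cantor
correction `K = -3/4 · ln(1 - 4/3 p)`. NG86 was chosen because the survey
tooling this emulates (DnaSP) is NG86-based; the method is recorded in the
result object. A correction is undefined when a proportion reaches 3/4; the
result is then flagged `saturated` rather than extrapolated. Codon
alignments come from `codon_align()`, which aligns the translations and
back-threads codons so gaps cannot break frame.

Divergence times use the synonymous clock
`Mya = Ks / (2λ) × 10⁻⁶` with λ = 6.5 × 10⁻⁹ substitutions·site⁻¹·year⁻¹,
the standard grass rate; the grouping of the formula was validated against
every row of the published dating table that this package's fixture
carries. `ratio_and_date()` classifies ratios < 1, = 1 (within 1e-9), > 1
as purifying, neutral, positive.

## Exon–intron structure

`infer_structure()` does exact spliced chaining: it searches for an exon
chain on the genomic sequence whose concatenation reproduces the CDS with
zero mismatches, which is the right model when CDS and genomic sequence
come from the same assembly. Among solutions the preference order is (1)
introns ≥ 20 bp — always enforced, to exclude degenerate zero-length
"introns" — then (2) canonical GT..AG boundaries, then (3) leftmost intron
placement; the search tries the reverse complement when the plus strand
fails, and failure is a structured `no-splice-solution` error. UTR exons
are not modeled (CDS-only structures). Intron phase is the cumulative
upstream exon length mod 3.

## Promoter cis-elements

`scan_promoter()` matches IUPAC degenerate patterns at every position and
on both strands, counting overlapping and self-overlapping hits — a
deterministic superset of any counting convention. The packaged
`place_elements()` table carries 17 named elements whose IUPAC strings were
entered from the public PLACE records; PLACE itself is not redistributed,
and genome-wide element counts (such as "137 elements" in any particular
survey) are database-version dependent, so only planted-element recovery
and oracle equality are asserted. Shared elements are those hit in every
promoter, gene-specific ones those hit in exactly one.

## Phylogeny and groups

`poisson_distance()` uses pairwise deletion of gap/X sites and
`d = -ln(1 - p)`; saturated pairs (p at 1) are flagged rather than
silently capped into inference. `nj_tree()` is Saitou–Nei neighbor joining
with a deterministic lexicographic tie-break, and clamps negative branch
lengths to zero moving the deficit to the sibling edge so path lengths are
preserved; on additive matrices it recovers the generating tree exactly
(tested on 50 random 4–8 taxon trees, and against ape's independent NJ).
NJ under the Poisson model was chosen over likelihood methods because it is
fully self-contained and, for well-separated family groups, yields the
same topology. `bootstrap_support()` resamples alignment columns with a
fixed seed (taxa are sorted internally, so supports are invariant to input
order and bit-reproducible). `assign_groups()` gives each query leaf the
label of the smallest split containing it whose reference members are
unanimous — mixed smallest splits leave the leaf `unplaced` rather than
guessing. The alignment itself is an input: multiple sequence alignment is
a solved problem for external tools and is not re-implemented.

## Tissue specificity

The survey literature calls genes "tissue-specific" without defining it;
`specificity()` operationalizes this as the tau index
`Σ(1 - x_i/x_max)/(n - 1)` (0 uniform, 1 single-tissue) with an expressed
flag at max FPKM ≥ 1. Tau is scale-invariant, so FPKM normalization
constants do not affect it; tau of a silent gene is reported as `NA`, not
0. Developmental time-courses are ingested as additional matrices; no
trend statistic is computed.

## What the generators emulate — and what they do not

The generators reproduce the *statistical structure* each stage assumes,
with defaults set to the maize survey's conditions: 12 family members plus
11 AKT/KAT-like decoys at 326–745 aa; 0–7 canonical introns of ≥ 20 bp;
1,500-bp promoters; duplicate pairs at Ks ≈ 0.18, ω ≈ 0.14 (the maize
within-genome duplication magnitudes) with a transition/transversion ratio
of 2; 12 × 6 FPKM matrices with specific/uniform/silent classes. Residue
and nucleotide backgrounds are uniform — real maize GC content and codon
bias are not emulated, which affects chance-match rates but not the
correctness properties being tested. Planted divergence uses
single-nucleotide codon changes at distinct sites per class, so the
expected observed difference proportion equals the Jukes–Cantor inversion
of the target rate and recovery tests have a sharp expectation; it is not
a full codon substitution model. The gene generator verifies that its
planted structure is the unique solution preferred by
`infer_structure()`'s tie-breaks and redraws the rare ambiguous layouts.
Consequently, green tests demonstrate algorithmic correctness on inputs
with known truth — not robustness to assembly errors, misannotation, or
alignment noise in real genome data.

## Numerical and scale choices

Bisection tolerance 1e-4 charge units (pI reported to 2 decimals needs
~1e-3 pH accuracy); JC correction refuses p ≥ 3/4; NJ tie-break tolerance
1e-12 on Q. Problem sizes in the test suite — 100 random 30-codon pairs
for the path-enumeration oracle, 50 duplicate pairs of 900 codons, 50
random additive trees of 4–8 taxa, 100–200 bootstrap replicates on 8-taxon
alignments — were chosen as the smallest sizes at which the statistical
claims (mean bias, exact recovery, reproducibility) are sharp.

## Known limitations

No profile-HMM scoring or E-values; no mismatch-tolerant spliced
alignment; no PWM promoter scanning; no maximum-likelihood or Bayesian
phylogenetics; ortholog detection (synteny) is out of scope, so dating
tables for cross-species pairs take published Ka/Ks values as inputs.
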