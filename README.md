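# famscan

An offline R toolkit for genome-wide surveys of the plant **cyclic
nucleotide-gated channel (CNGC)** gene family — and, more generally, for
motif-defined ion-channel families. CNGCs are Ca²⁺-permeable channels whose
C-terminal cyclic nucleotide-binding domain (CNBD) is shared with potassium
AKT/KAT (Shaker-type) channels; what distinguishes a plant CNGC is a short
diagnostic motif spanning the phosphate-binding cassette (PBC) and hinge
inside the CNBD:

```
L-X(2)-G-[ED]-ELL-[TSG]-W-[ACY]-L-X(10,20)-[SA]-X-T-X(7)-[EQ]-[AG]-F-X-L
```

famscan implements the full survey pipeline around that motif:

* **Identification** — a PROSITE-dialect pattern compiler and scanner
  (`compile_pattern()`, `scan_motif()`), plus the candidate filter pipeline
  (`identify_cngc()`: motif presence, ≥ 200 aa, redundancy collapse).
* **Characterization** — molecular weight, theoretical pI
  (Bjellqvist/ExPASy pKa set, bisection) and Kyte–Doolittle GRAVY
  (`protein_properties()`).
* **Duplication dating** — Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor
  correction (`kaks_pair()`, `codon_align()`) and the synonymous clock
  `Mya = Ks/(2λ) × 10⁻⁶`, λ = 6.5 × 10⁻⁹ site⁻¹·yr⁻¹
  (`ratio_and_date()`); Ka/Ks < 1, = 1, > 1 read as purifying, neutral,
  positive selection.
* **Gene structure** — exact spliced chaining of a CDS into its genomic
  sequence with canonical-GT..AG/leftmost preferences, intron lengths and
  phases (`infer_structure()`, `intron_phases()`), GFF3 export.
* **Promoters** — IUPAC cis-element scanning of 1,500-bp upstream regions
  against PLACE-style tables, shared/gene-specific summaries
  (`scan_promoters()`, `summarize_elements()`, packaged
  `place_elements()` mini-table).
* **Phylogeny** — Poisson-corrected protein distances, Saitou–Nei
  neighbor joining, seeded bootstrap supports, and clade-based group
  assignment (Groups I–IVb style) (`poisson_distance()`, `nj_tree()`,
  `bootstrap_support()`, `assign_groups()`).
* **Expression** — FPKM ingestion and tau tissue-specificity summaries
  (`read_fpkm()`, `specificity()`).
* **Synthetic data** — seeded generators (`gen_proteome()`,
  `gen_gene_model()`, `gen_duplicate_pair()`, `gen_promoter()`,
  `gen_fpkm()`, `gen_clade_msa()`) that emulate every input with recorded
  ground truth, so the pipeline runs and is tested without genome
  downloads.

See the methods vignette (`vignettes/cngc-survey-methods.Rmd`) for the
models, conventions and design decisions.

## Worked example

```r
library(famscan)

## a 12-member family plus 11 AKT/KAT-like decoys, with known truth
pg  <- gen_proteome(seed = 2024)
rep <- identify_cngc(pg$proteome)
print(rep)
#> Family identification: 12 accepted of 23 scanned (12 with motif,
#>   0 below length cutoff, 0 redundant)
```

All 12 motif-bearing proteins are accepted and all 11 decoys rejected —
the decoys carry a CNBD-like architecture in length terms but lack the
PBC+hinge motif, which is exactly the false-positive class the filter must
remove.

```r
props <- protein_properties(pg$proteome[rep$accepted][1:3])
transform(props, mw = round(mw, 2), pi = round(pi, 2), gravy = round(gravy, 3))
#>       id length       mw   pi  gravy
#> 1 CNGC01    431 51496.40 8.74 -0.428
#> 2 CNGC02    705 82953.89 6.50 -0.349
#> 3 CNGC03    713 84113.11 8.31 -0.663

## duplication dating on a simulated duplicate pair (Ks target 0.18)
dp  <- gen_duplicate_pair(seed = 1)
aln <- codon_align(dp$cds_a, dp$cds_b)
kk  <- kaks_pair(aln$a, aln$b)
print(kk)
#> NG86 over 900 codons: S=663.83 N=2036.17 Sd=89.00 Nd=48.00  Ka=0.0240 Ks=0.1477
rd <- ratio_and_date(kk$Ka, kk$Ks)
#> Ka/Ks = 0.162 (purifying), divergence 11.36 Mya
```

`S` and `N` are the NG86 synonymous/nonsynonymous site counts (they sum to
3 per codon), `Sd`/`Nd` the path-averaged observed differences; the ratio
below 1 indicates purifying selection and the date follows the synonymous
clock. On the published maize segmental-duplication estimates the same
arithmetic gives:

```r
ratio_and_date(0.0258, 0.1829)
#> ratio 0.141061, 14.06923 Mya, purifying
```

```r
## exon-intron structure with planted ground truth
gm <- gen_gene_model(seed = 7, n_introns = 3)
m  <- infer_structure(gm$cds, gm$genomic, "ZmCNGC_like")
print(m)
#> Gene model ZmCNGC_like (+ strand): 4 exon(s), 3 intron(s), genomic span 2203 bp
intron_phases(m)
#> [1] 0 1 0
```

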