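# ltrclass

Structural annotation and lineage classification of plant
LTR-retrotransposons.

## The problem

LTR-retrotransposons dominate plant genomes, yet their DNA sequences are so
diverse that most copies share no detectable similarity at the nucleotide
level. What is conserved is their anatomy — two long terminal repeats (LTRs)
flanking an internal region with a polyprotein — and the amino-acid sequence
of the polyprotein domains. `ltrclass` annotates and classifies candidate
elements from that anatomy:

* **Structure**: LTR-pair detection under the standard screening constraints
  (LTR length 100–6000 bp, inter-LTR distance 1000–20,000 bp, 5'/3' LTR
  similarity ≥ 95%, TG…CA termini), target site duplication (TSD, 4–6 bp)
  detection from host flanks, and QC filters (more than ten ambiguous bases,
  suspected nested insertions, missing polyprotein).
* **Protein domains**: six-frame translated Smith–Waterman search (BLOSUM62)
  against a REXdb-style reference database
  (`Ty1-RT__<element>` naming), with frameshift-tolerant chaining of split
  hits. Domain order separates the superfamilies — GAG-PROT-INT-RT-RH for
  Ty1/copia, GAG-PROT-RT-RH-INT for Ty3/gypsy — and elements with unexpected
  order, duplicated domains or mixed-superfamily best hits are flagged.
* **Primer binding site (PBS)**: classified as a full tRNA match (≥ 12 bp
  exact complement of a tRNA 3' end within 50 bp of the 5' LTR), a
  half-molecule tRNA match (ending in the anticodon cleavage window, with
  inosine-edited positions pairing with A/T/C), a fuzzy tRNA match (TGG
  anchor 0–5 bp after the LTR, ≤ 2 differences of which ≤ 1 indel), a
  self-primer (≥ 10 bp complement of the downstream sequence inside the 5'
  LTR), or none.
* **Extra ORFs**: ORFs of ≥ 250 codons outside the polyprotein, labeled
  eORF-5'F / 5'R / 3'F / 3'R by side and orientation, with exclusion of
  artifacts born of tandem repeats (≥ 3 monomers spanning > 150 bp).
* **Lineage**: score-weighted best-hit voting of the PROT/RT/RH/INT domains
  over the reference classification (chromovirus clades CRM, Tekay, Reina,
  Galadriel, Tcn1, Chlamyvir; the OTA superclade with Athila and the Tat
  subclades TatI–TatIII, Ogre, Retand; the Ty1/copia lineages), plus
  consistency checks of chromodomain type (CHDCR is confined to CRM,
  chromodomains to chromoviruses), aRH position (PROT↔RT for TatI/TatII,
  after INT for TatIII, RH↔INT for Ogre/Retand), aromatic-cage inspection
  (F/Y/W triad) and expected PBS type.
* **Redundancy and phylogeny**: clustering of concatenated PROT-RT-RH-INT
  proteins at ≥ 80% identity over ≥ 90% of length, CD-HIT-style greedy
  representative selection (0.90 identity), observed-distance (p-distance)
  matrices and neighbor-joining trees in newick format.

A deterministic simulator (`make_corpus()`) builds reference databases, tRNA
libraries and complete synthetic elements with ground-truth manifests, so
the whole pipeline is testable without downloading anything.

## A worked example

```r
library(ltrclass)

cfg    <- pipeline_config()
refdb  <- make_toy_refdb(seed = 42)     # 9 lineages, 2 reference elements each
trnas  <- make_toy_trnas(42)

spec <- element_spec("demo", "Ogre", seed = 1)
elem <- build_element(spec, refdb, trnas, cfg)
ann  <- annotate_element(elem$seq, refdb, trnas, cfg)
ann
```

```
<ltr_element> demo (5579 bp)
  LTRs: [1,300] / [5280,5579], similarity 98.0%
  TSD: ACTGC (5 bp)
  domains: GAG-PROT-RT-RH-aRH-INT (Ty3/gypsy)
  PBS: fuzzy_tRNA (tRNA-Arg)
  lineage: Ty3/gypsy|non-chromovirus|OTA|Tat|Ogre (vote 1.00)
```

Reading the output: the two 300 bp LTRs diverged to 98% identity (recent
insertion); the element is flanked by the 5 bp TSD `ACTGC`; the polyprotein
carries the Ty3/gypsy domain order with an additional ribonuclease H (aRH)
between RH and INT — the hallmark of the Ogre/Retand subclades — and the PBS
is an imperfect tRNA-Arg complement, so the element votes unanimously
(vote share 1.00) for the Ogre lineage with no consistency flags.

Batch use mirrors this: `annotate_elements()` over a FASTA read with
`read_dna_fasta()`, `format_report()` for the per-element TSV plus summary
tables, `write_gff3()` for GFF3 output. A thin command-line wrapper with
`annotate`, `cluster`, `tree` and `simulate` subcommands is installed under
`inst/cli/ltrclass`.

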