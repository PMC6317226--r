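---
title: "Annotating and classifying LTR-retrotransposons with ltrclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying LTR-retrotransposons with ltrclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrclass)
```

## The model

An intact LTR-retrotransposon consists of two direct long terminal repeats
(LTRs) flanking an internal region that encodes a polyprotein with at least
five domains: GAG, protease (PROT), reverse transcriptase (RT), ribonuclease
H (RH) and integrase (INT). Because the two LTRs are identical at insertion
and diverge neutrally afterwards, their similarity dates the insertion;
because integration duplicates 4–6 bp of host sequence, a target site
duplication (TSD) brackets genuine insertions; and because reverse
transcription is primed at a primer binding site (PBS) just downstream of
the 5' LTR, the PBS sequence records which primer — a tRNA, a tRNA
half-molecule, or a fragment of the element's own LTR — the element uses.
The order of the polyprotein domains distinguishes the two superfamilies
(INT before RT in Ty1/copia, after RH in Ty3/gypsy), and the amino-acid
sequences of PROT/RT/RH/INT remain alignable across hundreds of millions of
years, which is what makes reference-based classification below the
superfamily rank possible at all.

`ltrclass` implements this reasoning as a pipeline of independent,
separately testable detectors, plus a classifier that combines the domain
evidence and checks it against per-lineage structural expectations
(chromodomain type, position of the additional ribonuclease H, PBS type).

## Parameters and their defaults

All thresholds live in one flat configuration (`pipeline_config()`); the
defaults are the values of the screening protocol the package implements.

| parameter | default | meaning |
|---|---|---|
| `ltr_min_len`, `ltr_max_len` | 100, 6000 bp | admissible LTR length |
| `inter_ltr_min`, `inter_ltr_max` | 1000, 20000 bp | distance between LTR starts |
| `ltr_min_similarity` | 95% | minimum 5'/3' LTR identity (recent insertions) |
| `require_tg_ca` | true | 5' LTR starts TG, 3' LTR ends CA |
| `max_n` | 10 | maximum ambiguous bases per element |
| `pbs_window` | 50 bp | search window downstream of the 5' LTR |
| `pbs_min_exact` | 12 bp | minimum exact tRNA 3'-end complement |
| `tgg_max_offset` | 5 bp | TGG anchor offset for fuzzy/self searches |
| `fuzzy_max_diffs`, `fuzzy_max_indels` | 2, 1 | fuzzy-PBS edit budget |
| `self_primer_min` | 10 bp | minimum self-primer complement |
| `eorf_min_codons` | 250 | minimum extra-ORF length |
| `tandem_min_monomers`, `tandem_min_span` | 3, 150 bp | qualifying tandem array |
| `cluster_min_identity`, `cluster_min_coverage` | 80%, 90% | clustering rule |
| `rep_identity` | 0.90 | representative selection (CD-HIT `-c` convention) |
| `eorf_group_evalue` | 1e-10 | eORF protein grouping threshold |

Alignment scoring is a convention, not a biological rule, and is therefore
configurable but fixed by default: global DNA alignment at match +1 /
mismatch −1 / gap open −4 / extend −1 (LTR similarity is matches over all
alignment columns), local protein alignment under BLOSUM62 with gap open
−10 / extend −1 (identity over alignment columns). The translated search
reports hits with score ≥ 80 and identity ≥ 25%, ignores translation
segments under 20 aa, and chains same-type colinear hits across ≤ 300 bp
gaps — the frameshift tolerance that recovers domains from elements with
disrupted reading frames. A shared-4-mer word prefilter (≥ 2 distinct
4-mers, the strongest `scan_max_refs_per_type = 4` references per domain
type scored in full) keeps the search fast; for very distant references
`scan_min_kmer_hits` can be lowered to 1.

## Design choices where the design was open

* **Coordinates.** All intervals are 1-based closed, the convention of the
  R/Bioconductor sequence stack this package is built on; GFF3 output needs
  no conversion. The TSD is reported as an attribute of the element row
  rather than as its own GFF3 feature because its bases lie in the host
  flanks, outside the element's coordinate system.
* **PBS precedence.** When several primer detectors fire, the call is
  resolved full tRNA > half tRNA > fuzzy tRNA > self-primer > none — from
  the most to the least specific evidence. The fuzzy comparison window is
  fixed at 18 bp (the edit budget is prescribed, the window length is not);
  the half-molecule cleavage window is anticodon start −3…+5, an
  operational proxy for cleavage "in the anticodon stem". All detectors are
  restricted to the same 50 bp window, and half-molecule matches reuse the
  12 bp minimum of full matches.
* **Nested insertions** are flagged, not resolved: a second LTR-like pair
  strictly inside the internal region raises `nested_insertion_suspect`.
* **Chimera proxy.** "Signs of chimerical origin" is operationalized as
  disagreement among the best-hit superfamily tokens of the core domains
  (or between votes and the architecture template); the flag is recorded,
  never silently dropped.
* **Tandem repeats** are detected by scanning candidate periods proposed by
  repeated-8-mer spacings and scoring lagged self-agreement (+1 match, −4
  mismatch, so segments break even exactly at 80% agreement). This replaces
  a full alignment-based repeat finder; the qualifying thresholds (≥ 3
  monomers, > 150 bp) are applied to its output. The 50%-overlap rule for
  excluding eORFs is this package's choice of what "present at" a repeat
  region means.
* **eORF grouping** uses Karlin–Altschul E-values with the standard
  ungapped BLOSUM62 constants (λ = 0.3176, K = 0.134) over a search space
  of the pair's length product times the number of pairs; groups are
  connected components, so the partition is order-invariant.
* **Voting.** Only PROT, INT, RT and RH vote (GAG and the chromodomains are
  too variable or too restricted; chromodomains instead serve as
  consistency evidence). Votes are weighted by alignment score, which makes
  `vote_share` invariant under uniform score scaling. A `vote_share` below
  0.5 flags `low_confidence` — a reporting device, not an established
  cutoff. Tat subclade disambiguation beyond the aRH position relies on
  best hits, not phylogeny — a documented limitation.
* **Clustering coverage** is measured against the shorter sequence;
  identity is local-alignment identity. Representative selection follows
  the greedy incremental scheme of CD-HIT (`-c 0.90`): members sorted by
  length, each joining the first seed it matches, the representative being
  the seed of the largest sub-group.
* **Neighbor joining** is the classic agglomeration; negative branch
  lengths, impossible on additive input but possible otherwise, are clamped
  to zero with the deficit moved to the sister branch so the joined pair's
  path length is preserved. BioNJ's variance weighting is not implemented;
  on the matrices used here the two agree.

## What the simulator emulates — and what it does not

`make_corpus()` builds complete elements: flank + TSD + 5' LTR (TG…CA) +
PBS + optional 5' eORF + in-frame polyprotein cassette + optional 3' eORF
and tandem-repeat decoys + diverged 3' LTR + TSD + flank, each with a
ground-truth manifest verified against the emitted sequence at generation
time (the PBS and ORF detectors are replayed; the rare draw in which random
sequence collides with the intended ground truth — e.g. a chance primer
site in a "no PBS" element — is rejected and rebuilt from a derived
sub-seed). Per-lineage defaults encode the characteristic feature
combinations: CHDCR and tRNA-Met priming for CRM, self-priming for Tcn1 and
TAR, the edited half-tRNA-Ile for Bianca, half-tRNA-Met for Osser, the aRH
positions of the Tat subclades, eORF sides/orientations for Ogre, Retand,
Athila and SIRE. Corpus-level slices add the observations that individual
elements cannot carry: about 6% of elements get no PBS and a small slice a
6 bp TSD, and every second eORF-bearing OTA element carries a
tandem-repeat-borne decoy ORF that the filter must exclude.

The reference database derives each domain type from one ancestor per
type, each lineage from that ancestor at a chosen between-lineage identity
(default 0.5), and two entries per lineage and type at the within-lineage
identity (default 0.95); the aromatic cage (F/Y/W at three protected
columns) is planted in every CHD entry.

Deliberately absent: realistic base composition and codon usage (reverse
translation draws codons uniformly), indel mutation between LTR copies
(substitution-only by default, so similarity targets are analytic), nested
elements, and insertion-age structure. Passing the round-trip therefore
shows that the detectors invert the generative anatomy exactly; it does not
show robustness to diverged real elements, fragmentary copies, or
reference databases less cleanly separated than the toy one.

## Numerical behaviour and degenerate inputs

Detection is deterministic throughout; the only randomness in the package
is the simulator's, and it is fully seed-derived (a master seed spawns
per-element sub-seeds, so corpora are reproducible element by element).
Ties are broken explicitly: longest match, then smallest offset, then tRNA
id for PBS calls; higher similarity, then longer LTR, then leftmost start
for LTR pairs; deeper path then lexicographic for tied lineage votes.
Degenerate inputs return empty results or flagged records rather than
errors (no LTR pair → no PBS call; no domains → `no_polyprotein`; flanks
too short → no TSD with a warning); hard errors are reserved for malformed
inputs (unparseable reference names, ragged alignments, fewer than three
taxa for a tree).

## Scale of the shipped checks

The test suite and acceptance script use a 200-element corpus over nine
lineages for the round-trip, 100 random pairs (≤ 200 residues) for the
alignment-oracle comparison, 100 random 18-mers for the fuzzy-PBS oracle,
and 4- and 6-taxon additive matrices for neighbor joining — sizes chosen so
the full suite runs in minutes on one CPU while every code path, boundary
and tie rule is exercised.
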