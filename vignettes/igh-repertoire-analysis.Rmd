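---
title: "IGH repertoire simulation and analysis with ighrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IGH repertoire simulation and analysis with ighrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighrep)
```

## The problem

High-throughput sequencing of the immunoglobulin heavy-chain (IGH) locus
yields millions of reads, each carrying one somatic V(D)J rearrangement
plus a constant-region (C) prefix that identifies the isotype. Turning
those reads into biology requires (i) assigning each read its germline V,
D, J and C segments, (ii) extracting the hypervariable CDR-H3 junction,
(iii) filtering to productive rearrangements, and (iv) summarising each
sample as a feature vector — segment usage, clonal diversity, CDR-H3
length and hydrophobicity, somatic hypermutation (SHM) load, and the
germline index — that can be compared across clinical groups.

`ighrep` implements that pipeline, together with a V(D)J recombination
simulator that produces reads with complete per-read ground truth. The
simulator is first-class, tested code: it is the only way to validate the
annotator end to end when real repertoire data are unavailable, and it
makes every downstream estimator testable against a known generative
state.

## The annotation model

Reads are aligned locally (affine-gap Smith–Waterman, match +2, mismatch
−2, gap of length $k$ costing $5 + k$) against every candidate segment of
a class; the best score wins, ties broken by fewer mismatches and then by
lexicographically smallest id. V is sought over the whole read, J strictly
3′ of the V alignment, C 3′ of J, and D only inside the inter-anchor
window. A read lacking any of V, J or C is rejected with a reason;
rejections are data, not errors. Score floors (30 for V/J/C, 12 for D)
separate genuine segment matches from chance local alignments; D is
best-effort because heavily trimmed D segments are frequently unalignable,
and inventing D coverage would bias the germline index upward.

The CDR-H3 **junction** is the read span from the first base of the V
2nd-CYS codon through the last base of the J TRP codon, **inclusive of
both anchors** (note that IMGT "CDR3" excludes them; every output labels
the convention). Anchor positions are mapped from the segment onto the
read through the alignment columns; if either anchor codon is destroyed by
mutation the junction is reported absent with a note (`lost 2nd-CYS`,
`lost J-TRP`). A rearrangement is **productive** when its junction is
present, the junction length is a multiple of 3, and the V-anchor-framed
translation carries no stop codon through the junction end.

**SHM counting.** The SHM rate is the pooled ratio
$100 \times \sum \text{mutations} / \sum \text{aligned V nt}$, with the
junction window excluded from both numerator and denominator: junction
mismatches conflate non-templated (N) nucleotides with SHM. Pooling (rather
than averaging per-read rates) weights long alignments more, reading
"point mutations per V-gene nucleotide" literally.

**Germline index (GI).** Per record, the fraction of junction nucleotides
covered by the V, D or J alignments — 1 for a fully germline junction, low
when many N/P nucleotides intervene. Records whose D call is absent count
only V/J coverage, which can under- rather than over-estimate GI.

## Diversity and junction indices

With clonotype abundances $n_i$ (reads per collapsed clonotype,
$N = \sum_i n_i$):

$$\text{Shannon} = -\sum_i \frac{n_i}{N}\log_2\frac{n_i}{N}, \qquad
  \text{Simpson} = 1\Big/\sum_i \Big(\frac{n_i}{N}\Big)^2 .$$

The species unit is the collapsed clonotype — records identical in
(V, J, C, junction, full amino-acid sequence) — which is the field
convention; both clonotype and read weighting are exposed for usage and
junction summaries.

Hydrophobicity uses the Kyte–Doolittle hydropathy constants divided by
4.5, the largest absolute value in the scale, mapping each residue onto
$[-1, 1]$ (Ile $\to +1$, Arg $\to -1$); a junction scores the mean over
its residues. The normalization constant is a documented package choice —
the scale is configurable through a two-column text table
(`inst/extdata/kyte_doolittle.tsv` ships the default).

## What the simulator emulates

Each clone draws V/D/J/C segments from configurable multinomial usage
vectors (clone-level usage; read-level frequencies then inherit the
power-law clone sizes, so diversity indices respond to the expansion
exponent). Junctions are built as: V trimmed at 3′, palindromic (P)
extension at an untrimmed V end, non-templated N insertion, D trimmed at
both ends, N insertion, P extension at an untrimmed J 5′ end, trimmed J,
then a constant-region prefix. SHM applies point substitutions (no
indels) over the V-derived span at an isotype-specific rate; sequencing
errors hit each read independently, never on an SHM position, so the two
sources are distinguishable in truth. Qualities are constant Q37 with Q15
at error positions.

Defaults, chosen once as field-plausible where no external value exists:

| parameter | default | rationale |
|---|---|---|
| trim per end | geometric, mean 2 nt | typical exonucleolytic chewback |
| N per junction | geometric, mean 4 nt | ~8 nt non-templated per read |
| P extension | prob 0.5 at untrimmed ends, ≤ 2 nt | short palindromes only |
| SHM by isotype | IGHM 0.5%, IGHD 0.3%, IGHG 2.5%, IGHA 3%, IGHE 2% | naive vs class-switched compartments |
| clone sizes | discrete power law, exponent 2.5 | heavy-tailed clonal expansion |
| non-productive clones | 10%, via frame-shifting N insertions | exercises the productive filter |
| sequencing error | 0.1%/base | Illumina-like |
| C usage | typical blood isotype mix | IGHM-dominated PBMC repertoire |

Trims resample rather than cross anchor codons, so the C…W rule is always
satisfiable on truth and annotator failures are isolated from generative
ones. The realized productive fraction is *below* 90% because chance stop
codons arise in N/D junction codons and through SHM; the truth flag and
the annotator apply the same rule, so recovery comparisons are exact.

The simulator does **not** model SHM hotspot motifs (WRCY), indels, UMIs,
paired-end reads, or chimeras. A green recovery test therefore
establishes that the annotator inverts this generative model — not that
it is robust to every artefact of real libraries.

### Synthetic germline references

`build_synthetic_reference()` generates random but structurally faithful
segments: V segments are stop-free in frame with a TGT 2nd-CYS codon 9 nt
from their 3′ end; J segments carry the W-G-x-G motif at their anchor; C
segments take the canonical isotype names (IGHM, IGHD, IGHG1–4, IGHA1–2,
IGHE, plus IGHGP as a tenth). All pairwise identities within a class are
forced below `1 − min_pairwise_divergence` (identity = 1 − edit
distance / length), with resampling and a hard error if the bound is
unsatisfiable. Real IMGT references load through `load_germline_fasta()`:
the gapped dialect takes the 2nd-CYS at IMGT codon 104 and maps it onto
the ungapped sequence; J anchors are located by the W-G-x-G scan.
Segments containing N are rejected rather than imputed, because mutation
counting must be exact.

## Statistics

Group contrasts use the Mann–Whitney U test (unpaired) or the Wilcoxon
signed rank test (paired pre/post designs); correlations with continuous
covariates (e.g. an autoantibody titer) use Spearman's rank correlation.
All tests are two-sided. Exact null distributions are used when
$n_x n_y \le 400$ with no ties (Mann–Whitney) or effective $n \le 25$
with untied magnitudes (Wilcoxon); otherwise the normal approximation
with tie and continuity correction. `compare_features()` runs one test
per feature, zero-fills usage features (absence of a segment is signal,
not missingness), reports the sign of the median difference as the
direction, and by default applies **no** multiple-testing correction —
mirroring the original univariate reporting — with Benjamini–Hochberg
available behind an explicit flag; output headers always state which was
used.

## Numerical and design choices

- **Coordinates** are 1-based and closed throughout (the R convention);
  TSV headers state this.
- **Gap convention**: a gap of length $k$ costs
  `gap_open + k * gap_extend`; the brute-force test oracle and the
  Biostrings cross-check use the same convention.
- **Alignment tie-breaks** are deterministic (score, then mismatches,
  then id), so annotation is reproducible to the byte.
- **Determinism**: every stochastic step runs under `with_seed()`, which
  restores the caller's RNG state; the same seed gives byte-identical
  FASTQ/TSV outputs across runs and platforms.
- **Anchor mapping under gaps**: anchors are mapped through the alignment
  column map, with gap-adjusted extrapolation past alignment ends; the
  anchor codon is then verified on the read, so a wrong extrapolation can
  only produce an "absent junction", never a wrong junction silently.
- **Degenerate inputs**: empty FASTA, all-zero paired differences,
  constant features and constant covariates raise informative errors
  (or p = 1 where the spec of the test defines it); an empty group is an
  error, an unannotatable read is a rejection record.
- **CDR-H3 length** includes the anchor residues; every output header
  labels the convention.
- **Config files** are flat `key = value` text or JSON (no YAML parser is
  assumed in the environment).

## Known limitations

- D-call accuracy is intrinsically limited for heavily trimmed D
  segments; GI uses V/J coverage only in those records.
- SHM is substitution-only; indel SHM would be misread as gaps.
- The annotator assumes the V region starts at the 5′ end of the read
  (5′-RACE-style libraries).
- Isotype subclass resolution is only as good as the best C alignment on
  a short constant prefix.
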