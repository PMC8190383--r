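# ighrep

Simulation and analysis of immunoglobulin heavy-chain (IGH) B-cell
receptor repertoires.

Repertoire sequencing studies compare clinical groups through per-sample
summaries of the IGH rearrangement pool: V/D/J/C segment usage, clonal
diversity, CDR-H3 junction length and hydrophobicity, somatic
hypermutation (SHM) load, and the germline index. `ighrep` provides the
full desk-side pipeline for that analysis, plus a V(D)J recombination
simulator with per-read ground truth so every estimator can be validated
against a known generative state:

- **Germline references** — load IMGT-style FASTA (plain or gapped
  dialect) or build synthetic V/D/J/C sets with guaranteed pairwise
  divergence (`load_germline_fasta()`, `build_synthetic_reference()`).
- **Simulation** — multinomial segment usage, geometric trimming,
  palindromic and non-templated junction nucleotides, isotype-specific
  SHM, power-law clone sizes, per-base sequencing error
  (`sim_config()`, `simulate_sample()`).
- **Annotation** — affine-gap Smith–Waterman segment assignment (Rcpp
  core), CDR-H3 junction extraction between the conserved 2nd-CYS and
  J-TRP anchors, productive filtering, V-region mutation counting,
  duplicate collapsing to clonotypes; AIRR-style rearrangement TSV out
  (`annotate_sample()`, `collapse_duplicates()`).
- **Metrics** — usage frequencies at gene/family level, Shannon and
  inverse Simpson diversity, CDR-H3 length distributions, normalized
  Kyte–Doolittle hydrophobicity, pooled SHM rate, germline index
  (`repertoire_profile()`, `profile_table()`).
- **Statistics** — two-sided Mann–Whitney U, Wilcoxon signed rank and
  Spearman correlation with exact small-sample nulls, feature-wise
  comparison tables with optional Benjamini–Hochberg adjustment
  (`compare_features()`, `correlate_features()`).

The core indices, for clonotype abundances `n_i` (`N = sum n_i`):

    Shannon = -sum_i (n_i/N) log2(n_i/N)         [bits]
    Simpson = 1 / sum_i (n_i/N)^2                [inverse form]
    SHM%    = 100 * sum(mutations) / sum(aligned V nt)
    GI      = junction nt covered by V/D/J / junction length   [0..1]
    KD      = mean residue hydropathy / 4.5                    [-1..1]

## Worked example

```r
library(ighrep)

ref <- build_synthetic_reference(n_v = 10, seed = 7)
cfg <- sim_config(ref, reads_per_sample = 400L, clone_count = 60L,
                  shm_rate_by_isotype = c(IGHM = 0.01), shm_default = 0.01,
                  seq_error_rate = 0, seed = 11)
sim <- simulate_sample(cfg, "demo")
ann <- annotate_sample(sim$reads, ref)
col <- collapse_duplicates(ann$rearrangements)

# how well did annotation recover the simulated truth?
tr <- sim$truth[match(ann$rearrangements$sequence_id, sim$truth$read_id), ]
mean(ann$rearrangements$v_call == tr$v_call)
#> [1] 1

repertoire_profile(col, "demo")
#> repertoire_profile 'demo': 31 clonotypes / 239 reads
#>   shannon 4.781 bits, simpson 24.132, gi 0.865
#>   CDR-H3 mean 15.94 aa, hydrophobicity -0.048, SHM 0.892%
```

All 400 reads annotate; the configured 1% SHM is recovered as 0.89%, the
germline index of 0.86 reflects the simulated N/P insertion load, and the
31 productive clonotypes carry the diversity indices. Group comparisons
then take a table of such profiles plus a sample metadata table:

```r
cmp <- compare_features(profile_table(list_of_profiles), metadata,
                        design = "unpaired", adjust = "none")
```

## Pipeline stages and CLI

Each stage is re-runnable and file-based: `cmd_simulate()`,
`cmd_annotate()`, `cmd_profile()`, `cmd_compare()` read flat
`key = value` or JSON configs, stamp every output with tool version,
config hash and seed, and write a JSON run manifest.
`exec/ighrep.R` is a thin shell wrapper:

```sh
Rscript exec/ighrep.R simulate --config sim.cfg
Rscript exec/ighrep.R annotate reads=out/S1.fastq reference=out/reference.fasta out_dir=out
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch —
reference synthesis, two-group simulation, annotation, profiling and
group comparison — under a caller-supplied seed and writes the JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
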