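---
title: "Targeted expression profiling with multiplexed probe panels: models and methods"
author: "tealseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted expression profiling with multiplexed probe panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Measuring gene expression for a chosen bacterial species inside a complex
community is hard: microbial abundances and transcript levels span orders of
magnitude, and most sequencing effort lands on host RNA or on organisms that
are not of interest. Targeted sequencing addresses this with large pools of
species-specific oligonucleotide probes that enrich transcripts of the
species under study before sequencing. `tealseq` implements the
computational side of such an assay end to end:

1. **Target selection** — choose which genes to target from a pangenome
   presence/absence matrix.
2. **Probe design** — tile 40-mer candidates over the target CDS, filter
   them thermodynamically and compositionally, and assemble panels for two
   chemistries: SPE (single-primer extension, one 40-base primer per site)
   and MIP (molecular inversion probes, two 40-base arms flanking a gap
   that is filled by extension and sealed by ligation).
3. **Specificity screening** — require probes to match enough genomes of
   the target species perfectly, to stay far (in Hamming distance) from
   every off-target genome, and to share fewer than 25 of their 40 bases
   with the host transcriptome.
4. **Quantification** — trim method-specific adapters, filter alignments on
   MAPQ and NM, count reads over probe intervals, and normalise to CPM per
   sample and species (RPKM for bulk CDS counts).
5. **Differential expression** — per-probe negative-binomial Wald tests,
   aggregated per gene by the median of probe statistics.
6. **Simulation** — a fully seeded generator of pangenomes, expression
   states and captured reads, with ground truth, so that every stage above
   is testable at desk scale.

# Target selection

A gene cluster is targeted when it is present in at least `min_genomes`
genomes of the species' pangenome. This is the assay's core-gene prevalence
rule: panels should quantify genes that most strains of the species carry,
so that an unknown community strain is still covered. Prevalence counts a
genome once regardless of paralog copy number. The bridge from cluster IDs
to reference-strain coordinates is an explicit input table
(`map_targets_to_reference()`), because cluster naming conventions differ
between pangenome pipelines; unmapped clusters are always reported, never
silently dropped.

# Probe design

## Candidate tiling

Candidates are every 40-base window of a target CDS, step 1, on both
strands — after second-strand cDNA synthesis the capture template is
double-stranded, so both orientations are usable binding sites. Windows
containing `N` are rejected outright: probes are synthesised oligos and
must be fully specified.

## Melting temperature

The two-state nearest-neighbor model with the unified Watson–Crick
parameter set (SantaLucia & Hicks 2004): duplex ΔH/ΔS accumulated over
dinucleotide stacks plus initiation and terminal A·T penalties, entropy
salt correction `0.368 (N−1) ln[Na+]`, and

  Tm = 1000 ΔH / (ΔS + R ln(CT/4)) − 273.15.

Defaults are 50 mM monovalent salt and CT = 250 pM total oligo — capture
pools hold thousands of probes, so each species is present at picomolar
concentration. Both are configurable (`panel_config(na_mM=, oligo_conc_M=)`).
The implementation is checked against an independent published-parameter
calculator to well below 0.5 °C.

## Composition filter

A candidate fails if it contains a homopolymer run longer than 6 bases
(a run of exactly 6 passes — the rule is "no runs of more than 6") or if
its Tm is extreme. "Extreme" is, by default, a percentile rule: the lowest
and highest 5% of the candidate Tm distribution per species are trimmed.
The underlying assay description calls for removing *extremes* of melting
temperature rather than enforcing fixed bounds, which is why trimming is
the default; an absolute window (`tm_window = c(low, high)` in °C) is
available when a fixed hybridisation temperature is known.

## Specificity screens

* **Inclusion**: a probe must match perfectly (zero mismatches, either
  strand) in at least `inclusion_min_genomes` target genomes. When unset,
  the threshold defaults to 60% of the genomes supplied, rounded up — the
  same majority-prevalence level as the target-selection rule (e.g. 50 of
  86, 30 of 51). Requiring *all* genomes is usually self-defeating at
  realistic strain-level SNP densities.
* **Exclusion**: a probe fails if any off-target genome contains an
  ungapped full-length placement with **4 or fewer** mismatches (fewer
  than five mismatches disqualifies). A 40-mer alignment with ≤4
  mismatches is effectively ungapped, so gapped off-target alignments are
  out of scope. The production path uses a pigeonhole seed-and-verify
  search (max_mm + 1 disjoint exact seeds, each verified by Hamming
  distance); its completeness against a full scan at every offset is a
  test, not an assumption.
* **Host screen**: a probe fails when 25 or more of its 40 bases match a
  host transcript. "Matching" is read as matched bases within the best
  ungapped local alignment on either strand — mismatches inside the
  alignment are allowed but not counted, and partial overlaps at
  transcript ends count only their overlapping identities. Whether the
  original rule counted identities in a gapped alignment instead is not
  decidable from the assay description; the ungapped-identities reading is
  recorded here and used consistently.

The full Hamming search (`find_hits()`) evaluates the mismatch count at
every offset of every contig on both strands, so its completeness holds by
construction; the test suite re-derives the hit sets with an independent
plain-R sliding-window oracle, exactly, for 0–4 mismatches.

## Panel assembly

Within a gene, accepted probes must start at least `min_spacing = 100`
bases apart. Per gene the package selects a *maximum-cardinality* spaced
subset (greedy left-to-right sweep, provably optimal for points on a line
and verified against exhaustive search), then applies the per-gene budget
`max_probes_per_cds = 4`, keeping probes whose Tm is closest to the
species median (ties: smaller start, then + strand). The budget default
reflects the observed panel density of roughly 3.5–4 probes per CDS in
practice. Spacing is enforced **within genes only** — probes of adjacent
genes may fall closer than 100 bases; enforcing it genome-wide would
penalise compact operons for no assay-chemistry reason, and the choice is
recorded here.

MIP assembly pairs candidate arms on a common contig and strand so the
genomic gap between left-arm end and right-arm start is `mip_gap_len ±
mip_gap_tol` (default 120 ± 10 bases; the final library size constrains
but does not pin this value, so it is a free, configurable parameter).
Each arm is used at most once; left arms of distinct MIPs honour the
100-base spacing across strands. Pairing is greedy (leftmost available
left arm, earliest feasible right arm) and matches an exhaustive
maximum-matching oracle on instances up to 10 arms.

`design_panel()` wires these stages together. Screens are expensive, so
they run on the assembled shortlist rather than on every tiled window;
probes failing a screen are retired from the candidate pool and the
affected genes re-assembled until the panel is stable. Two accelerations
keep this loop short without weakening the guarantee: inclusion is
prechecked for every composition-passing candidate with a bulk exact
dictionary lookup, and a screen failure retires the candidate's
neighbourhood (the off-target-homologous gene region, or all windows
overlapping a host-similar segment) in one step. The emitted panel is
gated by a final clean verdict, and an acceptance test re-screens every
emitted probe independently.

# Quantification

* **Trimming**: SPE and bulk reads are truncated at the first occurrence
  of the bait adapter `AGATCGGAAGAG`; MIP reads lose a fixed five bases
  from the 5′ end. Reads shorter than 30 bases after trimming are
  discarded and tallied (the 30-base floor is a configurable default; the
  assay description leaves it unstated).
* **Alignment filters** (all bounds strict): MAPQ > 30 everywhere;
  NM < 1 for SPE probe alignments (perfect match), NM < 3 for MIP,
  NM < 4 for genome/bulk alignments. MAPQ = 30 is rejected; SPE NM = 1 is
  rejected; MIP NM = 2 is kept. Secondary and supplementary records are
  dropped — multi-mapping is resolved by the upstream aligner's primary
  alignment, and MAPQ > 30 makes residual multi-mapping negligible.
* **Counting**: a kept read increments a probe when its aligned span
  overlaps the probe interval by at least one base (half-open intervals),
  the default semantics of interval-coverage counting; a read spanning two
  probes increments both. MIP probes appear in the BED as two arm rows
  (`/L`, `/R`) whose counts are summed into one probe count.
* **CPM**: `cpm = 1e6 × r / R` with the total `R` computed per sample
  *and species* — the two species of a mixed panel are normalised
  independently, so CPM columns sum to exactly 1e6 within each
  (sample, species) stratum. **RPKM** for bulk CDS counts is
  `count / (total/1e6) / (length/1000)`.

# Differential expression

Per probe, raw counts are modelled with a negative-binomial GLM on the
condition factor (optionally condition × covariate, e.g. an amplification
protocol indicator), with log library-size offsets. Dispersion is a pooled
method-of-moments estimate `(s² − μ)/μ²` per condition group with a floor
(default 0.01) and ceiling (10): at n = 3 the MoM estimate is noisy and
the floor keeps Wald standard errors honest. The Wald test reads the
condition coefficient with dispersion fixed at 1 (overdispersion lives in
θ, not in a Pearson scale factor). P-values are Benjamini–Hochberg
adjusted across all tested probes *before* any gene-level subsetting.
`log2fc` is computed from library-size-normalised counts with pseudocount
0.5, which stays finite for zero groups.

This engine is intentionally simpler than shrinkage-based frameworks — no
dispersion shrinkage, no fold-change moderation — and is documented as
non-identical to them. Its validated surface is recovery of planted
effects in simulation (recall ≥ 0.9, empirical FDR ≤ 0.1 at 20 planted
genes among 200, |log2FC| = 3, n = 3 vs 3), not coefficient-level parity
with any particular package.

Gene calls use the **median of probes**: a gene is `up` iff its median
probe log2FC strictly exceeds 2 and its median adjusted p is strictly
below 0.05 (`down` symmetric). The median (interpolated for even probe
counts) is robust to outlier probes with poor capture performance. Two
stated threshold conventions — "fold-change magnitude > 4, adjusted
p < 0.01" and "|median log2FC| > 2, median adjusted p < 0.05" — coincide
on the fold-change scale (FC 4 ≡ log2FC 2); the p threshold defaults to
0.05 and is configurable. Whether probe p-values should be adjusted before
or after subsetting to detected probes is not specified anywhere
authoritative; this package adjusts across all tested probes first.

Set-level agreement between two DEG lists uses the upper-tail
hypergeometric over-representation test, `P(X ≥ k)`, with a Bonferroni
multiplier equal to the number of directional set comparisons executed in
the same batch (recorded in the output). Protocol-distortion comparisons
use per-CDS squared differences of `log2(CPM + 1)` between paired samples
and a two-sided Wilcoxon rank-sum test between two squared-error
distributions (exact up to 25 values per group without ties, normal
approximation with tie correction otherwise). Sample-similarity structure
is summarised by pairwise Pearson correlations on `log2(CPM + 1)` and by
Euclidean distances between rows of the correlation matrix.

# The simulator

The generator emulates, at desk scale, the data the assay consumes:

* **Pangenome**: per species, 100 core genes (present in every strain)
  and 20 accessory genes (present with probability 0.5), lengths uniform
  in 300–900 bases — typical bacterial CDS lengths — separated by 100-base
  random intergenic spacers; 6 strains whose non-reference genomes carry
  substitutions at `snp_rate = 0.01` per base, a realistic within-species
  nucleotide diversity for staphylococci. Two target species, plus two
  off-target species of which 5% of genes are diverged (10%) copies of
  target genes, so the exclusion screen faces realistic near-matches, and
  a host transcriptome of 100 × 500-base transcripts.
* **Expression**: baseline abundances i.i.d. log-normal(meanlog 3,
  sdlog 1.2) — a heavy-tailed distribution of the kind bulk RNA-seq
  libraries show; 10% of genes are planted as differentially expressed at
  |log2FC| = 3 with alternating signs; all other genes are identical
  across conditions.
* **Capture efficiency**: for SPE, logistic in (Tm − panel median Tm)
  times a per-mismatch penalty of 0.5 per probe-vs-strain mismatch —
  encoding the observed positive Tm–yield relationship and strong
  mismatch sensitivity of one-primer capture. For MIP, flat with full
  tolerance of up to 3 total arm mismatches and zero capture above —
  encoding the observed robustness of gap-fill/ligation chemistry to a
  few arm mismatches. These magnitudes are *stylised, declared constants
  for testing*, not fitted to any data.
* **Reads**: 1e5 per sample, 100 bases, substitution errors at 0.002 per
  base, 50% host background by default. Raw reads carry the method's
  adapter structure (SPE reads end in the bait; MIP reads begin with five
  junk bases) so trimming is exercised end to end. Reads are emitted in
  reference orientation; the capture strand does not affect counting, so
  strand-flipping the FASTQ would only complicate the trimming-consistency
  checks. A read's genomic span is anchored at the probe's (or left
  arm's) start so that the cleaned read overlaps the probe interval —
  the arrangement under which interval-coverage counting of probe BED
  files is coherent. The truth table places every on-target cleaned read
  on the species' reference genome with its exact NM (strain SNPs plus
  sequencing errors); background reads are recorded unmapped.
* **Determinism**: the seed is mandatory, and every stage derives its
  stream from it (pangenome: seed; expression: seed + 1; counts:
  seed + 2; each read batch: an explicit per-sample seed). Identical
  configuration and seed give byte-identical output files.

What the simulator does **not** model — and therefore what passing tests
do *not* establish about real data: rRNA and structured transcript
abundance, amplification bias of isothermal pre-amplification, indel
errors and quality-score structure, gapped homology between species,
operon-level expression correlation, and genome rearrangements. The
simulator validates the pipeline's arithmetic and guarantees, not the wet
chemistry.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally everywhere; conversion to
  1-based GFF3 and native BED happens only in the readers/writers, and
  round-trips are lossless for retained fields.
* Ambiguity codes collapse to `N` on FASTA input; `N` never matches in
  any screen, so masked sequence cannot create spurious hits.
* Tie-breaks are fixed (smaller start, then + strand) so panel design is
  a pure function of inputs and configuration.
* Hit reporting caps at 1,000 placements per probe per genome to bound
  low-complexity pathologies; capped pairs are recorded on the result.
* Zero-total CPM strata yield all-zero CPM with a warning flag; zero
  totals are an error for RPKM. Probes with all-zero counts are excluded
  from DE and listed. Zero-variance samples yield `NA` correlations,
  reported. The BED score column carries no information and is written
  as 0.
* Probe searches concatenate subjects with `N` separators of exactly the
  probe length, so no alignment window can straddle two sequences; for
  the host screen the same construction makes partial end overlaps score
  exactly their overlapping identities.

# Problem sizes in the shipped tests

The test suite runs the oracle-equivalence checks at 200 probes × 20 × 10
kb genomes (mismatch search) and 100 probes × 50 kb transcripts (host
screen); the end-to-end study at 2 species × 100 core genes, ~3 probes
per gene and 1e5 reads per sample; and the DE recovery study at 200 genes
with 20 planted DEGs, n = 3 vs 3. These sizes were chosen so that a
complete run exercises every guarantee in a few minutes on a laptop while
remaining large enough that the property checks are non-trivial.

# Known limitations

* The exclusion screen is ungapped; a gapped off-target alignment with
  few substitutions would be missed (not expected for 40-mers at ≤4
  mismatches, but stated).
* Secondary-structure and cross-probe dimer screening are out of scope,
  as are vendor-specific backbone/adapter sequences.
* The NB-Wald DE engine does not shrink dispersions; at n = 2–3 its
  per-probe power is below that of moderated engines, which the
  median-of-probes aggregation partly compensates.
* The SSE pairing (which sample pairs enter each squared error) is an
  explicit input, since no canonical pairing exists in general.
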