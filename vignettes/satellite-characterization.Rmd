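---
title: "Characterizing satellite DNA from shotgun and ChIP-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing satellite DNA from shotgun and ChIP-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satkit)
```

## The problem

Satellite DNA (satDNA) forms megabase-scale arrays of tandemly repeated
monomers. Because such arrays collapse in genome assemblies, satDNA is
characterized directly from reads: low-pass shotgun reads are assigned to
repeat-family consensus sequences by similarity, the assigned fraction
converts to a physical genome fraction, and reads from a CenH3 chromatin
immunoprecipitation compared against a pre-IP input pool identify the
families bound by centromeric chromatin. `satkit` implements this pipeline
at desk scale together with a simulator that plants known family abundances
and enrichment factors, so every stage can be scored against ground truth.

The packaged summary table (`read_satellite_table()`) describes 26 satellite
families of a large-genome legume (1C = 13.41 Gbp): 23 novel families plus
three previously described repeats, with monomers from ~26 bp to 2033 bp,
genomic abundances from 0.008% to 2.723%, and seven families with CenH3
ChIP/input ratios above 10 (41.2- to 149.2-fold).

## The simulator and what it does (not) emulate

`build_genome()` lays each family down as one uninterrupted head-to-tail
array of monomer copies, each copy independently mutated at a per-base
substitution rate (`divergence`, default 5% — chosen so that simulated
"cloned" array segments match their consensus at 92–99% identity, the band
typical of homogenized satellite arrays). Copy number is the nearest whole
number of monomers to `target_fraction * genome_length`, so planted
fractions are honored to within one monomer. Coordinates are 0-based,
half-open throughout; a read belongs to the family in whose array it
*starts*, one consistent rule for boundary-crossing reads.

`simulate_reads()` draws uniform start positions on both strands and applies
independent substitution errors; qualities are Phred+33, constant Q30 by
default, with a `low_tail` mode that degrades 3' tails to exercise the
quality filter. Read length defaults to 101 nt, the single-end Illumina mode
this kind of survey typically uses.

`simulate_chip()` samples a ChIP read from family *i* with probability
`fraction_i * factor_i`, with the unbound background absorbing the
remainder. This choice (rather than renormalizing family-plus-background
weights) reflects what an IP does — it depletes unbound bulk chromatin — and
it has two useful consequences: a factor of 1 samples a family exactly at
its genomic fraction, and the *expected* measured ChIP/input ratio equals
the planted factor, making the factor a recoverable truth parameter. The
summed `fraction x factor` mass must stay below 1.

The simulator does **not** model indels or structural mutation, higher-order
repeat evolution, paired-end reads, GC bias, or the fragment-size and
chromatin-accessibility biases of a real ChIP library (read sampling is
uniform within arrays). Passing recovery tests therefore demonstrate that
the estimator chain is consistent and unbiased under idealized sampling —
not that real libraries are free of such biases.

At desk scale the synthetic genome is 100 kb–1 Mb; 200 kb with 100k reads
per pool gives per-family input counts of a few hundred to a few thousand,
comparable in relative sampling error to low-pass survey sequencing of a
multi-Gbp genome.

## Read preparation

`process_fastq()` reproduces a standard pre-mapping protocol: drop the first
base, truncate to 100 nt, and keep a read only if at least 95 positions
reach Phred 10. The cutoff is read inclusively (quality >= 10); a `strict`
flag provides the strictly-greater reading, which differs only for reads
sitting exactly at the boundary. Reads shorter than 100 nt after trimming
are discarded — uniform length keeps proportion arithmetic exact, and the
101-nt simulator never produces them. Counts are conserved:
`reads_in = reads_out + discarded_short + failed_quality`.

## Best-hit assignment

`local_align_score()` is an affine-gap Smith–Waterman scorer with BLASTn-style
parameters: match +2, mismatch −3, a gap of length *k* costing 5 + 2*k*,
exact-word seeding of width 9. Two deliberate choices:

* **Score threshold instead of an E-value.** An E-value cutoff calibrates a
  raw score against database size; at desk scale that calibration is
  meaningless, so assignment uses a raw `min_score` (default 100, roughly 50
  matched bases). It is configurable.
* **No low-complexity masking, ever.** Satellite monomers *are*
  low-complexity sequence; dusting would delete the signal the analysis is
  about.

Each read is scored against every member sequence of every family and both
strands; it is assigned to the family with the strictly highest score at or
above the threshold. Ties break to the lexicographically smallest family
name and are counted. The word-9 seed index is an accelerator only: a family
is aligned whenever it shares one exact 9-mer with the read, and unassigned
reads report score 0, so seeded and unseeded runs give identical tables on
the test conditions. Output rows are sorted by read id, making the table
independent of input order.

References should be at least read-length long: against a bare 50-bp
monomer a 100-nt read's best local score is capped at 100, which starves
short-monomer families. `truth_references()` therefore multimerizes short
consensus monomers head-to-tail (mirroring the assembled repeat contigs used
as mapping references in practice).

## Abundance and enrichment

`abundance_table()` converts per-family counts to percent of reads processed
and to Mbp/1C via `pct/100 * genome_mbp`, reported at one decimal with
half-away-from-zero rounding (this convention reproduces the large majority
of the packaged table's printed values; `audit_physical_size()` reports the
residual disagreements — e.g. one family printed 17.6 where the percentage
recomputes to 17.7 — without correcting them).

`enrichment_table()` computes per-family pool proportions, their ratio, and
the centromere call: ratio strictly greater than 10 *and* a genomic
proportion of at least 0.002% (the evaluation floor below which counts are
too sparse), evaluated among the 500 most abundant families by input count.
A family with ChIP reads but no input reads reports an infinite ratio and is
called only if the ChIP-pool proportion clears the floor. Two normalization
denominators are provided: `"assigned"` (default — robust when the two pools
have different unassignable fractions, appropriate for real data mapped
against a broad repeat catalog) and `"all"` (per-pool totals). With only a
handful of synthetic families the assigned-reads denominator is dominated by
the enriched families themselves and carries no information, so the recovery
analyses use `"all"`; with a real, broad reference catalog the assigned
denominator is the sensible default. Neither is claimed to be the exact
normalization used with any particular published dataset.

`enrichment_recovery_study()` fixes the end-to-end conditions: three
families (monomers 191/58/50 bp, fractions 2%/1%/0.4%, 5% divergence),
factors 1/10/100, 100k reads per pool, assignment against multimerized
references. Over ten seeds the median relative error of recovered factors is
a few percent, factor-1 families are never called, and a constructed ratio
of exactly 10 is never called (the threshold is strict).

## Composition statistics

Four per-sequence indices mirror the summary table: AT content (N excluded),
and three strand-asymmetry ratios — max A/T, max C/G, max Pu/Py — each
reported as `max(x/y, y/x)` so 1 means balance; a zero denominator with a
nonzero numerator yields an infinity sentinel, two zeros report 1.
Asymmetry is computed on the given (consensus) orientation, the only
orientation available for a reconstructed monomer.

Di- and tri-nucleotide representation uses relative abundances on
strand-symmetrized counts (sequence pooled with its reverse complement, the
Karlin-school convention — read pools mix strands, and the asymmetry columns
carry the strand signal instead):

* rho\*(XY) = f\*(XY) / (f\*(X) f\*(Y))
* gamma\*(XYZ) = f\*(XYZ) f\*(X) f\*(Y) f\*(Z) / (f\*(XY) f\*(YZ) f\*(XnZ)),
  where f\*(XnZ) is the frequency of X and Z separated by one arbitrary base.

Monomers are counted circularly (a tandem-repeat consensus is an arbitrary
rotation of the repeating unit; circular counts are rotation-invariant),
read pools linearly. k-mers absent from the data report 0. The gamma formula
was transcribed independently twice — a vectorized implementation in the
package and a literal positional-count implementation in the test suite —
and the two agree to 1e-12 on random sequences; on iid uniform sequence all
80 values fall within [0.9, 1.1] at the tested lengths.

`pool_composition()` first orients each read to the reference strand by its
better-scoring strand, then pools counts; orientation exactly cancels a
50/50 strand mixture.

## Tandem-organization validation

* `estimate_period()` uses shifted identity (match autocorrelation): the
  period is the smallest lag in the window whose match fraction exceeds 0.8
  and is a local maximum. Transparent and oracle-checkable; the 0.8
  threshold tolerates ~10% per-copy divergence. It returns the monomer
  length, never a multiple, and is rotation-invariant.
* `detect_subrepeats()` reports off-diagonal exact-identity runs of at least
  `min_len` (default 20) in the self-comparison matrix — the dot-plot
  criterion. On random 1-kb sequence, runs of 20 are vanishingly rare, so an
  empty result is informative. The original dot-plot window/identity
  settings of any given study are unknowable; the parameters are exposed
  with documented defaults, not claimed to match.
* `design_outward_primers()` places a forward primer near the monomer's 3'
  end reading outward and a reverse primer near the 5' end reading outward
  (geometry `reverse$end <= forward$start`, lengths 18–25). GC is preferred
  in 40–60% and relaxed to >= 30% with a warning on AT-rich monomers; Tm is
  the Wallace rule 2(A+T) + 4(G+C), reported informationally only — the
  assay is a logical test of tandem arrangement, not thermodynamics, which
  is also why primer matching in `in_silico_pcr()` is exact in this version.
* `in_silico_pcr()` scans both orientations for exact primer sites; on an
  n-copy head-to-tail array an outward pair yields exactly n−1 junction
  products of equal length `(L − forward$start) + reverse$end`, and zero
  products on a single monomer — amplification is possible only between
  adjacent tandem copies.
* `percent_identity()` is overlap (free end-gap) global identity under the
  same scoring scheme, used to compare simulated clones with their
  consensus; at 5% divergence it lands in the 92–99% band.

## Replication-timing regression

Timing classes are encoded ordinally mid = 0, late = 1, latest = 2 — the
observed order of S-phase stages; no claim is made about spacing, and with
three levels any monotone encoding gives the same single-feature inference
up to sign. Each numeric feature is tested singly by OLS with a two-sided
slope test; no multiple-testing correction by default (a BH flag exists).
Which exact feature set enters the regression is configurable — the analysis
driver uses monomer length, AT%, the three asymmetry indices and
log-abundance. A planted AT-dependent timing is detected at alpha = 0.05; on
permuted labels the test rejects at ~5% (calibrated over 1000 permutations),
and p-values on pure-noise features are approximately uniform.

## Numerical conventions and degenerate inputs

* Rounding of reported Mbp: half away from zero at one decimal.
* Coordinates: 0-based half-open everywhere (arrays, primer sites, truth).
* Assignment ties: lexicographic, logged. Unassigned reads report score 0.
* Zero denominators: asymmetry ratios use an Inf sentinel (0/0 reports 1);
  enrichment with zero input count uses Inf plus the chip-pool floor;
  all-zero pools, empty sequences/pools, and infeasible fractions raise
  errors rather than propagating NaN.
* Determinism: every stochastic step takes a seed; identical spec + seed
  gives byte-identical FASTA/FASTQ.

## Problem sizes

The shipped analyses and tests use a 200-kb genome, 100k reads per ChIP
pool, ten recovery seeds, 1000 alignment oracle pairs (lengths <= 30) and
1000 regression permutations — sizes at which every stage completes in
minutes on one core while keeping per-family counts large enough for the
stated tolerances.

## Known limitations

* Substitution-only mutation and error models; no indels anywhere, so
  alignment gaps are exercised only synthetically in tests.
* The enrichment model treats families independently; no cross-hybridizing
  or chimeric reads beyond array-boundary spillover.
* The printed asymmetry columns of the packaged table derive from degenerate
  consensus sequences that a literal motif expansion oversimplifies, so
  those printed values are treated as data to filter, not quantities to
  recompute.
* `estimate_period()` is a validation-grade stand-in for full consensus
  reconstruction from read clusters, which is out of scope.
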