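---
title: "Models and methods behind sagcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sagcensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagcensus)
```

# Scope

`sagcensus` analyzes cohorts of single amplified genomes (SAGs): genome
assemblies obtained from individual flow-sorted, whole-genome-amplified
cells. The motivating application is the characterization of the candidate
superphyla Patescibacteria (bacteria) and DPANN (archaea) — ultrasmall cells
with small genomes whose apparent lack of respiratory machinery and whose
(in)frequency of physical association with other cells are cohort-level
questions: no single partial assembly can answer them, but hundreds of
partial assemblies can, if the analysis handles incompleteness and
contamination explicitly.

The package implements five analysis stages plus a synthetic-community
generator that makes every stage testable against known truth:

1. **Co-sort detection** — flagging SAGs that contain DNA from more than one
   cell, with a chi-square decomposition of the cohort table.
2. **Genetic-code-aware gene calling** — ORFs under translation tables 11
   and 25, code selection, and coding density.
3. **16S detection and phylum classification** — a k-mer panel detector and
   a naive-Bayes word classifier with bootstrap confidence.
4. **Respiratory profiling** — KO threshold-rule hits per electron-transport
   complex, oxygen-reductase homolog search, oxidoreductase (EC1) fraction.
5. **COG ordination and cohort reports** — classical scaling of COG-category
   profiles, rank-sum group tests, plate abundances, box statistics, and
   cumulative-completeness arithmetic.

# The synthetic community generator

## What it emulates

Each reference taxon (`make_taxon_profile()`) carries the generative truth
the downstream stages assume: a phylum with a taxon-specific 16S sequence, a
genetic code (11, or 25 where TGA is a sense codon), a target coding
density, the 56-gene universal single-copy marker complement, a probability
distribution over the 25 COG functional categories, an oxidoreductase (EC1)
annotation rate, electron-transport complex subunit complements, and
optional oxygen-reductase genes. `synthesize_genome()` lays these genes out
on both strands with i.i.d. uniform intergenic sequence; `sample_sag()`
models the partial genome recovery of single-cell sequencing by retaining
non-overlapping fragments covering a requested completeness fraction, and
models co-sorted wells by drawing fragments from two genomes into one
assembly. Truth records (sources, realized completeness, admixture) ride
along and are fully recoverable from the emitted FASTA/TSV files.

## Default conditions

The defaults are the study conditions the analyses are calibrated for, fixed
once:

* **Completeness ~ Uniform(0.06, 0.60)** (mean 33%). A cohort of 492 such
  assemblies cumulatively amounts to ~162 effective complete genomes, and a
  cohort of 81 to ~27 — the regime in which "absence of gene X across the
  cohort" becomes meaningful despite individual incompleteness.
* **Cohort mixture 16% Patescibacteria, 2% DPANN**, the remainder split
  between other bacteria and archaea.
* **Co-sort rate 2%.** The true in-situ rate is unknown; this is a free
  parameter of the generator, not an empirical estimate.
* **Style contrasts.** `patesci_like`/`dpann_like` taxa have no
  electron-transport complexes, no oxygen reductases, EC1 rate 0.01 (vs 0.05
  for `standard`), COG categories C/E/H/P depleted fivefold, small cell
  diameters (0.35 µm vs 0.8 µm), and — for `patesci_like` — a 30% chance of
  genetic code 25. `symbiont_like` lowers the coding-density mean to 0.85.
  Coding-density means are 0.91 (`patesci_like`), 0.90
  (`dpann_like`/`standard`), s.d. 0.02.
* **Genome lengths are desk-scaled** (75–100 kb rather than ~1 Mb) so that
  cohort-scale simulations run in seconds. Every downstream statistic is a
  fraction (densities, marker percentages, COG percentages, EC1 rates), so
  the scaling changes variances, not the quantities being tested; tests and
  power checks were sized accordingly.
* One global seed is split hierarchically per taxon/SAG (a hash of the seed
  and the entity id), so any subset of a community regenerates identically.

## What it does not emulate

No read-level simulation or assembler artifacts, no amplification bias, no
rRNA secondary structure or the 16S introns reported in some Patescibacteria,
no chimeras, and exactly one 16S copy per taxon. Intergenic sequence is
uniform-random, so spurious ORFs occur at the uniform-sequence rate —
real genomes have compositional structure the generator lacks. Passing tests
therefore demonstrate algorithmic correctness and statistical power under a
clean generative model, not robustness to every artifact of real SAG data.

# Co-sort detection

Two deliberately independent detectors:

* **Marker duplication.** `marker_census()` counts the 56 universal
  single-copy markers; completeness = % found, contamination = % of extra
  copies. A SAG with contamination ≥ 10% is flagged. This is a
  simplification of lineage-aware collocation estimates — the same threshold
  semantics on a simpler census — and on the generator, where single
  genomes are strictly single-copy, its false-positive rate is structurally
  near zero.
* **16S discordance.** A SAG carrying two 16S genes longer than 1,000 nt
  (classifier confidence ≥ 80, a conventional cutoff) with different
  phylum assignments is flagged. The 1,000 nt screening threshold and the
  1,200 nt ordination-eligibility threshold are distinct configuration keys.

`chisq_decomposition()` implements the Pearson chi-square test of
independence from the textbook formulas (no continuity correction), exposing
expected counts, Pearson residuals, and each cell's percent contribution
`100 r²/X²`. The p-value uses the chi-square distribution. Note the
asymptotic test is only calibrated when expected cell counts are moderate
(≥ 5 is the usual rule); cohort screens with very rare co-sorts in small
groups sit outside that regime, which is why the package's type-I
calibration checks use group sizes and rates that keep expected counts ≥ 5.

# Gene calling and code selection

`find_orfs()` is a deterministic longest-ORF caller: per strand and frame,
from the first ATG after the previous in-frame stop to the next in-frame
stop (stop included). Table 11 stops at TAA/TAG/TGA; table 25 stops only at
TAA/TAG. Codons containing N match nothing. This intentionally diverges from
probabilistic gene finders: no start scoring, no RBS motifs, ATG-only
starts, a fixed `min_orf_len` (default 90 nt for calling; 300 nt inside
`coding_density()`).

**Code selection needs a correction under this caller.** Removing TGA from
the stop set can only merge or extend ORFs, so on *any* sequence the
table-25 call total is at least the TAA/TAG-terminated table-11 total, and
in practice exceeds the full table-11 total: the five non-coding reading
frames and the intergenic sequence behave like uniform-random sequence, and
with fewer stop codons random reading frames yield longer ORFs. Measured on
synthetic genomes (40–100 kb, `min_orf_len` 300), the table-25/table-11
total ratio is 1.25–1.46 for true code-11 genomes and 3.3–6.7 for true
code-25 genomes (whose genes fragment catastrophically under table 11).
`coding_density()` therefore selects code 25 only when the table-25 total
exceeds `rt_factor` (default 2.0, between the two measured populations)
times the table-11 total; ties and everything below the factor select
table 11. Coding density is the chosen total divided by assembly length;
because totals are sums over calls in all six frames, densities above 1 are
possible and are flagged, never clipped.

# 16S detection and classification

Detection slides 200 nt windows (stride 100) along each contig and scores
the fraction of 16-mers shared with the reference panel; windows at or above
0.35 merge (gap tolerance 300 nt) and the merged region is trimmed to its
outermost matching 16-mers. Both strands are searched; minus-strand hits
report the reverse-complemented slice. With a panel of ~10⁴ 16-mers against
a 4¹⁶ space, random matches are vanishingly rare, and measured
false-positive rates on random contigs are zero.

Classification is the standard naive-Bayes word design: for each phylum,
`P(word) = (n_refs_containing_word + 0.5) / (n_refs + 1)`; the query's
distinct 8-mers vote by summed log-likelihood, and confidence is the percent
of 100 bootstrap subsamples (each ⌈W/8⌉ of the W distinct words) agreeing
with the full-set winner. The packaged reference database derives per-phylum
references at ~10% divergence from a common ancestor (~19% between phyla)
with three references per phylum at ~2% within-phylum divergence — ample
signal for 8-mers, as the self-classification and divergence-monotonicity
tests confirm. Only phylum-level labels are assigned.

# Respiratory profiling

* **KO rule.** A protein is a KEGG-ortholog hit when its profile score
  reaches 50% of the family's curated threshold (`apply_ko_rule()`, the
  fraction configurable). The HMM search itself is consumed as a score
  table, not reimplemented: the rule, not the engine, is the analysis.
* **Complex census.** Accepted hits map to respiratory complexes I–IV
  through a `complex_map`. The shipped default map is a small, clearly
  labeled configuration (canonical nuo/sdh/pet/cox-style subunit KOs with
  deterministic thresholds), not ground truth; real analyses should supply
  a curated map.
* **Oxygen reductases.** `detect_o2red()` runs affine-gap Smith–Waterman
  (BLOSUM62, gap open 11, extend 1; ties on score broken toward the longest
  traceback) of every query against a de-replicated reference set of
  oxygen-binding subunits, converts scores to Karlin–Altschul e-values
  (`E = K·m·n·e^(−λS)`, gapped BLOSUM62 constants λ = 0.267, K = 0.041),
  and accepts hits at e-value ≤ 1e-10. Family metadata carries the oxygen
  affinity class (heme-copper oxidase type A: low affinity; bd-ubiquinol:
  high). Hits longer than 400 aa form the tree-eligible subset; tree
  building itself is out of scope. The packaged reference peptides are
  synthetic stand-ins (deterministic random sequences), sufficient for the
  pipeline contract but carrying no biological signal.
* **EC1 fraction.** Oxidoreductase content is reported as
  `100 × EC1 proteins / all proteins`, which is robust to incompleteness
  and therefore comparable across assemblies of very different completeness.

# COG ordination and group tests

Profiles are percentages of assigned COGs per category (rows sum to 100);
genomes enter the ordination only with marker completeness ≥ 30% and a 16S
gene ≥ 1,200 nt. `ordinate_profiles()` performs classical scaling — the
eigen-decomposition of the centered Gram matrix — which for Euclidean
distances is exactly PCA of the centered matrix; the tests verify both the
Gower distance-reconstruction identity and agreement with `cmdscale` and
`prcomp`. Distances are Euclidean on the raw percentages by default (the
literal reading of ordinating relative abundances); a Hellinger option
exists for users who prefer composition-aware distances. The sign convention
(first nonzero loading of each axis positive) makes results reproducible
across runs and row permutations.

Group separation uses a two-sided rank-sum test per group pair: exact
enumeration of the midrank statistic when both groups have ≤ 8 members,
otherwise the tie-corrected normal approximation. On default cohorts the
C/E/H/P depletion places the depleted group on one side of PC1 with the
depleted categories loading toward the other side — the qualitative
parameter-recovery property asserted in the tests.

# Cohort reports

`pct()` rounds half away from zero (banker's rounding deliberately
rejected, so printed figures like 1.2% from 1/81 reproduce exactly).
`boxstats()` uses type-7 (linear interpolation) quartiles with whiskers at
Q1 − 1.5·IQR and Q3 + 1.5·IQR. `plate_abundance()` optionally subsamples
without replacement under a seed (no subsampling by default, depth
configurable). `cumulative_complete_genomes()` sums completeness fractions.
`cohort_summary()` ties these together per group; the effective-genome
column uses the first (sorted) source's completeness.

# Numerical choices and degenerate inputs

Chi-square decomposition refuses tables with zero margins (expected counts
undefined). Ordination zero-fills axes beyond the matrix rank with a
warning; eigenvalues are clipped at zero before square roots. Rank-sum
tests skip singleton groups with a warning. `marker_census()` warns on and
ignores ids outside the marker universe. Genome synthesis fails loudly when
the requested complements cannot fit the genome length, and the
coding-density draw is capped so the 16S gene always fits. Smith–Waterman
on an empty sequence scores 0 with alignment length 0.

# Problem sizes used by the test suite

The suite exercises: ORF-caller/oracle equivalence on 360 random sequences
of 300–3,000 nt; code-selection on 130 synthetic genomes; co-sort detector
sensitivity/false positives on 420 planted SAGs; chi-square type-I
calibration on 1,000 simulated null cohorts; ordination power on 50
simulated 40-vs-40 and 80-genome cohorts; and two full pipeline runs for
byte-identical determinism. These sizes were chosen to give tight Monte
Carlo error on every asserted bound while keeping the default test run fast.

# Known limitations

The ORF caller is a toy relative to probabilistic gene finders, and the
read-through correction factor is calibrated on the generator's
uniform-intergenic model; genomes with strongly biased composition would
need recalibration. The contamination estimate ignores lineage-specific
marker sets. The 16S machinery assumes intron-free genes and one copy per
genome. The packaged oxygen-reductase references are synthetic. The
chi-square decomposition inherits the asymptotic limits of the Pearson
test. None of the phylogenetic analyses (marker trees, oxygen-reductase
trees, transfer inference) are in scope.
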