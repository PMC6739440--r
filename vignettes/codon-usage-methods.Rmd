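---
title: "Methods: comparative codon usage and substitution asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative codon usage and substitution asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocodon)
```

# Scope and model

`orthocodon` implements a comparative analysis of codon usage across a set
of species for which only three kinds of inputs are needed: per-species
coding sequences (CDS), per-family protein alignments, and pairwise
protein similarity hit tables. The motivating biology is the observation,
in taxa whose genomes span a wide range of GC content (flatworms being a
dramatic example), that third-codon-position GC (GC3) varies far more than
GC at positions 1–2, reorganises species relationships when they are
clustered on synonymous codon usage, leaks into amino-acid composition,
and leaves a distinctive signature in orthologous substitution patterns:
non-synonymous codon pairs separated by **two** nucleotide changes are more
common than the single-step changes that would suffice — consistent with a
point mutation followed by a synonymous change restoring the genome's GC
bias (the *two-hit* mechanism).

The pipeline stages are:

1. **Orthology.** Reciprocal best hits (RBH) from 12-column tabular hit
   files at an e-value cutoff of `1e-5` (a hit exactly at the cutoff is
   kept). Core groups contain exactly one gene per species and are kept
   only when every species is represented.
2. **Codon alignments.** Protein alignments are back-translated against
   the validated CDS; any column with a gap in at least one species is
   removed; degapped families shorter than 35 residues are dropped
   (strictly: 35 survives, 34 does not); survivors are concatenated in
   ascending family id into one gap-free "super-sequence" per species.
3. **Composition.** Per gene and per species super-gene: codon counts, GC
   by codon position, relative synonymous codon usage (RSCU), Wright's
   effective number of codons (ENC), the mutation-pressure ENC
   expectation `2 + s + 29/(s^2 + (1-s)^2)`, the neutrality regression of
   GC12 on GC3, and per-codon correlations between RSCU and GC3 across
   genes.
4. **Clustering and expression.** Species are clustered on their dense
   super-gene RSCU vectors under a grid of hierarchical-clustering
   settings with a majority-rule consensus; genes are ordinated on codon
   frequencies (PCA, or correspondence analysis); *preferred* codons are
   those whose per-gene RSCU is significantly higher in the
   high-expression stratum than in the low one.
5. **Substitution analysis.** For ordered species pairs, asymmetric
   20×20 amino-acid and 61×61 codon count matrices over aligned
   positions; chi-square tests of usage deviation and of reciprocal
   asymmetry; classification of codon pairs as conserved / synonymous /
   non-synonymous; and the two-hit summary.

# Key definitions and conventions

**RSCU.** For codon $j$ of an amino acid with $k$ synonymous codons and
family counts $x$, $\mathrm{RSCU}_j = x_j / \bar{x}$. Methionine and
tryptophan are excluded (59 entries under the standard nuclear code).
Families with zero total are *missing*, never zero.

**ENC.** Wright's estimator. Per amino acid with $n \ge 2$ observations,
$F = (n\sum p_i^2 - 1)/(n-1)$; class means $\bar F_k$ are taken over
degeneracy classes ($k = 2, 3, 4, 6$) and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
When the three-fold class (isoleucine alone) is unobserved, $\bar F_3$ is
imputed as $(\bar F_2 + \bar F_4)/2$. The estimate is capped into
$[20, 61]$. These class-handling conventions follow standard practice for
the estimator; the boundary behaviour is exact:

```{r}
code <- genetic_code()
one_per_aa <- setNames(integer(61), code$sense_codons)
for (fam in code$families) one_per_aa[fam[1]] <- 10L
enc(one_per_aa)                                   # maximal bias
enc(setNames(rep(100L, 61), code$sense_codons))   # no bias, capped
```

**GC3 variant.** GC3 is computed over *all* sense codons, including Met
and Trp (simple and reproducible); `composition_profile(...,
gc3_synonymous = TRUE)` additionally reports the synonymous-family-only
variant, since published analyses are often silent about which they used.

**Chi-square tests.** Both substitution tests compare two observed counts
against their average as the expected value, df = 1, no continuity
correction. Cells with expected count below 5 are flagged `low_count` and
excluded from the default significant set — a standard validity guard.
Benjamini–Hochberg adjustment is applied across tests; raw p-values are
always reported alongside.

**Preferred codons.** The test is a two-sided Wilcoxon rank-sum on
per-gene RSCU between the strata (robust to the skewness of RSCU), BH
adjusted across the 59 codons; a chi-square mode on pooled family counts
is available as an alternative. Percentile boundaries are exclusive
(strictly above the 90th / strictly below the 10th percentile), genes
without expression values are excluded from percentile computation, and a
codon is preferred only when the high-stratum mean *exceeds* the low one:
a significant drop is never a preferred call. Because stratification is
percentile-based, calls are invariant under monotone transformations of
expression.

**Two-hit summary.** For each ordered amino-acid change $Z \to X$ and
each source codon $c$ of $Z$, the observed target codons of $X$ are split
into single-step (one nucleotide from $c$) versus multi-step ($\ge 2$).
The single-step-favouring baseline posits that the target is always a
minimal-distance codon of $X$ (ties split equally), so its multi-step
fraction is 0 whenever a one-step target exists. The reported *excess* is
the observed minus baseline multi-step fraction, aggregated over cells by
observation weight. This baseline is an operationalisation chosen for
this package: it is deliberately the most conservative "mutation takes
the shortest path" null, and it is exactly recoverable by the simulator
(below).

# Design decisions

- **Orthology strategy.** Whether core groups should be 22-way cliques or
  anchored on one species is genuinely open; both are implemented.
  `anchor` (first species alphabetically) is the default for $O(k)$
  scaling; `clique` additionally verifies every within-group pair and is
  the stricter choice. The strategy is recorded on the output.
  Determinism of best hits is guaranteed by the tie rule: lowest e-value,
  then highest bitscore, then lexicographically smallest subject id.
- **Concatenation order** is sorted family id — statistically inert but
  reproducibility demands a fixed order.
- **Ordination.** PCA on per-gene codon frequencies is the default;
  correspondence analysis on the count table is available (`mode =
  "coa"`), since both appear in practice for this figure type.
- **Clustering grid.** Euclidean distance crossed with complete, average
  and Ward linkage. The consensus is majority rule (> 50% of settings),
  with per-clade support frequencies written into the Newick output.
- **Amino-acid GC grouping.** Amino acids are scored by the mean GC
  fraction of their synonymous codons and split into tertiles by rank
  (7 / 6 / 7); ties break alphabetically by one-letter code. This places
  lysine (score 1/6) in the low group and alanine (5/6) and arginine
  (13/18) in the high group, with lysine strictly below arginine.
- **Terminal stop codons are trimmed** (and recorded), because all
  downstream statistics are defined over the 61 sense codons; any other
  deviation (internal stop, ambiguity code, ragged length) rejects the
  sequence with a structured reason rather than repairing it.

# The simulator: what it emulates, and how

`simulate_ortholog_set()` generates ortholog families whose statistical
structure matches what the analysis assumes: species-specific GC3
targets spanning a wide range (defaults 0.30–0.70, mirroring the spread
seen in compositionally diverse phyla), property-conservative amino-acid
divergence, occasional gap columns (partly private, partly shared), and
a tunable two-hit coupling `two_hit_theta`.

Three design choices matter and are deliberate:

- **Calibrated tilt.** Synonymous codons are sampled with a logit tilt on
  third-position G/C; the tilt is solved numerically per gene so the
  *expected* GC3 equals the species target. Unreachable targets (below
  the floor set by Met/Trp content) are rejected with the achievable
  range. Realized species GC3 lands within ±0.02 of the target at the
  default sizes, and is strictly monotone in the target.
- **Coupled sampling.** All per-site draws — the family inverse-CDF
  position, the substitution target, the tie-break — are shared between
  the ancestor and every species (common random numbers). Species with
  identical GC3 targets therefore carry *identical* codons wherever no
  substitution occurred; between-species differences reflect only
  substitution events and tilt differences, never independent synonymous
  noise. This is what makes the null for the two-hit analysis exact.
- **Substitutions are point mutations.** A site substitutes to an amino
  acid that is both property-similar (aliphatic / aromatic / polar /
  negative / positive groups) and reachable by a *single* nucleotide
  change from the ancestral codon. Sites with no such neighbour — Trp,
  notably — never substitute, which matches its empirical status as the
  most conserved residue. Under `two_hit_theta = 0` the derived codon is
  the point-mutation product itself, so every non-synonymous codon pair
  sits at distance 1 in both directions and the two-hit excess is
  *exactly zero*; under `theta > 0` the codon is re-equilibrated to the
  species tilt, producing the multi-step enrichment the analysis must
  detect. Allowing substitutions to arbitrary similar residues instead
  would bias the null upward, because minimal paths are not symmetric
  under the genetic code (a Ser→Cys change via TCA→TGT leaves AGT one
  step from TGT on the way back); the point-mutation constraint removes
  that artefact at the source rather than hiding it in the statistic.

The two-hit mechanism is implemented as an instantaneous re-sample, not a
temporal two-step process; this is sufficient to create (and calibrate)
the double-substitution excess the analysis targets.

**What the simulator does not emulate.** Evolution is pairwise-star
shaped (independent draws from one ancestor), with no tree structure, no
indel realism (gap columns are inserted, not evolved), no rate variation
across sites, no isochore structure, and no paralogy unless decoy hits
are requested. Passing tests on simulated data therefore validate the
*bookkeeping and statistics* of the pipeline and the detectability of the
planted effects — they do not certify inferences about any real genome.

# Problem sizes and numerical choices

The test suite exercises the pipeline at deliberately modest sizes chosen
to give each check clear statistical power: parameter-recovery and
clustering checks use 6 species × 100 families × ~300 codons; two-hit
calibration uses 50 null and 20 paired replicates of 2 species × 12
families; preferred-codon calibration uses 50 null replicates of 80 genes
and a planted-signal run of 200 genes. Oracle-equivalence checks (RSCU,
ENC, GC by position, both chi-square forms) run against independent
brute-force implementations on 100 randomized inputs at tolerance 1e-10.
Tolerances that are not exact are stated next to the property they check
(e.g. ±0.02 on realized GC3, from the binomial standard error at the
simulated sizes).

Floating-point guards worth knowing about: the inverse-CDF sampler pins
the final cumulative weight to 1; `enc()` returns missing (never an
error) when a required degeneracy class is absent after imputation;
correlation entries are missing under zero variance or fewer than three
informative genes.

# Limitations

- Counts are pairwise, as in the underlying figures: no ancestral
  reconstruction or phylogenetic correction is applied, so substitution
  direction is confounded between the two lineages of a pair.
- The two-hit baseline is intentionally extreme (always-minimal-path);
  its excess should be read comparatively (between pairs, against the
  simulator's null), not as an absolute rate.
- RBH orthology is a proxy; paralogy beyond decoy-level noise, gene loss
  and fusion are out of scope.
- The consensus-clustering grid is a documented default, not an attempt
  to reproduce any particular published grid.
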