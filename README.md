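# orthocodon

Comparative codon-usage and substitution-asymmetry analysis from
orthologous coding sequences.

`orthocodon` is for molecular evolutionists studying how mutational GC
bias and selection jointly shape coding sequences across a clade —
typically a set of species whose genomes span a wide range of GC content
(flatworms are the canonical example). Starting from per-species CDS
FASTA files, per-family protein alignments and pairwise BLAST-style hit
tables, it derives a core set of one-per-species orthologue groups,
builds gap-free codon alignments and concatenated per-species
super-sequences, and computes the field's standard compositional and
substitution statistics. A built-in simulator generates ortholog families
with known GC3 targets, expression-coupled codon preference and a tunable
two-hit signal, so the entire pipeline is testable without downloading a
single genome.

## What it computes

- **GC by codon position** — GC1, GC2, GC3 and GC12 = (GC1+GC2)/2, per
  gene and per species super-gene.
- **RSCU** — relative synonymous codon usage,
  RSCU_j = x_j / mean(x_family); 1 means unbiased use.
- **ENC** — Wright's effective number of codons,
  ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ with
  F = (n·Σp² − 1)/(n − 1) per amino acid, capped into [20, 61]; plus the
  mutation-pressure expectation ENC(s) = 2 + s + 29/(s² + (1−s)²).
- **Neutrality regression** — OLS of GC12 on GC3 across genes (or across
  species super-genes); slope near 1 is the mutation-driven limit, near 0
  indicates constrained positions 1–2.
- **RSCU consensus clustering** — hierarchical clustering of species RSCU
  vectors under a distance × linkage grid, majority-rule consensus with
  support values, exported as Newick.
- **Expression-stratified preferred codons** — codons whose per-gene RSCU
  is significantly higher above the 90th expression percentile than below
  the 10th (Wilcoxon rank-sum, Benjamini–Hochberg across codons), plus
  PCA / correspondence-analysis ordination of genes by codon frequency.
- **Asymmetric substitution matrices** — 20×20 amino-acid and 61×61 codon
  count matrices over aligned orthologous positions for each ordered
  species pair, with chi-square tests of usage deviation and reciprocal
  asymmetry (expected value = average of the two counts, df = 1),
  conserved / synonymous / non-synonymous classification, and a **two-hit
  summary** quantifying the excess of amino-acid changes realised through
  two or more nucleotide substitutions over a minimal-path baseline.

## Worked example

A four-species simulation whose GC3 targets span 0.30–0.70, run through
every stage:

```r
library(orthocodon)

cfg <- simulation_config(seed = 1, n_species = 4, n_cogs = 120,
                         protein_length = list(mean = 120, min = 40),
                         gc3_target = c(0.30, 0.40, 0.55, 0.70),
                         aa_sub_rate = 0.05, two_hit_theta = 0.5,
                         gap_rate = 0.06)
run_pipeline(pipeline_config(simulate = cfg), "demo_run")

read.delim("demo_run/composition_species.tsv")[, c("gc3", "gc12", "enc")]
#>     gc3  gc12    enc
#> 1 0.307 0.440 48.774
#> 2 0.403 0.438 56.120
#> 3 0.550 0.440 60.924
#> 4 0.697 0.440 54.779
```

Realized super-gene GC3 tracks each species' target to within a few
thousandths while GC12 stays flat near 0.44 — the classic signature of a
third-position mutational gradient with constrained positions 1–2 — and
ENC rises toward its ceiling of 61 as GC3 approaches 0.5 and falls off at
both compositional extremes.

```r
readLines("demo_run/rscu_consensus.nwk")
#> ((sp01,sp02)1.00,(sp03,sp04)1.00)1.00;
```

The RSCU consensus clustering splits the species exactly by GC3, with
full support across the clustering-settings grid.

```r
th <- read.delim("demo_run/two_hit_sp01__sp04.tsv")
sum(th$excess * th$n) / sum(th$n)
#> [1] 0.392

pref <- read.delim("demo_run/preferred_codons_sp01.tsv")
pref$codon[pref$preferred]
#> [1] "GCC"
```

The two-hit excess between the most GC-divergent pair is strongly
positive (39% of non-synonymous changes sit beyond the minimal mutational
path relative to a single-step baseline, the re-equilibration signature),
and the preferred-codon caller recovers exactly the codon the simulator
planted in high-expression genes (`GCC`), with no false calls.

`report("demo_run")` writes a single `report.md` summarising composition,
neutrality slopes, the consensus tree, preferred codons, significant
reciprocal asymmetries and two-hit excesses.

## Layout

- `R/` — genetic code and codon arithmetic, FASTA/TSV IO and CDS
  validation, RBH orthology, codon alignments and super-sequences,
  composition statistics, consensus clustering and expression analysis,
  substitution matrices and tests, the simulator, and the pipeline
  orchestrator (`run_pipeline()` / `report()`).
- `inst/scripts/run_pipeline.R` — thin command-line wrapper
  (`--config config.yaml --outdir dir --report`).
- `vignettes/codon-usage-methods.Rmd` — the methods notes: model,
  conventions, simulator design and limitations.
- `tests/testthat/` — unit, property and end-to-end suites, including
  brute-force oracle checks for every core statistic.
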