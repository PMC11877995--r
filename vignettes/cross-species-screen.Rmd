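---
title: "Reference-anchored cross-species co-expression screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored cross-species co-expression screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(orthoscreen)
```

## The problem and the model

Mouse and zebrafish are the two workhorse models of congenital craniofacial
disease, but their developmental timelines are not directly comparable:
mouse palatogenesis spans embryonic days E8.5–E13.5 while the homologous
zebrafish programme (formation of the ethmoid plate from cranial neural
crest) runs from the 20-somite stage to 72 hours post-fertilization. Rather
than aligning stages explicitly, the screen implemented here anchors both
species on a shared reference gene — Sox9 in mouse and its co-ortholog
sox9b in zebrafish, a master regulator of chondrogenesis whose expression
rises from the onset of neural crest development and plateaus once
cartilage primordium forms (around E11.5 and 48 hpf respectively).

For each gene $g$ in species $s$ the package builds a *stage profile*
$x_{g,s} = (x_{g,s,1}, \dots, x_{g,s,T_s})$: replicate-averaged, log2
normalized expression over the $T_s$ ordered stages. The screen statistic
is the within-species Pearson correlation with the reference profile,

$$ r_{g,s} = \mathrm{cor}\!\left(x_{g,s},\; x_{\mathrm{ref},s}\right), $$

and an ortholog pair $(g_A, g_B)$ is retained when $r_{g_A,A} > \tau$ *and*
$r_{g_B,B} > \tau$, with $\tau = 0.7$ by default. Correlation is never
computed across species — the two stage axes have different lengths (6 vs
5 under the default design) and no assumed correspondence; the reference
gene carries all the cross-species alignment. One-to-many ortholog pairs
(zebrafish retains many duplicated gene pairs, e.g. sox9a/sox9b for mouse
Sox9) are screened independently per pair, so a divergent duplicate can
fail while its sibling passes; a gene counts toward the passing list if
any of its pairs passes.

The passing species-A gene list is then tested for gene-set
over-representation. For a universe of $N$ genes, a set with $K$ members
in the universe and a query of $n$ genes overlapping the set in $k$, the
p-value is the hypergeometric upper tail $P(X \ge k)$, computed in log
space from log-binomial coefficients so it remains exact at genome scale.
Benjamini–Hochberg step-up adjustment controls the FDR across the tested
sets, with significance declared at adjusted values strictly below 0.05.

## Normalization choices

The expression scale is $\log_2(\mathrm{CPM} + 1)$:
`log2(count / library_total * 1e6 + pseudocount)` with pseudocount 1, a
standard choice for 3'-tag bulk RNA-seq counts. Because any per-sample
scale factor becomes an additive per-sample constant after the log, and
stage profiles are averages of those values, the choice of library-size
normalization has little leverage on a correlation-based screen; the
pseudocount is configurable. No between-sample normalization beyond
library-size scaling (no TMM or quantile) and no batch correction is
applied — the screen consumes count matrices as produced by quantification.

Replicate handling: correlations are computed on **per-stage means** by
default. The two species have very unequal replicate counts per stage
(29 mouse embryos at E9.5 vs 11 elsewhere; 8 zebrafish pools at 32 hpf vs
16 elsewhere), so correlating at the sample level would weight stages by
their replicate counts. An `all-samples` mode is provided for comparison
and recorded in the run summary.

Per-gene z-scaling across stages ("scaled log2 normalized expression") is
applied by default for display comparability. Pearson correlation is
invariant to per-gene affine transforms, so scaling never changes a screen
verdict — a property the test suite checks end-to-end. Genes whose profile
is constant across stages have no defined correlation; they are flagged,
fail the screen, and are counted in the run log rather than being assigned
$r = 0$.

The threshold is applied as a strict inequality ($r > \tau$), and $\tau$
is configurable. Records are reported sorted by $\min(r_A, r_B)$
descending, ties broken lexicographically, with undefined correlations
last.

## The simulator

`simulate_experiment()` generates truth-labelled data with the statistical
structure the screen assumes, at the study's design scale by default:

* **Stages and replicates.** Six mouse stages (E8.5–E13.5) with 11
  replicates each and 29 at E9.5; five zebrafish stages (20 ss, 24, 32,
  48, 72 hpf) with 16 pooled replicates each and 8 at 32 hpf.
* **Reference shape.** A linear ramp in log2 units from `ref_low = 3` to
  `ref_high = 7` that plateaus at the fourth stage (E11.5 / 48 hpf) — any
  monotone rise-then-plateau satisfies the biology; linear is the simplest.
  The 16-fold dynamic range is typical of a strongly stage-regulated
  transcription factor.
* **Planted pairs** share the reference shape in both species plus iid
  per-stage Gaussian noise of sd `profile_noise_sd = 0.4` log2 units.
  With the default ramp (across-stage variance $\approx 2.84$ in mouse),
  the expected true profile correlation is approximately
  $1/\sqrt{1 + 0.16/2.84} \approx 0.97$, i.e. the planted class is
  genuinely but not perfectly reference-correlated.
* **Null pairs** get per-stage log2 means drawn iid $N(5, 1.5^2)$,
  independently in the two species. Note this makes chance correlation a
  real phenomenon: with only 6 (or 5) stages, an individual null gene
  exceeds $r > 0.7$ against the reference in one species with probability
  around 6–9%, and in both species (independently) at roughly the product
  of those rates — which is exactly the calibration property the tests
  verify. It also means "perfect" recovery is only defined relative to the
  true profiles, not the class labels: very occasionally a null gene is
  truly correlated by construction.
* **Divergent paralog trios** map one species-A gene to two species-B
  genes: one tracks the reference shape, the other follows a reversed
  (falling) ramp, reproducing qualitatively the sox9b-passes/sox9a-fails
  behaviour that motivates per-pair screening.
* **Counts.** Per-sample library sizes are log-normal around
  `library_size_mean = 2e6` reads (sdlog 0.25; set
  `library_size_sdlog = 0` for fixed depth), so normalization is
  non-trivial. Given a sample at stage $t$ with library size $L$, gene
  counts are negative binomial with mean
  $\mu_g = L \cdot 2^{m_{g,t}} / \sum_h 2^{m_{h,t}}$ and size (inverse
  dispersion) parameter `dispersion = 5`, i.e.
  $\mathrm{Var} = \mu + \mu^2/5$ — moderate biological overdispersion for
  whole-embryo bulk RNA-seq. The parameterization is the mean/size one of
  `rnbinom`; the mean–variance relation is verified empirically in the
  tests at 10,000 draws per gene.

Identical configurations (including the seed) give byte-identical outputs.

What the simulator does **not** emulate: read-level artefacts (3' bias,
UMI structure, mapping ambiguity), correlated noise across genes
(co-regulation beyond the planted module), stage-dependent dispersion, or
ortholog-mapping errors. Passing tests therefore demonstrate that the
screen's statistics behave as designed under its own assumptions, not that
the biological screen on real data is free of those upstream effects.

## Design decisions where the design was open

* **Ortholog pairing.** Name-based pairing matches symbols
  case-insensitively and also pairs a species-A symbol with species-B
  symbols extended by a single "a" or "b" (the zebrafish duplicate-gene
  convention), yielding one-to-many pairs. An externally supplied pair
  table can be passed instead and is validated, with rows referencing
  absent genes dropped and counted.
* **Enrichment universe.** Defaults to all species-A genes appearing in
  the ortholog map — the population the screen actually drew from.
  An `all` policy (every gene in the count matrix) is available.
* **Set-size filters** default to 10–500 members within the universe,
  the conventional range for over-representation analysis.
* **BH subtlety.** Step-up adjusted values are not monotone under removal
  of an arbitrary competing set: removing a *small*-p competitor shifts
  ranks and can raise another set's adjusted value. Removing the weakest
  (largest-p) competitor never does, and that is the monotonicity property
  the tests assert.
* **Degenerate inputs.** Samples with zero total counts, declared stages
  with no samples, reference genes missing from a profile matrix, and
  malformed tables all raise errors naming the offending sample, stage,
  gene or column; constant genes and out-of-universe query genes are
  non-fatal and logged.

## Problem sizes used by the test suite

Unit tests run on small designs (3 replicates per stage, tens of genes).
The statistical acceptance checks run at the design scale the package
defaults to: 950 null + 50 planted pairs over 84 mouse and 72 zebrafish
samples, aggregated over 20 simulation seeds for recovery/calibration and
10 seeds for the enrichment construction; the hypergeometric tail is
checked against exhaustive enumeration of every urn with up to 12 genes,
and the correlation and BH implementations against independent reference
evaluations on 1,000 random inputs each. A full `devtools::test()` run
takes about half a minute on one CPU.

## A worked run

```{r example, eval = FALSE}
cfg <- list(
  sim = list(n_null_genes = 950, n_planted_genes = 50,
             n_divergent_paralogs = 1),
  out_dir = "run1", seed = 1
)
summary <- run_pipeline(cfg)
summary
```

The run directory contains the simulated inputs (`sim/`), stage profiles,
the screen table (`screen.tsv`: gene_a, gene_b, r_a, r_b, pass flags), the
enrichment table when a GMT is configured, and `run_summary.json` echoing
the configuration, seed and all stage counts and warnings — the screen is
sensitive to exactly the provenance (normalization dialect, replicate
handling, universe choice) that is usually left unstated, so every run
records it.

## Known limitations

* Name-based orthology is a heuristic; it inherits every inconsistency of
  cross-species gene nomenclature and finds no orthologs whose symbols
  diverged. Use a curated pair table where one exists.
* With 5–6 stage points, Pearson correlation has large sampling
  variance; the screen is a coarse filter, not an effect-size estimate,
  and the null false-pass rate at $\tau = 0.7$ is a few per mille per
  pair even under independence.
* Gene sets are taken as given (pre-propagated GMT); no ontology DAG
  handling or term-similarity collapsing is performed.
* Spearman correlation is available as a logged option but the screen's
  calibration properties are only characterized for Pearson.
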