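---
title: "Profiling gut-microbiome LPS acylation capacity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling gut-microbiome LPS acylation capacity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpsacyl)
```

## The scientific problem

Lipopolysaccharide (LPS) is the outer-membrane glycolipid of Gram-negative
bacteria; its lipid A moiety is the ligand of human TLR4. How strongly lipid A
activates TLR4 depends on its acylation state: hexa-acylated lipid A is a
potent agonist, while penta- and tetra-acylated forms are weak agonists or
antagonists. In patients receiving anti-PD-1 immunotherapy, the balance of
hexa- versus penta-acylated LPS encoded by the gut microbiome is a candidate
determinant of clinical response, so a taxonomic census of "Gram-negative
bacteria" is not informative enough — what matters is which *acylation
machinery* the community encodes.

`lpsacyl` implements that functional readout as a reusable pipeline:

1. **Rule-based structure prediction.** Each bacterial species' pangenome
   gene-frequency row is thresholded into an encoded gene set, and a small
   rule engine over the lipid A biosynthesis (*lpx*) pathway assigns an LPS
   category.
2. **Quantification.** Gene- and taxon-level count matrices are normalized
   (GCPM, CPM, CLR), filtered, and summarized into hexa:penta taxa ratios and
   *lpxM*:*lpxL* gene ratios.
3. **Functional enterotyping.** Samples are clustered on their functional
   profiles with the square-root Jensen–Shannon distance and partitioning
   around medoids (PAM), the cluster number chosen by a Calinski–Harabasz
   index; between-class analysis and PCoA support the clustering.
4. **Association testing.** Mann–Whitney, Kruskal–Wallis with Dunn/Bonferroni
   post hoc, pooled two-proportion Z-tests (no continuity correction), NMDS
   ordination with restart-based convergence, and t-tests on ordination axes.
5. **A synthetic cohort generator** with planted, recoverable effects, so the
   whole chain can be validated against known ground truth.

## Structure prediction rules

A gene counts as encoded by a species when it is present in **at least 50%**
of the genomes of that species' pangenome (the comparison is inclusive, so a
frequency of exactly 0.5 passes). When two annotation evidence channels are
available, a species encodes a gene if *at least one* channel says so
(`pmax`), with one exception: `lpxM` calls are taken from schema A alone,
because the second schema systematically over-calls this gene in taxa known
not to encode it.

The classification itself:

* `lpxA, lpxB, lpxC, lpxD, lpxK` all encoded → the species can build lipid
  IVA and counts as an **LPS producer**;
* additionally `waaA` (`kdtA`) → **KDO2**-lipid IVA;
* producer with `lpxL` and `lpxM` and/or `lpxJ` → **hexa**-acylated (the
  routes record which acyl-transferase(s); a species carrying both is counted
  once in hexa totals but appears in both route-specific tallies);
* producer with `lpxL` only → **penta**;
* producer without `lpxL` → **tetra**;
* anything else → **none**.

Two deliberate choices here. First, `lpxH` appears in the backbone operon and
is accepted in the vocabulary, but it is *not* required by the rule: the
operational five-gene backbone definition is what the published taxon counts
are built on, and we follow it. Second, the lipid A modification genes
(`lpxE`, `lpxF`, `pagL`, `pagP`) are carried through annotation and reporting
but never alter the acylation class; the class is a statement about acyl-chain
count, not about downstream modification. Taxa absent from the pangenome
catalogue are conservatively treated as non-producers and counted in a
message.

The rule engine is validated exhaustively: the test suite compares it against
an independently written truth table on all $2^{10}$ subsets of the core
vocabulary, so the classifier is exact by construction, not by sampling.

## Normalizations

For single-cohort gene abundance we use **GCPM** (gene count per million),

$$\mathrm{GCPM}_i = \frac{q_i / l_i}{\sum_j q_j / l_j} \times 10^6,$$

with $q_i$ raw mapped reads and $l_i$ gene length in bp, so samples are
comparable across sequencing depth and genes across length. For pooled
multi-batch analyses, counts are first passed through a light batch
adjustment (below) and scaled as **CPM**, $A_i / \sum A \times 10^6$. Both
scalings force per-sample sums of $10^6$, which the tests assert to relative
$10^{-6}$ on random matrices.

One wrinkle deserves a note. The narrative description of the pooled pipeline
("log-transform, add a pseudocount of $10^{-6}$, then scale to CPM") cannot be
executed literally: the log of a zero count is undefined, and once counts are
on the log scale their per-sample sums are sign-indefinite, so the printed CPM
formula no longer has its sum-to-$10^6$ meaning. We therefore apply the
printed CPM formula to the batch-adjusted counts by default, and expose
`method = "cpm_pseudolog"` to apply the pseudocount log *after* scaling when a
variance-stabilized version is wanted. The pseudocount is always added before
the log (`log(A + 10^{-6})`), and the natural logarithm is used everywhere a
base is unstated, consistent with the JSD convention below.

**CLR** (centred log-ratio) uses deterministic multiplicative zero
replacement: zeros in a sample are replaced by half that sample's smallest
nonzero value before closing and logging. Per-sample CLR values sum to zero
to $10^{-9}$.

Filters mirror the study design: features detected in fewer than five samples
are dropped (a feature seen in exactly five is kept), and samples in which a
quantity is undetected (zero, or an undefined ratio with a zero denominator)
are excluded from group summaries, with the exclusion count reported.

The batch adjustment is deliberately minimal plumbing, not a re-implementation
of published batch-correction methods: for each feature, every batch's counts
are rescaled multiplicatively so the batch's median log nonzero count matches
the feature's global median. Zeros stay zero, a single batch is the identity,
a constructed constant log-shift between batches is removed exactly, and
singleton batches are left alone with a warning.

## Enterotyping

Distances between samples are $\sqrt{\mathrm{JSD}}$ with
$\mathrm{JSD}(a,b) = \tfrac12 KL(a\|m) + \tfrac12 KL(b\|m)$, $m = (a+b)/2$,
natural log. The square-root form is a true metric bounded by
$\sqrt{\ln 2}$; the tests verify the bound, symmetry and the triangle
inequality on 1,000 random triples. Plain JSD is available by flag.

Clustering is k-medoids. For instances with at most 2,000 candidate medoid
sets the optimum is found by exact enumeration (deterministic, lexicographic
tie-breaking); larger instances use the classical BUILD phase followed by
best-improvement SWAP exchanges. The enumeration shortcut exists because
BUILD+SWAP is a local search: on a few percent of small random instances both
our SWAP and the canonical reference implementation stall in a local optimum
that exhaustive search exposes. At enterotyping scale (dozens to hundreds of
samples, $k \le 6$) the SWAP route is used and is deterministic without any
seed.

The number of clusters is chosen by the Calinski–Harabasz index computed
directly from distances via the Huygens identity
($W_C = \sum_{i<j \in C} d_{ij}^2 / |C|$), since JSD space has no
coordinates; ties prefer the smaller $k$. CH computed this way is checked
against the explicit centroid formula on Euclidean embeddings. Between-class
analysis centres profiles per feature (covariance, not correlation, scaling),
eigen-decomposes the size-weighted between-class covariance, and reports the
between-to-total inertia ratio; the tests calibrate that ratio against a
permutation null. PCoA is classical scaling; axes with non-positive
eigenvalues are dropped and eigenvalues reported.

## Association statistics

* **Mann–Whitney**: exact enumeration of all rank assignments when both
  groups have ≤ 8 observations (midranks handle ties), otherwise the
  tie-corrected normal approximation without continuity correction — which
  also makes the two-group Kruskal–Wallis p value agree with it
  asymptotically. The approximation is checked against a $10^5$-permutation
  oracle.
* **Kruskal–Wallis** (tie-corrected, chi-square reference) with **Dunn post
  hoc** z tests from pooled midranks. The pairwise p values are
  family-wise-adjusted with Bonferroni: the cited convention pairs Dunn with
  Bonferroni, and although one source text calls this a "false discovery
  rate" correction, Bonferroni is a FWER method — we implement Bonferroni and
  note the wording conflict here.
* **Two-proportion Z-test**: pooled standard error, no continuity
  correction, one-tailed by default. When comparing responder proportions
  between enterotypes the test is run one-tailed in the direction of the
  observed difference (the screening convention); treat those p values as
  descriptive rather than strictly calibrated. Degenerate pooled proportions
  (0 or 1) return p = 1 with a warning.
* **NMDS**: Kruskal stress-1 via `vegan::monoMDS`, first restart initialized
  from PCoA, the rest from random Gaussian configurations; up to
  `n_restarts` (default 1,000) restarts, stopping early once the symmetric
  Procrustes RMSE between the two best solutions falls below $10^{-4}$ —
  "iterate, or the best solution achieved". The best stress is non-increasing
  in the number of restarts under a shared seed stream, and the solution is
  deterministic given the seed.
* **Axis t-tests**: two-tailed pooled-variance t on ordination coordinates
  between responders and non-responders.

## What the synthetic cohort emulates — and what it does not

The generator plants a two-arm (responder/non-responder) cohort across study
batches with known ground truth at every level:

| parameter | default | rationale |
|---|---|---|
| `category_mix` | non-LPS 0.706, tetra 0.036, penta 0.179, hexa-lpxM 0.042, hexa-lpxJ 0.037 | the observed split of ~3,000 gut species into 884 LPS producers (107 tetra / 538 penta / 127 + 112 hexa) |
| `hexa_fold_responder` | 2 | hexa:penta ratios roughly double in responders |
| `total_lps_fold_nonresponder` | 1.3 | total LPS-encoding load is elevated in non-responders; magnitude unreported, chosen once as a modest effect |
| `batch_sd` | 0.3 | log-multiplicative per-(batch, species) effects of the size batch correction is meant to absorb |
| `dispersion` | 0.005 | Dirichlet-multinomial total concentration 200: visibly overdispersed counts without swamping the planted folds |
| `depth` | 1e5 | genus-level classified reads per sample at desk scale |
| `n_background_kos` | 30 | non-LPS gene families so LPS genes occupy a minority of the per-million scale, as in real KO profiles |
| `annotation_flip_rate` | 0.02 | per-channel annotation disagreement; schema A `lpxM` exempt, mirroring the curated channel |

Base abundances are log-normal (meanlog 0, sdlog 1) per species — heavy
tailed like real communities — and shared across samples; batch effects are
log-additive N(0, `batch_sd`²) per (batch, species); taxa counts are
Dirichlet-multinomial; gene counts are Poisson around abundance × presence ×
length, scaled to depth. Category assignment uses largest-remainder
apportionment so planted tallies are exact. All generators are pure functions
of (config, seed): they neither read nor perturb the global RNG state.

What passing tests on this cohort *show*: the rule engine, normalization
identities, ratio contrasts, clustering, and test calibration behave
correctly on data with the study's structure (planted fold recovered within
10% at 50 samples/arm over 100 seeds; null rejection ≤ 7%; three planted
functional clusters recovered with ARI ≥ 0.9 and k = 3 selected in ≥ 90% of
seeds). What they *do not* show: behaviour under real-world annotation bias,
strain-level variation, compositional interactions between hundreds of taxa,
or read-level artefacts — the generator emits no sequences, and no claim is
made that the synthetic cohort reproduces any published cohort's numbers,
which derive from ~112 external patient metagenomes and versioned external
databases.

Validation problem sizes were chosen for a laptop-class single core: default
cohorts of 150 species × 100 samples, 100-seed Monte-Carlo loops for
recovery properties, 20–50 seeds for the heavier end-to-end checks, and 100
NMDS restarts in the orchestrated run (the restart cap is configurable; the
convergence check usually stops far earlier).

## Numerical and degenerate-input conventions

* Threshold comparisons are inclusive (`>= 0.5`; "at least 50%").
* Undefined ratios (zero denominator) are flagged, excluded from summaries,
  and counted — mirroring zero-sample exclusion.
* All-zero samples are errors that name the sample; unknown gene names are
  errors that list the names; missing gene lengths name the gene.
* PAM ties break to the lowest sample index / lexicographically smallest
  medoid set; CH ties to the smaller k; all-equal distance matrices are
  rejected as non-informative rather than clustered arbitrarily.
* The orchestrated run (`run_all`) derives per-stage seeds from the single
  master seed by fixed offsets and writes a manifest with config hash and
  per-file checksums; two runs with the same config are byte-identical.

## Known limitations

* The enterotype Z-tests condition on clusters derived from the same data;
  their p values are descriptive, as in the source methodology.
* The batch adjustment is a median-matching stand-in; it removes
  feature-wise multiplicative shifts but not interaction or library-prep
  effects that dedicated tools model.
* Classification treats the pangenome threshold as crisp; species near 50%
  gene frequency flip categories under annotation noise, which the
  `annotation_flip_rate` parameter lets you stress.
* GCPM/CPM remain compositional; the CLR view is provided for analyses where
  that matters, but no attempt is made to resolve absolute abundances
  (except via the faecal-weight normalization, when pellet weights exist).

## A minimal session

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
manifest <- run_all(cfg, "pipeline-out")

# or piecewise:
co <- simulate_cohort(simulation_config(seed = 1))
calls <- classify_pangenome(co$pangenome)
tally_lps_categories(calls)
ab <- category_abundance(co$taxa, calls)
hp <- hexa_penta_ratio(ab)
arm <- setNames(co$metadata$response, co$metadata$sample_id)
mann_whitney(hp$ratio[arm[hp$sample_id] == "R"],
             hp$ratio[arm[hp$sample_id] == "NR"])
```
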