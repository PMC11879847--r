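# lpsacyl

Functional profiling of gut-microbiome lipopolysaccharide (LPS) acylation
capacity from metagenomic count data.

## What it is for

The lipid A moiety of LPS activates human TLR4, but how strongly depends on
its acylation: hexa-acylated lipid A is a potent agonist while penta- and
tetra-acylated forms are weak agonists or antagonists. In cohorts of patients
treated with anti-PD-1 immunotherapy, the *ratio* of hexa- to penta-acylated
LPS encoded by the gut community — not the overall load of Gram-negative
bacteria — is a candidate correlate of clinical response. `lpsacyl` is for
microbiome researchers who want that functional readout from standard
metagenomic inputs: species pangenome gene-frequency tables, per-sample gene
(KEGG-ortholog) count tables with gene lengths, taxonomic read-count
profiles, and sample metadata.

## What it computes

**Structure prediction.** A species encodes a gene when it is present in at
least 50% of its pangenome's genomes (two annotation channels are merged by
union, except *lpxM*, which trusts only the curated channel). The rule set
over the lipid A pathway then assigns a category:

- *lpxA, lpxB, lpxC, lpxD, lpxK* ⊆ genes → lipid IVA producer ("LPS-encoding");
- plus *waaA* → KDO2–lipid IVA;
- plus *lpxL* and (*lpxM* or *lpxJ*) → **hexa**-acylated (routes recorded);
- plus *lpxL* alone → **penta**; producer without *lpxL* → **tetra**.

**Quantification.** Gene count per million with length correction,
GCPM_i = (q_i/l_i) / Σ_j(q_j/l_j) × 10⁶; CPM on batch-adjusted counts;
centred log-ratio with deterministic zero replacement; the <5-sample feature
filter and zero-sample exclusions; per-sample hexa:penta taxa ratios and
*lpxM*:*lpxL* gene ratios.

**Functional enterotyping.** Square-root Jensen–Shannon distances, k-medoids
(PAM; exact enumeration on small instances, BUILD + best-improvement SWAP
above), cluster number by a distance-based Calinski–Harabasz index,
between-class analysis and PCoA.

**Association tests.** Mann–Whitney (exact for small groups, tie-corrected
normal otherwise), Kruskal–Wallis with Dunn/Bonferroni post hoc, pooled
two-proportion Z-tests without continuity correction, NMDS (Kruskal stress-1,
restarts with a Procrustes convergence check), and t-tests on ordination
axes.

**Synthetic cohorts.** A generator that plants known LPS category mixes,
responder/non-responder fold effects, batch effects and overdispersed count
noise, so every stage of the pipeline can be validated against ground truth.
See the methods vignette (`vignettes/lps-acylation-pipeline.Rmd`) for the
model, parameter defaults and their rationale.

## Worked example

```r
library(lpsacyl)

co    <- simulate_cohort(simulation_config(seed = 1))   # 150 species, 100 samples
calls <- classify_pangenome(co$pangenome)
unlist(tally_lps_categories(calls))
#>   n_species encodes_lps        kdo2       tetra       penta        hexa
#>         150          44          44           5          27          12
#>   hexa_lpxM   hexa_lpxJ
#>           6           6

ab  <- category_abundance(co$taxa, calls)   # fractions of classified reads
hp  <- hexa_penta_ratio(ab)                 # per-sample hexa:penta taxa ratio
arm <- setNames(co$metadata$response, co$metadata$sample_id)
r   <- hp$ratio[hp$defined & arm[hp$sample_id] == "R"]
nr  <- hp$ratio[hp$defined & arm[hp$sample_id] == "NR"]
round(c(R = mean(r), NR = mean(nr), contrast = mean(r) / mean(nr)), 3)
#>        R       NR contrast
#>    1.823    0.887    2.055

mann_whitney(r, nr)
#> Mann-Whitney (normal approximation): statistic = 2421, p = 6.878e-16 (two-tailed)
```

The tallies say 44 of 150 species encode LPS, split into 5 tetra-, 27 penta-
and 12 hexa-acylated producers. The responder arm's mean hexa:penta ratio is
about twice the non-responder arm's — recovering the two-fold enrichment the
generator planted — and the Mann–Whitney test finds the difference decisively
at n = 50 per arm.

The whole chain (simulate → classify → quantify → enterotype → associate)
runs with one call and writes plain-text outputs plus a checksummed manifest:

```r
manifest <- run_all(pipeline_config(seed = 1), "pipeline-out")
```

A thin command-line wrapper with `simulate | classify | quantify |
enterotype | associate | run-all` subcommands lives in
`inst/scripts/lps-pipeline.R`.

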