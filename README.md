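# ligevol

Evolutionary analysis of protein–ligand binding sites in one-to-one
primate orthologs.

Most protein function happens at interaction interfaces, so the
residues that contact DNA, RNA, small molecules, ions and peptides are
prime candidates for both strong conservation and, where they do vary,
functionally consequential change. `ligevol` implements the full
comparative pipeline for studying these sites across a fixed primate
phylogeny:

1. **Interface annotation** — per-match-state binding frequencies `f`
   and cross-validation precisions `p` from domain binding profiles
   classify each domain position (*binding* iff `f ≥ 0.10` and
   `p ≥ 0.50`, ions `p ≥ 0.75`; *non-binding* iff `f = 0`; otherwise
   *excluded*), and the labels are transferred through domain matches
   onto human-anchored alignment columns.
2. **Alignment QC** — Needleman–Wunsch global alignment of each species
   against human (BLOSUM62, gap open 10 / extend 0.5); sequences are
   dropped at similarity < 80% or gaps > 10%, or when domain match
   states are shifted; orthogroups keep ≥ 10 sequences or are rejected.
3. **Per-site metrics** — column Shannon entropy
   `H = −Σ q_a ln q_a` (gaps excluded) and a per-site ML evolutionary
   rate: the multiplier `r ∈ [10⁻⁶, 20]` scaling all branch lengths of
   the fixed species tree that maximises the Felsenstein-pruning
   likelihood under an empirical amino-acid model (JTT by default,
   WAG/LG available), grid-then-refine optimisation, rates normalised
   to mean one per orthogroup.
4. **Comparative statistics** — conservation tables by site class;
   two-sided Fisher's exact tests (log-space, million-count-safe);
   Mann–Whitney U on rates and entropies; Kruskal–Wallis across ligand
   types with Conover–Iman post-hoc comparisons, Bonferroni-adjusted
   and directional.
5. **Fixed-site scans** — binding columns where human (or the great-ape
   clade) carries one residue against a fixed (strict) or merely
   non-overlapping (relaxed) background, filtered against population
   variants (allele frequency ≤ 0.01 passes, disease-flagged fails).
6. **Enrichment** — genes with population-rare variable binding sites,
   per-gene fold enrichment of interface variability
   (`(variable binding/binding) ÷ (variable in-domain background /
   in-domain background)`, qualifying at ≥ 2-fold with ≥ 2 variable
   sites), and hypergeometric GO over-representation with BH FDR.
7. **Synthetic data** — `simulateStudy()` evolves orthogroups along the
   packaged 18-primate synthetic tree with known per-site rates
   (gamma(1), binding sites slowed by a 0.5 multiplier), plants
   human-specific substitutions and GO enrichment, and emits matching
   variant/annotation tables, so every stage can be validated against
   ground truth.

## Worked example

```r
library(ligevol)

cfg <- pipelineConfig(
  simConfig = simulationConfig(n_orthogroups = 6,
                               n_planted_human_specific = 3, seed = 42),
  seed = 42)
res <- runPipeline(cfg)

res$conservation
#>                        class n_sites n_conserved percent_conserved
#> 1                other_sites     691         343             49.64
#> 2 other_sites_within_domains     280         136             48.57
#> 3             ligand_binding     164         105             64.02
#> 4                        DNA      72          50             69.44
#> 5                        RNA      14          11             78.57
#> 6             small_molecule      63          38             60.32
#> 7                        ion      21           9             42.86
#> 8                    peptide       0           0                NA

res$tests$fisher_binding_vs_within   # 0.00163
res$tests$mwu_rate                   # 0.0388
res$tests$mwu_entropy                # 0.000557

res$scans$human_strict
#>    gene column human_position   ligand_types focal_residue background_residues
#> 1 G0001     18             18        DNA,ion             E                   G
#> 2 G0002     43             43            DNA             E                   Y
#> 3 G0003     45             45 small_molecule             T                   F
#>           mode population_pass reason
#> 1 human_strict            TRUE
#> 2 human_strict            TRUE
#> 3 human_strict            TRUE
```

Reading the output: binding sites in this small simulated study are
fully conserved at 64% against 49% for in-domain background sites —
the planted constraint (binding sites evolve at half speed) shows up in
the conservation table, the Fisher test on that 2×2 contrast
(p ≈ 0.002) and the rank tests on rates and entropies. The strict
human scan recovers exactly the three planted human-specific
binding-site substitutions, and all three pass the population filter
because planted sites only ever receive rare, non-disease variants.

On real data, replace the synthetic study with file inputs
(`pipelineConfig(synthetic = FALSE, msaDir = ..., treeFile = ...,
profilesFile = ..., matchesFile = ..., variantsFile = ..., goFile =
...)`); formats are aligned FASTA, Newick and tab-separated tables as
documented in `?readBindingProfiles` and friends.

## Package layout

S4 classes (`PrimatePhylogeny`, `SubstitutionModel`, `Orthogroup`,
`SiteAnnotationTable`, `SiteMetrics`) carry the central objects;
`vignettes/ligand-site-evolution.Rmd` documents the models, thresholds,
design decisions and limitations in detail.
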