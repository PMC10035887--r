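---
title: "Quantifying the evolution of protein-ligand binding sites across primates"
author: "ligevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the evolution of protein-ligand binding sites across primates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligevol)
```

## The analysis

Proteins act through their interactions, so the amino-acid positions
that contact DNA, RNA, small molecules, ions and peptides are where
sequence change is most likely to matter. `ligevol` implements a
comparative pipeline for one-to-one orthologs across a fixed primate
phylogeny: it transfers domain-level ligand-binding annotations onto
human-anchored multiple sequence alignments, filters orthogroups for
alignment quality, quantifies per-column conservation with Shannon
entropy and per-site maximum-likelihood (ML) evolutionary rates,
compares site classes with nonparametric statistics, scans for
lineage-specific fixed binding-site residues filtered against human
population variation, and tests genes with variable interfaces for
functional over-representation.

Every stage can also be run against a synthetic study with complete
ground truth, which is how the package validates itself.

## Site classification

Domain binding profiles give, for each (domain, ligand type) pair and
each match state, a *binding frequency* `f` — the fraction of co-complex
structures in which the position contacts the ligand — and a
per-(domain, ligand) *cross-validation precision* `p`. A match state is

* **binding** when `f >= 0.10` and `p >= 0.50` (`p >= 0.75` for ions,
  whose coordination geometry inflates false positives),
* **non-binding** when `f == 0`,
* **excluded** otherwise (observed in contact too rarely, or from an
  unreliable profile); excluded positions take no part in any
  comparison.

Labels transfer through domain matches onto human sequence positions.
Where overlapping matches disagree, precedence is
`ligand_binding > excluded > non_binding`: a position observed in
contact with any ligand in any structure is a binding site. Multi-ligand
positions keep the union of their ligand types; they count once in the
pooled binding class and once per ligand in per-ligand analyses.
Positions covered by no match are `other_outside_domain`; non-binding
domain positions are `other_within_domain`. "Other sites" is the union
of the last two. Columns where the human sequence has a gap are
`unannotated`. All coordinates are 1-based; columns index the MSA,
positions the ungapped human sequence.

The in-domain background (`other_within_domain`) is the comparison set
used throughout: domains are functional units under their own
constraint, so comparing binding sites against it separates
interface-specific constraint from domain-level constraint.

## Alignment quality control

Each non-human sequence is globally aligned to the human sequence
(Needleman–Wunsch under BLOSUM62, affine gap penalties 10 open / 0.5
extend — the EMBOSS Needle defaults, via `Biostrings`). *Similarity* is
the percentage of aligned pairs that are identical or biochemically
conservative (positive BLOSUM62 score); *gaps* is the percentage of gap
columns. Both use the full alignment length as denominator. A sequence
is removed when similarity `< 80` **or** gaps `> 10` (the removal rule
is disjunctive; the 80% threshold is inclusive, i.e. exactly 80 passes —
a choice worth revisiting in sensitivity analyses, exposed as the
`minSimilarity` argument).

The match-state check guards the annotation transfer itself: within any
human domain span, a species fails if the whole span is deleted or if it
has an internal gap (a gap with residues on both sides inside the span),
both of which shift homology between match states. Gaps at span edges or
outside domains are tolerated. This operationalisation is a declared
reconstruction — the criterion is usually stated only informally — and
is deliberately conservative.

Orthogroups keep at least 10 surviving sequences (human always counts)
or are rejected outright. Filtering is idempotent.

## Per-site conservation metrics

**Entropy.** `H = -sum(q_a log q_a)` over amino-acid frequencies among
non-gap residues, in nats, so `H` lies in `[0, log 20]`. No sliding
window, no gap penalty: gaps are simply left out of the frequencies. A
column is *conserved* iff exactly one distinct residue occurs
(equivalently `H == 0`), *variable* otherwise.

**ML evolutionary rate.** Each column gets a rate multiplier `r` scaling
all branch lengths of the fixed species tree under an empirical
amino-acid model: the likelihood is computed by Felsenstein pruning with
transition matrices `P(t) = exp(Q r t)` and the root weighted by the
stationary frequencies. The default model is JTT (the traditional
default of per-site rate programs); WAG and LG are available, and
stationary frequencies can be overridden. Rate matrices are built from
the published exchangeabilities, normalised to one expected substitution
per unit branch length, and eigendecomposed once through the
`sqrt(pi)`-symmetrisation, which makes evaluating a whole vector of
candidate rates in one pruning pass cheap — the package's optimiser
relies on this.

`r` is maximised over `[1e-6, 20]` by a 17-point log-spaced grid
followed by bounded scalar refinement (tolerance `1e-6`) inside the
bracketing grid interval; the bounds comfortably bracket realistic
per-site multipliers on a tree of this depth. Invariant columns return
the lower bound directly (their likelihood increases monotonically as
`r` decreases), and so do columns with fewer than two residues. These
are ML point estimates, not empirical-Bayes posterior means. Gap species
are removed by pruning the tree, which for a reversible model equals
treating them as missing data. The implementation is verified against
exhaustive enumeration over internal-node states on 4-leaf trees
(agreement to `1e-10`), a 10,000-point dense-grid oracle (ML rates to
`1e-3`), closed forms for one- and two-leaf trees, and an independent
phylogenetics library.

**Normalisation.** Per-site rate programs differ in output scale (raw
multipliers, mean-one, z-scores), so pooled absolute means are not
comparable across implementations. The package emits raw ML rates and a
per-orthogroup mean-one normalisation, and all cross-class statements
use ranks or the normalised scale; only the *direction* binding < other
is treated as a reproducible claim. An all-invariant orthogroup
normalises to all ones, with a warning.

## Statistical battery

* `fisherExact2x2`: two-sided Fisher's exact test by the
  point-probability convention (sum of all hypergeometric outcomes no
  more likely than observed), in log space, so tables with counts in the
  millions are exact. Zero-margin tables return `p = 1` with a warning.
  The two-sided definition is documented because mid-p and doubling
  variants exist.
* `mannWhitneyU`: exact null distribution when both samples have at most
  20 observations (full enumeration under ties), otherwise the
  tie-corrected normal approximation with continuity correction. The
  pipeline's site-class comparisons are always deep in the asymptotic
  regime.
* `kruskalWallis`: tie-corrected H with a chi-square reference
  (delegated to `stats::kruskal.test`); all-tied input returns
  `H = 0, p = 1`.
* `conoverPosthoc`: Conover–Iman t statistics on pooled midranks with
  the `(N - 1 - H)/(N - k)` tie/effect correction, `N - k` degrees of
  freedom, two-sided p-values Bonferroni-adjusted over the `k(k-1)/2`
  pairs, and a per-pair direction from mean ranks (which group evolves
  faster). No installed package provides this test, so it is implemented
  from the published formulation and cross-checked in the test suite
  against an independently coded oracle.

Per-ligand comparisons pool normalised rates across orthogroups;
multi-ligand sites contribute to each of their ligand groups.

## Lineage-specific fixed sites

A binding column is a **strict** lineage-specific candidate for a focal
clade when all focal taxa share residue X, all other retained species
share a single residue Y, and X differs from Y; in **relaxed** mode the
background may vary as long as X appears nowhere in it. Columns with a
gap in any retained species are ineligible — fixation cannot be
verified across species that lack the residue. Candidates then pass a
population filter: every overlapping variant must have allele frequency
at most 0.01 (inclusive: exactly 0.01 still counts as fixed) and must
not be disease-flagged. Matching is on (gene, position) only, not on the
allele, since a site with any common variation is not fixed in the
population. Whether a *rare but disease-associated* variant should
disqualify a site is genuinely ambiguous; the package disqualifies
(the conservative reading), and the reason codes in the output make the
affected calls easy to re-admit.

## Variable-interface enrichment

Genes enter the variable-interface set when at least one variable
binding column has no common variant at its human position — the
exclusion is per site, so one commonly-varying site does not evict a
gene whose other variable binding site is population-rare. Per-gene fold
enrichment divides the variable fraction of binding sites by the
variable fraction of in-domain background sites; genes qualify at
fold `>= 2` with at least two variable binding sites ("multiple"
read as >= 2). A zero-variability background with variable binding
sites gives `Inf`, which sorts above all finite folds and qualifies.
Over-representation of the resulting gene set uses the one-sided
hypergeometric upper tail against the ligand-binding background with
Benjamini–Hochberg FDR across tested terms; annotation tables are
assumed ancestor-propagated, and no ontology structure is handled.

## The synthetic-data generator

`simulateStudy()` builds a complete toy study: domain binding profiles
with a known binding-position fraction; orthogroups whose ancestral
sequences are drawn from the model's stationary frequencies and evolved
down the fixed tree with per-site rates `gamma(shape = 1, mean = 1)`,
multiplied by `rate_multiplier_binding = 0.5` at binding sites; a
population-variant table from a rare/common mixture (5% of positions
carry a variant, 10% of variants common, 2% disease-flagged); and a GO
table with a term planted on the genes that received human-specific
substitutions. Simulation is indel-free — columns align by construction
— because alignment inference is outside the package's scope; the QC
stage is exercised instead with deliberately perturbed fixtures.
Planted human-specific substitutions are placed at binding columns that
evolved invariant and overwrite the human residue with an amino acid
absent from the column, so the strict scanner's definition is met
exactly; requesting more planted sites than eligible columns is an
error, and planted positions only ever receive rare, non-disease
variants. Everything is a deterministic function of the configuration
and its seed.

The simulation model equals the inference model by default, which makes
parameter recovery well-posed; passing a different
`SubstitutionModel` to `simulateOrthogroup()` gives a model-mismatch
mode for robustness checks. The effect size 0.5 is a simulation
parameter, not an empirical estimate — real data fix the direction, not
the magnitude.

**Tree calibration.** The packaged 18-taxon tree (six apes, eight
monkeys, four prosimians; clade sets `human` and `great_apes`) is a
synthetic stand-in with primate-like topology and relative depths. Its
overall scale — total length about 1.16 substitutions/site — was set in
a design study so that per-site rates are identifiable: at a literal
primate protein divergence (total length near 0.6) roughly 70% of
simulated columns are invariant and tie at the optimiser's floor, which
degrades rank agreement between true and estimated rates below a useful
level. At the chosen scale a unit-rate column carries about one
substitution in expectation, true-versus-estimated Spearman correlation
stabilises around 0.64, and binding-versus-background rate differences
are detected essentially always. The cost is that simulated
conservation fractions (roughly 65% of binding and 48% of background
in-domain sites conserved) are lower than real primate values (around
89% and 85%) — one reason the generator validates *method behaviour*,
not dataset-level numbers.

What passing the synthetic checks does **not** show about real data:
robustness to indels and alignment error, to domain-detection error, to
rate variation along the sequence beyond the gamma model, to
non-reversible or site-heterogeneous substitution processes, or to the
ascertainment structure of real variant and annotation databases.

## Validation experiments and problem sizes

`rateRecoveryExperiment()` (50 seeds by default, 12 orthogroups each —
well over 200 sites per class per seed) and
`nullCalibrationExperiment()` (200 replicates of 2 small orthogroups,
the smallest size that still yields honest contingency tables) are the
package's standing experiments; `scripts/acceptance.R` re-runs them
from scratch together with the oracle-agreement and scanner checks.
Under the reference conditions the recovery experiment detects slower
binding sites (MWU `p < 0.01`) in every seed with mean Spearman
agreement about 0.64, and the null experiment rejects at close to the
nominal 5% for both tests.

## Degenerate inputs and numerical choices

All-gap columns yield missing entropy/variability/rate. Likelihood
clamping at `1e-320` prevents `log(0)` at extreme rates. Transition
matrices are clamped to non-negative and re-normalised row-stochastic
(round-off can produce tiny negatives). All-tied statistical inputs
return the no-evidence answers (`H = 0`, `p = 1`) rather than NaN.
Zero-margin Fisher tables warn and return 1. The rate optimiser falls
back to the best grid point with a warning if refinement fails. Warning
counts appear in the pipeline manifest.

## Limitations

The package does not infer alignments or trees, does not detect domains
(match tables are an input contract), does not model indels or use them
as characters, performs no branch-site or dN/dS selection tests, and
treats GO annotation tables as flat. Dataset-level published counts
depend on specific external database snapshots and are out of scope;
the reported-scale tables shipped with the package are used only to
re-derive the contingency-table statistics computed from them.
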