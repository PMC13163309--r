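---
title: "Methods: network-guided target and metabolite prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-guided target and metabolite prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`netprio` implements the analysis spine of a network-guided drug-repurposing
workflow for chemotherapy stress-adaptation studies: transcriptome-level
differential expression feeds pathway over-representation, both feed a
composite gene prioritization score whose top genes define a protein–protein
interaction module; in parallel, a metabolite feature table is filtered by
multivariate (PLS-DA/VIP) and univariate statistics, the surviving
metabolites are ranked per target from a docking table, and candidate
compounds are finally characterized by four-parameter-logistic dose–response
fits. This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## Differential expression

Counts are transformed to damped log2 counts-per-million,
$\log_2\!\big(\tfrac{c + c_0}{L + 2c_0}\,10^6\big)$ with prior count
$c_0 = 0.5$ (the common convention; the underlying study does not state
one). Per-gene two-group comparison uses an empirical-Bayes moderated t:
the pooled gene variance $s^2$ on $d$ degrees of freedom is shrunk toward a
prior $s_0^2$ with weight $d_0$,
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the statistic is referred
to a t distribution on $d + d_0$ df. Defaults are $d_0 = 4$ and $s_0^2$
estimated by method of moments as the mean gene-wise variance. This
deliberately preserves the *character* of moderated linear modelling
without reproducing voom's precision weights: full limma-voom replication
is out of scope, and correctness is assessed by recovery of planted effects
in synthetic data rather than by matching another implementation's output.
With $d_0 = 0$ the test reduces exactly to the classical pooled two-sample
t-test, which the test suite verifies against `stats::t.test` at 1e-10.

A gene is called differentially expressed when $|\log_2 FC| \ge 0.5$
(inclusive) and BH-adjusted $p < 0.05$ (strict) — the threshold semantics
are fixed exactly as printed in the source analysis. FPKM is computed as
$c \cdot 10^9 / (L_{\text{lib}} \cdot \ell)$ with per-sample library size
equal to the sample's total counts (true mapped-read totals are not
available to a reanalysis), and the value carried into scoring is the mean
over treated samples.

The RNA QC gate (RINe $\ge$ 7, 28S/18S $>$ 2.0, DV200 $>$ 70%) is a small
predicate with the boundary semantics exactly as written: RINe inclusive,
the other two strict.

## Over-representation and pathway relevance

Enrichment of the DEG list against a gene-set collection is the one-sided
hypergeometric (Fisher exact upper-tail) test — the standard ORA — with the
universe taken as all genes retained after expression filtering, not the
genome. Adjusted p-values reuse the same BH routine as the expression
stage; pathways are ranked by (adjusted p, raw p, pathway id) so ranks are
deterministic under input reordering.

The pathway-relevance weight entering the composite score is 1.0 for genes
in any of the five top-ranked significant pathways, 0.5 for genes in any
other significant pathway, and 0.0 otherwise. Two interpretation choices
were open and are fixed as follows: "top five" means the five smallest
adjusted p among *significant* pathways (all significant pathways carry 1.0
when fewer than five are significant), and weight-0 genes are dropped
before scoring, since every row of the published worked example carries
weight 1.0 or 0.5.

## The composite score

$$\mathrm{Score} = 0.5\,[-\log_{10}(p_{\text{adj}})] +
0.3\,\log_2(\mathrm{FPKM}+1) + 0.2\,\mathrm{Relevance}$$

evaluated exactly, unclipped, at full precision; 3-decimal rounding is
applied only when comparing against the printed table. The packaged 20-row
worked example reproduces to within half a printed unit on 19 of 20 rows;
the remaining row (SOD2) computes to 3.350515, which prints as 3.351 under
round-half-up but appears as 3.350 in the source table — evidently a
truncation. The comparison function reports the row-wise differences so
this is visible rather than hidden.

Ranking ties are a genuinely open point: the published equal-score pairs
are ordered inconsistently (one pair follows |log2FC| descending, another
does not), so no undisclosed tie rule is guessed. The package convention is
score descending, then |log2FC| descending, then gene id ascending, as a
stable sort; fixture comparisons are made set-wise within tied blocks.

The multi-criteria target gate keeps a gene only if it is significantly
differentially expressed, ranks in the top 20, *and* carries a documented
functional-involvement flag. That last criterion is literature knowledge
and is not computable; it must be supplied as an explicit boolean vector
and is never inferred.

## Interaction network topology

Edges at combined confidence $\ge 0.700$ (inclusive) are retained,
duplicate unordered pairs collapse to their maximum score, and self-loops
are dropped. The graph is treated as unweighted afterwards. The
network-average clustering coefficient counts degree-<2 nodes as 0 by
default (the common convention); an exclusion variant is exposed because
the published value cannot be re-derived without the original edge list —
only the average-degree identity $2|E|/|V|$ is exactly reproducible, and
the package verifies it on a 20-node, 116-edge graph (11.6). Hub ranking is
by degree with node-id tie-breaks.

## Metabolite selection

PLS-DA is implemented in-package (NIPALS with deflation) rather than
delegated, because the VIP definition used downstream depends on the exact
weight normalization: with unit-norm weight vectors $w_a$ and per-component
explained response variance $ssy_a$,
$$\mathrm{VIP}_j = \sqrt{p \,\frac{\sum_a ssy_a w_{aj}^2}{\sum_a ssy_a}},$$
which forces $\mathrm{mean}_j(\mathrm{VIP}_j^2) = 1$ — an identity the test
suite checks to 1e-10 on every fitted model, alongside equivalence with an
independently coded closed-form-per-component implementation at 1e-8.
Numerical details: features are autoscaled to unit variance by default
(SIMCA-style; pareto and none available), constant features are dropped
with a warning, convergence is declared when the score vector moves less
than 1e-10 (max 500 iterations), initialization is deterministic from the
response, and successive weight iterates are sign-aligned because the
iteration is otherwise defined only up to sign. Two components are fitted
by default; the source analysis states no number.

Univariate significance is a Welch t on log2 intensities (no test is named
in the source; Welch is the defensive default for heteroscedastic
intensities), with BH adjustment across features. A feature is selected
when VIP > 1.5, p < 0.05, FDR < 0.05 and FC > 2.0, all strict, with FC the
raw-scale treated/control mean ratio. The FC criterion is printed
one-sided; the default mode enforces it literally, and a documented
`two_sided` option additionally admits FC < 0.5, since down-regulated
metabolites plausibly matter. Redundant ions are merged when masses agree
within 5 ppm (relative to the lower mass, strict) and retention times
within 0.2 min (inclusive), transitively, keeping the brightest member.

## Docking-table ranking and assay candidates

Docking results are consumed, never computed. Ligands are ranked per
target by docking score ascending (most negative first); binding free
energy breaks ties. Docking score — not $\Delta G_{bind}$ — is the primary
key because the published per-target prioritized triples are exactly the
top-3 docking scores for all five targets, whereas an energy ordering
would differ. Multi-target profiles collect, per compound, the targets
where it appears in a top-3 set.

Assay-candidate selection picks, per target, the MD-stability-passing
top-3 member with the best binding free energy. The MD-stage MM-GBSA
energies differ systematically from the docking-table energies for the
same complexes; both are shipped as separate fixtures and no
reconciliation is attempted — the MD-stage values are supplied to the
selector as an override table, which reproduces the three experimentally
assayed compounds.

## Dose–response

Viability is $100(A_{s}-A_{b})/(A_{c}-A_{b})$, unclipped (clipping would
bias the lower asymptote). Technical replicates are averaged within each
biological replicate before fitting; biological replicates stay separate.
The 4PL model $y = b + (t-b)/(1 + (x/\mathrm{IC}_{50})^h)$ is fitted by
Levenberg–Marquardt with $\log_{10}\mathrm{IC}_{50}$ as the free parameter
for conditioning, 8 multi-starts (asymptotes from the data extremes, IC50
starts from the concentration nearest half-response and the geometric mean
of the range, hill slopes of both signs), keeping the converged start with
the lowest residual sum of squares. The model's exact
$(b, t, h) \leftrightarrow (t, b, -h)$ symmetry is canonicalized so `top`
is always the zero-dose asymptote. Constant input yields an explicit
"undetermined" fit rather than an error deep in the optimizer. The
published IC50 values themselves are not reproduction targets: the
per-well absorbances behind them are only partially printed, which is not
enough to refit.

## The synthetic generators

Because no expression, metabolomics or network data are deposited with the
source study, the generators define the study conditions under which the
pipeline is validated, with known planted truth:

* **Counts** — negative binomial, gene means log-normal (meanlog 5,
  sdlog 1.2, i.e. genes that survived low-expression filtering), one shared
  dispersion of 0.02 (cell-line replicate range), 2000 genes, three
  replicates per condition, 5% of genes shifted by |log2FC| = 1.5. The
  dispersion and mean scale were fixed by a pilot: at dispersion 0.1 a
  3-vs-3 design has essentially no BH-adjusted power at this effect size,
  which is a statement about small-n RNA-seq, not about the implementation.
* **Metabolites** — log-normal intensities (sdlog 0.3 ≈ 30% CV), 300
  features, six samples per class, 5% of features multiplied by 3.0 in the
  treated class (multiplicative, so the raw-scale FC is the planted value).
* **Graph** — Erdős–Rényi background (150 nodes, p = 0.05) plus five hubs
  wired at six times the background probability; weights uniform on
  [0.4, 1] so the 0.700 threshold genuinely bisects the edge set. Six
  rather than the minimal two times background because thresholding halves
  all degrees and top-k hub recovery should not ride on lucky draws.
* **Plate** — the assay's six concentrations (0.03–100 µM), two biological
  × three technical replicates, Gaussian viability noise of 3 percentage
  points mapped onto an OD450 range of 0.10 (blank) to 1.10 (control).

Every generator is a pure function of its config: same seed, bit-identical
output. What the generators do *not* emulate: gene-length/GC biases,
library-size variation, correlated genes, batch effects, adduct and isotope
structure in the metabolite table, STRING's evidence-channel structure, or
plate edge effects. Passing recovery tests therefore demonstrates that the
pipeline's statistics behave as designed under their own assumptions — not
that the original study's numbers are regenerated, which without the raw
data is not possible for the DEG counts, the clustering coefficient 0.74,
the binding energies, or the IC50s.

## Problem sizes in the test suite

The suite exercises: exhaustive BH-vs-oracle comparison over all sorted
p-vectors of length ≤ 5 on a 0.05 grid plus randomized vectors at lengths
6–8; exhaustive hypergeometric enumeration for all universes N ≤ 12;
exhaustive graph-statistic oracles over all graphs on ≤ 5 nodes plus 2000
random 6-node graphs; 100-seed Monte-Carlo batteries for hub recovery,
planted-pathway ranking, VIP identity and noisy IC50 recovery; and 50-seed
null simulations for type-I control. These sizes are the package's chosen
trade-off between evidential value and a test suite that runs in about a
minute.

## Known limitations

Single-factor two-group designs only; no voom precision weights or batch
correction; ORA ignores pathway topology; PLS-DA is two-class; the
docking stage trusts its input table entirely; and the annotation flags in
the target gate encode external literature knowledge that the package
cannot audit.
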