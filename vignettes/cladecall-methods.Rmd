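---
title: "From glucose-inducible expression signatures to adaptive driver mutations"
author: "cladecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From glucose-inducible expression signatures to adaptive driver mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladecall)
```

## The problem

When *Saccharomyces cerevisiae* populations of different ploidy evolve for
hundreds of generations on raffinose — a carbon source yeast metabolises
slowly — the dominant route to higher fitness is stronger glucose uptake:
mutations in the glucose sensors and repressors (*SNF3*, *RGT2*, *MTH1*,
*MOT3*), amplification of the *HXT6/7* transporter locus, or loss of
*IPT1*, all of which de-repress or boost hexose-transporter expression.
Different driver genes leave characteristically different footprints on a
small glucose-inducible panel — the transporters *HXT2*, *HXT3*, *HXT4*,
*HXT6/7* and the invertase *SUC2* — measured by qRT-PCR relative to the
unevolved ancestor and normalised to *ACT1*. cladecall implements the
complete phenotype-to-genotype workflow on such data:

1. **quantify** — Ct tables to ancestor-relative log2 ratios with
   propagated replicate error;
2. **cluster** — complete-linkage hierarchical clustering of the clone
   profiles and an explicit rule for choosing the number of primary
   clades;
3. **predict** — label clades by the known drivers of genotyped members
   and call the driver of every other clone by clade co-membership;
4. **separate** — Fisher linear discriminant analysis comparing how well
   driver identity versus ancestral ploidy organises the expression
   space, with 95% confidence ellipses;
5. **recurrence** — an exact binomial test for parallel evolution
   (independent clones hitting the same gene).

A seeded synthetic-cohort generator reproduces the statistical structure
this workflow assumes, so every stage is testable end to end without
strain data.

## Relative quantification

For clone $c$, gene $g$ and biological replicate $b$, with technical
replicates averaged first, the efficiency-corrected log2 ratio against
the ancestor $a$ is

$$ r_b \;=\; \Delta Ct_{ref,b}\,\log_2(1+E_{ref}) \;-\;
             \Delta Ct_{g,b}\,\log_2(1+E_{g}), \qquad
   \Delta Ct_{x,b} = Ct_x(c,b) - \overline{Ct}_x(a), $$

and the reported ratio is $\bar r = \tfrac1B \sum_b r_b$. With all
amplification efficiencies $E = 1$ (perfect doubling) this is the
classical $2^{-\Delta\Delta Ct}$ model; efficiencies estimated from a
dilution series (`fit_standard_curve()`, $E = 10^{-1/\text{slope}}-1$)
plug in per primer pair. Because the analysis underlying this design did
not pin down one quantification model, both are available; the
efficiency-corrected form is the default and the two coincide at the
default $E=1$.

"Error propagated for replicates" is likewise under-determined, so two
conventions are implemented: the default reports the standard error of
the per-biological-replicate ratios ($B$ in the denominator; technical
replicates only enter through their mean), and a quadrature mode
propagates the technical-replicate standard errors of all four Ct means.
The default is the more common convention and has the convenient
property that identical replicates give $se = 0$ exactly.

Ancestor matching: when the Ct table carries a `batch` column, each
clone replicate is referenced to the ancestor processed in the same
batch; otherwise the pooled ancestor mean is used. Missing technical
replicates are tolerated (mean of what is present); a clone with no
biological replicate for a panel gene is an error that names every gap.

## Clustering and the number of clades

Profiles are clustered with complete linkage on Euclidean distance of
the log2 ratios (a correlation metric is available). The agglomeration
is written out explicitly so that distance ties resolve by a fixed rule
— merge the pair whose lexicographically smallest leaf labels compare
lowest — making the partition invariant under row permutation. The
result is a standard `hclust` object.

The number of primary clades is chosen from the within-group sum of
squares $W(k)$ of the cuts $k = 1..k_{max}$ ($k_{max}$ defaults to 10):
the selected $k$ maximises the second forward difference
$W(k{-}1) - 2W(k) + W(k{+}1)$ over $2 \le k \le k_{max}-1$. This is a
deliberate formalisation of the usual by-eye elbow judgement: a
reproducible pipeline needs an explicit rule, and the full trace is
always emitted so a human can override with a forced `k`. The statistic
peaks where the marginal gain of one more clade collapses; it behaves
well when the between-clade merge costs are comparable, and can fall
back to a coarse $k$ on unluckily scattered cohorts — which is why the
trace, not just the selected $k$, is part of the output.

## Driver prediction

Within the selected clades, genotyped clones vote: each clade takes the
majority driver class of its labeled members (ties and label-free clades
abstain, yielding `UNDETERMINED`), and every clone inherits its clade's
label together with a support fraction. Two design choices matter:

* **Ties abstain** rather than picking at random — an undetermined call
  is more honest than a coin flip and mirrors how mixed clades are
  treated in practice.
* **Conflicted clades are refined.** When more than 5% of a clade's
  labeled members disagree with its majority (`conflict_threshold`),
  the clade is re-cut into as many sub-clades as it has distinct labels
  and the vote repeats inside each sub-clade; a sub-clade with no
  genotyped member inherits the nearest labeled sub-clade's vote
  (centroid distance). The low threshold is intentional: a genuine
  minority class that is small in absolute numbers (three or four
  clones) must still trigger refinement once hold-outs shrink it
  further. This is the formal analogue of reading a distinct sub-clade
  (say, *MTH1* mutants inside a predominantly *SNF3* clade) off the
  dendrogram before calling the driver.

Classes whose signatures are genuinely identical cannot be separated by
any of this — they are resolvable only to their shared clade, which is
exactly the situation where targeted sequencing or copy-number assays
must confirm the call. `predict_loocv()` quantifies the labelling's
internal consistency by hiding one genotyped clone's label at a time.

## Class separation by LDA

`fit_lda()` implements Fisher's construction explicitly: the axes solve
the generalized eigenproblem of between- versus within-class scatter,
computed via Cholesky whitening of the within-class scatter. The
within-class scatter is always ridge-regularised by
$\lambda\,\overline{\text{diag}(S_W)}\,I$ with $\lambda = 10^{-6}$ —
with five genes and classes of three or four clones, singular scatter is
the rule, not the exception. Classification (for leave-one-out
cross-validation, the deterministic default at cohort scale) uses the
Gaussian rule with pooled covariance and class-proportional priors
(uniform priors are a flag).

Confidence ellipses use the sample mean and covariance of the per-class
scores scaled by $\sqrt{\chi^2_2(0.95)}$ — the known-covariance
convention common in score plots; an F-based (Hotelling) variant is
available and is noticeably wider below $n \approx 10$. Pairwise ellipse
overlap areas are integrated on a 200-point-per-axis grid.
`separation_report()` contrasts the mutation grouping with the ploidy
grouping on identical clones and flags when every mutation class
cross-validates better than every ploidy class.

## Recurrence testing

For each gene hit in $k \ge 2$ distinct clones (multiple hits inside one
clone count once — recurrence means independent lineages), the exact
binomial upper tail $P(X \ge k)$, $X \sim \text{Bin}(n, p)$, is computed
under one of two neutral placement nulls:

* `per_mutation` (default): every one of the cohort's $n$ total
  mutations hits the gene with probability
  $p = L_{gene}/L_{target}$;
* `per_clone`: every one of $n$ clones hits the gene with probability
  $1-(1-L_{gene}/L_{target})^{m}$, $m$ the mean mutation count per
  clone.

Benjamini–Hochberg adjustment is applied across tested genes
(Bonferroni available). The package deliberately does not claim to
reproduce any particular published p-value for these genes: the $n$,
$p$, and null construction behind such numbers are rarely printed, so
all inputs here are explicit and user-controlled.

## The synthetic cohort

The generator emulates the study design the workflow targets: 92 evolved
clones (27 haploid-, 32 diploid-, 33 tetraploid-derived) plus the
diploid ancestor, each measured for the five panel genes and *ACT1* in
triplicate reactions for each of two biological replicates. Per clone
and biological replicate, true log2 ratios are drawn from the clone's
class signature $\mathcal N(\mu_{class}, \sigma_{class}^2)$ and
converted to Ct values by inverting the quantification model,
$Ct = B_g - r/\log_2(1+E_g)$ around per-gene ancestor baselines, with
$\mathcal N(0, 0.25^2)$ cycles of technical noise per reaction. The
ancestor's true ratios are identically zero — forced by the ratio
definition — so its expected Ct is the baseline itself.

Nine driver classes are shipped (`default_signatures()`), encoding the
qualitative tiers seen in raffinose-evolved clones: strong *HXT2-4*
induction (`SNF3_high`, clade *a*), moderate induction
(`SNF3_moderate` and `MTH1`, clade *b*), weak induction with relatively
high *SUC2* (`SNF3_low`, clade *c*), near-ancestral profiles (`RGT2`,
`IPT1`, `ancestor_like`, clade *d*), and *HXT6/7*-driven profiles with
repression of the rest of the panel (`HXT67_amp`, `MOT3`, clade *e*).

**Calibration.** The numeric signature values are not measurements; no
published table prints them. They were fixed once, by a constrained
search under the generator's own noise model, to satisfy the two
properties the defaults are documented to have: (i) classes expected to
share a primary clade co-cluster under complete linkage while the
second-difference elbow recovers five clades with a positive margin
across seeds, and (ii) within-clade class pairs keep a
separation-to-noise ratio above ~3.5 so that sub-clade refinement can
resolve them. The search moved means only inside sign and tier bounds
fixed in advance (e.g. `SNF3_high` strictly positive and strongest on
*HXT2-4*; `HXT67_amp` positive only on *HXT6/7*), with per-class
biological standard deviations between 0.12 and 0.38 log2 units.
Everything is overridable: `signature_set()` accepts any class matrix.

What the generator does **not** emulate: plate/batch effects beyond the
shared ancestor baseline, amplification-curve artefacts, aneuploidy
dosage effects on the reference gene, cross-hybridising primers, or any
linkage between a clone's mutation count and its expression class. A
green test suite on synthetic cohorts therefore demonstrates the
statistical machinery, not the wet-lab robustness of the panel.

The mutation simulator is plain artifact plumbing for the recurrence
test: Poisson mutation counts per clone placed into genes proportionally
to length × selection weight inside a larger target, the remainder
falling in intergenic/other sequence.

## Numerical choices and edge cases

* Distance ties in clustering: resolved lexicographically (above);
  heights are non-decreasing by the complete-linkage update.
* One clone: a single-leaf dendrogram, not an error; `k_max < 3` with
  automatic selection: an error instructing a forced `k`.
* Standard curves with non-negative slope: flagged invalid with a
  warning object, never silently used.
* LDA with a one-member class: an error naming the class (except inside
  cross-validation refits, where the singleton contributes zero
  scatter); identical class means: a `degenerate` flag.
* Confidence ellipses need three points and a non-singular score
  covariance; two points are an error by construction.
* Binomial tails use the survival form of the CDF rather than
  `1 - P(X < k)`, keeping tiny tails accurate; `k = 0` returns exactly 1.
* All tables are `#`-headered TSVs carrying the seed and a configuration
  hash, and the pipeline restarts from any intermediate.

## Problem sizes

The shipped analyses and tests run at the cohort's natural scale: 92
clones × 5 genes, ~3,350 Ct records, dendrograms of ≤ 92 leaves.
Monte-Carlo checks use 100,000 points for ellipse coverage, 200 label
permutations for the LDA null, 800 neutral replicates for the
recurrence type-I rate and 500 for its power — sizes at which the
binomial/Gaussian error bands in the tests are decisive. A full run of
the analysis scripts takes well under a minute on one core.

## Known limitations

* The elbow rule can return a coarse clade count on cohorts whose
  between-clade distances are very uneven; inspect `clade_trace.tsv`
  and force `k` when the biology says otherwise.
* Prediction is only as good as the genotyped scaffold: a class with no
  labeled member in a cohort can never be called, only flagged
  `UNDETERMINED`.
* The recurrence nulls assume mutations land independently and
  uniformly within the target; regional mutation-rate variation is not
  modelled.
* Efficiency correction assumes a single efficiency per primer pair
  across the dynamic range — the standard-curve linear-range check is
  the guard rail.
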