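---
title: "Two-stage penalized least squares for gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage penalized least squares for gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twospls)
```

## The model

Genetical-genomics experiments measure, for each individual in a segregating
population, genome-wide genotypes and genome-wide expression. `twospls`
models the expression levels of $p$ genes, $Y = (Y_1, \dots, Y_p)$, and the
genotypes of $q$ markers, $X = (X_1, \dots, X_q)$, with a system of
structural equations

$$Y = Y\Gamma + X\Psi + E,$$

where the $p \times p$ matrix $\Gamma$ holds gene-on-gene regulatory effects
($\Gamma_{ij} \neq 0$ means gene $i$ regulates gene $j$; the diagonal is
zero), the $q \times p$ matrix $\Psi$ holds causal cis-genotype effects
(nonzero only at a gene's own cis-eQTL), and $E$ is an error matrix with
independent Gaussian entries, independent of $X$. Expression levels are
*endogenous* — each gene's level appears on both sides of the system — so
ordinary regression of one gene on the others is inconsistent. The cis-eQTL
genotypes are *exogenous instruments*: they shift their own gene's
expression but are randomized by meiosis, which is what makes the directed
effects identifiable.

## The two stages

Each gene is fit independently at each stage, which makes the procedure
embarrassingly parallel and cheap enough to bootstrap.

**Stage 1 (ridge prediction).** Each node gene's expression is regressed on
the common instrument matrix (by default the union of all genes' selected
cis markers) with a ridge penalty; the fitted vector $\hat{E}[y \mid X]$
replaces the raw, endogenous expression as a regressor in stage 2. The
ridge penalty is chosen per gene by generalized cross-validation (GCV) over
a fixed grid of 25 log-spaced points on $10^{-4} \dots 10^{4}$; GCV is
deterministic and costs nothing extra once the instrument matrix has been
factored (one SVD serves all genes). The intercept is never penalized: the
fit is computed on mean-centered data and the mean added back.

**Stage 2 (adaptive-lasso selection).** Gene $j$'s expression is regressed
on the stage-1 predictions of all other node genes together with gene $j$'s
own selected cis genotypes. The coefficient vector minimizes

$$\frac{1}{2n}\lVert y - D\beta \rVert^2 + \lambda \sum_k w_k |\beta_k|,$$

where the penalty applies to the regulator columns only — own-cis columns
are unpenalized so that every node always retains its instrument
(identifiability; a `penalize_cis` flag reverses this). The adaptive
weights are $w_k = 1 / |\tilde\beta_k|^\gamma$ with $\gamma = 1$ and
$\tilde\beta$ from a ridge pilot fit of the same regression (GCV-tuned); a
pilot coefficient of exactly zero receives a large finite cap ($10^{12}$),
which forces the effect out without creating infinities. $\lambda$ is
selected by BIC, $n\log(\mathrm{RSS}/n) + \log(n)\,\mathrm{df}$ with df =
number of nonzero coefficients, over a descending log-spaced grid of 50
points spanning four decades below the null-model threshold. BIC was chosen
over cross-validation because it is deterministic, which keeps bootstrap
replicates exactly reproducible and worker-count invariant.

## cis-eQTL mapping

Candidate instruments for a gene are the markers inside its *cis window*:
the gene body plus 500 bp upstream, strand-aware (a strand-ignorant mode
exists for replication of analyses that did not record strand), clamped at
coordinate zero. Missing genotype calls are mean-imputed per marker before
anything else. Each candidate is tested by simple linear regression
(two-sided $t$ test on the slope, $n - 2$ degrees of freedom) at a
per-marker significance level of 0.05 with no multiple-testing correction —
the convention of the segregant studies this pipeline follows. The
significant markers are then filtered greedily in ascending-$p$ order
(ties broken by genomic position, leftmost first): a marker is retained
only if its absolute genotype correlation with every already-retained
marker is below 0.90, and at most 3 markers are kept. Genes with an empty
selection have no instrument and are excluded from the network node set.
Correlations for the pruning are computed on the imputed genotypes.

## Bootstrap edge confidence

`bootstrap_network()` redraws the $n$ segregants with replacement
(expression and genotype rows jointly), reruns the full two-stage fit on
each replicate, and reports for every directed edge the fraction of
replicates in which its stage-2 coefficient was nonzero. Frequencies are
exact rationals with denominator $B$. Edges above the 80% threshold
(strictly greater, matching the "more than 80%" convention) fall into the
bins $[0.80, 0.90)$, $[0.90, 0.95)$, $[0.95, 1.00)$ and the singleton
$1.00$.

Two decisions here were genuinely open:

* **cis-eQTL selection is not redone inside replicates.** Re-scanning would
  change the node set from replicate to replicate, making per-edge
  frequencies ill-defined. A `rescan_eqtl` flag provides the alternative
  as a sensitivity analysis.
* **An edge counts as "identified" regardless of its sign** in a given
  replicate; the modal sign and the sign-agreement proportion are reported
  separately so sign-unstable edges are visible rather than silently
  dropped.

Replicate seeds are drawn once from the master seed, so the frequency table
is byte-identical for any worker count.

## The synthetic world

`sim_dataset()` emulates the shape of a classical biparental yeast
segregant cross at desk scale: haploid segregants, biallelic markers coded
0/1, linked markers along chromosomes, genes driven by 1–3 cis-eQTL plus
sparse inter-gene regulation plus Gaussian noise. Genotypes follow a
two-state Markov chain along each chromosome with Haldane's map function
$r = \tfrac12(1 - e^{-2d})$ converting genetic distance to recombination
fraction — the standard model for a single meiosis without interference.
Defaults state the world once: $n = 112$ segregants (the historical cross
size), cis effects of absolute size 0.8–1.2, regulatory effects 0.5–1,
noise standard deviation 0.3, and an expected out-degree of 2.

Each gene owns a small block of tightly linked markers (5 cM spacing inside
a block, 30 cM between blocks) and its gene body spans exactly that block,
so the cis window recovers the intended instruments and neighbouring genes'
instruments decorrelate. All markers of one gene share an effect sign —
opposite signs on markers correlated at $\approx 0.8$ would let cis signals
cancel, which is not the situation the generator is meant to state.

Ground-truth networks are acyclic by default (edges run from lower to
higher gene index), for a concrete reason: with $p = 30$, two edges per
gene and effects up to 1, an unconstrained random $\Gamma$ has spectral
radius near 1.1, and the reject-until-stable loop (at most 100 draws,
then an error) would reject nearly every draw. Cyclic simulation is fully
supported at lower densities or effect sizes (`acyclic = FALSE`), and the
reciprocal-regulation algebra is exercised by closed-form tests instead.

What the generator does **not** emulate — so a green test does not
establish robustness to it: microarray normalization artefacts,
heteroscedastic or heavy-tailed noise, genotyping error, segregation
distortion, crossover interference, epistasis, hotspot trans-regulation,
or diploid genetics.

## Numerical choices

* Coordinate descent converges on a maximum coefficient change of
  $10^{-8}$ per sweep, with at most 10,000 sweeps; each coordinate update
  is an exact minimization, so the KKT residual at convergence is at
  machine precision (tests assert $\le 10^{-6}$). Non-convergence is an
  error carrying the residual, never a silent result.
* Active-set cycling (converge on the nonzero support, then one full sweep
  to admit new coordinates) plus warm starts along the $\lambda$ path keep
  stage 2 fast; the path stops early once BIC has not improved for 10
  consecutive grid points, because the dense small-$\lambda$ tail is both
  expensive and never selected.
* Zero-variance columns (monomorphic markers, constant stage-1
  predictions) are never updated and report coefficient 0; the cis scan
  skips them with a warning naming the marker.
* An exactly singular $I - \Gamma$ (reduced-form solve) is rejected with
  an explicit error, as is a reciprocal condition number below $10^{-12}$.
* BIC ties prefer the sparser (larger-$\lambda$) model; RSS is floored at
  $10^{-12}$ before the log.

## Runtime scaling in the test suite

The acceptance tests state the conditions of the stated world but scale
replicate counts to a single-CPU budget: edge recovery uses 20 replicates
at $n = 300$ and 8 per point on the $n \in \{100, 200, 400\}$ monotonicity
grid; the bootstrap criterion uses $B = 100$; the end-to-end determinism
check uses $B = 25$. The Monte-Carlo $1/\sqrt{B}$ property is checked via
the analytic binomial standard error at $B = 50$ rather than the full
$B \in \{50, 200, 800\}$ sweep, purely for runtime. The `run_config()`
default remains $B = 10{,}000$.

## Limitations

Only cis effects enter $\Psi$; trans-eQTL act indirectly through the gene
network. Per-marker testing at 0.05 without correction is a stated
convention, not a recommendation. Edge direction identifiability rests on
instrument validity and the Gaussian-error SEM; violations (shared cis
variants, feedback faster than the sampling design) bias edges in ways the
bootstrap cannot detect. The pipeline reports selection frequencies, not
calibrated error rates.
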