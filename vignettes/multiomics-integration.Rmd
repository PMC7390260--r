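---
title: "Knowledge-driven integration of transcriptomic and metabolomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-driven integration of transcriptomic and metabolomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicslink)
```

## The model

`omicslink` relates two sample-matched feature panels — transcripts
(HGNC symbols) and metabolites (ChEBI ids) — through a pipeline of
knowledge-driven dimension reduction followed by two multivariate engines.
The statistical engines assume complete, pre-normalized, approximately
multivariate-normal data; normalization, quality control and imputation are
deliberately out of scope, and matrices containing missing values are
rejected at the door rather than silently patched.

### Functional grouping

The transcript panel is first reduced to genes with a documented biochemical
link to the measured metabolites. Each metabolite id is looked up in a
metabolite-to-pathway snapshot table; ids absent from the table are resolved
through the ChEBI ontology (a DAG of child→parent edges). The search prefers
the *descendant* direction: the nearest mapped node anywhere in the subtree
below the query is its representative, and only when no descendant is mapped
does the search turn to ancestors. "Nearest" means fewest ontology edges;
the snapshot defines no distance, so hop count is the only defensible
metric. Ties at equal depth break to the smallest numeric ChEBI id, which
makes resolution a pure function of the inputs. Metabolites with no mapped
relative are reported `UNMAPPED` and contribute nothing downstream.

Genes of all reached pathways form the *seed set*, which is expanded exactly
one hop through a scored gene–gene interaction network: a neighbour joins if
its edge's combined score (0–1000) meets the threshold. The default of 400
is the conventional "medium confidence" cutoff for STRING-style scores; it
is a logged, mandatory parameter rather than a constant because no
principled value exists independent of the network snapshot in use. One hop
— not a transitive closure — because the intent is to decorate a pathway's
gene set with direct interactors, not to crawl the network; applying the
expansion twice would grow the set further, and the pipeline deliberately
applies it once.

Only after mapping and expansion is the group intersected with the genes
actually measured, so the report distinguishes "biologically implicated but
unmeasured" from "measured and analyzed". Gene symbols are compared
case-insensitively (uppercased): mixed-case mouse-style symbols otherwise
fail to match their uppercase human counterparts, and the knowledge
snapshots in practical use are human. The knowledge base carries a species
label that is logged, not enforced — cross-species mapping is an explicit,
visible approximation left to the caller's judgement.

### Decorrelation

Classical CCA requires invertible within-set correlation matrices and
suffers when predictors are collinear, so each set is thinned to mutually
weakly-correlated representatives. The rule is a greedy scan in input column
order: keep the first column; drop any later column whose absolute
correlation with an already-kept column reaches the threshold, recording the
kept column with the largest |r| as its representative. Among the defensible
selection rules (clique clustering, connectivity ranking, random choice)
the greedy scan was chosen because it is deterministic, order-reportable and
trivially auditable — the output can be re-verified by recomputing one
correlation matrix. Absolute correlation is compared, since a strong
negative correlation is the same redundancy as a positive one. Constant
columns have no defined correlation and are dropped with a warning.
Dropped features stay in the result object and its TSV report: they matter
at the interpretation stage even though they leave the model.

### Canonical correlation analysis

For standardized $X$ ($n \times p$) and $Y$ ($n \times q$), CCA finds
$a_i, b_i$ maximizing $r_i = \mathrm{cor}(a_i'X, b_i'Y)$ with variates
$u_i = X a_i$, $v_i = Y b_i$ mutually uncorrelated within and across sets.
Computation is by SVD of $R_{xx}^{-1/2} R_{xy} R_{yy}^{-1/2}$: whitening
each block before the SVD treats the two sets symmetrically and avoids the
asymmetric eigenproblem of $R_{xx}^{-1}R_{xy}R_{yy}^{-1}R_{yx}$, whose
conditioning is the square of the whitened problem's. Inputs are always
standardized so weights are comparable across variables. Sign of each
canonical pair is arbitrary; the convention here makes the
largest-magnitude X-loading of each variate positive and flips the Y side
with it, keeping every $r_i \ge 0$.

Diagnostics per variate: *loadings* (correlation of each variable with the
variate; the square is the variance share of that variable explained),
*adequacy* (mean squared loading within a set), *communality* (per-variable
sum of squared loadings over variates), *redundancy* ($r_i^2$ times the
opposite set's adequacy on variate $i$ — the fraction of one set's variance
explained by the other set's variate). Significance uses Bartlett's
sequential chi-squared test with the classic multiplier,

$$\chi^2_i = -\left[n - 1 - \tfrac{p + q + 1}{2}\right] \ln
\prod_{j \ge i} (1 - r_j^2), \qquad df_i = (p - i + 1)(q - i + 1),$$

without the Lawley refinement; the variant choice is recorded in the result
object's notes. The exported `bartlett_test()` requires every tested
correlation to lie in $[0, 1)$; inside `fit_cca()` a correlation that is
numerically 1 (e.g. when one set is an invertible transform of the other)
yields $\Lambda = 0 \Rightarrow \chi^2 = \infty,\ p = 0$ rather than an
error, so degenerate-but-valid fits still report a complete table.

Error policy: $n \le \max(p, q) + 1$ and singular within-set correlation
matrices (tolerance $10^{-10}$ relative to the largest eigenvalue) are hard
errors — the second with a pointer at the prune step. The rule of thumb of
20 samples per variable is only a warning: small-panel studies (say 40
samples against 12 + 12 features) routinely violate it, and the diagnostics
remain interpretable with care. Outlier rejection is not automated; CCA's
sensitivity to outliers is real, but an automatic rule would hide a
judgement that belongs to the analyst.

`helio_data()` exports, for one variate, each variable's loading with an
angular position — the numbers behind a circular bar ("helio") plot where
positive loadings point outward and negative inward.

### Partial least squares

PLS avoids both restrictions that motivate pruning — it tolerates collinear
predictors and $n < p$ — at the price of a less direct interpretation. The
implementation is NIPALS with X-deflation (orthogonal scores): per
component, the weight vector $w$ maximizes covariance between $Xw$ and the
Y block, both blocks are regressed on the score $t = Xw$, and $X$ is
deflated. This variant was chosen because its named matrices ($T$, $W$,
$P$, $Q$) are the ones practitioners expect to inspect. The regression
coefficients use $B = W (P'W)^{-1} Q'$; the shorthand $B = WQ'$ is correct
only without deflation, and the result object's notes say so explicitly
rather than leaving two inconsistent formulas in circulation. The inner
loop stops at a relative score change below $10^{-12}$ or 500 iterations;
iteration counts are stored in the fit.

Centering is always on. Unit-variance scaling of *both* blocks is on by
default because omics panels mix measurement scales freely; it can be
switched off, and fitting pre-standardized data with scaling off is
numerically identical to fitting raw data with scaling on. Cumulative
explained variance is reported for both blocks — a single "% variance
explained" sequence is ambiguous about which block it describes, so the
ambiguity is surfaced instead of hidden.

`cross_validate()` refits per fold with the same centering/scaling policy
and pools squared prediction errors into RMSEP, MSEP and $R^2$ curves per
response and component count, including the 0-component baseline (predict
the training mean). $R^2$ is $1 - \mathrm{PRESS}/\mathrm{SS}_{tot}$ with
$\mathrm{SS}_{tot}$ about the full-data mean. Leave-one-out is the default
scheme: it is deterministic and matches the small-$n$ regime this toolkit
targets; k-fold is available but demands an explicit seed so the fold
shuffle is reproducible.

## The synthetic generator

`generate_paired_omics()` plants known canonical structure: for each
$\rho_i$ a shared latent $z_i \sim N(0,1)$ gives $u_i = z_i$ and
$v_i = \rho_i z_i + \sqrt{1-\rho_i^2}\,\epsilon_i$, the latent blocks are
embedded through random orthonormal loadings, and isotropic noise of sd
$\sigma$ is added to every feature. Population canonical correlations of
the construction are $\rho_i/(1+\sigma^2)$ — equal to the plants when
noiseless. The latent construction (rather than specifying a joint
covariance matrix directly) also hands PLS experiments a ground-truth
latent count.

Defaults: `noise_sd = 0.1`, i.e. an attenuation of about 1%, small enough
that recovery checks against the planted values are meaningful while
keeping all matrices full-rank (a noiseless generation with more features
than latents is rank-deficient and rightly rejected by `fit_cca`). The
generator emulates exactly the multivariate-normal world the statistics
assume, and deliberately **not** heteroscedastic platform noise, batch
effects or count distributions — a green test suite says the estimators
work where their assumptions hold, not that real microarray data meets
those assumptions.

`generate_fixture_knowledgebase()` writes a complete miniature snapshot
(four TSVs with header rows naming the columns) whose query metabolites
provably exercise all four resolution branches; the via-child metabolite
also carries a mapped ancestor at the same distance so the child-precedence
rule is observable, not vacuous.

All generator randomness flows through one local RNG stream seeded from the
spec; the caller's global RNG state is saved and restored, and identical
spec + seed reproduces files bit for bit.

## Validation choices and problem sizes

The test suite checks estimator correctness against independent oracles:
an alternating least-squares maximizer of $\mathrm{cor}(a'X, b'Y)$ with
deflation (and base R's QR-based `cancor`) for CCA; `lm`/QR least squares
for the full-rank PLS limit; brute-force refits for leave-one-out; a plain
breadth-first search over the raw edge table for ontology resolution; and
direct recomputation of correlation matrices for pruning.

Stochastic properties run at sizes chosen to keep Monte-Carlo error well
inside the asserted bands: planted-structure recovery uses
$\rho = (0.9, 0.6, 0)$ at $n = 1000$, $p = q = 3$ over 10 seeds, with the
$\pm 0.05$ band applied to the across-seed mean — the null component's
single-seed estimate has sampling sd $\approx n^{-1/2} \approx 0.03$, so a
per-seed band of that width would be a coin flip, and choosing
$p = q$ equal to the planted latent count keeps the null estimate's upward
bias (which grows like $\sqrt{pq/n}$) negligible. Bartlett calibration uses
2000 independent replicates at $n = 100$, $p = q = 3$; component selection
uses 20 seeds of a 2-latent plant at $n = 100$, $p = 10$, $q = 5$ with
leave-one-out. These sizes make the full suite run in well under a minute
on one CPU.

## Known limitations

* No missing-data handling, by design: every downstream statistic assumes
  complete data and no imputation rule would be anything but arbitrary here.
* No regularized or generalized CCA; when $n$ is too small even after
  pruning, PLS is the supported alternative.
* Pathway granularity is taken from the snapshot as given; no distinction
  between reactions and pathways is reconstructed.
* The pruning representative rule is greedy-by-column-order — declared, not
  derived; a different input column order can keep a different (equally
  valid) representative set.
* No namespace translation (HGNC ↔ Ensembl ↔ UniProt); matrices declare a
  namespace tag and the knowledge base must match it.
* Bartlett's test relies on the chi-squared approximation and multivariate
  normality; its calibration is verified by simulation under exactly those
  conditions and degrades outside them.
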