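---
title: "Methods: edge scoring, random featuring, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge scoring, random featuring, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larfnet)
```

## The inference problem

A gene regulatory network (GRN) over $n$ genes is a directed graph in which
an edge $G_j \to G_i$ means gene $j$ activates or suppresses target gene
$i$.  Given an expression matrix $X \in \mathbb{R}^{N \times n}$ ($N$
samples), an inference method returns a weight matrix
$W \in \mathbb{R}^{n \times n}$ whose entry $W^i_j$ is the confidence that
target $i$ is regulated by gene $j$; thresholding or ranking $W$ yields the
predicted network.  Throughout this package $W$ is indexed
*(target, regulator)*, self-edges are never scored (the diagonal is exactly
zero), and evaluation ranks all $n(n-1)$ candidate edges.

Three complementary criteria score edges, and two integrated methods
combine them:

* **MI** — Gaussian mutual information between gene pairs (undirected
  dependency).
* **ZS** — z-scores of knockout-induced expression variation (directed,
  causal, but only available with knockout data).
* **LARF** — lasso regression with random featuring (directed, works on
  any expression matrix).
* **IMLARF** $= M \circ F$ and **ISLARF** $= S \circ F$ — entry-wise
  (Hadamard) products of the corresponding matrices.  The symmetric factor
  contributes dependency strength, the LARF frequency matrix contributes
  direction, and an edge scores highly only when both criteria agree.

## Gaussian mutual information

Assuming bivariate normality, mutual information has the closed form

$$I(X_i, X_j) = -\tfrac12 \log
  \frac{\lvert \mathrm{cov}(X_i, X_j)\rvert}
       {\lvert \mathrm{cov}(X_i, X_i)\rvert \,
        \lvert \mathrm{cov}(X_j, X_j)\rvert}
  = -\tfrac12 \log (1 - \rho_{ij}^2),$$

with $\rho_{ij}$ the sample Pearson correlation.  Numerical choices:

* **Natural logarithm** (nats).  Rankings, and hence AUROC, are invariant
  to the base, so the base that makes the closed form simplest is used.
* **Sample covariance with denominator $N-1$.**  The determinant ratio
  depends only on $\rho$, so the $N$ vs $N-1$ choice does not affect the
  value, let alone the ranking.
* **Perfectly correlated pairs.**  The closed form diverges as
  $|\rho| \to 1$; pairs with $\rho^2 \ge 1 - 10^{-12}$ are clamped at
  $-\tfrac12\log(10^{-12}) \approx 13.8$ nats with a warning, keeping
  rankings finite and stable.
* Zero-variance genes are rejected up front with the offending genes
  named: MI against a constant is undefined.

MI is symmetric and cannot orient edges, and chains of regulation induce
correlation between genes that are not directly connected, so relevance
networks built from MI alone over-predict indirect edges.  That is
precisely the weakness the integration with LARF addresses.

## Knockout z-scores

Knockout data carries causal information: if deleting gene $i$ moves gene
$j$ far from its wild-type level, $j$ is likely downstream of $i$.  With
$X^{-i}_j$ the expression of gene $j$ after knocking out gene $i$ and
$X^{wt}_j$ the wild-type level, the variation matrix is

$$D^i_j = X^{-i}_j - X^{wt}_j,$$

and the edge weight of $G_i \to G_j$ is the absolute z-score of that
variation within column $j$:

$$S^j_i = \left| \frac{D^i_j - \mu_{D_j}}{\sigma_{D_j}} \right|.$$

Two conventions deserve emphasis:

* **Signed variations are z-scored**, and only the final z is taken in
  absolute value.  Z-scoring $|D^i_j|$ instead would measure deviation
  from the mean *magnitude* and can fail to rank the largest variations
  first; a fixture in the test suite shows the two conventions produce
  different rankings.
* **The self-knockout entry $D^j_j$ is excluded** from $\mu_{D_j}$ and
  $\sigma_{D_j}$ by default (`exclude_self = TRUE`).  A gene's own
  collapse when it is deleted is systematically extreme, the self-edge is
  never scored, and leaving it in inflates $\sigma$ for every column.
  Whether the column statistics should include it is genuinely open —
  both behaviours are implemented, the default is documented here as this
  package's choice, and rankings within a column are unaffected by the
  companion $n-1$ vs $n-2$ denominator choice.

Columns with $\sigma < 10^{-12}$ raise an error naming the gene and
suggesting observation noise or exclusion: a column of identical
variations carries no ranking information.

## LARF: lasso with random featuring

For target gene $i$, lasso regression selects regulators by solving

$$\hat\beta_i = \arg\min_\beta
  \tfrac{1}{2m}\,\lVert X_i - X^{\setminus i}\beta \rVert_2^2
  + \lambda \lVert \beta \rVert_1 .$$

A single fit at a single $\lambda$ is unstable, and a weak true regulator
is shadowed whenever a strongly correlated competitor sits in the same
design matrix.  LARF therefore *sweeps* $\lambda$ upward from zero in
increments of `stepsize`, and at **every step** redraws

* $\lceil \alpha (n-1) \rceil$ candidate regulators (the target is never
  its own candidate), and
* $\lceil r N \rceil$ samples,

both uniformly without replacement.  Every candidate whose coefficient
exceeds $10^{-8}$ in absolute value gets its selection count incremented.
The sweep is repeated `t` times (fresh draws throughout), counts are
summed, and each target row of the count matrix $F$ is min-max
normalized:

$$F^i_j \leftarrow
  \frac{F^i_j - \min(F^i_{-i})}{\max(F^i) - \min(F^i_{-i})},$$

with the diagonal zeroed afterwards.  Rows whose off-diagonal counts are
all equal carry no information and are set to zero with a warning.
Summing the `t` repeats *before* normalizing (rather than normalizing each
repeat and averaging) is the reading adopted here; with counts of equal
expected magnitude per repeat the two differ only at the margin.

### Parameterization and numerical choices

* **Objective scaling.**  The residual term is divided by $2m$ and
  predictors are standardized (zero mean, unit population variance) per
  fit.  Under this convention a lone standardized predictor leaves the
  model at $\lambda = |x^\top y|/m$.  Within the sweep the response is
  standardized too, which puts that threshold on the correlation scale:
  every selection threshold scales linearly with $\mathrm{sd}(y)$ and
  the per-row min-max normalization removes any common scale, so the
  frequency matrix is unchanged while the sweep is bounded at
  $\max_j |\rho_j| / \texttt{stepsize}$ fits — the default
  `stepsize = 0.001` resolves a sweep into at most a thousand fits
  regardless of the data's units.  `fit_lasso()` itself only centers the
  response and returns coefficients on the original predictor scale.
* **Solver.**  Coordinate descent on the Gram form, tolerance $10^{-8}$
  on coefficient updates (well inside the $10^{-6}$ accuracy asserted by
  the tests); at $\lambda = 0$ the minimum-norm least-squares solution is
  used.  The inner loop is compiled (C++) because a benchmark run
  performs on the order of $10^5$ independent small fits; the test suite
  cross-checks the solver against glmnet and against soft-threshold
  closed forms on univariate and orthonormal designs.
* **Sweep termination.**  The sweep ends once $\lambda$ exceeds the
  largest full-data marginal covariance between the target and any
  candidate — the level beyond which no candidate could be selected no
  matter which subset is drawn (`stop_rule = "exhaustion"`).  The
  alternative of stopping at the first step whose fit selects nothing
  (`stop_rule = "empty_step"`) is equivalent when $\alpha = 1, r = 1$,
  but with small candidate subsets it fires as soon as one unlucky draw
  consists only of already-dead features: sweeps then end at essentially
  random penalties, and the selection counts lose most of their signal.
  On a three-gene cascade that single choice is the difference between
  the direct regulator winning almost always and winning barely more
  than half the time, which is why exhaustion is the default.  A safety
  cap `lambda_max = 10` guards against pathological inputs and warns
  when hit.
* **Randomness.**  One root seed; per-target, per-repeat substreams are
  derived deterministically, so the frequency matrix is independent of
  the order in which targets are computed and the whole computation is
  bit-reproducible.

### Defaults

$\alpha = 0.5$, $r = 1$, `stepsize = 0.001`, $t = 10$: featuring on,
subsampling off.  The parameter-grid protocol (`parameter_grid()`) —
repeated LARF runs per $(\alpha, r)$ cell with mean and standard
deviation of AUROC — is the instrument for revisiting that choice on a
given dataset; once featuring is active, subsampling rarely helps, and
very small values of both make results noisy on small $N$.

## Evaluation

Ranked edges are compared against a gold standard by tracing TPR
$= \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$ against FPR
$= \mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$ over every top-$k$ cutoff,
$k = 0, \dots, n(n-1)$, so the curve always spans $(0,0)$–$(1,1)$.  Tied
scores make the top-$k$ set ambiguous; each tied block contributes its
*expected* true-positive count under a random tie order, which makes the
per-$k$ points collinear within the block and the trapezoidal area equal
to the Mann–Whitney probability that a true edge outranks a non-edge.
AUROC is therefore invariant under any strictly monotone transform of the
scores, and the test suite checks it against brute-force concordant-pair
counting on small instances.

## The synthetic benchmark generator

The DREAM3 in-silico benchmarks this package's file dialect mirrors are
produced by an external nonlinear ODE simulator that is out of scope
here.  Instead, the generator uses **linear-Gaussian steady-state
kinetics**, which keep closed-form oracles available at desk scale: a
network is a sparse signed weight matrix $W$ (spectral radius kept below
0.9, so a unique steady state exists) with basal expression $b$, and a
sample solves

$$x = b + W x + e, \qquad e \sim \mathcal N(0, \sigma_p^2 I),$$

plus observation noise $\mathcal N(0, \sigma_o^2)$.  Knockouts clamp one
gene to zero, delete its equation, and solve the reduced system; the wild
type is the noiseless steady state — the same
wild-type-plus-$n$-knockouts layout as the DREAM3 knockout files.

Fixed generator conditions, chosen once as plausible for this class of
benchmark and not tuned thereafter:

* random networks: $n = 10$ genes, average in-degree 1.5, weights uniform
  on $\pm[0.5, 1]$, basal levels uniform on $[0.5, 1.5]$,
  $\sigma_o = 0.1$;
* expression samples: $\sigma_p = 0.5$, $N = 20$ for motif experiments;
* motifs: cascade $G_1 \to G_2 \to G_3$ and feed-forward loop with all
  edge weights 0.8, basal 1 — the cascade leaves $G_1$ and $G_3$
  correlated with no direct edge, the classic indirect-regulation trap.

What the generator does *not* emulate: nonlinear (saturating) kinetics,
transcription/translation dynamics, heterozygous knockdowns, time series,
and the heavy-tailed measurement noise of real microarrays.  Passing the
benchmark therefore shows that the estimators recover linear-Gaussian
steady-state structure from small samples; it does not certify
performance on real expression data.

### Benchmark protocol

The knockout-only protocol runs every method on the same simulated
knockout dataset: ZS on the knockouts directly, MI and LARF on the
wild-type row plus the $n$ knockout rows treated as $N = n + 1$
expression samples (the layout of knockout-only experiments; the wild
type can be excluded with a flag).  Ten networks (seeds) form a batch;
ten batches are used when comparing method means, a scale at which the
whole comparison completes in minutes on one CPU.  Mean AUROC is called
above chance when it exceeds 0.5 by more than three standard errors of
the mean.  On a clean cascade, note, random sampling is not expected to
trail random featuring systematically: along a Markov chain the marginal
correlation order equals the partial correlation order, so both variants
rank the direct edge first in almost all runs; featuring's advantage
appears when a target's true regulator competes with a correlated
confounder, a structure three-gene chains do not contain.

## Command-line interface

`exec/larfnet` exposes `simulate`, `infer`, `evaluate` and `grid`
subcommands over the same functions, with `--config FILE` for
`key = value` defaults (explicit flags win), a single `--seed` feeding
every random draw, exit status 0/1/2 for success / handled error / usage
error, and ranked-edge output that the `evaluate` subcommand consumes
unchanged.  Scores are written with six significant digits;
expression-matrix round-trips use seventeen, which reproduces doubles
bit-exactly.

## Known limitations

* The Gaussian MI estimator sees only linear dependence; nonlinear
  regulation is visible to it exactly as far as it induces correlation.
* ZS requires a complete single-gene knockout panel and one wild type; it
  degrades gracefully with observation noise but has no defense against
  systematic batch effects between wild-type and knockout measurements.
* LARF's sweep cost grows with the largest marginal covariance divided by
  `stepsize`; strongly correlated panels with large dynamic range are the
  slow case.
* The entry-wise product leaves scores unnormalized; only rankings are
  meaningful downstream, which is all AUROC evaluation requires.
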