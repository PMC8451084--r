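---
title: "Inferring gene regulatory networks with complex-valued ODE models"
author: "cvgrn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks with complex-valued ODE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvgrn)
```

## The model

Gene regulation unfolds in time: the expression level of a target gene
changes at a rate determined by the current levels of its regulators.
`cvgrn` models each target gene $i$ of an $m$-gene system with a
complex-valued ordinary differential equation (CVODE)

$$\frac{dZ_i}{dt} \;=\; \sum_{k} \beta_k \, e_k(Z), \qquad
\beta_k \in \mathbb{C},$$

where $Z = (Z_1,\dots,Z_m)$ is the complex-valued state, the $e_k$ are
expression terms built from the gene variables with $\sin$, $\cos$,
$+$, $-$, $\times$ and protected $\div$, and the $\beta_k$ are complex
coefficients.  Compared with a real-valued ODE of the same structural
budget, the complex coefficients double the parameter space per term and
let a single term encode amplitude and rotation jointly; with an all-real
coefficient vector, real-embedded data and a real read-out the model
reduces exactly to the ordinary real ODE, so the complex family strictly
generalizes the real one (a property the test suite asserts numerically).

The regulators of gene $i$ are read off structurally: every gene variable
that appears anywhere in the fitted right-hand side of gene $i$'s equation
is a regulator of $i$.  No coefficient-magnitude threshold is applied
afterwards.  Collecting the per-gene regulator sets gives the inferred
directed network over all $m^2$ ordered pairs (self-loops are legitimate
candidates: autoregulation is common, and the candidate space must be
$m^2$ for the specificity denominators to come out right).

## From real data to complex states and back

Microarray/RNA time series are real.  Each gene is first min–max
normalized, $g' = (g - g_{\min})/(g_{\max} - g_{\min})$, per gene by
default (each gene then spans $[0,1]$, the standard convention in GRN
work; a global scope is available by flag).  A constant gene cannot be
normalized and is mapped to zero with a warning.

The normalized values are then embedded in $\mathbb{C}$.  The embedding is
an observation-model choice, and `cvgrn` ships three invertible modes:

* `phase45` (default): $z = g'\,e^{i\pi/4}$ — the value is the modulus
  along the 45° ray; the inverse read-out is $|z|$.
* `embed`: $z = g' + 0i$; read-out $\operatorname{Re} z$.
* `unit_phase`: $z = e^{i\pi g'}$; read-out $\arccos(\operatorname{Re}
  z)/\pi$ with clamping against numeric drift.

`phase45` is the default because a plain real embedding makes the
imaginary part of a coefficient invisible to the fitness whenever the
target gene does not feed back on itself (the imaginary response is
discarded by the read-out), which would defeat the point of searching
complex coefficients.  The mode is recorded in the fit object, and
predictions are converted back with the same mode.  All three round-trip
to machine precision on $[0,1]$ data.

## Fitness: trajectory prediction, not slope matching

A candidate model for gene $i$ is scored by how well it *predicts the
trajectory*: the equation is integrated over the training window with
classic fourth-order Runge–Kutta (4 substeps per sample interval by
default), the complex trajectory is converted back to real values, and the
fitness is the RMSE against the observed series, plus two small structure
penalties (below).  Integration is *decoupled*: while gene $i$'s state
evolves under its candidate equation from the observed initial value, the
other genes' states are linearly interpolated from the observed data at
the Runge–Kutta stage times.  This mirrors the per-gene independence of
the inference loop and keeps each gene's search problem one-dimensional.
Models whose state exceeds $|Z| = 10^6$ are aborted and assigned the
penalty fitness $10^9$ — evolved structures can be wildly unstable, and a
constant population size is easier to reason about than rejection.

Two deliberate numerical choices:

* **Protected division.**  On data normalized to $[0,1]$, zeros occur, so
  $a/b$ is replaced by $a/(\varepsilon\, b/|b|)$ whenever
  $|b| < \varepsilon = 10^{-6}$ (and by $a/\varepsilon$ at $b = 0$).  The
  quotient stays finite and direction-preserving.
* **RK4.**  Fourth order at fixed step is ample at the sampling densities
  of expression time series; the suite verifies the ~16× error decay per
  step halving and the analytic landing $e^{i\pi} = -1$ to $10^{-6}$.

## Structure search: grammar-guided genetic programming

Candidate right-hand sides are sentences of a small context-free grammar
with nonterminals $\{s, expr, op, pre, var\}$, terminals
$\{\sin, \cos, +, -, \times, \div, x_1,\dots,x_m\}$ and productions

```
s    -> expr
expr -> expr op expr | pre expr | var
pre  -> sin | cos
op   -> + | - | * | /
var  -> x_1 | ... | x_m
```

Working with derivation trees rather than raw expression trees means every
crossover and mutation product is syntactically valid by construction
(grammar closure — property-tested over thousands of operations).  Integer
powers are written as repeated `*`; the terminal set is the smallest one
that can express the fitted equations the method typically reports
(products, quotients, squares, trigonometric terms).

* **Initialization** draws derivations of depth ≤ 6 (node levels, root
  and terminal leaves counted), choosing uniformly among the productions
  that can still complete within the remaining budget — this tie-break
  guarantees termination.
* **Crossover** swaps a subtree pair whose roots carry the same
  nonterminal.  **Mutation** regrows the subtree under a uniformly chosen
  nonterminal, or resamples a terminal within its production slot.
  Both respect a hard depth cap of 10 (bloat control); violating
  offspring are retried and the parents returned unchanged after 20
  attempts.
* **Selection** is tournament selection of size 3 with elitism 1 —
  standard and parameter-light.
* Default rates follow common practice for this method family:
  population 50, crossover 0.9, mutation 0.1.

The top-level `+`/`-` operands of a tree become the model terms, read as a
flat signed sum; each term gets one complex coefficient, matching how such
fitted equations are conventionally written (coefficient × subexpression).

### Coefficients inside the structure search

A structure is only as good as its best coefficients, and comparing
structures through random coefficient draws is hopelessly noisy.  Every
new individual therefore receives a deterministic starting vector by
*gradient matching*: since the right-hand side is linear in $\beta$ given
the observed states, a ridge least-squares fit of the term values against
the finite-difference derivative of the target series (central differences
in the interior) is cheap and lands close to the optimum whenever the
structure is close to right.  The trajectory-RMSE fitness then evaluates
that vector, and the swarm refinement below polishes the incumbent best.
When the least-squares system is singular the coefficients fall back to a
uniform draw in the complex initialization box.

### Structure penalties

Noise-free or near-noise-free series make regulator recovery ill-posed at
the margin: an extra variable with a tiny coefficient can always shave an
infinitesimal amount of RMSE.  Two additive penalties resolve those ties:

* `parsimony` ($10^{-4}$ per leaf token): classic bloat control.
* `regulator_penalty` ($10^{-3}$ per *distinct* variable): a sparsity
  prior on the regulator set — a regulator is kept only if it buys more
  than $10^{-3}$ RMSE.  On $[0,1]$-normalized data this is a mild prior;
  it is the quantity to raise for noisy data where spurious regulators
  are more tempting.

## Coefficient search: the complex-valued firefly algorithm

With the structure fixed, the coefficient vector
$\beta \in \mathbb{C}^K$ is optimized by a firefly swarm whose positions
are complex vectors; brightness is negative fitness.  The update is the
canonical firefly rule applied to real and imaginary parts in parallel —
equivalently, on the $2K$-dimensional real unfolding:

$$p \leftarrow p + \beta_0\, e^{-\gamma r^2} (q - p)
  + \alpha\,(u - 0.5), \qquad u \sim \mathrm{U}(0,1)
  \text{ per real coordinate},$$

for every pair with $q$ brighter than $p$, with $r$ the Euclidean distance
between unfoldings.  Defaults: population 100, step size $\alpha = 0.02$,
$\beta_0 = 1$, $\gamma = 1$, 50 iterations, initialization uniform in the
complex box $[-5, 5]^2$ per coefficient.  Three deterministic details:
brightness comparisons within an iteration use the fitness values from the
iteration start; ranking ties break by firefly index; and the brightest
firefly performs a pure random walk instead of sitting still, the standard
anti-stagnation variant.  Best-ever bookkeeping makes the fitness trace
non-increasing, and seeding the swarm with the incumbent coefficient
vector guarantees refinement never returns something worse.

During evolution the swarm refines the current best individual every
`cfa_every = 5` generations ("at some iterations") and always refines the
final best.  $\alpha$-decay is off by default (a single step size is
given); a geometric decay flag exists.

## The synthetic benchmark generator

Real benchmark series (SOS DNA repair, HeLa cell cycle, E. coli
compendium subsets) are external downloads; the generator replaces them
with systems whose ground truth is known exactly, so every stage is
testable offline:

* per gene, a regulator set is drawn (each candidate with probability
  `edge_density`, at least one forced), and 1–2 terms are random
  derivations of the grammar restricted to those regulators;
* coefficients are uniform in $[-1, 1]$ — **real by default**: the
  complex→real read-out is lossy (phase and imaginary response are
  discarded), so a generating system with truly complex coefficients
  cannot be exactly self-consistent under the embed/modulus read-outs.
  Keeping the generating dynamics on the real slice makes "the true model
  fits its own data with ≈ 0 error" hold exactly, which is what a
  recovery experiment needs.  `complex_coef = TRUE` exists for stress
  tests where approximate self-consistency is acceptable;
* the initial state is the complex conversion of uniform values in
  $[0.2, 0.8]$ (avoids boundary pile-up);
* candidate systems are rejection-sampled against three screens: the
  coupled noise-free trajectory must stay within $|Z| \le 10^3$; the
  read-out may be required to stay inside given bounds (recovery
  experiments use $(0.02, 0.98)$ so the series live in the unit interval
  without renormalization); and each gene's read-out must span at least
  `min_amplitude` — a gene that barely moves is unidentifiable, since any
  near-constant expression fits it.

Simulation integrates the *coupled* system (all genes simultaneously),
converts to real, adds Gaussian observation noise, and by default min–max
normalizes, mirroring how real data would arrive.  The recovery harness
sets `normalize = FALSE` instead: renormalization is a per-gene affine
map, and the image of a grammar sentence under an affine change of
variables is generally *not* a grammar sentence (the grammar has no
constants), so exact recovery would be ill-defined on renormalized data.
The screened trajectories already live in $(0,1)$, making the flag safe.

What the generator does **not** emulate: measurement error structure of
microarrays (it uses i.i.d. Gaussian noise), unobserved regulators,
hidden-state dynamics (protein levels), irregular sampling, and the sheer
stiffness of some real transcriptional responses.  Passing recovery tests
therefore demonstrate correctness of the machinery and identifiability
under clean conditions, not performance on real data.

## Problem sizes used in the validation runs

The shipped validation harness (`recovery_experiment()`, also used by the
acceptance script and the test suite) runs ten replicates of a 2-gene,
one-term-per-gene, noise-free system with 46 samples at spacing 0.25, the
first 40 training and the last 6 held out, GGGP population 50 for 30
generations, and an inner swarm of 30 fireflies for 25 iterations.  These
sizes are the package's choice of a desk-scale experiment: across
development seed batches they recover the exact generating edge set in
8–9 of 10 replicates with held-out RMSE around $10^{-4}$, and one batch
completes in about a minute on a single core.  The inner-swarm size is
deliberately smaller than the package-default firefly settings
(population 100, 50 iterations), which are tuned for the larger real-data
fits; with gradient-matched starting vectors the small swarm is a polish
step, not the workhorse.

## Degenerate inputs and edge cases

* Constant genes: normalized to zero with a warning; they stay in the
  candidate pool, and their own equations are still fitted.
* `n_train = n`: no test window; test RMSE is `NA`.
* Time stamps missing from a file header: indices $0..n-1$ at spacing 1.
* Multi-start grammars are supported (a start symbol is drawn uniformly)
  but only the single-start grammar above is exercised in anger.
* Derivation depth is counted in node levels (root = 1, terminal leaves
  counted); the minimal derivation `s → expr → var → x_k` has depth 4.

## Known limitations

* Per-gene decoupled fitting cannot represent feedback that only exists
  through the joint dynamics; it sees other genes as exogenous inputs.
* Regulator read-off is purely structural; with noisy data the sparsity
  prior, not a significance test, separates signal from spurious terms.
* The firefly defaults ($\gamma = 1$, box $[-5,5]$) assume coefficients
  of order unity, which normalized data encourages but does not
  guarantee.
* Exact recovery claims are only meaningful for the screened,
  unnormalized synthetic regime described above.

## A worked micro-example

```{r example, eval = FALSE}
set.seed(1)
sys <- random_system(2, edge_density = 1e-9, terms_per_gene = c(1, 1),
                     n_points = 46, readout_bounds = c(0.02, 0.98),
                     min_amplitude = 0.1, max_tries = 500, seed = 42001)
dat <- simulate_grn(sys$system, sys$z0, n_points = 46, normalize = FALSE)
fit <- cvgrn(dat, n_train = 40, mode = "embed", normalize = FALSE,
             params = gggp_params(generations = 30,
                                  cfa = cfa_params(population = 30,
                                                   iterations = 25)),
             seed = 7)
summary(fit)
confusion_counts(fit, sys$network$edges, m = 2)
```
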