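---
title: "Interpreting whole-cell-model flux behaviour with wcflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting whole-cell-model flux behaviour with wcflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Whole-cell models simulate every cellular process across a cell's life
cycle and emit time series for thousands of variables. After a single gene
knockout, the question "which metabolic reactions now behave abnormally,
and what does that imply for the phenotype?" is hard to answer by eye:
each simulation carries hundreds of reaction-flux trajectories, tens of
thousands of seconds long, and "normal" behaviour is defined only
implicitly by the spread of wild-type simulations of a stochastic model.

wcflux implements a pipeline for this setting. It (1) summarises each flux
trajectory by simple regression features, (2) learns per-reaction
boundaries of normal behaviour from wild-type simulations and combines
three boundary rules into probabilistic *weak labels*, (3) trains one
neural-network classifier per reaction on those weak labels, (4) encodes
every simulation as a binary *flux profile* (one bit per reaction, 1 =
abnormal), and (5) interprets the profiles through the stoichiometric
reaction network: driver nodes, noise thresholds, per-class affected
sub-networks, and phenotype markers.

## The model, stage by stage

### Regression features

Each series is reduced to the four features of an ordinary least-squares
fit of flux on time: intercept, gradient, coefficient of determination
$R^2$, and mean squared residual (MSE). These capture level, drift,
linearity, and smoothness-versus-oscillation respectively. For a constant
series the total sum of squares is zero; we define $R^2 = 1$ there (the
constant fit is exact) and MSE $= 0$.

### Per-reaction PCA and wild-type boundaries

For one reaction, the feature vectors of all simulations (wild-type and
knockout pooled) form one PCA problem. The four features live on wildly
different scales — an intercept can be tens of flux units while a gradient
is of order $10^{-4}$ per second — so columns are z-standardised before
centring and projection; without standardisation the MSE dominates the
decomposition. Two components are retained. The sign of each loading
column is fixed by making its largest-magnitude entry positive, so scores
are reproducible across platforms.

Boundaries of normal behaviour are axis-aligned rectangles around the
wild-type scores:

* **extrema** — the bounding box of all wild-type points;
* **ci99** — the per-axis empirical $[0.5, 99.5]$ percentile box;
* **ci95** — the per-axis empirical $[2.5, 97.5]$ percentile box.

"Confidence intervals" are read as empirical per-axis percentiles
(type-7 quantiles), not parametric or bivariate regions; the boxes
therefore nest (ci95 $\subseteq$ ci99 $\subseteq$ extrema) by
construction. The boundary is closed: a point on an edge or corner counts
as normal, so ties break toward normality.

### The label model

Each boundary is a labelling function: a simulation is "abnormal" for that
function iff its score falls outside the box. The three votes are combined
by a simplified generative label model: each function's accuracy is
estimated by its mean pairwise agreement with the other two, the functions
vote with those accuracies as weights, and the emitted label is the one
with the larger weighted mass. The label's probability is its normalised
weighted mass, so unanimity gives probability 1 and the probability always
lies in $[0.5, 1]$. Weighted-mass ties (impossible with three functions
under unit weights) fall back to the unit-weight majority.

Because of nesting, a point outside the extrema box is outside all three
boxes, and a point outside ci99 is outside ci95 too; in practice the
combined label behaves like "abnormal iff outside the ci99 box", with the
weights softening borderline cases.

### Per-reaction classifiers

Each reaction gets a multilayer perceptron trained on its weak labels:
four equally wide ReLU hidden layers, softmax output, cross-entropy loss
and the Adam optimiser, trained on the trajectory itself, linearly
resampled to a fixed length and min-max scaled to $[0,1]$ per series
(constant series become all-zeros). The canonical hyperparameter grid
crosses epochs $\{5,10,15\}$, batch sizes $\{50,100,150\}$ and hidden
widths $\{750,1500,2250\}$; `grid_search()` evaluates all 27 points and
breaks ties toward fewer epochs, then smaller width, then larger batch.
Every stochastic step (initialisation, shuffling, splits) derives from an
explicit seed, so a fit is bit-reproducible.

Accuracy is estimated on a stratified 80/20 holdout; stratified 10-fold
cross-validation (`cross_validate()`) is the overfitting check — fold
means that agree with the holdout accuracy indicate the network has not
overfitted. Classifiers below 70% holdout accuracy are removed; exactly
70% is retained. Reactions whose weak labels contain a single class cannot
be trained and are dropped the same way.

### Flux profiles and their reduction

The retained classifiers turn each simulation into a binary flux profile.
Profiles are reduced by *centred, unstandardised* PCA — all bits share a
scale, so standardisation would only amplify near-constant columns. An
all-identical profile matrix has zero variance; the reduction then returns
all-zero scores with a warning rather than failing.

### Network analysis

From the stoichiometric matrix $S$ (metabolites $\times$ reactions), the
reaction graph is $A = \mathbb{1}[S^{\mathsf T}S > 0]$ computed on the
binarised matrix, with the diagonal zeroed: two reactions are adjacent iff
they share at least one metabolite, and self-sharing carries no
information for matchings. Driver nodes are the nodes left unmatched by a
matching of this undirected graph. The default strategy is
maximum-cardinality matching (a blossom implementation), which gives the
minimum possible driver count and is implementation-independent; a
deterministic greedy maximal matching over lexicographically sorted edges
is kept as an option mirroring the common greedy approach, and can only
leave the same number of drivers or more. Isolated nodes are always
drivers. Boundary metabolites of transport reactions are kept as matrix
rows, so two transport reactions can be adjacent through a shared boundary
species.

Wild-type simulations still show occasional abnormal classifications
because the underlying model is stochastic. An exponential distribution is
fitted by maximum likelihood to the wild-type per-reaction abnormality
frequencies ($\hat\lambda = 1/\bar f$) and the noise threshold is the
`coverage` quantile, $-\ln(1-c)/\hat\lambda$ with $c = 0.95$ by default.
A reaction is "consistently abnormal" in a group when its group frequency
*strictly* exceeds the threshold. (The description this reading replaces
conflates the 95% interval with the rate parameter; we fit the rate and
take the 95% quantile, and record the choice here.) All-zero wild-type
frequencies are a degenerate fit: the threshold is defined as 0 with a
warning.

### Markers

For each driver reaction, two statistics link its behaviour to phenotype:

* the **phi coefficient** between its abnormality bit and membership of
  each phenotypic class,
  $\phi = (ad - bc)/\sqrt{(a{+}b)(c{+}d)(a{+}c)(b{+}d)}$, oriented so a
  positive value means abnormality associates with the class;
* **linear separability**: a linear-kernel SVM (cost 1) fitted in the 2-D
  profile-PC space against the reaction's normality, scored on the fitted
  points themselves — the question is whether the plotted data are
  linearly separable, not held-out generalisation — passing above 95%
  accuracy.

Phenotype classes come from production flags (DNA, RNA, protein, growth,
division). The printed flag rows for "slow growing" and "septum" are
identical; they are separated by an auxiliary `division_initiated` flag
(slow-growing cells begin division at the end of the simulation but do not
complete it). The DNA class row is implemented exactly as printed
(DNA production absent, RNA/protein/growth present) even though the class
name makes the combination surprising. Unlisted combinations raise an
error rather than being guessed.

## The synthetic-data generator

The generator emulates the qualitative variety of whole-cell-model fluxes
rather than their mechanism: steady, ramping, oscillatory (sinusoid),
stepping and bursting (Poisson-timed rectangular pulses) trajectories with
additive white noise, on a uniform grid of 50,000 s at 100 s resolution
(500 points) by default, configurable to 1 s. Wild-type stochasticity is
emulated by jittering baseline, slope and amplitude by ±10% per
simulation. Fluxes may be negative (reversible reactions); nothing is
clipped. Knockouts apply perturbations whose `effect_size` is expressed in
units of the wild-type parameter's scale, so `effect_size >= 5` is a
drastic, unambiguous disruption; `collapse_to_zero` silences a reaction
entirely. Ground-truth labels mark exactly the perturbed reactions.

What the generator does **not** emulate: mass balance or any mechanistic
coupling between reactions (no FBA/ODE), realistic flux magnitudes,
correlated failures cascading through pathways, or time-varying phenotype
expression. Passing tests on synthetic ensembles therefore demonstrate
that the pipeline recovers planted signal under controlled conditions, not
that it resolves the subtler behaviours of real whole-cell-model output.

## The benchmark study and its desk-scale choices

`synthetic_benchmark()` freezes one study design: a random stoichiometric
network of 19 reactions plus one planted transport marker (20 reactions),
60 wild-type and 200 knockout simulations (five phenotypic classes of 40),
500 time points, effect size 6. The planted marker `TX_MARK` exchanges a
metabolite no other reaction touches, so it is isolated in the reaction
graph and is guaranteed to be a driver node; it collapses to zero exactly
in the metabolic class, making it a planted class marker.

Perturbation modes are matched to archetype kind so that every disruption
changes the *shape* of the trajectory: slope shifts for steady/ramp
reactions (gradient and $R^2$ move together), collapses for
oscillation/step/burst reactions (MSE and $R^2$ move together). This
matters because of a genuine property of the method: a perturbation that
moves only **one** of the four standardised features (for example a pure
offset, which changes only the intercept) creates a bimodal direction
whose variance is still 1 after z-scaling, indistinguishable in eigenvalue
terms from the three noise directions — two-component PCA can then drop
it, and the boundaries never see the separation. Disruptions that move two
or more features coherently create correlated columns whose shared
direction dominates the spectrum and is always retained. Users labelling
real data should keep this in mind when a knockout is expected to shift
only the level of a flux.

The benchmark classifier is deliberately desk-scale: trajectories
resampled to length 100, width 128, batch 50, 10 epochs. With 260
simulations and batch 50 an epoch is only five gradient updates, and a
larger epoch budget starts to memorise the weak labels' false positives
rather than the planted signal, degrading downstream marker statistics;
10 epochs sits in the canonical grid and generalises past the label
noise. The full 27-point grid at widths 750-2250 is available through
`grid_search()` for realistically sized datasets.

### What boundary false positives imply

Empirical boundaries have an intrinsic false-positive floor: a fresh
normal point falls outside a box built from $n$ reference points with
probability about $2/(n{+}1)$ per axis per tail, *independently of the
underlying distribution* (an order-statistics fact). With 60 wild-type
references and two axes this is a 6-9% false-positive rate on normal
simulations, which is exactly why the exponential noise threshold exists
downstream: occasional wild-type "abnormal" flags are expected and are
absorbed by the threshold, while consistently abnormal reactions stand
out. On the benchmark, detection of truly perturbed simulations is
complete while the all-simulation weak-label accuracy sits at 92-95%,
bounded by this floor; more wild-type references tighten it as
$2/(n{+}1)$.

## Numerical choices

* Percentiles are type-7 (sorted order statistics with linear
  interpolation), matching the default convention of the statistical
  environment.
* $R^2$ is clamped to $[0,1]$ against floating-point drift; zero-variance
  series take $R^2 = 1$, MSE $= 0$.
* PCA loading signs: largest-magnitude entry positive per column.
* Grid-search ties: fewer epochs, then smaller width, then larger batch.
* Matching: blossom maximum matching by default (driver count is then the
  graph invariant $n - 2\,|M_{\max}|$); greedy matching iterates edges in
  lexicographic reaction-id order so its result is deterministic.
* The SVM hyperplane is re-oriented so that the positive side is the
  abnormal class, making `sign(x'w + b)` a self-contained decision rule.
* Stratified folds are dealt round-robin continuing across classes, so
  per-class counts *and* total fold sizes differ by at most one.
* All seeds are explicit; a fixed seed reproduces ensembles, fits and
  scores bit-for-bit on one machine.

## Known limitations

* The reaction graph is undirected; directed controllability (and hence
  direction-aware driver sets) is out of scope.
* Pathway annotation is an offline join against a user-supplied
  reaction-to-pathway table; no live database lookups.
* The label model estimates accuracies from pairwise agreement only; a
  full generative model with explicit correlation handling could sharpen
  probabilities when labelling functions are strongly dependent.
* SVM separability is scored on the data used for fitting, by design; it
  answers "are the plotted points separable", not "would separation
  generalise".
* Synthetic ensembles cannot certify behaviour on real whole-cell-model
  output, whose trajectories are richer than the five archetype kinds.
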