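---
title: "Federated synthetic tabular data generation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated synthetic tabular data generation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fedtabsim` simulates a case study in sharing clinical tabular data through
synthetic records: tabular generative models are trained either centrally or
under horizontal federated learning (HFL) over several client partitions of
an acute-myeloid-leukemia-like (AML) clinical table, and the generated
tables are scored for fidelity (how well they reproduce the real table's
distributions and dependence structure) and privacy (how much the synthetic
records leak about the training records). This vignette explains the models,
the metrics, the tunable parameters, and the design decisions taken where
the procedure was genuinely open.

## The synthetic study table

The real cohort behind this design — 1540 patients and 12 clinical,
demographic and disease-related features after removal of the mutation
variables — is access-controlled, and the identities of the 12 retained
variables are not public. `build_aml_schema()` therefore defines an explicit
*emulation* with the same shape and mixed types: `age` (the non-IID
conditioning variable) plus four lab/disease measurements (white-cell count
and platelets as truncated log-normals, haemoglobin and marrow blast
percentage as truncated normals), and seven categorical features with 2–5
levels (sex, ECOG performance status, de-novo/secondary type, cytogenetic
risk, a disease-class variable, transplant, induction response). Categorical
cells are label-encoded integers, as in the study's preprocessing.

Records are drawn by `generate_fixture()` from a Gaussian copula: latent
multivariate-normal draws are transformed through each column's marginal
quantile function. The schema carries a target Spearman matrix coupling
clinically related pairs (age with performance status and transplant,
white-cell count with blast percentage, cytogenetic risk with response, and
so on); Spearman targets are mapped to the latent Pearson scale by
$r = 2\sin(\pi\rho/6)$, which is exact for continuous marginals and a close
approximation for the discretised ones. The copula was chosen because it
gives controllable cross-type dependence with a simple oracle: the empirical
Spearman correlation of a large draw must match the target (tested at
n = 20000 within ±0.05), and each marginal must pass a Kolmogorov–Smirnov
check against its specified distribution (statistic < 0.02).

What the fixture does *not* emulate: missingness (the study table had none
after preprocessing), the real variables' exact marginal shapes, and any
dependence beyond pairwise rank correlation. Passing tests on the fixture
therefore demonstrate that the *pipeline* behaves correctly, not that the
real AML results are reproduced; the study's printed metric values are not
reachable without the real table.

## Global encoding

Both models train on a continuous representation produced by a transformer
fitted **once on the full table before partitioning** and shared by every
client — this mirrors the study setup and guarantees no client encounters an
unseen category. Categorical columns become one-hot blocks over the schema's
label set. Each continuous column gets mode-specific normalization: a
univariate Gaussian mixture is fitted (components selected by BIC up to
`max_modes = 10`, fitted via `mclust`, then components with weight < 0.005
pruned), and a value $v$ is represented by a sampled mode indicator $k^*$
(probability proportional to the mode responsibilities) plus the normalized
scalar $\alpha = (v - \mu_{k^*}) / (4\sigma_{k^*})$ clipped to $[-1, 1]$.
Decoding inverts this by block-wise argmax (ties break to the lowest index;
an all-zero block decodes to its first position) and clips continuous values
to the schema range so any model output is schema-valid. A constant column
degenerates to a single mode with floor scale $10^{-6}$ rather than failing.
Transform round-trips are exact (to $10^{-9}$) wherever $\alpha$ is
unclipped; a `deterministic_modes` flag replaces mode sampling by argmax for
exact reproducibility in tests.

## Client partitions

Three scenarios split the 1540 rows across $N \in \{3, 5, 7, 10\}$ nodes:

* **B** (balanced): uniformly random sets of $\lfloor n/N \rfloor$ rows,
  remainder spread one per node.
* **IB** (imbalanced): $N-1$ minority nodes of $\mathrm{round}(0.05\,n)$
  rows each (77 at $n = 1540$); the last node keeps the rest.
* **IB_non_iid**: age-dependent skew. Rows are binned into quantile strata
  of `age` (default $N$ strata); within each stratum a symmetric
  Dirichlet($\alpha$) draw ($\alpha = 10$, the study value) sets per-node
  allocation proportions, realised by largest-remainder rounding. Large
  $\alpha$ recovers the balanced composition; $\alpha = 0.1$ produces
  extreme skew. The strata/Dirichlet recipe is the standard label-skew
  construction generalised to a continuous covariate; the study does not
  state how its age-dependent sampling was implemented, so this choice is
  ours. An empty node is repaired by moving one row from the largest node.

Plans are computed before training and serialize to JSON for traceability.

## Generative models

**Conditional tabular GAN.** A WGAN with gradient penalty ($\lambda = 10$)
and the training-by-sampling scheme: each training sample fixes one
categorical column (chosen uniformly) and one of its levels (log-frequency
weighted), conditioning both the generator input and the matched real row.
The generator is two FC–BatchNorm–ReLU blocks of 256 units with a linear
head; continuous scalars pass through tanh and every one-hot block through a
Gumbel-softmax with temperature 0.2. The discriminator stacks `pac = 10`
samples per input row and uses two 256-unit leaky-ReLU layers with dropout
0.5. Both networks use Adam at learning rate $2\times 10^{-4}$, weight decay
$10^{-6}$, betas (0.5, 0.9), batch size 500. The generator loss adds the
cross-entropy between the conditioning one-hot and its generated block. At
generation time the conditional vector follows the *original* category
frequencies (log-frequency weighting is a training-only device). All
forward/backward passes are hand-written over BLAS matrix operations; the
gradient of the gradient penalty uses the fixed-activation-mask derivation,
exact almost everywhere for piecewise-linear activations and verified
against finite differences to $10^{-9}$ in the tests.

**Diffusion model.** A standard DDPM over the encoded representation:
linear $\beta$ schedule from $10^{-4}$ to $0.02$ over $T$ steps (study value
$T = 500$; $\bar\alpha_T < 0.01$, so the terminal state is essentially pure
noise), a {512, 512} ReLU MLP denoiser with a 6-dimensional sinusoidal time
embedding predicting the added noise under squared error, Adam at
$10^{-4}$ with a linear per-epoch decay, and ancestral sampling. One-hot
blocks are treated as continuous during diffusion and re-argmaxed at decode.

Both models expose their state as one flat weight vector (trainable
parameters first, then the generator's batch-norm running statistics —
included because the usual FL client serialisation ships them with the
weights). `set_weights(get_weights(s))` is exact, and training is
resumable: one call of $e_1 + e_2$ epochs is bitwise identical to
consecutive calls of $e_1$ and $e_2$ epochs, because each state owns its
RNG stream and optimizer moments.

A third model kind, `resampler`, bootstraps rows of its training table. It
is the fast stub used to exercise the experiment protocol and is also a
useful null reference: its folds are real data, so fidelity metrics sit at
their calibration points.

## Federated simulation

`run_federation()` simulates FedAvg with full participation: every round
the server broadcasts the global weight vector, each client trains
`local_epochs` (default 1) on its partition, and the server aggregates by
sample-count-weighted averaging. Client environments persist across rounds:
the broadcast overwrites *weights only*, while Adam moments and the local
RNG stream continue. This makes single-node federation bitwise identical to
centralized training — the suite's keystone invariant, since every
comparison in the study is federated-versus-centralized. The study's "500
epochs and 500 federation rounds" is read as one local epoch per round, so
the federated budget equals the centralized one; this reading is
configurable. A consequence worth stating plainly: with one local step per
round and persistent optimizer state, FedAvg is close to distributed
gradient averaging, which is *benign* — at desk scale we observe federated
and centralized fidelity statistically tied, rather than the strong uniform
degradation the study reports. Simulations in which clients are
re-instantiated every round (losing optimizer state, as stateless
simulation frameworks do) would degrade federated training, but are
incompatible with the keystone invariant; we chose the keystone.

Per-client minibatches are capped at the local sample count rounded down to
a pac multiple — training on more rows per step than a client owns adds
compute without information; this was checked not to change the
federated-versus-centralized comparison before adoption.

## Fidelity metrics

* **$\phi_k$ correlation + cosine similarity (CS).** $\phi_k$ extends
  correlation to mixed numeric/categorical pairs: continuous columns are
  discretised into 10 equal-frequency bins, the pair's Pearson $\chi^2$ is
  corrected by subtracting the $(r-1)(c-1)$ independence pedestal, and the
  corrected value is inverted to the $\rho$ of a binned bivariate normal
  with matching margins (monotone root-find, tolerance $10^{-6}$; rectangle
  probabilities by 24-node Gauss–Legendre quadrature). The real and
  synthetic $\phi_k$ matrices are compared by cosine similarity of their
  strict upper triangles (the unit diagonal would only inflate similarity;
  a full-matrix option exists).
* **Vendi score (VS).** Effective diversity of the numeric block:
  $\exp(-\sum \lambda \log \lambda)$ over the eigenvalues of $K/n$, with $K$
  the cosine-similarity kernel of z-scored continuous columns (z-scoring so
  scale cannot dominate the cosine geometry; zero-variance columns stay
  raw). The nonzero eigenvalues are computed from the $d \times d$ Gram
  matrix, so the cost does not grow quadratically in $n$.
* **Hellinger distance**, per column over the union of labels (categorical)
  or 20 equal-width bins spanning the pooled range (continuous), averaged
  over the 12 columns.
* **DD-plot $R^2$.** Mahalanobis depths of the pooled continuous rows with
  respect to the real and synthetic samples (ridge $10^{-6}$), scored
  against the theoretical identity line $x = y$ (not a fitted line) and
  floored at 0. Mahalanobis depth was chosen because the study names no
  depth function.
* **Detection analysis (DLA).** Six classifier families (logistic
  regression, decision tree, random forest, gradient-boosted trees,
  k-nearest-neighbour, naive Bayes) are trained to separate real (0) from
  synthetic (1) rows on one-hot + z-scored features with a stratified 30%
  test split; per-classifier AUC, F1 and recall are reported and the fold's
  representative classifier is the F1 maximiser — the most restrictive
  case. The fixed roster replaces the study's auto-ML sweep for
  determinism. Each class is capped at a seeded subsample of 1000 rows
  before training, which keeps the battery affordable without changing its
  null behaviour (chance AUC on held-out real data). Null calibration is
  asserted in the tests: real-versus-held-out-real best AUC must land in
  [0.45, 0.60].

## Privacy attacks

All four attacks report an excess-over-baseline risk
$\max(0, (s - b) / (1 - b))$ for success rate $s$ and baseline rate $b$, the
convention of the standard anonymity-evaluation tools. Record distances are
Gower: per-column range-normalised absolute differences (numeric, capped at
1) or mismatch indicators (categorical), averaged.

* **Membership inference (MIA):** a record is claimed a member if its
  nearest synthetic neighbour is within Gower distance 0.05 (study value);
  the baseline is the claim rate on an equally sized control sample drawn
  fresh from the fixture generator (the study does not name its non-member
  set).
* **Attribute inference (AIA):** each column in turn is the secret,
  predicted from the Gower-nearest synthetic neighbour on the other
  columns; numeric success within 0.05 of the column range, categorical
  exact. The baseline attacker draws from the synthetic marginal. The
  overall risk is the mean per-column excess risk.
* **Linkability:** two disjoint column views (default: first half / second
  half of the schema; configurable) must point to intersecting
  k-nearest-synthetic-neighbour sets (k = 1 default); the baseline is the
  analytic intersection probability of random k-subsets.
* **Multivariate singling out:** 500 predicates, each the conjunction over
  *all* attributes of conditions read off a sampled synthetic record
  (categorical equality, numeric ±0.05·range — reusing the AIA tolerance);
  success means matching exactly one real record. The baseline builds
  predicates from an independent fixture draw.

Saturation and null behaviours are property-tested: copying the training
table drives MIA risk and AIA success to 1, a fully duplicated real table
drives singling-out success to 0, and independent synthetic data keeps all
risks at or below 0.05.

## Experiment protocol and statistics

`run_experiment()` runs cells of the grid {model} × {baseline, B, IB,
IB_non_iid} × {N}: one transformer fit on the full fixture, one training
per cell, then **10 synthetic tables per cell** (one trained model, ten
sampling seeds — the reading of the study's "10 different synthetic
datasets"; per-fold retraining is available via configuration), each scored
with the metric battery. Fold seeds are a pure function of (base seed,
cell, fold), so any cell reruns identically. Comparisons use the pooled
two-sample Student t (the study's printed df of 18 at 10 + 10 folds implies
pooled variance), two-sided, at significance 0.05, with no multiplicity
correction (matching the study; Benjamini–Hochberg is available), and cells
with zero variance on both sides skip the test with a flag, as the study's
tables do. Baseline-versus-federated tests and adjacent node-count tests (3
vs 5, 5 vs 7, 7 vs 10) are emitted per metric.

## Problem sizes and numerical choices

The desk-scale profile used by the tests, the analysis scripts and the
acceptance script trains for 60–100 epochs/rounds on the 1540-row fixture
with $T = 100$ diffusion steps and scores 5–10 folds per cell; the
study-scale values (500 epochs, 500 rounds, $T = 500$) are configuration
away. These sizes are the package's choice of a problem small enough to
re-run end-to-end while leaving every structural property (shapes, seeds,
protocol, calibrations) at study value. At desk scale the generative models
are far from converged, so absolute fidelity numbers are modest and the
federated-versus-centralized contrast is statistically tied (see the
federation section); the pipeline's correctness claims rest on the oracle,
calibration and keystone tests, not on reproducing the study's printed
values.

Other numerical choices: Glorot-uniform initialisation; Adam betas (0.5,
0.9) for the GAN (the reference implementation's values) and (0.9, 0.999)
for the diffusion model; batch-norm epsilon $10^{-5}$ and momentum 0.1;
$\phi_k$ root-find bracket [0, 0.999] with values above mapping to 1;
Gower distance on zero-range columns falls back to an equality indicator;
all tie-breaks are lowest-index.

## Known limitations

* The fixture emulates shape and pairwise dependence, not the real AML
  marginals; the study's printed metric values are out of reach by design.
* The hand-written networks are desk-scale: no GPU, no residual blocks in
  the generator, and runtimes grow quickly beyond a few hundred epochs.
* Federated damage mechanisms that depend on stateless clients (optimizer
  resets each round) or on multiple local epochs per round are not active
  under the default configuration, which was pinned by the
  single-node-equals-centralized invariant.
* Privacy attacks follow the cited evaluation tool's conventions but are
  re-implementations; absolute risk values should be compared within this
  package, not across tools.
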