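---
title: "Mapping dissociated transcriptomes onto a landmark reference: models and choices"
author: "spatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dissociated transcriptomes onto a landmark reference: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dissociation-based single-cell and single-nucleus RNA sequencing measures
thousands of genes per cell but destroys the tissue. Targeted in situ
sequencing (ISS) measures a small curated panel of *landmark genes* — cell
type-restricted markers — directly in a tissue section, at sub-cellular
resolution. `spatmap` combines the two: it asks, for every dissociated
transcriptome, *which positions in the section have a landmark signature
this cell's expression is compatible with*, and turns the answer into a
probabilistic mapping that lets any per-cell quantity (a gene, a cluster
label, a gene-set or regulon activity score) be painted back onto the
section as a virtual in situ image.

## The model, stage by stage

### Binning and signatures

ISS spots arrive as `(gene, x, y)` records in fractional pixel coordinates
of a fixed reference space. The space is tiled with square bins (default 16
px; partial edge tiles are kept, so a $W \times H$ space yields
$\lceil H/16 \rceil \times \lceil W/16 \rceil$ bins); a bin's *signature*
is the binary vector recording which landmarks had at least one read in it.
Tiles are half-open, so a read exactly on the outer boundary is rejected
rather than silently clamped. Presence/absence, not counts, is the default
representation: with tiles near cell size, a second read of the same gene
in the same tile adds little information, and the binary array keeps the
downstream density model honest about what was actually measured.

### On/off expression summaries

For each landmark, the dissociated expression (normalized log-expression)
is first smoothed by graph diffusion — a k-nearest-neighbour affinity
matrix with adaptive Gaussian bandwidth, symmetrised, row-normalised, and
applied $t$ times (defaults $k = 15$, $t = 3$). Raw droplet counts are
sparse and zero-inflated; a few diffusion steps make the per-landmark
marginals close to mixtures of normals without erasing the bimodal on/off
structure the mapping relies on. The operator is deterministic, so the
whole pipeline is reproducible given a seed.

Each smoothed landmark vector is then fit with one-dimensional Gaussian
mixtures for every component count $k \in \{2,\dots,8\}$ (EM, 5 seeded
restarts per $k$, convergence tolerance $10^{-6}$, variance floor
$10^{-6}$, at most 200 iterations per restart). The component count is
selected by BIC; the raw-likelihood alternative is available as
`selection = "loglik"`. The choice matters because of what happens next:
the component with the highest mean becomes the "on" population and all
remaining components are pooled by moment matching (weighted mean;
weighted second moment minus squared pooled mean) into a single "off"
normal — pooling to one normal is forced by the scoring stage, which needs
exactly one (mean, variance) pair per landmark per state. Raw likelihood
is monotone in $k$ for nested mixtures, so it always selects the top of
the range, and the surplus components split the expressing mode; the
highest-mean rule would then summarise only a sliver of the "on"
population and pool the rest into "off", destroying the very two-moment
summary the selection serves. BIC keeps the component count at the scale
of the real modes and recovers the generating parameters exactly on
simulated two-population draws.

### Scoring and the mapping matrix

A bin's signature selects, per landmark, the on or the off moments,
defining a diagonal multivariate normal over landmark expression. The
log-density of every cell under every *unique* signature is computed once
(three matrix products) and broadcast to all bins sharing the signature.

Per bin, the vector of cell log-densities is converted into a probability
distribution over cells. Softmax would give every cell non-zero weight
everywhere; instead the scores are normalised with *sparsegen-lin*, the
sparsity-scaled generalisation of sparsemax (Euclidean projection onto the
probability simplex): `sparsegen_lin(z, lam) = sparsemax(z / (1 - lam))`.
The projection zeroes out implausible cells exactly, so each bin's
distribution has small support. Choices made here:

* sparsegen operates on the log-densities — the same scores softmax would
  receive; with 80+ landmarks raw densities underflow.
* `lam = 0.9` by default. The support shrinks monotonically as `lam` grows;
  0.9 keeps a handful of candidate cells per bin at the default synthetic
  conditions. It is a config parameter, not a constant.
* Scores are shifted by their per-bin maximum after the $1/(1-\lambda)$
  scaling; sparsemax is shift-invariant, so this changes nothing but
  conditioning.
* Normalisation is per bin (column), never per cell: each column of the
  cells $\times$ bins matrix $P$ is a proper distribution over cells.

### Projection, smoothing, thresholding

The expectation of a per-cell feature $f$ under bin $i$'s distribution is
$(P^\top f)_i$ — linear, convex (fields inherit the bounds of $f$), and
exact for indicator features (giving per-bin annotation probabilities).
Because distributions are inferred per unique signature, adjacent bins can
jump; an optional Gaussian blur (separable convolution, reflective
boundary, default $\sigma = 1$ bin) suppresses the high-frequency noise.

Virtual in situ images come from thresholding. Percentile thresholds are
computed over *non-zero* values only (zeros dominate sparse fields and
would collapse the quantiles); ties at the threshold are kept
($\ge$ convention). The automatic threshold exploits the inverted-sigmoid
shape of the sorted unique non-zero values: one line is fit to $k$
consecutive values starting at the median index, another to the $k$
largest, and the threshold is the value nearest the lines' intersection.
The phrase "k smallest values starting from the median" admits two
readings; the median-anchored one is the default (`anchor = "median"`)
because the smallest values sit deep in the background plateau and their
fitted line would be nearly flat far below the signal; `anchor =
"smallest"` provides the literal reading. Default $k = 20$.

### Evaluation: divergence, LOOCV, spatial null

Reconstruction fidelity compares the measured bin set of a landmark with
the projected field binarized to the same cardinality (top-$n$ bins; ties
broken by row-then-column order so results are machine-independent). The
binarization is confined to the assayed tissue support — bins with at
least one read of any landmark. Bins never measured carry no signal to
compare against, and because every unassayed bin shares the all-zero
signature (hence one common distribution over cells and one common field
value), leaving them in lets a single tie group flood the top-$n$ cut
with a lexicographic block of background bins. The same mask is applied
to the ligand/receptor abundance fields in the communication stage. The
distance is the debiased Sinkhorn divergence
$S_\varepsilon(a,b) = OT_\varepsilon(a,b) - \tfrac12 OT_\varepsilon(a,a) -
\tfrac12 OT_\varepsilon(b,b)$ with cost $\lVert x - y\rVert^2/2$ in bin
units and $\varepsilon = \mathrm{blur}^2$ (default blur 2 bins — about one
cell diameter at 16-px tiles, enough regularisation to be fast and stable
while preserving the transport geometry). The solver anneals
$\varepsilon$ from the cost scale down to the target (two iterations per
halving) and then refines until the plan's row-marginal L1 violation drops
below $10^{-3}$ (at most 20 refinement sweeps); self-terms use a damped
symmetric fixed point. Against a tightly converged reference this is
accurate to about 1% across near, intermediate and far configurations, and
exact on small instances, where the refinement converges outright.

Significance is calibrated against a uniform spatial null: each bootstrap
replicate scatters as many bins as the measured signal uniformly over the
grid and records its divergence from the measured distribution; the tail
probability is the fraction of null divergences at or below the observed
one (threshold 0.05, no multiplicity correction). The published wording
conflates replicate count and sample size; the default reading is many
replicates each of measured cardinality (`pooled = FALSE`), with the
single-large-sample alternative behind a flag. LOOCV removes one landmark
from both the signature grid and the model, rebuilds the mapping from the
remainder, projects the held-out landmark's smoothed expression, and
scores it identically; mixture fits are shared because removing a landmark
cannot change another landmark's fit.

### Cluster marking probabilities

Whether a transcriptional cluster is "marked" by a gene is posed as a
Bayesian decision: cluster means $\mu_k$ (Normal prior with hyper-mean/SD
estimated from the reference expression pool) and SDs $\sigma_k$
(positive-truncated Cauchy located and scaled by the pool's MAD) carry the
likelihood $x_j \sim N(\mu_{c(j)}, \sigma_{c(j)}^2)$; a latent threshold
$T$ and sharpness $\alpha$ define the per-draw marking probability
$\mathrm{logistic}(\alpha(\mu_k - T))$. $T$ and $\alpha$ do not appear in
the likelihood, so their posteriors are their priors — which makes the
prior choice part of the model, not a nuisance. A symmetric prior on
$\alpha$ would force every cluster's posterior mean marking probability to
exactly 0.5 (positive and negative slopes mirror each other), so
$\alpha$ is half-Cauchy(0, 10): sharpness is a positive quantity. An
unanchored wide prior on $T$ leaves substantial mass above every cluster
mean and caps the achievable certainty regardless of separation, so $T$ is
anchored by the gene's own on/off mixture:
$T \sim N\big((\mu_{on}+\mu_{off})/2,\ ((\mu_{on}-\mu_{off})/6)^2\big)$,
placing essentially all prior mass between the two expression modes. A
consequence worth knowing: for a unimodal gene (no real on population) the
anchor collapses toward the bulk of the data and clusters come out
*unmarked* with overlapping intervals, rather than sitting at 0.5.

Sampling is Metropolis-within-Gibbs: conjugate Gibbs for $\mu_k$, adaptive
random-walk on $\log \sigma_k$ (tuned toward 44% acceptance during the 50%
warm-up), direct prior draws for $T, \alpha$; 4 chains, split-$\hat R$ on
the means must stay below 1.05. Summaries are posterior means with
equal-tailed 89% credible intervals (a percentile interval, not an HDI).
Default 2000 retained draws; 10000 in `mode = "paper"`.

### Ligand-receptor inference with reach-limited transport

Receptor complexes are functional only where all subunits are present, so
complex expression per cell is the minimum over component genes; ligand
and receptor complex expressions are projected through $P$ into spatial
mass distributions (support capped at the 400 heaviest bins — the
transport cost grows with the square of the support). Ligand mass is moved
toward receptor mass by unbalanced entropic optimal transport with KL-relaxed
marginals of strength $\rho = \mathrm{reach}^2$: mass within roughly one
reach of receptor signal is delivered (transported fraction decays as
$\exp(-d^2/4\rho)$), mass beyond it stays put. Because the KL relaxation
can locally overshoot a physical budget, the plan is projected back under
the caps (rows to ligand supply, columns to receptor capacity) before
per-bin received mass and saturation (received/capacity, clipped to [0,1])
are read off.

Interactions are ranked by
$\bar a_L \bar a_R\, e^{-S/\mathrm{reach}^2}$ — mean ligand abundance
times mean receptor abundance, damped by the spatial separation $S$
(Sinkhorn divergence between the two fields) relative to the squared
reach. No canonical integration formula exists for this combination; the
score is one documented choice and every raw term is emitted so users can
re-rank. Default reach 10 bins at desk scale, configurable; scoring can be
restricted to a region with a mask.

## The synthetic tissue

Every stage is testable without external data through a generator that
emulates exactly the statistical structure the model assumes: a circular
section organised as three concentric zones (areas 0.25/0.35/0.40 of the
disc, mimicking a cortex / intermediate / medulla layout), six
zone-restricted cell types (two per zone), and two specific landmarks per
type (12 total). Cells (default 1800) are placed uniformly within their
zone; a landmark is "on" in a cell of its own type with probability 0.9
and in others with probability 0.03; on-state expression is
$N(4, 0.6^2)$, off-state $N(0.2, 0.2^2)$, clipped at zero (log-expression
units). ISS reads are one Bernoulli(detection) trial per on-state
cell-landmark at the cell's position, with detection 0.35 — a per-molecule
efficiency in the plausible range for padlock-probe chemistry that leaves
each landmark with on the order of a hundred measured bins on the
128 x 128-bin default grid, the scale at which the evaluation stack (a
thousand bootstrap transports per landmark) runs in minutes on one CPU.
Dissociated profiles are the same expression plus $N(0, 0.3^2)$ noise with
rows shuffled; optional dropout exercises the imputation path.

What the generator does *not* emulate: optical crowding and segmentation
errors in ISS, ambient RNA and doublets in droplet data, library-size
variation (profiles are already "normalized"), continuous gradients within
zones, and cell types sharing graded rather than switch-like markers.
Passing tests on this tissue shows the machinery is correct under the
model's own assumptions; it does not certify performance on tissues where
those assumptions degrade.

## Problem sizes and numerical choices

Desk-scale defaults used throughout the tests and the acceptance script:
1800 cells, 12 landmarks on a 128 x 128-bin grid with 1000 bootstrap
replicates per landmark; the ligand-receptor re-ranking experiment uses
twenty 800-cell tissues on a 64 x 64-bin grid; the marking model runs
2000 retained draws. `mode = "paper"` switches replicates and draws to
10000. Further numerical fixtures: EM restarts are seeded and the best
likelihood wins, dead mixture components abort a restart rather than
limping on a floor; Sinkhorn tolerances as above; sparsemax tie-breaks are
exact (sorting), binarization ties lexicographic; all randomness flows
from explicit integer seeds.

## Known limitations

* The diagonal covariance ignores landmark-landmark correlation within a
  bin; strongly co-regulated landmarks make signatures look more
  informative than they are.
* Bins are treated independently given their signature; no spatial prior
  links neighbouring bins (smoothing happens only after projection).
* The marking model's threshold anchor assumes the gene genuinely has an
  on population; for unimodal genes the marking probabilities are
  conservative by construction.
* Unbalanced transport with the feasibility projection is a model of
  diffusion-limited delivery, not a kinetic binding model; competition
  between ligand species is out of scope.
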