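---
title: "Binding-energy models and PBM quality control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-energy models and PBM quality control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbem)
```

This vignette is the package's own account of its models and of the design
choices behind them: what is computed, under which assumptions, which knobs
matter, and what the bundled synthetic data can and cannot tell you about
real protein-binding microarray (PBM) experiments.

## The biophysical occupancy model

A transcription factor (TF) binding a double-stranded DNA probe is modelled
as a two-state system per sequence window. For a window $S$ of length $L$,
the binding energy is

$$E(S) \;=\; \sum_{i=1}^{L} E_{i,S_i} \;+\; \sum_{j=1}^{L-1} D_{j,(S_j,S_{j+1})},$$

where $E$ is the $L \times 4$ position-specific energy matrix (columns A, C,
G, T; lower energy = stronger binding; units of $k_BT$) and $D$ is an
optional $(L-1) \times 16$ block of adjacent dinucleotide corrections —
restricting pair terms to adjacent positions reduces the pair-parameter
count from $16L^2$ to $16(L-1)$. Window occupancy follows the Fermi–Dirac
form

$$P(S) \;=\; \frac{1}{1 + e^{E(S) - \mu}},$$

with the chemical potential $\mu$ set by the TF concentration: a window
whose energy equals $\mu$ is bound half the time. The predicted probe
intensity is a linear readout of the summed occupancies over all sliding
windows of the probe and, by default, of its reverse complement
($Y = w_1 \sum_S P(S) + b_1$). PBM probes are double-stranded, so both
strands are scanned unless `both_strands = FALSE`; a model fitted this way
is automatically invariant to reverse-complementing a probe.

Assumptions worth keeping in mind: windows contribute independently (no
cooperativity or steric exclusion between overlapping sites), the readout is
linear in total occupancy, and probe position effects are ignored.

### Identifiability and the interaction subspace

Two exact degeneracies exist. First, adding a constant to all four energies
of one position shifts every window energy equally and is absorbed by
$\mu$: only within-position contrasts of $E$ are identified. Comparisons of
energy matrices (`align_energy_matrices()`) therefore row-center both
matrices, and also scan window phase and strand, which are equally
unidentified from probe data.

Second, the 16 pair indicators of adjacent positions are collinear with the
mononucleotide indicators: their row and column sums reproduce the mono
indicators, so any marginal (single-base) energy can be written into $D$
instead of $E$. Under a symmetric Gaussian prior the fit actively prefers
*splitting* such effects across both blocks (it halves the quadratic
penalty), which would leave a large, uninterpretable $D$ even when the data
contain no interaction at all. The package therefore constrains $D$ to the
interaction subspace: each adjacent-pair $4\times4$ block is doubly
centered (all row and column sums zero, 9 free dimensions per block), and
the fit projects both the gradient and the parameter vector onto this
subspace at every step. The model's span is unchanged — marginal content
simply lives in $E$, where it belongs — and the dinucleotide block is
exactly the part of the energy function a mononucleotide model cannot
represent. The block additionally starts at zero under a stronger initial
shrinkage (`alpha_dinuc0 = 1` versus `0.01` for the other groups): it is
the higher-complexity hypothesis and must earn its parameters through the
evidence updates.

## Sparse Bayesian learning

Parameters $\theta = \{E, D, \mu, w_1, b_1\}$ are estimated by minimizing

$$F \;=\; \beta E_D + \sum_g \alpha_g E_{w,g}, \qquad
E_D = \tfrac12 \sum_i (T_i - Y_i)^2, \qquad
E_{w,g} = \tfrac12 \sum_{j \in g} \theta_j^2,$$

with one shrinkage strength $\alpha_g$ per parameter group (energy matrix,
dinucleotide block, chemical potential, output layer) and noise precision
$\beta$. The $\tfrac12$ factors make the hyperparameter updates
textbook-standard; any other constant would be absorbed by $\beta$ and
$\alpha$.

*Optimization.* Gradients are analytic (chained through the Fermi–Dirac
window sums; validated against central finite differences to $10^{-5}$
relative error in the test suite) and the step rule is resilient
backpropagation (Rprop with weight backtracking): per-parameter step sizes
grow by 1.2 while the gradient sign is stable, shrink by 0.5 on a sign flip
with the last move reverted, clamped to $[10^{-6}, 50]$, initial step 0.1.
Rprop ignores gradient magnitude, which makes it robust to the poor scaling
between the sigmoid-saturated energy parameters and the linear output
layer.

*Evidence updates.* Every 50 epochs the hyperparameters are re-estimated by
the evidence approximation with a Gauss–Newton Hessian
$H = \beta J^\top J + \mathrm{diag}(\alpha)$ (where $J = \partial Y /
\partial \theta$): the effective number of well-determined parameters in
group $g$ is $\gamma_g = N_g - \alpha_g \sum_{j \in g} [H^{-1}]_{jj}$, then
$\alpha_g \leftarrow \gamma_g / (2 E_{w,g})$ and $\beta \leftarrow (N -
\sum_g \gamma_g)/(2 E_D)$. A group whose weights collapse
($2E_{w,g} < 10^{-12}$) or whose $\alpha$ exceeds $10^6$ is frozen at zero
— the sparsity mechanism; $\beta$ is capped at $10^8$ for exactly fitted
data. The 50-epoch interval (rather than a very short one) matters: the
first update should see a partially data-adapted model, otherwise the
energy group is shrunk while still near its random initialization.

*Epoch budget.* The objective surface has a long, shallow valley between a
quasi-linear regime (small energies, $\mu$ near zero, nearly linear
occupancies) and the saturated regime that actually identifies the energy
scale. Prediction accuracy plateaus early in that valley, but the energy
matrix remains scale-compressed until the fit leaves it. Convergence to the
correct scale takes on the order of a thousand Rprop epochs; the defaults
are `max_epochs = 1500`, `tol = 1e-7` on the relative objective change,
checked between consecutive epochs under the same hyperparameters. Short
caps (a few hundred epochs) reproduce predictions well but report
systematically flattened energies — worth knowing when trading accuracy
for speed.

*Restarts and motif ranking.* Each restart draws $E$ uniformly from
$[-0.1, 0.1]$, with $\mu = b_1 = 0$, $w_1 = 1$, and restart $r$ seeded
`seed + r - 1`. A dependent fit is best warm-started from a fitted
independent model (`init_model`): the dinucleotide block then starts at
zero on top of an established energy matrix and the fit refines rather
than rediscovers the motif — from a random start, leaving the
mononucleotide plateau can take several thousand epochs on unlucky data
realizations, and a dependent-versus-independent comparison should measure
what the pair terms add, not restart luck. Restarts are ranked by training
error $E_D$ (final objectives carry each restart's own fitted $\beta$ and
are not comparable across restarts) and deduplicated: two fits whose aligned, row-centered
energy matrices correlate above 0.95 count as one motif, so ranks 1 and 2
are the first and second distinct motifs. Model selection across motif
lengths (`scan_motif_lengths()`, default grid 7–13) picks the candidate
with the highest held-out prediction correlation, breaking ties toward the
shorter motif, then the better rank.

## The PCA quality-control ellipse

Paired observations $(x_1, x_2)$ — the MA scatter of one array, or the
Z-scored 8-mer medians of two arrays — are summarized by the
eigendecomposition of their $2\times2$ sample covariance. The Hotelling
$T^2$ of a point is its Mahalanobis distance from the sample mean, computed
through unit-variance principal-component scores. The control limit at tail
probability $p$ is

$$T^2_{\mathrm{lim}} = \frac{2(n-1)(n+1)}{n(n-2)} F_{1-p}(2,\, n-2),$$

the exact two-component form; for $n > 5000$ the $\chi^2_{1-p}(2)$ quantile
is used instead (the difference is below $10^{-3}$ there and the $F$
quantile is numerically less stable at extreme tails). The default
$p = 0.0027$ gives the conventional three-standard-deviation (99.73%)
ellipse. Semi-axis $i$ has length $\sqrt{\ell_i T^2_{\mathrm{lim}}}$ along
eigenvector $i$; the package reports *full* axis lengths (twice the
semi-axis) throughout, a convention the tests assert. The slope of the
major axis is $V_{21}/V_{11}$ and of the minor axis $-V_{11}/V_{21}$ with
$V = U \mathrm{diag}(\sqrt{\ell})$; the axes cross at the sample mean.

The major axis measures the shared dynamic range; the minor axis the
disagreement between the two measurements — a narrow ellipse is a
good-quality pair. A point is flagged out of control when its $T^2$ exceeds
the limit *and* at least one coordinate lies below its mean: bright
outliers above both means are strong binders, not quality failures.
Perfectly collinear data are not an error: the ellipse degenerates to a
segment (minor length 0) and flags are computed along the major axis only.

Four parameters are reported per array or pair: major and minor axis
lengths, the Pearson correlation (between normalized signal and background
for a single array; between the paired 8-mer medians for a pair), and an
OLS slope (M on A for single arrays; array 2 on array 1 for pairs — the
orientation is a documented convention). Correlation alone is a poor
agreement measure — outlier-driven and scale-free — which is exactly why
the ellipse geometry is carried alongside it.

*Normalization.* All intensities are normalized as Z-scores of natural-log
values with the sample ($n-1$) standard deviation. The log base is
immaterial (a Z-score cancels it); natural log is used and stated so tests
can be exact. 8-mer tables collapse each 8-mer with its reverse complement
onto the lexicographic minimum by default (`collapse_rc`), the standard
practice for double-stranded probes; both behaviours are supported since
upstream pipelines differ.

## Quality classification

`fuzzy_neural_gas()` combines neural-gas prototype adaptation (rank-based
soft-max weights $h(r) = e^{-r/\lambda}$, $\lambda$ annealed geometrically
from $k/2$ to 0.01 over 100 epochs, learning rate 0.3) with fuzzy-c-means
memberships $u_{ij} \propto (1/d_{ij}^2)^{1/(m-1)}$, fuzzifier $m = 2$, on
column-standardized features. The exact update equations of this algorithm
family were never fully standardized; these constants are conventional for
neural gas and are frozen for reproducibility, with an $10^{-12}$ guard on
squared distances before inversion. As $\lambda \to 0$ the update
degenerates to winner-take-all k-means, which the tests check on a toy.
`consensus_clustering()` repeats the run (default ten times), aligns labels
by greedy prototype matching to the first run, and takes majority labels
and mean memberships — the label convention of any single run is
arbitrary. `label_quality_groups()` names the cluster with the longer mean
major axis "good" (tie-break: shorter minor axis, then cluster 1 with a
warning).

## Genomic affinity scanning

A fitted or converted energy model scans peak sequences with a unit output
layer ($w_1 = 1$, $b_1 = 0$): the affinity of a peak is the summed
Fermi–Dirac occupancy over both strands of the central 200 bp (window
$[\mathrm{mid}-100, \mathrm{mid}+100)$ around the floor midpoint, BED-style
0-based half-open coordinates, clipped to the peak). Windows containing
non-ACGT bases are skipped rather than discarding the peak. Tag counts are
then regressed on affinities by OLS; the reported $r = \sqrt{R^2}$ equals
the absolute Pearson correlation in this simple regression, and the
analysis is repeated for the top/bottom 500, 1000, 2000 and all peaks
ranked by tag count (ties keep input order).

PWMs are converted to energies as $E_{i,a} = \ln\big((f_{i,a} +
\varepsilon)/(\max_b f_{i,b} + \varepsilon)\big)$ with
$\varepsilon = 10^{-6}$: nonpositive everywhere, consensus base at zero,
finite for zero probabilities. This max-normalized log transform is a
documented convention choice; $\mu$ for scanning converted PWMs defaults
to 0 and is exposed as a flag, since nothing in a PWM determines a TF
concentration.

The motif-level summary `energy_level()` is $\ln(-\mathrm{median}(E < 0))$
— the log absolute median of the negative (binding) energies — and is
proportional to the motif's information content; it requires at least one
negative entry and is computed on the signed matrix as fitted.

## What the synthetic generators emulate

`random_truth_model()` builds a motif with one consensus base per position
(energy 0) and mismatch penalties uniform on 0.5–2 $k_BT$, with $\mu$ set
3 $k_BT$ above the consensus energy: consensus sites are bound ~95% of the
time, single mismatches are graded, and typical random windows are nearly
unbound. These values were chosen once as representative of published
protein-binding energy matrices and frozen; they matter because a much
weaker motif leaves the sigmoid in its linear regime, where the energy
scale is only weakly identified from array data. When a dinucleotide term
is requested, the default plants a single adjacent-pair correction of
$-2\,k_BT$ on the second-best bases of the two positions and lowers those
two mismatch penalties to 0.5, creating a genuine alternative binding mode
— interdependence a mononucleotide model cannot absorb into its marginals.
A pair correction planted *on* the consensus path would be nearly
equivalent to a marginal shift and would test nothing.

`simulate_pbm()` draws uniform random probe sequences (default 35 bp) and
adds Gaussian noise (default sd 0.2) to the model's predicted occupancy
directly on the normalized scale, so simulated tables are immediately
fittable; `scale = "raw"` maps through an exponential to positive
fluorescence-like values whose log Z-score recovers the normalized data.
The background column is independent noise plus a 10% signal leak.

`simulate_paired_pbm()` builds two arrays on *disjoint* random designs from
the same truth. Agreement between the arrays' 8-mer medians is limited by
coverage: each canonical 8-mer must be seen in enough distinct probe
contexts for the median to suppress the contribution of neighbouring
windows. Real array designs guarantee roughly 16–32 occurrences per 8-mer;
uniform random 35-mers reach comparable coverage only through design size,
which is why the default is 24,000 probes per array (good-pair 8-mer
correlations around 0.78 — close to, but below, the high agreement of a
good de Bruijn-designed pair; smaller designs degrade gracefully and are
used in the faster unit tests). A "bad" second array carries a per-8-mer
lognormal measurement-efficiency factor ($e^{N(0, 3)}$ by default) applied
to each window's occupancy contribution: it reorders exactly the binder
8-mers that carry the cross-array agreement, while single-array
characteristics survive. This emulates an array whose sequence-dependent
measurement biases swamp the binding signal, the failure mode that makes a
training/testing pair unusable.

What passing tests on these data do *not* show: robustness to spatial
artifacts, saturation nonlinearity, probe position effects, non-uniform
probe designs, or TFs that bind no probe at all. The generators produce
arrays whose noise is well-behaved by construction; conclusions about real
arrays rest on the methods, not on these fixtures.

`simulate_qc_features()` plants two unit-variance Gaussian clusters in
(major, minor) axis-length space a chosen number of standard deviations
apart; `simulate_peak_set()` embeds consensus sites into a synthetic
chromosome and draws Poisson tag counts increasing with true affinity.

## Problem sizes and numerical choices

The verification suite runs at sizes chosen to make each property sharp but
cheap: ellipse coverage on 200,000 points; gradient checks on 30 random
models of lengths 3, 5 and 8 with 50 probes each (central differences,
$h = 10^{-5}$); parameter recovery on 10,000 probes at noise sd 0.2 with
two restarts; the dinucleotide benefit and sparsity contrasts on 5,000
probes; paired-quality contrasts at the default 24,000-probe designs.
Recovery is scored after row-centering and phase/strand alignment, as the
model is identified only up to those transformations. Degenerate inputs
follow a simple rule: conditions that real pipelines produce (collinear QC
scatters, zero-variance groups, peaks shorter than the motif, ambiguous
bases) are handled and flagged; conditions that indicate caller error
(nonpositive intensities for log normalization, constant training signal,
empty intersections) raise typed errors.

## Known limitations

The occupancy model ignores cooperative and overlapping-site effects; the
evidence approximation is a point estimate, not a posterior; Rprop
convergence is to a local optimum and restarts are the only global device;
fuzzy neural gas fixes $k = 2$ quality groups by design; and the affinity
scan assumes tag counts respond linearly to summed occupancy, which is a
deliberate simplification of ChIP enrichment.
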