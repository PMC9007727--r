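---
title: "MEG source reconstruction with fMRI spatial priors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEG source reconstruction with fMRI spatial priors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pebmeg)
```

## The inverse problem and its hierarchical model

MEG measures the magnetic field of cortical currents at a few hundred
sensors; the distributed inverse problem asks for source amplitudes at
thousands of cortical locations, and is therefore ill posed.  `pebmeg`
frames it as a two-level Gaussian hierarchy,

$$ B = L X + E, \qquad E \sim \mathcal N(0,\, C_e), \qquad
   X \sim \mathcal N(0,\, \Gamma), $$

with $B$ the channels-by-time data, $L$ the lead field of a single-sphere
conductor, and both covariances expressed as weighted sums of fixed
components:

$$ C_e = \sum_j e^{\lambda_j} Q_j, \qquad
   \Gamma = \sum_i e^{\lambda_i} Q_i . $$

The sensor level carries a single white-noise component by default.  The
source level carries a *multiple sparse priors* (MSP) dictionary — several
hundred small cortical patches — optionally augmented with components
derived from an fMRI statistical map.  The log-scale hyperparameters
$\lambda$ are estimated from the data by restricted maximum likelihood
(ReML), i.e. by maximising the free energy — here exactly the Gaussian log
evidence of the data's second-order statistics plus the log density of a
weak Gaussian hyperprior on $\lambda$ — so that unsupported components are
switched off by the data themselves.  The posterior mean
$\hat X = \Gamma L^\top (L\Gamma L^\top + C_e)^{-1} B$ is the MAP source
estimate, and the maximised free energy (augmented with the Laplace
volume term $\tfrac12 \log\lvert\Pi\Sigma_\lambda\rvert$) is the model
evidence used to compare component sets.

This is the mechanism by which *invalid* spatial priors are harmless:
a component whose support does not help explain the measured covariance
receives a vanishing weight, so adding a wrong fMRI cluster costs little,
while a valid cluster concentrates posterior amplitude at the right
location.

## fMRI priors

An fMRI SPM{T} volume enters as probabilistic information about *where*
sources may be, never about amplitudes:

1. **Threshold** the volume at a height threshold $T$ with an extent
   threshold $k$; each surviving face-connected cluster becomes a separate
   prior, so ReML can weight clusters independently.
2. **Binarize and project** each cluster onto the cortical mesh: every
   suprathreshold voxel is assigned to its nearest mesh vertex (a Voronoi
   interpolation); the result is a binary vertex indicator.  Voxels
   farther than 20 mm from the mesh are discarded.
3. **Smooth** the indicator with the mesh Green's function
   $G = \exp(\sigma A) \approx \sum_{i=0}^{8} \sigma^i A^i / i!$, where
   $A$ is the 0/1 vertex adjacency matrix, to absorb registration error.
   The truncation at order 8 bounds the support spread to eight mesh hops;
   the remainder is below $(\sigma\lVert A\rVert)^9/9!\,e^{\sigma\lVert A\rVert}$.
4. **Form** the rank-one covariance component $Q_i = q_i q_i^\top$ from
   the smoothed indicator, scaled to unit Euclidean norm so that
   hyperparameters are comparable across clusters.

Defaults: $\sigma = 0.6$, truncation order 8, 6-connectivity for clusters,
binary (Heaviside) priors.  Continuous weighting by the T statistic is a
deliberate non-feature: binarized priors keep the fMRI contribution purely
spatial.

## Numerical design of the ReML optimizer

The data covariance is rescaled to unit mean sensor variance and sensor
components to trace $p$; source components share **one** common scale
(their mean projected trace).  Per-component normalization would silently
multiply a deep patch's implied source variance by $1/\lVert L q\rVert^2$
and push posterior amplitude into the depths; the shared scale preserves
the lead field's genuine depth weighting.

Hyperparameters ascend the free energy by damped (Levenberg) Fisher
scoring.  Two numerical rules matter at realistic problem sizes, where
$|F| \sim 10^8$ and double-precision evaluation noise is of order
$\epsilon|F| \approx 20$:

* a step is accepted if it does not *decrease* $F$ by more than
  $10^{-9}(1+|F|)$, and the damping is raised tenfold until a step is
  accepted (monotone trajectory up to that slack);
* convergence is declared only on an essentially undamped step whose
  $|\Delta F|$ falls below $\max(10^{-4},\, 10^{-7}|F|)$, or after three
  consecutive refused steps; the iteration cap is 128.

The hyperprior is $\lambda \sim \mathcal N(\log 10^{-6},\, 32)$ — weak (a
3-SD interval spans $e^{\pm 17}$ in weight) yet firm enough that redundant
components come to rest at the mean, which is what prunes them.  The lower
clamp on $\lambda$ equals the hyperprior mean, so the assembled model
covariance never drops below a $10^{-6}$ relative floor.  This floor is a
modelling statement, not only a numerical convenience: even a nominally
noiseless recording is inverted against a nonzero instrumental noise
floor.  Without it the noiseless fit is degenerate — the likelihood is
dominated by hundreds of junk dimensions at the clamp, the free-energy
surface fractures into inconsistent local optima (we observed nested
models ranked *below* their submodels), and source maps are decided by
basin roulette.

For evoked analyses the hyperparameters are fitted on the trial-averaged
data; for induced analyses on the trial-pooled second-order statistics
$\sum_i B_i B_i^\top / (N T)$, since induced power survives averaging of
covariance but not of waveforms.  Per-trial posteriors then reuse the
fixed $\lambda$ (the posterior is linear in the data at fixed
hyperparameters).

## The simulation study

The synthetic-data module emulates the paradigm the evaluation battery
scores:

* two dipoles in MNI coordinates, an **evoked** source at $(-38, 43, 5)$
  mm with waveform $\sin[2\pi \cdot 10 (t - t_0) + \pi/2]$, and an
  **induced** source at $(-54, -13, 5)$ mm with waveform
  $\sin[2\pi \cdot 24 (t-t_0)/(i\delta) + \pi/2]$, over
  $t \in [0.55, 0.85]$ s, 100 trials;
* white Gaussian sensor noise scaled per trial to a requested total SNR
  (noiseless, $+10$ dB, $-10$ dB), with SNR defined as
  $10\log_{10}$(signal power / noise power) over the whole trial;
* a synthetic SPM{T} volume with Gaussian blobs (peak T = 8, radius 8 mm)
  at both dipole sites (valid priors) and one right-frontal site at
  $(44, 31, 9)$ mm, $\ge 30$ mm from either dipole (invalid prior), on a
  4 mm grid.

Choices the source text of the paradigm leaves open, fixed here once:

* $t_0 = 0.55$ s, the window start, so both waveforms begin at amplitude 1;
* the induced trial-scale law: read literally, a trial-$i$ frequency
  $24/(i\delta)$ collapses towards DC as $i$ grows; the default instead
  draws $\rho_i = i\,\delta_i \sim \mathrm{Uniform}(0.5, 2)$ so the
  induced frequency spans 12–48 Hz on every trial while preserving the
  functional form (the literal law stays available via
  `delta_law = "literal"`);
* sampling rate 600 Hz (all simulated content is below 48 Hz, so this is
  lossless and cheap); dipole moment 10 nA·m, a typical cortical source —
  the scale cancels in every reported metric.

### Fixture geometry

Real cortical geometry is replaced by a deterministic shell: a jittered
latitude–longitude sphere of radius 66.5 mm inside a 90 mm head sphere
(centre $(0,0,40)$ mm), with the vertices nearest the two dipole sites
snapped onto them, and 275 radially oriented point magnetometers on a
120 mm helmet cap.  One geometric fact forces a design decision: in a
spherical conductor a radially oriented dipole produces *no* external
field, and the geometric normals of a sphere-like shell are radial.
Source orientations are therefore a smooth field tilted 75° from the
radial direction towards the local polar tangent — locally coherent but
non-radial, as folded cortex is in the aggregate.  Without this the
lead field is jitter noise and no method localizes anything.

What the fixture does **not** emulate: sulcal folding (and the abrupt
orientation flips across sulcal banks), gradiometer pickup geometry,
correlated or non-Gaussian sensor noise, head movement, and a template
mesh mismatched to the "subject".  Passing the battery therefore shows
that the machinery behaves as the theory predicts under a well-specified
geometry; it does not certify performance on real recordings.  One
consequence is visible in the results: with the simulated sources sitting
exactly on mesh vertices and a matched patch dictionary, the no-priors
inversion of noiseless data is already sharp (AUC ≈ 0.94), sharper than
published template-mesh simulations, so the headroom for priors at the
noiseless level is small; the classical contrast pattern is expressed at
the $-10$ dB level, where the battery asserts it.

## Evaluation battery

* **Source map**: per-vertex RMS posterior amplitude across trials (max
  over the window), normalized to $[0,1]$ — the trial-RMS is what keeps
  induced activity visible in a map.
* **ROC/AUC**: vertices within 10 mm of a true dipole are labelled
  positive (the VOI radius doubles as the labelling rule); 101 uniform
  decision thresholds on $[0,1]$; sensitivity/specificity per threshold;
  trapezoidal AUC with the $(0,0)$ and $(1,1)$ endpoints appended.  The
  implementation is checked against the Mann–Whitney rank statistic.
* **Localization**: peak error is the distance from each region's peak
  vertex to its true position (mesh partitioned by nearest true source,
  so the stronger source cannot absorb both scores); the centre-of-mass
  error uses the amplitude-weighted centroid of the connected cluster at
  50% of the map maximum containing the peak (falling back to 50% of the
  regional peak if that level excludes it).
* **Time courses**: first eigenvariate (dominant singular mode, scaled by
  its singular value, sign-aligned to the VOI mean) over a 10 mm VOI at
  each dipole; RMSE after scaling both signals to unit maximum amplitude
  (reconstructed amplitudes carry arbitrary units); one global sign flip
  per source, fixed on the averaged pair, since dipole orientation signs
  are arbitrary but per-trial flips would hide phase cancellation.
* **Spectra**: single-sided amplitude spectra calibrated so a unit
  sinusoid peaks at 1; frequency-domain RMSE on spectra of the normalized
  time courses.
* A **virtual sensor** (unit-gain LCMV spatial filter with adaptive
  diagonal loading) is included for comparison only and marked
  experimental; it takes part in no acceptance decision.

## Problem sizes and determinism

The standard battery runs five seeds × two noise levels ({noiseless,
$-10$ dB}) × four prior variants at 2000 mesh vertices, 275 channels, 100
trials and 512 MSP patches — a few minutes end to end on one CPU, chosen
so the whole study re-runs comfortably inside a test suite.  A single
global seed expands into per-stage seeds by fixed offsets (geometry:
seed; MSP sampling: seed+1; simulation: seed+101+level-index), so every
stage is independently reproducible and the entire metric bundle is a
deterministic function of the seed.

## Known limitations

* The single-sphere forward model and point magnetometers are the
  simplest defensible physics; realistic (BEM) head models and
  gradiometer baselines are out of scope.
* ReML's free-energy surface is multimodal at very high effective SNR
  even with the noise floor; different component sets can settle in
  different basins, which is visible as occasional non-monotone AUC
  across nested variants on individual seeds.
* The fMRI pathway consumes statistical volumes; estimating them from
  BOLD series, and any cross-subject registration, are out of scope.
* Binary priors only; continuous fMRI weighting is an extension point.
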