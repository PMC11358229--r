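---
title: "Models and methods behind emosearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emosearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

In a visual-search task probing the *anger superiority effect* (ASE),
children see a 3 × 3 grid of dynamic faces and report whether all faces
share the same expression or one face differs. Three display types occur:
an angry target among neutral distractors, a happy target among neutral
distractors, or nine neutral faces. Half of the trials are target-absent.
Two behavioral signatures are analysed separately:

* **Speed** — reaction-time (RT) distributions per age group × condition,
  modelled with a hierarchical Bayesian ex-Gaussian.
* **Accuracy** — yes/no detection performance, decomposed into sensitivity
  (d′) and criterion with a hierarchical Bayesian equal-variance
  signal-detection (SDT) model.

Because the attentional claim is about *emotional content*, not low-level
image properties, the package also implements the two stimulus-validation
computations used to certify that angry and happy stimuli are visually
equated: an Itti–Koch bottom-up saliency analysis over simulated search
displays, and a block-reduction image-motion metric for dynamic stimuli.

Everything is testable without any restricted face database: the
`synthetic_data` layer generates trial tables with known ground truth and
parametric face-like patches with controllable low-level content.

# Reaction times: the hierarchical ex-Gaussian model

An ex-Gaussian random variable is the sum of a Normal(µ, σ) and an
independent Exponential with mean τ; its mean is µ + τ and its variance
σ² + τ². It is the standard distributional model for RTs: the Gaussian
part captures symmetric perceptual/motor variability, the exponential
part the long right tail.

For one age group with participants *i*, conditions *k* and trials *j*:

$$\mathrm{rt}_{ikj} \sim \mathrm{exGauss}(\mu_{ik}, \sigma_{ik}, \tau_{ik})$$
$$\mu_{ik} \sim \mathrm{N}(M_{\mu k}, S_{\mu k}), \quad
  \sigma_{ik} \sim \mathrm{N}^{+}(M_{\sigma k}, S_{\sigma k}), \quad
  \tau_{ik} \sim \mathrm{N}^{+}(M_{\tau k}, S_{\tau k})$$

(N⁺ is a Normal truncated to positive values.) Partial pooling is the
point: a child can only complete a few dozen trials per condition, far too
few for stable per-participant maximum-likelihood ex-Gaussian estimates.

**Priors** are weakly informative and scale-adaptive. Writing $\bar m$ and
$\bar s$ for the mean and SD of the RTs entering the fit: group means
$M_{\mu k} \sim \mathrm{N}^{+}(\bar m, (2\bar s)^2)$,
$M_{\sigma k}, M_{\tau k} \sim \mathrm{N}^{+}(0, (2\bar s)^2)$, and all
between-participant SDs are half-Normal with scale $\bar s$. Because the
priors adapt to the data scale, the fit is equivariant under a common
rescaling of all RTs (doubling every RT doubles the posterior µ and τ) —
a property the test suite checks. Each age group is fitted in a separate
model with its conditions jointly, which matches how group-wise posteriors
are conventionally reported for this design.

## Posterior computation

No pre-packaged sampler exists in this environment for this likelihood, so
the package ships its own, written for exactly this model family:

* **Participant level.** Adaptive random-walk Metropolis on each of
  µ, σ, τ per participant × condition, plus a correlated move that
  proposes (µ + δ, τ − δ). The latter tracks the well-known µ/τ trade-off
  of the ex-Gaussian likelihood (the data pin down the sum µ + τ much more
  tightly than the difference).
* **Group level.** Conjugate Gibbs for $M_{\mu}$; adaptive MH for the
  other group means and the SDs (SDs on the log scale), with the
  truncation normalizer Φ(M/S) of the participant priors included exactly.
* **Funnel moves.** Hierarchical SD parameters mix poorly under
  single-site updates when the group SD is small (the "funnel": small S
  pins the participant values, which in turn keep S small). Two joint
  families of moves break this: *translation* (θᵢ + δ, M + δ for a whole
  family) and *rescale* (S′ = αS, θᵢ′ = M + α(θᵢ − M)), both
  Metropolis-corrected, the rescale applied several times per sweep for
  the weakly identified σ and τ spreads. A conditional inverse-gamma
  independence proposal additionally refreshes each SD globally.
* **Adaptation** of all proposal scales happens during warm-up only
  (Robbins–Monro style, targeting 44% acceptance), so the post-warm-up
  chain is a fixed Markov kernel.

The ex-Gaussian log-density is evaluated in log space. Its textbook closed
form suffers catastrophic cancellation when σ/τ is large; past a cutoff
the implementation switches to an asymptotic Mills-ratio expansion that
collapses analytically to the limiting Gaussian density (absolute accuracy
better than 1e-8 throughout, checked against a quadrature oracle).

**Run lengths.** Two presets: `"desk"` (4 chains × 2,000 iterations, 500
warm-up) for simulation and recovery work, and `"paper"` (2 chains ×
50,000 iterations, 5,000 warm-up) mirroring the long runs typical of
published analyses. Each recorded iteration performs a small fixed number
of internal update sweeps (2 for the ex-Gaussian model, 5 for the cheaper
SDT model) — sweep-level thinning that lowers autocorrelation at fixed
memory. Convergence is summarized by the split-chain R̂ for every
group-level quantity; the package warns above a threshold of 1.01.

# Accuracy: the hierarchical SDT model

Counts per participant: hits per target emotion (target-present trials
answered "different") and false alarms (target-absent trials answered
"different"). The equal-variance model with participant sensitivity
$d_{ie}$ and criterion $c_i$:

$$\mathrm{hits}_{ie} \sim \mathrm{Bin}\!\big(n^{sig}_{ie},\,
  \Phi(d_{ie}/2 - c_i)\big), \qquad
  \mathrm{fa}_{i} \sim \mathrm{Bin}\!\big(n^{noise}_{i},\,
  \Phi(-\bar d_i/2 - c_i)\big)$$

with $d_{ie} \sim \mathrm{N}(\mu_{d e}, \sigma_d)$ and
$c_i \sim \mathrm{N}(\mu_c, \sigma_c)$; priors
$\mu_d, \mu_c \sim \mathrm{N}(0, 2)$ and half-Normal(1) SDs, all weakly
informative on the probit scale.

**One criterion per participant.** The target-absent trials that generate
false alarms are shared between the two target emotions in this design, so
the model uses a single criterion per participant and lets the shared
noise response depend on the participant's *average* sensitivity
$\bar d_i$. An emotion-specific criterion would double-count the same
noise trials. The synthetic generator uses the same convention, so
generator and model agree by construction; with real data this is a
modelling choice to be aware of.

The sampler mirrors the ex-Gaussian one (conjugate Gibbs for group means,
adaptive MH elsewhere, the same funnel-breaking joint moves). Because the
binomial likelihood is orders of magnitude cheaper, it runs 5 internal
sweeps per recorded iteration by default. A unit test cross-checks the
group-level posterior against an independent Gibbs implementation of the
identical model in JAGS.

`collapse_and_refit()` relabels chosen groups to a single merged group and
refits — the standard move when a more precise pooled posterior is wanted
for older age bands whose separate posteriors are indistinguishable.

Edge rates (0 or 1) need no correction inside the Bayesian model, which
works on counts; the point-estimate utility `dprime_point()` applies the
conventional 1/(2N) correction instead.

# Inference rules

* **CI overlap.** Two cells are *credibly different* when their central
  95% credible intervals do not overlap. A shared endpoint counts as
  overlap — the conservative reading. This is deliberately a crude rule
  (it under-calls differences relative to a posterior of the contrast);
  it is used because it is the decision rule this literature reports.
* **Effect size δt.** Per posterior draw,
  $\delta_t = (\text{mean}_A - \text{mean}_B)\big/\sqrt{\textstyle\sum
  \text{variance components}}$, summarized by median and 95% CI. The
  component set is a genuine ambiguity for multilevel models. The
  package's defaults: for RT µ contrasts, the between-participant variance
  *plus* the within-participant ex-Gaussian variance (σ² + τ²), averaged
  across the two cells; for d′ contrasts, the between-participant d′
  variance. The choice is exposed through `delta_t()`'s interface, which
  accepts any set of SD component draws; reported effect sizes are only
  comparable across analyses that use the same component set.

# The synthetic-data generator

The generator is the package's testbed: it emulates the design —
configurable participants per group; 96 trials per participant by default
(48 target-absent, 24 angry-target, 24 happy-target — the session length
of a school-aged child caps realistic trial counts; counts are exact,
not stochastic, and an odd present-half assigns the extra trial
deterministically by participant parity); three age groups "I", "V", "IX"
— with group-level ex-Gaussian and SDT truths defaulting to posterior
medians typical of this paradigm (e.g. first-graders around µ ≈ 3.2 s,
σ ≈ 1.0 s, τ ≈ 1.5 s with d′ near 2.9 for angry and 2.3 for happy
targets; ninth-graders faster and more sensitive).

Participant-level parameters vary around the group truth: natural scale
for µ and d′ (SD = 10% of the group value), log scale for σ and τ (SD
0.1, guaranteeing positivity), absolute SD 0.1 for the criterion (whose
group value may be 0). The 10% figure is a convention — hierarchical
analyses of this design imply participant variation but rarely quantify
it — chosen once as a realistic middle ground and used everywhere.

RTs and responses are generated independently given the design: RT does
not depend on accuracy, matching the fact that the two models are fitted
separately. Non-positive ex-Gaussian draws are rejected and redrawn
(negligible probability at these scales, but the contract `rt > 0` is
absolute). What the generator does *not* emulate: sequential effects,
practice/fatigue drifts, attention lapses and fast guesses, RT–accuracy
coupling, or real faces. Passing recovery tests therefore certify the
*estimation machinery*, not robustness to those real-data features.

# Stimulus validation

## Saliency

`compute_saliency_map()` follows the classic conspicuity architecture:
9-level Gaussian pyramid per feature channel; channels are intensity,
red–green and blue–yellow opponency (for color input), and four
orientation-energy channels from quadrature Gabor pairs at 0°, 45°, 90°,
135°; center-surround feature maps |center − surround| for center scales
2–4 and surround offsets 3–4; Itti–Koch max-normalization N(·) (scale to
[0, 1], then weight by (1 − m̄)² where m̄ is the mean of the non-global
local maxima — maps with one dominant peak win); summation at pyramid
level 4; a second N(·) per channel; equal-weight channel average;
upsampling back to input resolution.

Implementation choices worth knowing:

* All filtering uses a **circular (wrap-around) boundary**. Consequence:
  the map of a spatially periodic display is periodic, so a display of
  nine identical patches on the 3 × 3 lattice has *exactly* equal regional
  activations and saliency index 1 — a sharp invariant the tests exploit.
* Zero-DC Gabor kernels and an absolute activation floor (1e-9) in N(·)
  make a featureless image produce an exactly null map rather than
  amplified floating-point noise.
* Images must be at least 64 px on a side; the 9-level pyramid is
  meaningless below that.
* The saliency *index* of a display is the target region's summed
  activation divided by the mean summed activation of the eight distractor
  regions. Regions are the (jittered) patch rectangles.

`run_salience_simulation()` reproduces the equating check: per replicate,
a uniformly drawn target slot, a random target identity, eight distinct
distractor identities, jittered placement, one saliency map, one index;
504 replicates per emotion by convention. The angry−happy mean index
difference is reported with its SE and a 95% percentile bootstrap
interval (the interval construction is a package choice; the quantity
itself is just a difference of means).

The face patches are parametric and synthetic by design (oval + eyes +
brows + mouth + oriented carrier texture): they give controllable
contrast and orientation energy, not photorealism. Emotion presets differ
by mouth curvature and brow tilt.

## Image motion

`image_motion()` reduces each grayscale frame by summing non-overlapping
20 × 20-pixel blocks and returns the sum of absolute differences of the
two reduced frames. "20 × 20" is read as the *block size in pixels* (a
200 × 200 frame reduces to 10 × 10); the alternative reading — a 20 × 20
grid of blocks — can be obtained by setting `block_size` to frame-size/20.
The raw value scales with frame size and intensity units;
`normalize = TRUE` divides by the number of blocks for a size-comparable
scale. Comparisons are only meaningful within one convention.

# Numerical and testing choices

* Quartiles in the Tukey filter use linear interpolation between order
  statistics (R's default type 7); Tukey's original hinges differ on small
  samples, so the convention is pinned. Fences are strict: a value exactly
  on a fence is kept. Filtering defaults to participant × condition cells,
  respecting the large group and condition RT differences; the pooled
  removal fraction is reported for comparability. RT models are fitted to
  correct trials by default (`correct_only`), a switch because the
  convention is common but not universal.
* Recovery testing uses the "desk" MCMC preset at the design's scale
  (30 participants × 48 trials for RT recovery; 85 participants with
  24 signal/48 noise trials for SDT recovery; 20 replicates each), sizes
  chosen to exercise the models at realistic data volumes while staying
  comfortably runnable on a single workstation core.
* Pipeline runs are bit-reproducible: all chain seeds derive from one run
  seed, and the manifest records MD5 checksums of every artifact.

# Known limitations

* The CI-overlap rule is conservative; contrasts of interest are better
  judged from the posterior of the difference (the δt posterior is
  reported for exactly that reason).
* The SDT shared-criterion convention and the δt component set are
  documented choices, not facts of nature; alternatives fit within the
  same interfaces.
* The saliency implementation targets the architecture, not numerical
  equality with any specific toolbox; conclusions should rest on its
  *relative* comparisons (angry vs happy under identical processing).
* Group-level σ and τ spreads are weakly identified at realistic trial
  counts; their posteriors lean on the half-Normal prior scale.
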