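# emosearch

Simulation and hierarchical Bayesian analysis of emotional visual-search
experiments, built around the *anger superiority effect* (ASE): the
finding that an angry face among distractors is detected faster and/or
more accurately than a happy one. The package is aimed at researchers who
run (or re-analyse) developmental visual-search studies and want the full
computational chain — from trial-level data to group-level credible
intervals and effect sizes — reproducible, testable, and free of any
license-restricted stimulus material.

## What it computes

**Reaction times.** RT distributions are modelled per age group ×
condition with the ex-Gaussian distribution — the convolution of a
Normal(µ, σ) with an Exponential of mean τ, so that
E[RT] = µ + τ and Var[RT] = σ² + τ². Participant-level parameters
(µᵢ, σᵢ, τᵢ) are partially pooled toward group-level means in a
hierarchical Bayesian model fitted by an adaptive
Metropolis-within-Gibbs sampler written for this likelihood (with joint
translation/rescale moves that break the hierarchical funnel).

**Accuracy.** Yes/no detection is decomposed with a hierarchical
equal-variance signal-detection model: hits ~ Binomial(n, Φ(d/2 − c)),
false alarms ~ Binomial(n, Φ(−d̄/2 − c)), with participant sensitivities
d per target emotion and a single criterion c per participant (the
target-absent trials are shared between emotions). Group-level posterior
medians and 95% credible intervals correspond to the µ_d tables such
studies report; `collapse_and_refit()` reproduces the pooled refit of
older age groups.

**Inference.** Cells are *credibly different* when their 95% credible
intervals do not overlap; standardized effect sizes use the δt index
(posterior of the mean difference divided by the square root of summed
variance components).

**Stimulus validation.** An Itti–Koch-style bottom-up saliency pipeline
(9-level pyramids, intensity/color/orientation center-surround
conspicuity, max-normalization) with a Monte-Carlo saliency-index
simulation over 3 × 3 face grids, and the block-reduction image-motion
metric for dynamic stimuli (20 × 20-pixel block sums, L1 difference of
the reduced frames).

**Synthetic data.** A first-class generator produces trial tables with
exact design counts (half target-absent; angry/happy split of the present
half), known group truths, and participant-level variation — plus
parametric face-like image patches with controllable contrast and
orientation energy for the saliency/motion modules.

## Worked example

```r
library(emosearch)

cfg <- run_config(
  input      = "simulate",
  sim_config = simulation_config(n_participants_per_group = 8,
                                 n_trials_per_participant = 96),
  out_dir    = "ase_run",
  rng_seed   = 3)
report <- run_pipeline(cfg)
report$sdt_cells[, c("group", "emotion", "median", "ci_low", "ci_high")]
```

```
   group emotion   median   ci_low  ci_high
1      I   angry 3.017357 2.271658 3.797745
2      I   happy 2.548442 2.067500 3.067229
7      V   angry 2.615559 1.982600 3.255777
8      V   happy 3.024603 2.457032 3.655372
13    IX   angry 3.042120 2.483485 3.630001
14    IX   happy 2.580434 2.042018 3.107319
```

Each row is a group-level posterior for the sensitivity µ_d of one age
group to one target emotion: first-graders ("I") separate angry targets
from noise by about 3.0 SD units of the latent evidence axis and happy
targets by about 2.5, with 95% credible intervals attached (8 simulated
participants; intervals tighten with real sample sizes). The full report
also contains the 27 ex-Gaussian RT cells (3 groups × 3 conditions ×
{µ, σ, τ}) and a comparison table with CI-overlap decisions and δt
effect sizes. All artifacts (filtered trials, posterior summaries,
comparisons, a checksummed manifest) are written to `ase_run/`.

The stimulus-validation side in two lines:

```r
disp <- generate_display(grid_layout(target_slot = 5),
                         patch_set(9, "neutral"), rng_seed = 1)
saliency_index(compute_saliency_map(disp$image), disp$layout)$saliency_index
#> [1] 1.025908
```

An index near 1 means the target patch is no more conspicuous than the
average distractor — the property a well-equated stimulus set must have.

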