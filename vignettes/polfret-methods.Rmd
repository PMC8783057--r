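---
title: "polfret: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polfret: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polfret)
```

## The experiment being modelled

A donor/acceptor-labelled Klenow fragment (KF) of DNA polymerase I binds
transiently to primer-template DNA molecules immobilised in a TIRF field
of view. Under donor excitation, the donor-emission (DD) and
acceptor-emission (DA) intensities at each DNA report on (i) whether a KF
is bound and (ii) the conformation of its fingers subdomain through the
apparent FRET efficiency

$$E^* = \frac{DA}{DA + DD},$$

with $E^* \approx 0.4$ for fingers-open and $E^* \approx 0.6$ for
fingers-closed. Movies are taken at 25 Hz (40 ms frames). Nucleotides can
be introduced mid-acquisition (time `t_add`), converting the binary
complex's spontaneous open/closed dynamics into processive nucleotide
addition: each added base is one open (dNTP-wait) plus one closed
(incorporation) step. The analysis chain turns raw traces into binding
events, decoded conformational state paths, dwell-time distributions and
rate constants.

## The simulator

`simulate_state_path()` runs an exact stochastic (Gillespie) simulation of
a continuous-time Markov scheme per molecule:

* unbound → open at `binding_rate` (pseudo-first-order; enzyme
  concentration folded in),
* binary complex: open ↔ closed at `k_close`/`k_open`, dissociation at
  `unbinding_rate_pre` (default 0.1 s⁻¹, mean bound time ≈ 10 s),
* after `t_add`: open → closed at `dntp_wait_rate` (∝ [dNTP]; a single
  pseudo-first-order step, with no explicit Michaelis constant), closed →
  open at the per-base incorporation rate, repeated until `n_max` bases
  are added,
* after extension stalls: binary dynamics again, with dissociation at
  `unbinding_rate_post` *only if* the leftover template overhang is at
  most `overhang_cutoff` (default 4) bases — blunt and short-overhang DNA
  bind KF weakly, whereas a long leftover overhang retains KF at the
  binary off-rate.

Rate switches at `t_add` truncate the pending exponential dwell and
redraw, which is exact by memorylessness.

Default rates are the measured ones where measurements exist: binary
complex `k_close` = 1.4 s⁻¹ and `k_open` = 5.3 s⁻¹ on extensible DNA
(1.1 and 29 s⁻¹ for dideoxy-terminated controls), incorporation rates
dTTP 3.4, dATP 2, dGTP 1.5, dCTP 1 s⁻¹ keyed by the incorporated
nucleotide (the template supplies the complementary base per position).
`binding_rate` (0.05 s⁻¹) and `unbinding_rate_post` (1 s⁻¹) are not
reported anywhere and are qualitative choices reproducing the observed
trace texture (several binding events per minute before addition; prompt
dissociation after full extension); treat them as non-literal.

`render_trace()` maps a state path to camera frames. A frame straddling a
state switch takes the occupancy-weighted mean intensity, because the
camera integrates photons over the exposure — note that $E^*$ is
invariant to partial-frame occupancy (both channels scale together), so
partial frames dilute intensity but not FRET. Each binding event is a
fresh KF drawn from the labelling mixture (defaults dual 15%, donor-only
30%, acceptor-only 30%, unlabelled 25%, the stoichiometry reported for
the enzyme preparation); acceptor bleaching converts dual → donor-only
emission mid-event and donor bleaching extinguishes the event. Constant
per-channel backgrounds (100 AU), an initial red-laser DA excess (first
2.4 s, from DNA localisation), and Gaussian camera noise (40 AU per
channel, giving an $E^*$ SD of ≈ 0.05 at the 600 AU bound intensity) are
added; noisy intensities may go negative and are deliberately not
clipped (offset-subtracted cameras do the same); `E_star` is `NA`
wherever the background-subtracted total is non-positive.

`simulate_experiment()` adds the population structure seen in real fields
of view: a `no_binding_fraction` (default 0.32) of DNAs with no KF
activity, and a `contaminant_fraction` (default 0.13) of "persistent
binders" — surface-adsorbed complexes that stay bound essentially
throughout and ignore nucleotide addition. Every stochastic operation
takes an explicit seed; a master seed fans out through a counter-based
map (`fan_seed`), so runs are bit-reproducible.

What the generator deliberately does **not** emulate: chemistry-step
substructure (Mg²⁺ binding, pyrophosphate release, translocation),
partially-closed mismatch states, spectral crosstalk, camera EM gain
statistics, drift, or diffraction optics beyond Gaussian spots. Passing
tests on these synthetic data therefore demonstrate correctness of the
*analysis chain* under the stated generative assumptions, not robustness
to every artefact of real recordings.

## Event detection

Detection works on total intensity DD + DA. The threshold adapts to
illumination per molecule: `factor` (default 0.5) times the median of
samples inside a 400–3000 AU window (the bound-intensity range; with the
default photophysics, bound ≈ 800 AU and background ≈ 200 AU, so the
threshold sits halfway at ≈ 400 AU). The mapping from median to
threshold is not published; `factor` is exposed and recorded in outputs.
Runs above threshold become events; single-frame dips are bridged
(`bridge_gap` = 1), events shorter than 0.5 s are discarded
(predominantly non-specific surface sticking), frames inside the
red-laser window are excluded, and events touching trace boundaries or
`t_add` carry censoring flags. In movie mode, events whose emission
centroid sits more than 0.5 px from the DNA spot are removed;
trace-table input passes through unchanged.

## HMM segmentation

Within each event (first 5 s by default, the published fitting window),
1–3-state Gaussian hidden Markov models are fitted to $E^*$ by
variational Bayes with conjugate priors: Normal-Gamma emissions weakly
anchored at $E^*$ = 0.2/0.45/0.65 (bleached-or-donor-only, open, closed)
with pseudo-count 0.25, a broad precision prior around an $E^*$ SD of
0.07, and Dirichlet transition rows with concentration 1 plus a
self-transition bonus of 2. The variational lower bound is the model
evidence surrogate; it is non-decreasing over iterations (a tested
invariant), five jittered restarts keep the best bound, and the state
count is chosen by maximum evidence with ties broken toward fewer states.
A BIC score at the posterior-mean parameters is reported alongside as a
robustness cross-check of the selection rule. States are decoded by
Viterbi (verified against exhaustive enumeration on short sequences) and
converted to dwells by run-length encoding; the first/last dwell of each
event is censored at the event boundary. State labels reuse the ensemble
classification bins (below) so "open"/"closed" mean the same thing in
every module.

## Dwell kinetics

`fit_exponential_rate()` is the workhorse: exponential MLE with
right-censored dwells entering as survival terms and left-truncation at
two frames, which compensates the systematic undercounting of one- and
two-frame dwells near the exposure time. Decoded dwells are integer frame
multiples, and a continuous-likelihood MLE applied to frame-quantised
data overestimates rates by a factor approaching
$k\,\Delta t/(1 - e^{-k \Delta t})$ (≈ 11% at 5.3 s⁻¹); the estimator
therefore uses the shifted-geometric (discrete-time) closed form
$\hat q = S/(n_{obs} + S)$, $\hat k = -\log(\hat q)/\Delta t$ whenever a
frame quantum is supplied. Under frame rounding the truncated excess is
exactly geometric, making this form unbiased and insensitive to constant
edge offsets. With continuous input and `t_min = 0` it reduces to
1/mean. Uncertainties are seeded nonparametric bootstraps; the
"drop-censored" policy is available for sensitivity analysis (the
published analysis does not state its censoring policy).

The apparent polymerisation time is the first fingers-closed dwell of an
event that begins closed (a leading open dwell of at most one frame is
tolerated — closure within the temporal resolution). Right-censored first
dwells are kept but flagged, and both including/excluding variants are
available since the published treatment is unstated; a
return-to-open-only filter reproduces the dissociation/bleaching
control. `fit_extension_model()` compares the three published treatments
of multi-base extension times: gamma with a fixed externally measured
rate, gamma with free identical rate (closed-form MLE `n/mean`), and a
per-base-type hypoexponential whose density is computed by
trapezoid-corrected FFT convolution of Erlang components — numerically
stable for arbitrarily close rates, where the textbook partial-fraction
formula cancels catastrophically — and maximised with restarts. All
variants report a Kolmogorov–Smirnov statistic; note the hypoexponential
likelihood depends on the rates only as a multiset, so recovered rates
are comparable after sorting.

`postsync_mean_fret()` aligns events at their start and fits the mean-E*
relaxation $E^*(t) = E_\infty + \Delta E\,e^{-kt} + bt$. The linear term
absorbs the slow drift produced by acceptor photobleaching of long-lived
complexes; without it the fitted rate depends strongly on the window
(validated on synthetic ground truth). The window (default 5 s) should
span several decay times so the exponential and the baseline separate.
Ensembles with $|\Delta E| < 0.02$ or with a decay unresolved within the
window are flagged unidentifiable — the expected outcome of the
no-nucleotide and mismatch controls. `arrhenius_delta_e()` converts a
rate ratio into an energy via $\Delta E = k_BT\ln(k_1/k_2)$ with
$k_BT$ = 0.593 kcal/mol at 298 K ("room temperature"); the printed form
of that expression in the source literature is typographically garbled,
but this definition reproduces its stated ≈ 1 kcal/mol for the 29/5.3
ratio.

## Ensemble views

Frames inside events are classified by fixed $E^*$ bins: donor-only
[0, 0.3), open [0.3, 0.53), closed [0.53, 0.8), unassigned-high [0.8, 1];
bins are half-open with boundary values assigned upward (the published
strict inequalities leave boundaries undefined), out-of-range values
clamp to the nearest bin, and frames below the intensity threshold are
unbound regardless of $E^*$. The heat map sorts molecules in two passes:
molecules with pre-addition binding extent below `low_binding_cutoff`
(default 0.05, a declared assumption — only the resulting ~32% fraction
is reported, not the rule) are removed as group c; the rest are sorted by
post-addition extent. Group a ("persistent binders") is ≥ 50% binding
over the final 20 s; the remaining molecules split into b-bright/b-dark
by whether any closed-class frame occurs within 10 s after `t_add`.
These three thresholds operationalise qualitative published descriptions
and are config with defaults, validated only against synthetic ground
truth. The fixed colour map is white/blue/green/red/black for
unbound/donor-only/open/closed/high.

## Numerical choices and degenerate inputs

* `compute_fret` returns `NA` (an undefined marker, not an error) when
  DD + DA ≤ 0; raw ratios are never clamped.
* Thresholding falls back to global median + 3 MAD when no sample lands
  in the AU window.
* VB-HMM: at most 200 iterations, absolute ELBO tolerance 1e-6;
  non-convergence returns the best-so-far fit flagged `converged =
  FALSE`. Empty states are regularised by the prior (no divide-by-zero).
* Hypoexponential grids use 2¹⁵–2¹⁶ points out to mean + 20 SD; the
  density integrates to 1 within 1e-6 and collapses analytically to the
  gamma when rates coincide (grouping tolerance 1e-9 relative).
* Exponential MLEs error informatively below 10 usable dwells, when all
  dwells sit at the truncation bound, or when censoring removes all
  observations under "drop-censored".
* Ties in heat-map sorting break by molecule id, making the ordering a
  pure function of the extents.

## Recovery properties and known limitations

The acceptance suite regenerates each study condition and re-runs the
whole chain: binary-complex recovery on 300 molecules × 160 s,
single-dTTP recovery on 600 molecules × 60 s, decay recovery on 400
molecules × 60 s, and 100-replicate model-selection studies on 125-frame
segments (sizes chosen to give a few hundred to a few thousand dwells per
estimate). Recovered rates are compared with the generative ones within
three *combined* standard errors, $\sqrt{se_{fit}^2 + se_{reported}^2}$,
where $se_{reported}$ is the uncertainty printed for the measured rate
that defines the condition — the generative values are themselves
measurements, not exact constants.

The dominant systematic is frame averaging: dwells shorter than about one
frame are invisible, and a missed short dwell merges its two neighbours,
so dwell-based rates are biased downward — the left-truncated likelihood
removes the quantisation bias but cannot restore merged events. The
effect grows with rate: it stays inside the combined-error band at the
binary-complex rates, while for the dideoxy opening rate (29 s⁻¹, mean
dwell below one frame at 25 Hz) the suite asserts only that the
recovered rate is biased low by less than a factor of two — the
frame-rate margin analysis for that condition. The post-synchronised
mean-E* decay is HMM-free and therefore a useful cross-check at fast
rates. No attempt is made at an explicit missed-event (dead-time)
correction; that is a deliberate scope limit.
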