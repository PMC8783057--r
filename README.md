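# polfret

Single-molecule FRET analysis of DNA-polymerase fingers dynamics during
DNA synthesis — with a built-in generative simulator of the TIRF
experiment, so the entire analysis chain is testable without any
experimental data.

## The problem

The Klenow fragment (KF) of *E. coli* DNA polymerase I moves its fingers
subdomain between an **open** and a **closed** conformation while
selecting and incorporating nucleotides. With a donor dye on the fingers
and an acceptor on the thumb, the apparent FRET efficiency

    E* = DA / (DA + DD)

of a KF bound to surface-immobilised primer-template DNA reports the
fingers state in real time (E* ≈ 0.4 open, ≈ 0.6 closed, 40 ms frames).
Adding nucleotides mid-acquisition converts the binary complex's
spontaneous open/closed dynamics into processive synthesis, and the
duration of the **first fingers-closed dwell** of a binding event is the
apparent time to polymerise the permitted number of bases. From dwells
one obtains fingers opening/closing rates, single-nucleotide
incorporation rates (dwell histograms fit single exponentials, e.g.
dTTP at ~3.4 s⁻¹), multi-base polymerisation-time distributions (sums of
exponential steps — gamma/hypoexponential models), nt/s polymerisation
rates (n nt / mean dwell), and the ~1 kcal/mol Arrhenius stabilisation of
the closed state by the primer 3′-OH, ΔE = k_B·T·ln(k₁/k₂).

The package implements that full chain:

| stage | functions |
|---|---|
| kinetic Monte Carlo simulator + camera rendering | `kinetic_scheme()`, `photophysics_model()`, `simulate_state_path()`, `render_trace()`, `simulate_experiment()`, `sample_extension_dwells()` |
| trace extraction (movie mode optional) | `compute_fret()`, `localise_spots()`, `extract_trace()`, `render_movie()` |
| binding-event detection | `adaptive_threshold()`, `detect_events()`, `proximity_filter()`, `split_by_addition()` |
| HMM segmentation (variational Bayes, max evidence) | `fit_hmm()`, `select_model()`, `decode_states()`, `extract_dwells()`, `segment_events()` |
| dwell kinetics | `fit_exponential_rate()`, `first_closed_dwell()`, `polymerisation_times()`, `fit_extension_model()`, `postsync_mean_fret()`, `polymerisation_rate()`, `arrhenius_delta_e()` |
| ensemble views | `classify_frames()`, `build_heatmap()`, `classify_groups()`, `postsync_fret_histogram()`, `render_heatmap()` |
| orchestration | `run_config()`, `run_pipeline()`, `make_demo_configs()` |

See `vignettes/polfret-methods.Rmd` for the models, priors, estimator
derivations and known limitations.

## Worked example

Simulate a binary-complex experiment (no nucleotides) at the measured
fingers rates, detect events, segment them with HMMs, and re-estimate the
rates from the decoded dwells:

```r
library(polfret)

scheme <- kinetic_scheme(n_max = 0, t_add = Inf, k_close = 1.4, k_open = 5.3)
phys   <- photophysics_model()
ex     <- simulate_experiment(scheme, phys, n_molecules = 60, duration = 160, seed = 7)

events <- detect_events_set(ex$traces)
seg    <- segment_events(ex$traces, events, seed = 8)
dw     <- seg$dwells
table(dw$state_label)
#>     closed donor_only       open
#>         76         44         93

fit_exponential_rate(dw[dw$state_label == "open", ],   frame_dt = 0.04, n_boot = 500, seed = 9)
#> rate_estimate [mle_exponential]: 1.06 +/- 0.12 s^-1 (n = 89, 15 censored)
fit_exponential_rate(dw[dw$state_label == "closed", ], frame_dt = 0.04, n_boot = 500, seed = 9)
#> rate_estimate [mle_exponential]: 3.97 +/- 0.49 s^-1 (n = 67, 3 censored)
```

The exit rate of the open state estimates the closing rate (the
generative 1.4 s⁻¹; dwells ending in dissociation are censored, so the
fit targets the conformational hazard only), and the closed-state exit
rate estimates opening (generative 5.3 s⁻¹). Fast rates near the frame
rate read low — sub-frame dwells merge their neighbours; the vignette
discusses this bias and how the acceptance suite bounds it. Donor-only
dwells come from KF molecules lacking an acceptor and are excluded from
conformational kinetics. The 3′-OH closed-state stabilisation follows
directly from the measured opening rates:

```r
arrhenius_delta_e(29, 5.3)   # dideoxy vs extensible opening, kcal/mol
#> [1] 1.006474
```

A ready-made set of desk-scale experiment designs (binary complex,
dideoxy control, 5/10/15-nt extensions, single dTTP, no-dNTP and
mismatch controls) is available via `make_demo_configs()`; run one with
`run_pipeline(cfg, "out_dir")` to get traces, events, dwells, kinetics
JSON, the sorted ensemble heat-map matrix and a manifest with hashes and
seeds.

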