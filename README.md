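# baseflip

Analysis toolkit for DNA base-eversion studies of the bacterial
8-oxoguanine (oxoG) glycosylase **Fpg/MutM**.

DNA glycosylases locate rare oxidized bases by everting ("flipping")
candidate nucleotides out of the duplex into their active site. How Fpg
discriminates the oxoG lesion from the vastly more abundant normal
guanine along that eversion pathway is quantified with three kinds of
analysis, all implemented here:

1. **A base-eversion reaction coordinate.** The eversion angle is a
   center-of-mass pseudodihedral over four points — P1, the COM of the
   four bases flanking the target pair; P2, the 5′ phosphate group COM;
   P3, the 3′ phosphate group COM; P4, the COM of the Watson–Crick edge
   of the everting base — unwrapped onto a continuous 0→~280° axis
   (intrahelical ≈ 0°, fully everted ≈ 280°).
2. **Umbrella-sampling free energies.** Windows restrained by a harmonic
   bias *U = k·Δθ²* (*k* = 0.183 kcal·mol⁻¹·deg⁻², 64 windows at 4°
   spacing, 330 K) are combined with the weighted histogram analysis
   method (WHAM) into a potential of mean force *G(θ)* anchored to
   0 kcal/mol at the intrahelical endpoint, with error bars from the
   difference of two independent runs. Per-frame observables (distances,
   hydrogen bonds, base-step twist, pairwise Coulomb + Lennard-Jones
   energies) are aggregated into 5° eversion-angle bins with the same
   two-run error convention.
3. **Steady-state kinetics.** Michaelis–Menten fits
   *v₀ = k_cat·[E]·[S]/(K_M+[S])* per replicate (active-enzyme
   normalized), specificity constants *k_sp = k_cat/K_M* (or the slope
   of the linear part of *v₀* vs *[S]* for heavily impaired mutants),
   and relative-activity tables for wild-type vs mutant enzymes.

Because trajectory data of this kind require cluster-scale MD, the
package ships first-class seeded generators that emulate all inputs at
desk scale — Metropolis sampling of analytic sum-of-Gaussian free-energy
landscapes (presets mimicking the lesion-like and normal-base-like
eversion profiles), toy multi-model PDB trajectories whose eversion
angle is known analytically, and noisy initial-velocity datasets — so
every estimator is validated end to end.

## Worked example

```r
library(baseflip)

# synthesize a two-run umbrella campaign on the lesion-like landscape
ls  <- make_landscape("oxoG_like")
mp  <- synthesize_us_campaign(ls, make_windows(0, 4, 64, 0.183),
                              seeds = c(101, 102), dir = "campaign",
                              n_samples = 5000)

# WHAM -> anchored two-run PMF with run-difference error bars
res <- run_freeenergy(mp, bin_width = 1, anchor = 0)
res$summary[c("dG_endpoints", "barrier")]
#> $dG_endpoints
#> [1] -6.106333
#>
#> $barrier
#> [1] 7.337894
```

The endpoint difference says the everted state sits ~6.1 kcal/mol below
the intrahelical state over the sampled 0–253° segment (the preset's
analytic drop over that segment is −5.99), and the highest point of the
profile relative to the intrahelical state — the eversion barrier — is
~7.3 kcal/mol (preset: 6.9). Fitting synthetic wild-type kinetics
reproduces the published-style report:

```r
ds  <- generate_kinetics_data(K_M = 8.1, k_cat = 1.7, E_total = 1,
                              noise_sd = 0, replicates = 3, seed = 1)
fit <- mm_fit(ds)
fit
#> <mm_fit> WT/oxoG: K_M 8.1 +/- 0 nM, k_cat 1.7 +/- 0 /s, k_sp 0.21 +/- 0 /nM/s (3 replicate(s))
```

*K_M* = 8.1 nM and *k_cat* = 1.7 s⁻¹ give the wild-type specificity
constant *k_sp* = 0.21 nM⁻¹s⁻¹; mutant *k_sp* values divided by this
number give the relative-activity percent column of the kinetics report
(`table_report()`).

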