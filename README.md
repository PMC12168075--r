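# rnacleave

Top-down mass spectrometry of RNA backbone cleavage: exact-mass and
fragment-ion modelling for chemically modified RNA, synthetic CAD spectra
with known ground truth, fragment assignment with internal recalibration,
guanosine cleavage-preference statistics, and alkaline-hydrolysis product
kinetics.

## The problem

Gaseous (M − *n*H)<sup>*n*−</sup> ions of RNA, vibrationally activated by
low-energy collisionally activated dissociation (CAD), cleave their
phosphodiester backbone preferentially on the 5′ side of guanosine,
producing complementary *c* (2′,3′-cyclic phosphate) and *y* (5′-OH)
fragments — the same products as ribozyme-catalysed and alkaline
self-cleavage in solution. Quantifying that preference, and how
site-specific modifications (deazaguanosine, N2-methylguanosine, inosine)
suppress it, requires a pipeline that can

1. compute exact monoisotopic masses and fragment m/z for modified RNA
   (McLuckey a/b/c/d/w/x/y/z nomenclature, base-loss variants, negative
   mode);
2. deisotope and assign centroided FT-ICR peak lists, recalibrating
   internally on assigned c/y fragments;
3. turn assignments into site-specific yields, compare them with the
   random-cleavage null, and express the preference as a single factor;
4. analyse alkaline-hydrolysis ladders h<sub>i-j</sub> and their
   pseudo-first-order kinetics.

The package is aimed at nucleic-acid MS practitioners and at anyone who
needs a tested, scriptable reference implementation of oligonucleotide
fragment-mass arithmetic.

## The statistic at the core

For an N-mer with S = N − 1 backbone sites, n<sub>G</sub> of them 5′ of a
guanosine, the observed overall G-yield Y is the percent of all c/y
signal from G-sites. Under random cleavage E[Y] = 100·n<sub>G</sub>/S
(35% for the packaged 18-mer, 29% for the 8-mer). If G-sites cleave γ-fold
faster than the rest,

    Y(γ) = 100 · n_G γ / (n_G γ + S − n_G),

and inverting gives the effective preference factor

    γ̂ = Y/(100 − Y) · (S − n_G)/n_G,

with γ̂ = 1 exactly at the random expectation. A synthetic-spectrum
generator with a per-site propensity model (γ, per-modification
suppression factors, charge partitioning, base loss, isotope envelopes,
noise) provides ground truth for every stage.

## Worked example

```r
library(rnacleave)
seq18 <- rna_studied()$sequence[1]     # ACCCG CAAGG CCGAC GGC

monoisotopic_mass(seq18)
#> 5764.869

sim  <- simulate_cad_spectrum(seq18, n = 7, n_ions = 1e5, seed = 1)
cand <- enumerate_fragments(seq18, c("c", "y", "precursor"),
                            max_charge = 7, base_loss = TRUE)
asg  <- match_fragments(sim$peaks, cand, tol_ppm = 3)
yt   <- site_specific_yields(asg, seq18, n = 7)

overall_g_yield(yt)
#> # A tibble: 1 x 4
#>   observed random_expectation n_g_sites n_sites
#> 1     61.4               35.3         6      17

effective_preference_factor(overall_g_yield(yt)$observed, seq18)
#> 2.91
dissociation_yield(asg)
#> 63
```

The simulated run used the default preference model (γ = 2.75, 35%
precursor survival): the observed G-yield of 61% against a 35% random
expectation recovers γ̂ ≈ 2.9, and 63% of precursor ions dissociated. The
text cleavage map shows where the signal sits (`#` marks sites above 10%
combined yield):

```
cat(cleavage_map(yt, threshold = 2), sep = "\n")
#> c      |   |||||||||| 
#> 5'  ACCCGCAAGGCCGACGGC  3'
#> y   |||||||||  |       
#> G?     G   GG  G  GG
```

`autoplot(yt)` draws the per-site bar chart; `fold_change_correlation()`
compares a modified RNA against its reference and `autoplot()` of the
result gives the log-log correlation plot;
`simulate_hydrolysis_timecourse()` → `hydrolysis_site_yields()` →
`rate_estimate()` (with broom-style `tidy()`/`glance()`) covers the
solution-phase side. A thin CLI wrapping the same functions lives at
`inst/scripts/rnacleave.R` (subcommands `mass`, `fragments`, `simulate`,
`assign`, `yields`, `compare`, `hydrolysis`).

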