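---
title: "Models and methods behind rnacleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnacleave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacleave)
```

`rnacleave` models the sequence dependence of RNA phosphodiester backbone
cleavage as observed by top-down mass spectrometry: gaseous (M − *n*H)^*n*−^
ions of short RNAs subjected to low-energy collisionally activated
dissociation (CAD) cleave preferentially on the 5′ side of guanosine,
producing complementary *c* (2′,3′-cyclic phosphate) and *y* (5′-OH)
fragments, and the same chemistry drives alkaline hydrolysis in solution.
This vignette describes the models the package implements, the
parameters that matter, and the limits of what the synthetic data can
show.

## Exact-mass chemistry

Every mass in the package derives from elemental compositions over C, H,
N, O and P with fixed monoisotopic atomic masses (C 12, H 1.0078250,
N 14.0030740, O 15.9949146, P 30.9737615 Da). Seven-decimal constants are
needed so that ~9 kDa oligonucleotide masses are stable at the third
decimal, where reference tables print them. An RNA of N residues with
5′-OH/3′-OH termini is the sum of its nucleoside compositions plus N − 1
phosphodiester condensations (HPO~3~ − H~2~O each).

The residue alphabet lives in a plain-text table
(`inst/extdata/residues.tsv`): token, nucleoside formula, neutral-base
formula, and a `g_class` flag. Modified nucleosides are expressed as
composition deltas relative to guanosine — deaza variants (c^1^G, c^3^G,
c^7^G) are −N +CH, N2-methylation +CH~2~, N2,N2-dimethylation +C~2~H~4~,
and inosine −NH. The table is validated on load: nucleoside minus base
must leave the C~5~H~8~O~4~ ribose remainder, so a typo in either formula
is caught immediately. Users can point `residue_table()` at their own file
to add modifications without touching code.

We deliberately implement monoisotopic masses only; average-mass mode is
out of scope because isotope-resolved FT-ICR work never uses it.

## Fragment-ion model

Backbone fragments follow the McLuckey a/b/c/d/w/x/y/z nomenclature. The
whole table reduces to one rule: with B~i~ the neutral mass of the intact
5′ i-mer (OH/OH) and Y~j~ that of the 3′ j-mer, each ion type is the
subsequence mass plus a fixed end-group term (−H~2~O, 0, +HPO~3~ − H~2~O,
or +HPO~3~). This encodes the transesterification chemistry — no atoms are
created or destroyed, the *c* fragment carries the cyclic phosphate — and
makes the conservation identity a + w = b + x = c + y = d + z = M hold by
construction; the tests verify it to 10^−6^ Da on every site of every
packaged sequence.

Charging is modelled as pure deprotonation (m/z = (M − z·1.00727646)/z)
with no further electron-mass correction, which is exact at the
three-decimal tolerance used throughout. A fragment can carry at most as
many charges as it has phosphate moieties (one is always allowed), and
base loss is restricted to a single neutral base BH; double losses are
rare enough in low-energy CAD that they are out of scope. Losing the same
base from different retained positions is indistinguishable by mass, so
enumeration collapses such variants into one species keyed by the 5′-most
position.

Isotope envelopes are computed by exact polynomial convolution of the
elemental isotope distributions, truncated at 99.9% cumulative abundance
and indexed by extra-neutron count (spacing 1.00336 Da) — the resolution
at which FT-ICR deisotoping operates; isotopologue fine structure is not
resolved. When only a mass is known, an "RNA averagine" surrogate is used:
the mean residue of an equimolar A/C/G/U RNA (C~9.5~H~11.75~N~3.75~O~7~P
per residue), scaled to the target mass with hydrogen making up the
rounding remainder. On the packaged 8-mer the averagine envelope agrees
with the exact one within 0.05 absolute abundance at every peak.

## The synthetic-data generator

No public repository holds the spectra this kind of experiment produces,
so the package ships a generator whose ground truth is known exactly, and
every downstream stage is tested against it. One simulated spectrum draws
`n_ions` precursor ions; each either survives (fraction
`precursor_survival`) or cleaves at one site, multinomially over
normalized per-site propensities.

The propensity model has one scientific dial: sites immediately 5′ of a
guanosine-class residue carry `gamma` times the baseline propensity.
Defaults are the conditions the package's analyses emulate:

* `gamma = 2.75` — on the 18-mer reference topology (6 G-sites of 17)
  this puts 60% of the c/y signal at G-sites, the headline preference at
  0.39 charges/nt, since the expected G-yield is
  100·n~G~γ/(n~G~γ + S − n~G~).
* `modified_factors` — suppression of the preference by modification:
  ×1/10 for c^3^G (the N3 hydrogen-bond acceptor replaced by CH), ×1/3
  for inosine and m^2^G (exocyclic amino group removed or methylated),
  ×1/20 for m^2^~2~G (both interactions blocked sterically), ×1 for c^1^G
  and c^7^G, which leave the interacting positions intact.
* `precursor_survival = 0.35` — matching ~65% dissociation at the highest
  collision energies studied.
* `base_loss_fraction = 0.1`, `ay_fraction = 0` — routine nucleobase-loss
  levels; the a/w channel is off by default because the standard analysis
  uses c/y-only spectra of >10-nt RNA, and can be switched on to emulate
  high-energy or short-RNA behaviour.

The precursor charge n is partitioned between complementary fragments by
drawing the 5′-side charge from Binomial(n, i/N) — charge proportional to
fragment length, the simplest law consistent with charges arranged by
Coulombic repulsion along an extended chain — clamped so neither side
exceeds its phosphate count. No quantitative partitioning law has been
measured; the binomial choice is a stand-in to sensitivity-test against,
not a fitted model. Zero-charge fragments are invisible.

Rendered intensity is ion count × charge × isotopologue abundance:
image-current detection measures charge, and this convention makes the
summed signal of a complementary pair equal its precursor's, so the
dissociation-yield statistic reads directly off the spectrum. Intensity
noise is log-normal (mean-preserving, given CV), m/z error Gaussian in
ppm, plus uniform chemical-noise peaks — standard FT-ICR behaviour, all
exposed in `noise_default()`. Secondary fragmentation (fragments of
fragments) is not simulated; the experiments the defaults mirror choose
collision energies that minimize it.

What the simulator does *not* emulate: charge-state-dependent structure
(the real preference peaks near 0.45 charges/nt and varies per site),
site-to-site variation beyond the G/non-G contrast, detector saturation,
and isotopologue fine structure. Passing tests therefore demonstrate that
the pipeline recovers a known propensity model from realistic peak lists —
not that real spectra obey that model.

## Assignment

Vendor deisotoping algorithms are proprietary, so matching uses a
transparent rule: a candidate is accepted when at least
`min_isotopologues` (default 2) consecutive isotopologues each match
within `tol_ppm` (default 3) and the matched intensities have cosine
similarity ≥ 0.9 with the theoretical envelope. For heavy fragments whose
monoisotopic peak is lost in the noise, the matched run may start past
k = 0, up to the envelope apex. A major isotopologue (≥ 5% of the
envelope) claimed by two accepted candidates marks both assignments
ambiguous; ambiguous assignments are excluded from statistics rather than
intensity-split, mirroring the exclusion of non-unambiguous products in
the hydrolysis analysis. The defaults are engineering choices documented
here, not values inferred from any instrument.

Internal recalibration fits theoretical on observed m/z by least squares
over assigned c/y fragments — the standard internal-calibrant practice —
and applies the line to all peaks. It requires two calibrants spanning the
range, reports post-fit residuals, and in tests reduces an injected
2-ppm + 1-mDa error to < 0.1 ppm median residual.

## Cleavage statistics

Site-specific yields follow the figure-caption convention: yield of c~k~
(respectively y~N−k~) as percent of all c and y signal, base-loss variants
pooled into their parent fragment, a/w and other channels excluded from
the denominator. Yields sum to 100 by construction. The overall G-yield
sums sites 5′ of guanosine-class residues — modified guanosines count,
inosine does not, and `include` lets an analysis reclassify (inosine sites
are displayed separately when studying the amino-group contribution). The
random-cleavage null, 100·n~G~/S, depends only on topology: 35% for the
18-mer (6/17), 29% for the 8-mer (2/7).

The effective preference factor inverts the null:
γ̂ = Y/(100 − Y) · (S − n~G~)/n~G~, equal to 1 exactly at the random
expectation, 2.75 at the 60% headline. The round trip through the
analytic yield is an identity for any γ and topology (tested), and on
simulated ensembles γ̂ recovers the generator's γ within a few percent.

Fold changes between a modified and a reference run first normalize each
run to its total c/y signal — correlation plots compare separately
acquired spectra, which have no common intensity scale — then ratio the
normalized c~k~ + y~N−k~ sums at the site of interest. Overall yields are
abundance-weighted across charge states (a stated convention; the
alternative, count-weighting, is not implemented because abundance is
what the spectra measure). Reported percentages are conventionally
rounded to the nearest integer; the tables keep full precision.

## Hydrolysis

Alkaline hydrolysis products h~i-j~ retain residues i through j of the
parent. Only products keeping an original terminus are analysed (3(N − 1)
species per sequence): the 5′-terminal piece in both its 2′,3′-cyclic and
linear 3′-phosphate forms — at high pH cyclic phosphates open, neither
form is assumed to dominate, and the two are pooled after matching (2′-
versus 3′-linear isomers are isobaric and not distinguished) — and the
3′-terminal piece with free 5′-OH. Interior products from multiple cuts
can be simulated but are flagged and excluded, since their assignment is
not unambiguous in practice.

Kinetics follow the single-cut competing-risks model: site k cleaves at
pseudo-first-order rate k~k~, so the first cut lands at site k by time t
with probability (k~k~/k~tot~)(1 − e^−k~tot~t^). Site yields are reported
against all species including intact RNA (the convention of time-resolved
hydrolysis figures; a cut contributes both of its products to the
numerator). Rate estimation inverts that denominator back to first-cut
fractions, fits k~tot~ by nonlinear least squares on 1 − e^−k~tot~t^, and
gets per-site shares by regression through the origin; k~k~ = share ×
k~tot~ with delta-method standard errors. The two-stage fit is used
instead of a joint 17-parameter nonlinear fit because it is robust at few
time points and its errors are well-calibrated in the regime tested
(5 time points, 10^4^ molecules: median relative error ~2%, comfortably
inside the 15% design target). Grossly non-monotone yield curves set a
warning flag but still return a fit.

## Numerical choices and degenerate inputs

* Compositions refuse negative atom counts; subtraction that would owe
  atoms is an error, which catches malformed residue definitions early.
* Empty sequences, out-of-range fragment indices, zero charges, empty
  candidate lists, zero assigned c/y signal, single-m/z calibrant sets and
  negative times/rates all raise immediate errors with specific messages.
* Isotope convolution truncates terms below 10^−15^ and caps envelopes at
  64 isotopologues; truncation keeps ≥ 99.9% of the distribution.
* Ties in peak matching resolve to the nearest peak; equidistant peaks
  take the lower-m/z one.
* Simulation problem sizes in the tests (10^4^–10^5^ ions per spectrum,
  20–50-seed ensembles, 10^4^ molecules per hydrolysis time point) are
  chosen so that sampling error sits well below the tolerances being
  asserted while a full test run stays in the tens of seconds.

## Worked example

```{r example, eval = FALSE}
seq18 <- rna_studied()$sequence[1]

sim <- simulate_cad_spectrum(seq18, n = 7, n_ions = 1e5, seed = 1)
cand <- enumerate_fragments(seq18, c("c", "y", "precursor"),
                            max_charge = 7, base_loss = TRUE)
asg <- match_fragments(sim$peaks, cand, tol_ppm = 3)
yt <- site_specific_yields(asg, seq18, n = 7)
overall_g_yield(yt)
autoplot(yt)
```

## Known limitations

* The charge-partitioning law is a modelling assumption; conclusions that
  depend on the detail of fragment charge-state distributions should be
  sensitivity-tested against it.
* The generator's per-site model has a single G/non-G contrast plus
  per-modification factors; real spectra show site- and
  charge-state-specific structure it does not reproduce.
* Peak lists are assumed centroided; profile-mode data, peak picking and
  decoy-based FDR estimation are out of scope.
* DNA, 2′-modified backbones, phosphorothioates and positive-mode
  (M + *n*H)^*n*+^ chemistry are not modelled.
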