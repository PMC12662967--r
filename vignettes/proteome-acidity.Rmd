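---
title: "Methods: quantifying proteome acidity shifts under carbonate chemistry gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying proteome acidity shifts under carbonate chemistry gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidome)
```

## The scientific question

Marine organisms exposed to shifting seawater carbonate chemistry (high
CO~2~, alkalinity enrichment, or both) can remodel the acidity of their
expressed proteome: the isoelectric points (pI) of up-regulated proteins
shift relative to down-regulated ones, plausibly buffering intracellular
pH. `acidome` provides the full quantitative tool chain for this
analysis: a sequence-based pI engine, carbonate-system speciation, a
differential-abundance stage for label-free intensities, the
acidity-shift contrast itself, chemistry–composition correlation, and
cross-species proteome comparison — plus a synthetic-data generator so
that every stage can be validated against known ground truth.

## The charge model and pI engine

A protein's net charge at a given pH is the sum of Henderson–Hasselbalch
occupancies over its ionizable groups,

$$Z(\mathrm{pH}) = \sum_{b \in \mathrm{basic}}
  \frac{n_b}{1 + 10^{\mathrm{pH} - pK_b}}
  \;-\; \sum_{a \in \mathrm{acidic}}
  \frac{n_a}{1 + 10^{pK_a - \mathrm{pH}}},$$

with basic groups H, K, R and the N-terminal amine, and acidic groups
D, E, C, Y and the C-terminal carboxyl; one terminal group of each kind
per chain. $Z$ is strictly decreasing in pH, so the isoelectric point —
the root of $Z$ on $[0, 14]$ — is unique and is found by bisection to a
bracket width of $10^{-4}$ pH (a 200-iteration cap; convergence needs
about 50). That tolerance is far below the 7.0 threshold convention
that drives all downstream acidic/basic classification, so solver error
never moves a protein across a class boundary.

Three pKa scales are registered (`EMBOSS`, the default; `Bjellqvist`;
`Lehninger`). The default matches the most widely used pI calculators
so that results are comparable with the common tool chain; scale
sensitivity can be probed by switching scales by name. Ambiguity codes
(X, B, Z, U, O) are accepted in sequences but carry no charge: guessing
a residue identity would inject irreproducible assumptions, while a
zero contribution is deterministic and documented. Cysteine redox state
and post-translational modifications are ignored — the scale's table is
applied to every C and Y.

A pI exactly at the classification threshold is labelled `neutral` and
excluded from both the acidic (pI < 7) and basic (pI > 7) counts, so no
protein is counted twice; with continuous pI values this is a
measure-zero event.

## Differential abundance and the acidity-shift contrast

Label-free intensity matrices are filtered to *quantifiable* proteins —
observed in at least 2 replicates of at least one treatment group —
then log2-transformed. Remaining missing values are treated as
left-censored and imputed by seeded draws from
$N(q_{0.01}^{\text{sample}} - s,\ 0.3)$, where $q_{0.01}$ is the
sample's observed 1st percentile. The default downshift is $s = 0$
(the MinProb convention: missing values are assumed to sit at the
detection floor); $s = 1.8$ gives the Perseus-style variant. Each
protein is then tested with a two-sample Welch t-test and
Benjamini–Hochberg adjustment across all tested proteins; direction
calls use fdr < 0.05 by default.

We use a plain Welch test rather than an empirical-Bayes moderated one:
with the generator's replicate structure (n = 4 per group) the moderated
test changes calls only for proteins whose variance is dominated by
imputation, and for those no variance model rescues the underlying
information loss (below). Keeping the test elementary makes the
pipeline's behaviour auditable.

**Power under censoring is intrinsically limited.** A protein whose
intensities in one group sit entirely below the detection limit has all
of that group's values imputed near the detection floor, which
compresses its apparent fold change toward the floor-to-baseline gap;
a protein with a *single* imputed cell instead pays a variance penalty.
At 10% overall missingness with intensity-dependent censoring, roughly
10–15% of truly down-regulated proteins fall into these regimes, and
simulated recall of the differential stage plateaus near 85–90% even
though precision stays above 95%. This is a property of the
impute-then-test paradigm itself (shared by the standard label-free
workflows this stage mirrors), not of a particular imputation setting;
users should read "n of 4 replicates missing in one group" flags, not
only fdr, when interpreting borderline proteins. Only an explicitly
censored-likelihood model would recover these proteins, and that is out
of scope here.

The acidity-shift contrast takes the up- and down-regulated sets and
reports:

* the 2×2 direction-by-acidity table (pI < 7 vs > 7), tested with a
  two-sided Fisher exact test computed by hypergeometric enumeration
  under the probability-mass rule (all tables with the observed margins
  whose probability does not exceed the observed one, with a $10^{-7}$
  relative tie guard). The probability-mass rule is exact and symmetric,
  unlike doubling one tail;
* `delta_median_pi`, the difference of median pI (up − down), with a
  label-permutation p-value: up/down labels are reshuffled preserving
  set sizes, and $p = (1 + \#\{|\Delta^*| \ge |\Delta|\})/(B + 1)$ with
  $B = 10{,}000$ by default. The +1 smoothing keeps p strictly positive;
  medians make the location contrast robust to the long tails of pI
  distributions.

## Carbonate-system speciation

From total alkalinity (TA), total-scale pH, temperature and salinity,
the solver subtracts the borate ($B(\mathrm{OH})_4^-$, with total borate
proportional to salinity) and water ($\mathrm{OH}^- - \mathrm{H}^+$)
contributions from TA to get carbonate alkalinity, then applies the
standard speciation fractions
$\alpha_0, \alpha_1, \alpha_2$ at $H = 10^{-\mathrm{pH}}$ to obtain DIC,
CO~2~(aq), HCO~3~^−^ and CO~3~^2−^. Equilibrium constants follow the
common defaults of spreadsheet-style carbonate calculators: K1/K2 from
the Lueker et al. (2000) refit on the total scale, K~B~ from Dickson
(1990), K~W~ from Millero (1995), borate from Uppström (1974). The
constants set is swappable; setting `KW = 0` (and `BT = 0`) selects a
pure carbonate system in which the water self-ionization *and*
free-proton terms are dropped, so the identity
$TA = \mathrm{HCO_3^-} + 2\,\mathrm{CO_3^{2-}}$ holds exactly — the
degenerate case used for closed-form validation. Phosphate, silicate
and ammonia alkalinity are not modelled (the measurements this supports
do not constrain them), nor are pressure corrections or pH-scale
conversions.

Buffer capacity is operationalized as $|\partial \mathrm{DIC} /
\partial \mathrm{pH}|$ at fixed TA, evaluated by a central difference
with step $10^{-3}$ pH and reported in mmol kg⁻¹ per pH unit. The
published buffer-factor family contains several closely related
derivative definitions; the fixed-TA DIC derivative is the member that
is fully determined by the quantities this package computes, and the
step is two orders below the scale on which the derivative varies (the
$10^{-3}$ vs $10^{-4}$ step estimates agree to $10^{-4}$ relative).

## Composition and chemistry correlation

Residue classes follow the standard four-way scheme: acidic {D, E},
basic {K, H, R}, nonpolar {G, A, V, L, I, M, F, W, P}, polar
{S, T, C, Y, N, Q}. "Rich in residue X" is defined by the *fraction* of
the sequence (count/length), making rankings length-independent; a
count-based ranking is available by flag since the choice is a genuine
convention. Ties are broken by protein id so that top-N sets are
reproducible run to run.

Per-sample abundances of a protein set (translation machinery from a
user annotation, or top-N residue-rich sets) are summarized by the mean
over observed members (sum and median available) and correlated with
CO~2~, HCO~3~^−^, CO~3~^2−^, pH and alkalinity. Spearman rank
correlation is the default because treatments span an ordered but
non-linearly spaced chemistry gradient; p-values are BH-adjusted across
the whole set-by-parameter grid.

## Cross-proteome comparison

Genome-encoded proteome pI distributions are summarized by acidic/basic
fractions, median pI and a binned density (bin width 0.2 pH for display
only; all statistics use raw pI values, and bins span [0, 14] since
extreme-composition proteins can fall below pH 2). Two proteomes are
contrasted with the two-sample Kolmogorov–Smirnov statistic on raw pI
vectors — chosen because the underlying claim is a *distributional*
shift, not a mean shift — with `delta_basic_fraction` carrying the
direction in the acidic/basic framing.

## The synthetic-data generator

The generator emulates the study design the pipeline targets:

* a proteome of ~4,000 proteins, 100–600 residues, sampled
  residue-by-residue from class weights (acidic 0.14, basic 0.14,
  nonpolar 0.47, polar 0.25 — near the composition of real proteomes).
  The binomial spread of the acidic-minus-basic residue count makes the
  pI distribution bimodal around neutrality, as in real proteomes;
* a 5-treatment × 4-replicate design (control, HC, HA, HCHA1, HCHA2)
  with chemistry profiles following the treatment pattern: control
  (TA 2300 µmol kg⁻¹, pH 8.13), HC (2300, 7.58), HA (3200, 8.21),
  HCHA1/2 (3000, 7.94), at 26 °C and salinity 33, with 1%
  multiplicative TA jitter and ±0.01 pH jitter per replicate —
  realistic replicate spread that never reorders treatments;
* baseline log2 intensities ~ N(25, 2); 200 up- and 200 down-regulated
  proteins at ±2 log2 units; per-cell noise sd 0.3; 10% overall
  missingness, logistic in the true log2 intensity with slope 3 per
  log2 unit (detection probability falls 90% → 10% over ~1.5 log2
  units, a realistic detection-limit width). Every injected assignment
  is recorded in a truth table.

**Choosing the up/down sets.** A nonzero target `pi_shift_delta` is hit
by *paired selection*: each down-set member is accepted only together
with an unused partner whose pI lies within ε of its own pI + δ
(ε = 0.04, doubled where the pI density is too sparse, capped at 0.16).
The up set is therefore a pointwise location shift of the down set, so
the mean *and* the median pI difference both equal δ to within ε — in a
bimodal distribution these two can otherwise diverge badly, because the
median sits near the sparse valley between modes. When δ = 0 the sets
are instead an unconstrained random split: the null scenario must be
label-exchangeable for the permutation test to be exact, and any
constraint forcing the realized difference toward zero would make the
test anticonservative-looking in construction but conservative in
operation. Under the random split the mean difference is zero in
expectation with sampling scale $\approx 2\sqrt{2/n}$.

An optional chemistry–composition coupling (`alk_coupling`, log2 units
per SD of group alkalinity per SD of a protein's acidic-minus-basic
composition score) makes acidic-rich protein abundance rise, and
basic-rich fall, along the alkalinity gradient; it defaults to 0 so the
truth table is the sole source of differential signal, and is switched
on explicitly in correlation scenarios.

**What the generator does not emulate:** peptide-level quantification
and protein inference, batch effects, correlated protein modules,
compositional biases of real genomes beyond class frequencies, and
shared evolutionary structure between species. Passing tests therefore
demonstrate the correctness and calibration of the statistical
machinery under the stated generative model, not the biological claims
themselves on real data.

## Validation scale and numerical choices

The shipped validation suite runs the pI solver against a dense-grid
oracle (100 peptides, lengths 5–500), checks charge and composition
monotonicity on 1,000 randomized probes, closes the alkalinity/carbon
budget on 200 random seawater states, compares the Fisher test with
exhaustive enumeration on all 2×2 tables with margins ≤ 30, calibrates
the permutation test's size on 1,000 null datasets (200 proteins per
direction, 199 permutations each — the resolution at which a 5% test is
exactly attainable), and measures shift recovery over 100 simulated
experiments at 1,000 proteins with 200 DAPs per direction. These sizes
were chosen so the whole suite completes in a couple of minutes while
leaving binomial confidence bands narrow enough to detect
miscalibration.

Degenerate inputs are handled explicitly: zero-variance proteins get
p = 1 when means agree and p = 0 otherwise; constant vectors in the
correlation grid produce a missing rho with a warning rather than an
error; pI ties at the class threshold go to neutral; permutation
p-values are never exactly zero.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)          # the default study design
sim <- gen_experiment(cfg)
daps <- differential(filter_quantifiable(sim$abundance),
                     treatment = "HA", control = "control", seed = 1)
shift <- acidity_shift(daps, sim$pis, seed = 1)
shift
```

The printed object reports the up/down set sizes, the acidic/basic
counts on each side, the median pI difference, and the Fisher and
permutation p-values. `summary(shift)` returns the same as a one-row
data frame for tabulation across contrasts, and `run_workflow()` wires
the stages together from a declarative config with a checksummed run
manifest.

## Known limitations

* pI is computed from sequence alone: no structure-derived pKa shifts,
  no post-translational modifications, no cysteine redox state.
* The differential stage's recall under heavy left-censoring plateaus
  (see above); interpret borderline down-calls with the missingness
  pattern in hand.
* The carbonate solver is not a full CO2SYS replacement: input pair is
  (TA, pH) only, no pressure, phosphate/silicate, or saturation states.
* The KS contrast treats proteins as independent draws; for real
  proteomes, paralog families violate independence and p-values are
  optimistic — effect sizes (`delta_basic_fraction`, `ks_d`) matter
  more than p there.
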