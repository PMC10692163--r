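---
title: "Methods: two-tier active-learning screening with synthetic oracles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tier active-learning screening with synthetic oracles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`alscreen` re-implements, at desk scale, a structure-based discovery
workflow for inhibitors that bind the nucleotide-binding domain (NBD) of an
ABC efflux transporter: a fast docking-like score is screened over a very
large make-on-demand library under an active-learning loop, a slower
physics-based score rescores a curated subset, and the resulting hits are
analysed (atom attribution, pharmacophore feature densities) and validated
in cell and vesicle assays (calcein-AM efflux, vanadate-sensitive ATPase).
Commercial docking engines, molecular-dynamics rescoring and the proprietary
billion-compound library are out of reach on a desk, so the package replaces
the two scoring stages with *synthetic oracles* whose statistical structure
is calibrated to the reference campaign, and generates its own enumerable
combinatorial library. Everything downstream of the scores — selection
logic, surrogate modelling, recall estimation, enrichment metrics, density
grids, assay fitting — is implemented in full and is directly usable on real
inputs (SMILES/CSV lists, SDF poses, CSV assay tables).

# The synthetic library

The library emulates a synthon-style make-on-demand space in which many
building blocks are amino acids. Three packaged fragment sets — carboxylic
acids (103), bifunctional amino-acid cores (97) and amines (107) — combine
through amide couplings into two-component (acid + amine) and
three-component (acid + core + amine) products, 1,080,058 in total. Set
sizes near 100 per list were chosen so that the enumeration space exceeds
one million unique products, the library size used by the calibration
checks; the default desk-scale campaign library subsamples 200,000 of them.
Enumeration is mixed-radix and deterministic; a seeded subsample without
replacement defines the library, and identifiers encode the enumeration
index so that every quantity derived from a molecule is a pure function of
(configuration, seed).

Because the coupling chemistry is uniform, descriptors are computed
*additively* from per-fragment values with exact junction corrections:
molecular weight loses one water per amide bond; the OpenBabel
atom-contribution logP shifts by a constant per coupling (verified constant
to ~1e-15 across fragment pairs); ring counts add; rotatable bonds add with
a +1 correction when the coupling nitrogen's alpha carbon is non-terminal.
Tests cross-check the additive values against direct computation on the
assembled SMILES.

# Scoring oracles

Tier-1 scores take the form

    score = mu_1 + sigma_1 * (a*g + b*h),  a = sqrt(signal_fraction),
                                           b = sqrt(1 - signal_fraction)

where `h` is a standard-normal deviate derived from a 64-bit hash of
(identifier, seed) — reproducible across platforms with no global RNG state —
and `g` is a fixed monotone function of five descriptors (size, lipophilicity,
acceptor count, aromatic-ring count and a carboxylic-acid indicator with a
favourable weight, echoing the phosphate-mimetic chemistry that a Walker A
motif rewards). The raw weighted descriptor combination is passed through a
frozen quantile map that renders `g` standard normal over the default
enumeration space; the map's knots are package constants regenerated by
`tools/dev-calibrate.R` whenever the fragment sets change. With both
components standard normal, the score is Normal(mu_1, sigma_1^2) to high
accuracy deep into the tails, and the defaults mu_1 = -5.70,
sigma_1 = 0.887 place the 1e-4 quantile (the top-0.01-percent cutoff) at
-9.0 kcal/mol.

Tier-2 shares the tier-1 latent:
`z2 = rho*z1 + sqrt(1-rho^2)*eps(id, seed)`, rescaled to mu_2 = -40,
sigma_2 = 8 (a plausible end-point binding-energy scale; arbitrary and
documented as such). The default rho = 0.42 reproduces the global
docking/rescoring correlation of the reference campaign.

`signal_fraction` (default 0.64) controls how much of the tier-1 variance a
structure-based surrogate can in principle learn. What the generator does
*not* emulate: pose-dependent scoring, conformational noise, activity
cliffs, assay-specific artefacts. Passing tests therefore demonstrate that
the pipeline's statistics and selection logic behave correctly under a
controlled signal/noise model — not that any particular surrogate would
achieve the same enrichment on a real docking campaign.

# Descriptors, filter and fingerprints

The lead-like filter passes molecules with MW < 460 g/mol, logP in [-4, 4],
fewer than 4 rings and fewer than 10 rotatable bonds; all "fewer than"
bounds are strict and the logP interval is inclusive, with boundary
behaviour unit-tested. Ring count is the cyclomatic (smallest-set) count;
rotatable bonds are non-ring single bonds between non-terminal heavy atoms
excluding amide C–N; logP is OpenBabel's additive scheme. Roughly 83% of
the default library passes the filter (the generator contract documents
>= 80%).

Fingerprints are hashed circular environments of radius 2 folded into 2048
bits — the conventional Morgan/ECFP setting. Hashing combines neighbour
environments in sorted order, making bits invariant to atom numbering, and
aromatic ring bonds are normalized to a dedicated bond order after
perception so that the kekule form a parser happens to emit cannot change a
fingerprint. Bit positions are internally consistent but not comparable to
other toolkits' Morgan bits. Tanimoto similarity is intersection over
union, with the empty/empty case defined as 0 so diversity selection is
total.

Per-atom feature selections (carboxylic-acid carbons, sulphones,
sulfonamides, amide carbonyls, aromatic atoms, H-bond donors `[N,O;!H0]`
and acceptors N/O excluding amide N) are rule-based graph predicates
equivalent to the conventional SMARTS definitions; arbitrary SMARTS are
supported for match *counting* through the OpenBabel engine.

# Surrogate model and attribution

The default surrogate is a ridge-regularized linear model on the 2048-bit
fingerprints, with the penalty chosen by validation error over a 50-step
path — the linear analogue of early stopping. The reference protocol used a
graph neural network; on a synthon-combinatorial library with an additive
descriptor signal, fingerprint bits act as fragment indicators and a linear
model recovers the learnable signal comfortably (validation Pearson R² ≈
0.63 against the 0.64 ceiling at default settings, versus the 0.4
acceptance floor), at a small fraction of the cost and with exact
reproducibility. The backend is pluggable: any function honouring the
fit/predict contract can stand in, and `batch_size` (default 128) is
recorded in the training metadata for such backends. A 90/10 seeded
train/validation split reports held-out Pearson R²; pure-noise oracles
train to R² < 0.05, i.e. the surrogate does not hallucinate signal.

Atom attribution follows an atom-removal scheme: the contribution of heavy
atom *i* is the prediction for the full molecule minus the prediction for
the molecule with atom *i* and its bonds deleted — no valence repair, all
remaining fragments kept in the featurization, hydrogens not attributed.
Attribution is invariant to input atom renumbering.

# Screening campaign

The default schedule rescales the reference campaign by library fraction:
round sizes 1/2654, 1/2654, 1/2654 and 3/2654 of the library (6 million of
2.654 billion at reference scale; 75/75/75/225 of 200,000 at desk scale),
with rounds 2–4 drawing from the top 100/2654 ≈ 3.77% of fresh
whole-library surrogate predictions. Round 1 is a uniform random sample;
rounds 2–3 apply a leader-algorithm similarity filter to the
prediction-sorted pool ("some degree of exploration"); the final round is
greedy. Already-scored molecules are excluded from later pools by default.
The exploration filter's ceiling defaults to 0.5 rather than the 0.4 used
for tier-2 diversity: in a synthon-combinatorial top-pool the 0.4 ceiling
admits only ~25 unique leaders — fewer than the round budget — which would
silently shrink the campaign. Sorts and top-k selections break ties by
lexicographic identifier so campaigns are bit-reproducible.

Hit recall is estimated from the initial uniform sample by extrapolating
its hit prevalence to the library (T̂ = k/n × N) with a percentile bootstrap
(B = 1000, seeded) on the sample; recall = found/T̂ with the CI transformed
from the total-count CI and clamped to [0, 1] in the report. The interval
construction (percentile, B) is a package choice; coverage is verified by
simulation (≥ 90% across 50 synthetic campaigns).

# Rescoring campaign

Tier-2 selection follows the reference stages: a diverse seed set at
Tanimoto < 0.4 among tier-1 hits (its size set by the diversity filter
itself); a loop of train → predict → top-1500-equivalent →
200-equivalent batch at minimal similarity to everything scored or
selected, until a 1700-equivalent total; a refinement slice
(top-4000-equivalent, keep molecules with fewer than two carboxylic acids,
diversity-select 800-equivalent); and a final 522-equivalent round over the
relaxed pool (tier-1 < -4). Counts rescale by the campaign's library
fraction and floor at 1; at the default 200k scale this makes most stages
single-molecule — faithful but degenerate — so `rescoring_config(scale=)`
exposes the factor for non-degenerate runs, and the test suite exercises
the stage contracts at scale 1/20 with a relaxed eligibility threshold.
While fewer than 50 tier-2 scores exist, candidate ranking falls back to
the (known) tier-1 scores instead of an undertrained surrogate.

# Enrichment metrics

`roc_auc` is the Mann–Whitney probability that a random active scores
better (lower) than a random decoy, ties counted one half; it is verified
against explicit pair enumeration. `rie` is the exponentially rank-weighted
early-enrichment ratio with closed-form random-ranking normalization;
alpha defaults to 20 (emphasis on roughly the top 8% of the list — the
conventional setting), ties broken deterministically, and the null
expectation of 1 and the analytic maximum are both tested.

# Density grids

Feature atoms of 3D poses are binned into half-open voxels of 0.5 Å
(default) with 2 Å bounding-box padding; binned counts plus an overflow
tally equal the matched atoms exactly. Optional isotropic Gaussian
smoothing uses a separable kernel with half-sample-reflecting boundaries,
which preserves total mass. Grids export and re-import as OpenDX scalar
fields (z index fastest), readable by common molecular viewers. Synthetic
poses come from OpenBabel's 3D builder; across seeds, pose variability is
emulated by seeded rigid-body rotation/translation (the builder itself is
deterministic), and fixture mode places a designated feature atom within
0.5 Å of a declared hotspot so grid tests have a known maximum.

# Assay analysis

Calcein-AM efflux is the inverse of the compound/control fluorescence-slope
ratio, `m_control/m_compound`; slopes come from ordinary least squares on
background-corrected series. Dose–response curves are fitted by
Levenberg–Marquardt least squares to the standard three-parameter logistic
`Y = Bottom + (Top - Bottom)/(1 + 10^(X - LogIC50))` with X = log10(µM);
starting values take Top/Bottom from the response extremes and LogIC50 from
the concentration nearest their midpoint, iterations cap at 500 with
relative tolerances of 1e-14, and standard errors come from the
Gauss–Newton covariance at the optimum (exact fits report SE 0). The
parameterization permits either curve orientation. IC50 = 10^LogIC50 is
reported in µM to match the conventional tabulation. Vanadate-sensitive
ATPase activity converts absorbances to nmol phosphate through a free-
intercept linear standard curve, normalizes by reaction time and protein,
and subtracts the matched vanadate condition; negative activities are
reported with a warning rather than clamped.

# Problem sizes and determinism

The test suite uses libraries of 1,000–20,000 molecules for unit
properties, 10,000 for surrogate learnability, and the full default
200,000-molecule library (5 seeds, with matched random baselines) for the
campaign enrichment property; the calibration checks generate 1,000,000
molecules. These sizes were chosen so the full suite and the calibration
script each complete in minutes on a single core while keeping every
statistical check adequately powered. All stochastic components — library
subsampling, oracle noise, train/validation splits, batch sampling,
bootstrap resampling, pose placement, fixture noise — are driven by
explicit seeds through hash streams or locally scoped RNG state, so every
reported number is reproducible.

# Known limitations

The oracles are statistical stand-ins: they reward a fixed descriptor
profile, not three-dimensional complementarity, so structure-activity
conclusions cannot be read off the synthetic campaign. The combinatorial
library is far more homogeneous than a billion-compound make-on-demand
space, which is why diversity thresholds behave differently (see the
exploration-filter default). Fingerprint bits are not interchangeable with
other toolkits' Morgan implementations. Stereochemistry and protonation
states are taken as given — inputs are not enumerated or standardized
beyond parsing. The rescoring stage counts at default desk scale are
degenerate by construction; treat the default rescoring run as a shape
test, not a powered experiment.
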