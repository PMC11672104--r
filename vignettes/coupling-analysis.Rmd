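---
title: "Troponin phosphorylation coupling: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Troponin phosphorylation coupling: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tncoupling)
library(dplyr)
```

## The scientific setting

PKA phosphorylation of cardiac troponin I Ser22/23 lowers thin-filament
Ca²⁺ sensitivity 2–3-fold and thereby accelerates relaxation
(lusitropy). Many cardiomyopathy mutations *uncouple* this modulation:
Ca²⁺ sensitivity stops responding to the phosphorylation state. Some
small molecules restore it (*recoupling*). The phenomenon is observable
at three scales, and this package implements the quantitative analysis
for each:

1. **Troponin-core dynamics** (per-frame geometric observables of a
   simulation trajectory),
2. **In vitro motility** (Ca²⁺-activation curves of reconstituted thin
   filaments),
3. **Intact myocyte contractility** (cell-shortening transients under
   dobutamine).

Every tier also has a synthetic generator that plants known ground
truth, so each analysis function has a recovery test against an exact
manifest rather than against another implementation.

## Trajectory metrics

### Helix A/B interhelix angle

The opening of the cNTnC hydrophobic patch is tracked as the angle
between the axes of TnC helices A and B. A helix axis is defined here
as the **first principal component of the helix Cα coordinates**,
sign-oriented from the N-terminal to the C-terminal residue; the
interhelix angle is the arc-cosine of the dot product of the two
oriented unit axes, so it lies in [0°, 180°] and is symmetric in its
arguments. PCA is the standard axis construction, is exactly testable
(a planted rotation of one helix by θ is recovered as θ to machine
precision), and degrades gracefully for slightly curved helices.
Helix residue ranges are **configuration values**, shipped with the
canonical cNTnC assignments used by the synthetic scaffold (helix A
14–28, helix B 38–48 on the TnC chain) and overridable per structure,
since assignments differ between numbering conventions.

### Interdomain hinge angle and distance

The dominant motion of the troponin core is a hinge between two
quasi-rigid bodies: the NcTnC lobe (plus the TnI N-terminal peptide)
and the ITC domain. The hinge angle is measured at the centroid of a
user-specified **pivot** selection (default: the Cα of the TnC
central-linker residue) between the vectors pointing to the Cα
centroids of the two domains. The interdomain distance is the
Euclidean distance between the same two centroids, in Å. Domain
membership is user-specified, not detected: quasi-rigid-domain
decomposition is out of scope, and fixed selections keep the metric
deterministic and comparable across conditions.

### Salt-bridge occupancy

The G159D mutation introduces an aspartate that can form an ionic bond
with R83 across the hinge. Occupancy is the fraction of frames in
which the minimum distance between the D159 carboxylate oxygens and
the R83 guanidinium nitrogens is **strictly below 4.0 Å** — the
conventional ionic-contact threshold, exposed as a config value since
no single cutoff is canonical. For wild-type Gly159 the acidic
selection is empty and the occupancy is 0 by definition rather than an
error.

### Ligand contacts and attachment

A ligand is in contact with a residue in a frame when the minimal
distance between *any* atom of the ligand and *any* atom of the
residue is **strictly lower than 2.5 Å**; hydrogens participate when
present (a heavy-atom-only switch exists but is off by default).
Residue-wise application gives the contact profile; *hotspots* are
residues contacted strictly more than 10% of the time, sorted by
probability (ties broken by chain and residue number so output order
is reproducible). *Attachment* applies the same criterion against the
whole protein; episodes are maximal runs of constant bound/unbound
state with no smoothing (an optional debounce window exists, default
0). The strict inequalities and the pooled-frames default are
deliberate, documented conventions; both thresholds are config values.
No periodic-boundary imaging is applied — the analysis assumes
pre-imaged coordinates, which also matches the synthetic data (no box).

### Distribution summaries, deltas, recoupling calls

Metric series are pooled across runs (per-run summaries are retained
for dispersion reporting) and reduced to: sample mean and sd, the
percentage of samples strictly above a threshold (110° is the
open-state boundary for the A/B angle), and the FWHM of a kernel
density estimate. The KDE uses a **Gaussian kernel with Scott
bandwidth on a 1024-point grid** extended 3 bandwidths beyond the
sample range, and the FWHM takes only the half-height crossings that
flank the **global-maximum peak**, located by linear interpolation —
a main-peak convention is mandatory because some conditions (EGCG) are
multi-modal. The percent-above statistic is computed on the raw
samples, not on the KDE, because that is exact and estimator-free.
Note the KDE convolution widens the FWHM of a Gaussian sample by a
factor √(1 + (h/σ)²); with Scott bandwidth at n = 3750 that is ≈ 2%,
well inside the tolerances used in the tests.

Phosphorylation deltas are always **phosphorylated minus
unphosphorylated**. A candidate condition is called *restored*
(recoupled) when its delta has the same sign as the wild-type delta
and exceeds a dead-band in magnitude — defaults 0.5° for angles,
0.25 Å for distances, 1 percentage point for percent-above. The
dead-band prevents near-zero changes (e.g. a −0.2° shift) from being
called restored; its value is declared, not inferred from any source,
and is config-exposed.

## Motility coupling

Activation curves are fitted with the four-parameter Hill model

$$f = f_{\min} + \frac{f_{\max} - f_{\min}}{1 + (EC_{50}/[\mathrm{Ca}^{2+}])^{n_H}}$$

parameterised on log-EC₅₀ and fitted on log-concentration with
Levenberg–Marquardt least squares (minpack.lm). Free plateaus, slope
and midpoint are the field standard for motility activation data. At
least 5 distinct concentrations are required; a fitted EC₅₀ outside
the measured span warns (extrapolation), and a flat curve is a
non-convergence error rather than a garbage estimate.

Coupling is the ratio EC₅₀(P)/EC₅₀(unP). Replicate pairs are
summarised as the **mean of per-pair ratios** (the convention that
makes single-replicate rows exact divisions), with SEM for n ≥ 2 and a
paired two-tailed t-test on log-EC₅₀ (ratios are multiplicative) for
n ≥ 3. The call is *coupled* when the mean ratio exceeds **1.5** and,
when testable, p < 0.05; in the reference data coupled conditions have
ratios ≥ 1.73 and uncoupled ones ≤ 1.33, so 1.5 separates them with
margin — it is nevertheless a config value. Single-pair calls carry an
explicit `significance_tested = FALSE` flag. The single-concentration
rapid screen is a paired t-test on fraction motile at one [Ca²⁺]
(positive iff the phosphorylated mean is lower with p < 0.05); the
concentration is an input, never hard-coded.

## Myocyte transients

Traces are cell length versus time at 1 Hz field stimulation, 10 s per
cell. Beat onsets are detected as downward crossings of 10% of the
beat amplitude on a 5-sample moving average, with hysteresis (the
detector re-arms only once the trace has recovered near baseline) and
a half-period refractory time, so noise wiggles on the relaxation limb
cannot spawn spurious beats. Onset fraction and smoothing window are
arguments because instrument conventions differ.

Per beat: L₀ is the median pre-onset length; amplitude is
100·(L₀ − peak)/L₀; **ttp₉₀** is the time from onset to the first
crossing of 90% of peak shortening (linear interpolation between
samples); **ttb₉₀** is the time from the peak to recovery of 90% of
the shortening amplitude back toward L₀ — the common "time to 90%
baseline" convention, spelled out here because instruments document it
loosely. The peak position is refined by a parabolic vertex through
the three samples around the minimum, which removes sampling-grid
quantisation (the raised-cosine beats are asymmetric, so an unrefined
argmin is biased by up to two samples). Per-cell features are medians
over accepted beats, robust to one aberrant beat. Lusitropy is
1 − ttb₉₀(+dob)/ttb₉₀(−dob): positive values mean faster relaxation;
group analysis uses per-cell paired deltas, two-tailed paired t-tests
and two-level star coding (* p < 0.05, ** p < 0.01).

## The synthetic generators

### Trajectories

The scaffold is an abstract Cα-level stand-in shaped like the troponin
core: a TnC-like chain "C" of residues 1–161 (straight helix-A and
helix-B arms, a static central linker whose residue 90 is the hinge
pivot, an ITC-like rigid body for 95–161, R83 guanidinium and —
in the G159D variant — D159 carboxylate pseudo-atoms), a TnI-peptide
chain "I" (1–33), and an optional HETATM ligand chain "L". Residue
numbering mimics the real system so the default region set works
unchanged on synthetic data.

Per frame the generator **realises the sampled observables exactly by
rigid placement** rather than approximately by dynamics: helix B is
rotated about its own centroid so the A/B angle equals the sampled
value to machine precision (the rotation leaves the domain centroid,
and hence the hinge geometry, untouched); the NcTnC-like body is
translated so that the pivot-centroid angle equals the sampled hinge
angle *and* the centroid separation equals the sampled distance
simultaneously (law-of-cosines placement); the salt-bridge minimum
distance is set to 3.0 Å (bonded) or 8.0 Å (unbonded) against the
4.0 Å cutoff by an independent Bernoulli draw per frame; the ligand is
placed 2.0 Å from a target residue Cα when bound and parked far
outside the protein envelope when unbound. Exact realisation matters:
recovery tests then isolate analysis-code error from generator error,
and the generator verifies a sample of frames against the planted
angles (tolerance 10⁻⁶ degrees) at construction time.

Ligand binding follows a two-state Markov chain with stationary bound
fraction p_on/(p_on + p_off). The default mean bound episode is 25
frames (10 ns at 0.4 ns/frame): episodes long enough to be episodic,
short enough that the Monte-Carlo error of the attachment fraction at
3750 frames stays within ±0.01 (the autocorrelation of the chain
inflates that error by √((1+ρ)/(1−ρ)); prolonged episodes would make
the stationary fraction unrecoverable at single-run length). Angle
samples are drawn from Gaussian mixtures (the defaults are single
Gaussians with the wild-type apo means and sds: A/B 101.81° (9.15),
hinge 121.61° (7.24), distance 30.18 Å (1.34)), clamped to [1°, 179°];
runs are 3750 frames at 0.4 ns/frame, five runs per condition,
emulating 5 × 1500 ns sampling. All randomness flows from one seed;
per-run sub-seeds are derived deterministically.

What the generator does **not** emulate: physically continuous
dynamics (frames are independent draws, except the ligand chain),
solvent, side-chain chemistry, periodic boxes, or correlated motion
between metrics. Passing recovery tests therefore demonstrates that
the analysis measures what it claims on data with known truth — not
that it handles force-field artefacts, imaging errors or conformational
kinetics of real simulations.

### Activation curves and transients

Curves are generated from the same Hill model the fitter assumes, with
EC₅₀(P) = EC₅₀(unP)·ratio, Gaussian noise on fraction motile (default
sd 0.05; fractions are not clipped, matching how noisy motility
fractions can stray past the plateau), and 8 concentrations log-spaced
over 0.01–10 µM — a grid wide enough to bracket every EC₅₀ in the
reference set. Defaults plant the native condition (0.059 µM, ratio
2.24, n_H = 2 as typical thin-filament cooperativity; the reference
tables do not report n_H).

Transients are built from a smooth two-phase raised-cosine template.
The rise and decay phase durations are solved from the requested
ttp₉₀/ttb₉₀ via the template's closed-form crossing times under the
10%-onset convention, so the *measured* features equal the request;
per-cell parameters vary with a 5% coefficient of variation, and
traces carry additive noise (default 0.1 µm) plus a slow sinusoidal
baseline drift. A cell whose contraction-plus-relaxation cannot fit
inside the stimulus period is an error at the group level and is
gently compressed (with the realised values recorded as truth) when
produced by per-cell jitter. Dobutamine is modelled as per-cell
multiplicative effects on the planted parameters — same cells, paired —
with defaults amplitude ×1.47 and ttb₉₀ ×0.79 (lusitropy 0.21), the
coupled wild-type response.

## The reference study configuration

`default_config()` encodes one full study: seven trajectory conditions
(wild-type and G159D apo; G159D with EGCG, resveratrol, silybin A,
silybin B, ECG; each in uP and P states, using the reference means/sds
and occupancies), nine motility conditions (native, E180G, G159D and
R92Q backgrounds with and without ligands, using the reference EC₅₀s
and ratios with their replicate counts), and six myocyte conditions.
The myocyte kinetics use mouse-like times (ttp₉₀ 0.12 s, ttb₉₀
0.31–0.45 s): at 1 Hz pacing the raised-cosine template requires
contraction plus relaxation to fit inside the stimulus period, and
these values keep every condition — including the uncoupled mutants,
whose ttb₉₀ *lengthens* under dobutamine — realisable. The acceptance
script runs this configuration at 5 × 3750 frames per trajectory
condition and 20 cells per myocyte condition; the test suite uses
reduced sizes (2 × 250 frames, 4 cells) for speed, with the sampling
sizes chosen as the package's own test design.

`run_pipeline()` executes the tiers, assembles the table-shaped
outputs (cells, deltas, restored flags; coupling calls; paired myocyte
statistics), and is deterministic given the config, whose hash is
recorded in the report. Externally computed binding free energies
(e.g. MMPBSA values) can be echoed into the attachment table via an
optional CSV side-input; they are never computed here.
`cross_level_summary()` lines up the restored/coupled calls per ligand
across tiers and scores agreement against the majority call — the
package-level statement of the recoupling story.

## Numerical choices and degenerate inputs

- Angles are computed through `acos` of a clamped cosine, so numerical
  overshoot can never produce NaN; all angle metrics are invariant to
  global rigid transforms to 10⁻⁶.
- `helix_axis()` refuses fewer than 4 atoms and coincident points;
  `hinge_angle()` refuses a pivot that coincides with a domain
  centroid.
- `summarize_distribution()` refuses n < 10 and all-identical samples
  (degenerate density).
- The Hill fit starts from data-driven values (plateaus from the
  response range, midpoint from interpolating the half-range crossing)
  and reports an error, not a number, when the model cannot converge.
- Paired tests with exactly constant differences return p = 1 (no
  change) or p = 0 (constant nonzero shift) instead of erroring on
  degenerate synthetic input.
- PDB round-trips are exact to the format's 0.001 Å; DCD is
  single-precision. Residue insertion codes are rejected on load.

## Known limitations

- XTC trajectories are not read; convert to DCD or multi-model PDB.
- Helix assignments, domain memberships and the hinge pivot are
  configuration, not inference; results are only as meaningful as
  those selections.
- The FWHM inherits KDE bandwidth bias (≈ 2% at n = 3750); comparisons
  across conditions at equal n are unaffected, absolute values
  slightly widened.
- Synthetic frames are temporally independent (except ligand state),
  so autocorrelation-aware error estimates cannot be exercised on
  them.
- The fraction-motile error model is homoscedastic Gaussian; real
  motility fractions are bounded and heteroscedastic near 0 and 1.
- Single-replicate EC₅₀ ratios are intrinsically noisy (the free
  four-parameter fit propagates point noise into ~10% ratio sd at
  noise sd 0.02); the package reports them with an explicit
  no-significance flag rather than pretending precision.
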