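---
title: "Methods: whole-brain ALN modelling of resting-state connectivity and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain ALN modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`alnsim` implements a delay-coupled whole-brain network of mean-field
nodes, each an adaptive exponential integrate-and-fire (AdEx) population
pair (one excitatory, one inhibitory population per cortical region — the
"ALN" low-dimensional cascade reduction), driven by a structural
connectome, converted to BOLD through the Balloon–Windkessel model and
scored with resting-state connectivity and temporal-dynamics measures:
functional connectivity (FC), global brain connectivity (GBC), the
Kuramoto order parameter and metastability.  On top of the forward model
sit four perturbation experiments over fixed-seed virtual-subject cohorts
(reduced GABAergic weights, reduced glutamatergic drive onto inhibition,
reduced global coupling, increased background noise) with
group-comparison statistics, and a synthetic-data arm that replaces the
MRI-derived inputs so the whole analysis runs and is tested offline.

# The node model

Each population $a \in \{E, I\}$ carries a mean membrane current
$\mu_a$ (mV/ms; all currents are expressed as current per capacitance),
with

$$\tau_a \frac{d\mu_a}{dt} = \mu_a^{syn} + \mu_a^{ext} + \mu_a^{ou} - \mu_a,
\qquad \mu_a^{syn} = J_{aE}\bar{s}_{aE} + J_{aI}\bar{s}_{aI}.$$

The saturating synaptic gates $\bar{s}_{ab} \in [0,1]$ (fraction of
active synapses) and their variances follow

$$\frac{d\bar{s}_{ab}}{dt} = \tau_{s,b}^{-1}\left[(1-\bar{s}_{ab})\,r_{ab} - \bar{s}_{ab}\right],$$
$$\frac{d\sigma^2_{s,ab}}{dt} = \tau_{s,b}^{-2}\left[(1-\bar{s}_{ab})^2\rho_{ab} + \left(\rho_{ab} - 2\tau_{s,b}(r_{ab}+1)\right)\sigma^2_{s,ab}\right],$$

driven by the dimensionless effective input rate and its variance

$$r_{ab} = c_{ab}\left[K_b\,r_b(t - d_{ab}) + \delta_{abE} K_{gl} \sum_j C_{ij}\, r_{E,j}(t - D_{ij})\right],$$

$\rho_{ab}$ identically with $c_{ab}^2$ and $C_{ij}^2$.  Inter-regional
coupling is exclusively excitatory-to-excitatory
($\delta_{abE} = 1$ iff $a = b = E$), weighted by the max-normalised
structural matrix $C$ and delayed by $D_{ij}$ (fibre length divided by
the global signal speed).  The membrane-current variance combines the
synaptic fluctuations with the external white-noise amplitude:

$$\sigma_a^2 = \sum_b \frac{2 J_{ab}^2 \sigma^2_{s,ab} \tau_{s,b} \tau_m}
{(1 + r_{ab})\tau_m + \tau_{s,b}} + \sigma_{ext}^2 .$$

Rates, mean voltage and the effective timescale are read every step from
precomputed transfer tables (next section) at
$(\mu_E - \bar{I}_A / C,\ \sigma_E)$ for the excitatory population — the
mean adaptation current shifts the operating point adiabatically — and at
$(\mu_I, \sigma_I)$ for the inhibitory one.  Adaptation obeys

$$\frac{d\bar{I}_A}{dt} = \tau_A^{-1}\left[\alpha(\bar{V}_E - E_A) - \bar{I}_A\right] + \beta\, r_E ,$$

an inhibitory membrane current combining subthreshold ($\alpha$) and
spike-triggered ($\beta$) adaptation; the spike-triggered term enters
with a positive sign so that firing *charges* the adaptation current, the
standard AdEx semantics.  Background noise is an independent
Ornstein–Uhlenbeck process per population per region,
$d\mu^{ou} = -\mu^{ou}/\tau_{ou}\,dt + \sigma_{ou}\sqrt{dt}\,\xi$, whose
stationary variance is $\sigma_{ou}^2 \tau_{ou}/2$.

**Unit conventions.** Time in ms, rates internally in kHz, currents as
current/capacitance in mV/ms, noise amplitudes in mV/$\sqrt{\text{ms}}$;
conversion to Hz happens only at reporting boundaries.  The effective
input rate $r_{ab}$ is treated as dimensionless (kHz·ms reading).  The
amplitude $c_{ab}$ plays the role of the single-spike contribution: the
microscopic synapse consistent with the gate equation above jumps by
$(c_{ab}/\tau_{s,b})(1-s)$ per presynaptic spike, i.e. a single-spike
postsynaptic current amplitude of order $c_{ab}$.  This is one of two
self-consistent readings of the model family's synaptic bookkeeping; we
chose it because the alternative (gate jumps of $c_{ab}(1-s)$, effective
rates carrying an extra $\tau_{s,b}$) saturates the gates at the default
parameters so strongly that inter-regional coupling ceases to shape the
BOLD correlation structure — the defining phenomenon this model exists to
study.  The consequences for mean-field fidelity are described under
*Limitations*.

# Transfer tables

The node nonlinearity is the stationary input–output map of an
exponential integrate-and-fire population: on a rectangular grid of mean
input $\mu$ and noise amplitude $\sigma$ we solve the stationary
Fokker–Planck equation by threshold integration (backward integration in
voltage from the spike boundary, exponential stepping, reinjection at the
reset potential, refractory mass accounted at reset), yielding

* $\Phi_r(\mu, \sigma)$ — stationary rate (kHz), with $\Phi_r < 1/T_{ref}$;
* $\Phi_V(\mu, \sigma)$ — stationary mean membrane voltage (mV);
* $\Phi_\tau(\mu, \sigma)$ — effective timescale (ms), from a one-pole
  (exponential filter) fit $A(\omega) = A_0/(1 + i\omega\tau)$ to the
  linear rate response at a single low probe frequency (default 5 Hz);
  the zero-frequency gain $A_0 = dr/d\mu$ comes from a central finite
  difference of the stationary solver.

Numerical choices: voltage step 0.01 mV, lower bound −200 mV, with
dynamic rescaling so that subthreshold barriers spanning hundreds of
orders of magnitude stay representable; halving the voltage step changes
rates by $\sim 2\times 10^{-5}$ relative.  Quiescent grid points (rate
below $10^{-9}$ kHz) take $\Phi_\tau = \tau_m$, flagged in the output;
genuinely failed points are flagged and warned about, never silently
zeroed.  The default grid spans $\mu \in [-2, 6]$ mV/ms in steps of 0.05
and $\sigma \in [0.1, 5]$ mV/$\sqrt{\text{ms}}$ in steps of 0.1, which
brackets the operating points reachable from the default parameters under
all perturbation families; analyses that visit stronger drives (the
spiking-fidelity checks) extend the grid to $\mu = 10$.  Lookup is
bilinear with clamping at the grid boundary; against a 4× refined grid
the relative interpolation error for rates above 1 Hz stays below the
declared 5% provenance tolerance.  Tables serialize to a single archive
with full provenance and bit-identical round-trip.

Adaptation is deliberately *outside* the tables: $\bar I_A$ shifts the
queried $\mu$ at simulation time, keeping the table two-dimensional.

# Integration scheme

The network is integrated with a forward Euler(–Maruyama) scheme at
$dt = 0.1$ ms, per-edge delay ring buffers (delays rounded to the nearest
step, minimum one step), 70 s duration with the first 5 s discarded, and
excitatory rate traces stored at 1 ms resolution.  One exception to plain
Euler: the synaptic gate and gate-variance equations treat their linear
self-term implicitly.  Their relaxation time $\tau_{s}/(1+r_{ab})$ drops
below $dt$ during rate excursions, where forward Euler overshoots the
$[0,1]$ bounds; the semi-implicit update preserves the bounds and the
non-negativity of the variance exactly, so the full default simulation
runs without a single clamping event (the integrator still counts and
reports clamps defensively).  Halving $dt$ changes the time-averaged rate
of a noiseless run by well under 2%.

Determinism: a virtual subject is one master seed, which deterministically
spawns one independent noise-stream seed per population per region
(xoshiro256++ streams with a Box–Muller normal, independent of R's RNG
state).  Identical inputs give bit-identical trajectories; a node inside
a zero-coupling network reproduces the same node simulated alone with the
same stream seeds, and a scale-1 "perturbation" is bit-identical to the
default condition.

# Hemodynamics

Excitatory rates drive the standard four-state Balloon–Windkessel system
(vasodilatory signal, inflow, venous volume, deoxyhemoglobin) per region,
with the conventional parameter set $\kappa = 0.65\,s^{-1}$,
$\gamma = 0.41\,s^{-1}$, $\tau_h = 0.98$ s, Grubb exponent 0.32, resting
extraction 0.34, $V_0 = 0.02$, $k_1 = 7\rho_E$, $k_2 = 2$,
$k_3 = 2\rho_E - 0.2$; output is percent signal change decimated to the
repetition time (default TR = 2 s, matching the empirical arm).  The
neural drive is the mean-centred rate in kHz times a documented constant
(default 1); the exact normalisation used upstream of published BOLD
models is not recoverable, and the correlation-based measures downstream
are insensitive to this choice over a wide range.  A 1 s rate pulse
produces the canonical response: a positive deflection peaking a few
seconds after onset followed by an undershoot; halving the integration
step changes the peak by well under 1%.

# Connectivity and dynamics measures

* **FC**: Pearson correlations of the regional BOLD series over the whole
  acquisition.
* **GBC**: region-wise mean FC to the other regions.  The implementation
  excludes the self-correlation and divides by $n-1$; a switch restores
  the literal all-$n$ average (an affine shift that cancels in group
  differences).  Global, per-network and association/sensory summaries are
  plain means over the respective regions; association = default mode,
  control, salience/ventral attention; sensory = somato-motor, visual,
  dorsal attention; the limbic network belongs to neither super-group.
* **Synchrony / metastability**: signals are band-passed to
  0.04–0.07 Hz with a second-order Butterworth filter applied forward
  and backward (zero phase) with reflective padding — no samples are
  trimmed afterwards, so filter edge effects are accepted identically for
  every group and condition; instantaneous phases come from the
  FFT-based analytic signal; $R(t)$ is the modulus of the mean unit
  phasor, synchrony its time average, metastability its standard
  deviation.  When a series spans fewer than five cycles of the band
  centre, the functions warn that the phase measures are
  window-dominated; 70 s of simulation (3.9 cycles) is marginal in this
  respect, which is the main reason synchrony contrasts carry less power
  than connectivity contrasts throughout.

# Statistics

Group contrasts follow the study conventions: Welch t from summary
statistics (the demographic table's age row reproduces $|t| = 0.82$),
Pearson 2×2 chi-square (delegated to `stats::chisq.test`), small-sample
bias-corrected Hedges' g ($J = 1 - 3/(4\,df - 1)$) with a
normal-approximation 95% CI (the CI method is our choice and is recorded
here; the source tables do not state theirs), and two-sided label
permutation tests with 5,000 permutations, identity included in numerator
and denominator, exact enumeration whenever the label splits number at
most `n_perm`.  For condition contrasts over a cohort whose noise seeds
are held fixed, the package additionally reports a paired sign-flip
permutation over the within-subject differences (exhaustively enumerated
up to $2^n \le$ `n_perm`), the sharper test for that design; comparison
tables emit both conventions of the mean difference explicitly
(`diff_default_minus_condition`, `diff_condition_minus_default`) because
the published table captions and signs disagree with each other.  No
multiple-testing correction is applied across measures, mirroring the
source analysis.

# Perturbation experiments

Four families, applied multiplicatively to the default parameters with
the reference scale 1 always present: `gaba_weights` scales $J_{EI}$ and
$J_{II}$ jointly (range 100–60%), `glut_drive_to_I` scales $J_{IE}$
(100–60%), `global_coupling` scales $K_{gl}$ (100–60%), `noise_level`
scales $\sigma_{ou}$ (100–140%), each in steps of 5%.  The virtual cohort
(default 40 subjects; the validation suite uses 10) is created once and
reused for every condition.  The qualitative expectation, and what the
validation suite checks at 10 subjects / 70 s runs, is the global-vs-local
contrast: reducing global coupling to 80% or raising noise to 120%
lowers global GBC (and, with less power, synchrony), while the two local
synaptic families at 80% leave global GBC statistically unaltered with
effect sizes below the global families'.

# Synthetic data generators

All generators are pure functions of their parameters and a seed.

* **Connectome**: `n` regions placed uniformly on a 70 mm sphere;
  weights follow an exponential distance rule (length scale 40 mm) with
  multiplicative lognormal jitter (log-sd 0.8), thresholded to density
  0.3, symmetrised and max-normalised; lengths are Euclidean distances.
  The jitter and density were chosen so the weight distribution has the
  heavy tail typical of max-normalised probabilistic-tractography
  matrices, giving mean row strengths near 2; with the default
  $K_{gl} = 250$ this places the network at the upper knee of its
  synchronization transition — the near-bifurcation operating point at
  which this model family is operated — so that coupling reductions
  de-correlate the network while local synaptic changes mostly slide it
  along the transition plateau.  These are generator properties fixed
  once; they are not fitted quantities.
* **Partition**: seven functional networks with realistic size imbalance
  (every network non-empty).
* **Two-group BOLD**: each subject mixes a latent common narrowband
  (0.04–0.07 Hz) drive into region-specific noise with mixing
  coefficient $\lambda = \sqrt{u}$, so the expected inter-regional
  correlation — hence GBC — equals the subject's latent level $u$
  regardless of the noise spectrum.  Patients' mean $u$ is lowered by
  `gbc_effect` (default 0.11, between-subject sd 0.16, so the imposed
  standardized effect is $\approx -0.69$); their region-noise variance is
  shifted *into* the analysis band (fraction $\nu$, solved in closed form
  from $R \approx \lambda/\sqrt{\lambda^2 + (1-\lambda^2)\nu}$) so that
  phase synchrony drops by about `sync_effect` (default 0.12) while
  broadband correlations are untouched.  With both effects zero the two
  groups are exchangeable by construction, which the null-calibration
  test exploits.  This generator reproduces the statistical structure the
  analysis assumes — it does not emulate scanner physics, anatomical
  geometry, motion artefacts or the spatial covariance patterns of real
  parcellations, so passing tests certify the pipeline's statistical
  behaviour, not real-data validity.
* **Motion table**: gamma-distributed framewise displacement with a
  patient-group shift, for the exclusion-threshold sensitivity
  re-analysis.

# Problem sizes of the validation suite

The test suite runs: transfer tables on a 121 × 25 grid (voltage step
0.01 mV); the perturbation contrast at 80 regions (one fixed reference connectome,
generator seed 1, shared by all conditions), 10 virtual subjects,
70 s runs (the study's own run length; at the 30 s sometimes used for
quick desk checks the synchrony measures carry fewer than two passband
cycles and are unusable); mean-field fidelity against 10,000-neuron
spiking networks for 12 s at two tonic operating points; 500 null
replicates for permutation calibration; and 100 replicates of the
two-group generator at the study's 43/38 sample sizes (40 regions, 120
volumes per subject) for effect-size recovery.  The pipeline smoke test uses 12–20 regions and a coarse table
grid.

# Known limitations

* The adiabatic mean-field agrees with the spiking AdEx network to ~2% in
  tonic (asynchronous, adaptation-saturated) regimes and to ~10% around
  burst onset, but in the deeply bursting limit-cycle regime it
  underestimates time-averaged rates by up to ~35%: population bursts
  violate the adiabatic and quasi-stationarity assumptions.  The
  fidelity checks therefore quote tonic operating points; the default
  resting-state operating point *is* in the fluctuation/burst regime,
  where the model should be read as a dynamical caricature rather than a
  quantitative rate predictor.
* Synchrony and metastability on 65 s of band-passed data rest on ~4
  cycles of signal; their between-subject variance is correspondingly
  large, and the coupling-family synchrony contrast at 10 subjects is
  under-powered (the connectivity contrast is not).
* The model is homogeneous across regions (no regional parameter
  gradients), cortex-only, and uses one average connectome; reproducing
  the published numerical table values requires the study's
  tractography-derived connectome, which is external data.
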