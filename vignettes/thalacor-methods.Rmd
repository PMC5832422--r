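---
title: "Model and methods: state-dependent entrainment of alpha oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: state-dependent entrainment of alpha oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented in **thalacor**, the
conventions and numerical choices behind it, and what the synthetic
experiments can and cannot show. Code chunks are illustrative and not
evaluated at build time (full-network simulations take seconds to
minutes each).

## The scientific question

Periodic brain stimulation (e.g. alternating-current stimulation at a
fixed frequency) affects cortical rhythms very differently depending on
brain state: during rest, when alpha oscillations (8–12 Hz) are strong,
stimulation barely entrains the cortex; during task engagement, when
alpha is suppressed and firing is irregular, the same stimulation
readily takes over the rhythm. `thalacor` implements a spiking
thalamo-cortical network model in which this state dependence emerges
from two cooperating mechanisms:

1. a **noise-induced Hopf bifurcation** — irregular thalamic drive
   linearizes the effective gain of the delayed thalamo-cortical loop
   and thereby suppresses the endogenous alpha limit cycle; and
2. **stochastic resonance (SR)** — intermediate noise amplifies the
   transmission of a weak periodic stimulus through the network's
   threshold nonlinearity, with an interior optimum in noise intensity
   (as opposed to dithering, which improves monotonically).

## The spiking network

Four populations on the segment $[0, \Omega]$, $\Omega = 1$: cortical
excitatory ($e$, $N_e = 800$), cortical inhibitory ($i$, $N_i = 200$),
thalamic relay (LGN, $N = 200$) and reticular (RTN, $N = 200$) cells.
Each neuron $j$ of population $n$ carries a membrane potential $u$, an
adaptation variable $v$ and an exponential synaptic trace $E$:

$$\alpha_n^{-1}\,du = \bigl(-u + b\,v + \textstyle\sum_m S_{nm} + I_n +
\text{stim}\bigr)\,dt + \sqrt{2 D_n}\,dW,$$
$$a^{-1}\,dv = (-v + u)\,dt, \qquad
E \leftarrow E\,e^{-dt/\tau_m} + \text{spike}/\tau_m,$$

with spikes drawn per time bin as Bernoulli thinning of the saturating
rate $f(u) = f_o\,[1 + e^{-\beta(u - h)}]^{-1}$ (an inhomogeneous
Poisson process; $f_o\,dt = 0.02 \ll 1$). Recurrent input is the
delayed, weight-normalized sum
$S_{nm}(t) = N_n^{-1} \sum_k W_{jk}\,E_k(t - \tau_{jk})$.

Connectivity is sparse (probability $c = 0.2$ per ordered pair) and
spatially topographic: a present edge carries weight
$w^o_{nm}/\sqrt{2\pi\sigma^2_{nm}}\cdot
\exp[-(x_j - x_k)^2 / 2\sigma^2_{nm}]$ and delay
$|x_j - x_k|/v$ plus the fixed loop latency (45 ms between cortex and
thalamus in either direction, 10 ms between reticular and relay
populations). All parameters, their units and defaults are documented
in `?tc_params`; time is in milliseconds throughout, voltages in the
model's arbitrary units.

Brain state is set by a single knob, the relay-population noise
intensity: `tc_state("rest")` fixes $D_{LGN} = 10^{-4}$ and
`tc_state("task")` fixes $D_{LGN} = 1$. Stimulation
$S \sin(2\pi\,\omega_{stim} t)$ is applied to cortical excitatory and
inhibitory neurons only (`tc_stimulus`); the simulated EEG is a
positively weighted average of cortical somatic potentials with weights
drawn once per run from $U(0,1)$.

```{r}
library(thalacor)
sim <- tc_simulate(tc_params(), tc_state("rest"), duration_ms = 2000,
                   seed = 1)
eeg_psd(sim)$peak_frequency   # 8 Hz
```

## Conventions resolved during implementation

Several conventions of the source model description are ambiguous or
internally inconsistent; the package fixes them as follows, and each is
exposed as an explicit parameter so that the alternatives remain one
keystroke away.

**Kernel normalization** (`kernel_norm`). The source connectivity
kernel expression is ambiguous in where the connection probability
$c$ enters. `"raw"` (default) uses
$W = w^o/\sqrt{2\pi\sigma^2}\cdot e^{-\Delta x^2/2\sigma^2}$ on sampled
edges, so the dense-equivalent coupling is $\approx c\,w^o$;
`"expected"` divides by $c$ and by each target's realized kernel mass,
making the expected summed input exactly $w^o$. With `"expected"` the
couplings (up to $w^o = 85$ against a firing threshold of $h = 0.1$)
saturate every population into a binary switching regime in which noise
cannot act as a gain control; `"raw"` places the network in the
moderate-coupling regime where the full state-dependence phenomenology
emerges, and is therefore the default.

**Adaptation sign** (`b = -0.3`). The dynamics are written with a
$+b\,v$ term and the parameter table lists the adaptation gain as
magnitude 0.3. Spike-frequency adaptation is by definition
hyperpolarizing — a positive coupling to a slow copy of $u$ would be
facilitation, and indeed with $b = +0.3$ the network has no alpha limit
cycle at all (the slow positive feedback stabilizes a tonic
asynchronous state). The default is therefore $b = -0.3$.

**Conduction velocity** (`v = 0.01` segment lengths per ms). The
stated velocity of 0.35 m/s equals 0.35 mm/ms; mapping the unit
segment onto a cortical/thalamic sheet of ≈35 mm gives
$v = 0.01\,\Omega$/ms. This matters dynamically: with negligible
axonal dispersion the rhythm locks to the bare 90 ms cortico-thalamic
loop (≈11 Hz and its period-2 harmonic at ≈22 Hz); the
distance-dependent delay dispersion of the broad ($\sigma^2 = 0.25$)
projections stretches the effective loop period to ≈125 ms, i.e. the
8 Hz alpha, which is exactly the stated mechanism (slow adaptation
plus finite conduction velocity).

**Noise floor** (`D = 10^{-3}` for non-LGN populations). The source model
specifies only $D_{LGN}$. With a floor of $10^{-4}$
everywhere else the silent network state is absorbing (the spontaneous
rate at $u = 0$ is $f_o/(1+e^{15}) \approx 6\times10^{-8}$/ms) and the
rest-state cycle, once perturbed, can die irreversibly; $10^{-3}$ keeps
re-ignition possible while remaining ~40× below threshold crossing at
rest.

**Initialization and burn-in.** The quiescent state coexists with the
alpha limit cycle, so a simulation must be actively ignited: cortical
potentials are jittered ($u_0 = I_n + U(0, 0.2)$) and the cortical
adaptation variable starts 0.5 below its fixed point, which via the
$b\,v$ term yields a smooth depolarizing ramp decaying on the 100 ms
adaptation timescale. This ignites the limit cycle deterministically
across seeds; the first 500 ms are flagged as burn-in and excluded from
every analysis. A millisecond-scale jitter alone ignites unreliably
(the regenerative cortical burst races the ~1 ms membrane decay and
fast inhibition).

**Subnormal flush.** Synaptic traces decaying below $10^{-12}$ are set
to zero (they are $10^{11}$ times smaller than a single spike's
contribution); this avoids pathological subnormal-arithmetic slowdowns
without measurable effect on the dynamics. Weights are rounded to
single precision once at network construction so the packed compiled
core and the pure-R reference integrator are bit-identical.

## Spectral, phase and information analyses

**PSD** (`compute_psd`): Welch averaging with 1000 ms Hann windows and
50% overlap — 1 Hz resolution, enough to separate the 8 Hz endogenous
peak from 11 Hz stimulation. Scaling is chosen so the integral of the
PSD equals the time-domain variance (checked to $10^{-6}$ relative on
deterministic signals with a full-length rectangular window). The peak
search excludes DC and, by default, frequencies above 100 Hz.
`detect_spectral_peak` additionally requires the peak to exceed three
times the median 1–30 Hz power before calling it "detectable" — the
task state's suppressed spectrum then still shows a small residual bump
at 7–8 Hz, which is a real feature (the damped precursor of the
bifurcation), not an artifact.

**Phase locking** (`phase_locking`, `phase_experiment`): per trial a
random 500 ms window is drawn and the single DFT bin nearest the
stimulation frequency extracted from the cortical excitatory mean rate
and the stimulus (with 500 ms windows the bins are 2 Hz apart, so
11 Hz maps to the 12 Hz bin; the bin actually used is recorded as
`f_used`). The circular variance of the phase differences measures
clustering. Significance (`shuffle_significance`) permutes the
pairing between response and stimulus phases and, per shuffle,
computes the mean circular variance over a random two-group split;
the observed statistic is computed through the same split machinery,
because circular variance estimates are biased by sample size —
comparing a full-sample statistic against half-sample nulls would
produce badly mis-calibrated p-values (this is verified by a
uniformity test in the suite).

**Mutual information** (`mutual_information`, `mi_from_rho`): the
Gaussian-channel formula $MI = \tfrac12\log_2(1 + \rho/(1-\rho))$
applied to a cross-spectral correlation $\rho$. Over the full band the
real-valued $\rho$ equals the time-domain Pearson correlation
(Parseval), which is the printed definition but is blind to signal
content at a constant phase lag — an entrained response lagging the
stimulus by a quarter cycle would register as zero information. The SR
sweep (`sr_sweep`) therefore uses the modulus of the cross-spectral
sum restricted to a ±2 Hz band around the stimulation frequency; both
variants are available through `method` and `band` arguments.

**SR noise grid.** `sr_sweep` applies a common noise intensity to all
four populations and sweeps eight log-spaced values over
$[10^{-4}, 10^2]$: from rest-state intensity, through the task state,
to far beyond it, so that both the rising flank (noise releases the
stimulus from the endogenous attractor) and the falling flank (noise
swamps the response) of the resonance are covered.

## The reduced delayed oscillator

The loop is reduced to one delayed scalar with slow adaptation:

$$\dot U = -U + b V + F_{th}\bigl(U(t-T)\bigr) + S\sin ft, \qquad
s\,\dot V = -V + U,$$

with threshold response
$F_{th}(U) = \tfrac{g}{2}\bigl(1 + \mathrm{erf}(U/\sqrt{2\Gamma})\bigr)$,
$g<0$. Noise of variance $\Gamma$ smooths the response; linearizing
about the fixed point gives the effective gain
$R_{th} = g/\sqrt{2\pi\Gamma}\cdot e^{-u_o^2/2\Gamma}$
(`effective_gain`), which shrinks as noise grows — the analytic
skeleton of the state dependence.

**Units.** The reduced model runs in dimensionless time; one unit
corresponds to the effective relaxation time of the cortical
population, ≈10 ms, so the loop delay $T = 2\times 45$ ms is $T = 9$
units. This is the unique reading under which the classical
delayed-feedback boundary condition
$T\sqrt{R_c^2 - 1} = \cos^{-1}(1/R_c)$ yields the reference critical
gain $R_c \approx -1.05$ (in millisecond units the same condition
would give $-1.0006$).

**Hopf boundary** (`hopf_boundary`): the characteristic equation
$\lambda = -1 + b/(1 + s\lambda) + R e^{-\lambda T}$ is solved on the
imaginary axis on the first-instability branch
($\omega T \in (\pi/2, \pi)$, the branch with the smallest critical
$|R|$). In the slow-adaptation limit ($b = 0$; equivalently $s$ large,
where the adaptation term drops out of the characteristic equation)
this reduces to the closed-form condition above, which is also
implemented verbatim (`condition = "printed"`); the two routes agree
to $10^{-8}$, and with the network's $b = 0.3$, $s = 10$ the boundary
moves by less than 1%. Note the source linearization writes the
decay as $(b-1)U$, which is inconsistent with its own printed boundary
condition (that condition assumes decay $-1$); the package follows the
boundary condition. The DDE integrator (`integrate_dde`,
Euler–Maruyama, history held at the fixed point) cross-validates the
boundary by bisection to within 2%.

**Resonance curves** (`resonance_amplitude`): substituting
$U = A\sin ft + B\cos ft$ into the linearized equation gives exactly
$A = -SP/(P^2+Q^2)$, $B = -SQ/(P^2+Q^2)$ with $P = a + R\cos fT$,
$Q = f + R\sin fT$ ($a = -1$), amplitude $S/\sqrt{P^2+Q^2}$ — linear
in $S$ and matching the DDE steady state to <1%. The source's
closed forms agree with this solution up to two evident typos in
transcription. `rest_vs_task_curves` places the rest gain 5% above and
the task gain 20% below the critical gain: with symmetric ±10%
placement the two resonant peaks come out nearly equal (the response
denominator is locally symmetric in $R$ about $R_c$) and the
state-dependence signature — higher resonant peak at rest, higher
non-resonant amplitudes in task — would be invisible.

## Experiment drivers and problem sizes

`drive_sweep`, `frequency_sweep`, `arnold_tongue`, `phase_experiment`,
`sr_sweep` and `run_all` orchestrate the standard experiment battery
with deterministic child seeds spawned from one master seed, failure
records instead of silent gaps, and (for the tongue) an incremental
CSV checkpoint enabling resumption. Entrainment is classified
per (S, frequency) cell as: EEG peak within one 1-Hz PSD bin of the
stimulation frequency, with the stimulation frequency itself more than
one bin away from the endogenous rhythm (where entrainment and
resonance cannot be told apart).

Default problem sizes are chosen for desk-scale reproducibility: 2 s
analysis windows after 500 ms burn-in; three seeds for spectral-peak
claims; 10×10 tongue grids over $S \in [0, 0.5]$,
$\omega_{stim} \in [0, 50]$ Hz; 20 trials per noise level in scaled SR
sweeps (200 at full scale); and a quarter-size network
(`tc_params_small`, 200/50/50/50 neurons) for sweeps. The expected
synaptic input per neuron is size-invariant under the kernel scaling,
so reduced networks preserve the mean-field dynamics with larger
finite-size fluctuations: the quarter network's rest peak sits at
8–9 Hz (vs 8–8.5 Hz at full size) and its rest-state alpha *power* is
seed-variable (0.008–0.065 vs 0.12–0.17 at full size). Analyses that
compare endogenous against stimulus-driven spectral power — Arnold
tongue classification in particular — therefore run on a 3/8-scale
network (300/75/75/75), the smallest size at which the rest attractor's
power is robust (0.05–0.15); the stimulus contributes a direct
membrane-polarization component to the EEG that does not shrink with
network size, and against a weak attractor it would dominate the
spectrum spuriously.

## What the synthetic experiments do and do not show

Everything here is simulation: there is no empirical EEG anywhere in
the pipeline. Passing tests demonstrate that the implemented equations
reproduce the reference phenomenology — an 8 Hz rest rhythm whose
power falls and whose peak drifts up by ≤0.5 Hz under rising thalamic
drive, 11 Hz entrainment in the task state, an interior SR optimum,
state-dependent Arnold tongues, and the analytic behaviour of the
reduced oscillator. They do not validate the model against biological
recordings, physical field strengths (model voltages are arbitrary
units), cellular biophysics (conductances, compartments), or
plasticity, all of which are outside the model class.

Two reference qualitative claims are only partly reproduced and are
documented rather than hidden. First, pairwise excitatory rate
correlations under stimulation: the implementation reproduces the
crossover (stimulation lowers correlations at rest, raises them in the
task state relative to sham) but not a monotone increase along the
drive sweep — in this parameter regime the task-state cortex sits near
rate saturation, so the common 11 Hz modulation is too shallow to
outweigh the loss of endogenous synchrony. Second, in the rest state a
weak stimulus still leaves a measurable phase preference at the
stimulation frequency (the reference behaviour is a flat distribution); the
ordering rest ≫ task in circular variance is robust, the rest-state
uniformity is not. Both are properties of the calibrated operating
point, not of the analysis code.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh seed: the critical
gain of the reduced oscillator at $T = 90$ ms; the rest-state EEG peak
frequency (3 seeds, median); the task-state peak under 11 Hz, S = 0.15
stimulation (3 seeds, median); and the maximum detected alpha-peak
frequency across a sham drive sweep. See the README for invocation.
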