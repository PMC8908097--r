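---
title: "Simulating heterogeneous responses to changes in inhibitory synaptic strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterogeneous responses to changes in inhibitory synaptic strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(izhnet)
```

## The scientific question

When all inhibitory synapses in a recurrent network are weakened by the
same amount — as happens, crudely, when a GABA~A~ antagonist such as
bicuculline is applied to a neuronal culture — one might expect every
neuron to fire more. In simulations of spiking networks this expectation
fails: individual neurons may increase, decrease, or not change their
firing rate, because each neuron's synaptic current depends on the firing
histories of its presynaptic partners, not only on its own synaptic
weights. Whether the *network-average* rate responds at all turns out to
depend on a structural feature: the shape of the distribution of per-neuron
average outgoing synaptic weights. Networks in which that distribution is
long-tailed (a few "hub" presynaptic neurons carry disproportionately
strong outgoing synapses) burst and respond to disinhibition with a net
rate increase; networks in which it is approximately Gaussian fire
asynchronously, do not burst, and show essentially no net response.

`izhnet` packages this in-silico experiment end to end: network
construction, stochastic simulation, suppression operators, and spike-train
analysis.

## The model

Each of the $N$ neurons follows the two-variable quadratic
integrate-and-reset dynamics with a stochastic drive,

$$\frac{dv_i}{dt} = 0.04 v_i^2 + 5 v_i + 140 - u_i + I_i + \alpha\,\xi_i(t),
\qquad \frac{du_i}{dt} = a (b v_i - u_i),$$

with a spike recorded whenever $v_i \ge 30$ mV, followed by the reset
$v_i \to c$, $u_i \to u_i + d$. Excitatory neurons are regular-spiking
($a = 0.02$, $d = 8$), inhibitory neurons fast-spiking ($a = 0.1$,
$d = 2$); both share $b = 0.2$ and $c = -65$ mV. $\xi_i$ is unit-variance
Gaussian white noise, independent across neurons, and $\alpha$ scales it.

Synapses are conductance-based:

$$I_i = G^{exc}_i\,(V_E - v_i) + G^{inh}_i\,(V_I - v_i),$$

with $V_E = 0$ mV, $V_I = -80$ mV. A spike of presynaptic neuron $j$
increments the excitatory (or inhibitory) conductance of each of its
targets by $|w_{ij}|$; between spikes conductances decay exponentially with
$\tau_{exc} = 5$ ms and $\tau_{inh} = 6$ ms, so

$$G^{exc}_i(t) = \sum_{j,\,w_{ij}>0} w_{ij} \sum_k
  e^{-(t - t_{j,k})/\tau_{exc}}\,\theta(t - t_{j,k}),$$

and analogously for inhibition. `conductance_closed_form()` evaluates this
sum directly and serves as the independent oracle for the integrator.

### Numerical scheme

Integration is Euler–Maruyama with `dt = 0.125` ms over `total_time = 7500`
ms by default. Choices the equations themselves do not pin down:

* **Recovery-variable initialization.** Only $v(0) = -65$ mV is stated by
  the model; we set $u(0) = b\,v(0)$ (the recovery nullcline), which makes
  the noise-free network flow to the stable fixed point $(-70, -14)$
  without firing — the documented quiescence property.
* **Noise scaling.** The stochastic increment is $\alpha \sqrt{dt}\, z$
  with fresh standard-Gaussian $z$ per neuron per step, entering only the
  membrane equation.
* **Conductance decay.** The exact factor $e^{-dt/\tau}$ is used, not the
  first-order $1 - dt/\tau$, so the closed-form solution holds to
  floating-point accuracy between deliveries.
* **Delivery timing.** A spike detected in a step is stamped with the
  step's end time and first affects its targets' synaptic currents at the
  following step. This avoids any dependence on neuron ordering within a
  step. Consequently the conductance sampled at a delivery instant includes
  the just-delivered increment (the boundary case $\theta(0)$ is taken as
  1 on the sampling grid).
* **Reset ordering.** The membrane update uses the pre-reset state;
  threshold detection and reset happen after the full state update.
* **Divergence guard.** If $|v|$ exceeds $10^3$ mV without crossing the
  spike threshold the run aborts with a diagnostic rather than continuing
  silently; with the default parameters this indicates a pathologically
  strong network (the explicit Euler scheme destabilizes once total
  conductances approach $2/dt$).

`simulate_network()` is bit-reproducible for a fixed `seed`, and
`izh_step()` exposes a pure-R reference step against which the compiled
loop is tested.

## Synthetic networks

The reference networks this package emulates were effective-connectivity
estimates from multi-electrode-array recordings of cortical cultures:
$N = 4095$ nodes, connection probability around 1.1–1.5%, inhibitory
fractions 0.14–0.28, Dale-consistent signs, and long-tailed distributions
of the per-neuron average weights $s_{in}^+$, $|s_{in}^-|$ and $|s_{out}|$.
Those weight matrices are not available, so `generate_longtailed_network()`
draws networks with the same stated statistics:

* every ordered pair is connected independently with probability
  `connection_probability` (default 0.015);
* each neuron is inhibitory with probability `inhibitory_fraction`
  (default 0.28, the densest culture's value);
* neuron $j$ draws an outgoing weight scale $m_j$ from a log-normal
  distribution (`out_scale_log_mean`, `out_scale_log_sd`), and each of its
  outgoing weight magnitudes from a gamma distribution with mean $m_j$ and
  coefficient of variation `within_neuron_weight_cv` (gamma guarantees
  positivity; CV 0 collapses to equal weights);
* signs follow the neuron's type; neurons left without outgoing links are
  labeled `silent`.

The log-normal across neurons is what produces the long tail of
$|s_{out}|$; the incoming-side averages are near-Gaussian by the central
limit theorem since incoming weights are independent draws. This is a
deliberate simplification: real reconstructed networks also showed
long-tailed *incoming* averages, but the column-shuffled control (below)
demonstrates that the outgoing tail is the feature that matters for the
phenomena studied here, so the generator reproduces that feature
faithfully and leaves incoming correlations out.

### Calibration of the default weight scale

The generator's weight unit is arbitrary, so the default scale was fixed
once by calibration, as the statement of the study conditions: with
$\alpha = 3$ the network-average spontaneous rate should be of order 1–10
spikes/s (comparable to culture recordings), the pooled ln(ISI)
distribution should be bimodal (bursting), and the Gaussian-weight
surrogate of the same network should fire asynchronously without bursts.
The defaults are `out_scale_log_sd = 0.8`, `within_neuron_weight_cv = 0.2`
and `out_scale_log_mean = log(0.0145) - 0.32` (mean scale
$\bar m = 0.0145$). The within-neuron CV default of 0.2 keeps the per-edge
weight spread modest: a larger CV inflates the reference's weight SD,
which directly strengthens the Gaussian surrogate (its magnitudes scale
with that SD) and erodes the contrast the surrogate is meant to exhibit.

This working point deserves honesty about its fragility. Three onsets
squeeze it: (i) isolated neurons driven by $\alpha = 3$ noise fire at only
$\sim$0.35 spikes/s, and global bursting ignites once the mean coupling
crosses a sharp threshold near $\bar m \approx 0.015$; (ii) the
row-shuffled surrogate keeps the *same per-edge weight distribution* and
therefore has nearly the same threshold, offset upward by only $\sim$10%
(the contribution of per-column weight grouping — the hubs); (iii) the
Gaussian surrogate redraws weights with the reference's signed mean and SD,
and for a heavy-tailed reference its mean weight *magnitude*
($\approx 0.8 \times$ SD) exceeds the reference's mean, moving it toward
bursting as the tail grows. With an Erdős–Rényi backbone at 1.5%
connectivity these three constraints leave only a narrow band of weight
scales in which the long-tailed network bursts while both surrogates do
not, and within that band the outcome still varies with the network
realization (the drawn hub set) and the noise path. The acceptance checks
therefore run at this calibrated point with fixed seeds, and the package
documents — rather than hides — that bursting is a near-threshold
collective transition: the dichotomy is reproduced as a typical-case
property, not a guarantee for every realization.

## Surrogate networks and the suppression operator

Three controls isolate which structural feature matters, all preserving
Dale consistency and the empty diagonal:

* `generate_gaussian_surrogate()` — random graph at the reference's
  empirical connection probability, weights drawn
  $\mathcal N(\text{mean}, \text{SD})$ of the reference's signed weights,
  then signs forced to each presynaptic neuron's type with magnitudes kept.
  Note the sign adjustment shifts the signed mean of the final matrix by a
  modest fraction of the SD (toward $E|X|\,(f_{exc} - f_{inh})$); the SD is
  essentially preserved.
* `shuffle_within_columns()` — permutes each column over off-diagonal
  positions: every neuron keeps its out-degree and outgoing weight multiset
  (hence exactly its $|s_{out}|$), while incoming structure randomizes.
* `shuffle_within_rows()` — permutes each row: every neuron keeps its
  incoming weight-magnitude multiset, while the outgoing-average
  distribution collapses toward Gaussian. The sign adjustment may flip
  signs here, so incoming averages are close to, not identical to, the
  reference's.

Uniform suppression of inhibition replaces every negative weight $w$ by
$\min(w + k\sigma,\,0)$, where $\sigma$ is the *population* standard
deviation (denominator $n$: the edge set is a complete enumeration, not a
sample) of all inhibitory weights of the unmodified network, and $k \in
\{0.25, 0.5, 1\}$ is the study grid. The clamp guarantees an inhibitory
synapse is removed rather than turned excitatory. Enhancement is the
unclamped opposite shift $w - k\sigma$. `suppression_ratio()` reports the
achieved relative decrease in mean inhibitory magnitude, computed over the
original network's inhibitory edge positions with clamped edges
contributing zero — this keeps the ratio interpretable as "fraction of
inhibitory weight removed" even when edges vanish.

## Spike-train analysis

* `firing_rates()` — spike count over the whole window divided by the
  window, in spikes/s; silent neurons count with rate 0, so
  $\sum_i r_i \, T$ equals the total spike count exactly.
* `rate_change()` — per-neuron $\Delta r$ between two runs, classified as
  increased / decreased / unchanged with tolerance $\varepsilon$
  defaulting to one spike per window ($1000/T$ spikes/s with $T$ in ms),
  the smallest resolvable rate difference; plus the network rate ratio
  $(\bar r_{mod} - \bar r_{base})/\bar r_{base}$ and the skewness of the
  $\Delta r$ distribution (symmetry about zero means no net network
  response).
* `pooled_log_isi()` — inter-spike intervals computed within each neuron,
  pooled across neurons (the burst diagnostic is network-level), natural
  log, ms units.
* `classify_modality()` — Gaussian kernel density over the pooled ln(ISI)
  with Silverman's rule-of-thumb bandwidth; local maxima with relative
  prominence $\ge 0.05$ of the global maximum are counted; two or more
  peaks mean "bimodal" (bursting), with peak locations reported in ms.
  Two caveats are documented behavior: modes separated by less than about
  one bandwidth merge and read as unimodal; and because simulated spike
  times are quantized to multiples of `dt`, very large ISI samples can
  drive the data-led bandwidth below the quantization spacing and resolve
  a comb of spurious short-interval peaks — a bandwidth floor
  (`min_bandwidth = 0.15` in ln units, about the spacing of representable
  intervals near 1 ms) merges the comb while leaving burst/inter-burst
  modes, typically 2–4 ln units apart, untouched.
* `generate_burst_fixture()` — ground-truth spike trains whose ISIs come
  from a two-component log-normal mixture (defaults: modes near 5 ms and
  100 ms, the two timescales of culture bursting), used to validate the
  classifier: well-separated modes must be called bimodal, single modes
  unimodal, across seeds.

What passing on these synthetic inputs does and does not show: the
generator emulates stated summary statistics (sparsity, type fractions,
outgoing-weight tail) but not everything real cultures have — no spatial
structure, no degree–weight correlations, no refractory or adaptation
heterogeneity, no long-tailed incoming averages. Conclusions about those
features are outside what this package's tests can support.

## The experiment grid

`run_suppression_sweep()` executes the full design: resolve or generate
the network, simulate a baseline, then for each suppression level derive
the modified network, simulate, and analyze. Per-level noise seeds are
derived deterministically from a master seed (`derive_seed()`), so adding
a level does not perturb the other levels' streams. The baseline and the
modified runs use independent noise by default — the comparison mimics
independent experiments; set `common_noise = TRUE` to reuse the baseline
stream (then $k = 0$ reproduces the baseline exactly, a useful plumbing
check). Problem sizes used by the package's own checks: full-scale
simulations run at $N = 4095$, $T = 7500$ ms; reduced sanity runs use
$N = 500$, $T = 2000$ ms, where the noise-driven (non-bursting) regime is
representative.

A thin command-line driver (`inst/exec/izhnet-cli.R`) exposes `generate`,
`surrogate`, `suppress`, `simulate`, `analyze` and `sweep` subcommands over
these functions, reading INI-style configuration files and writing
tab-separated outputs with provenance headers.

## Worked example

```{r example, eval = FALSE}
prof <- long_tail_profile(seed = 1)
net <- generate_longtailed_network(prof)
compute_summaries(net)

plan <- experiment_plan(net, levels = c(0.25, 0.5, 1), master_seed = 1)
sweep <- run_suppression_sweep(plan, progress = TRUE)
sweep$summary
```

The summary table reports, per suppression level, the achieved suppression
ratio, the network mean rate, the relative change of the network-average
rate, the fractions of neurons with increased/decreased rates, the skewness
of the rate-change distribution, and the ln(ISI) modality label.

## Known limitations

* The bursting dichotomy is a near-threshold collective effect (see the
  calibration section): at the default working point a minority of network
  realizations on either side can cross the transition.
* Erdős–Rényi topology only; no spatial embedding or clustering.
* Synaptic delays are a single integration step; no short-term plasticity;
  only the regular-spiking and fast-spiking parameter classes.
* The modality classifier answers "bimodal or not" — it does not segment
  individual bursts or report burst rates.
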