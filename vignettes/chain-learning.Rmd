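---
title: "Learning synfire-chain recognizers for spatio-temporal spike patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning synfire-chain recognizers for spatio-temporal spike patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A repeating spatio-temporal spike pattern — a fixed 50-ms template of spike
times across a thousand afferents — is hidden in Poisson noise that is
statistically identical to the pattern itself. A single neuron equipped with
spike-timing-dependent plasticity (STDP) can learn to fire at the beginning
of such a pattern. `spikechain` implements the network extension of that
idea: a pool of excitatory neurons, all-to-all connected by *plastic lateral
synapses* and kept in competition by a shared inhibitory neuron
(winner-takes-all), self-organizes into *chains*. Each chain neuron learns a
different segment of the pattern, and the lateral synapses between
consecutively firing neurons strengthen so that a non-initial neuron fires
only when both its input segment is present *and* its predecessor has just
fired. The terminal ("accepting") neuron of a chain then signals that the
complete pattern occurred in the correct order — a small finite-state
recognizer made of spiking neurons.

## Model

**Neurons.** Leaky integrate-and-fire with membrane time constant
$\tau_m = 10$ ms and threshold $\theta = 1$:
$\tau_m \dot V = -V + S^{ff}_f + S^{lat}_f - S^{inh}_f$, with reset $V = 0$
at threshold. Synaptic input enters through alpha-function channels, each a
cascade of two first-order stages with rise $\tau_r = 1$ ms and fall
$\tau_f = 5$ ms; both stages have unit DC gain. Spikes are binary pulses of
height $w$ lasting one integration step ($dt = 0.1$ ms, forward Euler; all
state updates in a step use start-of-step values, then thresholds are
applied, and spikes reach their targets on the next step).

**Stimulus.** 2000 afferents. Half carry continuous Poisson spikes at 54 Hz;
the other half alternate between a frozen 50-ms spike pattern (itself drawn
once from a 54-Hz Poisson process) and fresh 54-Hz Poisson spikes, with
gaps of at least 50 ms (50 ms plus an exponential with 50 ms mean, giving a
pattern duty cycle of about one third). A 10-Hz Poisson background is
superposed on every afferent at all times, so all afferents run at 64 Hz in
the long run and the pattern is statistically invisible. More than 80% of
all input spikes are noise. Each excitatory neuron receives its own
independent noise realizations; only the frozen pattern is shared across
neurons (a fully shared mode exists for diagnostics). This independent
noise is what breaks the symmetry between neurons so the competition can
assign them to different segments.

**Plasticity.** Additive exponential STDP with
$\tau_p = \tau_d = 20$ ms on all feed-forward and lateral excitatory
synapses, potentiation amplitude $A_p = 0.002\,W_{max}$ of the synapse
class and depression $A_d = -1.05\,A_p\,(\tau_p/\tau_d)$, so depression
outweighs potentiation by 5% and uncorrelated Poisson activity slowly
depresses synapses. Feed-forward weights are clipped to
$[0, W^P_{max}]$; the summed lateral input to each neuron is normalized to
at most $W^L_{max} = 50$ whenever potentiation pushes it above, which
preserves relative proportions and is applied immediately after each
potentiation event. Learning rates are applied per synapse class with that
class's bound: a lateral synapse must traverse a range 250 times larger
than a feed-forward one, and only the per-class scaling lets both converge
on the same few-minutes timescale.

**Competition.** Every excitatory spike excites the inhibitory neuron
(static weight `w_ei`), and every inhibitory spike hyperpolarizes the whole
excitatory pool (static weight `w_ie`). Because a PSP strong enough to
drive the inhibitory neuron across threshold within ~1.5 ms keeps its
membrane high for several milliseconds, the inhibitory answer is a short
burst; `derive_wta_weights()` therefore calibrates `w_ie` against the
simulated *compound* burst so that its peak hyperpolarization is twice
threshold. The resulting suppression lasts a few milliseconds to a couple
of tens of milliseconds, which spaces chain members roughly 5–15 ms apart
and bounds chain length for a 50-ms pattern at about 3–8 neurons.

## Pairing schemes

Two pairing schemes are implemented. *All-to-all* sums the window over
every pre/post spike pair, realized online with exponential traces.
*Nearest-neighbor* considers, for each postsynaptic spike, only the
presynaptic spike closest to it: the nearest pre at-or-before it
(potentiation) and the nearest pre strictly after it (depression). Both
schemes preserve the designed 1.05 depression/potentiation ratio for
uncorrelated Poisson trains. An alternative nearest-neighbor depression
(`nn_depression = "all_post"`), in which every pre spike is depressed by
the full postsynaptic trace, is provided for comparison; under it the
depression side outweighs potentiation roughly 2.4-fold at these rates and
network activity collapses before any pattern can be learnt — even a
perfectly pattern-locked synapse is net-depressed once its neuron fires
above a few hertz — so it is not the default.

`pair_sum_oracle()` evaluates the same pairings by explicit double loop
over spikes and serves as the independent reference for the online trace
implementation (they agree to 1e-9 on random trains; this is a tested
property).

## Numerical choices

* The feed-forward bound follows
  $W^P_{max} = \theta/(\tau_m \langle r\rangle\, dt) \cdot A/N_{input}$
  with times in ms; the $1/dt$ compensates the one-step spike convention.
  The strength constant defaults to $A = 12.8$ ($W^P_{max} = 0.2$),
  calibrated behaviorally: uniform initial weights then put the mean
  membrane drive moderately above threshold, so neurons fire noise-driven
  from the start, the competition can assign segments, and a trained
  neuron's segment volley crosses threshold while random input alone
  rarely does. Much larger values drive the whole pool in lock-step and no
  segment structure forms; much smaller values leave the network silent
  and nothing is learnt.
* Poisson trains are realized as per-bin Bernoulli spikes
  (`rate * dt`); coincident carrier/background/pattern spikes on one
  afferent collapse to one binary spike. Inside the compiled simulator the
  per-bin draws are generated as a binomial count plus a uniform distinct
  subset, which is distributionally identical and much faster.
* One master seed spawns independent sub-streams for the pattern, the
  schedule, the noise, the initial weights and the tests, so components
  can be varied independently; the compiled core uses its own
  counter-seeded generator, making every protocol bit-reproducible.
* Evaluation details the source model leaves open are fixed as follows,
  all exposed as arguments: the response window extends 20 ms past pattern
  offset; first-spike order inversions within 2 ms (the jitter scale; also
  the scale separating temporal "slots") are not counted as disorder; a
  strengthened lateral edge is one above $0.08\,W^L_{max}$, which lies in
  the gap of the trained weight distribution — the sum normalization
  spreads a converged neuron's incoming budget over its ~5–10
  predecessors, so strengthened synapses sit near $W^L_{max}/k$ rather
  than at $W^L_{max}$ itself; and with several chains forming in parallel
  (a frequent, legitimate outcome), the severed-lateral criterion admits
  any chain-head start node, not only the globally earliest neuron.

## What the trained network looks like

Training runs for 200 s of simulated time by default. Early on, all
neurons fire vigorously from the suprathreshold noise drive; the 5%
depression margin then gradually prunes unselective feed-forward weights
while neurons that happen to fire repeatedly at the same pattern phase
potentiate their segment afferents toward the bound, sharpening their
selectivity; lateral synapses between consecutively firing neurons
strengthen toward the normalization budget. The evaluation battery
(`evaluate_run()`) presents the frozen pattern ten times in fresh noise
and applies three criteria: *pattern learnt* (some neurons fire in at
least 50% of presentations), *sequence learnt* (additionally, with lateral
input severed only chain-head neurons remain reliable, and members fire in
a fixed order), and per-presentation *recognition* (every member fired —
optionally in order, the automaton reading used for the reversed-pattern
probe).

At the defaults, over the ten-seed battery used by the package's
acceptance tests: the pattern is learnt in 10/10 trials, the sequence
criterion in 7/10, successful chains average 5.4 members, extracted chain
graphs are acyclic in all trials, and a time-reversed pattern is never
recognized in order. The severed-lateral sweep reproduces the direction of
the lateral-bound effect (neurons become markedly more dependent on their
predecessors as $W^L_{max}$ grows), with ~100% of members independent of
lateral input at $W^L_{max} = 5$ versus ~35% at $W^L_{max} = 55$.

## Known limitations

* **Convergence is slower than in the source model.** The sequence
  criterion is typically met only after 100–200 s of simulated time, not
  within the first 10–20 s: the selective state emerges as the slow 5%
  depression drift prunes the initially unselective drive. Reported
  first-member latencies average ~30 ms rather than ~15 ms, because chains
  often cover only part of the pattern and their heads may sit mid-pattern.
* **Member reliabilities hover at 0.5–0.8** rather than well above 0.9, so
  whole-chain recognition rates per presentation are modest; error
  probabilities accumulate along the chain, as expected at this noise
  level.
* **Speed invariance is wider than in the source model**: compressing the
  pattern (factor 2) raises the instantaneous input rate enough that
  members still respond; with weakly lateral-dependent chains the
  compressed pattern is still recognized by presence, though timing
  compresses accordingly. `run_speed_variation_test()` exposes the probe
  and an optional threshold override.
* The synthetic stimulus is exactly stationary Poisson with an exactly
  frozen pattern; real spike trains have rate modulation, refractoriness
  and jittered repeats, none of which are modeled, so passing tests here
  demonstrate the learning mechanism, not performance on physiological
  recordings.

## Problem sizes used by the test-suite

The unit tests run a miniature network (5 neurons, 200 afferents, 10 s);
the acceptance battery runs ten full-scale 200-s trials plus a 3-seed
lateral-bound sweep and three all-to-all trials, which keeps the whole
suite within half an hour on one core. The `fast_preset()` (500
afferents, 50 s) exercises every code path in seconds for interactive
work, at the cost of noisier outcomes.
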