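# spikechain

Self-organizing synfire-chain recognizers for spatio-temporal spike
patterns.

## What it does, and for whom

`spikechain` is a simulation package for computational neuroscientists
studying how spiking networks can *learn to recognize temporal structure*.
A frozen 50-ms spatio-temporal spike pattern is repeatedly inserted into
half of 2000 Poisson afferents, embedded in statistically identical
carrier noise (plus 10 Hz background everywhere, so over 75% of all input
spikes are noise). A pool of *N* = 20 leaky integrate-and-fire neurons —
all-to-all connected by plastic lateral synapses and kept in
winner-takes-all competition by one shared inhibitory neuron — is trained
with additive exponential STDP on both the feed-forward and the lateral
synapses. The neurons self-organize into directed *chains*: each neuron
becomes selective for a different segment of the pattern, and the lateral
synapses between consecutively firing neurons strengthen so that a
non-initial neuron fires only when its input segment arrives *and* its
predecessor has just fired. The terminal ("accepting") neuron then signals
that the whole pattern was seen in order — a finite-state recognizer made
of spiking neurons.

## Model in brief

Membrane: τ_m dV/dt = −V + S_f, reset V = 0 at threshold θ = 1
(τ_m = 10 ms). Each synaptic channel is an alpha function, i.e. two
first-order stages: τ_r dS_r/dt = −S_r + I, τ_f dS_f/dt = −S_f + S_r
(τ_r = 1 ms, τ_f = 5 ms), integrated by forward Euler at dt = 0.1 ms with
binary one-step spikes.

STDP window: f(τ) = A_p exp(−τ/τ_p) for τ ≥ 0, f(τ) = A_d exp(τ/τ_d) for
τ < 0, with τ_p = τ_d = 20 ms, A_p = 0.002·W_max of the synapse class and
A_d = −A_p (τ_p/τ_d) · 1.05, so uncorrelated activity slowly depresses.
Nearest-neighbor pairing uses, per postsynaptic spike, only the closest
presynaptic spike on either side; all-to-all sums every pair via
exponential traces. Feed-forward weights are bounded by
W^P_max = θ/(τ_m·⟨r⟩·dt) · A/N_input; incoming lateral sums are
normalized to W^L_max = 50 (proportional rescale whenever exceeded).

## Worked example

```r
library(spikechain)

cfg <- network_config(seed = 204)   # 20 neurons, 200 s training
rec <- run_training(cfg)
rec
#> <sim_record> 20 excitatory neurons, 200 s training, nearest_neighbor STDP
#>   28131 excitatory spikes, 1319 presentations, wp_max = 0.2, wl_max = 50

ev <- evaluate_run(rec)             # 10 test presentations in fresh noise
ev
#> <evaluation_report> pattern learnt: TRUE | sequence learnt: TRUE
#>   chain: 10 -> 5 -> 18 -> 9 -> 19 -> 15 (6 members), recognition rate 0.00

ev$graph
#> <chain_graph> 6 members, 8 edges (threshold 4)
#>   order: 10 -> 5 -> 18 -> 9 -> 19 -> 15
#>   start: 10, 5, 18, 9, 19  accepting: 10, 5, 18, 15
```

Six neurons respond reliably (≥ 50% of presentations) to successive
segments of the pattern: neurons 10 and 5 at ~7 ms after pattern onset,
18 at ~11 ms, and 9, 19, 15 at ~45 ms — two parallel sub-chains covering
the start and the end of the pattern, linked by 8 strengthened lateral
synapses. "Sequence learnt" means that with the lateral synapses severed
only chain-head neurons keep responding (the others need both their
segment and their predecessor's spike), and that members fire in a fixed
order. The per-presentation recognition rate (all members firing in one
presentation) is low at this noise level: missing spikes accumulate along
a six-neuron chain.

Useful probes on a trained record:

```r
run_test(rec, lateral_enabled = FALSE)   # severed-lateral test
run_test(rec, reverse = TRUE)            # time-reversed pattern
run_speed_variation_test(rec, 1.02)      # compressed replay
sweep_wlmax(cfg, c(5, 25, 55))           # lateral-bound sweep
run_suite("train-nn", n_seeds = 10)      # multi-seed battery
```

A thin command-line driver with the same protocols lives at
`inst/cli/spikechain` (subcommands `train`, `test`, `sweep-wlmax`,
`multi-pattern`, `concatenate`, `speed-test`; `--fast` runs a scaled-down
preset).

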