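# retinoconn

Cell-type-specific monosynaptic connectivity analysis for retinocollicular
spike trains.

High-density probes inserted tangentially along the superficial superior
colliculus (SC) record the somatic spikes of collicular neurons together
with the axonal spikes of the retinal ganglion cells (RGCs) innervating
them. A monosynaptic RGC→SC connection appears as a fast, transient peak at
a 0.5–3.5 ms lag in the spike-train cross-correlogram (CCG). `retinoconn`
is for electrophysiologists who have such paired recordings (or want to
validate methods on simulated ones): it takes sorted spike trains plus
event tables and produces detected connected pairs, their synaptic strength
and dynamics, and cell-type-resolved population statistics.

## What it computes

For an ordered pair with presynaptic train *pre* (n_pre spikes) and
postsynaptic train *post*:

* **Jitter-corrected CCG** — raw CCG (0.1 ms bins, ±50 ms) minus its
  expectation under interval jitter: presynaptic spikes redrawn uniformly
  within fixed consecutive 10 ms windows (mean of 100 resamples). Rate
  comodulation slower than the window cancels; millisecond synchrony
  survives.
* **Detection** — connected iff ≥ 5 consecutive bins in (+0.5, +3.5) ms
  exceed baseline + 4 SD of the corrected flanks; latency = lag of the
  corrected-CCG maximum in that window.
* **Efficacy** — `(Σ_peak raw − n_bins·baseline) / n_pre` with baseline the
  mean raw count over (−1, 0.4) ms and peak window (0.4, 3.5) ms: the
  probability that a presynaptic spike triggers a postsynaptic spike.
* **Contribution** — fraction of postsynaptic spikes with a presynaptic
  spike in the preceding (0.5, 3) ms: how much of the target's firing the
  afferent accounts for.
* **Paired-spike ratio** — `PSR = eff_second / eff_first` over presynaptic
  spike pairs with 5–30 ms inter-spike interval after ≥ 30 ms of silence;
  PSR > 1 is paired-spike enhancement (facilitation).
* **Cell typing** — optotagging (pulse-locked rate increase: paired
  Wilcoxon p < 0.001, ratio ≥ 1.5, onset ≤ 20 ms, corroborated across
  protocols) separates inhibitory from excitatory SC units within the
  light-activated channel range; multi-channel waveform shape (triphasic /
  wide / propagating vs biphasic / compact) separates retinal axons from
  somata.
* **Functional similarity** — mean of five Pearson correlations between the
  pair's responses: light/dark sparse-noise receptive fields (from
  spike-triggered averages, SNR > 8 gate) and PSTHs under three repeated
  stimuli.

A synthetic-session generator (`sim_config()`, `simulate_session()`) plants
all of the above — efficacy, facilitation, latency distribution, rate
comodulation, light-gain of inhibitory units, receptive fields, waveform
classes — and returns the ground truth, so every estimator can be validated
end to end. See the vignette in `vignettes/` for the model and the design
choices.

## A worked example

```r
library(retinoconn)

rgc  <- simulate_rgc_train(rate = 10, duration_s = 600, seed = 1)
pair <- simulate_connected_pair(rgc,
          synapse_params(efficacy_base = 0.2, facilitation = 1.5,
                         background_rate = 5), seed = 2)

cc  <- corrected_ccg(rgc, pair$sc, ccg_params(seed = 3))
det <- detect_connection(cc)
det$connected                      # TRUE
det$latency_ms                     # 1.65
efficacy(cc)                       # 0.2196
contribution(rgc, pair$sc)         # 0.3293

ps <- paired_spike_analysis(rgc, pair$sc)
c(ps$n_pairs, ps$eff_first, ps$eff_second, ps$psr)
# 914  0.1853  0.3001  1.62
```

The planted transmission probability 0.2 comes back as an efficacy of 0.22
(the excess reflects the facilitated spikes, which transmit at 0.3), the
latency estimate 1.65 ms sits next to the generator's 1.5 ms mean, and the
paired-spike analysis recovers the planted facilitation factor 1.5 as
PSR = 1.62 from 914 qualifying spike pairs (first spikes transmit at the
base rate 0.19, second spikes at 0.30). Contribution is 0.33: a third of the
postsynaptic spikes directly follow a presynaptic spike.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study flow on a
reference synthetic session and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_session.R   # session + ground truth
Rscript analysis/02_qc.R                 # ISI-violation quality control
Rscript analysis/03_cell_typing.R        # optotagging + waveform classes
Rscript analysis/04_connectivity.R       # CCG scan: detection, efficacy, contribution
Rscript analysis/05_paired_spike.R       # PSR per pair and per class
Rscript analysis/06_similarity.R         # receptive fields + similarity index
Rscript analysis/07_population_stats.R   # class comparisons (rank-sum, Cohen's d)
```

Sessions live in a plain-text directory format (`manifest.json`,
`spikes.csv`, `pulses.csv`, `stim_events.csv`, `exclusions.csv`, per-unit
waveform CSVs) read and written by `read_session()` / `write_session()`;
`run_pipeline()` runs all stages on any such directory from a single JSON
config.

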