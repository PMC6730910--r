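# cvep

Simulation and decoding of code-modulated visual evoked potentials
(c-VEP) for high-speed brain-computer interfaces.

In a c-VEP BCI every selectable target flickers with its own pseudo-random
binary code (one bit per 60 Hz monitor frame; 0 = black, 1 = white). The
flicker evokes visual evoked potentials in the EEG, and the **EEG2Code**
backward model inverts the mapping: it predicts each bit of the
stimulation code from the *following 250 ms* of 32-channel EEG sampled at
600 Hz, sliding the prediction window sample-wise (600 predictions per
second, averaged in blocks of 10 into one probability per bit). This
package implements that model twice — a closed-form linear ridge
regression baseline and a five-layer convolutional network whose first
layer learns spatial filters (16 kernels of size 1×32) and whose second
layer learns temporal filters (8 kernels of size 64×1) — together with

* generation and serialization of random (and greedily decorrelated)
  stimulation codes,
* a forward EEG simulator: linear superposition of a triphasic
  single-flash VEP kernel, occipital-weighted spatial mixing, pink/white
  noise at a configurable SNR, and an optional saturating nonlinearity,
* synchronous target selection by pattern correlation, asynchronous
  self-paced selection by thresholding the one-sided correlation p-value
  `t = r·sqrt((n−2)/(1−r²))`, and discrimination of the true code among
  up to 500,000 candidates,
* the standard BCI performance measures, per minute:

  ```
  ITR = (log2 N + P log2 P + (1−P) log2((1−P)/(N−1))) · 60/T
  UTR = (2P − 1) · log2(N − 1) · 60/T
  CLM = 60 (2P − 1)/T  if P ≥ 0.5, else 0
  ```

* and an experiment layer that runs the full protocols (training phase,
  pattern-prediction runs, synchronous/asynchronous spelling, big-set
  discrimination) end-to-end on synthetic data and writes result tables.

## Worked example

```r
library(cvep)

cfg <- experiment_config(
  model = "ridge", training_seconds = 60, snr_db = 0,
  sync = list(runs = 2L)
)
model <- run_training_phase(cfg, seed = 1)$model
tab <- run_synchronous_spelling(cfg, model, seed = 2)
tab
#>    run acc itr_bpm
#> 1    1   1     200
#> 2    2   1     200
#> 3 mean   1     200
```

Each row is one run over the 32-target matrix-keyboard layout in
lexicographic order (1 s trials + 0.5 s inter-trial). `acc` is the
fraction of correctly selected targets and `itr_bpm` the information
transfer rate at `N = 32`, `T = 1.5 s` — at perfect accuracy exactly
`60·log2(32)/1.5 = 200` bit/min, the ceiling of this layout (a ceiling
the decoder reaches here because 0 dB SNR is generous for 1 s trials).
The mean row is the arithmetic mean of the per-run metric values.

Per-bit decoding with the same model (the trailing sample-wise
prediction that does not fill a 10-sample block is dropped with a
warning):

```r
pat <- random_pattern(120, seed = 7)                      # a 2 s code
rec <- simulate_eeg(pat, noise = noise_model(snr_db = 0), seed = 8)
pred <- aggregate_bits(predict(model, extract_windows(rec)))
bit_accuracy(pred, pat)
#> [1] 0.95
itr(0.95, 2, 1/60)         # per-bit ITR, one 60 Hz frame per prediction
#> [1] 2568.971
```

A command-line front end is installed with the package
(`system.file("cli", "cvep", package = "cvep")`) with subcommands
`patterns`, `simulate`, `metrics` and `experiment`.

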