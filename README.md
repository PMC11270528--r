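# jressr — symmetry-aware super-resolution of 2D J-Res NMR spectra

`jressr` is for NMR metabolomics practitioners who acquire 2D J-resolved
(J-Res) ¹H spectra and want higher effective resolution without longer
acquisitions. It implements, end to end and in pure R:

* **simulation** of mixture J-Res spectra (linear combinations of
  parametric pure-compound signatures with truncated-normal
  concentrations) and their **degraded low-resolution counterparts**
  (Gaussian blur, kernel (5, 7), then ×2 areal down-sampling);
* a **×2 GAN super-resolution network** (residual CNN generator +
  patch discriminator, Adam, hand-written backprop on BLAS) whose loss
  stack adds a **symmetric loss** exploiting the mirror symmetry of J-Res
  spectra about J = 0:

  ```
  L_sym = 1 − (1/n) Σ_{i∈P} r(S_iu, S_il)
  ```

  with `r` the Pearson correlation of the log-transformed upper and
  (mirrored) lower halves of column *i*, summed over the `n` columns `P`
  containing nonzero pixels;
* **evaluation** by peak picking, 3-nearest-neighbour pair formation
  (30 px cutoff ≈ 0.031 ppm ≈ 18.6 Hz at 600 MHz), HR-anchored matching,
  and the **resolvability score**

  ```
  R = 1 − 2·h_v / (h_i + h_j)   ∈ [0, 1]
  ```

  (`h_i`, `h_j` the two peak heights, `h_v` the valley floor between
  them; 1 = fully resolved, 0 = merged), plus a **reliability analysis**
  matching LR/SR detections to higher-resolution ground-truth peaks
  within 2 px across detection thresholds.

Spectra live in a `jres_spectrum` container (float32 grid + explicit
Hz/ppm axes) with a native `.jres` file format; NMRPipe and Bruker
processed 2D data are read-only supported.

## Worked example

```r
library(jressr)

fx <- demo_fixture(seed = 1)          # 20 paired HR/LR spectra, 64 x 1024
st <- demo_train(fx, iterations = 200, seed = 1)   # ~1.5 min on one CPU

# held-out plasma-style mixtures
tds <- build_dataset(mixture_config(c(1, 3, 6, 9, 12, 15), 1,
                                    demo_grid(), seed = 101))
hr <- tds$spectra[[4]]
lr <- degrade(hr)
sr <- enhance(lr, st)                 # 32x512 -> 64x1024

pairs <- form_pairs(pick_peaks(hr, 0.01), k = 3, max_dist_px = 30)
rec   <- score_pairs(hr, lr, sr, pairs)
summarize_scores(rec)
```

On the full six-spectrum held-out set this prints:

```
<jres_eval_summary> 316 pairs (316 scored)
  SR >= LR: 91.5% | SR > LR: 83.9% | cor(HR, SR): 0.647
```

i.e. after a 200-iteration desk-scale training run, the median pair
resolvability rises from 0.939 (LR) to 1.0 (SR) and ~91% of peak pairs
are at least as well resolved in the super-resolved spectrum as in its
low-resolution input. (At this reduced grid the degradation is mild, so
the LR baseline is already high; the direction and coverage of the
improvement are the meaningful desk-scale observables.)

A thin CLI wraps the same functions
(`inst/exec/jressr demo --outdir out --seed 1`, plus `degrade`,
`enhance`, `evaluate`, `reliability` subcommands), and `run_pipeline()`
drives simulate → degrade → train → enhance → evaluate → reliability from
a single seeded config, writing a manifest with file checksums.

## Documentation

The methods vignette (`vignettes/jressr-methods.Rmd`) documents the
model, the loss stack and its numerical safeguards, the simulator's
assumptions (and what it deliberately does not model), every convention
the evaluation fixes, and known limitations.
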