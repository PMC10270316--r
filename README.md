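# willdecode

Decoding self-initiated ("willed") covert spatial attention from EEG
alpha oscillations.

## The scientific problem

When people choose **where and when** to attend — with no cue, prompt, or
external trigger — does the well-known posterior alpha-band (here 9–11 Hz)
lateralization of covert spatial attention still appear, and can the chosen
side be read out from the EEG on single trials? In the paradigm this package
models, observers view bilateral flickering dot patches (4 and 6 Hz),
spontaneously commit attention to one hemifield, monitor it for a target
event, and press a left/right button that simultaneously reports the
attended side and ends the trial. Trials are therefore self-paced (mean
latency ≈ 3.9 s with a broad right-skewed spread), and the attention onset
precedes the press by at least one ~1 s stimulus cycle.

The analysis chain is:

1. **Preprocessing** — re-reference to the averaged TP9/TP10 mastoid-adjacent
   sites, zero-phase band-pass 0.05–50 Hz, downsample to 250 samples/s,
   epoch without baseline subtraction (stimulus-locked −1000..4000 ms,
   response-locked −4000..1400 ms), then moving-window peak-to-peak artifact
   rejection (100 µV, 100 ms windows in 50 ms steps) and an eye-movement
   screen on FT9/FT10 (20 µV).
2. **Alpha power** — per trial and channel, a sliding Hann taper of three
   cycles per frequency extracts power at 9, 10, 11 Hz on a 20 ms grid; the
   three frequencies are averaged. The band avoids the 4/6 Hz flicker and
   its first harmonics.
3. **Decoding** — per timepoint, attend-left vs attend-right classification
   with a threefold cross-validated linear SVM: trial counts equalized by
   random subsampling, trials averaged into one exemplar per class per fold,
   10 re-randomized iterations. Channel sets: the 19 parieto-occipital
   electrodes, a 19-electrode central/frontocentral control set (mu-rhythm
   confound), or all 62 non-reference electrodes (for covariance-corrected
   weight maps).
4. **Inference** — per-timepoint one-sample t of subject accuracies against
   chance (0.5), contiguous supra-threshold clusters summed into cluster
   masses, and a Monte-Carlo null built by re-decoding with i.i.d. random
   labels; the max-mass distribution controls the family-wise error at the
   cluster level. Posterior alpha asymmetry (Welch t), a surface-Laplacian
   current source density, and IRASA fractal/oscillatory separation support
   the attentional interpretation.

Because the original recordings are not public, the package includes a
first-class **synthetic session generator** with known ground truth:
lateralized occipital alpha, a side-invariant central mu rhythm, 4/6 Hz
flicker components, 1/f background, and blink artifacts, written out as
EDF + TSV sidecars. Every downstream stage is validated against that truth.

## A worked example

```r
library(willdecode)

run <- run_pipeline(pipeline_config(master_seed = 5))
run
#> <wd_run> 4 subjects, locks: response, channel sets: posterior_19
#>   response.posterior_19: 8 cluster(s), 1 significant

tidy(run$clusters$response.posterior_19)
#> # A tibble: 8 × 5     (abridged; the significant cluster:)
#>   cluster_id start_ms end_ms    mass       p
#>        <int>    <dbl>  <dbl>   <dbl>   <dbl>
#> 6          6    -1400    -40 1187.   0.00498
```

The significant cluster spans roughly the last 1.4 s before the button
press: decoding of the chosen side rises above chance once covert attention
is deployed, and the cluster p-value (floored at `1/(1+n_permutations)`)
says no random-label pipeline produced a comparable cluster mass. The
latency histogram, alpha-difference topographies, decoding curves with SE
ribbons and cluster shading come from `render_report(run, "figures")` or
the `autoplot()` methods; `tidy()`/`glance()` turn every result into a
tibble.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/willdecode.R run --seed 5 --out out/
Rscript inst/cli/willdecode.R report --run out/ --out figures/
```

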