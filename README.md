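# tremorindex

Wavelet-based tremor quantification from wrist-worn accelerometry in
free-living conditions.

People with Parkinson's disease experience rest and action tremor that
fluctuates over hours and medication cycles, while clinical scales sample it
once, coarsely. `tremorindex` turns multi-day recordings from a wrist-worn
three-axis accelerometer (Empatica-E4-style CSV, 32 Hz, counts of 1/64 g)
into a per-frequency **Tremor Index (TI)** — the energy of a wavelet detail
band of the wrist elevation angle per sampling-time window — and implements
the inter-hand separation analysis that validates the index when one hand is
more affected than the other. It is aimed at researchers working on digital
mobility biomarkers who need a context-independent tremor measure that does
not rely on activity labelling.

## Method in brief

From the dorsal (Oz) acceleration the elevation angle
`θ = arctan(a_z / 1)` is formed. For each frequency
`f ∈ {3, …, 12}` Hz the signal is resampled to `f_s,f = 8f/3` Hz, so that
`f` is the centre of the first dyadic detail band `(2f/3, 4f/3]` of a
shift-invariant Daubechies (db4) multi-resolution analysis. The index per
window is

    TI_f = β · Σ_{i=1}^{q} θ_f(i)² ,   q = ST · f_s,f ,   β = 10⁴

reported in tiu (1 tiu = 100 mrad²/window) over wall-clock-aligned ST = 15 min
windows. Recordings are segmented into calendar days; a day is dropped when
≥ 50% of the expected samples in the standardized daytime window
(07:01–23:59) are missing. For validation, valid TI values of the most (T)
and least (nT) tremor-affected hand are pooled per frequency, binned into
λ = 20 shared bins, and compared through log-log PDF fits, kurtosis/skewness,
and the distance between the hands' second-highest histogram bins; the count
`C` of separated frequencies is correlated with the clinical tremor symptom
load `L = (Σ types present)·(Σ item intensities)`.

A seedable synthetic-data module generates two-hand, multi-day recordings
with known ground truth (activity bouts, broadband movement noise,
episode-gated tremor bursts, sensor noise, quantization, gaps), so the whole
pipeline is testable without device data. See the methods vignette
(`vignettes/tremor-index-methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

Simulate one participant with persistent 5–6 Hz tremor in one hand, then run
the Mode I frequency-mapping analysis:

```r
library(tremorindex)
m <- as.numeric(as.POSIXct("2024-03-04 09:00:00", tz = "UTC"))
set.seed(42)
prof_T <- sim_profile(tremor = sim_components(c(5, 6), c(0.45, 0.4), duty = 0.75),
                      amp_sd = 0.05, episode_duty = 0.45, episode_s = 900)
sim_T  <- simulate_hand(prof_T, m, 4 * 3600, hand = "T")
sim_nT <- simulate_hand(sim_profile(), m + 86400, 4 * 3600, hand = "nT")

cfg <- ti_run_config(frequencies = c(4, 5, 6, 9), st_minutes = 2,
                     missing_threshold = 1)
res <- run_mode1(sim_T$recording, sim_nT$recording, cfg)
res$separation
#> <separation_result> C = 3 separated frequencies (rule: linear)
#>  f  bin_T bin_nT    D_f ti_max c_f
#>  4 301501  31190 0.9853 415864   1
#>  5 693328  63030 1.0414 840397   1
#>  6 703468  72773 0.9853 970300   1
#>  9 208180  69393 0.4771 925246   0
```

The tremor hand's secondary TI mode sits roughly an order of magnitude above
the other hand's (`D_f ≈ 1` in log10) at the injected frequencies 5 and 6 Hz
— and at 4 Hz, their dyadic-band neighbour — but not at 9 Hz, so `C = 3`. The
corresponding clinical anchor for this phenotype would be, e.g.,
`symptom_load(postural = 1, kinetic = 0, rest = 3)`, giving `L = 8`.

For longitudinal tracking of a single hand use `run_mode2()`, which returns
the long TI table (96 windows per day per frequency at the defaults) and
per-day summaries. `simulate_cohort()` + `cohort_separation()` run the whole
seven-participant study design end to end.

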